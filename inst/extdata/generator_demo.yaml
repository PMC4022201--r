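# Demo generator configuration: seven layers of twenty entities wired with
# the canonical herb-to-gene backbone properties plus 20% distractor triples.
layer_sizes: [20, 20, 20, 20, 20, 20, 20]
classes: [Herb, Disease, Drug, Target, Protein, EntrezID, Gene]
properties: [treatment, possibleDrug, hasTarget, hasAccession, classifiedWith, symbol]
out_degree: 2
distractor_fraction: 0.2
injective: false
seed: 42
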