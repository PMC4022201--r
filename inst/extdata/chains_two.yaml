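# Two overlapping chains sharing the "treatment" edge: herb -> gene through
# the six-property backbone, and herb -> drug ingredient through possibleDrug
# and hasIngredient.
chains:
- id: herb_gene
  source_class: Herb
  sink_class: Gene
  properties: [treatment, possibleDrug, hasTarget, hasAccession, classifiedWith, symbol]
- id: herb_ingredient
  source_class: Herb
  sink_class: Ingredient
  properties: [treatment, possibleDrug, hasIngredient]
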