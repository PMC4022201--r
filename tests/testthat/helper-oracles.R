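# Shared helpers: independent boolean matrix-chain reachability oracle,
# small random graph builders, and set comparison of association pairs.

# Endpoint pairs via boolean adjacency-matrix products, independent of the
# package's join-based oracle and reasoners.
matrix_reach_pairs <- function(graph, chain) {
  props <- unlist(opc_components(rrc_to_pcs(chain)), use.names = FALSE)
  nodes <- sort(unique(c(graph$subject, graph$object)))
  n <- length(nodes)
  adj <- function(p) {
    m <- matrix(0, n, n, dimnames = list(nodes, nodes))
    e <- graph[graph$predicate == p, , drop = FALSE]
    if (nrow(e)) m[cbind(e$subject, e$object)] <- 1
    m
  }
  M <- adj(props[[1]])
  for (p in props[-1]) M <- (M %*% adj(p)) > 0
  hits <- which(M > 0, arr.ind = TRUE)
  pairs <- tibble::tibble(source = nodes[hits[, 1]], sink = nodes[hits[, 2]])
  dplyr::arrange(pairs, source, sink)
}

pairs_of <- function(res) {
  if (inherits(res, "chain_reasoning")) res <- res$associations
  dplyr::arrange(tibble::as_tibble(res)[c("source", "sink")], source, sink)
}

# Unstructured random graph: entities e0..e<k>, predicates drawn from a pool,
# good for stressing cycles, convergence and repeated-property chains.
random_messy_graph <- function(seed, n_triples = 40, n_entities = 10,
                               predicates = c("p", "q", "r", "noise")) {
  withr::with_seed(seed, {
    ents <- paste0("e", seq_len(n_entities) - 1)
    triple_graph(subject = sample(ents, n_triples, replace = TRUE),
                 predicate = sample(predicates, n_triples, replace = TRUE),
                 object = sample(ents, n_triples, replace = TRUE))
  })
}
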