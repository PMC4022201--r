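# Multichain variant: several property chains run through the same iterated
# jobs. Keys carry the chain id, so reducers of different chains never mix;
# a triple whose predicate sits on a chain intersection fans out to one
# keyed record per matching chain.

#' Map step of the multichain algorithm
#'
#' Applies the parity-rule map of every active chain (PCS length >= 2) to
#' the chain's working graph, prefixing keys with the chain id. A predicate
#' present in `m` chains produces `m` keyed emissions; a predicate in no
#' chain is dropped.
#'
#' @param graph A triple graph (used for every chain without a specific
#'   working graph).
#' @param chains A chain set from [read_chain_config()] or [chain_set()].
#' @param pcs_list Optional named list of current per-chain PCSs (defaults to
#'   each chain's initial properties).
#' @param graphs Optional named list of per-chain working graphs.
#' @return A keyed tibble as in [efficient_map()], with `chain_id` filled in.
#' @export
multichain_map <- function(graph, chains, pcs_list = NULL, graphs = NULL) {
  chains <- as_chain_set(chains)
  if (is.null(pcs_list)) {
    pcs_list <- stats::setNames(lapply(chains$properties, as_pcs),
                                chains$chain_id)
  }
  active <- names(pcs_list)[lengths(pcs_list) > 1L]
  mapped <- purrr::map(active, function(id) {
    g <- if (!is.null(graphs)) graphs[[id]] else graph
    efficient_map(g, pcs_list[[id]], chain_id = id)
  })
  out <- dplyr::bind_rows(mapped)
  if (!nrow(out)) {
    out <- tibble::tibble(key = character(), subject = character(),
                          predicate = character(), object = character(),
                          pid = integer(), chain_id = character())
  }
  out
}

#' Run several chains through shared reasoning jobs
#'
#' All chains advance together: each shared pass runs one map/shuffle/reduce
#' job whose keys are chain-labelled, then halves every active chain's PCS.
#' A chain that completes early parks its result triples and contributes
#' nothing to later passes, so chains never interfere: every chain's
#' association set equals its standalone [efficient_reason()] run. The number
#' of shared passes is `ceiling(log2(max chain length))`.
#'
#' @param graph A triple graph.
#' @param chains A chain set from [read_chain_config()] or [chain_set()].
#' @return A `multichain_reasoning` object holding one `chain_reasoning` per
#'   chain; see [tidy.multichain_reasoning()].
#' @examples
#' multichain_reason(fixture_g0(), chain_set(herb_gene = herb_gene_chain()))
#' @export
multichain_reason <- function(graph, chains) {
  chains <- as_chain_set(chains)
  g0 <- as_triple_graph(graph)
  ids <- chains$chain_id
  pcs_list <- stats::setNames(lapply(chains$properties, as_pcs), ids)
  working <- stats::setNames(rep(list(g0), length(ids)), ids)
  iterations <- 0L
  trace <- list()
  while (any(lengths(pcs_list) > 1L)) {
    active <- ids[lengths(pcs_list)[ids] > 1L]
    res <- run_job(
      NULL,
      map_fn = function(...) multichain_map(g0, chains, pcs_list = pcs_list,
                                            graphs = working),
      reduce_fn = function(k, grp) {
        cid <- parse_join_key(k)$chain_id
        efficient_reduce(k, grp, pcs_list[[cid]])
      })
    iterations <- iterations + 1L
    for (id in active) {
      derived <- res$reduced[res$reduced$chain_id == id,
                             c("subject", "predicate", "object"),
                             drop = FALSE]
      pass <- if (nrow(res$passthrough)) {
        res$passthrough[res$passthrough$chain_id == id,
                        c("subject", "predicate", "object"), drop = FALSE]
      } else {
        empty_derived()
      }
      working[[id]] <- as_triple_graph(dplyr::bind_rows(derived, pass))
      pcs_list[[id]] <- halve_pcs(pcs_list[[id]])
    }
    trace[[iterations]] <- tibble::tibble(
      iteration = iterations,
      derived = nrow(res$reduced),
      passthrough = nrow(res$passthrough))
  }
  results <- stats::setNames(purrr::map(ids, function(id) {
    final <- pcs_list[[id]][[1L]]
    hits <- working[[id]][working[[id]]$predicate == final, , drop = FALSE]
    n <- length(opc_components(final)[[1L]])
    new_chain_reasoning(
      associations = tibble::tibble(source = hits$subject,
                                    sink = hits$object),
      iterations = if (n > 1L) iterations else max(0L, ceiling(log2(max(n, 1L)))),
      algorithm = "multichain", opc = final,
      trace = if (length(trace)) dplyr::bind_rows(trace) else empty_trace(),
      chain_id = id)
  }), ids)
  new_multichain_reasoning(results, iterations,
                           if (length(trace)) dplyr::bind_rows(trace)
                           else empty_trace())
}
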