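# Naive iterative algorithm: each pass joins only the PID-0 and PID-1
# triples, merges the first two OPCs, and repeats. A length-N chain takes
# exactly N - 1 passes regardless of graph contents.

empty_derived <- function() {
  tibble::tibble(subject = character(), predicate = character(),
                 object = character())
}

#' Map step of the naive algorithm
#'
#' Separates input triples into three groups by PID: PID -1 triples are
#' dropped, PID 0 triples are keyed on their object (tagged `left`), PID 1
#' triples are keyed on their subject (tagged `right`), and PID >= 2 triples
#' are emitted to the passthrough channel to be processed in a later pass.
#'
#' @param graph A triple graph.
#' @param pcs The current property chain set (length >= 2).
#' @return A keyed tibble with columns `key`, `role`, `subject`, `predicate`,
#'   `object`, `pid`; `key` is `NA` for passthrough rows.
#' @export
naive_map <- function(graph, pcs) {
  pcs <- as_pcs(pcs)
  if (length(pcs) < 2L) stop("naive map needs a PCS of length >= 2",
                             call. = FALSE)
  f <- pid_fan_out(as_triple_graph(graph), pcs)
  key <- rep(NA_character_, nrow(f))
  role <- rep(NA_character_, nrow(f))
  i0 <- f$pid == 0L
  i1 <- f$pid == 1L
  key[i0] <- join_key(0L, f$object[i0])
  key[i1] <- join_key(0L, f$subject[i1])
  role[i0] <- "left"
  role[i1] <- "right"
  tibble::tibble(key = key, role = role, subject = f$subject,
                 predicate = f$predicate, object = f$object, pid = f$pid)
}

#' Reduce step of the naive algorithm
#'
#' Materializes the join candidate set of one key: the cross product of the
#' subjects of left-tagged (PID 0) members with the objects of right-tagged
#' (PID 1) members, each derived triple carrying the merged OPC. Unmatched
#' one-sided groups yield nothing, pruning dead-end paths.
#'
#' @param key The group key (unused beyond diagnostics).
#' @param group Payload rows sharing the key.
#' @param opc_name Canonical name of the merged first-two OPC.
#' @return A tibble of derived triples.
#' @export
naive_reduce <- function(key, group, opc_name) {
  lefts <- unique(group$subject[!is.na(group$role) & group$role == "left"])
  rights <- unique(group$object[!is.na(group$role) & group$role == "right"])
  if (!length(lefts) || !length(rights)) return(empty_derived())
  out <- tidyr::expand_grid(subject = lefts, object = rights)
  tibble::tibble(subject = out$subject, predicate = opc_name,
                 object = out$object)
}

#' Run the naive chain reasoner
#'
#' Repeats map/shuffle/reduce passes, after each pass replacing the working
#' graph by the derived triples plus the passthrough channel and merging the
#' first two OPCs of the PCS, until the PCS has length 1. The associations
#' are the triples whose predicate equals the fully composed chain.
#'
#' @param graph A triple graph.
#' @param chain A rule chain tibble or property-name vector.
#' @return A `chain_reasoning` object; see [tidy.chain_reasoning()].
#' @examples
#' naive_reason(fixture_g0(), herb_gene_chain())
#' @export
naive_reason <- function(graph, chain) {
  pcs <- as_pcs(chain)
  g <- as_triple_graph(graph)
  iterations <- 0L
  trace <- list()
  while (length(pcs) > 1L) {
    opc_name <- opc_compose(pcs[[1L]], pcs[[2L]])
    res <- run_job(g,
                   map_fn = function(df) naive_map(df, pcs),
                   reduce_fn = function(k, grp) naive_reduce(k, grp, opc_name))
    derived <- if (nrow(res$reduced)) {
      res$reduced[c("subject", "predicate", "object")]
    } else {
      empty_derived()
    }
    pass <- if (nrow(res$passthrough)) {
      res$passthrough[c("subject", "predicate", "object")]
    } else {
      empty_derived()
    }
    g <- as_triple_graph(dplyr::bind_rows(derived, pass))
    iterations <- iterations + 1L
    trace[[iterations]] <- tibble::tibble(
      iteration = iterations,
      derived = nrow(dplyr::distinct(derived)),
      passthrough = nrow(dplyr::distinct(pass)))
    pcs <- merge_first_two(pcs)
  }
  final <- pcs[[1L]]
  hits <- g[g$predicate == final, , drop = FALSE]
  new_chain_reasoning(
    associations = tibble::tibble(source = hits$subject, sink = hits$object),
    iterations = iterations, algorithm = "naive", opc = final,
    trace = if (length(trace)) dplyr::bind_rows(trace) else empty_trace())
}
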