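# Parity-rule algorithm: the join key of a PID-k triple is (k - 1, subject)
# when k is odd and (k, object) when k is even, so every adjacent position
# pair joins in the same pass and the PCS halves each iteration; a length-N
# chain finishes in ceiling(log2 N) passes.

#' Parity-rule join key of a triple
#'
#' Odd PID `k` keys on `(k - 1, subject)`; even PID `k` keys on
#' `(k, object)`, except the unpaired last OPC of an odd-length PCS, which
#' has no partner and returns `NA` (the triple is passed through unchanged).
#'
#' @param pid Integer PID vector (all non-negative).
#' @param subject,object Triple components, same length as `pid`.
#' @param n Length of the current PCS.
#' @param chain_id Chain identifier prefix for multichain runs.
#' @return Character keys, `NA` for unpaired triples.
#' @export
parity_join_key <- function(pid, subject, object, n, chain_id = "") {
  pid <- as.integer(pid)
  if (any(pid < 0L)) {
    stop("negative PIDs must be dropped before key assignment", call. = FALSE)
  }
  key <- rep(NA_character_, length(pid))
  odd <- pid %% 2L == 1L
  key[odd] <- join_key(pid[odd] - 1L, subject[odd], chain_id)
  even <- !odd & pid < n - 1L
  key[even] <- join_key(pid[even], object[even], chain_id)
  key
}

#' Map step of the parity-rule algorithm
#'
#' PID -1 triples are dropped; the unpaired last OPC of an odd-length PCS is
#' emitted to the passthrough channel; every other triple becomes a keyed
#' record under its parity-rule key, carrying its PID.
#'
#' @param graph A triple graph.
#' @param pcs The current property chain set (length >= 2).
#' @param chain_id Chain identifier prefix for multichain runs.
#' @return A keyed tibble with columns `key`, `subject`, `predicate`,
#'   `object`, `pid`, `chain_id`.
#' @export
efficient_map <- function(graph, pcs, chain_id = "") {
  pcs <- as_pcs(pcs)
  if (length(pcs) < 2L) stop("parity map needs a PCS of length >= 2",
                             call. = FALSE)
  f <- pid_fan_out(as_triple_graph(graph), pcs)
  tibble::tibble(
    key = parity_join_key(f$pid, f$subject, f$object, length(pcs), chain_id),
    subject = f$subject, predicate = f$predicate, object = f$object,
    pid = f$pid, chain_id = rep(chain_id, nrow(f)))
}

#' Reduce step of the parity-rule algorithm
#'
#' A group holds triples of one even PID `k` (contributing subjects) and of
#' PID `k + 1` (contributing objects); the output is their cross product
#' under the merged OPC of positions `k` and `k + 1`.
#'
#' @param key The group key; its PID component identifies `k`.
#' @param group Payload rows sharing the key.
#' @param pcs The PCS the key positions refer to.
#' @return A tibble of derived triples (with `chain_id` carried through).
#' @export
efficient_reduce <- function(key, group, pcs) {
  pcs <- as_pcs(pcs)
  k <- parse_join_key(key)$pid
  if (!all(group$pid %in% c(k, k + 1L))) {
    stop(sprintf("group for position %d contains PIDs outside {%d, %d}",
                 k, k, k + 1L), call. = FALSE)
  }
  subs <- unique(group$subject[group$pid == k])
  objs <- unique(group$object[group$pid == k + 1L])
  cid <- if ("chain_id" %in% names(group) && nrow(group)) {
    group$chain_id[[1L]]
  } else {
    ""
  }
  if (!length(subs) || !length(objs)) {
    out <- empty_derived()
    out$chain_id <- character()
    return(out)
  }
  grid <- tidyr::expand_grid(subject = subs, object = objs)
  tibble::tibble(subject = grid$subject,
                 predicate = opc_compose(pcs[[k + 1L]], pcs[[k + 2L]]),
                 object = grid$object,
                 chain_id = cid)
}

#' Run the parity-rule chain reasoner
#'
#' Each pass maps every relevant triple to its parity-rule key, joins all
#' adjacent position pairs at once, then halves the PCS; a length-N chain
#' completes in `ceiling(log2(N))` passes independent of graph size.
#'
#' @param graph A triple graph.
#' @param chain A rule chain tibble or property-name vector.
#' @return A `chain_reasoning` object; see [tidy.chain_reasoning()].
#' @examples
#' efficient_reason(fixture_g0(), herb_gene_chain())
#' @export
efficient_reason <- function(graph, chain) {
  pcs <- as_pcs(chain)
  g <- as_triple_graph(graph)
  iterations <- 0L
  trace <- list()
  while (length(pcs) > 1L) {
    res <- run_job(g,
                   map_fn = function(df) efficient_map(df, pcs),
                   reduce_fn = function(k, grp) efficient_reduce(k, grp, pcs))
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
    pcs <- halve_pcs(pcs)
  }
  final <- pcs[[1L]]
  hits <- g[g$predicate == final, , drop = FALSE]
  new_chain_reasoning(
    associations = tibble::tibble(source = hits$subject, sink = hits$object),
    iterations = iterations, algorithm = "efficient", opc = final,
    trace = if (length(trace)) dplyr::bind_rows(trace) else empty_trace())
}
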