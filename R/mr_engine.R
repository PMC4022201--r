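# Deterministic local emulation of the map -> shuffle/group -> reduce
# contract, plus a passthrough channel for payloads that bypass reduction
# (the "write directly to the output" shortcut of the distributed original).

key_sep <- "\u0001"

#' Encode a join key
#'
#' Keys are `<chain_id> SOH <pid> SOH <resource>` with a control-character
#' separator, so resource labels containing underscores can never collide
#' with the positional part of the key.
#'
#' @param pid Integer position component of the key.
#' @param resource The joining resource (a subject or object label).
#' @param chain_id Chain identifier prefix; empty for single-chain runs.
#' @return A character vector of keys.
#' @export
join_key <- function(pid, resource, chain_id = "") {
  paste(chain_id, as.integer(pid), resource, sep = key_sep)
}

#' Decode a join key
#'
#' @param key A single key produced by [join_key()].
#' @return A list with elements `chain_id`, `pid` (integer) and `resource`.
#' @export
parse_join_key <- function(key) {
  parts <- strsplit(key, key_sep, fixed = TRUE)[[1L]]
  list(chain_id = parts[[1L]], pid = as.integer(parts[[2L]]),
       resource = paste(parts[-(1:2)], collapse = key_sep))
}

sort_rows <- function(df) {
  df <- tibble::as_tibble(df)
  if (nrow(df) > 1L) df <- df[do.call(order, unname(as.list(df))), , drop = FALSE]
  df
}

#' Run one deterministic map/shuffle/reduce job
#'
#' `map_fn` receives the full input table and returns a table with a `key`
#' column plus arbitrary payload columns; rows with `NA` key are emitted
#' directly to the passthrough channel, untouched. Keyed rows are grouped by
#' exact key equality, keys are visited in sorted order, and `reduce_fn` is
#' invoked exactly once per key with the key and its group (payload columns
#' only). Both output channels are sorted by all columns, so the result is
#' invariant under any permutation of the input rows.
#'
#' @param inputs Input payload table handed to `map_fn`.
#' @param map_fn Function `inputs -> tibble` with a `key` column.
#' @param reduce_fn Function `(key, group_tibble) -> tibble` of outputs.
#' @return A list with `reduced` (bound reduce outputs), `passthrough`
#'   (direct emits) and `n_groups` (number of distinct keys).
#' @export
run_job <- function(inputs, map_fn, reduce_fn) {
  mapped <- map_fn(inputs)
  if (!is.data.frame(mapped) || !"key" %in% names(mapped)) {
    stop("map_fn must return a data frame with a `key` column", call. = FALSE)
  }
  mapped <- tibble::as_tibble(mapped)
  payload_cols <- setdiff(names(mapped), "key")
  passthrough <- mapped[is.na(mapped$key), payload_cols, drop = FALSE]
  keyed <- mapped[!is.na(mapped$key), , drop = FALSE]
  reduced <- list()
  n_groups <- 0L
  if (nrow(keyed)) {
    keyed <- sort_rows(keyed)
    groups <- split(keyed[payload_cols], keyed$key)
    n_groups <- length(groups)
    reduced <- purrr::imap(groups, function(grp, k) {
      tryCatch(reduce_fn(k, grp), error = function(e) {
        stop(sprintf("reduce failed for key %s: %s",
                     gsub(key_sep, "_", k, fixed = TRUE),
                     conditionMessage(e)), call. = FALSE)
      })
    })
  }
  list(reduced = sort_rows(dplyr::bind_rows(reduced)),
       passthrough = sort_rows(passthrough),
       n_groups = n_groups)
}
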