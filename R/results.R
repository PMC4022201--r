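# Result containers for reasoning runs, with broom-style methods.

new_chain_reasoning <- function(associations, iterations, algorithm, opc,
                                trace, chain_id = NA_character_) {
  associations <- dplyr::arrange(tibble::as_tibble(associations),
                                 .data$source, .data$sink)
  structure(list(associations = associations,
                 iterations = as.integer(iterations),
                 algorithm = algorithm,
                 opc = opc,
                 trace = tibble::as_tibble(trace),
                 chain_id = chain_id),
            class = "chain_reasoning")
}

empty_trace <- function() {
  tibble::tibble(iteration = integer(), derived = integer(),
                 passthrough = integer())
}

#' @export
print.chain_reasoning <- function(x, ...) {
  cat(sprintf("<chain_reasoning: %s>\n", x$algorithm))
  if (!is.na(x$chain_id)) cat(sprintf("  chain:        %s\n", x$chain_id))
  cat(sprintf("  property chain: %s\n",
              paste(opc_components(x$opc)[[1L]], collapse = " (x) ")))
  cat(sprintf("  iterations:   %d\n", x$iterations))
  cat(sprintf("  associations: %d\n", nrow(x$associations)))
  if (nrow(x$associations)) {
    print(utils::head(x$associations, 10L))
    if (nrow(x$associations) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' Tidy a reasoning result into its association table
#'
#' @param x A `chain_reasoning` object.
#' @param ... Unused.
#' @return A tibble with columns `source`, `sink`, `opc` and `chain_id`.
#' @export
tidy.chain_reasoning <- function(x, ...) {
  dplyr::mutate(x$associations, opc = x$opc, chain_id = x$chain_id)
}

#' One-row summary of a reasoning run
#'
#' @param x A `chain_reasoning` object.
#' @param ... Unused.
#' @return A one-row tibble: algorithm, chain length, iterations run, number
#'   of distinct associations.
#' @export
glance.chain_reasoning <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm,
                 chain_id = x$chain_id,
                 chain_length = length(opc_components(x$opc)[[1L]]),
                 iterations = x$iterations,
                 n_associations = nrow(x$associations))
}

#' Plot per-iteration derived and carried-over triple counts
#'
#' @param object A `chain_reasoning` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chain_reasoning <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("derived", "passthrough"),
                            names_to = "channel", values_to = "triples")
  ggplot2::ggplot(tr, ggplot2::aes(x = factor(.data$iteration),
                                   y = .data$triples,
                                   fill = .data$channel)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "iteration", y = "triples",
                  title = sprintf("%s reasoning (%d iterations)",
                                  object$algorithm, object$iterations)) +
    ggplot2::theme_minimal()
}

new_multichain_reasoning <- function(results, iterations, trace) {
  structure(list(results = results, iterations = as.integer(iterations),
                 trace = tibble::as_tibble(trace)),
            class = "multichain_reasoning")
}

#' @export
print.multichain_reasoning <- function(x, ...) {
  cat(sprintf("<multichain_reasoning: %d chain(s), %d shared iteration(s)>\n",
              length(x$results), x$iterations))
  for (res in x$results) {
    cat(sprintf("  %s: %d associations\n", res$chain_id,
                nrow(res$associations)))
  }
  invisible(x)
}

#' Tidy a multichain result into one association table
#'
#' @param x A `multichain_reasoning` object.
#' @param ... Unused.
#' @return Row-bound [tidy.chain_reasoning()] tables of every chain.
#' @export
tidy.multichain_reasoning <- function(x, ...) {
  purrr::map_dfr(x$results, tidy)
}

#' One-row-per-chain summary of a multichain run
#'
#' @param x A `multichain_reasoning` object.
#' @param ... Unused.
#' @return A tibble with one row per chain.
#' @export
glance.multichain_reasoning <- function(x, ...) {
  purrr::map_dfr(x$results, glance)
}

#' Plot association counts per chain
#'
#' @param object A `multichain_reasoning` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.multichain_reasoning <- function(object, ...) {
  ggplot2::ggplot(glance(object),
                  ggplot2::aes(x = .data$chain_id, y = .data$n_associations)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "chain", y = "associations",
                  title = sprintf("multichain reasoning (%d shared iterations)",
                                  object$iterations)) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
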