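# Evaluation formulas for the validation report: precision from curated
# true/false positive counts, and speedup/sizeup ratios for scalability
# summaries of timed runs.

#' Precision from true and false positive counts
#'
#' `TP / (TP + FP)`: the fraction of reported associations confirmed as
#' correct by independent curation.
#'
#' @param tp,fp Non-negative counts (vectorized); `tp + fp` must be >= 1.
#' @return Precision values in `[0, 1]`.
#' @examples
#' precision(126, 24) # 0.84
#' @export
precision <- function(tp, fp) {
  if (any(tp < 0) || any(fp < 0)) {
    stop("`tp` and `fp` must be non-negative", call. = FALSE)
  }
  if (any(tp + fp < 1)) {
    stop("precision is undefined when tp + fp == 0", call. = FALSE)
  }
  tp / (tp + fp)
}

#' Speedup of a measured run over a baseline
#'
#' Baseline time divided by measured time: how many times faster the
#' measured configuration is than the designated baseline configuration.
#'
#' @param baseline,measured Strictly positive times in the same unit.
#' @return `baseline / measured`.
#' @examples
#' speedup(8.45, 4.96)
#' @export
speedup <- function(baseline, measured) {
  if (any(baseline <= 0) || any(measured <= 0)) {
    stop("times must be strictly positive", call. = FALSE)
  }
  baseline / measured
}

#' Sizeup of a run on enlarged input
#'
#' Measured time divided by baseline time: how much longer processing the
#' enlarged input takes than processing the base input.
#'
#' @param baseline,measured Strictly positive times in the same unit.
#' @return `measured / baseline`.
#' @examples
#' sizeup(3.07, 5.75)
#' @export
sizeup <- function(baseline, measured) {
  if (any(baseline <= 0) || any(measured <= 0)) {
    stop("times must be strictly positive", call. = FALSE)
  }
  measured / baseline
}
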