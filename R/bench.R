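## Weighted-average summaries for chunk-level timing reports: each input's
## speed-up is weighted by its sequence count (extraction step) or by its
## 16S fragment count (mapping step), so large inputs dominate.

#' Weighted average
#'
#' \deqn{\bar S = \sum_i w_i S_i / \sum_i w_i}
#' with nonnegative weights of positive sum. Used to summarize per-input
#' speed-ups weighted by sequence or fragment counts.
#'
#' @param weights nonnegative numeric vector with positive sum.
#' @param values numeric vector of the same length.
#' @return the weighted mean.
#' @examples
#' weightedAverage(c(2, 1), c(10, 4))  # 8
#' @export
weightedAverage <- function(weights, values) {
  if (length(weights) != length(values))
    stop("weights and values must have equal length", call. = FALSE)
  if (length(weights) < 1L)
    stop("need at least one (weight, value) pair", call. = FALSE)
  if (any(weights < 0))
    stop("weights must be nonnegative", call. = FALSE)
  if (sum(weights) <= 0)
    stop("weights must not all be zero", call. = FALSE)
  sum(weights * values) / sum(weights)
}

#' Summarize per-input speed-ups
#'
#' @param weights sequence (or fragment) counts per input.
#' @param values speed-up ratios per input.
#' @return a [SpeedupSummary-class] holding the pairs and their weighted
#'   average.
#' @export
speedupSummary <- function(weights, values) {
  new("SpeedupSummary", weights = as.numeric(weights),
      values = as.numeric(values),
      weightedAverage = weightedAverage(weights, values))
}

setMethod("show", "SpeedupSummary", function(object) {
  cat(sprintf("SpeedupSummary: %d input(s), weighted average %.2f\n",
              length(object@values), object@weightedAverage))
})
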