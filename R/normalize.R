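#' Optional input plumbing: log2 transform and quantile normalisation
#'
#' The analysis assumes normalised log2-scale input; this helper covers
#' the common case of raw linear intensities. `log2 = TRUE` applies
#' `log2(x + offset)`; `quantile = TRUE` then forces every sample to the
#' same empirical distribution (each column's sorted values are replaced
#' by the row-wise mean of all columns' sorted values, ties receiving the
#' mean of their positions). No background correction, loess or
#' variance-stabilising transformation is attempted.
#'
#' @param x An [expression_set()].
#' @param log2 Apply the log2 transform.
#' @param offset Pseudo-count added before the log (default 1).
#' @param quantile Apply quantile normalisation across samples.
#' @return An `expr_set` with transformed values.
#' @export
normalize_expression <- function(x, log2 = TRUE, offset = 1,
                                 quantile = TRUE) {
  if (!inherits(x, "expr_set")) stopf("'x' must be an expr_set")
  v <- x$values
  if (log2) {
    if (any(v + offset <= 0))
      stopf("log2 transform undefined: values + offset must be positive")
    v <- base::log2(v + offset)
  }
  if (quantile) {
    ranks <- apply(v, 2L, rank, ties.method = "average")
    target <- rowMeans(apply(v, 2L, sort))
    v <- apply(ranks, 2L, function(r) {
      lo <- target[floor(r)]
      hi <- target[ceiling(r)]
      (lo + hi) / 2  # midpoint for half-integer tie ranks
    })
    dimnames(v) <- dimnames(x$values)
  }
  expression_set(v, x$samples)
}
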