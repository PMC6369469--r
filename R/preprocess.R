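#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to share one empirical distribution: each
#' value is replaced by the mean, across samples, of the values holding
#' its rank, so after normalization all columns carry the identical
#' multiset (the per-rank across-sample means of the input) while the
#' within-column rank order is preserved. Ties within a column receive
#' the mean of the rank-means they span, which keeps the procedure
#' deterministic and independent of input row order.
#'
#' The transform is idempotent and conserves the grand mean of the
#' matrix (per-rank means redistribute values but conserve the total).
#'
#' @param m A linear-scale [expression_matrix()] with at least 2 samples.
#' @return A normalized `ExpressionMatrix`, linear scale.
#' @examples
#' v <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' rownames(v) <- paste0("p", 1:3)
#' m <- expression_matrix(v, c(s1 = "case", s2 = "control"))
#' quantile_normalize(m)$values  # both columns become 2.5, 3.5, 4.5
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale_tag != "linear")
    stop("quantile normalization expects linear-scale intensities")
  if (ncol(m$values) < 2L)
    stop("at least 2 samples are required")
  if (any(m$values <= 0))
    stop("non-positive intensities")
  q <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(q) <- dimnames(m$values)
  expression_matrix(q, m$groups, "linear")
}

#' Log2-transform an expression matrix
#'
#' Testing and clustering run on the log2 scale; fold changes are
#' computed on linear-scale normalized values. A matrix already tagged
#' log2 is rejected to guard against double transformation.
#'
#' @param m A linear-scale [expression_matrix()].
#' @return An `ExpressionMatrix` with log2 values and `scale_tag "log2"`.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale_tag == "log2")
    stop("matrix is already log2-transformed")
  expression_matrix(log2(m$values), m$groups, "log2")
}
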