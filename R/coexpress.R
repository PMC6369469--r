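#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson coefficient plus the usual t-based significance test:
#' t = r * sqrt((n-2) / (1-r^2)) on n-2 degrees of freedom. A perfect
#' |r| = 1 gives p = 0. A constant vector has no defined correlation;
#' the pair is reported as r = 0, p = 1 with a warning so that it can
#' never be retained as an edge.
#'
#' @param x,y Numeric vectors of equal length n >= 3.
#' @return Named numeric vector `c(r =, p =)`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined, returning r = 0, p = 1")
    return(c(r = 0, p = 1))
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2)
  c(r = r, p = p)
}

#' Call signed lncRNA-mRNA coexpression edges
#'
#' Evaluates every lncRNA x mRNA probe pair across all samples pooled
#' (both groups) and retains pairs with |r| >= `r_min` and p <= `p_max`
#' (both thresholds inclusive). With `p_only = TRUE` the magnitude gate
#' is skipped and only p <= `p_max` is required, the variant used for
#' building function-prediction partner sets. Constant probe rows get
#' r = 0, p = 1 (warned once) and are never retained.
#'
#' @param lnc,mrna [expression_matrix()] slices sharing the identical
#'   sample order (see [split_by_type()]). Correlations are computed on
#'   the values as given; the pipeline supplies log2 normalized signals.
#' @param r_min Inclusive threshold on |r|.
#' @param p_max Inclusive threshold on the correlation p-value.
#' @param p_only Drop the |r| gate.
#' @param group `NULL` pools all samples (the default; group contrast
#'   then contributes to the correlations, which is what produces the
#'   case/control-driven networks); `"case"` or `"control"` restricts
#'   the correlation to that group's samples.
#' @return A `data.frame` of retained edges with columns `lnc_id`,
#'   `mrna_id`, `r`, `p_value`, `sign` (`positive` iff r > 0), carrying
#'   attributes `n_evaluated`, `n_positive`, `n_negative`.
#' @export
build_edges <- function(lnc, mrna, r_min = 0.7, p_max = 0.05, p_only = FALSE,
                        group = NULL) {
  stopifnot(inherits(lnc, "ExpressionMatrix"), inherits(mrna, "ExpressionMatrix"))
  if (!identical(colnames(lnc$values), colnames(mrna$values)))
    stop("lncRNA and mRNA matrices must share the same sample order")
  keep_s <- if (is.null(group)) rep(TRUE, ncol(lnc$values)) else {
    stopifnot(group %in% c("case", "control"))
    if (!identical(unname(lnc$groups), unname(mrna$groups)))
      stop("lncRNA and mRNA matrices must share the same group labels")
    lnc$groups == group
  }
  n <- sum(keep_s)
  if (n < 3) stop("need at least 3 samples")
  xs <- t(lnc$values[, keep_s, drop = FALSE])
  ys <- t(mrna$values[, keep_s, drop = FALSE])
  const_x <- apply(xs, 2, stats::sd) == 0
  const_y <- apply(ys, 2, stats::sd) == 0
  if (any(const_x) || any(const_y))
    warning(sprintf("%d constant probe row(s): their pairs get r = 0, p = 1",
                    sum(const_x) + sum(const_y)))
  # guard constant columns so cor() does not emit NA; overwritten below
  xs[, const_x] <- xs[, const_x] + seq_len(n)
  ys[, const_y] <- ys[, const_y] + seq_len(n)
  r <- stats::cor(xs, ys)
  r[const_x, ] <- 0
  r[, const_y] <- 0
  rc <- pmin(abs(r), 1)
  p <- 2 * stats::pt(-rc * sqrt((n - 2) / pmax(1 - rc^2, 0)), n - 2)
  p[rc >= 1] <- 0
  p[const_x, ] <- 1
  p[, const_y] <- 1
  keep <- if (p_only) p <= p_max else abs(r) >= r_min & p <= p_max
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(lnc_id = rownames(lnc$values)[idx[, 1]],
                    mrna_id = rownames(mrna$values)[idx[, 2]],
                    r = r[idx], p_value = p[idx],
                    sign = ifelse(r[idx] > 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$lnc_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_evaluated") <- nrow(lnc$values) * nrow(mrna$values)
  attr(out, "n_positive") <- sum(out$sign == "positive")
  attr(out, "n_negative") <- sum(out$sign == "negative")
  out
}

#' Coexpressed mRNA partner symbols of one lncRNA
#'
#' The gene symbols of every mRNA probe sharing a retained edge (either
#' sign) with the given lncRNA; probes mapping to the same symbol
#' collapse to one entry. The lncRNA must exist in the annotation even
#' if it has no retained edges (then the set is empty).
#'
#' @param edges Edge table from [build_edges()].
#' @param lnc_id A lncRNA probe id.
#' @param annotation Probe annotation (see [read_annotation_tsv()]).
#' @return Character vector of mRNA gene symbols (sorted, unique).
#' @export
partners <- function(edges, lnc_id, annotation) {
  annotation <- validate_annotation(annotation)
  known <- annotation$probe_id[annotation$molecule_type == "lncRNA"]
  if (!lnc_id %in% known) stop("unknown lncRNA probe id: ", lnc_id)
  mr <- edges$mrna_id[edges$lnc_id == lnc_id]
  sort(unique(annotation$gene_symbol[match(mr, annotation$probe_id)]))
}
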