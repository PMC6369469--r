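#' Screen probes for differential expression
#'
#' For every probe: linear-scale group means of the (quantile-
#' normalized) intensities, the fold change reported as a magnitude
#' >= 1 plus an up/down direction, and a two-sided unpaired two-sample
#' t-test computed on log2 values. A probe is flagged significant when
#' `fold_change >= fc_min` and `p_value <= p_max` (double cut-off,
#' defaults 2.0 and 0.05).
#'
#' The pooled-variance (Student) test is the default; Welch's unequal-
#' variance test is available via `welch = TRUE`. Raw p-values drive the
#' cut-off by default; `bh = TRUE` adds a Benjamini-Hochberg adjusted
#' column and applies the cut-off to it. Probes with zero variance in
#' both groups and equal means carry no evidence and get `p = 1`
#' (reported with a warning).
#'
#' @param m Normalized linear-scale [expression_matrix()]; both groups
#'   need at least 2 samples.
#' @param fc_min Fold-change threshold (magnitude).
#' @param p_max Significance threshold on the p-value.
#' @param welch Use Welch's t-test instead of pooled-variance Student.
#' @param bh Apply Benjamini-Hochberg correction before thresholding.
#' @param log_scale_test Run the t-test on log2 intensities (the
#'   default, standard single-channel practice); `FALSE` tests the
#'   linear values instead. Fold change always uses linear means.
#' @param annotation Optional probe annotation; when given, the columns
#'   `molecule_type` and `gene_symbol` are attached.
#' @return A `data.frame` (one row per probe, input order) with columns
#'   `probe_id`, `mean_case`, `mean_control`, `fold_change`, `direction`,
#'   `p_value`, `significant` (plus `p_adj` when `bh`, and annotation
#'   columns when supplied).
#' @export
differential_expression <- function(m, fc_min = 2.0, p_max = 0.05,
                                    welch = FALSE, bh = FALSE,
                                    log_scale_test = TRUE,
                                    annotation = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale_tag != "linear")
    stop("expects linear-scale normalized intensities (log2 is taken internally)")
  case <- m$values[, m$groups == "case", drop = FALSE]
  ctrl <- m$values[, m$groups == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")

  mean_case <- rowMeans(case)
  mean_control <- rowMeans(ctrl)
  ratio <- mean_case / mean_control
  fold_change <- pmax(ratio, 1 / ratio)
  direction <- ifelse(mean_case > mean_control, "up", "down")

  if (log_scale_test) { l1 <- log2(case); l2 <- log2(ctrl) }
  else { l1 <- case; l2 <- ctrl }
  m1 <- rowMeans(l1); m2 <- rowMeans(l2)
  v1 <- rowSums((l1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((l2 - m2)^2) / (n2 - 1)
  diff <- m1 - m2
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(diff))
  }
  tstat <- diff / sqrt(se2)
  p_value <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    # zero variance in both groups: equal means carry no evidence (p = 1),
    # unequal means are infinitely separated (p = 0)
    p_value[degenerate] <- ifelse(diff[degenerate] == 0, 1, 0)
    if (any(degenerate & diff == 0))
      warning(sprintf("%d probe(s) constant in both groups; p set to 1",
                      sum(degenerate & diff == 0)))
  }

  out <- data.frame(probe_id = rownames(m$values),
                    mean_case = mean_case, mean_control = mean_control,
                    fold_change = fold_change, direction = direction,
                    p_value = p_value, stringsAsFactors = FALSE)
  if (bh) {
    out$p_adj <- stats::p.adjust(out$p_value, "BH")
    out$significant <- out$fold_change >= fc_min & out$p_adj <= p_max
  } else {
    out$significant <- out$fold_change >= fc_min & out$p_value <= p_max
  }
  if (!is.null(annotation)) {
    annotation <- validate_annotation(annotation)
    i <- match(out$probe_id, annotation$probe_id)
    out$molecule_type <- annotation$molecule_type[i]
    out$gene_symbol <- annotation$gene_symbol[i]
  }
  rownames(out) <- NULL
  out
}

#' Select the top up- and down-regulated probes
#'
#' Significant records only, ordered by the pipeline's total tie-break:
#' ascending p-value, then descending fold change, then ascending probe
#' id. If fewer significant probes exist than requested, all available
#' are returned with a warning.
#'
#' @param records Output of [differential_expression()].
#' @param k_up,k_down Number of up- / down-regulated probes to select.
#' @return List with `data.frame` elements `up` and `down`.
#' @export
select_top_k <- function(records, k_up, k_down) {
  stopifnot(is.data.frame(records), k_up >= 0, k_down >= 0)
  pick <- function(dirn, k) {
    sub <- records[records$significant & records$direction == dirn, , drop = FALSE]
    sub <- sub[rank_order(sub$p_value, sub$fold_change, sub$probe_id), , drop = FALSE]
    if (nrow(sub) < k)
      warning(sprintf("only %d significant %s-regulated probes available (%d requested)",
                      nrow(sub), dirn, k))
    utils::head(sub, k)
  }
  list(up = pick("up", k_up), down = pick("down", k_down))
}

#' Order probes by average-linkage hierarchical clustering
#'
#' Rows are log2-transformed (if needed) and standardized to zero mean
#' and unit variance; the dissimilarity is 1 - Pearson correlation and
#' agglomeration uses average linkage (UPGMA). A constant row has no
#' defined correlation: its r is treated as 0, i.e. distance 1 to every
#' other row, with a warning.
#'
#' @param m An [expression_matrix()].
#' @param probes Probe ids to cluster (>= 2).
#' @return An object of class `cluster_order`: list with `order`
#'   (probe ids in dendrogram leaf order), `merge` and `height` (the
#'   n-1 merges as in [stats::hclust()]), and `labels`.
#' @export
hierarchical_cluster <- function(m, probes) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (length(probes) < 2) stop("need at least 2 probes to cluster")
  x <- subset_probes(m, probes)$values
  if (m$scale_tag == "linear") x <- log2(x)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    warning(sprintf("%d constant probe row(s): correlation treated as 0",
                    sum(sds == 0)))
  z <- x
  ok <- sds > 0
  z[ok, ] <- (x[ok, , drop = FALSE] - rowMeans(x[ok, , drop = FALSE])) / sds[ok]
  r <- matrix(0, nrow(x), nrow(x), dimnames = list(probes, probes))
  if (any(ok)) r[ok, ok] <- stats::cor(t(z[ok, , drop = FALSE]))
  diag(r) <- 1
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  structure(list(order = probes[hc$order], merge = hc$merge,
                 height = hc$height, labels = probes),
            class = "cluster_order")
}

#' @export
print.cluster_order <- function(x, ...) {
  cat(sprintf("cluster_order: %d probes, %d merges\n",
              length(x$order), length(x$height)))
  invisible(x)
}
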