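#' Construct an expression matrix with group labels
#'
#' The central container of the pipeline: a probes x samples matrix of
#' signal intensities together with a two-level case/control assignment
#' of the sample columns and a scale tag recording whether values are on
#' the linear or the log2 scale.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). No missing values;
#'   strictly positive when `scale_tag = "linear"`.
#' @param groups Named character vector mapping every sample id to
#'   `"case"` or `"control"`; both groups must be non-empty.
#' @param scale_tag `"linear"` (raw or quantile-normalized intensities)
#'   or `"log2"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `groups` and `scale_tag`.
#' @examples
#' v <- matrix(2^rnorm(12, 8), 2, 6,
#'             dimnames = list(c("p1", "p2"), paste0("s", 1:6)))
#' g <- setNames(rep(c("case", "control"), each = 3), paste0("s", 1:6))
#' expression_matrix(v, g)
#' @export
expression_matrix <- function(values, groups, scale_tag = c("linear", "log2")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids")
  if (anyNA(values))
    stop("missing values are not allowed; drop incomplete probe rows at load time")
  if (scale_tag == "linear" && any(values <= 0))
    stop("linear-scale intensities must be strictly positive")
  groups <- groups[colnames(values)]
  if (anyNA(groups) || is.null(names(groups)))
    stop("'groups' must name every sample id in 'values'")
  if (!all(groups %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  if (length(unique(groups)) < 2L)
    stop("both groups must be non-empty")
  structure(list(values = values, groups = groups, scale_tag = scale_tag),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  cat(sprintf("  case: %d samples; control: %d samples\n",
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an expression matrix by probe ids
#'
#' @param m An [expression_matrix()].
#' @param probes Character vector of probe ids to keep (order preserved).
#' @return An `ExpressionMatrix` restricted to `probes`.
#' @export
subset_probes <- function(m, probes) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  missing <- setdiff(probes, rownames(m$values))
  if (length(missing))
    stop("unknown probe ids: ", paste(utils::head(missing, 5), collapse = ", "))
  expression_matrix(m$values[probes, , drop = FALSE], m$groups, m$scale_tag)
}

#' Read an expression matrix and its group sidecar from TSV
#'
#' The matrix file has a `probe_id` first column and one column per
#' sample; the sidecar maps `sample_id` to `group`. Probe rows with any
#' missing entry are dropped with a warning (the loader's missing-value
#' policy; normalization and testing assume complete rows).
#'
#' @param path Matrix TSV path.
#' @param groups_path Sidecar TSV path (columns `sample_id`, `group`).
#' @param scale_tag Scale of the stored values.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, groups_path, scale_tag = "linear") {
  df <- read_tsv(path)
  if (names(df)[1] != "probe_id") stop("first column must be 'probe_id'")
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$probe_id
  bad <- rowSums(is.na(v)) > 0
  if (any(bad)) {
    warning(sprintf("dropping %d probe row(s) with missing values", sum(bad)))
    v <- v[!bad, , drop = FALSE]
  }
  gdf <- read_tsv(groups_path)
  groups <- stats::setNames(gdf$group, gdf$sample_id)
  expression_matrix(v, groups, scale_tag)
}

#' Write an expression matrix and its group sidecar to TSV
#'
#' @param m An [expression_matrix()].
#' @param path Matrix TSV path.
#' @param groups_path Sidecar TSV path.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(m, path, groups_path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(probe_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(data.frame(sample_id = names(m$groups), group = unname(m$groups)),
            groups_path)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Columns: `probe_id`, `molecule_type` (`lncRNA` or `mRNA`),
#' `gene_symbol`. Every probe must be classified and ids must be unique.
#'
#' @param path Annotation TSV path.
#' @return A `data.frame` with the three columns above.
#' @export
read_annotation_tsv <- function(path) {
  df <- read_tsv(path)
  validate_annotation(df)
}

validate_annotation <- function(df) {
  need <- c("probe_id", "molecule_type", "gene_symbol")
  if (!all(need %in% names(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids in annotation")
  if (!all(df$molecule_type %in% c("lncRNA", "mRNA")))
    stop("molecule_type must be 'lncRNA' or 'mRNA' for every probe")
  df[need]
}

#' Split an expression matrix into lncRNA and mRNA sub-matrices
#'
#' @param m An [expression_matrix()].
#' @param annotation Probe annotation `data.frame`
#'   (see [read_annotation_tsv()]); every probe of `m` must be annotated.
#' @return List with `ExpressionMatrix` elements `lnc` and `mrna`.
#' @export
split_by_type <- function(m, annotation) {
  annotation <- validate_annotation(annotation)
  ids <- rownames(m$values)
  type <- annotation$molecule_type[match(ids, annotation$probe_id)]
  if (anyNA(type)) stop("unannotated probes in matrix")
  list(lnc = subset_probes(m, ids[type == "lncRNA"]),
       mrna = subset_probes(m, ids[type == "mRNA"]))
}
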