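#' Read a qPCR Ct table
#'
#' Long-format cycle-threshold table with columns `gene`, `sample`,
#' `group` (`case`/`control`) and `Ct` (cycles, > 0).
#'
#' @param path TSV path.
#' @return A validated `data.frame`.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv(path)
  validate_ct_table(df)
}

validate_ct_table <- function(df) {
  need <- c("gene", "sample", "group", "Ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  if (any(df$Ct <= 0)) stop("Ct values must be positive")
  df[need]
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = Ct(target) - Ct(reference); the group dCt is the
#' mean over that group's samples; ddCt = dCt(case) - dCt(control); and
#' the relative level is 2^-ddCt (ideal amplification efficiency of 2).
#' A sample missing the reference gene is dropped with a warning; a
#' group losing all its samples is an error.
#'
#' @param ct Ct table (see [read_ct_table()]).
#' @param reference Reference (housekeeping) gene id, e.g. `"GAPDH"`.
#' @param target Target gene id; must differ from `reference`.
#' @return A one-row `data.frame` with `gene`, `delta_ct_case`,
#'   `delta_ct_control`, `delta_delta_ct`, `relative_level`.
#' @examples
#' ct <- data.frame(gene = rep(c("T", "GAPDH"), each = 2),
#'                  sample = c("c1", "k1", "c1", "k1"),
#'                  group = c("case", "control", "case", "control"),
#'                  Ct = c(25, 28, 20, 21))
#' delta_delta_ct(ct, "GAPDH", "T")  # ddCt = -2, relative level 4
#' @export
delta_delta_ct <- function(ct, reference, target) {
  ct <- validate_ct_table(ct)
  if (identical(reference, target))
    stop("reference and target must differ")
  ref <- ct[ct$gene == reference, ]
  tar <- ct[ct$gene == target, ]
  if (nrow(tar) == 0) stop("target '", target, "' not in table")
  if (nrow(ref) == 0) stop("reference '", reference, "' not in table")
  i <- match(tar$sample, ref$sample)
  if (anyNA(i)) {
    warning(sprintf("dropping %d sample(s) without a reference measurement",
                    sum(is.na(i))))
    tar <- tar[!is.na(i), ]
    i <- i[!is.na(i)]
  }
  dct <- tar$Ct - ref$Ct[i]
  grp <- tar$group
  if (!any(grp == "case") || !any(grp == "control"))
    stop("target '", target, "' must be measured in both groups")
  dct_case <- mean(dct[grp == "case"])
  dct_control <- mean(dct[grp == "control"])
  ddct <- dct_case - dct_control
  data.frame(gene = target, delta_ct_case = dct_case,
             delta_ct_control = dct_control, delta_delta_ct = ddct,
             relative_level = 2^(-ddct), stringsAsFactors = FALSE)
}

#' Relative expression for several targets at once
#'
#' @param ct Ct table.
#' @param reference Reference gene id.
#' @param targets Character vector of target gene ids (default: every
#'   gene in the table except the reference).
#' @return A `data.frame`, one row per target (see [delta_delta_ct()]).
#' @export
relative_expression <- function(ct, reference, targets = NULL) {
  ct <- validate_ct_table(ct)
  if (is.null(targets)) targets <- setdiff(unique(ct$gene), reference)
  out <- do.call(rbind, lapply(targets, function(g) delta_delta_ct(ct, reference, g)))
  rownames(out) <- NULL
  out
}

#' Direction concordance between qPCR and microarray
#'
#' For each gene shared between the differential-expression table and
#' the qPCR relative-expression table: the platforms agree when the
#' array direction is up and the relative level exceeds 1, or the
#' direction is down and the relative level is below 1. A relative
#' level of exactly 1 is indeterminate and excluded from the agreement
#' fraction.
#'
#' @param de Output of [differential_expression()]; matched to qPCR by
#'   `probe_id` (or by `gene_symbol` when present and matching).
#' @param rel Output of [relative_expression()].
#' @return An object of class `concordance_report`: list with
#'   `per_gene` (gene, direction, relative_level, agree) and
#'   `fraction_agree` over the determinate genes.
#' @export
concordance <- function(de, rel) {
  stopifnot(is.data.frame(de), is.data.frame(rel))
  key <- de$probe_id
  i <- match(rel$gene, key)
  if ("gene_symbol" %in% names(de)) {
    j <- match(rel$gene, de$gene_symbol)
    i[is.na(i)] <- j[is.na(i)]
  }
  shared <- !is.na(i)
  if (!any(shared)) stop("no genes shared between the DE and qPCR tables")
  per <- data.frame(gene = rel$gene[shared],
                    microarray_direction = de$direction[i[shared]],
                    relative_level = rel$relative_level[shared],
                    stringsAsFactors = FALSE)
  per$agree <- ifelse(per$relative_level == 1, NA,
                      (per$microarray_direction == "up") == (per$relative_level > 1))
  structure(list(per_gene = per,
                 fraction_agree = mean(per$agree, na.rm = TRUE)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  det <- sum(!is.na(x$per_gene$agree))
  cat(sprintf("concordance_report: %d shared gene(s), %d determinate\n",
              nrow(x$per_gene), det))
  cat(sprintf("  fraction agreeing: %.3f\n", x$fraction_agree))
  invisible(x)
}
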