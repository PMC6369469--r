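#' Construct a gene-set collection
#'
#' Flat gene sets (GO/KEGG-style functional terms or TF target lists)
#' identified by a unique set id with a display name, a category and
#' non-empty member gene symbols.
#'
#' @param set_id Character vector of unique set ids.
#' @param name Display names.
#' @param category One of `GO_BP`, `GO_CC`, `GO_MF`, `KEGG`, `TF` per set.
#' @param members List of character vectors of member gene symbols.
#' @return An object of class `gene_set_db`.
#' @export
gene_set_db <- function(set_id, name = set_id, category, members) {
  stopifnot(length(set_id) == length(name),
            length(set_id) == length(category),
            length(set_id) == length(members))
  if (anyDuplicated(set_id)) stop("duplicate set ids")
  if (!all(category %in% c("GO_BP", "GO_CC", "GO_MF", "KEGG", "TF")))
    stop("unknown category")
  if (any(lengths(members) == 0)) stop("empty member sets are not allowed")
  members <- lapply(members, function(g) unique(as.character(g)))
  structure(list(set_id = as.character(set_id), name = as.character(name),
                 category = as.character(category), members = members),
            class = "gene_set_db")
}

#' @export
print.gene_set_db <- function(x, ...) {
  cat(sprintf("gene_set_db: %d sets (%s), member sizes %d-%d\n",
              length(x$set_id), paste(unique(x$category), collapse = "/"),
              min(lengths(x$members)), max(lengths(x$members))))
  invisible(x)
}

#' @export
length.gene_set_db <- function(x) length(x$set_id)

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member gene
#' symbols. The description field is kept as the display name.
#'
#' @param path GMT file path.
#' @param category Category assigned to every set in the file.
#' @return A [gene_set_db()].
#' @export
read_gmt <- function(path, category = "KEGG") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): need name, description, >=1 gene")
  gene_set_db(set_id = vapply(parts, `[[`, "", 1),
              name = vapply(parts, `[[`, "", 2),
              category = rep(category, length(parts)),
              members = lapply(parts, function(p) p[-(1:2)]))
}

#' Write a gene-set collection as GMT
#'
#' @param db A [gene_set_db()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "gene_set_db"))
  lines <- vapply(seq_along(db$set_id), function(i)
    paste(c(db$set_id[i], db$name[i], db$members[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' The enrichment p-value: probability of drawing at least `k` annotated
#' genes when `n` genes are drawn without replacement from a universe of
#' `N` genes of which `K` are annotated,
#' p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n),
#' evaluated through the stable log-space tail of [stats::phyper()].
#' `k = 0` gives p = 1 (the whole distribution).
#'
#' @param k Observed overlap count.
#' @param K Annotated genes in the universe (set size).
#' @param n Query size.
#' @param N Universe size.
#' @return The upper-tail probability in (0, 1].
#' @examples
#' hypergeom_tail(2, 4, 5, 10)  # 186/252
#' @export
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (k < 0 || K < 0 || n < 0 || N < 1 || K > N || n > N || k > min(K, n))
    stop("invalid hypergeometric configuration: need 0 <= k <= min(K, n), K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of a query gene set
#'
#' Restricts query and database sets to the declared universe (dropped
#' query symbols are warned about with a count), scores every set with
#' nonzero overlapable size by the hypergeometric upper tail, and ranks
#' records by ascending p, then descending overlap, then ascending set
#' id. Sets disjoint from the universe are omitted (K = 0).
#'
#' @param query Character vector of gene symbols.
#' @param db A [gene_set_db()].
#' @param universe Character vector of background gene symbols; by
#'   convention the symbols of all annotated mRNA probes on the array.
#' @param bh Add a Benjamini-Hochberg adjusted p column.
#' @return A `data.frame` with columns `set_id`, `name`, `category`,
#'   `k`, `K`, `n`, `N`, `p_value` (and `p_adj` when `bh`).
#' @export
enrich <- function(query, db, universe, bh = FALSE) {
  stopifnot(inherits(db, "gene_set_db"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  query <- unique(as.character(query))
  dropped <- sum(!query %in% universe)
  if (dropped > 0)
    warning(sprintf("%d query symbol(s) outside the universe dropped", dropped))
  query <- intersect(query, universe)
  if (length(query) == 0) stop("query empty after restriction to the universe")
  N <- length(universe); n <- length(query)
  Ks <- vapply(db$members, function(g) length(intersect(g, universe)), 0L)
  ks <- vapply(db$members, function(g) length(intersect(intersect(g, universe), query)), 0L)
  keep <- Ks > 0
  p <- vapply(which(keep), function(i) hypergeom_tail(ks[i], Ks[i], n, N), 0)
  out <- data.frame(set_id = db$set_id[keep], name = db$name[keep],
                    category = db$category[keep],
                    k = ks[keep], K = Ks[keep], n = n, N = N,
                    p_value = p, stringsAsFactors = FALSE)
  out <- out[rank_order(out$p_value, out$k, out$set_id), , drop = FALSE]
  if (bh) out$p_adj <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

#' Rank lncRNA-TF associations by target-set enrichment
#'
#' For each lncRNA, its coexpressed-mRNA partner set (from
#' [partners()]) is tested against every TF target set and the `top_k`
#' lowest-p TFs with nonzero overlap are retained as candidate
#' regulators. A lncRNA with an empty partner set contributes no pairs
#' (reported via message).
#'
#' @param lnc_ids Character vector of lncRNA probe ids.
#' @param partner_sets Named list mapping each lncRNA id to its partner
#'   gene-symbol set.
#' @param tf_db TF target [gene_set_db()].
#' @param universe Background gene symbols.
#' @param top_k Pairs retained per lncRNA.
#' @return A `data.frame` with columns `lnc_id`, `tf`, `k`, `K`, `n`,
#'   `N`, `p_value`.
#' @export
lnc_tf_pairs <- function(lnc_ids, partner_sets, tf_db, universe, top_k = 5) {
  stopifnot(inherits(tf_db, "gene_set_db"), top_k >= 0)
  rows <- lapply(lnc_ids, function(l) {
    ps <- partner_sets[[l]]
    if (is.null(ps) || length(ps) == 0) {
      message("lncRNA ", l, " has no coexpressed partners; no TF pairs emitted")
      return(NULL)
    }
    e <- enrich(ps, tf_db, universe)
    e <- e[e$k > 0, , drop = FALSE]
    e <- utils::head(e, top_k)
    if (nrow(e) == 0) return(NULL)
    data.frame(lnc_id = l, tf = e$set_id, k = e$k, K = e$K, n = e$n, N = e$N,
               p_value = e$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(data.frame(lnc_id = character(), tf = character(),
                                          k = integer(), K = integer(),
                                          n = integer(), N = integer(),
                                          p_value = numeric(),
                                          stringsAsFactors = FALSE)), rows))
  rownames(out) <- NULL
  out
}
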