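# Shared fixture builders; all randomness is seeded by the caller.

make_expr <- function(values, n_case = NULL, scale_tag = "linear") {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%d", seq_len(nrow(values)))
  if (is.null(n_case)) n_case <- ncol(values) %/% 2
  groups <- stats::setNames(
    rep(c("case", "control"), c(n_case, ncol(values) - n_case)),
    colnames(values))
  expression_matrix(values, groups, scale_tag)
}

# Independent hypergeometric upper tail: explicit pmf enumeration from
# binomial coefficients (exact in doubles for the small N used here).
hyper_tail_enum <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Independent average-linkage agglomeration: at every step merge the
# pair of clusters with the smallest mean original pairwise distance.
average_linkage_enum <- function(d) {
  dm <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (a in seq_along(clusters)) for (b in seq_len(a - 1)) {
      h <- mean(dm[clusters[[a]], clusters[[b]]])
      if (h < best_h) { best_h <- h; best <- c(b, a) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

tiny_ct_table <- function() {
  data.frame(gene = rep(c("TARG", "GAPDH"), each = 4),
             sample = rep(c("c1", "c2", "k1", "k2"), 2),
             group = rep(c("case", "case", "control", "control"), 2),
             Ct = c(25, 25, 28, 28, 20, 20, 21, 21),
             stringsAsFactors = FALSE)
}
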