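test_that("pearson_with_p matches hand values and cor.test", {
  expect_equal(unname(pearson_with_p(1:3, c(2, 4, 6))["r"]), 1)
  expect_equal(unname(pearson_with_p(1:3, c(6, 4, 2))["r"]), -1)
  expect_equal(unname(pearson_with_p(1:3, c(2, 4, 6))["p"]), 0)
  r <- pearson_with_p(1:3, c(1, 2, 4))
  expect_equal(unname(r["r"]), 1.5 / sqrt(7 / 3), tolerance = 1e-12)  # 0.98198
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    o <- cor.test(x, y)
    got <- pearson_with_p(x, y)
    expect_equal(unname(got["r"]), unname(o$estimate))
    expect_equal(unname(got["p"]), o$p.value)
  }
  expect_warning(z <- pearson_with_p(rep(1, 5), rnorm(5)), "constant")
  expect_equal(unname(z), c(0, 1))
  expect_error(pearson_with_p(1:2, 1:2), "3")
  expect_error(pearson_with_p(1:4, 1:5), "equal length")
})

test_that("r matches the direct covariance formula on many random pairs", {
  set.seed(8)
  for (i in 1:1000) {
    x <- rnorm(6); y <- rnorm(6)
    direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(pearson_with_p(x, y)["r"]), direct, tolerance = 1e-12)
  }
})

test_that("build_edges evaluates every pair and applies both gates", {
  set.seed(9)
  lnc <- make_expr(matrix(rnorm(3 * 6), 3, 6,
                          dimnames = list(paste0("L", 1:3), paste0("s", 1:6))),
                   scale_tag = "log2")
  mrna <- make_expr(matrix(rnorm(4 * 6), 4, 6,
                           dimnames = list(paste0("M", 1:4), paste0("s", 1:6))),
                    scale_tag = "log2")
  e <- build_edges(lnc, mrna, r_min = 0, p_max = 1)
  expect_equal(attr(e, "n_evaluated"), 12L)
  expect_equal(nrow(e), 12L)
  e2 <- build_edges(lnc, mrna, r_min = 0.7, p_max = 0.05)
  expect_true(all(abs(e2$r) >= 0.7 & e2$p_value <= 0.05))
  expect_identical(e2$sign, ifelse(e2$r > 0, "positive", "negative"))
  expect_equal(attr(e2, "n_positive") + attr(e2, "n_negative"), nrow(e2))
  # sample order mismatch rejected
  perm <- mrna
  perm$values <- perm$values[, c(2, 1, 3:6)]
  expect_error(build_edges(lnc, perm), "sample order")
})

test_that("a pair just below the r threshold is excluded, at it included", {
  # construct y with exact correlation 0.69 and 0.70 against x
  x <- scale(rnorm(30))[, 1]
  z <- scale(resid(lm(rnorm(30) ~ x)))[, 1]
  for (r0 in c(0.69, 0.71)) {
    y <- r0 * x + sqrt(1 - r0^2) * z
    lnc <- make_expr(matrix(x, 1, dimnames = list("L1", paste0("s", 1:30))),
                     scale_tag = "log2")
    mrna <- make_expr(matrix(y, 1, dimnames = list("M1", paste0("s", 1:30))),
                      scale_tag = "log2")
    e <- build_edges(lnc, mrna, r_min = 0.7, p_max = 1)
    expect_equal(nrow(e), if (r0 < 0.7) 0L else 1L)
  }
})

test_that("retained-edge counts are monotone in both thresholds", {
  set.seed(10)
  lnc <- make_expr(matrix(rnorm(10 * 6), 10, 6,
                          dimnames = list(paste0("L", 1:10), paste0("s", 1:6))),
                   scale_tag = "log2")
  mrna <- make_expr(matrix(rnorm(20 * 6), 20, 6,
                           dimnames = list(paste0("M", 1:20), paste0("s", 1:6))),
                    scale_tag = "log2")
  counts_r <- vapply(c(0, 0.3, 0.6, 0.8, 0.95),
                     function(r) nrow(build_edges(lnc, mrna, r, p_max = 1)), 0L)
  expect_true(all(diff(counts_r) <= 0))
  counts_p <- vapply(c(1, 0.5, 0.1, 0.01),
                     function(p) nrow(build_edges(lnc, mrna, 0, p)), 0L)
  expect_true(all(diff(counts_p) <= 0))
})

test_that("within-group correlation equals correlation on the subset matrix", {
  set.seed(15)
  lnc <- make_expr(matrix(rnorm(4 * 8), 4, 8,
                          dimnames = list(paste0("L", 1:4), paste0("s", 1:8))),
                   n_case = 4, scale_tag = "log2")
  mrna <- make_expr(matrix(rnorm(6 * 8), 6, 8,
                           dimnames = list(paste0("M", 1:6), paste0("s", 1:8))),
                    n_case = 4, scale_tag = "log2")
  a <- build_edges(lnc, mrna, r_min = 0, p_max = 1, group = "case")
  # oracle: plain correlation over the case samples only
  for (i in seq_len(nrow(a)))
    expect_equal(a$r[i], cor(lnc$values[a$lnc_id[i], 1:4],
                             mrna$values[a$mrna_id[i], 1:4]))
  expect_error(build_edges(lnc, mrna, group = "treated"))
})

test_that("edges are invariant under a joint permutation of samples", {
  set.seed(11)
  lnc <- make_expr(matrix(rnorm(5 * 6), 5, 6,
                          dimnames = list(paste0("L", 1:5), paste0("s", 1:6))),
                   scale_tag = "log2")
  mrna <- make_expr(matrix(rnorm(8 * 6), 8, 6,
                           dimnames = list(paste0("M", 1:8), paste0("s", 1:6))),
                    scale_tag = "log2")
  perm <- sample(6)
  lnc2 <- lnc; lnc2$values <- lnc$values[, perm]; lnc2$groups <- lnc$groups[perm]
  mrna2 <- mrna; mrna2$values <- mrna$values[, perm]; mrna2$groups <- mrna$groups[perm]
  a <- build_edges(lnc, mrna, 0.5, 0.2)
  b <- build_edges(lnc2, mrna2, 0.5, 0.2)
  attributes(a) <- attributes(a)[c("names", "row.names", "class")]
  attributes(b) <- attributes(b)[c("names", "row.names", "class")]
  expect_equal(a, b)
})

test_that("null pairs pass the p gate at close to the nominal 5% rate", {
  set.seed(12)
  lnc <- make_expr(matrix(rnorm(100 * 6), 100, 6,
                          dimnames = list(paste0("L", 1:100), paste0("s", 1:6))),
                   scale_tag = "log2")
  mrna <- make_expr(matrix(rnorm(200 * 6), 200, 6,
                           dimnames = list(paste0("M", 1:200), paste0("s", 1:6))),
                    scale_tag = "log2")
  e <- build_edges(lnc, mrna, r_min = 0, p_max = 0.05, p_only = TRUE)
  frac <- nrow(e) / attr(e, "n_evaluated")
  se <- sqrt(0.05 * 0.95 / attr(e, "n_evaluated"))
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("partner sets collapse probes to symbols and validate the lncRNA", {
  ann <- data.frame(probe_id = c("L1", "L2", "M1", "M2", "M3"),
                    molecule_type = c("lncRNA", "lncRNA", "mRNA", "mRNA", "mRNA"),
                    gene_symbol = c("LncA", "LncB", "GeneX", "GeneX", "GeneY"),
                    stringsAsFactors = FALSE)
  edges <- data.frame(lnc_id = c("L1", "L1", "L1"),
                      mrna_id = c("M1", "M2", "M3"),
                      r = c(0.9, 0.8, -0.9), p_value = c(0.01, 0.02, 0.01),
                      sign = c("positive", "positive", "negative"),
                      stringsAsFactors = FALSE)
  expect_identical(partners(edges, "L1", ann), c("GeneX", "GeneY"))
  expect_identical(partners(edges, "L2", ann), character(0))
  expect_error(partners(edges, "M1", ann), "unknown lncRNA")
})
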