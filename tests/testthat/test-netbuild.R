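edge_row <- function(lnc, mrna, r, p = 0.01) {
  data.frame(lnc_id = lnc, mrna_id = mrna, r = r, p_value = p,
             sign = ifelse(r > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

test_that("typed_graph enforces endpoint types and simple edges", {
  nodes <- data.frame(id = c("L1", "M1", "T1"),
                      node_type = c("lncRNA", "mRNA", "TF"))
  ok <- typed_graph(nodes, data.frame(source = "L1", target = "M1",
                                      edge_type = "coexpr_pos", weight = 0.9))
  expect_s3_class(ok, "typed_graph")
  expect_error(typed_graph(nodes, data.frame(source = "M1", target = "L1",
                                             edge_type = "coexpr_pos", weight = 1)),
               "lncRNA -> mRNA")
  expect_error(typed_graph(nodes, data.frame(source = "L1", target = "M1",
                                             edge_type = "tf_regulates_lnc",
                                             weight = 1)),
               "TF -> lncRNA")
  dup <- data.frame(source = c("L1", "L1"), target = c("M1", "M1"),
                    edge_type = "coexpr_pos", weight = c(1, 1))
  expect_error(typed_graph(nodes, dup), "duplicate")
})

test_that("coexpression network counts nodes and maps signs", {
  edges <- rbind(edge_row("L1", c("M1", "M2", "M3"), c(0.9, 0.8, -0.75)),
                 edge_row("L2", c("M4", "M5", "M6"), c(0.95, -0.9, 0.85)))
  g <- build_lnc_mrna_network(c("L1", "L2"), edges)
  s <- summary(g)
  expect_equal(s$n_nodes, 8)
  expect_equal(s$n_edges, 6)
  expect_equal(s$n_positive, 4)
  expect_equal(s$n_negative, 2)
  expect_equal(s$n_positive + s$n_negative, s$n_edges)
  # a shared mRNA appears once; an edge-less seed lncRNA stays isolated
  edges2 <- rbind(edge_row("L1", "M1", 0.9), edge_row("L2", "M1", 0.8))
  g2 <- build_lnc_mrna_network(c("L1", "L2", "L3"), edges2)
  expect_equal(sum(g2$nodes$id == "M1"), 1)
  expect_true("L3" %in% g2$nodes$id)
  expect_equal(summary(g2)$n_nodes, 4)
  g_empty <- suppressMessages(build_lnc_mrna_network("L9", edges2[0, ]))
  expect_equal(summary(g_empty)$n_edges, 0)
})

test_that("TF network is bipartite with shared TFs as hubs", {
  pairs <- data.frame(lnc_id = c("L1", "L2", "L3"), tf = "TFA",
                      k = 3L, K = 10L, n = 5L, N = 100L,
                      p_value = c(1e-4, 1e-3, 1e-2), stringsAsFactors = FALSE)
  g <- build_lnc_tf_network(pairs)
  expect_equal(sum(g$nodes$node_type == "TF"), 1)
  expect_equal(sum(g$edges$source == "TFA"), 3)
  g0 <- build_lnc_tf_network(pairs[0, ])
  expect_equal(summary(g0)$n_edges, 0)
})

test_that("tripartite network respects per-lncRNA degree bounds", {
  edges <- rbind(edge_row("L1", c("M1", "M2", "M3"), c(0.9, 0.95, 0.8),
                          p = c(0.01, 0.001, 0.02)),
                 edge_row("L2", "M1", 0.9, p = 0.01))
  pairs <- data.frame(lnc_id = c("L1", "L1", "L1", "L2"),
                      tf = c("TFA", "TFB", "TFC", "TFA"),
                      k = c(4L, 3L, 2L, 2L), K = 10L, n = 5L, N = 100L,
                      p_value = c(1e-5, 1e-4, 1e-3, 1e-3),
                      stringsAsFactors = FALSE)
  g <- suppressMessages(
    build_lnc_target_tf_network(c("L1", "L2", "L3"), edges, pairs,
                                k_mrna = 2, k_tf = 2))
  deg <- table(c(g$edges$source[g$edges$edge_type == "lnc_targets_mrna"],
                 g$edges$target[g$edges$edge_type == "tf_regulates_lnc"]))
  expect_true(all(deg <= 4))
  # L1 keeps its two lowest-p mRNAs and TFs
  l1m <- g$edges$target[g$edges$source == "L1" &
                          g$edges$edge_type == "lnc_targets_mrna"]
  expect_setequal(l1m, c("M1", "M2"))
  l1t <- g$edges$source[g$edges$target == "L1" &
                          g$edges$edge_type == "tf_regulates_lnc"]
  expect_setequal(l1t, c("TFA", "TFB"))
  # shared TF appears as one node with two regulation edges
  expect_equal(sum(g$nodes$id == "TFA"), 1)
  expect_equal(sum(g$edges$source == "TFA"), 2)
  # degenerate parameters: isolated seed lncRNAs only
  g0 <- suppressMessages(
    build_lnc_target_tf_network(c("L1", "L2"), edges, pairs, 0, 0))
  expect_equal(summary(g0)$n_nodes, 2)
  expect_equal(summary(g0)$n_edges, 0)
})

test_that("SIF export has one line per edge plus isolated nodes", {
  edges <- rbind(edge_row("L1", "M1", 0.9), edge_row("L1", "M2", -0.8))
  g <- build_lnc_mrna_network(c("L1", "L2"), edges)
  f <- withr::local_tempfile(fileext = ".sif")
  export_graph(g, f, "sif")
  lines <- readLines(f)
  expect_length(lines, 2 + 1)   # 2 edges + isolated L2
  expect_match(lines[1], "^L1\tcoexpr_pos\tM1$")
  expect_error(export_graph(g, f, "dot"))
})

test_that("edge-TSV and GraphML exports round-trip losslessly", {
  edges <- rbind(edge_row("L1", c("M1", "M2"), c(1 / 3, -sqrt(0.5))),
                 edge_row("L2", "M1", 0.87654321987654321))
  pairs <- data.frame(lnc_id = "L1", tf = "TFA", k = 2L, K = 5L, n = 3L,
                      N = 50L, p_value = 0.0123456789012345678,
                      stringsAsFactors = FALSE)
  g <- suppressMessages(
    build_lnc_target_tf_network(c("L1", "L2", "L3"), edges, pairs, 2, 2))
  for (fmt in c("tsv", "graphml")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_graph(g, f, fmt)
    back <- import_graph(f, fmt)
    expect_equal(back, g, info = fmt)
  }
  # empty graph exports and re-imports
  g0 <- typed_graph(data.frame(id = character(), node_type = character()))
  f0 <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g0, f0, "tsv")
  expect_equal(summary(import_graph(f0, "tsv"))$n_nodes, 0)
})
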