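small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_lnc_probes = 4, n_mrna_probes = 10, n_terms = 3,
         term_size_range = c(3, 5), n_tfs = 3,
         tf_target_size_range = c(3, 5)),
    list(...))
  do.call(sim_config, args)
}

test_that("zero noise and no signal give probe-constant matrices", {
  ds <- simulate_dataset(small_cfg(noise_log2_sd = 0, seed = 5))
  rng <- apply(ds$expr$values, 1, function(x) diff(range(x)))
  expect_true(all(rng == 0))
})

test_that("a noiseless planted fold change is exact on the group-mean ratio", {
  cfg <- small_cfg(noise_log2_sd = 0, seed = 5, planted_de = list(
    list(probe_id = "LNC_0001", fc = 4, direction = "up"),
    list(probe_id = "MRNA_0002", fc = 3, direction = "down")))
  ds <- simulate_dataset(cfg)
  v <- ds$expr$values
  g <- ds$expr$groups
  r_up <- mean(v["LNC_0001", g == "case"]) / mean(v["LNC_0001", g == "control"])
  r_dn <- mean(v["MRNA_0002", g == "control"]) / mean(v["MRNA_0002", g == "case"])
  expect_equal(r_up, 4)
  expect_equal(r_dn, 3)
})

test_that("group-mean ratios converge to the planted fold change under noise", {
  cfg0 <- small_cfg(noise_log2_sd = 0.1, planted_de = list(
    list(probe_id = "LNC_0001", fc = 4, direction = "up")))
  ratios <- vapply(1:200, function(i) {
    cfg <- small_cfg(noise_log2_sd = 0.1, seed = i, planted_de = cfg0$planted_de)
    ds <- simulate_dataset(cfg)
    v <- ds$expr$values; g <- ds$expr$groups
    mean(v["LNC_0001", g == "case"]) / mean(v["LNC_0001", g == "control"])
  }, 0)
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 4), 3 * se)
})

test_that("fixed seed gives byte-identical written outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_sim_dataset(simulate_dataset(small_cfg(seed = 7)), d1)
  p2 <- write_sim_dataset(simulate_dataset(small_cfg(seed = 7)), d2)
  for (i in seq_along(p1))
    expect_identical(unname(tools::md5sum(p1[i])), unname(tools::md5sum(p2[i])))
  # and a different seed actually changes the data
  p3 <- write_sim_dataset(simulate_dataset(small_cfg(seed = 8)),
                          withr::local_tempdir())
  expect_false(identical(unname(tools::md5sum(p1["expression"])),
                         unname(tools::md5sum(p3["expression"]))))
})

test_that("module pairs at loading 0.95 usually exceed r = 0.7 over 6 samples", {
  hits <- vapply(1:500, function(i) {
    cfg <- small_cfg(noise_log2_sd = 0.2, seed = i, planted_modules = list(
      list(lnc = "LNC_0001", mrna = "MRNA_0001", loading = 0.95)))
    v <- log2(simulate_dataset(cfg)$expr$values)
    cor(v["LNC_0001", ], v["MRNA_0001", ]) > 0.7
  }, NA)
  expect_gte(mean(hits), 0.8)
})

test_that("planted TF target sets cover their module's mRNA symbols", {
  cfg <- small_cfg(planted_modules = list(
    list(lnc = "LNC_0001", mrna = sprintf("MRNA_%04d", 1:5), loading = 0.9)))
  ds <- simulate_dataset(cfg)
  link <- ds$truth$tf_planted_links[[1]]
  expect_identical(link$lnc_id, "LNC_0001")
  mod_syms <- ds$annotation$gene_symbol[match(sprintf("MRNA_%04d", 1:5),
                                              ds$annotation$probe_id)]
  tf_set <- ds$tf_targets$members[[match(link$tf, ds$tf_targets$set_id)]]
  expect_gte(length(intersect(tf_set, mod_syms)), ceiling(0.8 * 5))
  # every ground-truth id exists in the annotation
  ids <- c(vapply(ds$truth$true_de, `[[`, "", "probe_id"),
           ds$truth$true_coexpr_pairs$lnc_id, ds$truth$true_coexpr_pairs$mrna_id)
  expect_true(all(ids %in% ds$annotation$probe_id))
})

test_that("invalid configurations are rejected", {
  expect_error(small_cfg(planted_de = list(
    list(probe_id = "LNC_0001", fc = 2, direction = "up"),
    list(probe_id = "LNC_0001", fc = 3, direction = "down"))), "conflicting")
  expect_error(small_cfg(planted_de = list(
    list(probe_id = "LNC_0001", fc = 0.5, direction = "up"))))
  expect_error(simulate_dataset(small_cfg(term_size_range = c(50, 60))),
               "universe")
  expect_error(small_cfg(planted_modules = list(
    list(lnc = "LNC_0001", mrna = "MRNA_0001", loading = 1.5))))
})

test_that("noiseless qPCR tables encode the planted fold change exactly", {
  cfg <- small_cfg(planted_de = list(
    list(probe_id = "LNC_0001", fc = 4, direction = "up"),
    list(probe_id = "LNC_0002", fc = 1, direction = "up")))
  truth <- simulate_dataset(cfg)$truth
  ct <- simulate_qpcr_ct(truth, c("LNC_0001", "LNC_0002"))
  r1 <- delta_delta_ct(ct, "GAPDH", "LNC_0001")
  expect_equal(r1$delta_delta_ct, -2)   # 2^2 = 4
  expect_equal(r1$relative_level, 4)
  r2 <- delta_delta_ct(ct, "GAPDH", "LNC_0002")
  expect_equal(r2$delta_delta_ct, 0)
  expect_equal(r2$relative_level, 1)
  ref <- ct[ct$gene == "GAPDH", ]
  expect_equal(mean(ref$Ct[ref$group == "case"]),
               mean(ref$Ct[ref$group == "control"]))
  expect_error(simulate_qpcr_ct(truth, character()), "empty")
  expect_error(simulate_qpcr_ct(truth, "LNC_0003"), "absent")
})
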