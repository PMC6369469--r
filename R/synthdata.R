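#' Configuration for the synthetic microarray generator
#'
#' Describes a two-group single-channel array experiment with known
#' ground truth. Intensities are log-normal: log2 intensity = per-probe
#' baseline + group effect + latent module factor + Gaussian noise,
#' exponentiated to the linear scale, so that a planted fold change is
#' exact in expectation on the ratio of linear group means.
#'
#' @param n_lnc_probes,n_mrna_probes Number of lncRNA / mRNA probes.
#' @param n_per_group Arrays per group (3 in the emulated design).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-probe
#'   baseline log2 intensity.
#' @param noise_log2_sd Per-observation Gaussian noise on the log2 scale.
#' @param planted_de List of planted differential probes, each
#'   `list(probe_id=, fc=, direction=)` with `fc >= 1` (magnitude) and
#'   direction `"up"` or `"down"` (case relative to control).
#' @param planted_modules List of latent-factor coexpression modules,
#'   each `list(lnc = <lnc probe ids>, mrna = <mrna probe ids>,
#'   loading = <value in [0,1]>)`. All probes of a module share one
#'   standard-normal factor per sample, scaled by the loading; at
#'   loading >= 0.9 and moderate noise the expected pairwise Pearson
#'   correlation exceeds 0.7.
#' @param n_terms Number of functional term sets to sample.
#' @param term_size_range Length-2 integer vector, min/max term size.
#' @param n_tfs Number of TF target sets. One designated TF per planted
#'   module receives at least 80 percent of that module's mRNA symbols
#'   as targets, so that enrichment recovery is testable.
#' @param tf_target_size_range Length-2 integer vector of TF set sizes.
#' @param seed Integer; fixed seed implies byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_lnc_probes = 300, n_mrna_probes = 900,
                       n_per_group = 3,
                       baseline_log2_mean = 8, baseline_log2_sd = 1.5,
                       noise_log2_sd = 0.25,
                       planted_de = list(), planted_modules = list(),
                       n_terms = 50, term_size_range = c(10, 40),
                       n_tfs = 40, tf_target_size_range = c(10, 50),
                       seed = 1) {
  cfg <- list(n_lnc_probes = as.integer(n_lnc_probes),
              n_mrna_probes = as.integer(n_mrna_probes),
              n_per_group = as.integer(n_per_group),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              noise_log2_sd = noise_log2_sd,
              planted_de = planted_de,
              planted_modules = planted_modules,
              n_terms = as.integer(n_terms),
              term_size_range = as.integer(term_size_range),
              n_tfs = as.integer(n_tfs),
              tf_target_size_range = as.integer(tf_target_size_range),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_lnc_probes > 0, n_mrna_probes > 0, n_per_group > 0,
              baseline_log2_sd >= 0, noise_log2_sd >= 0,
              n_terms > 0, n_tfs > 0,
              length(term_size_range) == 2, length(tf_target_size_range) == 2,
              all(term_size_range > 0), all(tf_target_size_range > 0))
  })
  for (d in cfg$planted_de) {
    stopifnot(is.character(d$probe_id), d$fc >= 1, d$direction %in% c("up", "down"))
  }
  dirs <- stats::setNames(vapply(cfg$planted_de, `[[`, "", "direction"),
                          vapply(cfg$planted_de, `[[`, "", "probe_id"))
  if (anyDuplicated(names(dirs))) {
    for (id in unique(names(dirs)[duplicated(names(dirs))])) {
      if (length(unique(dirs[names(dirs) == id])) > 1)
        stop("probe '", id, "' planted with conflicting directions")
    }
    stop("probe planted more than once in planted_de")
  }
  for (mod in cfg$planted_modules) {
    stopifnot(length(mod$lnc) >= 1, length(mod$mrna) >= 1,
              mod$loading >= 0, mod$loading <= 1)
  }
  structure(cfg, class = "sim_config")
}

#' A fully planted default configuration
#'
#' Emulates the statistical structure the pipeline assumes at desk
#' scale: 300 lncRNA and 900 mRNA probes over 3 + 3 arrays, 8
#' latent-factor modules (2 lncRNAs + 8 mRNAs each, loading 0.9) whose
#' members are all differentially expressed in the module's direction
#' (fold change 4, modules alternating up/down) so that, as in real
#' two-group arrays, coexpression is carried jointly by the shared
#' group contrast and the latent factor; 24 additional dysregulated
#' lncRNAs and 10 dysregulated mRNAs with fold changes between 2.5 and
#' 8; log2 noise 0.25; 50 functional terms and 40 TF target sets with
#' one planted TF per module.
#'
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
default_sim_config <- function(seed = 1) {
  lnc_ids <- sprintf("LNC_%04d", seq_len(300))
  mrna_ids <- sprintf("MRNA_%04d", seq_len(900))
  modules <- list()
  de <- list()
  for (i in seq_len(8)) {
    ml <- lnc_ids[(2 * i - 1):(2 * i)]
    mm <- mrna_ids[(8 * (i - 1) + 1):(8 * i)]
    modules[[i]] <- list(lnc = ml, mrna = mm, loading = 0.9)
    dirn <- if (i %% 2 == 1) "up" else "down"
    for (id in c(ml, mm))
      de[[length(de) + 1]] <- list(probe_id = id, fc = 4, direction = dirn)
  }
  extra_lnc <- lnc_ids[17:40]
  fcs <- rep(c(2.5, 3, 4, 5, 6, 8), length.out = 24)
  for (j in seq_along(extra_lnc)) {
    de[[length(de) + 1]] <- list(probe_id = extra_lnc[j], fc = fcs[j],
                                 direction = if (j %% 2) "up" else "down")
  }
  extra_mrna <- mrna_ids[101:110]
  for (j in seq_along(extra_mrna)) {
    de[[length(de) + 1]] <- list(probe_id = extra_mrna[j], fc = 2.5 + j %% 4,
                                 direction = if (j %% 2) "up" else "down")
  }
  sim_config(planted_de = de, planted_modules = modules, seed = seed)
}

#' Simulate a two-group microarray dataset with known ground truth
#'
#' Generates linear-scale probe intensities, a probe annotation, a
#' functional-term collection, a TF-target collection and the ground
#' truth of everything planted. Planted differential probes carry their
#' full log2 effect on the case group, so the expected linear-scale
#' ratio of group means equals the planted fold change; probes of a
#' planted module additionally share one standard-normal per-sample
#' factor scaled by the module loading. The term/TF gene universe is the
#' set of annotated mRNA gene symbols, sampled without replacement; the
#' designated TF of each planted module receives at least 80 percent of
#' the module's mRNA symbols as targets.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements `expr`
#'   (`ExpressionMatrix`, linear scale), `annotation` (data.frame),
#'   `terms` and `tf_targets` ([gene_set_db()]), and `truth` (list with
#'   `true_de`, `true_coexpr_pairs`, `tf_planted_links`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  lnc_ids <- sprintf("LNC_%04d", seq_len(cfg$n_lnc_probes))
  mrna_ids <- sprintf("MRNA_%04d", seq_len(cfg$n_mrna_probes))
  probe_ids <- c(lnc_ids, mrna_ids)
  known <- vapply(cfg$planted_de, `[[`, "", "probe_id")
  if (!all(known %in% probe_ids)) stop("planted_de references unknown probes")
  for (mod in cfg$planted_modules) {
    if (!all(mod$lnc %in% lnc_ids)) stop("module lnc ids must be lncRNA probes")
    if (!all(mod$mrna %in% mrna_ids)) stop("module mrna ids must be mRNA probes")
  }

  annotation <- data.frame(
    probe_id = probe_ids,
    molecule_type = rep(c("lncRNA", "mRNA"), c(cfg$n_lnc_probes, cfg$n_mrna_probes)),
    gene_symbol = c(sprintf("Lnc%04d", seq_len(cfg$n_lnc_probes)),
                    sprintf("Gene%04d", seq_len(cfg$n_mrna_probes))),
    stringsAsFactors = FALSE)
  sym_of <- stats::setNames(annotation$gene_symbol, annotation$probe_id)
  universe <- annotation$gene_symbol[annotation$molecule_type == "mRNA"]
  if (max(cfg$term_size_range) > length(universe) ||
      max(cfg$tf_target_size_range) > length(universe))
    stop("term/TF set sizes exceed the mRNA gene universe")

  n <- cfg$n_per_group
  sample_ids <- c(sprintf("case_%d", seq_len(n)), sprintf("control_%d", seq_len(n)))
  groups <- stats::setNames(rep(c("case", "control"), each = n), sample_ids)

  ## expression: baseline + group effect + latent factor + noise, on log2
  set.seed(component_seed(cfg$seed, "expression"))
  p <- length(probe_ids)
  baseline <- stats::rnorm(p, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  log2v <- matrix(baseline, p, 2 * n, dimnames = list(probe_ids, sample_ids))
  for (d in cfg$planted_de) {
    eff <- log2(d$fc) * if (d$direction == "up") 1 else -1
    log2v[d$probe_id, groups == "case"] <- log2v[d$probe_id, groups == "case"] + eff
  }
  for (mod in cfg$planted_modules) {
    f <- stats::rnorm(2 * n)   # one shared factor value per sample
    members <- c(mod$lnc, mod$mrna)
    log2v[members, ] <- log2v[members, ] +
      matrix(mod$loading * f, length(members), 2 * n, byrow = TRUE)
  }
  if (cfg$noise_log2_sd > 0)
    log2v <- log2v + matrix(stats::rnorm(p * 2 * n, 0, cfg$noise_log2_sd), p, 2 * n)
  expr <- expression_matrix(2^log2v, groups, "linear")

  ## functional terms over the mRNA symbol universe
  set.seed(component_seed(cfg$seed, "terms"))
  term_sizes <- sample(cfg$term_size_range[1]:cfg$term_size_range[2],
                       cfg$n_terms, replace = TRUE)
  cats <- rep(c("GO_BP", "GO_CC", "GO_MF", "KEGG"), length.out = cfg$n_terms)
  term_members <- lapply(term_sizes, function(s) sort(sample(universe, s)))
  terms <- gene_set_db(set_id = sprintf("TERM_%04d", seq_len(cfg$n_terms)),
                       name = sprintf("synthetic term %d", seq_len(cfg$n_terms)),
                       category = cats, members = term_members)

  ## TF target sets; designated TF per module gets >= 80% of its mRNA symbols
  set.seed(component_seed(cfg$seed, "tfs"))
  n_mod <- length(cfg$planted_modules)
  if (cfg$n_tfs < n_mod) stop("need at least one TF per planted module")
  tf_names <- sprintf("TF%03d", seq_len(cfg$n_tfs))
  tf_members <- vector("list", cfg$n_tfs)
  links <- list()
  for (i in seq_len(cfg$n_tfs)) {
    s <- sample(cfg$tf_target_size_range[1]:cfg$tf_target_size_range[2], 1)
    if (i <= n_mod) {
      mod <- cfg$planted_modules[[i]]
      mod_syms <- unname(sym_of[mod$mrna])
      take <- max(ceiling(0.8 * length(mod_syms)),
                  min(length(mod_syms), s))
      core <- sort(sample(mod_syms, min(take, length(mod_syms))))
      pad <- setdiff(universe, mod_syms)
      extra <- max(0L, s - length(core))
      tf_members[[i]] <- sort(c(core, sample(pad, min(extra, length(pad)))))
      for (l in mod$lnc)
        links[[length(links) + 1]] <- list(tf = tf_names[i], lnc_id = l)
    } else {
      tf_members[[i]] <- sort(sample(universe, s))
    }
  }
  tf_db <- gene_set_db(set_id = tf_names, name = tf_names,
                       category = rep("TF", cfg$n_tfs), members = tf_members)

  truth <- list(
    true_de = lapply(cfg$planted_de, function(d)
      list(probe_id = d$probe_id, direction = d$direction, fc = d$fc)),
    true_coexpr_pairs = do.call(rbind, c(list(
      data.frame(lnc_id = character(), mrna_id = character(),
                 sign = character(), stringsAsFactors = FALSE)),
      lapply(cfg$planted_modules, function(mod)
        expand.grid(lnc_id = mod$lnc, mrna_id = mod$mrna, sign = "positive",
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))),
    tf_planted_links = links)

  structure(list(expr = expr, annotation = annotation, terms = terms,
                 tf_targets = tf_db, truth = truth, config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d lncRNA + %d mRNA probes, %d + %d samples\n",
              x$config$n_lnc_probes, x$config$n_mrna_probes,
              x$config$n_per_group, x$config$n_per_group))
  cat(sprintf("  planted: %d DE probes, %d modules, %d TF links\n",
              length(x$truth$true_de), length(x$config$planted_modules),
              length(x$truth$tf_planted_links)))
  invisible(x)
}

#' Write every component of a simulated dataset to plain-text files
#'
#' Expression and annotation as TSV, term and TF collections as GMT,
#' ground truth as JSON. With a fixed seed the generator plus this
#' writer produce byte-identical files.
#'
#' @param ds A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_sim_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             groups = file.path(dir, "groups.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             terms = file.path(dir, "terms.gmt"),
             tf_targets = file.path(dir, "tf_targets.gmt"),
             truth = file.path(dir, "ground_truth.json"))
  write_expression_tsv(ds$expr, paths["expression"], paths["groups"])
  write_tsv(ds$annotation, paths["annotation"])
  write_gmt(ds$terms, paths["terms"])
  write_gmt(ds$tf_targets, paths["tf_targets"])
  jsonlite::write_json(ds$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Simulate a qPCR Ct table consistent with planted fold changes
#'
#' Produces cycle-threshold values such that the 2^-ddCt method recovers
#' each selected probe's planted fold change exactly under zero noise.
#' The reference gene ("GAPDH") has equal expected Ct in both groups; a
#' planted up-regulation of fold change F lowers the case-group target
#' Ct by log2(F) cycles (one cycle per doubling, ideal efficiency).
#'
#' @param truth Ground-truth list from [simulate_dataset()].
#' @param selected Character vector of planted DE probe ids to assay.
#' @param n_per_group Samples per group.
#' @param ct_sd Gaussian noise (cycles) added to every Ct; 0 = noiseless.
#' @param base_ct_target,base_ct_ref Baseline cycles for targets and the
#'   reference gene.
#' @param seed Integer seed (used only when `ct_sd > 0`).
#' @return A `data.frame` with columns `gene`, `sample`, `group`, `Ct`.
#' @export
simulate_qpcr_ct <- function(truth, selected, n_per_group = 3, ct_sd = 0,
                             base_ct_target = 28, base_ct_ref = 20, seed = 1) {
  if (length(selected) == 0) stop("empty probe selection")
  de <- truth$true_de
  ids <- vapply(de, `[[`, "", "probe_id")
  if (!all(selected %in% ids))
    stop("selected probes absent from ground truth: ",
         paste(setdiff(selected, ids), collapse = ", "))
  samples <- c(sprintf("case_%d", seq_len(n_per_group)),
               sprintf("control_%d", seq_len(n_per_group)))
  grp <- rep(c("case", "control"), each = n_per_group)
  rows <- list()
  for (pid in selected) {
    d <- de[[match(pid, ids)]]
    shift <- log2(d$fc) * if (d$direction == "up") 1 else -1
    ct <- ifelse(grp == "case", base_ct_target - shift, base_ct_target)
    rows[[length(rows) + 1]] <- data.frame(gene = pid, sample = samples,
                                           group = grp, Ct = ct,
                                           stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1]] <- data.frame(gene = "GAPDH", sample = samples,
                                         group = grp, Ct = base_ct_ref,
                                         stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  if (ct_sd > 0) {
    set.seed(component_seed(seed, "qpcr"))
    out$Ct <- out$Ct + stats::rnorm(nrow(out), 0, ct_sd)
  }
  rownames(out) <- NULL
  out
}
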