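#' Pipeline configuration
#'
#' All thresholds of the analysis in one validated object, defaulting
#' to the standard cut-offs: fold change >= 2.0 with p <= 0.05 for
#' differential expression, |r| >= 0.7 with p <= 0.05 for coexpression
#' edges, 100 + 100 seed lncRNAs for the coexpression network, the top
#' 5 TF pairs per lncRNA, and 10 + 10 seed lncRNAs with 2 + 2 links
#' each for the tripartite network.
#'
#' Inputs are either a [sim_config()] (the pipeline simulates its own
#' dataset, the default) or paths to an expression TSV, group sidecar,
#' probe annotation, term GMT and TF-target GMT, plus optionally a qPCR
#' Ct table.
#'
#' @param out_dir Run directory (created by [run_pipeline()]).
#' @param sim A [sim_config()], or `NULL` when file inputs are given.
#' @param expression_tsv,groups_tsv,annotation_tsv,term_gmt,tf_gmt,ct_tsv
#'   Input file paths (all but `ct_tsv` required when `sim` is `NULL`).
#' @param fc_min,p_max DE thresholds.
#' @param r_min,corr_p_max Coexpression thresholds.
#' @param k_up,k_down Seed lncRNAs for the coexpression network.
#' @param top_tf_k TF pairs per lncRNA.
#' @param k_up_tri,k_down_tri Seed lncRNAs for the tripartite network.
#' @param k_mrna,k_tf Links per lncRNA in the tripartite network.
#' @param welch,bh,p_only Test-variant flags (see
#'   [differential_expression()], [build_edges()]).
#' @param seed Integer seed driving every random stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = default_sim_config(seed),
                            expression_tsv = NULL, groups_tsv = NULL,
                            annotation_tsv = NULL, term_gmt = NULL,
                            tf_gmt = NULL, ct_tsv = NULL,
                            fc_min = 2.0, p_max = 0.05,
                            r_min = 0.7, corr_p_max = 0.05,
                            k_up = 100, k_down = 100, top_tf_k = 5,
                            k_up_tri = 10, k_down_tri = 10,
                            k_mrna = 2, k_tf = 2,
                            welch = FALSE, bh = FALSE, p_only = FALSE,
                            seed = 1) {
  stopifnot(fc_min >= 1, p_max > 0, p_max <= 1, r_min >= 0, r_min <= 1,
            corr_p_max > 0, corr_p_max <= 1,
            k_up >= 0, k_down >= 0, top_tf_k >= 0,
            k_up_tri >= 0, k_down_tri >= 0, k_mrna >= 0, k_tf >= 0)
  files <- c(expression_tsv, groups_tsv, annotation_tsv, term_gmt, tf_gmt, ct_tsv)
  if (is.null(sim)) {
    if (is.null(expression_tsv) || is.null(groups_tsv) || is.null(annotation_tsv) ||
        is.null(term_gmt) || is.null(tf_gmt))
      stop("without a sim config, all input file paths must be supplied")
  }
  for (f in files) if (!is.null(f) && !file.exists(f)) stop("input not found: ", f)
  structure(list(out_dir = out_dir, sim = sim,
                 expression_tsv = expression_tsv, groups_tsv = groups_tsv,
                 annotation_tsv = annotation_tsv, term_gmt = term_gmt,
                 tf_gmt = tf_gmt, ct_tsv = ct_tsv,
                 fc_min = fc_min, p_max = p_max,
                 r_min = r_min, corr_p_max = corr_p_max,
                 k_up = as.integer(k_up), k_down = as.integer(k_down),
                 top_tf_k = as.integer(top_tf_k),
                 k_up_tri = as.integer(k_up_tri), k_down_tri = as.integer(k_down_tri),
                 k_mrna = as.integer(k_mrna), k_tf = as.integer(k_tf),
                 welch = welch, bh = bh, p_only = p_only,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the six stages — normalize, diffexpr, qpcr, coexpress,
#' enrich, network — over simulated or file inputs, writes every stage
#' output as plain text under `cfg$out_dir`, and finishes with a
#' `manifest.json` recording the seed, every parameter and the MD5 of
#' every output file. Re-running the same configuration reproduces
#' byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)
  stages <- list()
  add_stage <- function(name, files) {
    stages[[length(stages) + 1]] <<- list(
      stage = name,
      outputs = lapply(files, function(f)
        list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  }

  ## inputs: simulate or load
  if (!is.null(cfg$sim)) {
    ds <- simulate_dataset(cfg$sim)
    dir.create(out("inputs"), showWarnings = FALSE)
    write_sim_dataset(ds, out("inputs"))
    expr <- ds$expr; annotation <- ds$annotation
    terms <- ds$terms; tf_db <- ds$tf_targets; truth <- ds$truth
  } else {
    expr <- read_expression_tsv(cfg$expression_tsv, cfg$groups_tsv)
    annotation <- read_annotation_tsv(cfg$annotation_tsv)
    terms <- read_gmt(cfg$term_gmt)
    tf_db <- read_gmt(cfg$tf_gmt, category = "TF")
    truth <- NULL
  }

  ## stage 1: normalize
  norm <- quantile_normalize(expr)
  write_expression_tsv(norm, out("normalized.tsv"), out("normalized_groups.tsv"))
  add_stage("normalize", c(out("normalized.tsv"), out("normalized_groups.tsv")))

  ## stage 2: differential expression + clustering order
  de <- differential_expression(norm, fc_min = cfg$fc_min, p_max = cfg$p_max,
                                welch = cfg$welch, bh = cfg$bh,
                                annotation = annotation)
  write_tsv(de, out("de_table.tsv"))
  de_lnc <- de[de$molecule_type == "lncRNA", , drop = FALSE]
  top <- select_top_warned(de_lnc, cfg$k_up, cfg$k_down)
  write_tsv(rbind(top$up, top$down), out("top_lncrnas.tsv"))
  sig <- de$probe_id[de$significant]
  files <- c(out("de_table.tsv"), out("top_lncrnas.tsv"))
  if (length(sig) >= 2) {
    cl <- hierarchical_cluster(norm, sig)
    writeLines(cl$order, out("cluster_order.txt"))
    files <- c(files, out("cluster_order.txt"))
  }
  add_stage("diffexpr", files)

  ## stage 3: qPCR concordance
  ct <- NULL
  if (!is.null(cfg$ct_tsv)) {
    ct <- read_ct_table(cfg$ct_tsv)
  } else if (!is.null(truth) && length(truth$true_de) > 0) {
    picks <- vapply(truth$true_de, `[[`, "", "probe_id")
    picks <- utils::head(picks[order(picks)], 4)
    ct <- simulate_qpcr_ct(truth, picks, n_per_group = sum(expr$groups == "case"),
                           seed = cfg$seed)
  }
  if (!is.null(ct)) {
    rel <- relative_expression(ct, "GAPDH")
    conc <- concordance(de, rel)
    rep_df <- conc$per_gene
    rep_df$delta_delta_ct <- rel$delta_delta_ct[match(rep_df$gene, rel$gene)]
    write_tsv(rep_df, out("qpcr_report.tsv"))
    add_stage("qpcr", out("qpcr_report.tsv"))
  } else {
    writeLines("no qPCR input", out("qpcr_report.tsv"))
    add_stage("qpcr", out("qpcr_report.tsv"))
  }

  ## stage 4: coexpression edges (log2 normalized signals, samples pooled)
  halves <- split_by_type(log2_transform(norm), annotation)
  edges <- suppressWarnings(build_edges(halves$lnc, halves$mrna,
                                        r_min = cfg$r_min, p_max = cfg$corr_p_max,
                                        p_only = cfg$p_only))
  write_tsv(edges, out("coexpression_edges.tsv"))
  add_stage("coexpress", out("coexpression_edges.tsv"))

  ## stage 5: enrichment — function prediction and TF association
  universe <- unique(annotation$gene_symbol[annotation$molecule_type == "mRNA"])
  top_ids <- c(top$up$probe_id, top$down$probe_id)
  partner_sets <- lapply(stats::setNames(top_ids, top_ids), function(l)
    partners(edges, l, annotation))
  fn_rows <- list()
  for (l in top_ids) {
    ps <- partner_sets[[l]]
    if (length(ps) == 0) next
    e <- utils::head(enrich(ps, terms, universe, bh = cfg$bh), 5)
    if (nrow(e)) fn_rows[[l]] <- cbind(lnc_id = l, e)
  }
  fn <- do.call(rbind, c(list(NULL), unname(fn_rows)))
  if (is.null(fn))
    fn <- data.frame(lnc_id = character(), set_id = character(),
                     name = character(), category = character(),
                     k = integer(), K = integer(), n = integer(), N = integer(),
                     p_value = numeric(), stringsAsFactors = FALSE)
  write_tsv(fn, out("predicted_functions.tsv"))
  pairs <- suppressMessages(
    lnc_tf_pairs(top_ids, partner_sets, tf_db, universe, top_k = cfg$top_tf_k))
  write_tsv(pairs, out("lnc_tf_pairs.tsv"))
  add_stage("enrich", c(out("predicted_functions.tsv"), out("lnc_tf_pairs.tsv")))

  ## stage 6: networks
  g1 <- build_lnc_mrna_network(top_ids, edges)
  g2 <- build_lnc_tf_network(pairs)
  tri_top <- select_top_warned(de_lnc, cfg$k_up_tri, cfg$k_down_tri)
  tri_ids <- c(tri_top$up$probe_id, tri_top$down$probe_id)
  g3 <- suppressMessages(build_lnc_target_tf_network(
    tri_ids, edges, pairs, k_mrna = cfg$k_mrna, k_tf = cfg$k_tf))
  net_files <- character()
  for (nm in c("coexpr", "tf", "tripartite")) {
    g <- switch(nm, coexpr = g1, tf = g2, tripartite = g3)
    for (fmt in c("tsv", "sif", "graphml")) {
      f <- out(sprintf("network_%s.%s", nm, fmt))
      export_graph(g, f, fmt)
      net_files <- c(net_files, f)
    }
  }
  stats_df <- do.call(rbind, lapply(list(coexpr = g1, tf = g2, tripartite = g3),
                                    function(g) as.data.frame(summary(g))))
  stats_df <- cbind(network = rownames(stats_df), stats_df)
  rownames(stats_df) <- NULL
  write_tsv(stats_df, out("network_stats.tsv"))
  add_stage("network", c(net_files, out("network_stats.tsv")))

  manifest <- list(
    seed = cfg$seed,
    parameters = cfg[c("fc_min", "p_max", "r_min", "corr_p_max", "k_up",
                       "k_down", "top_tf_k", "k_up_tri", "k_down_tri",
                       "k_mrna", "k_tf", "welch", "bh", "p_only")],
    simulated = !is.null(cfg$sim),
    stages = stages)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

# top-k selection that tolerates short supply quietly at pipeline scale
select_top_warned <- function(de, k_up, k_down) {
  suppressWarnings(select_top_k(de, k_up, k_down))
}
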