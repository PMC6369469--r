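#' Construct a typed heterogeneous network
#'
#' Nodes are lncRNAs, mRNAs or TFs; edges are signed coexpression links
#' (`coexpr_pos`/`coexpr_neg`, lncRNA-mRNA only, weighted by r),
#' TF-to-lncRNA regulation (`tf_regulates_lnc`, weighted by the
#' enrichment p) or lncRNA-to-target links (`lnc_targets_mrna`,
#' weighted by r). Graphs are simple per edge type: no duplicate
#' (source, target, edge_type) triple; parallel edges of different
#' types are allowed.
#'
#' @param nodes `data.frame` with columns `id`, `node_type`
#'   (`lncRNA`/`mRNA`/`TF`); ids unique.
#' @param edges `data.frame` with columns `source`, `target`,
#'   `edge_type`, `weight` (may have zero rows).
#' @return An object of class `typed_graph`.
#' @export
typed_graph <- function(nodes, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        edge_type = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
  stopifnot(is.data.frame(nodes), all(c("id", "node_type") %in% names(nodes)),
            all(c("source", "target", "edge_type", "weight") %in% names(edges)))
  nodes <- nodes[, c("id", "node_type")]
  edges <- edges[, c("source", "target", "edge_type", "weight")]
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(nodes$node_type %in% c("lncRNA", "mRNA", "TF")))
    stop("node_type must be lncRNA, mRNA or TF")
  if (!all(edges$edge_type %in% c("coexpr_pos", "coexpr_neg",
                                  "tf_regulates_lnc", "lnc_targets_mrna")))
    stop("unknown edge_type")
  if (!all(c(edges$source, edges$target) %in% nodes$id))
    stop("edge endpoint not in node table")
  if (anyDuplicated(edges[c("source", "target", "edge_type")]))
    stop("duplicate (source, target, edge_type) edge")
  ty <- stats::setNames(nodes$node_type, nodes$id)
  co <- edges$edge_type %in% c("coexpr_pos", "coexpr_neg", "lnc_targets_mrna")
  if (any(co) && !all(ty[edges$source[co]] == "lncRNA" & ty[edges$target[co]] == "mRNA"))
    stop("coexpression/target edges must run lncRNA -> mRNA")
  tf <- edges$edge_type == "tf_regulates_lnc"
  if (any(tf) && !all(ty[edges$source[tf]] == "TF" & ty[edges$target[tf]] == "lncRNA"))
    stop("regulation edges must run TF -> lncRNA")
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "typed_graph")
}

#' @export
print.typed_graph <- function(x, ...) {
  tn <- table(factor(x$nodes$node_type, c("lncRNA", "mRNA", "TF")))
  te <- table(factor(x$edges$edge_type,
                     c("coexpr_pos", "coexpr_neg", "tf_regulates_lnc",
                       "lnc_targets_mrna")))
  cat(sprintf("typed_graph: %d nodes (%d lncRNA, %d mRNA, %d TF), %d edges\n",
              nrow(x$nodes), tn[1], tn[2], tn[3], nrow(x$edges)))
  cat(sprintf("  coexpr +%d / -%d, TF->lnc %d, lnc->target %d\n",
              te[1], te[2], te[3], te[4]))
  invisible(x)
}

#' Summary counts of a typed graph
#'
#' @param object A [typed_graph()].
#' @param ... Unused.
#' @return Named list of node/edge counts and the positive/negative
#'   coexpression split.
#' @export
summary.typed_graph <- function(object, ...) {
  e <- object$edges
  list(n_nodes = nrow(object$nodes),
       n_edges = nrow(e),
       n_positive = sum(e$edge_type == "coexpr_pos"),
       n_negative = sum(e$edge_type == "coexpr_neg"),
       n_tf_edges = sum(e$edge_type == "tf_regulates_lnc"),
       n_target_edges = sum(e$edge_type == "lnc_targets_mrna"))
}

#' Coexpression network around selected lncRNAs
#'
#' Keeps every retained correlation edge incident to the seed lncRNAs
#' (typically the top 100 up- plus 100 down-regulated ones). Seed
#' lncRNAs without edges remain as isolated nodes; mRNAs linked to
#' several lncRNAs appear once.
#'
#' @param top_lnc Character vector of seed lncRNA probe ids.
#' @param edges Edge table from [build_edges()].
#' @return A [typed_graph()] with coexpression edges weighted by r.
#' @export
build_lnc_mrna_network <- function(top_lnc, edges) {
  e <- edges[edges$lnc_id %in% top_lnc, , drop = FALSE]
  if (nrow(e) == 0) message("no retained edges incident to the seed lncRNAs")
  nodes <- data.frame(
    id = c(sort(unique(top_lnc)), sort(unique(e$mrna_id))),
    node_type = rep(c("lncRNA", "mRNA"),
                    c(length(unique(top_lnc)), length(unique(e$mrna_id)))),
    stringsAsFactors = FALSE)
  ed <- data.frame(source = e$lnc_id, target = e$mrna_id,
                   edge_type = ifelse(e$sign == "positive", "coexpr_pos", "coexpr_neg"),
                   weight = e$r, stringsAsFactors = FALSE)
  typed_graph(nodes, ed)
}

#' Bipartite TF-to-lncRNA regulation network
#'
#' @param pairs Pair table from [lnc_tf_pairs()] (the top-k lowest-p TF
#'   associations per lncRNA).
#' @return A [typed_graph()] with `tf_regulates_lnc` edges weighted by
#'   the enrichment p-value.
#' @export
build_lnc_tf_network <- function(pairs) {
  nodes <- data.frame(
    id = c(sort(unique(pairs$lnc_id)), sort(unique(pairs$tf))),
    node_type = rep(c("lncRNA", "TF"),
                    c(length(unique(pairs$lnc_id)), length(unique(pairs$tf)))),
    stringsAsFactors = FALSE)
  ed <- data.frame(source = pairs$tf, target = pairs$lnc_id,
                   edge_type = rep("tf_regulates_lnc", nrow(pairs)),
                   weight = pairs$p_value, stringsAsFactors = FALSE)
  typed_graph(nodes, ed)
}

#' Tripartite lncRNA-target-TF network
#'
#' For each seed lncRNA (typically the top 10 up- plus 10 down-
#' regulated): its `k_mrna` lowest-p coexpression edges become
#' `lnc_targets_mrna` links and its `k_tf` lowest-p TF associations
#' become `tf_regulates_lnc` links, merged into one graph. A lncRNA
#' missing from either source keeps whatever edges are available
#' (reported via message). Ties break by ascending p, descending
#' magnitude (|r| or overlap), ascending partner id.
#'
#' @param top_lnc Seed lncRNA probe ids.
#' @param edges Edge table from [build_edges()].
#' @param pairs Pair table from [lnc_tf_pairs()].
#' @param k_mrna,k_tf Links of each kind kept per lncRNA.
#' @return A [typed_graph()].
#' @export
build_lnc_target_tf_network <- function(top_lnc, edges, pairs,
                                        k_mrna = 2, k_tf = 2) {
  stopifnot(k_mrna >= 0, k_tf >= 0)
  mr_rows <- list(); tf_rows <- list()
  for (l in top_lnc) {
    e <- edges[edges$lnc_id == l, , drop = FALSE]
    p <- pairs[pairs$lnc_id == l, , drop = FALSE]
    if (nrow(e) == 0 && nrow(p) == 0)
      message("lncRNA ", l, " absent from both edge and TF-pair tables")
    if (nrow(e) > 0 && k_mrna > 0) {
      e <- e[rank_order(e$p_value, abs(e$r), e$mrna_id), , drop = FALSE]
      e <- utils::head(e, k_mrna)
      mr_rows[[l]] <- data.frame(source = e$lnc_id, target = e$mrna_id,
                                 edge_type = "lnc_targets_mrna", weight = e$r,
                                 stringsAsFactors = FALSE)
    }
    if (nrow(p) > 0 && k_tf > 0) {
      p <- p[rank_order(p$p_value, p$k, p$tf), , drop = FALSE]
      p <- utils::head(p, k_tf)
      tf_rows[[l]] <- data.frame(source = p$tf, target = p$lnc_id,
                                 edge_type = "tf_regulates_lnc", weight = p$p_value,
                                 stringsAsFactors = FALSE)
    }
  }
  ed <- do.call(rbind, c(list(data.frame(source = character(), target = character(),
                                         edge_type = character(), weight = numeric(),
                                         stringsAsFactors = FALSE)),
                         unname(mr_rows), unname(tf_rows)))
  nodes <- data.frame(
    id = c(sort(unique(top_lnc)),
           sort(unique(ed$target[ed$edge_type == "lnc_targets_mrna"])),
           sort(unique(ed$source[ed$edge_type == "tf_regulates_lnc"]))),
    stringsAsFactors = FALSE)
  nodes$node_type <- rep(c("lncRNA", "mRNA", "TF"),
                         c(length(unique(top_lnc)),
                           length(unique(ed$target[ed$edge_type == "lnc_targets_mrna"])),
                           length(unique(ed$source[ed$edge_type == "tf_regulates_lnc"]))))
  typed_graph(nodes, ed)
}

#' Export a typed graph
#'
#' Three Cytoscape-readable formats: `tsv` (edge table with node types;
#' lossless, see [import_graph()]), `sif` (source, interaction label,
#' target; isolated nodes on their own line) and `graphml` (full node
#' and edge attributes, numeric values at full precision).
#'
#' @param g A [typed_graph()].
#' @param path Output file path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(g, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(g, "typed_graph"))
  format <- match.arg(format)
  ty <- stats::setNames(g$nodes$node_type, g$nodes$id)
  iso <- setdiff(g$nodes$id, c(g$edges$source, g$edges$target))
  if (format == "tsv") {
    df <- data.frame(source = g$edges$source,
                     source_type = unname(ty[g$edges$source]),
                     target = g$edges$target,
                     target_type = unname(ty[g$edges$target]),
                     edge_type = g$edges$edge_type,
                     weight = g$edges$weight, stringsAsFactors = FALSE)
    if (length(iso))
      df <- rbind(df, data.frame(source = iso, source_type = unname(ty[iso]),
                                 target = NA_character_, target_type = NA_character_,
                                 edge_type = NA_character_, weight = NA_real_,
                                 stringsAsFactors = FALSE))
    write_tsv(df, path)
  } else if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", g$edges$source, g$edges$edge_type, g$edges$target)
    writeLines(c(lines, iso), path)
  } else {
    writeLines(graphml_text(g), path)
  }
  invisible(path)
}

# GraphML serialization with %.17g weights so doubles round-trip exactly.
graphml_text <- function(g) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  head <- c('<?xml version="1.0" encoding="UTF-8"?>',
            '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
            '  <key id="d0" for="node" attr.name="node_type" attr.type="string"/>',
            '  <key id="d1" for="edge" attr.name="edge_type" attr.type="string"/>',
            '  <key id="d2" for="edge" attr.name="weight" attr.type="double"/>',
            '  <graph id="G" edgedefault="directed">')
  nodes <- sprintf('    <node id="%s"><data key="d0">%s</data></node>',
                   esc(g$nodes$id), esc(g$nodes$node_type))
  edges <- if (nrow(g$edges)) sprintf(
    '    <edge source="%s" target="%s"><data key="d1">%s</data><data key="d2">%s</data></edge>',
    esc(g$edges$source), esc(g$edges$target), esc(g$edges$edge_type),
    num_fmt(g$edges$weight)) else character()
  c(head, nodes, edges, "  </graph>", "</graphml>")
}

#' Import a typed graph written by [export_graph()]
#'
#' Lossless round-trip for the `tsv` and `graphml` formats (SIF does
#' not carry node types or weights and is export-only).
#'
#' @param path File path.
#' @param format `"tsv"` or `"graphml"`.
#' @return A [typed_graph()].
#' @export
import_graph <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv(path, colClasses = c(weight = "numeric"))
    iso <- is.na(df$target)
    nd <- unique(rbind(
      data.frame(id = df$source, node_type = df$source_type, stringsAsFactors = FALSE),
      data.frame(id = df$target[!iso], node_type = df$target_type[!iso],
                 stringsAsFactors = FALSE)))
    nd <- nd[order(match(nd$node_type, c("lncRNA", "mRNA", "TF")), nd$id), ]
    ed <- df[!iso, c("source", "target", "edge_type", "weight")]
    return(typed_graph(nd, ed))
  }
  doc <- xml2::read_xml(path)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  nx <- xml2::xml_find_all(doc, ".//g:node", ns)
  nd <- data.frame(id = xml2::xml_attr(nx, "id"),
                   node_type = xml2::xml_text(xml2::xml_find_first(nx, "./g:data[@key='d0']", ns)),
                   stringsAsFactors = FALSE)
  ex <- xml2::xml_find_all(doc, ".//g:edge", ns)
  ed <- data.frame(source = xml2::xml_attr(ex, "source"),
                   target = xml2::xml_attr(ex, "target"),
                   edge_type = xml2::xml_text(xml2::xml_find_first(ex, "./g:data[@key='d1']", ns)),
                   weight = as.numeric(xml2::xml_text(xml2::xml_find_first(ex, "./g:data[@key='d2']", ns))),
                   stringsAsFactors = FALSE)
  typed_graph(nd, ed)
}
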