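# GraphML persistence of the clonal graph.
#
# Fixed, versioned key set (schema 1.0): node keys kind, UniqueID, clu_id,
# cons_seq, num_aln, max_aln_score, seq_len, weight, shear, tag, combo,
# chrom, coordinate, strand, searchlabel, label_text, meta (sample
# metadata, flattened k=v pairs); edge keys kind, rule_id, n_links,
# target_id, centroid, offset, aln_score, rank, is_main. Dumps of the same
# graph are byte-identical modulo node ordering (nodes and edges are
# written in sorted order, so in practice byte-identical).

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

GRAPHML_NODE_KEYS <- c(kind = "string", UniqueID = "string",
                       clu_id = "string", cons_seq = "string",
                       num_aln = "int", max_aln_score = "double",
                       seq_len = "int", weight = "int", shear = "int",
                       tag = "int", combo = "int", chrom = "string",
                       coordinate = "long", strand = "string",
                       searchlabel = "string", label_text = "string",
                       meta = "string", order = "int")
GRAPHML_EDGE_KEYS <- c(kind = "string", rule_id = "int", n_links = "int",
                       target_id = "string", centroid = "int",
                       offset = "int", aln_score = "double", rank = "int")

fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)

# Flatten sample metadata (minus UniqueID) to "k=v" pairs, tab-separated.
meta_flatten <- function(attrs) {
  attrs <- attrs[setdiff(names(attrs), "UniqueID")]
  if (!length(attrs)) return("")
  attrs <- attrs[order(names(attrs))]
  paste(vapply(names(attrs), function(n)
    paste0(n, "=", as.character(attrs[[n]])), character(1)),
    collapse = "\t")
}

meta_unflatten <- function(s) {
  if (!nzchar(s)) return(list())
  kv <- strsplit(strsplit(s, "\t", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- lapply(kv, function(x) paste(x[-1], collapse = "="))
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}

#' Export a clonal graph to GraphML
#'
#' Writes the full graph -- all four node kinds, all six edge kinds, every
#' attribute -- as GraphML with the package's fixed key set, so that
#' [import_graphml()] reconstructs a structurally and attribute-wise
#' identical graph.
#'
#' @param g A [clonal_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(g, path) {
  datum <- function(key, val)
    sprintf("<data key=\"%s\">%s</data>", key, xml_escape(val))
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">")
  lines <- c(lines,
    sprintf("<key id=\"n_%s\" for=\"node\" attr.name=\"%s\" attr.type=\"%s\"/>",
            names(GRAPHML_NODE_KEYS), names(GRAPHML_NODE_KEYS),
            GRAPHML_NODE_KEYS),
    sprintf("<key id=\"e_%s\" for=\"edge\" attr.name=\"%s\" attr.type=\"%s\"/>",
            names(GRAPHML_EDGE_KEYS), names(GRAPHML_EDGE_KEYS),
            GRAPHML_EDGE_KEYS),
    "<graph id=\"clonal_graph\" edgedefault=\"directed\">")
  nid <- function(kind, key) xml_escape(paste0(kind, "::", key))
  for (s in sort(g$sample_order)) {
    lines <- c(lines, sprintf("<node id=\"%s\">%s%s%s%s</node>",
      nid("sample", s), datum("n_kind", "sample"),
      datum("n_UniqueID", s), datum("n_meta", meta_flatten(g$samples[[s]])),
      datum("n_order", fmt_num(match(s, g$sample_order)))))
  }
  for (u in sort(ls(g$subg, all.names = TRUE))) {
    node <- g$subg[[u]]
    lines <- c(lines, sprintf("<node id=\"%s\">%s</node>", nid("subg", u),
      paste0(datum("n_kind", "subg"), datum("n_clu_id", node$clu_id),
             datum("n_cons_seq", node$cons_seq),
             datum("n_num_aln", fmt_num(node$num_aln)),
             datum("n_max_aln_score", fmt_num(node$max_aln_score)),
             datum("n_seq_len", fmt_num(node$seq_len)),
             datum("n_weight", fmt_num(node$weight)),
             datum("n_shear", fmt_num(node$shear)),
             datum("n_tag", fmt_num(node$tag)),
             datum("n_combo", fmt_num(node$combo)))))
  }
  for (k in sort(ls(g$pos, all.names = TRUE))) {
    p <- g$pos[[k]]
    lines <- c(lines, sprintf("<node id=\"%s\">%s</node>", nid("pos", k),
      paste0(datum("n_kind", "pos"), datum("n_chrom", p$chrom),
             datum("n_coordinate", fmt_num(p$coordinate)),
             datum("n_strand", p$strand),
             datum("n_searchlabel", p$searchlabel))))
  }
  for (lb in sort(ls(g$labels, all.names = TRUE))) {
    lines <- c(lines, sprintf("<node id=\"%s\">%s%s</node>",
      nid("label", lb), datum("n_kind", "label"),
      datum("n_label_text", lb)))
  }
  edge <- function(src, tgt, data)
    sprintf("<edge source=\"%s\" target=\"%s\">%s</edge>", src, tgt, data)
  for (u in sort(ls(g$subg, all.names = TRUE))) {
    node <- g$subg[[u]]
    lines <- c(lines, edge(nid("sample", node$sample), nid("subg", u),
                           datum("e_kind", "sample2subg")))
    for (i in seq_along(node$targets)) {
      t <- node$targets[[i]]
      k <- pos_key(t$chrom, t$coordinate, t$strand)
      lines <- c(lines, edge(nid("subg", u), nid("pos", k),
        paste0(datum("e_kind", "insertion"),
               datum("e_target_id", t$target_id),
               datum("e_centroid", fmt_num(t$centroid)),
               datum("e_offset", fmt_num(t$offset)),
               datum("e_aln_score", fmt_num(t$aln_score)),
               datum("e_rank", fmt_num(i)))))
    }
    if (!is.na(node$main_pos))
      lines <- c(lines, edge(nid("subg", u), nid("pos", node$main_pos),
                             datum("e_kind", "main_insertion")))
    for (lb in node$labels)
      lines <- c(lines, edge(nid("subg", u), nid("label", lb),
                             datum("e_kind", "repeat")))
  }
  ge <- gtris_edges(g)
  if (nrow(ge)) {
    lines <- c(lines, edge(nid("subg", ge$a), nid("subg", ge$b),
      paste0(datum("e_kind", "gtris"),
             vapply(ge$rule_id, function(r) datum("e_rule_id", fmt_num(r)),
                    character(1)))))
  }
  for (sk in sort(ls(g$gtris_sample, all.names = TRUE))) {
    sp <- strsplit(sk, "\x1f", fixed = TRUE)[[1]]
    lines <- c(lines, edge(nid("sample", sp[1]), nid("sample", sp[2]),
      paste0(datum("e_kind", "gtris_sample"),
             datum("e_n_links", fmt_num(g$gtris_sample[[sk]])))))
  }
  lines <- c(lines, "</graph>", "</graphml>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

node_data_map <- function(xnode) {
  kids <- xml2::xml_find_all(xnode, "./data")
  stats::setNames(xml2::xml_text(kids), xml2::xml_attr(kids, "key"))
}

#' Import a clonal graph from GraphML
#'
#' Reads a dump written by [export_graphml()] and rebuilds the graph,
#' including indexes; `import_graphml(export_graphml(g))` is structurally
#' and attribute-wise equal to `g` (identical
#' [canonical_serialization()]).
#'
#' @param path GraphML file path.
#' @return A [clonal_graph()].
#' @export
import_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  g <- clonal_graph()
  nodes <- xml2::xml_find_all(doc, "//node")
  subg_raw <- new.env(parent = emptyenv())
  sample_order_idx <- integer(0)
  for (xn in nodes) {
    d <- node_data_map(xn)
    id <- xml2::xml_attr(xn, "id")
    kind <- d[["n_kind"]]
    key <- sub("^[a-z]+::", "", id)
    if (is.na(kind) || !kind %in% c("sample", "subg", "pos", "label"))
      ct_error(sprintf("unknown node kind '%s' in GraphML", kind),
               "clonetracker_format_error")
    if (kind == "sample") {
      attrs <- meta_unflatten(if (is.na(d["n_meta"])) "" else d[["n_meta"]])
      attrs$UniqueID <- d[["n_UniqueID"]]
      g$samples[[d[["n_UniqueID"]]]] <- attrs
      ord <- if (is.na(d["n_order"])) NA_integer_
             else as.integer(d[["n_order"]])
      sample_order_idx[[d[["n_UniqueID"]]]] <- ord
    } else if (kind == "pos") {
      upsert_pos(g, key = key)
    } else if (kind == "label") {
      upsert_label(g, d[["n_label_text"]])
    } else {
      subg_raw[[key]] <- list(
        clu_id = d[["n_clu_id"]],
        cons_seq = if (is.na(d["n_cons_seq"])) "" else d[["n_cons_seq"]],
        num_aln = as.integer(d[["n_num_aln"]]),
        max_aln_score = as.numeric(d[["n_max_aln_score"]]),
        seq_len = as.integer(d[["n_seq_len"]]),
        weight = as.integer(d[["n_weight"]]),
        shear = as.integer(d[["n_shear"]]),
        tag = as.integer(d[["n_tag"]]),
        combo = as.integer(d[["n_combo"]]),
        sample = NA_character_, targets = list(),
        ranks = integer(0), labels = character(0),
        main_pos = NA_character_)
    }
  }
  ids <- names(sample_order_idx)
  g$sample_order <- if (length(ids) && !anyNA(sample_order_idx))
    ids[order(sample_order_idx)] else sort(ids)
  edges <- xml2::xml_find_all(doc, "//edge")
  gtris_list <- list()
  for (xe in edges) {
    d <- node_data_map(xe)
    kind <- d[["e_kind"]]
    src <- sub("^[a-z]+::", "", xml2::xml_attr(xe, "source"))
    tgt <- sub("^[a-z]+::", "", xml2::xml_attr(xe, "target"))
    if (kind == "sample2subg") {
      subg_raw[[tgt]]$sample <- src
    } else if (kind == "insertion") {
      p <- parse_pos_key(tgt)
      t <- target_record(p$chrom, p$coordinate, p$strand,
                         aln_score = as.numeric(d[["e_aln_score"]]),
                         target_id = d[["e_target_id"]],
                         centroid = as.integer(d[["e_centroid"]]),
                         offset = as.integer(d[["e_offset"]]))
      node <- subg_raw[[src]]
      node$targets <- c(node$targets, list(t))
      node$ranks <- c(node$ranks, as.integer(d[["e_rank"]]))
      subg_raw[[src]] <- node
    } else if (kind == "main_insertion") {
      subg_raw[[src]]$main_pos <- tgt
    } else if (kind == "repeat") {
      subg_raw[[src]]$labels <- c(subg_raw[[src]]$labels, tgt)
    } else if (kind == "gtris") {
      gtris_list[[length(gtris_list) + 1]] <-
        list(a = src, b = tgt, rule_id = as.integer(d[["e_rule_id"]]))
    } else if (kind == "gtris_sample") {
      sp <- canonical_pair(src, tgt)
      g$gtris_sample[[paste(sp[1], sp[2], sep = "\x1f")]] <-
        as.integer(d[["e_n_links"]])
    } else {
      ct_error(sprintf("unknown edge kind '%s' in GraphML", kind),
               "clonetracker_format_error")
    }
  }
  for (u in ls(subg_raw, all.names = TRUE)) {
    node <- subg_raw[[u]]
    if (length(node$targets))
      node$targets <- node$targets[order(node$ranks)]
    node$ranks <- NULL
    node$labels <- sort(node$labels)
    node$uid <- u
    node$pos_keys <- vapply(node$targets, function(t)
      pos_key(t$chrom, t$coordinate, t$strand), character(1))
    class(node) <- "subgraph_record"
    g$subg[[u]] <- node
    for (k in unique(node$pos_keys)) idx_append(g$idx_pos, k, u)
    for (lb in node$labels) idx_append(g$idx_label, lb, u)
    idx_append(g$idx_sample, node$sample, u)
  }
  for (e in gtris_list) {
    pr <- canonical_pair(e$a, e$b)
    g$gtris[[paste(pr[1], pr[2], sep = "\x1f")]] <-
      list(a = pr[1], b = pr[2], rule_id = e$rule_id)
  }
  g
}
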