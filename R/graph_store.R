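# Typed in-memory property graph for clonal tracking.
#
# Four node kinds: sample, subg (IS cluster), pos (genomic position,
# keyed chrom_coordinate_strand), label (repeat annotation). Six edge
# kinds: sample2subg, insertion, main_insertion, repeat, gtris (same-clone
# link between subg of distinct samples, annotated with the matching rule
# that fired) and gtris_sample (sample-level consequence of gtris links,
# annotated with the number of supporting links).
#
# The graph is an environment with reference semantics: insertion mutates
# in place, as an import engine must. insertion/main_insertion/repeat edges
# are stored on the subg records themselves (targets, main_pos, labels);
# pos/label/sample indexes give exact candidate retrieval.

#' Create an empty clonal tracking graph
#'
#' @return An object of class `clonal_graph` (environment, mutable).
#' @export
clonal_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$samples <- new.env(parent = emptyenv())      # UniqueID -> attr list
  g$sample_order <- character()
  g$subg <- new.env(parent = emptyenv())         # uid -> record + derived
  g$pos <- new.env(parent = emptyenv())          # key -> pos attrs
  g$labels <- new.env(parent = emptyenv())       # label -> TRUE
  g$idx_pos <- new.env(parent = emptyenv())      # key -> subg uids
  g$idx_label <- new.env(parent = emptyenv())    # label -> subg uids
  g$idx_sample <- new.env(parent = emptyenv())   # UniqueID -> subg uids
  g$gtris <- new.env(parent = emptyenv())        # "a\x1fb" -> list(a,b,rule)
  g$gtris_sample <- new.env(parent = emptyenv()) # "sA\x1fsB" -> n links
  class(g) <- "clonal_graph"
  g
}

subg_uid <- function(sample_id, clu_id) paste(sample_id, clu_id, sep = "::")

#' Idempotently create a position node
#'
#' The same key always maps to the same node; keys differing only by strand
#' are distinct positions.
#'
#' @param g A [clonal_graph()].
#' @param chrom,coordinate,strand Locus; or pass a prebuilt key via `key`.
#' @param key Optional `<chrom>_<coordinate>_<strand>` key.
#' @return The position key, invisibly usable as node id.
#' @export
upsert_pos <- function(g, chrom = NULL, coordinate = NULL, strand = "*",
                       key = NULL) {
  if (is.null(key)) key <- pos_key(chrom, coordinate, strand)
  if (is.null(g$pos[[key]])) {
    p <- parse_pos_key(key)
    g$pos[[key]] <- list(chrom = p$chrom, coordinate = p$coordinate,
                         strand = p$strand,
                         searchlabel = pos_searchlabel(p$chrom, p$coordinate))
  }
  key
}

#' Idempotently create a label node
#'
#' @param g A [clonal_graph()].
#' @param text Label string.
#' @return The label, usable as node id.
#' @export
upsert_label <- function(g, text) {
  if (!nzchar(text))
    ct_error("label must be non-empty", "clonetracker_schema_error")
  if (is.null(g$labels[[text]])) g$labels[[text]] <- TRUE
  text
}

idx_append <- function(idx, key, uid) {
  idx[[key]] <- c(idx[[key]], uid)
  invisible(NULL)
}

# Low-level insertion of one validated record under an existing sample.
# Computes pos keys, upserts pos/label nodes, fills indexes and assigns the
# dominant alignment. Returns the number of new pos nodes created.
add_subg_node <- function(g, sample_id, rec, cfg) {
  uid <- subg_uid(sample_id, rec$clu_id)
  if (!is.null(g$subg[[uid]]))
    ct_error(sprintf("duplicate clu_id '%s' in sample '%s'",
                     rec$clu_id, sample_id), "clonetracker_import_error")
  new_pos <- 0L
  keys <- character(length(rec$targets))
  for (i in seq_along(rec$targets)) {
    t <- rec$targets[[i]]
    k <- pos_key(t$chrom, t$coordinate, t$strand)
    if (is.null(g$pos[[k]])) new_pos <- new_pos + 1L
    upsert_pos(g, key = k)
    keys[i] <- k
  }
  main <- select_main_insertion(rec$targets, cfg$threshold)
  main_key <- if (is.null(main)) NA_character_
              else pos_key(main$chrom, main$coordinate, main$strand)
  node <- rec
  node$sample <- sample_id
  node$uid <- uid
  node$pos_keys <- keys
  node$main_pos <- main_key
  g$subg[[uid]] <- node
  for (k in unique(keys)) idx_append(g$idx_pos, k, uid)
  for (lb in rec$labels) {
    upsert_label(g, lb)
    idx_append(g$idx_label, lb, uid)
  }
  idx_append(g$idx_sample, sample_id, uid)
  new_pos
}

#' Candidate clones sharing a position or a label
#'
#' Returns all subg reachable from the given subg through one pos or one
#' label node, excluding the subg itself and all subg of the same sample.
#' Exact by index construction: no false negatives against a full scan.
#'
#' @param g A [clonal_graph()].
#' @param uid Subg node id (`<sample>::<clu_id>`).
#' @return Character vector of subg uids (possibly empty), sorted.
#' @export
subgs_sharing_pos_or_label <- function(g, uid) {
  node <- g$subg[[uid]]
  if (is.null(node))
    ct_error(sprintf("unknown subg '%s'", uid), "clonetracker_lookup_error")
  hits <- character(0)
  for (k in unique(node$pos_keys)) hits <- c(hits, g$idx_pos[[k]])
  for (lb in node$labels) hits <- c(hits, g$idx_label[[lb]])
  hits <- unique(hits)
  hits <- hits[hits != uid]
  if (length(hits)) {
    same <- vapply(hits, function(h) g$subg[[h]]$sample, character(1)) ==
      node$sample
    hits <- hits[!same]
  }
  sort(hits)
}

canonical_pair <- function(a, b) {
  if (a < b) c(a, b) else c(b, a)
}

add_gtris_edge <- function(g, a, b, rule_id) {
  pr <- canonical_pair(a, b)
  key <- paste(pr[1], pr[2], sep = "\x1f")
  if (!is.null(g$gtris[[key]])) return(FALSE)
  sa <- g$subg[[pr[1]]]$sample
  sb <- g$subg[[pr[2]]]$sample
  if (identical(sa, sb))
    ct_error("gtris edges cannot connect subg of the same sample",
             "clonetracker_import_error")
  g$gtris[[key]] <- list(a = pr[1], b = pr[2], rule_id = as.integer(rule_id))
  sp <- canonical_pair(sa, sb)
  skey <- paste(sp[1], sp[2], sep = "\x1f")
  n <- g$gtris_sample[[skey]]
  g$gtris_sample[[skey]] <- if (is.null(n)) 1L else n + 1L
  TRUE
}

#' Node and edge counts, by kind, plus the single-position subg fraction
#'
#' @param g A [clonal_graph()].
#' @return A list of counts: samples, subg, pos, labels, the six edge
#'   kinds, and `single_pos_fraction` (fraction of subg with exactly one
#'   insertion link; `NA` on an empty graph).
#' @export
graph_stats <- function(g) {
  uids <- ls(g$subg, all.names = TRUE)
  n_ins <- 0L; n_main <- 0L; n_rep <- 0L; n_single <- 0L
  for (u in uids) {
    node <- g$subg[[u]]
    n_ins <- n_ins + length(node$pos_keys)
    if (!is.na(node$main_pos)) n_main <- n_main + 1L
    n_rep <- n_rep + length(node$labels)
    if (length(node$pos_keys) == 1L) n_single <- n_single + 1L
  }
  list(samples = length(g$sample_order),
       subg = length(uids),
       pos = length(ls(g$pos, all.names = TRUE)),
       labels = length(ls(g$labels, all.names = TRUE)),
       sample2subg = length(uids),
       insertion = n_ins,
       main_insertion = n_main,
       repeat_links = n_rep,
       gtris = length(ls(g$gtris, all.names = TRUE)),
       gtris_sample = length(ls(g$gtris_sample, all.names = TRUE)),
       single_pos_fraction = if (length(uids)) n_single / length(uids)
                             else NA_real_)
}

#' All gtris links as a data frame
#'
#' @param g A [clonal_graph()].
#' @return Data frame with columns `a`, `b` (canonically ordered subg uids)
#'   and `rule_id`, sorted by (`a`, `b`).
#' @export
gtris_edges <- function(g) {
  keys <- ls(g$gtris, all.names = TRUE)
  if (!length(keys))
    return(data.frame(a = character(), b = character(),
                      rule_id = integer(), stringsAsFactors = FALSE))
  rows <- lapply(keys, function(k) g$gtris[[k]])
  df <- data.frame(a = vapply(rows, `[[`, character(1), "a"),
                   b = vapply(rows, `[[`, character(1), "b"),
                   rule_id = vapply(rows, `[[`, integer(1), "rule_id"),
                   stringsAsFactors = FALSE)
  df[order(df$a, df$b), , drop = FALSE]
}

#' Validate the structural invariants of a clonal graph
#'
#' Checks, over the whole graph: every subg belongs to exactly one existing
#' sample and is indexed under it; every main_insertion points at a pos the
#' subg also has an insertion link to; gtris edges are canonically ordered,
#' never self-loops, never within one sample, with both endpoints present;
#' gtris_sample counts equal the number of supporting gtris links exactly;
#' pos/label index consistency in both directions.
#'
#' @param g A [clonal_graph()].
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_graph <- function(g) {
  bad <- character(0)
  note <- function(...) bad <<- c(bad, sprintf(...))
  for (u in ls(g$subg, all.names = TRUE)) {
    node <- g$subg[[u]]
    if (is.null(g$samples[[node$sample]]))
      note("subg '%s': sample '%s' missing", u, node$sample)
    if (!u %in% g$idx_sample[[node$sample]])
      note("subg '%s': not indexed under its sample", u)
    if (!is.na(node$main_pos) && !node$main_pos %in% node$pos_keys)
      note("subg '%s': main_insertion '%s' has no insertion link",
           u, node$main_pos)
    for (k in unique(node$pos_keys)) {
      if (is.null(g$pos[[k]])) note("subg '%s': pos '%s' missing", u, k)
      if (!u %in% g$idx_pos[[k]])
        note("subg '%s': missing from pos index '%s'", u, k)
    }
    for (lb in node$labels) {
      if (is.null(g$labels[[lb]])) note("subg '%s': label '%s' missing", u, lb)
      if (!u %in% g$idx_label[[lb]])
        note("subg '%s': missing from label index '%s'", u, lb)
    }
  }
  for (k in ls(g$idx_pos, all.names = TRUE)) {
    for (u in g$idx_pos[[k]]) {
      node <- g$subg[[u]]
      if (is.null(node) || !k %in% node$pos_keys)
        note("pos index '%s': stale entry '%s'", k, u)
    }
  }
  for (lb in ls(g$idx_label, all.names = TRUE)) {
    for (u in g$idx_label[[lb]]) {
      node <- g$subg[[u]]
      if (is.null(node) || !lb %in% node$labels)
        note("label index '%s': stale entry '%s'", lb, u)
    }
  }
  counts <- new.env(parent = emptyenv())
  for (k in ls(g$gtris, all.names = TRUE)) {
    e <- g$gtris[[k]]
    if (e$a >= e$b) note("gtris '%s': endpoints not canonical", k)
    na <- g$subg[[e$a]]; nb <- g$subg[[e$b]]
    if (is.null(na) || is.null(nb)) {
      note("gtris '%s': missing endpoint", k)
      next
    }
    if (identical(na$sample, nb$sample))
      note("gtris '%s': connects two subg of sample '%s'", k, na$sample)
    if (!e$rule_id %in% 1:4) note("gtris '%s': bad rule id", k)
    sp <- canonical_pair(na$sample, nb$sample)
    sk <- paste(sp[1], sp[2], sep = "\x1f")
    counts[[sk]] <- if (is.null(counts[[sk]])) 1L else counts[[sk]] + 1L
  }
  for (sk in union(ls(g$gtris_sample, all.names = TRUE), ls(counts, all.names = TRUE))) {
    want <- counts[[sk]]; have <- g$gtris_sample[[sk]]
    if (is.null(want)) want <- 0L
    if (is.null(have)) have <- 0L
    if (want != have)
      note("gtris_sample '%s': %d links recorded, %d supporting gtris edges",
           gsub("\x1f", "~", sk), have, want)
  }
  bad
}

# ---- Table-style query primitives -----------------------------------------

#' Query primitives over the clonal graph
#'
#' `subg_ids_by_pos_and_sample()` returns the clu_ids of clusters with an
#' insertion on a given searchlabel in samples with a given `DNAnumber`
#' attribute. `subg_count_per_sample()` and `pos_count_per_sample()` count
#' clusters and insertion links per sample. `subg_count_with_more_than_k_pos()`
#' counts clusters with more than `k` insertion links. All results equal the
#' naive full-scan evaluation of the same predicate.
#'
#' @param g A [clonal_graph()].
#' @param searchlabel Strand-less position key `<chrom>_<coordinate>`.
#' @param dna_number Value of the sample `DNAnumber` metadata attribute.
#' @param k Integer threshold on insertion-link count.
#' @return See each primitive.
#' @export
subg_ids_by_pos_and_sample <- function(g, searchlabel, dna_number) {
  samples <- Filter(function(s) identical(g$samples[[s]]$DNAnumber,
                                          dna_number),
                    g$sample_order)
  out <- character(0)
  for (s in samples) {
    for (u in g$idx_sample[[s]]) {
      node <- g$subg[[u]]
      sl <- vapply(unique(node$pos_keys),
                   function(k) g$pos[[k]]$searchlabel, character(1),
                   USE.NAMES = FALSE)
      if (searchlabel %in% sl) out <- c(out, node$clu_id)
    }
  }
  sort(out)
}

#' @rdname subg_ids_by_pos_and_sample
#' @export
subg_count_per_sample <- function(g) {
  vapply(stats::setNames(g$sample_order, g$sample_order),
         function(s) length(g$idx_sample[[s]]), integer(1))
}

#' @rdname subg_ids_by_pos_and_sample
#' @export
pos_count_per_sample <- function(g) {
  vapply(stats::setNames(g$sample_order, g$sample_order), function(s) {
    sum(vapply(g$idx_sample[[s]],
               function(u) length(g$subg[[u]]$pos_keys), integer(1)),
        0L)
  }, integer(1))
}

#' @rdname subg_ids_by_pos_and_sample
#' @export
subg_count_with_more_than_k_pos <- function(g, k) {
  sum(vapply(ls(g$subg, all.names = TRUE),
             function(u) length(g$subg[[u]]$pos_keys) > k, logical(1)))
}

# ---- Canonical serialization ----------------------------------------------

#' Canonical text serialization of a clonal graph
#'
#' Deterministic, insertion-order-independent dump used to compare graphs
#' structurally (round-trips, order-invariance). Two graphs are equal up to
#' node relabeling iff their canonical serializations are identical.
#'
#' @param g A [clonal_graph()].
#' @return A single string.
#' @export
canonical_serialization <- function(g) {
  fmt_attr <- function(x) {
    x <- x[order(names(x))]
    paste(vapply(names(x), function(n)
      sprintf("%s=%s", n, paste(format(x[[n]], scientific = FALSE,
                                       trim = TRUE), collapse = ",")),
      character(1)), collapse = ";")
  }
  lines <- character(0)
  for (s in sort(g$sample_order))
    lines <- c(lines, sprintf("sample %s {%s}", s, fmt_attr(g$samples[[s]])))
  for (u in sort(ls(g$subg, all.names = TRUE))) {
    node <- g$subg[[u]]
    tg <- vapply(node$targets, function(t)
      sprintf("%s:%s:%s:%g:%d:%d", t$target_id,
              pos_key(t$chrom, t$coordinate, t$strand), t$searchlabel,
              t$aln_score, t$centroid, t$offset), character(1))
    lines <- c(lines, sprintf(
      "subg %s sample=%s clu=%s cons=%s num_aln=%d max=%g len=%d w=%d sh=%d tg=%d cb=%d main=%s targets=[%s] labels=[%s]",
      u, node$sample, node$clu_id, node$cons_seq, node$num_aln,
      node$max_aln_score, node$seq_len, node$weight, node$shear, node$tag,
      node$combo, node$main_pos, paste(tg, collapse = "|"),
      paste(sort(node$labels), collapse = "|")))
  }
  for (k in sort(ls(g$pos, all.names = TRUE)))
    lines <- c(lines, sprintf("pos %s", k))
  for (lb in sort(ls(g$labels, all.names = TRUE)))
    lines <- c(lines, sprintf("label %s", lb))
  ge <- gtris_edges(g)
  if (nrow(ge))
    lines <- c(lines, sprintf("gtris %s -- %s rule=%d", ge$a, ge$b,
                              ge$rule_id))
  for (sk in sort(ls(g$gtris_sample, all.names = TRUE))) {
    sp <- strsplit(sk, "\x1f", fixed = TRUE)[[1]]
    lines <- c(lines, sprintf("gtris_sample %s -- %s n=%d", sp[1], sp[2],
                              g$gtris_sample[[sk]]))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.clonal_graph <- function(x, ...) {
  st <- graph_stats(x)
  cat(sprintf(
    "<clonal_graph> %d samples, %d subg, %d pos, %d labels, %d gtris links\n",
    st$samples, st$subg, st$pos, st$labels, st$gtris))
  invisible(x)
}
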