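# The tracking core: dominant-alignment selection, the four pairwise
# matching rules, incremental sample insertion, and the brute-force
# all-versus-all oracle used for validation.

#' Select the dominant alignment of an IS cluster
#'
#' A multi-mapping cluster gets a `main_insertion` only when its top
#' alignment clearly dominates: with the two best scores `s1 >= s2`, the
#' top target is dominant iff `(s1 - s2) / s1 > threshold`. A single-target
#' cluster is always dominated by its one target; an exact tie between the
#' two top scores never yields a dominant alignment; an empty target list
#' (label-only repeat cluster) yields none.
#'
#' @param targets List of [target_record()]s.
#' @param threshold Relative score gap in `[0, 1)`; default 0.3.
#' @return The dominant [target_record()], or `NULL`.
#' @export
select_main_insertion <- function(targets, threshold = 0.3) {
  if (length(targets) == 0) return(NULL)
  if (length(targets) == 1) return(targets[[1]])
  scores <- vapply(targets, `[[`, numeric(1), "aln_score")
  o <- order(scores, decreasing = TRUE)
  s1 <- scores[o[1]]; s2 <- scores[o[2]]
  if (s1 <= 0 || s1 == s2) return(NULL)
  if ((s1 - s2) / s1 > threshold) targets[[o[1]]] else NULL
}

# Unique position keys of a record (targets as chrom_coordinate_strand).
record_pos_keys <- function(rec) {
  if (!is.null(rec$pos_keys)) return(unique(rec$pos_keys))
  unique(vapply(rec$targets, function(t)
    pos_key(t$chrom, t$coordinate, t$strand), character(1)))
}

# Position key of the strict top-scoring target, or NA under a top tie.
record_top_pos <- function(rec) {
  if (length(rec$targets) == 0) return(NA_character_)
  scores <- vapply(rec$targets, `[[`, numeric(1), "aln_score")
  top <- max(scores)
  idx <- which(scores == top)
  if (length(idx) != 1) return(NA_character_)
  t <- rec$targets[[idx]]
  pos_key(t$chrom, t$coordinate, t$strand)
}

#' Evaluate the four same-clone matching rules on a cross-sample pair
#'
#' Two IS clusters from distinct samples are assigned to the same clone iff
#' at least one rule fires: (1) both map a single, identical genomic
#' position; (2) they share at least 50% of their genomic positions;
#' (3) they share at least one repeat label and at least one genomic
#' position; (4) their top-scoring alignments are the same genomic
#' position (undefined, hence not firing, when either cluster has a tie
#' for its top score). Rules are evaluated in order 1..4 and the first
#' match is recorded; the rules are a disjunction, so the order affects
#' only the stored rule id, never whether the pair links.
#'
#' The rule-2 denominator is configurable: `"min"` (default;
#' `|P_A inter P_B| / min(|P_A|, |P_B|) >= 0.5`), `"union"` (Jaccard-style)
#' or `"each"` (the fraction must hold against both sides).
#'
#' @param rec_a,rec_b Records (as stored in the graph or built by
#'   [subgraph_record()]) belonging to *distinct* samples. When records
#'   carry a `sample` field, same-sample pairs are a contract violation.
#' @param rule2_mode Denominator convention, see above.
#' @return A list of class `rule_match`: `rule_id` (1..4 or `NA` when no
#'   rule fires), `shared_positions`, `shared_labels`.
#' @export
match_rule <- function(rec_a, rec_b, rule2_mode = "min") {
  if (!is.null(rec_a$sample) && !is.null(rec_b$sample) &&
      identical(rec_a$sample, rec_b$sample))
    ct_error("match_rule is defined for subg of distinct samples",
             "clonetracker_contract_error")
  pa <- record_pos_keys(rec_a)
  pb <- record_pos_keys(rec_b)
  shared <- intersect(pa, pb)
  shared_lab <- intersect(rec_a$labels, rec_b$labels)
  rule <- NA_integer_
  if (length(pa) == 1 && length(pb) == 1 && pa == pb) {
    rule <- 1L
  } else if (length(pa) && length(pb) && length(shared)) {
    frac_ok <- switch(rule2_mode,
      min = length(shared) / min(length(pa), length(pb)) >= 0.5,
      union = length(shared) / length(union(pa, pb)) >= 0.5,
      each = length(shared) / length(pa) >= 0.5 &&
             length(shared) / length(pb) >= 0.5,
      ct_error(sprintf("unknown rule2_mode '%s'", rule2_mode),
               "clonetracker_config_error"))
    if (frac_ok) rule <- 2L
  }
  if (is.na(rule) && length(shared_lab) && length(shared)) rule <- 3L
  if (is.na(rule)) {
    ta <- record_top_pos(rec_a)
    tb <- record_top_pos(rec_b)
    if (!is.na(ta) && !is.na(tb) && ta == tb) rule <- 4L
  }
  structure(list(rule_id = rule, shared_positions = shared,
                 shared_labels = shared_lab), class = "rule_match")
}

#' Insert one sample into the graph, linking its clones incrementally
#'
#' Creates the sample node and all subg/pos/label nodes and
#' sample2subg/insertion/main_insertion/repeat links for the sample's
#' records, then, for each new cluster, retrieves candidate clusters of
#' *other* samples through the shared-position/shared-label indexes
#' ([subgs_sharing_pos_or_label()]) and adds one gtris link per firing
#' rule, updating the sample-level gtris_sample links. The resulting graph
#' is identical (up to node ids) to rebuilding from scratch in any sample
#' insertion order.
#'
#' @param g A [clonal_graph()], mutated in place.
#' @param sample Either a `sample_records` object from
#'   [parse_sample_file()] or a plain list of [subgraph_record()]s (then
#'   `unique_id` is required).
#' @param metadata Optional named list of sample attributes (e.g. one entry
#'   of [parse_metadata_table()]).
#' @param cfg A [run_config()].
#' @param unique_id Sample UniqueID when `sample` is a bare record list.
#' @return Import statistics: list with `sample`, `n_subg`, `new_pos`,
#'   `new_insertion_links`, `new_gtris_links` (class `import_stats`).
#' @export
insert_sample <- function(g, sample, metadata = NULL, cfg = run_config(),
                          unique_id = NULL) {
  if (inherits(sample, "sample_records")) {
    uid <- sample$unique_id
    records <- sample$records
  } else {
    uid <- unique_id
    records <- sample
  }
  if (is.null(uid) || !nzchar(uid))
    ct_error("sample UniqueID is required", "clonetracker_import_error")
  if (!is.null(g$samples[[uid]]))
    ct_error(sprintf("duplicate UniqueID '%s': sample already in graph", uid),
             "clonetracker_import_error")
  for (rec in records) validate_record(rec)
  attrs <- if (is.null(metadata)) list() else metadata
  attrs$UniqueID <- uid
  g$samples[[uid]] <- attrs
  g$sample_order <- c(g$sample_order, uid)
  new_pos <- 0L
  new_ins <- 0L
  uids <- character(length(records))
  for (i in seq_along(records)) {
    new_pos <- new_pos + add_subg_node(g, uid, records[[i]], cfg)
    new_ins <- new_ins + length(records[[i]]$targets)
    uids[i] <- subg_uid(uid, records[[i]]$clu_id)
  }
  new_gtris <- 0L
  for (u in uids) {
    cands <- subgs_sharing_pos_or_label(g, u)
    node <- g$subg[[u]]
    for (cand in cands) {
      m <- match_rule(node, g$subg[[cand]], cfg$rule2_mode)
      if (!is.na(m$rule_id) && add_gtris_edge(g, u, cand, m$rule_id))
        new_gtris <- new_gtris + 1L
    }
  }
  stats <- structure(list(sample = uid, n_subg = length(records),
                          new_pos = new_pos, new_insertion_links = new_ins,
                          new_gtris_links = new_gtris),
                     class = "import_stats")
  ct_log(cfg, "info",
         "imported sample %s: %d subg, %d new insertion links, %d new gtris links",
         uid, stats$n_subg, stats$new_insertion_links, stats$new_gtris_links)
  stats
}

#' Brute-force all-versus-all tracking (validation oracle)
#'
#' Evaluates [match_rule()] on every cross-sample pair of clusters, with no
#' index or graph involved. Quadratic; used only to validate the
#' incremental engine.
#'
#' @param samples Named list `UniqueID -> list of records`.
#' @param rule2_mode Passed to [match_rule()].
#' @return Data frame with columns `a`, `b` (canonically ordered
#'   `<sample>::<clu_id>` ids) and `rule_id`, sorted by (`a`, `b`).
#' @export
brute_force_track <- function(samples, rule2_mode = "min") {
  ids <- names(samples)
  flat <- list()
  for (s in ids) {
    for (rec in samples[[s]]) {
      r <- rec
      r$sample <- s
      r$pos_keys <- record_pos_keys(rec)
      flat[[subg_uid(s, rec$clu_id)]] <- r
    }
  }
  uids <- names(flat)
  n <- length(uids)
  out_a <- character(0); out_b <- character(0); out_r <- integer(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      ri <- flat[[i]]
      for (j in (i + 1):n) {
        rj <- flat[[j]]
        if (identical(ri$sample, rj$sample)) next
        m <- match_rule(ri, rj, rule2_mode)
        if (!is.na(m$rule_id)) {
          pr <- canonical_pair(uids[i], uids[j])
          out_a <- c(out_a, pr[1]); out_b <- c(out_b, pr[2])
          out_r <- c(out_r, m$rule_id)
        }
      }
    }
  }
  df <- data.frame(a = out_a, b = out_b, rule_id = out_r,
                   stringsAsFactors = FALSE)
  df[order(df$a, df$b), , drop = FALSE]
}
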