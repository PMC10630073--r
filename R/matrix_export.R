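# Clone x sample tracking matrix: propagate gtris connectivity into clone
# groups, choose a representative locus per group, fill cells with the
# selected quantification.

#' Group linked clusters into tracked clones
#'
#' Partitions all subg of the graph by propagating gtris links. With
#' `max_depth = Inf` (default) the groups are the connected components of
#' the gtris relation -- the unique order-invariant choice. A finite
#' `max_depth` limits the propagation to that many link hops from each
#' seed (seeds taken in sorted uid order; each subg is assigned once and
#' removed from the work list).
#'
#' @param g A [clonal_graph()].
#' @param max_depth `Inf` or a positive integer.
#' @return List of character vectors of subg uids (each sorted); the list
#'   is sorted by first member. Every subg appears in exactly one group.
#' @export
build_components <- function(g, max_depth = Inf) {
  uids <- sort(ls(g$subg, all.names = TRUE))
  adj <- new.env(parent = emptyenv())
  for (k in ls(g$gtris, all.names = TRUE)) {
    e <- g$gtris[[k]]
    adj[[e$a]] <- c(adj[[e$a]], e$b)
    adj[[e$b]] <- c(adj[[e$b]], e$a)
  }
  assigned <- new.env(parent = emptyenv())
  comps <- list()
  for (seed in uids) {
    if (!is.null(assigned[[seed]])) next
    comp <- seed
    assigned[[seed]] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) && depth < max_depth) {
      nxt <- character(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (is.null(assigned[[v]])) {
            assigned[[v]] <- TRUE
            nxt <- c(nxt, v)
          }
        }
      }
      comp <- c(comp, nxt)
      frontier <- nxt
      depth <- depth + 1
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps[order(vapply(comps, `[[`, character(1), 1))]
}

#' Representative locus of a tracked clone
#'
#' Each member contributes its genomic position when unambiguous: its
#' single position if it has exactly one insertion link, otherwise its
#' dominant (`main_insertion`) position if one was assigned. If at least
#' one position is collected, the most frequent one wins (ties broken by
#' the highest summed alignment score over members, then lexicographically
#' by key). If no member contributes (pure repeat clone), a deterministic
#' repeat identifier is derived from the sorted member label and position
#' sets, so exports are reproducible run to run.
#'
#' @param members Character vector of subg uids forming one group.
#' @param g A [clonal_graph()].
#' @return List with `type` (`"locus"` or `"repeat"`) and `id` (position
#'   key or `REPEAT_<hash>`).
#' @export
representative_locus <- function(members, g) {
  votes <- character(0)
  for (u in members) {
    node <- g$subg[[u]]
    keys <- unique(node$pos_keys)
    if (length(keys) == 1) votes <- c(votes, keys)
    else if (!is.na(node$main_pos)) votes <- c(votes, node$main_pos)
  }
  if (length(votes)) {
    tab <- table(votes)
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1) {
      score <- vapply(best, function(k) {
        s <- 0
        for (u in members) {
          node <- g$subg[[u]]
          for (t in node$targets)
            if (pos_key(t$chrom, t$coordinate, t$strand) == k)
              s <- s + t$aln_score
        }
        s
      }, numeric(1))
      best <- best[score == max(score)]
      best <- sort(best)[1]
    }
    return(list(type = "locus", id = best))
  }
  content <- character(0)
  for (u in sort(members)) {
    node <- g$subg[[u]]
    content <- c(content, sort(node$labels), sort(unique(node$pos_keys)))
  }
  list(type = "repeat", id = paste0("REPEAT_", content_hash(sort(content))))
}

quant_value <- function(node, quantification) {
  switch(quantification,
         weight = node$weight, shear = node$shear, tag = node$tag,
         combo = node$combo,
         ct_error(sprintf("unknown quantification '%s'", quantification),
                  "clonetracker_config_error"))
}

#' Export the clone x sample tracking matrix
#'
#' One row per tracked clone (gtris group), one column per sample in
#' insertion order, after the annotation header `ID, Chr, Pos, Strand,
#' numsubg, numexp, subg`. A cell is the sum of the chosen quantification
#' over the group members belonging to that sample (0 when the clone was
#' not observed there). `numsubg` is the member count, `numexp` the number
#' of samples with a non-zero cell, `subg` the `;`-joined member clu_ids.
#' Unique-locus rows carry the representative locus in `ID`/`Chr`/`Pos`/
#' `Strand`; pure repeat rows carry a deterministic `REPEAT_` id and empty
#' locus fields. Rows are sorted by `ID` (collisions between distinct
#' groups mapping to one locus are disambiguated with `#2`, `#3`, ...).
#'
#' @param g A [clonal_graph()].
#' @param quantification `"weight"`, `"shear"`, `"tag"`, `"combo"`, or
#'   `"all"` for a named list of all four matrices sharing rows.
#' @param cfg A [run_config()]; supplies `max_depth`.
#' @param partition Optional precomputed partition (list of uid vectors),
#'   e.g. an oracle-derived one; defaults to [build_components()].
#' @return A `tracking_matrix` data frame (or a named list of four for
#'   `"all"`), with attributes `samples` and `quantification`.
#' @export
export_matrix <- function(g, quantification = "weight", cfg = run_config(),
                          partition = NULL) {
  if (identical(quantification, "all")) {
    out <- lapply(c(weight = "weight", shear = "shear", tag = "tag",
                    combo = "combo"),
                  function(q) export_matrix(g, q, cfg, partition))
    return(out)
  }
  if (!quantification %in% c("weight", "shear", "tag", "combo"))
    ct_error(sprintf("unknown quantification '%s'", quantification),
             "clonetracker_config_error")
  if (is.null(partition)) partition <- build_components(g, cfg$max_depth)
  samples <- g$sample_order
  n <- length(partition)
  ids <- character(n); chr <- character(n); pos <- rep(NA_integer_, n)
  strand <- character(n); numsubg <- integer(n); numexp <- integer(n)
  memb <- character(n)
  cells <- matrix(0, nrow = n, ncol = length(samples),
                  dimnames = list(NULL, samples))
  for (i in seq_len(n)) {
    members <- partition[[i]]
    rep_loc <- representative_locus(members, g)
    if (rep_loc$type == "locus") {
      p <- parse_pos_key(rep_loc$id)
      ids[i] <- rep_loc$id
      chr[i] <- p$chrom; pos[i] <- p$coordinate; strand[i] <- p$strand
    } else {
      ids[i] <- rep_loc$id
      chr[i] <- ""; strand[i] <- ""
    }
    numsubg[i] <- length(members)
    memb[i] <- paste(vapply(sort(members),
                            function(u) g$subg[[u]]$clu_id, character(1)),
                     collapse = ";")
    for (u in members) {
      node <- g$subg[[u]]
      cells[i, node$sample] <- cells[i, node$sample] +
        quant_value(node, quantification)
    }
    numexp[i] <- sum(cells[i, ] > 0)
  }
  # deterministic disambiguation of ID collisions between distinct groups
  if (anyDuplicated(ids)) {
    o <- order(ids, memb)
    seen <- new.env(parent = emptyenv())
    for (j in o) {
      k <- ids[j]
      cnt <- seen[[k]]
      seen[[k]] <- if (is.null(cnt)) 1L else cnt + 1L
      if (!is.null(cnt)) ids[j] <- sprintf("%s#%d", k, cnt + 1L)
    }
  }
  df <- data.frame(ID = ids, Chr = chr, Pos = pos, Strand = strand,
                   numsubg = numsubg, numexp = numexp, subg = memb,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (length(samples))
    df <- cbind(df, as.data.frame(cells, check.names = FALSE))
  df <- df[order(df$ID), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("tracking_matrix", "data.frame"),
            samples = samples, quantification = quantification)
}

#' Column-normalize a tracking matrix to relative abundances
#'
#' Scales each sample column so it sums to 100 (percent of the sample's
#' total quantification). All-zero columns are left at zero and flagged in
#' the `empty_columns` attribute.
#'
#' @param m A `tracking_matrix`.
#' @return A `tracking_matrix` of percentages.
#' @export
relative_abundance <- function(m) {
  samples <- attr(m, "samples")
  empty <- character(0)
  for (s in samples) {
    tot <- sum(m[[s]])
    if (tot > 0) m[[s]] <- 100 * m[[s]] / tot
    else empty <- c(empty, s)
  }
  attr(m, "empty_columns") <- empty
  m
}

#' Write / read a tracking matrix as TSV
#'
#' Header order is exactly `ID, Chr, Pos, Strand, numsubg, numexp, subg`
#' followed by the sample UniqueIDs; `.` decimal separator, 0 for absent
#' cells, empty locus fields for repeat rows. `read_matrix()` reproduces
#' the written object.
#'
#' @param m A `tracking_matrix`.
#' @param path Output TSV path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` a
#'   `tracking_matrix`.
#' @export
write_matrix <- function(m, path) {
  out <- as.data.frame(m, check.names = FALSE)
  out$Pos[is.na(out$Pos)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = "character")
  fixed <- c("ID", "Chr", "Pos", "Strand", "numsubg", "numexp", "subg")
  if (!identical(names(tab)[seq_along(fixed)], fixed))
    ct_error("matrix header does not start with ID, Chr, Pos, Strand, numsubg, numexp, subg",
             "clonetracker_format_error")
  samples <- names(tab)[-seq_along(fixed)]
  tab$Pos <- suppressWarnings(as.integer(tab$Pos))
  tab$numsubg <- as.integer(tab$numsubg)
  tab$numexp <- as.integer(tab$numexp)
  for (s in samples) tab[[s]] <- as.numeric(tab[[s]])
  structure(tab, class = c("tracking_matrix", "data.frame"),
            samples = samples, quantification = NA_character_)
}

#' Canonical serialization of a tracking matrix
#'
#' Sorts columns by sample name and rows by `ID` and serializes to text;
#' identical strings mean identical matrices irrespective of sample
#' insertion order.
#'
#' @param m A `tracking_matrix`.
#' @return A single string.
#' @export
canonical_matrix_serialization <- function(m) {
  samples <- sort(attr(m, "samples"))
  fixed <- c("ID", "Chr", "Pos", "Strand", "numsubg", "numexp", "subg")
  df <- as.data.frame(m, check.names = FALSE)[, c(fixed, samples),
                                              drop = FALSE]
  df <- df[order(df$ID, df$subg), , drop = FALSE]
  lines <- vapply(seq_len(nrow(df)), function(i)
    paste(vapply(df[i, ], function(x)
      format(x, scientific = FALSE, trim = TRUE), character(1)),
      collapse = "\t"), character(1))
  paste(c(paste(names(df), collapse = "\t"), lines), collapse = "\n")
}
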