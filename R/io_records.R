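# Reading, validating and writing per-sample IS cluster records.
#
# One JSON file per sample. Each record ("subg") is one IS cluster with its
# consensus sequence, quantifications and the target list of genomic
# positions it aligns to. The schema is the package's interchange contract
# (see inst/schema/sample-record-schema.json, version 1.0).

RECORD_SCHEMA_VERSION <- "1.0"

#' Construct a genomic target of an IS cluster
#'
#' A target is one alignment of the cluster consensus on the reference:
#' identifier, locus, cluster centroid/offset bookkeeping and the alignment
#' score used for dominant-alignment selection.
#'
#' @param chrom Chromosome name.
#' @param coordinate 1-based base position (>= 1).
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param aln_score Non-negative alignment score.
#' @param target_id Opaque identifier; defaults to the searchlabel.
#' @param centroid,offset Integer cluster bookkeeping fields.
#' @return A list of class `target_record` with a `searchlabel` field equal
#'   to `<chrom>_<coordinate>`.
#' @export
target_record <- function(chrom, coordinate, strand = "*", aln_score = 0,
                          target_id = NULL, centroid = 0L, offset = 0L) {
  coordinate <- as.integer(coordinate)
  if (is.na(coordinate) || coordinate < 1)
    ct_error("target coordinate must be >= 1", "clonetracker_schema_error")
  if (!strand %in% c("+", "-", "*"))
    ct_error("target strand must be '+', '-' or '*'",
             "clonetracker_schema_error")
  if (is.na(aln_score) || aln_score < 0)
    ct_error("target aln_score must be >= 0", "clonetracker_schema_error")
  sl <- pos_searchlabel(chrom, coordinate)
  structure(list(
    target_id = if (is.null(target_id)) sl else as.character(target_id),
    chrom = as.character(chrom), coordinate = coordinate,
    strand = strand, centroid = as.integer(centroid),
    offset = as.integer(offset), aln_score = as.numeric(aln_score),
    searchlabel = sl), class = "target_record")
}

#' Construct one IS cluster record
#'
#' @param clu_id Cluster identifier, unique within its sample.
#' @param targets List of [target_record()]s (ordered; may be empty for
#'   label-only repeat clusters).
#' @param labels Character vector of repeat labels.
#' @param weight Sequencing-read count supporting the cluster.
#' @param shear Count of distinct sonication fragment lengths.
#' @param tag Count of distinct UMIs.
#' @param combo Count of distinct (UMI, fragment length) pairs.
#' @param cons_seq Consensus nucleotide sequence.
#' @param seq_len Consensus length; defaults to `nchar(cons_seq)`.
#' @param num_aln Number of alignments; defaults to `length(targets)`.
#' @param max_aln_score Top target score; defaults to the max over targets.
#' @return A list of class `subgraph_record`.
#' @export
subgraph_record <- function(clu_id, targets = list(), labels = character(),
                            weight = 1L, shear = 1L, tag = 1L, combo = 1L,
                            cons_seq = "", seq_len = NULL, num_aln = NULL,
                            max_aln_score = NULL) {
  if (is.null(seq_len)) seq_len <- nchar(cons_seq)
  if (is.null(num_aln)) num_aln <- length(targets)
  if (is.null(max_aln_score)) {
    max_aln_score <- if (length(targets))
      max(vapply(targets, `[[`, numeric(1), "aln_score")) else 0
  }
  rec <- structure(list(
    clu_id = as.character(clu_id), cons_seq = as.character(cons_seq),
    num_aln = as.integer(num_aln), max_aln_score = as.numeric(max_aln_score),
    seq_len = as.integer(seq_len), weight = as.integer(weight),
    shear = as.integer(shear), tag = as.integer(tag),
    combo = as.integer(combo), targets = targets,
    labels = as.character(labels)), class = "subgraph_record")
  validate_record(rec)
  rec
}

#' Validate one IS cluster record against the schema invariants
#'
#' Checks, and reports naming the offending `clu_id` and field:
#' `num_aln == length(targets)`; `max_aln_score == max(target scores)`;
#' `weight >= max(shear, tag) >= 1` whenever the record carries targets or
#' labels; per-target coordinate/strand/score sanity.
#'
#' @param rec A [subgraph_record()] (or plain list with the same fields).
#' @return The record, invisibly; throws `clonetracker_schema_error`
#'   otherwise.
#' @export
validate_record <- function(rec) {
  fail <- function(field, msg)
    ct_error(sprintf("record '%s', field '%s': %s", rec$clu_id, field, msg),
             "clonetracker_schema_error")
  if (!nzchar(rec$clu_id)) fail("clu_id", "must be non-empty")
  for (t in rec$targets) {
    if (is.na(t$coordinate) || t$coordinate < 1)
      fail("targets", "coordinate must be >= 1")
    if (!t$strand %in% c("+", "-", "*"))
      fail("targets", "strand must be '+', '-' or '*'")
    if (is.na(t$aln_score) || t$aln_score < 0)
      fail("targets", "aln_score must be >= 0")
    if (!identical(t$searchlabel, pos_searchlabel(t$chrom, t$coordinate)))
      fail("targets", "searchlabel must equal <chrom>_<coordinate>")
  }
  if (length(rec$targets) && rec$num_aln != length(rec$targets))
    fail("num_aln", sprintf("is %d but %d targets given",
                            rec$num_aln, length(rec$targets)))
  if (length(rec$targets)) {
    top <- max(vapply(rec$targets, `[[`, numeric(1), "aln_score"))
    if (abs(rec$max_aln_score - top) > 1e-9)
      fail("max_aln_score", sprintf("is %g but max target score is %g",
                                    rec$max_aln_score, top))
  }
  if (length(rec$targets) || length(rec$labels)) {
    if (min(rec$shear, rec$tag) < 1)
      fail("shear/tag", "must be >= 1")
    if (rec$weight < max(rec$shear, rec$tag))
      fail("weight", sprintf("is %d, below max(shear, tag) = %d",
                             rec$weight, max(rec$shear, rec$tag)))
  }
  invisible(rec)
}

rec_to_json_list <- function(rec) {
  list(clu_id = rec$clu_id, cons_seq = rec$cons_seq, num_aln = rec$num_aln,
       max_aln_score = rec$max_aln_score, seq_len = rec$seq_len,
       weight = rec$weight, shear = rec$shear, tag = rec$tag,
       combo = rec$combo,
       targets = lapply(rec$targets, function(t)
         list(target_id = t$target_id, chrom = t$chrom,
              coordinate = t$coordinate, strand = t$strand,
              centroid = t$centroid, offset = t$offset,
              aln_score = t$aln_score)),
       labels = as.list(rec$labels))
}

#' Write a per-sample record file
#'
#' @param records List of [subgraph_record()]s.
#' @param unique_id Sample UniqueID (becomes the file's `sample` field).
#' @param path Output path; conventionally `<unique_id>.json`.
#' @return `path`, invisibly.
#' @export
write_sample_file <- function(records, unique_id, path) {
  payload <- list(schema_version = RECORD_SCHEMA_VERSION,
                  sample = unique_id,
                  clusters = lapply(records, rec_to_json_list))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

json_to_rec <- function(cl) {
  targets <- lapply(cl$targets, function(t)
    target_record(chrom = t$chrom, coordinate = t$coordinate,
                  strand = t$strand, aln_score = t$aln_score,
                  target_id = t$target_id,
                  centroid = if (is.null(t$centroid)) 0L else t$centroid,
                  offset = if (is.null(t$offset)) 0L else t$offset))
  rec <- structure(list(
    clu_id = as.character(cl$clu_id),
    cons_seq = if (is.null(cl$cons_seq)) "" else as.character(cl$cons_seq),
    num_aln = as.integer(cl$num_aln),
    max_aln_score = as.numeric(cl$max_aln_score),
    seq_len = as.integer(cl$seq_len), weight = as.integer(cl$weight),
    shear = as.integer(cl$shear), tag = as.integer(cl$tag),
    combo = as.integer(cl$combo), targets = targets,
    labels = as.character(unlist(cl$labels))), class = "subgraph_record")
  validate_record(rec)
}

#' Parse a per-sample IS record file
#'
#' Reads one sample's JSON record file, validates every cluster and returns
#' a `sample_records` object: `unique_id` (the file's `sample` field, or the
#' file basename without extension when absent) plus the list of records.
#' A zero-byte file or a file with no clusters is the empty-sample signal
#' (failed PCR): the return value has zero records and attribute
#' `empty_sample = TRUE`, and importers skip it.
#'
#' @param path Path to the record file.
#' @return An object of class `sample_records`.
#' @export
parse_sample_file <- function(path) {
  if (!file.exists(path))
    ct_error(sprintf("record file '%s' does not exist", path),
             "clonetracker_io_error")
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(txt))) {
    return(structure(
      list(unique_id = tools::file_path_sans_ext(basename(path)),
           records = list()),
      class = "sample_records", empty_sample = TRUE))
  }
  payload <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  uid <- if (!is.null(payload$sample)) as.character(payload$sample)
         else tools::file_path_sans_ext(basename(path))
  clusters <- payload$clusters
  if (is.null(clusters)) clusters <- list()
  records <- lapply(clusters, json_to_rec)
  ids <- vapply(records, `[[`, character(1), "clu_id")
  if (anyDuplicated(ids))
    ct_error(sprintf("duplicate clu_id '%s' in sample '%s'",
                     ids[duplicated(ids)][1], uid),
             "clonetracker_schema_error")
  structure(list(unique_id = uid, records = records),
            class = "sample_records",
            empty_sample = length(records) == 0)
}

#' Parse the sample metadata table
#'
#' TSV with a header; the `UniqueID` column is required and must be unique.
#' All other columns become sample attributes verbatim.
#'
#' @param path Path to the TSV file.
#' @return Named list `UniqueID -> list of attributes` (each including
#'   `UniqueID` itself).
#' @export
parse_metadata_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (!"UniqueID" %in% names(tab))
    ct_error("metadata table lacks a UniqueID column",
             "clonetracker_schema_error")
  if (any(!nzchar(tab$UniqueID)))
    ct_error("metadata UniqueID must be non-empty",
             "clonetracker_schema_error")
  if (anyDuplicated(tab$UniqueID))
    ct_error(sprintf("duplicate UniqueID '%s' in metadata",
                     tab$UniqueID[duplicated(tab$UniqueID)][1]),
             "clonetracker_schema_error")
  out <- lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, , drop = FALSE]))
  names(out) <- tab$UniqueID
  out
}

#' Convert a sparse clone x sample matrix into per-sample record files
#'
#' Accepts the flat matrix format common to IS tools: a TSV whose first
#' column annotates each clone row with either a genomic locus
#' (`chrN_pos_strand`, or `chrN_pos` with unknown strand) or a repeat label,
#' and one numeric column per sample. Each non-zero cell becomes a
#' single-target record (or a label-only record for repeat rows) with
#' `weight = shear = tag = combo = cell value` -- a documented lossy default
#' when no richer quantification exists.
#'
#' @param matrix_path Input TSV.
#' @param out_dir Directory receiving one `<sample>.json` per column.
#' @return Character vector of written file paths, named by sample.
#' @export
matrix_to_records <- function(matrix_path, out_dir) {
  tab <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2)
    ct_error("matrix must have an annotation column and >= 1 sample column",
             "clonetracker_format_error")
  ann <- as.character(tab[[1]])
  samples <- names(tab)[-1]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  locus_re <- "^(.+)_([0-9]+)(_([+*-]))?$"
  parsed <- lapply(seq_along(ann), function(i) {
    a <- ann[i]
    if (grepl(locus_re, a)) {
      chrom <- sub(locus_re, "\\1", a)
      coord <- as.integer(sub(locus_re, "\\2", a))
      strand <- sub(locus_re, "\\4", a)
      if (!nzchar(strand)) strand <- "*"
      if (is.na(coord) || coord < 1)
        ct_error(sprintf("row %d: unparseable locus annotation '%s'", i, a),
                 "clonetracker_format_error")
      list(kind = "locus", chrom = chrom, coord = coord, strand = strand)
    } else if (nzchar(a)) {
      list(kind = "label", label = a)
    } else {
      ct_error(sprintf("row %d: empty annotation", i),
               "clonetracker_format_error")
    }
  })
  out <- character(0)
  for (s in samples) {
    vals <- as.numeric(tab[[s]])
    keep <- which(!is.na(vals) & vals > 0)
    recs <- lapply(keep, function(i) {
      v <- as.integer(round(vals[i]))
      p <- parsed[[i]]
      if (p$kind == "locus") {
        subgraph_record(
          clu_id = ann[i],
          targets = list(target_record(p$chrom, p$coord, p$strand,
                                       aln_score = 100)),
          weight = v, shear = v, tag = v, combo = v)
      } else {
        subgraph_record(clu_id = ann[i], labels = p$label,
                        weight = v, shear = v, tag = v, combo = v)
      }
    })
    path <- file.path(out_dir, paste0(s, ".json"))
    write_sample_file(recs, s, path)
    out[[s]] <- path
  }
  out
}
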