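# Dilution-standard assay simulator with known ground truth.
#
# Emulates the wet-lab validation design: clonal cell lines carrying fixed
# known ISs are mixed at stated percentages with a background line whose
# cells each carry one random IS. Cells are drawn multinomially; each cell
# contributes one sonication fragment per IS, fragment lengths are drawn
# without replacement within a clone (saturating at the length-range
# capacity) and UMIs uniformly from a finite UMI space, from which the
# weight/shear/tag/combo quantifications follow their definitions.

#' Toy genome model for the simulator
#'
#' Positions are what matter for tracking, not sequence, so a handful of
#' ~10 Mb chromosomes stands in for a reference genome.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @return Data frame with columns `chrom`, `length`.
#' @export
toy_genome <- function(n_chrom = 5, chrom_length = 1e7) {
  data.frame(chrom = paste0("chr", seq_len(n_chrom)),
             length = rep(as.numeric(chrom_length), n_chrom),
             stringsAsFactors = FALSE)
}

#' Define a clonal cell line with known integration sites
#'
#' A clonal line is a single clone: every cell carries all of the line's
#' known ISs (this is how a vector copy number above 1 is modelled -- a
#' line with six ISs has VCN 6, not a stochastic per-cell copy number).
#'
#' @param name Line name.
#' @param known_is Data frame with columns `chrom`, `coordinate`, `strand`.
#' @param vcn Mean vector copies per cell (bookkeeping; equals
#'   `nrow(known_is)` for clonal lines).
#' @return A list of class `cell_line_spec` with `clonal = TRUE`.
#' @export
cell_line_spec <- function(name, known_is, vcn = nrow(known_is)) {
  if (nrow(known_is) < 1)
    ct_error("a clonal cell line needs at least one known IS",
             "clonetracker_config_error")
  if (vcn <= 0)
    ct_error("vcn must be > 0", "clonetracker_config_error")
  structure(list(name = name, known_is = known_is, vcn = vcn,
                 clonal = TRUE), class = "cell_line_spec")
}

#' Generate a polyclonal background line with random integration sites
#'
#' The background population carries `n_is` loci sampled uniformly over the
#' genome (chromosomes weighted by length, positions uniform, no
#' duplicates); its cells are spread over those clones at mixing time, each
#' cell belonging to one background clone with one IS.
#'
#' @param n_is Number of random ISs (>= 1).
#' @param genome A [toy_genome()]-style data frame.
#' @param seed Integer seed; the same seed reproduces the same loci.
#' @param name Line name.
#' @param exclude Optional data frame of loci (`chrom`, `coordinate`,
#'   `strand`) the random draw must avoid.
#' @return A list of class `cell_line_spec` with `clonal = FALSE`.
#' @export
make_background_line <- function(n_is, genome = toy_genome(), seed = 1,
                                 name = "background", exclude = NULL) {
  if (n_is < 1)
    ct_error("n_is must be >= 1", "clonetracker_config_error")
  if (n_is > sum(genome$length))
    ct_error("n_is exceeds genome capacity", "clonetracker_config_error")
  loci <- with_preserved_seed(seed, {
    out <- NULL
    excl <- if (is.null(exclude)) character(0)
            else pos_key(exclude$chrom, exclude$coordinate, exclude$strand)
    while (is.null(out) || nrow(out) < n_is) {
      need <- n_is - if (is.null(out)) 0 else nrow(out)
      ci <- sample.int(nrow(genome), need, replace = TRUE,
                       prob = genome$length)
      draw <- data.frame(
        chrom = genome$chrom[ci],
        coordinate = vapply(genome$length[ci], function(L)
          sample.int(L, 1), integer(1)),
        strand = sample(c("+", "-"), need, replace = TRUE),
        stringsAsFactors = FALSE)
      out <- rbind(out, draw)
      keys <- pos_key(out$chrom, out$coordinate, out$strand)
      out <- out[!duplicated(keys) & !keys %in% excl, , drop = FALSE]
    }
    rownames(out) <- NULL
    out
  })
  structure(list(name = name, known_is = loci, vcn = 1, clonal = FALSE),
            class = "cell_line_spec")
}

#' Define one dilution mix
#'
#' @param mix_id Mix identifier (Table-style column name).
#' @param proportions Named numeric vector, cell-line name -> fraction;
#'   must be non-negative and sum to 1 (tolerance 1e-9).
#' @param n_cells Cells per simulated sample.
#' @param replicates Number of replicates of the mix.
#' @return A list of class `mix_design`.
#' @export
mix_design <- function(mix_id, proportions, n_cells = 1e4, replicates = 1) {
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    ct_error(sprintf("mix '%s': proportions must be >= 0 and sum to 1",
                     mix_id), "clonetracker_config_error")
  structure(list(mix_id = mix_id, proportions = proportions,
                 n_cells = as.integer(n_cells),
                 replicates = as.integer(replicates)),
            class = "mix_design")
}

# Deterministic per-clone annotations: whether a clone is emitted as a
# multi-mapping (repeat) record, its decoy loci and score profile, and its
# repeat label. Derived from the clone key so the same clone is emitted
# identically in every sample and replicate.
clone_repeat_profile <- function(clone_key, repeat_fraction, genome) {
  h <- strtoi(substr(content_hash(clone_key), 1, 7), 16L)
  if ((h %% 10000) / 10000 >= repeat_fraction)
    return(NULL)
  with_preserved_seed(h %% .Machine$integer.max, {
    n_decoy <- sample(2:5, 1)
    ci <- sample.int(nrow(genome), n_decoy, replace = TRUE,
                     prob = genome$length)
    decoys <- data.frame(
      chrom = genome$chrom[ci],
      coordinate = vapply(genome$length[ci], function(L)
        sample.int(L, 1), integer(1)),
      strand = sample(c("+", "-"), n_decoy, replace = TRUE),
      stringsAsFactors = FALSE)
    dominant <- stats::runif(1) < 0.5
    decoy_scores <- if (dominant) stats::runif(n_decoy, 20, 60)
                    else stats::runif(n_decoy, 85, 99)
    list(decoys = decoys, decoy_scores = round(decoy_scores, 2),
         dominant = dominant,
         label = paste0("RPT_", substr(content_hash(clone_key), 1, 8)))
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build the record for one clone observed with `cells` cells.
make_clone_record <- function(clu_id, locus, cells, repeat_profile,
                              fragment_range, umi_space, extra_read_rate) {
  capacity <- fragment_range[2] - fragment_range[1] + 1
  k <- min(cells, capacity)
  lens <- sample(seq(fragment_range[1], fragment_range[2]), k)
  if (cells > k)
    lens <- c(lens, sample(seq(fragment_range[1], fragment_range[2]),
                           cells - k, replace = TRUE))
  umis <- sample.int(umi_space, cells, replace = TRUE)
  weight <- cells
  if (extra_read_rate > 0)
    weight <- weight + stats::rpois(1, extra_read_rate * cells)
  targets <- list(target_record(locus$chrom, locus$coordinate, locus$strand,
                                aln_score = 100))
  labels <- character(0)
  if (!is.null(repeat_profile)) {
    for (i in seq_len(nrow(repeat_profile$decoys)))
      targets <- c(targets, list(target_record(
        repeat_profile$decoys$chrom[i],
        repeat_profile$decoys$coordinate[i],
        repeat_profile$decoys$strand[i],
        aln_score = repeat_profile$decoy_scores[i])))
    if (!repeat_profile$dominant) labels <- repeat_profile$label
  }
  subgraph_record(
    clu_id = clu_id, targets = targets, labels = labels,
    weight = weight, shear = length(unique(lens)),
    tag = length(unique(umis)),
    combo = nrow(unique(cbind(umis, lens))),
    cons_seq = random_dna(sample(30:60, 1)))
}

#' Simulate one dilution-standard sample
#'
#' Draws `n_cells` cells multinomially over the mix's cell lines. Each
#' known IS of a clonal line is one clone carrying all of that line's
#' cells; background cells are spread multinomially (uniform) over the
#' background line's random clones. Per clone, sonication fragment lengths
#' and UMIs are drawn and the four quantifications computed; at default
#' sequencing depth each fragment yields one read, so `weight` equals the
#' clone's cell count. A configurable fraction of clones is emitted as
#' multi-mapping records (clone-deterministic decoy targets, with a
#' dominant or non-dominant score profile and, for non-dominant profiles,
#' a repeat label). Optional noise adds spurious singleton clones of
#' weight 1-3.
#'
#' @param mix A [mix_design()].
#' @param lines List of [cell_line_spec()]s covering
#'   `names(mix$proportions)`.
#' @param seed Integer seed.
#' @param unique_id Sample UniqueID; defaults to the mix id.
#' @param repeat_fraction Fraction of clones emitted as multi-mapping
#'   records (0-1; default 0).
#' @param noise_rate Expected number of spurious clones per sample
#'   (Poisson; default 0 = off).
#' @param fragment_range Sonication fragment length range (bp).
#' @param umi_space Number of distinct UMIs available.
#' @param extra_read_rate Mean extra sequencing reads per cell fragment
#'   (Poisson; default 0 so weight = cell count).
#' @param genome Genome model for decoy/noise loci.
#' @return List of class `simulated_sample`: `records` (a `sample_records`
#'   object) and `truth` (data frame clone key / line / cells).
#' @export
simulate_sample <- function(mix, lines, seed = 1, unique_id = mix$mix_id,
                            repeat_fraction = 0, noise_rate = 0,
                            fragment_range = c(50, 1200),
                            umi_space = 65536, extra_read_rate = 0,
                            genome = toy_genome()) {
  line_names <- names(mix$proportions)
  specs <- stats::setNames(lines, vapply(lines, `[[`, character(1), "name"))
  missing <- setdiff(line_names, names(specs))
  if (length(missing))
    ct_error(sprintf("mix '%s' references undefined cell line '%s'",
                     mix$mix_id, missing[1]), "clonetracker_config_error")
  set.seed(seed)
  line_cells <- as.vector(stats::rmultinom(1, mix$n_cells,
                                           mix$proportions))
  names(line_cells) <- line_names
  clone_key <- character(0); clone_line <- character(0)
  clone_cells <- integer(0)
  clone_locus <- list()
  for (ln in line_names) {
    spec <- specs[[ln]]
    cells <- line_cells[[ln]]
    if (cells == 0) next
    if (spec$clonal) {
      for (i in seq_len(nrow(spec$known_is))) {
        loc <- spec$known_is[i, , drop = FALSE]
        clone_key <- c(clone_key,
                       pos_key(loc$chrom, loc$coordinate, loc$strand))
        clone_line <- c(clone_line, ln)
        clone_cells <- c(clone_cells, cells)
        clone_locus[[length(clone_locus) + 1]] <- loc
      }
    } else {
      n_cl <- nrow(spec$known_is)
      counts <- as.vector(stats::rmultinom(1, cells,
                                           rep(1 / n_cl, n_cl)))
      for (i in which(counts > 0)) {
        loc <- spec$known_is[i, , drop = FALSE]
        clone_key <- c(clone_key,
                       pos_key(loc$chrom, loc$coordinate, loc$strand))
        clone_line <- c(clone_line, ln)
        clone_cells <- c(clone_cells, counts[i])
        clone_locus[[length(clone_locus) + 1]] <- loc
      }
    }
  }
  records <- vector("list", length(clone_key))
  for (i in seq_along(clone_key)) {
    prof <- if (repeat_fraction > 0)
      clone_repeat_profile(clone_key[i], repeat_fraction, genome) else NULL
    records[[i]] <- make_clone_record(
      clu_id = sprintf("clu_%04d", i),
      locus = as.list(clone_locus[[i]]),
      cells = clone_cells[i], repeat_profile = prof,
      fragment_range = fragment_range, umi_space = umi_space,
      extra_read_rate = extra_read_rate)
  }
  if (noise_rate > 0) {
    n_noise <- stats::rpois(1, noise_rate)
    for (j in seq_len(n_noise)) {
      ci <- sample.int(nrow(genome), 1, prob = genome$length)
      w <- sample(1:3, 1)
      records[[length(records) + 1]] <- subgraph_record(
        clu_id = sprintf("noise_%03d", j),
        targets = list(target_record(genome$chrom[ci],
                                     sample.int(genome$length[ci], 1),
                                     sample(c("+", "-"), 1),
                                     aln_score = 100)),
        weight = w, shear = min(w, 1L) * 1L, tag = 1L, combo = 1L,
        cons_seq = random_dna(40))
    }
  }
  truth <- data.frame(clone = clone_key, line = clone_line,
                      cells = clone_cells, stringsAsFactors = FALSE)
  structure(list(
    records = structure(list(unique_id = unique_id, records = records),
                        class = "sample_records",
                        empty_sample = length(records) == 0),
    truth = truth), class = "simulated_sample")
}

#' Simulate a full dilution assay to disk
#'
#' One record file per design x replicate (replicates share clone
#' identities -- the cell lines are fixed -- but redraw all counts), plus
#' the sample metadata TSV and the ground-truth clone x sample cell-count
#' matrix.
#'
#' @param designs List of [mix_design()]s.
#' @param lines List of [cell_line_spec()]s.
#' @param out_dir Output directory (created).
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param project ProjectID written to the metadata.
#' @param ... Passed on to [simulate_sample()] (`repeat_fraction`,
#'   `noise_rate`, ...).
#' @return List: `record_files` (named character vector), `metadata_file`,
#'   `truth_file`, `truth` (clone x sample data frame of true cell
#'   counts), `samples`.
#' @export
simulate_assay <- function(designs, lines, out_dir, seed = 1,
                           project = "assay", ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  total <- sum(vapply(designs, function(d) d$replicates, integer(1)))
  sample_seeds <- sample.int(.Machine$integer.max - 1, total)
  files <- character(0)
  meta_rows <- list()
  truth_cols <- list()
  k <- 0
  for (d in designs) {
    for (r in seq_len(d$replicates)) {
      k <- k + 1
      uid <- sprintf("%s_%s_r%d", project, d$mix_id, r)
      sim <- simulate_sample(d, lines, seed = sample_seeds[k],
                             unique_id = uid, ...)
      path <- file.path(out_dir, paste0(uid, ".json"))
      write_sample_file(sim$records$records, uid, path)
      files[[uid]] <- path
      meta_rows[[uid]] <- data.frame(
        UniqueID = uid, ProjectID = project, PatientID = "standard",
        Tissue = "cell_mix", Timepoint = as.character(r),
        DNAnumber = d$mix_id, stringsAsFactors = FALSE)
      tc <- stats::setNames(sim$truth$cells, sim$truth$clone)
      truth_cols[[uid]] <- tc
    }
  }
  meta <- do.call(rbind, meta_rows)
  meta_path <- file.path(out_dir, "metadata.tsv")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  clones <- sort(unique(unlist(lapply(truth_cols, names))))
  truth <- data.frame(clone = clones, stringsAsFactors = FALSE)
  for (uid in names(truth_cols)) {
    v <- truth_cols[[uid]][clones]
    v[is.na(v)] <- 0
    truth[[uid]] <- as.integer(v)
  }
  truth_path <- file.path(out_dir, "ground_truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(record_files = files, metadata_file = meta_path,
       truth_file = truth_path, truth = truth, samples = names(files))
}
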