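# Dilution-standard assay designs: cell-line inventories and mixing
# proportions, mirroring the validation-assay design tables shipped as
# TSV fixtures (inst/extdata/table1.tsv, table2.tsv).

# Fixed known-IS loci per clonal line. The single CEM1 IS sits at the
# locus used throughout the query examples (chr2:24546570); one of the six
# CEM6 ISs sits at chr16:28497498, the locus followed across dilutions in
# the abundance comparisons. Other lines get deterministic, well-separated
# loci on the toy genome.
known_loci_table <- list(
  CEM1 = data.frame(chrom = "chr2", coordinate = 24546570L, strand = "+",
                    stringsAsFactors = FALSE),
  CEM6 = data.frame(
    chrom = c("chr16", "chr1", "chr2", "chr3", "chr4", "chr5"),
    coordinate = c(28497498L, 1204507L, 3308101L, 5412909L, 7516703L,
                   9620501L),
    strand = c("+", "+", "-", "+", "-", "+"),
    stringsAsFactors = FALSE)
)

generic_known_loci <- function(n_is, line_index, genome) {
  n_chr <- nrow(genome)
  i <- seq_len(n_is)
  chrom_i <- ((line_index + i - 2) %% n_chr) + 1
  coord <- 100003L + line_index * 524287L + i * 9973L
  data.frame(chrom = genome$chrom[chrom_i],
             coordinate = as.integer(coord %% (genome$length[chrom_i] - 1) + 1),
             strand = ifelse(i %% 2 == 0, "-", "+"),
             stringsAsFactors = FALSE)
}

#' Load a dilution assay design table
#'
#' The table is a TSV mirror of the printed assay designs: one row per
#' cell line with its known-IS inventory (`n_is`; `NA` marks the random
#' background line) and one percentage column per mix. Clonal lines get
#' fixed deterministic loci (the CEM lines use their documented loci); the
#' background line is generated with [make_background_line()], avoiding
#' all known loci.
#'
#' @param path Design TSV path.
#' @param n_cells Cells per simulated sample.
#' @param replicates Replicates per mix.
#' @param background_n_is Random-IS inventory of the background line.
#' @param background_seed Seed for the background loci.
#' @param genome Genome model.
#' @return List with `lines` (list of [cell_line_spec()]) and `designs`
#'   (list of [mix_design()], one per mix column).
#' @export
load_design_table <- function(path, n_cells = 1e4, replicates = 1,
                              background_n_is = 500, background_seed = 97,
                              genome = toy_genome()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  mix_ids <- names(tab)[-(1:2)]
  known <- NULL
  lines <- list()
  li <- 0
  for (i in seq_len(nrow(tab))) {
    nm <- tab$cell_line[i]
    n_is <- suppressWarnings(as.integer(tab$n_is[i]))
    if (!is.na(n_is)) {
      li <- li + 1
      loci <- known_loci_table[[nm]]
      if (is.null(loci)) loci <- generic_known_loci(n_is, li, genome)
      if (nrow(loci) != n_is)
        ct_error(sprintf("line '%s': %d loci defined but n_is = %d",
                         nm, nrow(loci), n_is), "clonetracker_config_error")
      lines[[nm]] <- cell_line_spec(nm, loci)
      known <- rbind(known, loci)
    }
  }
  for (i in seq_len(nrow(tab))) {
    nm <- tab$cell_line[i]
    if (is.na(suppressWarnings(as.integer(tab$n_is[i]))))
      lines[[nm]] <- make_background_line(background_n_is, genome,
                                          seed = background_seed,
                                          name = nm, exclude = known)
  }
  designs <- lapply(mix_ids, function(m) {
    prop <- stats::setNames(as.numeric(tab[[m]]) / 100, tab$cell_line)
    mix_design(m, prop, n_cells = n_cells, replicates = replicates)
  })
  names(designs) <- mix_ids
  list(lines = unname(lines), designs = designs)
}

#' Built-in dilution assay designs
#'
#' `table1_design()` is the serial-dilution standard: CEM1 (1 known IS)
#' diluted from 70% to 0% against a constant 30% of CEM6 (6 known ISs),
#' with the random JY background filling the remainder (mixes L..T).
#' `table2_design()` is the clonal-expansion standard: four clonal lines
#' A (1 IS), B (3), C (6), D (10) mixed at varying proportions with the JY
#' background (mixes 1..17).
#'
#' @inheritParams load_design_table
#' @return As [load_design_table()].
#' @export
table1_design <- function(n_cells = 1e4, replicates = 1,
                          background_n_is = 500, background_seed = 97,
                          genome = toy_genome()) {
  load_design_table(system.file("extdata", "table1.tsv",
                                package = "clonetracker", mustWork = TRUE),
                    n_cells, replicates, background_n_is, background_seed,
                    genome)
}

#' @rdname table1_design
#' @export
table2_design <- function(n_cells = 1e4, replicates = 1,
                          background_n_is = 500, background_seed = 97,
                          genome = toy_genome()) {
  load_design_table(system.file("extdata", "table2.tsv",
                                package = "clonetracker", mustWork = TRUE),
                    n_cells, replicates, background_n_is, background_seed,
                    genome)
}
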