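# Internal helpers shared across modules.

#' Raise a classed clonetracker error
#' @noRd
ct_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "clonetracker_error", "error")))
}

#' Canonical position key: chromosome, 1-based coordinate and strand
#'
#' Position identity is exact: two targets are the same genomic position iff
#' chromosome, coordinate and strand all agree. The strand-less
#' `<chrom>_<coordinate>` form is the `searchlabel` used by queries.
#'
#' @param chrom Chromosome name.
#' @param coordinate 1-based genomic base position.
#' @param strand One of `"+"`, `"-"` or `"*"` (unknown).
#' @return Character key `<chrom>_<coordinate>_<strand>`.
#' @export
pos_key <- function(chrom, coordinate, strand = "*") {
  paste(chrom, format(coordinate, scientific = FALSE, trim = TRUE), strand,
        sep = "_")
}

#' @rdname pos_key
#' @export
pos_searchlabel <- function(chrom, coordinate) {
  paste(chrom, format(coordinate, scientific = FALSE, trim = TRUE), sep = "_")
}

# Split a position key back into chrom / coordinate / strand. Chromosome
# names may themselves contain underscores, so split from the right.
parse_pos_key <- function(key) {
  parts <- strsplit(key, "_", fixed = TRUE)[[1]]
  n <- length(parts)
  if (n < 3) ct_error(sprintf("malformed position key '%s'", key),
                      "clonetracker_format_error")
  list(chrom = paste(parts[seq_len(n - 2)], collapse = "_"),
       coordinate = as.integer(parts[n - 1]),
       strand = parts[n])
}

# Deterministic 64-bit-ish content hash (two independent polynomial hashes
# modulo primes < 2^29, exact in double arithmetic). Used for reproducible
# repeat-clone row identifiers.
content_hash <- function(x) {
  s <- paste(x, collapse = "\x1f")
  bytes <- utf8ToInt(enc2utf8(s))
  m1 <- 536870909; m2 <- 536870879
  h1 <- 17; h2 <- 31
  for (b in bytes) {
    h1 <- (h1 * 33 + b) %% m1
    h2 <- (h2 * 37 + b) %% m2
  }
  sprintf("%08x%08x", h1, h2)
}

# Run code under a temporary RNG seed, restoring global RNG state after.
with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Run configuration for tracking and export
#'
#' Bundles the tunable parameters of the tracking engine. `threshold` is the
#' relative score gap above which the top alignment of a multi-mapping IS is
#' taken as its dominant (`main_insertion`) locus: with top scores
#' `s1 >= s2`, the top hit dominates iff `(s1 - s2)/s1 > threshold`.
#' `rule2_mode` selects the denominator of the shared-position fraction in
#' matching rule 2 (`"min"`, `"union"` or `"each"`). `max_depth` bounds the
#' link propagation when grouping linked ISs into matrix rows (`Inf` =
#' connected components, the order-invariant default).
#'
#' @param threshold Dominance threshold in `[0, 1)`. Default 0.3.
#' @param rule2_mode Denominator convention for rule 2.
#' @param max_depth Propagation depth for row grouping; `Inf` or a positive
#'   integer.
#' @param quantification Default quantification for exports: one of
#'   `"weight"`, `"shear"`, `"tag"`, `"combo"`, `"all"`.
#' @param seed Optional integer seed recorded for provenance.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(threshold = 0.3,
                       rule2_mode = c("min", "union", "each"),
                       max_depth = Inf,
                       quantification = c("weight", "shear", "tag", "combo", "all"),
                       seed = NULL,
                       log_level = c("info", "quiet", "debug")) {
  rule2_mode <- match.arg(rule2_mode)
  quantification <- match.arg(quantification)
  log_level <- match.arg(log_level)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold >= 1)
    ct_error("threshold must be a single number in [0, 1)",
             "clonetracker_config_error")
  if (!(is.infinite(max_depth) || (is.numeric(max_depth) && max_depth >= 1)))
    ct_error("max_depth must be Inf or a positive integer",
             "clonetracker_config_error")
  structure(list(threshold = threshold, rule2_mode = rule2_mode,
                 max_depth = max_depth, quantification = quantification,
                 seed = seed, log_level = log_level),
            class = "run_config")
}

#' Write / read a run configuration as flat key=value text
#'
#' Every output directory produced by the `cmd_*` entry points carries its
#' configuration for provenance.
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @return `read_config` returns a [run_config()].
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  vals <- cfg
  vals$max_depth <- if (is.infinite(vals$max_depth)) "Inf" else vals$max_depth
  vals$seed <- if (is.null(vals$seed)) "NA" else vals$seed
  writeLines(sprintf("%s=%s", names(vals), unlist(vals)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x)
    paste(x[-1], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1))
  run_config(
    threshold = as.numeric(vals[["threshold"]]),
    rule2_mode = vals[["rule2_mode"]],
    max_depth = if (vals[["max_depth"]] == "Inf") Inf
                else as.numeric(vals[["max_depth"]]),
    quantification = vals[["quantification"]],
    seed = if (vals[["seed"]] == "NA") NULL else as.integer(vals[["seed"]]),
    log_level = vals[["log_level"]]
  )
}

ct_log <- function(cfg, level = "info", ...) {
  lvl <- c(quiet = 0, info = 1, debug = 2)
  want <- if (is.null(cfg$log_level)) 1 else lvl[[cfg$log_level]]
  if (lvl[[level]] <= want && want > 0) message(sprintf(...))
  invisible(NULL)
}
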