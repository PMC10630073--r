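# Shared fixture builders: compact record constructors, a randomized
# multi-sample instance generator, and an independent union-find used as
# the component oracle.

# One single-target record at chrom:coordinate(strand).
rec1 <- function(clu_id, chrom, coordinate, strand = "+", weight = 10,
                 score = 100, labels = character()) {
  subgraph_record(clu_id,
                  targets = list(target_record(chrom, coordinate, strand,
                                               aln_score = score)),
                  labels = labels,
                  weight = weight, shear = min(weight, 3L),
                  tag = min(weight, 2L), combo = min(weight, 3L))
}

# A multi-target record from a data frame of loci and a score vector.
recN <- function(clu_id, loci, scores, weight = 10, labels = character()) {
  targets <- lapply(seq_len(nrow(loci)), function(i)
    target_record(loci$chrom[i], loci$coordinate[i], loci$strand[i],
                  aln_score = scores[i]))
  subgraph_record(clu_id, targets = targets, labels = labels,
                  weight = weight, shear = min(weight, 3L),
                  tag = min(weight, 2L), combo = min(weight, 3L))
}

# Randomized multi-sample tracking instance. Loci and labels are drawn
# from shared pools so that the four rules actually fire; repeat_frac is
# the probability a record is multi-target.
random_instance <- function(seed, n_samples = NULL, per_sample = NULL,
                            n_loci = 40, n_labels = 8, repeat_frac = 0.3) {
  set.seed(seed)
  if (is.null(n_samples)) n_samples <- sample(2:8, 1)
  pool <- data.frame(
    chrom = paste0("chr", sample(1:5, n_loci, replace = TRUE)),
    coordinate = sample.int(1e6, n_loci),
    strand = sample(c("+", "-"), n_loci, replace = TRUE),
    stringsAsFactors = FALSE)
  pool <- pool[!duplicated(pos_key(pool$chrom, pool$coordinate,
                                   pool$strand)), ]
  labels <- sprintf("LBL%d", seq_len(n_labels))
  samples <- list()
  for (s in seq_len(n_samples)) {
    n <- if (is.null(per_sample)) sample(5L:25L, 1) else per_sample
    recs <- lapply(seq_len(n), function(i) {
      k <- if (stats::runif(1) < repeat_frac)
        sample(2:4, 1) else 1L
      idx <- sample.int(nrow(pool), k)
      scores <- round(stats::runif(k, 50, 100), 1)
      lbl <- if (stats::runif(1) < 0.3)
        sample(labels, sample(1:2, 1)) else character()
      w <- sample(1:50, 1)
      sh <- sample.int(w, 1); tg <- sample.int(w, 1)
      subgraph_record(
        sprintf("s%d_c%03d", s, i),
        targets = lapply(seq_len(k), function(j)
          target_record(pool$chrom[idx[j]], pool$coordinate[idx[j]],
                        pool$strand[idx[j]], aln_score = scores[j])),
        labels = lbl, weight = w, shear = sh, tag = tg,
        combo = sample(max(sh, tg):w, 1))
    })
    samples[[sprintf("S%02d", s)]] <- recs
  }
  samples
}

# Build a graph by inserting samples in the given (or name) order.
build_graph <- function(samples, cfg = run_config(log_level = "quiet"),
                        order = names(samples)) {
  g <- clonal_graph()
  for (s in order) insert_sample(g, samples[[s]], cfg = cfg,
                                 unique_id = s)
  g
}

# Independent union-find over explicit pairs (the component oracle).
uf_components <- function(uids, pairs_a, pairs_b) {
  parent <- stats::setNames(uids, uids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(pairs_a)) {
    ra <- find(pairs_a[i]); rb <- find(pairs_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(uids, find, character(1))
  comps <- split(uids, roots)
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, `[[`, character(1), 1))])
}

# Total weight per sample straight from the records (conservation oracle).
sample_weight_totals <- function(samples) {
  vapply(samples, function(recs)
    sum(vapply(recs, `[[`, integer(1), "weight")), numeric(1))
}
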