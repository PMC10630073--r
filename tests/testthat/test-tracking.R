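quiet_cfg <- run_config(log_level = "quiet")

tgt <- function(score, chrom = "chr1", coordinate = 100)
  target_record(chrom, coordinate, "+", aln_score = score)

test_that("dominant-alignment selection follows the relative-gap criterion", {
  # single target: always dominant
  one <- tgt(42)
  expect_identical(select_main_insertion(list(one)), one)
  # relative gap (100-60)/100 = 0.4 > 0.3: top wins
  got <- select_main_insertion(list(tgt(100, "chr1", 1), tgt(60, "chr2", 2)))
  expect_identical(got$aln_score, 100)
  # gap 0.2 <= 0.3: no dominant alignment
  expect_null(select_main_insertion(list(tgt(100, "chr1", 1),
                                         tgt(80, "chr2", 2))))
  # exact tie: never dominant
  expect_null(select_main_insertion(list(tgt(100, "chr1", 1),
                                         tgt(100, "chr2", 2))))
  # empty target list (label-only repeat)
  expect_null(select_main_insertion(list()))
  # threshold is a parameter: 0.5 reproduces the "at least twice" reading
  pair <- list(tgt(100, "chr1", 1), tgt(49, "chr2", 2))
  expect_identical(select_main_insertion(pair, threshold = 0.5)$aln_score,
                   100)
  expect_null(select_main_insertion(list(tgt(100, "chr1", 1),
                                         tgt(51, "chr2", 2)),
                                    threshold = 0.5))
})

test_that("the four matching rules fire on their defining configurations", {
  A <- rec1("a", "chr2", 24546570, "+"); A$sample <- "SA"
  B <- rec1("b", "chr2", 24546570, "+"); B$sample <- "SB"
  m <- match_rule(A, B)
  expect_identical(m$rule_id, 1L)
  expect_identical(m$shared_positions, "chr2_24546570_+")

  # rule 2 under the min denominator: B's 2 positions are a subset of A's 5
  lociA <- data.frame(chrom = "chr1", coordinate = c(10, 20, 30, 40, 50),
                      strand = "+")
  lociB <- lociA[1:2, ]
  A2 <- recN("a", lociA, scores = c(90, 85, 80, 75, 70)); A2$sample <- "SA"
  B2 <- recN("b", lociB, scores = c(88, 70)); B2$sample <- "SB"
  expect_identical(match_rule(A2, B2)$rule_id, 2L)
  # under the union denominator the fraction is 2/5 < 0.5, so rule 2 no
  # longer fires and the shared top-scoring position fires rule 4 instead
  expect_identical(match_rule(A2, B2, rule2_mode = "union")$rule_id, 4L)

  # rule 3: shared label + one shared position, otherwise disjoint
  lociC <- data.frame(chrom = c("chr1", "chr5", "chr5"),
                      coordinate = c(10, 77, 88), strand = "+")
  lociD <- data.frame(chrom = c("chr1", "chr4", "chr4", "chr4"),
                      coordinate = c(10, 50, 60, 70), strand = "+")
  C <- recN("c", lociC, scores = c(90, 95, 85), labels = "L1")
  C$sample <- "SA"
  D <- recN("d", lociD, scores = c(90, 99, 85, 80), labels = c("L1", "L2"))
  D$sample <- "SB"
  m3 <- match_rule(C, D)
  expect_identical(m3$rule_id, 3L)
  expect_identical(m3$shared_labels, "L1")

  # rule 4: same top-scoring position, low overlap, no shared labels
  lociE <- data.frame(chrom = c("chr1", "chr5", "chr6"),
                      coordinate = c(10, 77, 88), strand = "+")
  lociF <- data.frame(chrom = c("chr1", "chr7", "chr8", "chr9"),
                      coordinate = c(10, 50, 60, 70), strand = "+")
  E <- recN("e", lociE, scores = c(99, 80, 70)); E$sample <- "SA"
  F_rec <- recN("f", lociF, scores = c(99, 90, 85, 80)); F_rec$sample <- "SB"
  expect_identical(match_rule(E, F_rec)$rule_id, 4L)
  # a top-score tie inside one record disables rule 4
  F_tie <- recN("f", lociF, scores = c(99, 99, 85, 80)); F_tie$sample <- "SB"
  expect_true(is.na(match_rule(E, F_tie)$rule_id))

  # disjoint positions, no shared labels: no rule
  G <- rec1("g", "chr1", 1); G$sample <- "SA"
  H <- rec1("h", "chr2", 2); H$sample <- "SB"
  expect_true(is.na(match_rule(G, H)$rule_id))

  # same-sample pairs are a contract violation
  H2 <- rec1("h2", "chr1", 1); H2$sample <- "SA"
  expect_error(match_rule(G, H2), class = "clonetracker_contract_error")
})

test_that("rule firing is symmetric on randomized pairs", {
  samples <- random_instance(53, n_samples = 2, per_sample = 30)
  a_recs <- lapply(samples$S01, function(r) { r$sample <- "S01"; r })
  b_recs <- lapply(samples$S02, function(r) { r$sample <- "S02"; r })
  for (ra in a_recs) {
    for (rb in b_recs) {
      fwd <- match_rule(ra, rb)$rule_id
      rev <- match_rule(rb, ra)$rule_id
      expect_identical(is.na(fwd), is.na(rev))
    }
  }
})

test_that("the first sample creates no gtris links; a minimal rule-1 pair creates one", {
  g <- clonal_graph()
  st1 <- insert_sample(g, list(rec1("c1", "chr1", 50),
                               rec1("c2", "chr2", 60)),
                       cfg = quiet_cfg, unique_id = "first")
  expect_identical(st1$new_gtris_links, 0L)
  expect_identical(st1$n_subg, 2L)
  st2 <- insert_sample(g, list(rec1("c1", "chr1", 50)),
                       cfg = quiet_cfg, unique_id = "second")
  expect_identical(st2$new_gtris_links, 1L)
  expect_identical(graph_stats(g)$gtris_sample, 1L)
  ge <- gtris_edges(g)
  expect_identical(ge$rule_id, 1L)
  # duplicate UniqueID rejected
  expect_error(insert_sample(g, list(rec1("c1", "chr1", 50)),
                             cfg = quiet_cfg, unique_id = "second"),
               class = "clonetracker_import_error")
})

test_that("incremental insertion equals the brute-force oracle on randomized instances", {
  for (seed in c(61, 67, 71)) {
    samples <- random_instance(seed)
    g <- build_graph(samples, quiet_cfg)
    inc <- gtris_edges(g)
    bf <- brute_force_track(samples)
    expect_identical(paste(inc$a, inc$b, inc$rule_id),
                     paste(bf$a, bf$b, bf$rule_id))
    expect_length(validate_graph(g), 0)
  }
})

test_that("adding a sample never removes existing gtris links", {
  samples <- random_instance(73, n_samples = 6, per_sample = 12)
  g <- clonal_graph()
  prev <- character(0)
  for (s in names(samples)) {
    insert_sample(g, samples[[s]], cfg = quiet_cfg, unique_id = s)
    now <- with(gtris_edges(g), paste(a, b))
    expect_true(all(prev %in% now))
    prev <- now
  }
})

test_that("brute-force oracle basics: disjoint samples give no pairs, one shared pos gives all pairs", {
  none <- brute_force_track(list(A = list(rec1("a", "chr1", 1)),
                                 B = list(rec1("b", "chr2", 2))))
  expect_identical(nrow(none), 0L)
  three <- brute_force_track(list(A = list(rec1("a", "chr1", 1)),
                                  B = list(rec1("b", "chr1", 1)),
                                  C = list(rec1("c", "chr1", 1))))
  expect_identical(nrow(three), 3L)
  expect_true(all(three$rule_id == 1L))
})
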