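quiet_cfg <- run_config(log_level = "quiet")

test_that("components: singletons without links, chains merge, depth limits propagation", {
  g <- build_graph(list(A = list(rec1("a1", "chr1", 1),
                                 rec1("a2", "chr2", 2)),
                        B = list(rec1("b1", "chr3", 3))), quiet_cfg)
  comps <- build_components(g)
  expect_length(comps, 3)
  expect_true(all(lengths(comps) == 1))

  # chain a--b--c through two rule-1 links
  g2 <- build_graph(list(A = list(rec1("a", "chr1", 10)),
                         B = list(rec1("b", "chr1", 10)),
                         C = list(rec1("c", "chr1", 10))), quiet_cfg)
  comps2 <- build_components(g2)
  expect_length(comps2, 1)
  expect_identical(comps2[[1]], c("A::a", "B::b", "C::c"))
  # depth 1 from the first seed already reaches both neighbours here;
  # build an actual 3-hop chain via distinct loci to exercise the limit
  gc <- clonal_graph()
  insert_sample(gc, list(recN("x", data.frame(chrom = "chr1",
                                              coordinate = c(1, 2),
                                              strand = "+"),
                              scores = c(90, 80))),
                cfg = quiet_cfg, unique_id = "S1")
  insert_sample(gc, list(recN("y", data.frame(chrom = "chr1",
                                              coordinate = c(2, 3),
                                              strand = "+"),
                              scores = c(90, 80))),
                cfg = quiet_cfg, unique_id = "S2")
  insert_sample(gc, list(recN("z", data.frame(chrom = "chr1",
                                              coordinate = c(3, 4),
                                              strand = "+"),
                              scores = c(90, 80))),
                cfg = quiet_cfg, unique_id = "S3")
  insert_sample(gc, list(recN("w", data.frame(chrom = "chr1",
                                              coordinate = c(4, 5),
                                              strand = "+"),
                              scores = c(90, 80))),
                cfg = quiet_cfg, unique_id = "S4")
  expect_length(build_components(gc), 1)
  limited <- build_components(gc, max_depth = 1)
  expect_length(limited, 2)
  expect_identical(limited[[1]], c("S1::x", "S2::y"))
})

test_that("component partition equals union-find over brute-force pairs", {
  for (seed in c(83, 89)) {
    samples <- random_instance(seed)
    g <- build_graph(samples, quiet_cfg)
    bf <- brute_force_track(samples)
    uids <- sort(ls(g$subg, all.names = TRUE))
    want <- uf_components(uids, bf$a, bf$b)
    expect_identical(build_components(g), want)
  }
})

test_that("components agree with an independent graph library", {
  skip_if_not_installed("igraph")
  samples <- random_instance(97, n_samples = 6, per_sample = 15)
  g <- build_graph(samples, quiet_cfg)
  ge <- gtris_edges(g)
  uids <- sort(ls(g$subg, all.names = TRUE))
  ig <- igraph::graph_from_data_frame(ge[, c("a", "b")], directed = FALSE,
                                      vertices = uids)
  mem <- igraph::components(ig)$membership
  want <- unname(lapply(split(names(mem), mem), sort))
  want <- want[order(vapply(want, `[[`, character(1), 1))]
  expect_identical(build_components(g), want)
})

test_that("representative locus: consensus, frequency vote and deterministic repeat ids", {
  # all members at one locus
  g <- build_graph(list(A = list(rec1("a", "chr2", 24546570)),
                        B = list(rec1("b", "chr2", 24546570))), quiet_cfg)
  rl <- representative_locus(c("A::a", "B::b"), g)
  expect_identical(rl, list(type = "locus", id = "chr2_24546570_+"))

  # frequency vote: three members at p1, one (multi-target, dominant) at p2
  loci <- data.frame(chrom = "chr1", coordinate = c(500, 100), strand = "+")
  g2 <- build_graph(list(
    A = list(rec1("a", "chr1", 100)),
    B = list(rec1("b", "chr1", 100)),
    C = list(rec1("c", "chr1", 100)),
    D = list(recN("d", loci, scores = c(100, 60)))), quiet_cfg)
  members <- sort(ls(g2$subg, all.names = TRUE))
  expect_identical(representative_locus(members, g2)$id, "chr1_100_+")

  # pure repeat component: label-only members, deterministic id
  mk <- function() list(subgraph_record("r1", labels = "ALU", weight = 2,
                                        shear = 1, tag = 1, combo = 1))
  g3 <- build_graph(list(A = mk(), B = mk()), quiet_cfg)
  rl3 <- representative_locus(c("A::r1", "B::r1"), g3)
  expect_identical(rl3$type, "repeat")
  expect_match(rl3$id, "^REPEAT_[0-9a-f]{16}$")
  g4 <- build_graph(list(A = mk(), B = mk()), quiet_cfg)
  expect_identical(representative_locus(c("A::r1", "B::r1"), g4)$id,
                   rl3$id)
})

test_that("matrix export: rows, cells, numsubg/numexp and weight conservation", {
  g <- build_graph(list(S1 = list(rec1("c1", "chr1", 1, weight = 4),
                                  rec1("c2", "chr2", 2, weight = 6),
                                  rec1("c3", "chr3", 3, weight = 2))),
                   quiet_cfg)
  m <- export_matrix(g)
  expect_identical(nrow(m), 3L)
  expect_identical(sum(m$S1), 12)

  g2 <- build_graph(list(SA = list(rec1("x", "chr2", 24546570,
                                        weight = 10)),
                         SB = list(rec1("y", "chr2", 24546570,
                                        weight = 5))), quiet_cfg)
  m2 <- export_matrix(g2)
  expect_identical(nrow(m2), 1L)
  expect_equal(unlist(m2[1, c("SA", "SB")], use.names = FALSE), c(10, 5))
  expect_identical(m2$numsubg, 2L)
  expect_identical(m2$numexp, 2L)
  expect_identical(m2$subg, "x;y")

  # randomized conservation: weight column sums = per-sample totals,
  # sum(numsubg) = total subg count, every subg in exactly one row
  samples <- random_instance(101)
  g3 <- build_graph(samples, quiet_cfg)
  m3 <- export_matrix(g3)
  totals <- sample_weight_totals(samples)
  for (s in names(samples)) expect_identical(sum(m3[[s]]), totals[[s]])
  expect_identical(sum(m3$numsubg), graph_stats(g3)$subg)
  all_members <- unlist(strsplit(m3$subg, ";", fixed = TRUE))
  expect_identical(length(all_members), graph_stats(g3)$subg)
})

test_that("the four quantifications are exported consistently under 'all'", {
  samples <- random_instance(103, n_samples = 3, per_sample = 8)
  g <- build_graph(samples, quiet_cfg)
  ms <- export_matrix(g, "all")
  expect_named(ms, c("weight", "shear", "tag", "combo"))
  expect_identical(ms$weight$ID, ms$tag$ID)
  # shear and tag never exceed weight, cell-wise
  for (s in names(samples)) {
    expect_true(all(ms$shear[[s]] <= ms$weight[[s]]))
    expect_true(all(ms$tag[[s]] <= ms$weight[[s]]))
  }
  expect_error(export_matrix(g, "reads"),
               class = "clonetracker_config_error")
})

test_that("relative abundance columns sum to 100 and zero columns are flagged", {
  g <- build_graph(list(S1 = list(rec1("a", "chr1", 1, weight = 30),
                                  rec1("b", "chr2", 2, weight = 70))),
                   quiet_cfg)
  ra <- relative_abundance(export_matrix(g))
  expect_equal(sort(ra$S1), c(30, 70))
  samples <- random_instance(107, n_samples = 4, per_sample = 10)
  g2 <- build_graph(samples, quiet_cfg)
  ra2 <- relative_abundance(export_matrix(g2))
  for (s in names(samples))
    expect_equal(sum(ra2[[s]]), 100, tolerance = 1e-9)
  uniform <- build_graph(list(U = list(rec1("a", "chr1", 1, weight = 5),
                                       rec1("b", "chr2", 2, weight = 5),
                                       rec1("c", "chr3", 3, weight = 5),
                                       rec1("d", "chr4", 4, weight = 5))),
                         quiet_cfg)
  expect_equal(relative_abundance(export_matrix(uniform))$U,
               rep(25, 4))
})

test_that("matrix TSV write/read round-trips, including repeat rows", {
  samples <- random_instance(109, n_samples = 3, per_sample = 10)
  samples$S01 <- c(samples$S01,
                   list(subgraph_record("rep_only", labels = "ALU",
                                        weight = 3, shear = 1, tag = 1,
                                        combo = 1)))
  g <- build_graph(samples, quiet_cfg)
  m <- export_matrix(g)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  back <- read_matrix(path)
  expect_identical(back$ID, m$ID)
  expect_identical(back$subg, m$subg)
  expect_identical(back$numsubg, m$numsubg)
  for (s in attr(m, "samples")) expect_equal(back[[s]], m[[s]])
  # header is exactly as documented
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(header[1:7],
                   c("ID", "Chr", "Pos", "Strand", "numsubg", "numexp",
                     "subg"))
  # empty matrix: header-only file
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(export_matrix(clonal_graph()), p2)
  expect_length(readLines(p2), 1)
  # two exports are byte-identical
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(export_matrix(g), p3)
  expect_identical(readLines(p3), readLines(path))
})
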