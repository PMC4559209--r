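test_that("annotation counting adds 1 for full spans and 0.5 for partial", {
  fs <- bin_genome(genome_index("c1", 4000), 2000)
  # fragment 1 = [1, 2000], fragment 2 = [2001, 4000]
  cases <- list(
    list(feat = c(1, 3000), expect = c(1, 0.5)),      # covers frag 1 fully
    list(feat = c(300, 500), expect = c(0.5, 0)),     # strictly inside
    list(feat = c(1500, 2500), expect = c(0.5, 0.5)), # straddles boundary
    list(feat = c(1, 4000), expect = c(1, 1)))        # covers both fully
  for (cs in cases) {
    tr <- annotate_features(fs, tibble::tibble(
      chrom = "c1", start = cs$feat[1], end = cs$feat[2], type = "gene"))
    expect_equal(track_values(tr), cs$expect)
  }
  expect_equal(track_kind(tr), "annotation_count")
})

test_that("annotation counting is additive over feature batches", {
  g <- generate_genome(c(a = 40000), site_rate = 1 / 1500, seed = 13)
  fs <- g$fragments
  set.seed(14)
  st <- sample(39000, 60)
  feats <- tibble::tibble(chrom = "a", start = st,
                          end = pmin(st + sample(5000, 60), 40000),
                          type = "gene")
  whole <- annotate_features(fs, feats)
  part1 <- annotate_features(fs, feats[1:30, ])
  part2 <- annotate_features(fs, feats[31:60, ])
  expect_equal(track_values(whole),
               track_values(part1) + track_values(part2))
  # features on unknown chromosomes are skipped with a warning
  expect_warning(
    tr <- annotate_features(fs, dplyr::bind_rows(
      feats[1, ], tibble::tibble(chrom = "zz", start = 1, end = 10,
                                 type = "gene"))),
    "unknown")
  expect_equal(attr(tr, "skipped_features"), 1L)
})

test_that("short-feature counts assign each read once by its 5' base", {
  fs <- bin_genome(genome_index("c1", 4000), 1000)
  reads <- tibble::tibble(chrom = "c1",
                          pos = c(500L, 600L, 700L, 800L, 900L, 1001L))
  tr <- count_short_features(fs, reads)
  expect_equal(track_values(tr), c(5, 1, 0, 0))
  expect_equal(sum(track_values(tr)), nrow(reads))
  expect_equal(track_values(count_short_features(fs, reads[0, ])),
               rep(0, 4))
})

test_that("density uses union coverage, not depth", {
  fs <- bin_genome(genome_index("c1", 100), 100)
  tr <- compute_density(fs, tibble::tibble(chrom = "c1",
                                           start = c(1, 21), end = c(30, 50)))
  expect_equal(track_values(tr), 50)   # union [1,50] = 50 of 100 bases
  # full cover and no cover bounds
  expect_equal(track_values(compute_density(
    fs, tibble::tibble(chrom = "c1", start = 1, end = 100))), 100)
  fs2 <- bin_genome(genome_index("c1", 200), 100)
  expect_equal(track_values(compute_density(
    fs2, tibble::tibble(chrom = "c1", start = 10, end = 20)))[2], 0)
  # concatenation of disjoint elements equals density of their union
  set.seed(3)
  st <- sample(180, 40)
  els <- tibble::tibble(chrom = "c1", start = st,
                        end = pmin(st + sample(15, 40, replace = TRUE), 200))
  red <- GenomicRanges::reduce(GenomicRanges::GRanges(
    "c1", IRanges::IRanges(els$start, els$end)))
  expect_equal(track_values(compute_density(fs2, els)),
               track_values(compute_density(fs2, red)))
})

test_that("methylation density pools calls and leaves empty fragments NA", {
  fs <- bin_genome(genome_index("c1", 4000), 2000)
  calls <- tibble::tibble(chrom = "c1", pos = c(100L, 200L),
                          methylated = c(5L, 0L), total = c(10L, 10L))
  tr <- methylation_density(fs, calls)
  expect_equal(track_values(tr), c(25, NA))   # pooled 5/20, not mean(50, 0)
  full <- tibble::tibble(chrom = "c1", pos = c(50L, 2500L),
                         methylated = c(10L, 7L), total = c(10L, 7L))
  expect_equal(track_values(methylation_density(fs, full)), c(100, 100))
  bad <- tibble::tibble(chrom = "c1", pos = 1L, methylated = 5L, total = 3L)
  expect_error(methylation_density(fs, bad), "exceeds")
})

test_that("aggregation sums counts and length-weights densities", {
  fine <- bin_genome(genome_index("c1", 4000), 1000)
  coarse <- bin_genome(genome_index("c1", 4000), 2000)
  cnt <- new_track(c(2, 3, 1, 0), fine, "n", "short_count")
  expect_equal(track_values(aggregate_track(cnt, fine, coarse)), c(5, 1))
  den <- new_track(c(40, 60, NA, 80), fine, "d", "density")
  agg <- aggregate_track(den, fine, coarse)
  expect_equal(track_values(agg), c(50, 80))  # equal lengths: plain mean
  # length weighting: a 2000-bp and a 1000-bp fragment in one coarse bin
  fine2 <- bin_genome(genome_index("c1", 3000), 2000)  # lengths 2000, 1000
  coarse1 <- bin_genome(genome_index("c1", 3000), 3000)
  den2 <- new_track(c(40, 80), fine2, "d", "density")
  expect_equal(track_values(aggregate_track(den2, fine2, coarse1)),
               (40 * 2000 + 80 * 1000) / 3000)
  # identity when coarse = fine
  expect_equal(track_values(aggregate_track(cnt, fine, fine)),
               track_values(cnt))
})

test_that("count totals are conserved and densities bounded under aggregation", {
  g <- generate_genome(c(a = 60000, b = 30000), site_rate = 1 / 1200,
                       seed = 17)
  fine <- g$fragments
  coarse <- bin_genome(g$sequences, 10000)
  labels <- alternating_blocks(fine, 5)
  sim <- simulate_tracks(fine, labels, effect_size = 2, seed = 18)
  cnt <- count_short_features(fine, sim$reads)
  agg <- aggregate_track(cnt, fine, coarse)
  expect_equal(sum(track_values(agg)), sum(track_values(cnt)))
  den <- methylation_density(fine, sim$calls)
  dagg <- aggregate_track(den, fine, coarse)
  v <- track_values(dagg)
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 100))
})

test_that("simulated track files reproduce the in-memory tracks", {
  g <- generate_genome(c(a = 50000), site_rate = 1 / 1500, seed = 23)
  fs <- g$fragments
  labels <- alternating_blocks(fs, 4)
  dir <- withr::local_tempdir()
  sim <- simulate_tracks(fs, labels, effect_size = 2, seed = 24, dir = dir)
  # GFF path equals direct interval path (1/0.5 arithmetic incl.)
  tr_file <- annotate_features(fs, sim$files$gff, feature_type = "gene")
  tr_mem <- annotate_features(fs, sim$features, feature_type = "gene")
  expect_equal(track_values(tr_file), track_values(tr_mem))
  # SAM path equals direct 5'-position path
  sc_file <- count_short_features(fs, sim$files$sam)
  sc_mem <- count_short_features(fs, sim$reads)
  expect_equal(track_values(sc_file), track_values(sc_mem))
  expect_equal(sum(track_values(sc_file)), nrow(sim$reads))
  # methylation TSV path
  md_file <- methylation_density(fs, sim$files$methylation)
  md_mem <- methylation_density(fs, sim$calls)
  expect_equal(track_values(md_file), track_values(md_mem))
})

test_that("track tables round-trip with their kind header", {
  fs <- bin_genome(genome_index("c1", 9000), 1000)
  tr1 <- new_track(rpois(9, 4), fs, "genes", "annotation_count")
  tr2 <- new_track(runif(9, 0, 100), fs, "chip", "density")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_track_table(list(tr1, tr2), fs, path)
  back <- read_track_table(path, fs)
  expect_equal(track_values(back$genes), track_values(tr1))
  expect_equal(track_kind(back$chip), "density")
})
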