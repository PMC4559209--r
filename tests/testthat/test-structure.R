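test_that("IDE of an exact power law equals its exponent", {
  n <- 100
  bs <- 1000
  fs <- bin_genome(genome_index("c1", n * bs), bs)
  d <- abs(outer(1:n, 1:n, "-"))
  mu <- 100 * (d * bs)^(-1)
  diag(mu) <- 1
  ide <- compute_ide(dense_to_interaction(mu, fs))
  expect_equal(ide$slope, -1, tolerance = 1e-9)
  # constant mean profile: slope 0
  flat <- matrix(7, n, n)
  ide0 <- compute_ide(dense_to_interaction(flat, fs))
  expect_equal(ide0$slope, 0, tolerance = 1e-12)
  # scale invariance: slope unchanged, intercept shifts by log10(c)
  ide10 <- compute_ide(dense_to_interaction(10 * mu, fs))
  expect_equal(ide10$slope, ide$slope, tolerance = 1e-9)
  expect_equal(ide10$intercept - ide$intercept, 1, tolerance = 1e-9)
})

test_that("IDE recovers a noisy planted exponent", {
  set.seed(89)
  n <- 120
  bs <- 1000
  fs <- bin_genome(genome_index("c1", n * bs), bs)
  d <- abs(outer(1:n, 1:n, "-"))
  mu <- 50 * pmax(d * bs, bs)^(-0.85) * 1e3
  noisy <- mu * exp(matrix(rnorm(n * n, 0, 0.1), n, n))
  noisy[lower.tri(noisy)] <- t(noisy)[lower.tri(noisy)]
  ide <- compute_ide(dense_to_interaction(noisy, fs))
  expect_lt(abs(ide$slope - (-0.85)), 0.03)
  expect_error(compute_ide(dense_to_interaction(noisy, fs),
                           fit_range = c(1000, 2000)),
               "fewer than 3")
})

test_that("IDE region subsetting restricts both endpoints", {
  ds <- sim_binned_dataset()
  whole <- compute_ide(ds$matrix)
  left <- compute_ide(ds$matrix,
                      regions = region_set("c1", 1, 250000, "left"))
  expect_s3_class(left, "ide_result")
  # the subset uses fewer pairs than the genome-wide fit
  expect_lt(sum(left$table$n_pairs), sum(whole$table$n_pairs))
})

test_that("FPC sign recovers a planted two-block checkerboard", {
  set.seed(97)
  n <- 80
  fs <- bin_genome(genome_index("c1", n * 1000), 1000)
  blocks <- rep(c("A", "B"), each = 40)
  model <- contact_model(decay_exponent = 0.85, block_contrast = 2,
                         blocks = blocks)
  sim <- simulate_pairs(fs, model, n_pairs = 2e5, seed = 101)
  res <- compartment_fpc(sim$truth)
  lab <- res$fragments$label
  acc <- max(mean((lab == "A-like") == (blocks == "A")),
             mean((lab == "B-like") == (blocks == "A")))
  expect_gte(acc, 0.95)
  expect_true(all(res$chromosomes$var_explained > 0))
})

test_that("FPC orientation follows the supplied track; magnitude is sign-stable", {
  set.seed(103)
  n <- 80
  fs <- bin_genome(genome_index("c1", n * 1000), 1000)
  blocks <- rep(c("A", "B"), each = 40)
  sim <- simulate_pairs(fs, contact_model(0.85, 2, blocks = blocks),
                        2e5, seed = 101)
  anchor <- new_track(ifelse(blocks == "A", 10, 1), fs, "genes",
                      "annotation_count")
  res_up <- compartment_fpc(sim$truth, orientation_track = anchor)
  flipped <- new_track(ifelse(blocks == "A", 1, 10), fs, "genes",
                       "annotation_count")
  res_dn <- compartment_fpc(sim$truth, orientation_track = flipped)
  expect_equal(abs(res_up$fragments$fpc), abs(res_dn$fragments$fpc))
  expect_equal(res_up$chromosomes$var_explained,
               res_dn$chromosomes$var_explained)
  expect_gt(cor(res_up$fragments$fpc, track_analysis_values(anchor)), 0)
  expect_equal(res_up$fragments$fpc, -res_dn$fragments$fpc)
})

test_that("a homogeneous chromosome is flagged as compartment-unstable", {
  set.seed(107)
  n <- 60
  fs <- bin_genome(genome_index("c1", n * 1000), 1000)
  sim <- simulate_pairs(fs, contact_model(decay_exponent = 0.85), 1e5,
                        seed = 109)
  res <- compartment_fpc(sim$truth, flag_below = 0.2)
  expect_true(res$chromosomes$flagged[1])
  # compared against strong planted structure, variance explained is low
  blocks <- rep(c("A", "B"), each = 30)
  sim2 <- simulate_pairs(fs, contact_model(0.85, 3, blocks = blocks), 1e5,
                         seed = 109)
  res2 <- compartment_fpc(sim2$truth)
  expect_gt(res2$chromosomes$var_explained,
            res$chromosomes$var_explained)
})

test_that("FPC/track correlation handles exact, opposite and constant tracks", {
  ds <- sim_binned_dataset()
  res <- compartment_fpc(ds$matrix)
  fpc <- res$fragments$fpc
  as_density <- function(v) {
    new_track(100 * (v - min(v)) / diff(range(v)), ds$fragments, "t",
              "density")
  }
  out <- fpc_track_correlation(res, list(
    same = as_density(fpc), opposite = as_density(-fpc),
    flat = new_track(rep(50, length(fpc)), ds$fragments, "flat", "density")))
  expect_equal(out$estimate[1], 1, tolerance = 1e-9)
  expect_equal(out$estimate[2], -1, tolerance = 1e-9)
  expect_true(is.na(out$estimate[3]))
  expect_lt(out$p_value[1], 1e-10)
})

test_that("sign-group enrichment computes ratios and Wilcoxon significance", {
  set.seed(113)
  n <- 80
  fs <- bin_genome(genome_index("c1", n * 1000), 1000)
  blocks <- rep(c("A", "B"), each = 40)
  sim <- simulate_pairs(fs, contact_model(0.85, 2, blocks = blocks),
                        2e5, seed = 101)
  anchor <- new_track(ifelse(blocks == "A", 10, 5), fs, "anchor",
                      "annotation_count")
  res <- compartment_fpc(sim$truth, orientation_track = anchor)
  enr <- fpc_sign_enrichment(res, anchor)
  expect_equal(enr$ratio, enr$mean_positive / enr$mean_negative)

  # hand-built groups: means 10 and 5 give ratio 2; disjoint supports give
  # the minimal exact Wilcoxon p for the group sizes
  pos_ids <- res$fragments$fpc > 0
  vals <- numeric(n)
  vals[pos_ids] <- 10
  vals[!pos_ids] <- 5
  exact <- fpc_sign_enrichment(res, new_track(vals, fs, "x", "density"))
  expect_equal(exact$ratio, 2)
  sep_vals <- ifelse(pos_ids, 90 + seq_len(n) / n, seq_len(n) / n)
  sep <- fpc_sign_enrichment(res, new_track(sep_vals, fs, "y", "density"))
  expect_equal(sep$p_value,
               wilcox.test(sep_vals[pos_ids], sep_vals[!pos_ids])$p.value,
               tolerance = 1e-9)
})

test_that("null tracks give ratio near 1 and uniform-ish enrichment p-values", {
  set.seed(127)
  ds <- sim_binned_dataset()
  res <- compartment_fpc(ds$matrix)
  pvals <- replicate(100, {
    tr <- new_track(runif(nrow(ds$fragments), 0, 100), ds$fragments, "r",
                    "density")
    fpc_sign_enrichment(res, tr)$p_value
  })
  expect_gt(mean(pvals > 0.05), 0.8)
  tr <- new_track(runif(nrow(ds$fragments), 40, 60), ds$fragments, "r",
                  "density")
  expect_lt(abs(fpc_sign_enrichment(res, tr)$ratio - 1), 0.1)
})
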