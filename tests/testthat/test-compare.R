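test_that("sample correlation is 1 for identical or rescaled matrices", {
  ds <- sim_binned_dataset()
  a <- ds$matrix
  b2 <- interaction_matrix(dplyr::mutate(a$counts, count = 2 * count),
                           ds$fragments)
  sc <- sample_correlation(list(a = a, twice = b2))
  expect_equal(unname(sc["a", "twice"]), 1, tolerance = 1e-12)
  expect_equal(diag(sc), c(a = 1, twice = 1))
  scm <- sample_correlation(list(a = a, twice = b2), statistic = "median")
  expect_equal(unname(scm["a", "twice"]), 1, tolerance = 1e-12)
})

test_that("independent random matrices correlate near zero", {
  set.seed(61)
  n <- 500
  fs <- bin_genome(genome_index("c1", n * 1000), 1000)
  mk <- function() {
    m <- matrix(rpois(n * n, 5), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    dense_to_interaction(m, fs)
  }
  sc <- sample_correlation(list(x = mk(), y = mk()))
  expect_lt(abs(sc["x", "y"]), 0.05)
})

test_that("relative differences follow the paired-average formula", {
  fs <- bin_genome(genome_index("c1", 2000), 1000)
  a <- dense_to_interaction(matrix(c(3, 3, 3, 0), 2), fs)
  b <- dense_to_interaction(matrix(c(1, 1, 1, 0), 2), fs)
  rd <- relative_difference(a, b)
  expect_equal(rd$matrix[1, 1], 1)          # (3-1)/((3+1)/2)
  expect_equal(rd$matrix[2, 2], 0)          # both zero -> 0
  # A = B -> all zeros
  expect_true(all(relative_difference(a, a)$matrix == 0))
  # antisymmetry
  expect_equal(relative_difference(b, a)$matrix, -rd$matrix)
})

test_that("relative differences are bounded by [-2, 2], attained at zeros", {
  set.seed(67)
  n <- 40
  fs <- bin_genome(genome_index("c1", n * 1000), 1000)
  for (rep in 1:3) {
    a <- matrix(rpois(n * n, 3), n, n); a[lower.tri(a)] <- t(a)[lower.tri(a)]
    b <- matrix(rpois(n * n, 3), n, n); b[lower.tri(b)] <- t(b)[lower.tri(b)]
    rd <- relative_difference(dense_to_interaction(a, fs),
                              dense_to_interaction(b, fs))
    expect_true(all(rd$matrix >= -2 & rd$matrix <= 2))
    one_sided <- a > 0 & b == 0
    if (any(one_sided)) expect_true(all(rd$matrix[one_sided] == 2))
  }
})

test_that("correlated differences find identical and opposite rows", {
  fs <- bin_genome(genome_index("c1", 4000), 1000)
  m <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(-1, -2, -3, -4), c(4, 1, 3, 2))
  m <- (m + t(m)) / 2  # keep it symmetric for the container contract
  rd <- structure(list(matrix = m, kind = "relative_difference",
                       fragments = fs), class = "comparison_result")
  cd <- correlated_difference(rd)
  expect_equal(cd$matrix[1, 2], cor(m[1, ], m[2, ]))
  expect_equal(diag(cd$matrix), rep(1, 4))
  expect_true(all(cd$matrix >= -1 & cd$matrix <= 1, na.rm = TRUE))
  expect_error(correlated_difference(cd), "relative_difference")
})

test_that("correlated differences expose planted difference blocks", {
  set.seed(71)
  n <- 60
  fs <- bin_genome(genome_index("c1", n * 1000), 1000)
  base <- matrix(rpois(n * n, 20) + 5, n, n)
  base[lower.tri(base)] <- t(base)[lower.tri(base)]
  # opposite-direction changes in two domains
  b1 <- 1:20
  b2 <- 31:50
  shifted <- base
  shifted[b1, b1] <- shifted[b1, b1] * 2
  shifted[b2, b2] <- round(shifted[b2, b2] * 0.5)
  rd <- relative_difference(dense_to_interaction(shifted, fs),
                            dense_to_interaction(base, fs))
  cd <- correlated_difference(rd)$matrix
  within <- mean(c(cd[b1, b1][upper.tri(cd[b1, b1])],
                   cd[b2, b2][upper.tri(cd[b2, b2])]))
  between <- mean(cd[b1, b2])
  expect_gt(within, between)
})

test_that("signed differences report extent and direction", {
  ds <- sim_binned_dataset()
  a <- dense_matrix(ds$matrix)
  offset <- a
  region <- 1:30
  offset[region, region] <- offset[region, region] + 1
  fs <- ds$fragments
  sd_off <- signed_difference(dense_to_interaction(offset, fs), ds$matrix,
                              permutations = 9, seed = 1,
                              regions = region_set("c1", 1, 150000, "boost"))
  expect_true(all(sd_off$matrix[region, region] == 1))
  rs <- sd_off$region_statistics
  expect_equal(rs$statistic[rs$label == "boost"], 1)
  # antisymmetry under swapping samples
  sd_ba <- signed_difference(ds$matrix, dense_to_interaction(offset, fs),
                             permutations = 9, seed = 1)
  expect_identical(sd_ba$matrix, -sd_off$matrix)
  expect_error(signed_difference(ds$matrix, ds$matrix, permutations = 0),
               "permutations")
})

test_that("the SDM statistic is near zero and non-significant under the null", {
  set.seed(73)
  n <- 50
  fs <- bin_genome(genome_index("c1", n * 1000), 1000)
  mk <- function() {
    m <- matrix(rpois(n * n, 10), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    dense_to_interaction(m, fs)
  }
  res <- signed_difference(mk(), mk(), permutations = 199, seed = 5)
  expect_lt(res$statistic, 0.1)
  expect_gt(res$p_value, 0.05)
})

test_that("SDM p-values are approximately uniform under the null", {
  set.seed(79)
  n <- 30
  fs <- bin_genome(genome_index("c1", n * 1000), 1000)
  pvals <- replicate(200, {
    a <- matrix(rpois(n * n, 8), n, n); a[lower.tri(a)] <- t(a)[lower.tri(a)]
    b <- matrix(rpois(n * n, 8), n, n); b[lower.tri(b)] <- t(b)[lower.tri(b)]
    signed_difference(dense_to_interaction(a, fs),
                      dense_to_interaction(b, fs),
                      permutations = 99)$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("replicate-label permutation provides the SDM null when given", {
  set.seed(83)
  n <- 30
  fs <- bin_genome(genome_index("c1", n * 1000), 1000)
  mk <- function(mu) {
    m <- matrix(rpois(n * n, mu), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    dense_to_interaction(m, fs)
  }
  res <- signed_difference(replicates_a = list(mk(8), mk(8), mk(8)),
                           replicates_b = list(mk(8), mk(8), mk(8)),
                           permutations = 99, seed = 3)
  expect_equal(res$null_type, "replicate_permutation")
  expect_gt(res$p_value, 0.05)
  # a real shift scores at the resolution limit of 3v3 label permutation:
  # only 2 of the 20 splits keep the groups intact, so p floors near 0.1
  res2 <- signed_difference(replicates_a = list(mk(12), mk(12), mk(12)),
                            replicates_b = list(mk(8), mk(8), mk(8)),
                            permutations = 99, seed = 3)
  expect_lt(res2$p_value, 0.15)
  expect_lt(res2$p_value, res$p_value)
  expect_gt(res2$statistic, 0.5)   # strongly one-sided shift
})

test_that("heatmaps are written for contact and comparison matrices", {
  ds <- sim_binned_dataset()
  p1 <- withr::local_tempfile(fileext = ".png")
  render_heatmap(ds$matrix, p1, width = 3, height = 3)
  expect_gt(file.size(p1), 0)
  rd <- relative_difference(ds$matrix, ds$matrix)
  p2 <- withr::local_tempfile(fileext = ".png")
  render_heatmap(rd, p2, width = 3, height = 3)
  expect_gt(file.size(p2), 0)
  expect_s3_class(autoplot(rd), "ggplot")
})
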