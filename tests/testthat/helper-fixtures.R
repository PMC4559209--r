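# Shared fixtures, generated in code and cached for the session.

fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, builder(), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

# 160-bin two-chromosome binned genome with planted compartments and biases,
# used by the normalization / structure / comparison tests
sim_binned_dataset <- function() {
  get_fixture("sim_binned", function() {
    fs <- bin_genome(genome_index(c("c1", "c2"), c(100 * 5000, 60 * 5000)),
                     5000)
    blocks <- alternating_blocks(fs, 20)
    set.seed(99)
    bias <- exp(stats::rnorm(nrow(fs), 0, 0.3))
    model <- contact_model(decay_exponent = 0.85, block_contrast = 2,
                           bias = bias, blocks = blocks)
    sim <- simulate_pairs(fs, model, n_pairs = 4e5, seed = 5)
    list(fragments = fs, blocks = blocks, bias = bias, model = model,
         matrix = sim$truth)
  })
}

# dense symmetric Poisson draw around a mean matrix
rpois_symmetric <- function(mu) {
  n <- nrow(mu)
  m <- matrix(stats::rpois(n * n, mu), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

dense_to_interaction <- function(m, fragments) {
  ut <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  interaction_matrix(
    tibble::tibble(id1 = ut[, 1], id2 = ut[, 2], count = m[ut]),
    fragments)
}

# hand-built pair tibble in the normalized (end1 lower) orientation
make_pairs <- function(chrom1, pos1, strand1, chrom2, pos2, strand2) {
  tibble::tibble(read = sprintf("r%03d", seq_along(chrom1)),
                 chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
                 chrom2 = chrom2, pos2 = pos2, strand2 = strand2)
}
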