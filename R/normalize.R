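new_normalized_matrix <- function(mat, fragments, method, params = list()) {
  ids <- as.character(fragments$fragment_id)
  dimnames(mat) <- list(ids, ids)
  structure(list(matrix = mat, fragments = fragments, method = method,
                 params = params),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d x %d, method = %s\n",
              nrow(x$matrix), ncol(x$matrix), x$method))
  invisible(x)
}

as_dense_input <- function(x) {
  if (inherits(x, "interaction_matrix")) {
    list(mat = dense_matrix(x), fragments = x$fragments)
  } else if (inherits(x, "normalized_matrix")) {
    list(mat = x$matrix, fragments = x$fragments)
  } else if (is.matrix(x)) {
    stop("raw matrices are not accepted: wrap counts in interaction_matrix()")
  } else {
    stop("expected an interaction_matrix or normalized_matrix")
  }
}

chrom_blocks <- function(fragments) {
  split(seq_len(nrow(fragments)), fragments$chrom)[unique(fragments$chrom)]
}

#' Distance (intra) and coverage (inter) normalization
#'
#' Intra-chromosomal entries are divided by the expected value at their
#' genomic distance: the mean of all intra-chromosomal entries in the same
#' distance class (fragment offset |i - j|), pooled across chromosomes by
#' default. After normalization the mean of every intra-chromosomal diagonal
#' equals 1 wherever it is defined. Inter-chromosomal entries are divided by
#' (row mean x column mean / overall mean) computed on inter-chromosomal
#' entries, the coverage expectation.
#'
#' @param x An `interaction_matrix`.
#' @param per_chromosome Compute distance expectations per chromosome
#'   instead of pooled (default FALSE).
#' @return A `normalized_matrix` (method `distance_coverage`). Entries in
#'   all-zero distance classes or with zero coverage are NA; their number is
#'   reported in `$params$masked`.
#' @export
normalize_distance_coverage <- function(x, per_chromosome = FALSE) {
  inp <- as_dense_input(x)
  mat <- inp$mat
  frags <- inp$fragments
  if (sum(mat) == 0) stop("empty interaction matrix")
  n <- nrow(mat)
  out <- matrix(NA_real_, n, n)
  blocks <- chrom_blocks(frags)

  # ---- intra-chromosomal: observed / expected-at-distance ----
  if (per_chromosome) {
    for (idx in blocks) {
      sub <- mat[idx, idx, drop = FALSE]
      out[idx, idx] <- .divide_by_distance_expectation(sub)
    }
  } else {
    # pooled expectation: mean over all chromosomes of same-offset entries
    m <- max(vapply(blocks, length, integer(1)))
    sums <- numeric(m)
    cnts <- numeric(m)
    for (idx in blocks) {
      sub <- mat[idx, idx, drop = FALSE]
      k <- nrow(sub)
      for (d in 0:(k - 1)) {
        diag_vals <- sub[cbind(seq_len(k - d), seq_len(k - d) + d)]
        sums[d + 1] <- sums[d + 1] + sum(diag_vals)
        cnts[d + 1] <- cnts[d + 1] + length(diag_vals)
      }
    }
    expected <- ifelse(cnts > 0, sums / cnts, NA_real_)
    expected[expected == 0] <- NA_real_
    for (idx in blocks) {
      k <- length(idx)
      d <- abs(outer(seq_len(k), seq_len(k), "-"))
      out[idx, idx] <- mat[idx, idx] / matrix(expected[d + 1], k, k)
    }
  }

  # ---- inter-chromosomal: coverage expectation ----
  chrom_of <- frags$chrom
  inter_mask <- outer(chrom_of, chrom_of, "!=")
  if (any(inter_mask)) {
    inter <- mat
    inter[!inter_mask] <- NA
    rm_ <- rowMeans(inter, na.rm = TRUE)
    cm_ <- colMeans(inter, na.rm = TRUE)
    om <- mean(inter, na.rm = TRUE)
    exp_inter <- outer(rm_, cm_) / om
    exp_inter[exp_inter == 0] <- NA
    out[inter_mask] <- mat[inter_mask] / exp_inter[inter_mask]
  }
  new_normalized_matrix(out, frags, "distance_coverage",
                        params = list(per_chromosome = per_chromosome,
                                      masked = sum(is.na(out))))
}

.divide_by_distance_expectation <- function(sub) {
  k <- nrow(sub)
  res <- matrix(NA_real_, k, k)
  for (d in 0:(k - 1)) {
    ii <- seq_len(k - d)
    e <- mean(sub[cbind(ii, ii + d)])
    if (e > 0) {
      res[cbind(ii, ii + d)] <- sub[cbind(ii, ii + d)] / e
      res[cbind(ii + d, ii)] <- res[cbind(ii, ii + d)]
    }
  }
  res
}

#' Iterative correction (ICE) of an interaction matrix
#'
#' Factors the observed matrix as O = B W B with a diagonal bias matrix B,
#' iteratively rescaling until all unmasked row sums of W are equal. Bins
#' with total coverage below the `mask_percentile` quantile (and all-zero
#' bins) are masked out before balancing. The recovered bias vector is
#' normalized to mean 1 over unmasked bins, which fixes the scale of W.
#'
#' @param x An `interaction_matrix`.
#' @param tolerance Convergence tolerance on the relative spread of row sums
#'   (default 1e-5).
#' @param max_iterations Maximum iterations (default 200); non-convergence
#'   is an error reporting the last residual.
#' @param mask_percentile Fraction of lowest-coverage bins to mask
#'   (default 0.02).
#' @return A `normalized_matrix` (method `iterative`); `$params` holds the
#'   `bias` vector (NA at masked bins), `iterations` and final `residual`.
#' @export
normalize_iterative <- function(x, tolerance = 1e-5, max_iterations = 200L,
                                mask_percentile = 0.02) {
  inp <- as_dense_input(x)
  mat <- inp$mat
  frags <- inp$fragments
  n <- nrow(mat)
  cov <- rowSums(mat)
  cut <- stats::quantile(cov[cov > 0], mask_percentile, names = FALSE)
  masked <- cov == 0 | cov < cut
  if (all(masked)) stop("all bins masked; matrix too sparse to balance")
  keep <- which(!masked)
  W <- mat[keep, keep, drop = FALSE]
  b <- rep(1, length(keep))
  residual <- Inf
  iters <- 0L
  for (it in seq_len(max_iterations)) {
    s <- rowSums(W)
    if (any(s == 0)) stop("zero row sum among unmasked bins during balancing")
    db <- s / mean(s)
    W <- W / outer(db, db)
    b <- b * db
    residual <- max(abs(s / mean(s) - 1))
    iters <- it
    if (residual < tolerance) break
  }
  if (residual >= tolerance) {
    stop(sprintf(
      "iterative correction did not converge in %d iterations (residual %g)",
      max_iterations, residual))
  }
  # fix the scale: bias has mean 1 over unmasked bins
  scale <- mean(b)
  b <- b / scale
  W <- W * scale^2
  out <- matrix(NA_real_, n, n)
  out[keep, keep] <- W
  bias <- rep(NA_real_, n)
  bias[keep] <- b
  new_normalized_matrix(out, frags, "iterative",
                        params = list(bias = bias, iterations = iters,
                                      residual = residual,
                                      masked = which(masked)))
}

#' Fragment covariates for Poisson-regression normalization
#'
#' @param fragments A `fragment_set`.
#' @param genome_seq Optional `DNAStringSet` (or FASTA path) to compute the
#'   per-fragment GC fraction from; default GC = 0.5 everywhere.
#' @param mappability Optional numeric vector in \[0, 1\] per fragment;
#'   default 1 (fully mappable).
#' @return A tibble `fragment_id`, `length`, `gc`, `mappability`.
#' @export
fragment_covariates <- function(fragments, genome_seq = NULL,
                                mappability = NULL) {
  gc <- rep(0.5, nrow(fragments))
  if (!is.null(genome_seq)) {
    if (is.character(genome_seq)) genome_seq <- read_genome_fasta(genome_seq)
    for (ch in unique(fragments$chrom)) {
      sel <- fragments$chrom == ch
      views <- Biostrings::Views(genome_seq[[ch]],
                                 start = fragments$start[sel],
                                 end = fragments$end[sel])
      freq <- Biostrings::letterFrequency(views, letters = c("G", "C"))
      gc[sel] <- rowSums(freq) / fragments$length[sel]
    }
  }
  if (is.null(mappability)) mappability <- rep(1, nrow(fragments))
  stopifnot(length(mappability) == nrow(fragments),
            all(mappability >= 0 & mappability <= 1))
  tibble::tibble(fragment_id = fragments$fragment_id,
                 length = fragments$length, gc = gc,
                 mappability = mappability)
}

#' Poisson-regression normalization (HiCNorm-style)
#'
#' Per chromosome, fits a log-linear Poisson model of the observed counts on
#' the upper triangle (diagonal excluded): log E\[O_ij\] = beta0 +
#' beta1 log(len_i len_j) + beta2 log(gc_i gc_j) + log(map_i map_j), the
#' last term a fixed offset. The normalized entry is the observed count
#' divided by the fitted systematic part (intercept excluded), which removes
#' fragment-length, GC and mappability biases while preserving overall
#' scale. Covariates with zero variance on a chromosome are dropped with a
#' warning. Inter-chromosomal entries are passed through unchanged.
#'
#' @param x An `interaction_matrix`.
#' @param covariates Tibble from [fragment_covariates()].
#' @return A `normalized_matrix` (method `poisson_regression`); `$params`
#'   holds the per-chromosome coefficient tables and the residual Spearman
#'   correlation of the normalized entries with log(len_i len_j).
#' @export
normalize_poisson <- function(x, covariates) {
  inp <- as_dense_input(x)
  mat <- inp$mat
  frags <- inp$fragments
  stopifnot(nrow(covariates) == nrow(frags))
  covariates <- covariates[match(frags$fragment_id, covariates$fragment_id), ]
  out <- mat
  blocks <- chrom_blocks(frags)
  coefs <- list()
  resid_rho <- c()
  for (ch in names(blocks)) {
    idx <- blocks[[ch]]
    k <- length(idx)
    if (k < 3L) next
    ut <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    o <- mat[idx, idx][ut]
    len <- covariates$length[idx]
    gc <- covariates$gc[idx]
    mp <- covariates$mappability[idx]
    x_len <- log(len[ut[, 1]] * len[ut[, 2]])
    x_gc <- log(gc[ut[, 1]] * gc[ut[, 2]])
    off <- log(mp[ut[, 1]] * mp[ut[, 2]])
    df <- data.frame(o = o, x_len = x_len, x_gc = x_gc, off = off)
    terms <- c("x_len", "x_gc")
    for (tm in terms) {
      if (stats::var(df[[tm]]) == 0) {
        warning("covariate ", tm, " constant on ", ch, "; dropped")
        terms <- setdiff(terms, tm)
      }
    }
    form <- stats::as.formula(paste(
      "o ~", if (length(terms)) paste(terms, collapse = " + ") else "1"))
    fit <- stats::glm(form, family = stats::poisson(),
                      offset = off, data = df)
    beta <- stats::coef(fit)
    systematic <- exp(off + as.matrix(df[, terms, drop = FALSE]) %*%
                        beta[terms])
    norm_vals <- o / as.numeric(systematic)
    sub <- out[idx, idx]
    sub[ut] <- norm_vals
    sub[ut[, c(2, 1), drop = FALSE]] <- norm_vals
    out[idx, idx] <- sub
    se <- summary(fit)$coefficients
    coefs[[ch]] <- tibble::tibble(term = rownames(se),
                                  estimate = se[, 1], std_error = se[, 2])
    if (stats::var(x_len) > 0) {
      resid_rho[ch] <- stats::cor(norm_vals, x_len, method = "spearman")
    }
  }
  new_normalized_matrix(out, frags, "poisson_regression",
                        params = list(coefficients = coefs,
                                      residual_rho_length = resid_rho))
}
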