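new_comparison_result <- function(mat, kind, fragments, extra = list()) {
  structure(c(list(matrix = mat, kind = kind, fragments = fragments), extra),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> kind = %s, %d x %d\n",
              x$kind, nrow(x$matrix), ncol(x$matrix)))
  if (!is.null(x$statistic)) {
    cat(sprintf("  |mean sign| = %.4f, empirical p = %.4g (%d permutations)\n",
                x$statistic, x$p_value, x$permutations))
  }
  invisible(x)
}

#' Sample correlation via virtual 4C profiles
#'
#' Each matrix row is the virtual 4C track of one bin: its interaction
#' profile against the whole genome. For every pair of samples, the Pearson
#' correlation of each bin's virtual 4C track between the two samples is
#' computed, and the correlations are summarized over bins by their mean or
#' median. Bins with zero variance in either sample are skipped for that
#' pair.
#'
#' @param matrices Named list of `interaction_matrix` / `normalized_matrix`
#'   objects on the same fragment set.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return A samples-by-samples correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(matrices, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stat_fun <- if (statistic == "mean") mean else stats::median
  if (length(matrices) < 2L) stop("need at least two samples")
  dense <- lapply(matrices, function(m) as_dense_input(m)$mat)
  dims <- vapply(dense, nrow, integer(1))
  if (length(unique(dims)) != 1L) {
    stop("all matrices must be on the same fragment set")
  }
  k <- length(dense)
  nm <- names(matrices) %||% paste0("sample", seq_len(k))
  out <- diag(1, k)
  dimnames(out) <- list(nm, nm)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      rs <- vapply(seq_len(dims[1]), function(i) {
        x <- dense[[a]][i, ]
        y <- dense[[b]][i, ]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
          return(NA_real_)
        }
        stats::cor(x[ok], y[ok])
      }, numeric(1))
      out[a, b] <- out[b, a] <- stat_fun(rs[!is.na(rs)])
    }
  }
  out
}

#' Relative differences between two samples
#'
#' Entrywise (A - B) / ((A + B) / 2): the difference of each fragment pair
#' divided by its average interaction frequency across the two samples.
#' Values are bounded by \[-2, 2\] for non-negative inputs; entries that are
#' zero in both samples are defined as 0 (no evidence of difference).
#'
#' @param a,b `interaction_matrix` / `normalized_matrix` objects on the same
#'   fragment set.
#' @return A `comparison_result` of kind `relative_difference`.
#' @export
relative_difference <- function(a, b) {
  da <- as_dense_input(a)
  db <- as_dense_input(b)
  if (!identical(dim(da$mat), dim(db$mat))) stop("matrix shapes differ")
  avg <- (da$mat + db$mat) / 2
  rd <- (da$mat - db$mat) / avg
  rd[!is.na(avg) & avg == 0] <- 0
  new_comparison_result(rd, "relative_difference", da$fragments)
}

#' Correlated differences
#'
#' Neighbouring genomic regions are physically linked and tend to change
#' together; correlating the rows of the relative-difference matrix makes
#' such coordinated domains visible. Entry (i, j) is the Pearson correlation
#' of rows i and j of the relative-difference matrix.
#'
#' @param rd A `comparison_result` of kind `relative_difference`.
#' @return A `comparison_result` of kind `correlated_difference` with unit
#'   diagonal; rows with zero variance yield NA entries.
#' @export
correlated_difference <- function(rd) {
  if (!inherits(rd, "comparison_result") || rd$kind != "relative_difference") {
    stop("input must be a relative_difference comparison_result")
  }
  m <- rd$matrix
  sds <- apply(m, 1, stats::sd, na.rm = TRUE)
  cc <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  cc[sds == 0 | is.na(sds), ] <- NA
  cc[, sds == 0 | is.na(sds)] <- NA
  diag(cc) <- 1
  new_comparison_result(cc, "correlated_difference", rd$fragments)
}

upper_entries <- function(n) which(upper.tri(matrix(0, n, n), diag = FALSE))

sdm_statistic <- function(signs, sel) {
  v <- signs[sel]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  abs(mean(v))
}

#' Signed difference matrix (SDM) between two samples
#'
#' The SDM is the entrywise sign of A - B. Its summary statistic is the
#' absolute mean sign over unmasked upper-triangle entries: 0 when gains and
#' losses balance, 1 when the difference is wholly one-sided. Significance
#' is an empirical one-sided p-value, p = (k + 1) / (n + 1), against a null
#' built either by permuting replicate labels (when per-sample replicate
#' matrices are supplied) or by flipping the signs of independent entry
#' blocks (contiguous fragment blocks, preserving the spatial correlation of
#' neighbouring entries).
#'
#' @param a,b `interaction_matrix` / `normalized_matrix` objects.
#' @param replicates_a,replicates_b Optional lists of per-replicate matrices
#'   for each sample; when given, `a` and `b` are ignored and the sample
#'   matrices are the replicate means, with a replicate-label permutation
#'   null.
#' @param permutations Number of null permutations (default 999).
#' @param seed Optional integer seed for the permutation null.
#' @param block_size Fragments per sign-flip block (default 1, i.e.
#'   independent entries; raise it to match the spatial correlation length
#'   of the data, at the price of a more conservative test).
#' @param regions Optional `region_set`: the statistic is also reported per
#'   region (entries with both fragments inside the region).
#' @return A `comparison_result` of kind `signed_difference` with elements
#'   `statistic`, `p_value`, `null_statistics`, and `region_statistics` when
#'   regions were supplied.
#' @export
signed_difference <- function(a = NULL, b = NULL, replicates_a = NULL,
                              replicates_b = NULL, permutations = 999L,
                              seed = NULL, block_size = 1L, regions = NULL) {
  if (permutations < 1L) stop("permutations must be >= 1")
  use_replicates <- !is.null(replicates_a) && !is.null(replicates_b)
  if (use_replicates) {
    dense_a <- lapply(replicates_a, function(m) as_dense_input(m)$mat)
    dense_b <- lapply(replicates_b, function(m) as_dense_input(m)$mat)
    frags <- as_dense_input(replicates_a[[1]])$fragments
    ma <- Reduce(`+`, dense_a) / length(dense_a)
    mb <- Reduce(`+`, dense_b) / length(dense_b)
  } else {
    da <- as_dense_input(a)
    db <- as_dense_input(b)
    if (!identical(dim(da$mat), dim(db$mat))) stop("matrix shapes differ")
    ma <- da$mat
    mb <- db$mat
    frags <- da$fragments
  }
  n <- nrow(ma)
  signs <- sign(ma - mb)
  ut <- upper_entries(n)
  observed <- sdm_statistic(signs, ut)

  if (!is.null(seed)) set.seed(seed)
  null_stats <- numeric(permutations)
  if (use_replicates) {
    pool <- c(dense_a, dense_b)
    na_ <- length(dense_a)
    for (p in seq_len(permutations)) {
      lab <- sample(length(pool))
      pa <- Reduce(`+`, pool[lab[seq_len(na_)]]) / na_
      pb <- Reduce(`+`, pool[lab[-seq_len(na_)]]) / (length(pool) - na_)
      null_stats[p] <- sdm_statistic(sign(pa - pb), ut)
    }
  } else {
    block <- ceiling(seq_len(n) / block_size)
    nb <- max(block)
    ut_ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    eb <- block[ut_ij[, 1]] + nb * (block[ut_ij[, 2]] - 1)
    eb <- match(eb, unique(eb))
    sv <- signs[ut]
    for (p in seq_len(permutations)) {
      flips <- sample(c(-1, 1), max(eb), replace = TRUE)
      v <- sv * flips[eb]
      null_stats[p] <- abs(mean(v[!is.na(v)]))
    }
  }
  k <- sum(null_stats >= observed, na.rm = TRUE)
  p_value <- (k + 1) / (permutations + 1)

  region_stats <- NULL
  if (!is.null(regions)) {
    region_stats <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
      ids <- region_fragment_ids(regions[i, ], frags)
      sel_mat <- matrix(FALSE, n, n)
      sel_mat[ids, ids] <- TRUE
      sel <- intersect(ut, which(sel_mat))
      tibble::tibble(label = regions$label[i],
                     statistic = sdm_statistic(signs, sel),
                     n_entries = length(sel))
    })
  }
  new_comparison_result(
    signs, "signed_difference", frags,
    extra = list(statistic = observed, p_value = p_value,
                 null_statistics = null_stats, permutations = permutations,
                 null_type = if (use_replicates) "replicate_permutation"
                             else "block_sign_flip",
                 region_statistics = region_stats, seed = seed))
}

#' @export
tidy.comparison_result <- function(x, ...) {
  n <- nrow(x$matrix)
  ids <- x$fragments$fragment_id
  ut <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  tibble::tibble(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
                 value = x$matrix[ut])
}

#' @export
glance.comparison_result <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_fragments = nrow(x$matrix),
    statistic = x$statistic %||% NA_real_,
    p_value = x$p_value %||% NA_real_,
    permutations = x$permutations %||% NA_integer_)
}
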