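#' Compartment calling from the first principal component
#'
#' Per chromosome: (1) distance-normalize the intra-chromosomal map
#' (observed / expected at each distance), (2) compute the Pearson
#' correlation matrix of its columns, (3) run PCA on that correlation
#' matrix. The first principal component (FPC) scores split the chromosome
#' into two structural compartments by sign (A-like / B-like, the classical
#' eigenvector compartment call). Because an eigenvector's sign is
#' arbitrary, the FPC is oriented so that its correlation with the supplied
#' orientation track (typically gene counts, positive in the open A-like
#' compartment) is positive; without a track the largest-magnitude score is
#' made positive, which is arbitrary but stable.
#'
#' Fragments with all-zero rows are masked before the correlation step and
#' labelled `masked`. Chromosomes whose FPC explains little variance are
#' flagged: their sign pattern carries no reliable compartment signal.
#'
#' @param x An `interaction_matrix`.
#' @param orientation_track Optional track used to orient the FPC sign.
#' @param min_fragments Minimum unmasked fragments per chromosome
#'   (default 10).
#' @param flag_below Flag chromosomes with FPC variance explained below this
#'   fraction (default 0.1).
#' @return A `compartment_result`: element `fragments` is a per-fragment
#'   tibble (`fragment_id`, `chrom`, `fpc`, `label`), element `chromosomes`
#'   the per-chromosome summary (`var_explained`, `n_used`, `flagged`).
#' @export
compartment_fpc <- function(x, orientation_track = NULL,
                            min_fragments = 10L, flag_below = 0.1) {
  inp <- as_dense_input(x)
  mat <- inp$mat
  frags <- inp$fragments
  gi <- fragment_genome(frags)
  fpc <- rep(NA_real_, nrow(frags))
  chrom_rows <- list()
  for (ch in gi$chrom) {
    idx <- which(frags$chrom == ch)
    sub <- mat[idx, idx, drop = FALSE]
    used <- which(rowSums(sub, na.rm = TRUE) > 0)
    if (length(used) < min_fragments) {
      stop("chromosome ", ch, " has fewer than ", min_fragments,
           " unmasked fragments")
    }
    sub <- sub[used, used]
    oe <- .divide_by_distance_expectation(sub)
    oe[is.na(oe)] <- 0
    cm <- suppressWarnings(stats::cor(oe))
    cm[is.na(cm)] <- 0
    if (stats::sd(cm) == 0) {
      stop("constant correlation matrix on chromosome ", ch)
    }
    pc <- stats::prcomp(cm, center = TRUE, scale. = FALSE)
    scores <- pc$x[, 1]
    varexp <- pc$sdev[1]^2 / sum(pc$sdev^2)
    # orient the sign
    flip <- FALSE
    anchor <- "largest_loading"
    if (!is.null(orientation_track)) {
      tv <- track_analysis_values(orientation_track)[idx[used]]
      if (stats::sd(tv, na.rm = TRUE) > 0) {
        r <- stats::cor(scores, tv, use = "complete.obs")
        flip <- is.finite(r) && r < 0
        anchor <- track_name(orientation_track)
      }
    } else {
      flip <- scores[which.max(abs(scores))] < 0
    }
    if (flip) scores <- -scores
    fpc[idx[used]] <- scores
    chrom_rows[[ch]] <- tibble::tibble(
      chrom = ch, var_explained = varexp, n_used = length(used),
      n_masked = length(idx) - length(used),
      flagged = varexp < flag_below, anchor = anchor)
  }
  label <- dplyr::case_when(
    is.na(fpc) ~ "masked",
    fpc > 0 ~ "A-like",
    fpc < 0 ~ "B-like",
    TRUE ~ "masked")
  structure(list(
    fragments = tibble::tibble(fragment_id = frags$fragment_id,
                               chrom = frags$chrom, fpc = fpc,
                               label = label),
    chromosomes = dplyr::bind_rows(chrom_rows),
    fragment_set = frags),
    class = "compartment_result")
}

#' @export
print.compartment_result <- function(x, ...) {
  tab <- table(x$fragments$label)
  cat(sprintf("<compartment_result> %d fragments: %s\n",
              nrow(x$fragments),
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
  print(x$chromosomes)
  invisible(x)
}

#' @export
tidy.compartment_result <- function(x, ...) x$fragments

#' @export
glance.compartment_result <- function(x, ...) {
  tibble::tibble(
    n_fragments = nrow(x$fragments),
    n_a_like = sum(x$fragments$label == "A-like"),
    n_b_like = sum(x$fragments$label == "B-like"),
    n_masked = sum(x$fragments$label == "masked"),
    mean_var_explained = mean(x$chromosomes$var_explained),
    n_flagged_chromosomes = sum(x$chromosomes$flagged))
}

#' Correlation of the FPC with genomic / epigenomic tracks
#'
#' Per track, the Pearson correlation of the FPC with the track values
#' (count tracks log2(x + 1)-transformed first) with the standard two-sided
#' test of zero correlation (`cor.test`).
#'
#' @param compartments A `compartment_result`.
#' @param tracks A track or (named) list of tracks on the same fragment set.
#' @return An `enrichment_result` tibble: `track`, `kind`, `estimate`
#'   (Pearson r), `p_value`, `n`. Constant tracks yield NA rows.
#' @export
fpc_track_correlation <- function(compartments, tracks) {
  if (inherits(tracks, "hic_track")) tracks <- list(tracks)
  fpc <- compartments$fragments$fpc
  rows <- purrr::map_dfr(tracks, function(tr) {
    v <- track_analysis_values(tr)
    ok <- !is.na(fpc) & !is.na(v)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0) {
      return(tibble::tibble(track = track_name(tr), kind = track_kind(tr),
                            estimate = NA_real_, p_value = NA_real_,
                            n = sum(ok)))
    }
    ct <- stats::cor.test(fpc[ok], v[ok], method = "pearson")
    tibble::tibble(track = track_name(tr), kind = track_kind(tr),
                   estimate = unname(ct$estimate), p_value = ct$p.value,
                   n = sum(ok))
  })
  class(rows) <- c("enrichment_result", class(rows))
  rows
}

#' FPC sign-group enrichment of tracks
#'
#' Fragments are split into two groups by the sign of the FPC (zero-FPC and
#' masked fragments excluded). Per track, enrichment is the ratio of the
#' average track value in the positive over the negative group, tested with
#' a two-sided Wilcoxon rank-sum test between the groups. A zero
#' denominator with a non-zero numerator reports an infinite ratio and is
#' flagged.
#'
#' @param compartments A `compartment_result`.
#' @param tracks A track or (named) list of tracks.
#' @return An `enrichment_result` tibble: `track`, `kind`, `mean_positive`,
#'   `mean_negative`, `ratio`, `p_value`, `flagged`.
#' @export
fpc_sign_enrichment <- function(compartments, tracks) {
  if (inherits(tracks, "hic_track")) tracks <- list(tracks)
  fpc <- compartments$fragments$fpc
  pos <- !is.na(fpc) & fpc > 0
  neg <- !is.na(fpc) & fpc < 0
  if (!any(pos) || !any(neg)) stop("one FPC sign group is empty")
  rows <- purrr::map_dfr(tracks, function(tr) {
    v <- track_values(tr)
    vp <- v[pos & !is.na(v)]
    vn <- v[neg & !is.na(v)]
    mp <- mean(vp)
    mn <- mean(vn)
    ratio <- if (mn == 0 && mp > 0) Inf else if (mn == 0) NA_real_ else
      mp / mn
    p <- tryCatch(
      suppressWarnings(stats::wilcox.test(vp, vn)$p.value),
      error = function(e) NA_real_)
    tibble::tibble(track = track_name(tr), kind = track_kind(tr),
                   mean_positive = mp, mean_negative = mn, ratio = ratio,
                   p_value = p, flagged = is.infinite(ratio))
  })
  class(rows) <- c("enrichment_result", class(rows))
  rows
}
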