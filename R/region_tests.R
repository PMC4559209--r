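#' Labelled genomic regions of interest
#'
#' @param chrom,start,end Region coordinates (1-based inclusive).
#' @param label Region labels (default region1..regionN).
#' @param class Optional region-class labels (e.g. "arm",
#'   "pericentromere") used by the balanced sampler.
#' @return A tibble of class `region_set`.
#' @export
region_set <- function(chrom, start, end, label = NULL, class = NULL) {
  n <- length(chrom)
  if (is.null(label)) label <- paste0("region", seq_len(n))
  rs <- tibble::tibble(chrom = as.character(chrom),
                       start = as.integer(start), end = as.integer(end),
                       label = as.character(label))
  if (!is.null(class)) rs$class <- as.character(class)
  if (any(rs$end < rs$start)) stop("region end before start")
  structure(rs, class = c("region_set", class(rs)))
}

#' Read regions from BED (0-based half-open) or 1-based TSV
#'
#' @param path File path.
#' @param format `"bed"` (0-based half-open, converted on read) or `"tsv"`
#'   (1-based inclusive with a header: chrom, start, end, optional label and
#'   class columns).
#' @return A `region_set`.
#' @export
read_region_file <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    region_set(tab[[1]], tab[[2]] + 1L, tab[[3]],
               label = if (ncol(tab) >= 4) tab[[4]] else NULL)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    region_set(tab$chrom, tab$start, tab$end, label = tab$label,
               class = tab$class)
  }
}

#' Fragments belonging to a region
#'
#' Membership is by fragment midpoint: a fragment belongs to a region when
#' its midpoint lies inside the region interval.
#'
#' @param region One-row `region_set`.
#' @param fragments A `fragment_set`.
#' @return Integer vector of fragment IDs.
#' @export
region_fragment_ids <- function(region, fragments) {
  mid <- (fragments$start + fragments$end) / 2
  fragments$fragment_id[fragments$chrom == region$chrom &
                          mid >= region$start & mid <= region$end]
}

#' Balanced random region sets
#'
#' The interactome depends strongly on a region's linear position (near
#' telomeres or centromeres) and on its chromosome, so a fair null must
#' match those properties. Each random set contains, for every region of
#' interest, one interval of identical length on the same chromosome
#' (and, when a class table is supplied, within the same region class),
#' with its start drawn uniformly over all valid placements.
#'
#' @param regions A `region_set` (the observed regions).
#' @param genome A `genome_index` (or `fragment_set`, whose genome is used).
#' @param n_sets Number of random sets.
#' @param seed Optional integer seed (draws are reproducible under it).
#' @param class_table Optional `region_set` whose `label` column names the
#'   classes; each observed region is assigned the class interval containing
#'   its midpoint and random placements are confined to that interval.
#' @return List of `n_sets` `region_set`s.
#' @export
sample_balanced_sets <- function(regions, genome, n_sets, seed = NULL,
                                 class_table = NULL) {
  if (n_sets < 1L) stop("n_sets must be >= 1")
  if (inherits(genome, "fragment_set")) genome <- fragment_genome(genome)
  genome <- as_genome_index(genome)
  if (!is.null(seed)) set.seed(seed)
  # placement window per region
  windows <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    len <- r$end - r$start + 1L
    if (!is.null(class_table)) {
      mid <- (r$start + r$end) / 2
      hit <- which(class_table$chrom == r$chrom & class_table$start <= mid &
                     class_table$end >= mid)
      if (length(hit) == 0L) {
        stop("region ", r$label, " falls in no class interval")
      }
      lo <- class_table$start[hit[1]]
      hi <- class_table$end[hit[1]]
    } else {
      lo <- 1L
      hi <- genome$length[match(r$chrom, genome$chrom)]
      if (is.na(hi)) stop("region ", r$label, " on unknown chromosome")
    }
    if (hi - lo + 1L < len) {
      stop("region ", r$label, " (", len,
           " bp) cannot be placed in its window")
    }
    tibble::tibble(chrom = r$chrom, label = r$label, length = len,
                   win_lo = lo, win_hi = hi - len + 1L)
  })
  lapply(seq_len(n_sets), function(s) {
    starts <- windows$win_lo +
      floor(stats::runif(nrow(windows)) *
              (windows$win_hi - windows$win_lo + 1))
    region_set(windows$chrom, starts, starts + windows$length - 1L,
               label = windows$label)
  })
}

new_sampling_test_result <- function(observed, null_stats, p_value, side,
                                     n_sets, seed, mode) {
  structure(list(observed = observed, null_statistics = null_stats,
                 p_value = p_value, side = side, n_sets = n_sets,
                 seed = seed, mode = mode),
            class = "sampling_test_result")
}

#' @export
print.sampling_test_result <- function(x, ...) {
  cat(sprintf(
    "<sampling_test_result> %s: observed = %.4g, null mean = %.4g (sd %.3g)\n",
    x$mode, x$observed, mean(x$null_statistics), stats::sd(x$null_statistics)))
  cat(sprintf("  one-sided (%s) empirical p = %.4g over %d balanced sets\n",
              x$side, x$p_value, x$n_sets))
  invisible(x)
}

#' @export
glance.sampling_test_result <- function(x, ...) {
  tibble::tibble(observed = x$observed, null_mean = mean(x$null_statistics),
                 null_sd = stats::sd(x$null_statistics), p_value = x$p_value,
                 side = x$side, n_sets = x$n_sets, mode = x$mode)
}

#' @export
tidy.sampling_test_result <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$null_statistics),
                 statistic = x$null_statistics)
}

empirical_p <- function(observed, null_stats, side) {
  k <- if (side == "enrichment") sum(null_stats >= observed) else
    sum(null_stats <= observed)
  (k + 1) / (length(null_stats) + 1)
}

between_region_mean <- function(mat, id_lists) {
  n_reg <- length(id_lists)
  vals <- c()
  for (a in seq_len(n_reg - 1)) {
    for (b in (a + 1):n_reg) {
      block <- mat[id_lists[[a]], id_lists[[b]], drop = FALSE]
      vals <- c(vals, block[!is.na(block)])
    }
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Test regions of interest for increased interaction frequency
#'
#' The observed statistic is the mean interaction frequency over all
#' between-region fragment pairs (within-region pairs excluded: the
#' question is whether the regions contact each other, not how dense they
#' are internally). The null distribution is the same statistic on balanced
#' random sets, and the one-sided empirical p-value is
#' p = (k + 1) / (n + 1), where k counts null statistics at least as large
#' as the observed one.
#'
#' @param x An `interaction_matrix` or `normalized_matrix`.
#' @param regions A `region_set` with >= 2 regions.
#' @param n_sets Number of balanced random sets (default 999).
#' @param seed Optional integer seed.
#' @param class_table Optional class table for the balanced sampler.
#' @return A `sampling_test_result`.
#' @export
test_interaction_enrichment <- function(x, regions, n_sets = 999L,
                                        seed = NULL, class_table = NULL) {
  inp <- as_dense_input(x)
  mat <- inp$mat
  frags <- inp$fragments
  obs_ids <- lapply(seq_len(nrow(regions)), function(i) {
    ids <- region_fragment_ids(regions[i, ], frags)
    if (length(ids) == 0L) {
      stop("region ", regions$label[i], " maps to no fragment")
    }
    ids
  })
  if (length(obs_ids) < 2L) stop("need >= 2 regions for between-region pairs")
  observed <- between_region_mean(mat, obs_ids)
  if (is.na(observed)) stop("no between-region fragment pairs")
  sets <- sample_balanced_sets(regions, frags, n_sets, seed = seed,
                               class_table = class_table)
  null_stats <- vapply(sets, function(rs) {
    ids <- lapply(seq_len(nrow(rs)), function(i) {
      region_fragment_ids(rs[i, ], frags)
    })
    if (any(vapply(ids, length, integer(1)) == 0L)) return(NA_real_)
    between_region_mean(mat, ids)
  }, numeric(1))
  null_stats <- null_stats[!is.na(null_stats)]
  p <- empirical_p(observed, null_stats, "enrichment")
  new_sampling_test_result(observed, null_stats, p, "enrichment",
                           length(null_stats), seed, "interaction")
}

region_track_statistic <- function(track, fragments, id_lists) {
  # concatenation, not union: a fragment covered by two regions contributes
  # twice, so overlapping random placements stay comparable to disjoint ones
  ids <- unlist(id_lists)
  v <- track_values(track)[ids]
  if (track_kind(track) %in% c("annotation_count", "short_count")) {
    sum(v, na.rm = TRUE)
  } else {
    w <- fragments$length[ids]
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
}

#' Test regions of interest for feature enrichment or depletion
#'
#' The observed statistic aggregates the track over the region fragments
#' (sum for count tracks, length-weighted mean for density tracks) and is
#' compared against the same statistic on balanced random sets, one-sided
#' in the requested direction with p = (k + 1) / (n + 1).
#'
#' @param track A track.
#' @param fragments The `fragment_set` the track lives on.
#' @param regions A `region_set`.
#' @param n_sets Number of balanced random sets (default 999).
#' @param seed Optional integer seed.
#' @param side `"enrichment"` (observed high) or `"depletion"` (observed
#'   low).
#' @param class_table Optional class table for the balanced sampler.
#' @return A `sampling_test_result`.
#' @export
test_feature_enrichment <- function(track, fragments, regions,
                                    n_sets = 999L, seed = NULL,
                                    side = c("enrichment", "depletion"),
                                    class_table = NULL) {
  side <- match.arg(side)
  if (nrow(track) != nrow(fragments)) {
    stop("track and fragment set sizes differ")
  }
  obs_ids <- lapply(seq_len(nrow(regions)), function(i) {
    ids <- region_fragment_ids(regions[i, ], fragments)
    if (length(ids) == 0L) {
      stop("region ", regions$label[i], " maps to no fragment")
    }
    ids
  })
  observed <- region_track_statistic(track, fragments, obs_ids)
  sets <- sample_balanced_sets(regions, fragments, n_sets, seed = seed,
                               class_table = class_table)
  null_stats <- vapply(sets, function(rs) {
    ids <- lapply(seq_len(nrow(rs)), function(i) {
      region_fragment_ids(rs[i, ], fragments)
    })
    region_track_statistic(track, fragments, ids)
  }, numeric(1))
  null_stats <- null_stats[!is.na(null_stats)]
  p <- empirical_p(observed, null_stats, side)
  new_sampling_test_result(observed, null_stats, p, side,
                           length(null_stats), seed, "feature")
}
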