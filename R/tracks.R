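#' Per-fragment data tracks
#'
#' A track is one numeric value per fragment with a kind tag that fixes its
#' semantics downstream: count kinds (`annotation_count`, `short_count`) are
#' summed when aggregated and log-transformed at analysis time; density
#' kinds (`density`, `methylation_density`) are percentages in \[0, 100\],
#' length-weighted-averaged when aggregated and never transformed.
#'
#' @param values Numeric vector, one value per fragment (NA = missing).
#' @param fragments The `fragment_set` the values are keyed to.
#' @param name Track name.
#' @param kind One of `annotation_count`, `short_count`, `density`,
#'   `methylation_density`.
#' @return A tibble (`fragment_id`, `value`) with class `hic_track` and
#'   attributes `track_name` and `kind`.
#' @export
new_track <- function(values, fragments, name, kind) {
  kind <- match.arg(kind, c("annotation_count", "short_count", "density",
                            "methylation_density"))
  values <- as.numeric(values)
  if (length(values) != nrow(fragments)) {
    stop("track length must equal the number of fragments")
  }
  ok <- !is.na(values)
  if (kind %in% c("density", "methylation_density")) {
    if (any(values[ok] < 0 | values[ok] > 100)) {
      stop("density values must lie in [0, 100]")
    }
  } else if (any(values[ok] < 0)) {
    stop("count values must be non-negative")
  }
  tr <- tibble::tibble(fragment_id = fragments$fragment_id, value = values)
  attr(tr, "track_name") <- as.character(name)
  attr(tr, "kind") <- kind
  class(tr) <- c("hic_track", class(tr))
  tr
}

#' @rdname new_track
#' @param x A track.
#' @export
track_kind <- function(x) attr(x, "kind")

#' @rdname new_track
#' @export
track_name <- function(x) attr(x, "track_name")

#' @rdname new_track
#' @export
track_values <- function(x) x$value

#' Analysis-time transform of a track
#'
#' Count tracks are log2(x + 1)-transformed for correlation-style analyses;
#' densities are used as-is. Storage is always untransformed.
#'
#' @param x A track.
#' @return Numeric vector of transformed values.
#' @export
track_analysis_values <- function(x) {
  v <- track_values(x)
  if (track_kind(x) %in% c("annotation_count", "short_count")) log2(v + 1)
  else v
}

fragments_as_granges <- function(fragments) {
  GenomicRanges::GRanges(
    seqnames = fragments$chrom,
    ranges = IRanges::IRanges(start = fragments$start, end = fragments$end))
}

intervals_as_granges <- function(x, genome) {
  if (inherits(x, "GRanges")) return(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start, end = x$end))
}

#' Annotation-count track from genome annotation features
#'
#' Features (genes, transposons, ...) can span several fragments, so simple
#' counting would over- or under-weight them. Per overlapping feature a
#' fragment gains 1 if the feature covers the whole fragment, and 0.5 for
#' any partial overlap (including a feature strictly inside the fragment).
#'
#' @param fragments A `fragment_set`.
#' @param features A GFF/GTF path, a `GRanges`, or a tibble with `chrom`,
#'   `start`, `end` (1-based inclusive) and optionally `type`.
#' @param feature_type If the features carry a `type` column, restrict to
#'   this type; `NULL` uses all features.
#' @param name Track name (defaults to the feature type or "annotation").
#' @return An `annotation_count` track. Features on chromosomes unknown to
#'   the fragment set are skipped (count reported via attribute
#'   `skipped_features`).
#' @export
annotate_features <- function(fragments, features, feature_type = NULL,
                              name = NULL) {
  gi <- fragment_genome(fragments)
  if (is.character(features) && length(features) == 1L) {
    features <- read_gff_features(features)
  }
  if (inherits(features, "GRanges")) {
    features <- tibble::tibble(
      chrom = as.character(GenomeInfoDb::seqnames(features)),
      start = BiocGenerics::start(features),
      end = BiocGenerics::end(features),
      type = if (!is.null(features$type)) as.character(features$type) else
        "feature")
  }
  if (!is.null(feature_type)) {
    if (!"type" %in% names(features)) stop("features carry no type column")
    features <- features[features$type == feature_type, ]
  }
  known <- features$chrom %in% gi$chrom
  skipped <- sum(!known)
  if (skipped > 0L) {
    warning(skipped, " feature(s) on unknown chromosomes skipped")
  }
  features <- features[known, ]
  fr_gr <- fragments_as_granges(fragments)
  ft_gr <- intervals_as_granges(features, gi)
  hits <- GenomicRanges::findOverlaps(fr_gr, ft_gr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  full <- features$start[si] <= fragments$start[qi] &
    features$end[si] >= fragments$end[qi]
  w <- ifelse(full, 1, 0.5)
  vals <- rep(0, nrow(fragments))
  if (length(qi) > 0L) {
    agg <- tapply(w, qi, sum)
    vals[as.integer(names(agg))] <- as.numeric(agg)
  }
  tr <- new_track(vals, fragments,
                  name = name %||% feature_type %||% "annotation",
                  kind = "annotation_count")
  attr(tr, "skipped_features") <- skipped
  tr
}

#' All annotation tracks of a GFF/GTF file
#'
#' One `annotation_count` track per distinct feature type in the file.
#'
#' @param fragments A `fragment_set`.
#' @param path GFF3/GTF file.
#' @return Named list of tracks.
#' @export
annotate_gff <- function(fragments, path) {
  features <- read_gff_features(path)
  types <- unique(features$type)
  out <- lapply(types, function(tp) {
    annotate_features(fragments, features, feature_type = tp)
  })
  names(out) <- types
  out
}

#' Read GFF/GTF features as a tibble
#'
#' @param path GFF3/GTF file (1-based inclusive coordinates, as in the
#'   format).
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `type`. Strand is
#'   read but not used by any track computation.
#' @export
read_gff_features <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path)
  tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = if (!is.null(gr$type)) as.character(gr$type) else "feature")
}

#' Short-count track from an alignment file
#'
#' Short features (RNA-Seq, smallRNA-Seq reads) are essentially always
#' contained in one fragment; each read is assigned to exactly one fragment
#' by its 5' position and counted once, so the track total equals the number
#' of assigned reads.
#'
#' @param fragments A `fragment_set`.
#' @param reads SAM/BAM path or a tibble with `chrom`, `pos` (5' position).
#' @param name Track name.
#' @return A `short_count` track.
#' @export
count_short_features <- function(fragments, reads, name = "short_count") {
  gi <- fragment_genome(fragments)
  if (is.character(reads) && length(reads) == 1L) {
    reads <- read_end_alignments(reads, min_mapq = 0L)
  }
  reads <- reads[reads$chrom %in% gi$chrom, ]
  vals <- rep(0, nrow(fragments))
  if (nrow(reads) > 0L) {
    ids <- locate_fragments(fragments, reads$chrom, reads$pos)
    tab <- table(ids)
    vals[as.integer(names(tab))] <- as.numeric(tab)
  }
  new_track(vals, fragments, name = name, kind = "short_count")
}

#' Density track: percent of fragment bases covered by any element
#'
#' Coverage is union semantics, not depth: a base covered by three reads
#' counts once. Density = 100 x covered bases / fragment length.
#'
#' @param fragments A `fragment_set`.
#' @param elements SAM/BAM path, `GRanges`, or tibble with `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param name Track name.
#' @return A `density` track with values in \[0, 100\].
#' @export
compute_density <- function(fragments, elements, name = "density") {
  gi <- fragment_genome(fragments)
  if (is.character(elements) && length(elements) == 1L) {
    ga <- GenomicAlignments::readGAlignments(
      Rsamtools::BamFile(as_bam_path(elements)))
    elements <- GenomicRanges::granges(ga)
  }
  gr <- intervals_as_granges(elements, gi)
  gr <- gr[as.character(GenomeInfoDb::seqnames(gr)) %in% gi$chrom]
  gr <- GenomicRanges::reduce(gr)
  fr_gr <- fragments_as_granges(fragments)
  hits <- GenomicRanges::findOverlaps(fr_gr, gr)
  covered <- rep(0, nrow(fragments))
  if (length(hits) > 0L) {
    inter <- IRanges::pintersect(
      fr_gr[S4Vectors::queryHits(hits)], gr[S4Vectors::subjectHits(hits)])
    wid <- BiocGenerics::width(inter)
    agg <- tapply(wid, S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(agg))] <- as.numeric(agg)
  }
  new_track(100 * covered / fragments$length, fragments, name = name,
            kind = "density")
}

#' Methylation-density track from per-cytosine calls
#'
#' Per fragment, the percentage of methylated cytosines: calls are pooled,
#' 100 x (sum methylated) / (sum total) over all covered positions in the
#' fragment. Fragments without any covered cytosine are missing (NA), not 0.
#'
#' @param fragments A `fragment_set`.
#' @param calls TSV path (`chrom pos methylated total`, 1-based) or a tibble
#'   with those columns.
#' @param name Track name.
#' @return A `methylation_density` track.
#' @export
methylation_density <- function(fragments, calls, name = "methylation") {
  gi <- fragment_genome(fragments)
  if (is.character(calls) && length(calls) == 1L) {
    calls <- read_methylation_tsv(calls)
  }
  stopifnot(all(c("chrom", "pos", "methylated", "total") %in% names(calls)))
  if (any(calls$methylated > calls$total)) {
    stop("methylated count exceeds total count")
  }
  calls <- calls[calls$chrom %in% gi$chrom, ]
  vals <- rep(NA_real_, nrow(fragments))
  if (nrow(calls) > 0L) {
    ids <- locate_fragments(fragments, calls$chrom, calls$pos)
    m <- tapply(calls$methylated, ids, sum)
    t <- tapply(calls$total, ids, sum)
    idx <- as.integer(names(m))
    vals[idx] <- 100 * as.numeric(m) / as.numeric(t)
  }
  new_track(vals, fragments, name = name, kind = "methylation_density")
}

#' @rdname methylation_density
#' @param path TSV path.
#' @export
read_methylation_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "methylated", "total") %in% names(tab)))
  tibble::as_tibble(tab)
}

#' Aggregate a fine-fragment track onto coarser fragments
#'
#' Each fine fragment is assigned to the coarse fragment containing its
#' midpoint. Count kinds are summed (conserving totals exactly); density
#' kinds are length-weighted averages of the non-missing member values, so
#' for equal-size members this is the plain mean.
#'
#' @param track A track on `fine_fragments`.
#' @param fine_fragments,coarse_fragments Two `fragment_set`s over the same
#'   genome.
#' @return A track of the same kind on `coarse_fragments`.
#' @export
aggregate_track <- function(track, fine_fragments, coarse_fragments) {
  g1 <- fragment_genome(fine_fragments)
  g2 <- fragment_genome(coarse_fragments)
  if (!identical(g1$chrom, g2$chrom) || !identical(g1$length, g2$length)) {
    stop("fine and coarse fragment sets are on different genomes")
  }
  mid <- floor((fine_fragments$start + fine_fragments$end) / 2)
  coarse_id <- locate_fragments(coarse_fragments, fine_fragments$chrom, mid)
  v <- track_values(track)
  kind <- track_kind(track)
  out <- rep(NA_real_, nrow(coarse_fragments))
  if (kind %in% c("annotation_count", "short_count")) {
    agg <- tapply(v, coarse_id, sum)
    out[] <- 0
    out[as.integer(names(agg))] <- as.numeric(agg)
  } else {
    ok <- !is.na(v)
    w <- fine_fragments$length[ok]
    agg <- tapply(v[ok] * w, coarse_id[ok], sum) /
      tapply(w, coarse_id[ok], sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  new_track(out, coarse_fragments, name = track_name(track), kind = kind)
}

#' Write / read a per-fragment track table
#'
#' Wide TSV: one row per fragment, one column per track; track kinds are
#' recorded on a `#kind:` comment line above the header.
#'
#' @param tracks A named list of tracks (all on the same fragment set).
#' @param fragments The `fragment_set`.
#' @param path TSV path.
#' @return Path (writer, invisibly); named list of tracks (reader).
#' @export
write_track_table <- function(tracks, fragments, path) {
  if (inherits(tracks, "hic_track")) tracks <- list(tracks)
  nm <- vapply(tracks, track_name, character(1))
  kinds <- vapply(tracks, track_kind, character(1))
  tab <- data.frame(fragment_id = fragments$fragment_id)
  for (i in seq_along(tracks)) tab[[nm[i]]] <- track_values(tracks[[i]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#kind:\tfragment_id\t", paste(kinds, collapse = "\t")),
             con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_table
#' @export
read_track_table <- function(path, fragments) {
  lines <- readLines(path, n = 1L)
  if (!startsWith(lines[1], "#kind:")) stop("missing #kind: header line")
  kinds <- strsplit(sub("^#kind:\t[^\t]*\t", "", lines[1]), "\t")[[1]]
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  cols <- setdiff(names(tab), "fragment_id")
  if (length(cols) != length(kinds)) stop("kind header does not match columns")
  out <- lapply(seq_along(cols), function(i) {
    new_track(tab[[cols[i]]], fragments, name = cols[i], kind = kinds[i])
  })
  names(out) <- cols
  out
}
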