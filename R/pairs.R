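#' Read single-end Hi-C read-end alignments
#'
#' Reads a SAM/BAM file of single-end alignments (one Hi-C read-end per
#' record) and reduces each alignment to its ligation-informative 5' base:
#' the leftmost mapped base on the plus strand, the rightmost on minus.
#'
#' @param path SAM or BAM file.
#' @param min_mapq Minimum mapping quality for an end to count as uniquely
#'   aligned (default 1, i.e. MAPQ > 0); secondary and supplementary
#'   alignments are never unique.
#' @return A tibble with columns `read`, `chrom`, `pos` (1-based 5'
#'   position), `strand`, `unique`; the file's sequence dictionary is kept in
#'   attribute `seqinfo` (named lengths, in header order).
#' @export
read_end_alignments <- function(path, min_mapq = 1L) {
  bf <- Rsamtools::BamFile(as_bam_path(path))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(bf, param = param)
  mc <- S4Vectors::mcols(ga)
  strand <- as.character(BiocGenerics::strand(ga))
  pos5 <- ifelse(strand == "+", BiocGenerics::start(ga),
                 BiocGenerics::end(ga))
  mapq <- mc$mapq
  mapq[is.na(mapq)] <- 0L
  secondary <- bitwAnd(mc$flag, 256L) != 0L
  supplementary <- bitwAnd(mc$flag, 2048L) != 0L
  out <- tibble::tibble(
    read = mc$qname,
    chrom = as.character(GenomeInfoDb::seqnames(ga)),
    pos = as.integer(pos5),
    strand = strand,
    unique = mapq >= min_mapq & !secondary & !supplementary)
  sl <- GenomeInfoDb::seqlengths(bf)
  attr(out, "seqinfo") <- sl
  out
}

# accept SAM transparently: samtools-backed readers want BAM
as_bam_path <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, destination = tempfile(),
                             indexDestination = FALSE)
  }
  path
}

strip_mate_suffix <- function(x) {
  x <- sub("\\s.*$", "", x)
  sub("/[12]$", "", x)
}

#' Pair separately aligned read-ends by read name
#'
#' Hi-C read-ends are aligned as two independent single-end runs; this pairs
#' them back up. Only ends uniquely aligned in both files form a pair; a read
#' name occurring more than once within one file is treated as non-unique.
#' Mate tags (`/1`, `/2`, or anything after whitespace) are stripped before
#' matching. Each pair is order-normalized so that end 1 is the lower
#' (chromosome order, position) end.
#'
#' @param forward,reverse Paths to SAM/BAM files, or tibbles from
#'   [read_end_alignments()].
#' @param min_mapq Passed to [read_end_alignments()] when paths are given.
#' @return A tibble of read pairs (`read`, `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`) with a `stats` attribute; see
#'   [pairing_stats()].
#' @export
pair_alignments <- function(forward, reverse, min_mapq = 1L) {
  if (is.character(forward)) forward <- read_end_alignments(forward, min_mapq)
  if (is.character(reverse)) reverse <- read_end_alignments(reverse, min_mapq)
  si_f <- attr(forward, "seqinfo")
  si_r <- attr(reverse, "seqinfo")
  if (!is.null(si_f) && !is.null(si_r) && !identical(si_f, si_r)) {
    stop("forward and reverse alignment files have different genome headers")
  }
  chrom_order <- if (!is.null(si_f)) names(si_f) else
    sort(unique(c(forward$chrom, reverse$chrom)))

  prep <- function(df) {
    df$read <- strip_mate_suffix(df$read)
    dup <- df$read %in% df$read[duplicated(df$read)]
    df$unique <- df$unique & !dup
    df
  }
  fwd <- prep(forward)
  rev <- prep(reverse)
  n_nonuniq <- sum(!fwd$unique) + sum(!rev$unique)
  fwd <- fwd[fwd$unique, ]
  rev <- rev[rev$unique, ]

  common <- intersect(fwd$read, rev$read)
  f <- fwd[match(common, fwd$read), ]
  r <- rev[match(common, rev$read), ]
  pairs <- tibble::tibble(
    read = common,
    chrom1 = f$chrom, pos1 = f$pos, strand1 = f$strand,
    chrom2 = r$chrom, pos2 = r$pos, strand2 = r$strand)
  # normalize end order: lower (chromosome order, position) first
  if (nrow(pairs) > 0L) {
    c1 <- match(pairs$chrom1, chrom_order)
    c2 <- match(pairs$chrom2, chrom_order)
    # ties on (chromosome, position) break on strand, "+" first, so the
    # pair orientation never depends on which file was called forward
    swap <- c2 < c1 | (c1 == c2 & pairs$pos2 < pairs$pos1) |
      (c1 == c2 & pairs$pos2 == pairs$pos1 &
         pairs$strand2 == "+" & pairs$strand1 == "-")
    pairs[swap, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")] <-
      pairs[swap, c("chrom2", "pos2", "strand2", "chrom1", "pos1", "strand1")]
    pairs <- dplyr::arrange(pairs, .data$read)
  }
  orphans <- (nrow(fwd) - length(common)) + (nrow(rev) - length(common))
  stats <- tibble::tibble(
    step = "pair",
    ends_forward = nrow(forward), ends_reverse = nrow(reverse),
    non_unique_discarded = n_nonuniq,
    pairs = nrow(pairs), orphans = orphans)
  attr(pairs, "stats") <- stats
  pairs
}

#' Pairing and filtering statistics
#'
#' @param x A pair tibble produced by [pair_alignments()] or
#'   [filter_close_pairs()], or an `interaction_matrix`.
#' @return The accumulated stats tibble.
#' @export
pairing_stats <- function(x) {
  s <- attr(x, "stats", exact = TRUE)
  if (is.null(s) && is.list(x) && !is.data.frame(x)) s <- x[["stats"]]
  s
}

classify_pair_orientation <- function(pairs) {
  same_chrom <- pairs$chrom1 == pairs$chrom2
  orient <- rep("other", nrow(pairs))
  # end 1 is upstream after order normalization
  orient[same_chrom & pairs$strand1 == "+" & pairs$strand2 == "-"] <- "inward"
  orient[same_chrom & pairs$strand1 == "-" & pairs$strand2 == "+"] <- "outward"
  orient[!same_chrom] <- "trans"
  orient
}

#' Remove close inward / outward read pairs
#'
#' Same-chromosome pairs with ends on opposite strands are classified as
#' inward (ends pointing toward each other) or outward (pointing away).
#' Short inward pairs arise from uncut DNA, short outward pairs from
#' self-ligation; both are removed below their span thresholds. The span is
#' the distance between the two 5' positions. Inter-chromosomal and
#' same-strand pairs always pass.
#'
#' @param pairs Pair tibble from [pair_alignments()].
#' @param inward_threshold Minimum span (bp) for inward pairs (default 1000).
#' @param outward_threshold Minimum span (bp) for outward pairs
#'   (default 25000).
#' @return The kept pairs, with the `stats` attribute extended by the
#'   removal counts.
#' @export
filter_close_pairs <- function(pairs, inward_threshold = 1000,
                               outward_threshold = 25000) {
  if (inward_threshold < 0 || outward_threshold < 0) {
    stop("thresholds must be non-negative")
  }
  if (nrow(pairs) == 0L) {
    st <- tibble::tibble(step = "filter", pairs_in = 0L, kept = 0L,
                         inward_removed = 0L, outward_removed = 0L)
    attr(pairs, "stats") <- dplyr::bind_rows(pairing_stats(pairs), st)
    return(pairs)
  }
  orient <- classify_pair_orientation(pairs)
  span <- abs(pairs$pos2 - pairs$pos1)
  drop_in <- orient == "inward" & span < inward_threshold
  drop_out <- orient == "outward" & span < outward_threshold
  kept <- pairs[!(drop_in | drop_out), ]
  st <- tibble::tibble(step = "filter",
                       pairs_in = nrow(pairs), kept = nrow(kept),
                       inward_removed = sum(drop_in),
                       outward_removed = sum(drop_out))
  attr(kept, "stats") <- dplyr::bind_rows(pairing_stats(pairs), st)
  kept
}

#' Count interactions per fragment pair
#'
#' Locates both 5' ends of every read pair in the fragment set and counts
#' each pair once under its unordered fragment-ID key. Pairs with an end on
#' a chromosome missing from the fragment set are skipped (and counted in
#' the stats), not an error.
#'
#' @param pairs Pair tibble ([pair_alignments()] / [filter_close_pairs()]).
#' @param fragments A `fragment_set`.
#' @return An `interaction_matrix`; its total equals the number of pairs
#'   mapped. Stats are carried in the `stats` attribute.
#' @export
count_interactions <- function(pairs, fragments) {
  gi <- fragment_genome(fragments)
  known <- pairs$chrom1 %in% gi$chrom & pairs$chrom2 %in% gi$chrom
  skipped <- sum(!known)
  pp <- pairs[known, ]
  if (nrow(pp) > 0L) {
    i <- locate_fragments(fragments, pp$chrom1, pp$pos1)
    j <- locate_fragments(fragments, pp$chrom2, pp$pos2)
    counts <- tibble::tibble(id1 = pmin(i, j), id2 = pmax(i, j), count = 1)
  } else {
    counts <- tibble::tibble(id1 = integer(), id2 = integer(),
                             count = numeric())
  }
  im <- interaction_matrix(counts, fragments)
  st <- tibble::tibble(step = "map", pairs_in = nrow(pairs),
                       mapped = nrow(pp), skipped_unknown_chrom = skipped)
  attr(im, "stats") <- dplyr::bind_rows(pairing_stats(pairs), st)
  im
}

#' Write / read a read-pair table
#'
#' @param pairs Pair tibble.
#' @param path TSV path.
#' @return Path (writer, invisibly) or pair tibble (reader).
#' @export
write_pair_table <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}
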