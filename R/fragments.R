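#' Genome index: ordered chromosome names and lengths
#'
#' The genome index fixes the chromosome order used everywhere downstream:
#' fragment IDs, matrix axes and track vectors all follow it.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in base pairs (>= 1).
#' @return A tibble with columns `chrom` and `length`, class `genome_index`.
#' @examples
#' genome_index(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_index <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) == 0L) stop("empty genome")
  if (any(!is.finite(length)) || any(length < 1)) {
    stop("chromosome lengths must be >= 1")
  }
  gi <- tibble::tibble(chrom = chrom, length = length)
  class(gi) <- c("genome_index", class(gi))
  gi
}

as_genome_index <- function(x) {
  if (inherits(x, "genome_index")) return(x)
  if (inherits(x, "DNAStringSet")) {
    return(genome_index(names(x), Biostrings::width(x)))
  }
  if (is.data.frame(x) && all(c("chrom", "length") %in% names(x))) {
    return(genome_index(x$chrom, x$length))
  }
  stop("cannot interpret object as a genome index")
}

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param site Recognition motif, ACGT only (no ambiguity codes), length >= 4.
#' @param cut_offset Cut position within the motif: the enzyme cuts after
#'   `cut_offset` bases of the site (0 = before the first base). HindIII
#'   (A^AGCTT) has offset 1, DpnII (^GATC) offset 0.
#' @return A one-row tibble with columns `name`, `site`, `cut_offset`.
#' @examples
#' restriction_enzyme("HindIII", "AAGCTT", 1)
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  site <- toupper(as.character(site))
  if (nchar(site) < 4L) stop("recognition site must be at least 4 bp")
  if (grepl("[^ACGT]", site)) {
    stop("recognition site must contain only A, C, G, T: ", site)
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site)) {
    stop("cut offset must lie within [0, motif length]")
  }
  tibble::tibble(name = as.character(name), site = site,
                 cut_offset = cut_offset)
}

#' Built-in restriction enzymes
#'
#' HindIII (AAGCTT, cut offset 1) and DpnII (GATC, cut offset 0), the two
#' enzymes most commonly used for Hi-C libraries. Other enzymes can be
#' defined with [restriction_enzyme()].
#'
#' @return A tibble of enzyme definitions.
#' @export
hic_enzymes <- function() {
  dplyr::bind_rows(
    restriction_enzyme("HindIII", "AAGCTT", 1L),
    restriction_enzyme("DpnII", "GATC", 0L)
  )
}

new_fragment_set <- function(frags, genome, mode, provenance) {
  frags <- tibble::as_tibble(frags)
  attr(frags, "genome") <- genome
  attr(frags, "mode") <- mode
  attr(frags, "provenance") <- provenance
  class(frags) <- c("fragment_set", class(frags))
  frags
}

#' @export
print.fragment_set <- function(x, ...) {
  gi <- attr(x, "genome")
  cat(sprintf("<fragment_set> %d fragments, %d chromosome(s), mode = %s\n",
              nrow(x), nrow(gi), attr(x, "mode")))
  NextMethod()
}

fragment_genome <- function(fragments) {
  gi <- attr(fragments, "genome")
  if (is.null(gi)) stop("not a fragment set: missing genome attribute")
  gi
}

validate_fragment_set <- function(fragments) {
  gi <- fragment_genome(fragments)
  stopifnot(identical(fragments$fragment_id, seq_len(nrow(fragments))))
  for (ch in gi$chrom) {
    f <- fragments[fragments$chrom == ch, ]
    len <- gi$length[gi$chrom == ch]
    if (nrow(f) == 0L) stop("chromosome ", ch, " has no fragments")
    if (f$start[1] != 1L || f$end[nrow(f)] != len) {
      stop("fragments do not tile chromosome ", ch)
    }
    if (nrow(f) > 1L && any(f$start[-1] != f$end[-nrow(f)] + 1L)) {
      stop("fragments on ", ch, " have gaps or overlaps")
    }
  }
  invisible(fragments)
}

build_fragments <- function(genome, boundaries_by_chrom, mode, provenance) {
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]
    len <- genome$length[i]
    # boundaries are 1-based start positions of fragments after the first
    b <- boundaries_by_chrom[[ch]]
    b <- sort(unique(b[b > 1 & b <= len]))
    starts <- c(1, b)
    ends <- c(b - 1, len)
    tibble::tibble(chrom = ch, start = as.integer(starts),
                   end = as.integer(ends))
  })
  frags <- dplyr::bind_rows(pieces)
  frags$fragment_id <- seq_len(nrow(frags))
  frags$length <- frags$end - frags$start + 1L
  frags <- frags[, c("fragment_id", "chrom", "start", "end", "length")]
  validate_fragment_set(new_fragment_set(frags, genome, mode, provenance))
}

#' Digest a genome into restriction fragments
#'
#' Scans each chromosome for exact, case-insensitive occurrences of the
#' recognition sites on the forward strand and cuts at each occurrence's cut
#' offset. Matching is exact: ambiguity codes (e.g. N runs) in the genome
#' never match, so no cut sites are fabricated in unsequenced regions. For
#' palindromic sites (the usual Hi-C case) a reverse-strand scan would be
#' redundant; non-palindromic enzymes are handled forward-strand only.
#'
#' @param genome_seq A [Biostrings::DNAStringSet] of chromosome sequences, or
#'   a path to a FASTA file.
#' @param enzymes A tibble of enzymes as returned by [restriction_enzyme()]
#'   or [hic_enzymes()]; cut positions from several enzymes are pooled and
#'   deduplicated.
#' @return A `fragment_set` tibble (`fragment_id`, `chrom`, `start`, `end`,
#'   `length`; 1-based inclusive coordinates) whose fragments tile each
#'   chromosome exactly.
#' @examples
#' gs <- Biostrings::DNAStringSet(c(chr1 = "TTAAGCTTGGAAGCTTCC"))
#' digest_genome(gs, restriction_enzyme("HindIII", "AAGCTT", 1))
#' @export
digest_genome <- function(genome_seq, enzymes) {
  if (is.character(genome_seq)) genome_seq <- read_genome_fasta(genome_seq)
  if (!inherits(genome_seq, "DNAStringSet")) {
    stop("genome_seq must be a DNAStringSet or FASTA path")
  }
  if (length(genome_seq) == 0L || any(Biostrings::width(genome_seq) == 0L)) {
    stop("empty genome sequence")
  }
  enzymes <- tibble::as_tibble(enzymes)
  if (nrow(enzymes) == 0L) stop("at least one enzyme required")
  # re-validate motifs (covers enzymes built by hand)
  for (i in seq_len(nrow(enzymes))) {
    restriction_enzyme(enzymes$name[i], enzymes$site[i],
                       enzymes$cut_offset[i])
  }
  genome <- as_genome_index(genome_seq)
  cuts <- lapply(seq_along(genome_seq), function(i) {
    subj <- genome_seq[[i]]
    pos <- integer(0)
    for (j in seq_len(nrow(enzymes))) {
      m <- Biostrings::matchPattern(enzymes$site[j], subj, fixed = TRUE)
      # cut after `cut_offset` bases of the site: next fragment starts there
      pos <- c(pos, BiocGenerics::start(m) + enzymes$cut_offset[j])
    }
    sort(unique(pos))
  })
  names(cuts) <- names(genome_seq)
  build_fragments(genome, cuts, mode = "restriction",
                  provenance = list(enzymes = enzymes))
}

#' Partition a genome into fixed-size bins
#'
#' @param genome A `genome_index`, a `DNAStringSet`, or a data frame with
#'   `chrom` and `length` columns.
#' @param bin_size Bin width in base pairs (>= 1). The last bin of each
#'   chromosome is truncated at the chromosome end.
#' @return A `fragment_set` tibble; see [digest_genome()].
#' @examples
#' bin_genome(genome_index("chr1", 10), bin_size = 4)
#' @export
bin_genome <- function(genome, bin_size) {
  genome <- as_genome_index(genome)
  bin_size <- as.numeric(bin_size)
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size < 1) {
    stop("bin size must be a single value >= 1")
  }
  bin_size <- as.integer(bin_size)
  bounds <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    if (bin_size >= len) integer(0) else seq(bin_size + 1L, len, by = bin_size)
  })
  names(bounds) <- genome$chrom
  build_fragments(genome, bounds, mode = "binned",
                  provenance = list(bin_size = bin_size))
}

#' Locate genomic positions in a fragment set
#'
#' Binary-search lookup of the fragment containing each position.
#'
#' @param fragments A `fragment_set`.
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions (recycled against `chrom`).
#' @return Integer vector of fragment IDs.
#' @examples
#' fs <- bin_genome(genome_index("chr1", 10), 4)
#' locate_fragments(fs, "chr1", c(1, 5, 10))
#' @export
locate_fragments <- function(fragments, chrom, pos) {
  gi <- fragment_genome(fragments)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  bad_chrom <- !(chrom %in% gi$chrom)
  if (any(bad_chrom)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[bad_chrom]), collapse = ", "))
  }
  len <- gi$length[match(chrom, gi$chrom)]
  if (any(pos < 1 | pos > len)) stop("position outside chromosome bounds")
  out <- integer(n)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    f <- fragments[fragments$chrom == ch, ]
    idx <- findInterval(pos[sel], f$start)
    out[sel] <- f$fragment_id[idx]
  }
  out
}

#' Read a multi-record FASTA genome
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @return A [Biostrings::DNAStringSet] named by record ID (first word of the
#'   header line).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write / read the fragment table
#'
#' The plain-text interface of the fragment coordinate system: one row per
#' fragment with 1-based inclusive coordinates, tab-separated with a header.
#'
#' @param fragments A `fragment_set`.
#' @param path Output TSV path.
#' @return `write_fragment_table()` returns `path` invisibly;
#'   `read_fragment_table()` returns a `fragment_set`.
#' @export
write_fragment_table <- function(fragments, path) {
  validate_fragment_set(fragments)
  utils::write.table(as.data.frame(fragments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_table
#' @export
read_fragment_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("fragment_id", "chrom", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("fragment table must have columns: ", paste(need, collapse = ", "))
  }
  tab$chrom <- as.character(tab$chrom)
  gi <- dplyr::summarise(dplyr::group_by(tab, .data$chrom),
                         length = max(.data$end), .groups = "drop")
  # preserve file order of chromosomes
  gi <- gi[match(unique(tab$chrom), gi$chrom), ]
  tab$length <- tab$end - tab$start + 1L
  fs <- new_fragment_set(tab[, c("fragment_id", "chrom", "start", "end",
                                 "length")],
                         genome_index(gi$chrom, gi$length),
                         mode = "file", provenance = list(path = path))
  validate_fragment_set(fs)
}
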