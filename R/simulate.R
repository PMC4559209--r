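#' Planted contact model for synthetic Hi-C data
#'
#' Ground-truth generative model for intra- and inter-chromosomal contacts:
#' the probability of a pair of fragments (i, j) on the same chromosome is
#' proportional to b_i b_j rho^\[same block\] d(i,j)^(-alpha), with d the
#' midpoint distance; inter-chromosomal pairs get a flat background
#' b_i b_j trans_weight. This plants the three structures the analyses are
#' designed to recover: a power-law distance decay (exponent alpha), a
#' block compartment pattern (within-block contrast rho), and per-fragment
#' multiplicative biases b.
#'
#' @param decay_exponent alpha >= 0 (default 0.85, a plant-like decay).
#' @param block_contrast rho >= 1, within-block enrichment (default 2).
#' @param trans_weight Relative weight of an inter-chromosomal pair against
#'   an intra pair at unit distance (default 1e-3).
#' @param bias Optional per-fragment positive bias vector (default all 1).
#' @param blocks Optional per-fragment block labels (default: none, no
#'   compartment structure).
#' @return A `contact_model` list.
#' @export
contact_model <- function(decay_exponent = 0.85, block_contrast = 2,
                          trans_weight = 1e-3, bias = NULL, blocks = NULL) {
  if (decay_exponent < 0) stop("decay exponent must be >= 0")
  if (block_contrast < 1) stop("block contrast must be >= 1")
  if (!is.null(bias) && any(bias <= 0)) stop("biases must be positive")
  structure(list(decay_exponent = decay_exponent,
                 block_contrast = block_contrast,
                 trans_weight = trans_weight, bias = bias, blocks = blocks),
            class = "contact_model")
}

#' Alternating compartment blocks along each chromosome
#'
#' Convenience block map: consecutive runs of `block_size` fragments
#' alternate between two compartments ("A", "B") per chromosome.
#'
#' @param fragments A `fragment_set`.
#' @param block_size Fragments per block.
#' @return Character vector of block labels per fragment.
#' @export
alternating_blocks <- function(fragments, block_size) {
  unlist(lapply(split(seq_len(nrow(fragments)), fragments$chrom),
                function(idx) {
    c("A", "B")[(ceiling(seq_along(idx) / block_size) - 1) %% 2 + 1]
  })[unique(fragments$chrom)], use.names = FALSE)
}

mutate_bases <- function(chars, at) {
  alt <- c(A = "C", C = "G", G = "T", T = "A")
  chars[at] <- alt[chars[at]]
  chars
}

#' Generate a random genome with planted restriction sites
#'
#' Random sequence with recognition-site occurrences planted at known,
#' approximately Poisson-spaced positions; accidental occurrences arising
#' from the random background are destroyed by point mutation, so the
#' planted sites are exactly the occurrences and the expected fragment
#' table is known in advance.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths
#'   (>= 1000 bp each).
#' @param enzyme A one-row enzyme tibble (default HindIII).
#' @param site_rate Expected planted sites per bp (default 1/4000, the
#'   genome-average density of a 6-cutter); 0 plants no sites.
#' @param gc Either a single GC probability (default 0.5) or a length-2
#'   range giving a linear GC gradient along each chromosome (used to test
#'   GC-dependent normalization).
#' @param seed Integer seed; output is byte-deterministic under it.
#' @return List with `sequences` (DNAStringSet), `sites` (tibble `chrom`,
#'   `pos` of planted motif starts, 1-based) and `fragments` (the expected
#'   `fragment_set`, computed from the planted cut positions alone).
#' @export
generate_genome <- function(chrom_lengths, enzyme = NULL, site_rate = 1 / 4000,
                            gc = 0.5, seed = 1L) {
  if (is.null(enzyme)) enzyme <- restriction_enzyme("HindIII", "AAGCTT", 1L)
  if (any(chrom_lengths < 1000)) stop("chromosome lengths must be >= 1 kb")
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  set.seed(seed)
  site <- strsplit(enzyme$site, "")[[1]]
  slen <- length(site)
  seqs <- character(length(chrom_lengths))
  sites <- list()
  for (ci in seq_along(chrom_lengths)) {
    len <- chrom_lengths[ci]
    gc_prob <- if (length(gc) == 2L) seq(gc[1], gc[2], length.out = len) else
      rep(gc, len)
    base_prob <- cbind((1 - gc_prob) / 2, gc_prob / 2, gc_prob / 2,
                       (1 - gc_prob) / 2)
    u <- stats::runif(len)
    cum <- t(apply(base_prob, 1, cumsum))
    chars <- c("A", "C", "G", "T")[
      1L + (u > cum[, 1]) + (u > cum[, 2]) + (u > cum[, 3])]
    # planted site positions: Poisson-spaced, non-overlapping, off the ends
    pos <- integer(0)
    if (site_rate > 0) {
      gaps <- stats::rexp(ceiling(len * site_rate * 3) + 10, rate = site_rate)
      pos <- floor(cumsum(gaps + slen))
      pos <- pos[pos >= 2 & pos <= len - slen]
    }
    # destroy accidental occurrences (mutations may create new ones: iterate)
    seq_str <- paste(chars, collapse = "")
    for (iter in 1:50) {
      occ <- BiocGenerics::start(
        Biostrings::matchPattern(enzyme$site,
                                 Biostrings::DNAString(seq_str)))
      stray <- setdiff(occ, pos)
      if (length(stray) == 0L) break
      chars <- strsplit(seq_str, "")[[1]]
      chars <- mutate_bases(chars, stray)
      seq_str <- paste(chars, collapse = "")
    }
    # plant the sites
    if (length(pos) > 0L) {
      chars <- strsplit(seq_str, "")[[1]]
      for (p in pos) chars[p:(p + slen - 1)] <- site
      seq_str <- paste(chars, collapse = "")
      # planting can abut and create no new occurrences because spacing
      # >= motif length is enforced above
    }
    seqs[ci] <- seq_str
    sites[[ci]] <- tibble::tibble(chrom = names(chrom_lengths)[ci],
                                  pos = as.integer(pos))
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- names(chrom_lengths)
  sites <- dplyr::bind_rows(sites)
  genome <- genome_index(names(chrom_lengths), chrom_lengths)
  bounds <- lapply(genome$chrom, function(ch) {
    sites$pos[sites$chrom == ch] + enzyme$cut_offset
  })
  names(bounds) <- genome$chrom
  truth <- build_fragments(genome, bounds, mode = "restriction",
                           provenance = list(enzymes = enzyme,
                                             planted = TRUE))
  list(sequences = dna, sites = sites, fragments = truth)
}

#' Write a DNAStringSet as FASTA
#' @param sequences A `DNAStringSet`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(sequences, path, width = 70L)
  invisible(path)
}

#' Write read-end records as a minimal SAM file
#'
#' Single-end records carrying only the fields the readers use: name, flag
#' (strand), chromosome, leftmost position, MAPQ and a full-match CIGAR.
#' Sequences and qualities are omitted (`*`), since alignment happens
#' upstream of this tool.
#'
#' @param ends Tibble with `read`, `chrom`, `pos` (5' position), `strand`,
#'   and optionally `mapq` (default 60).
#' @param genome A `genome_index` (for the header sequence dictionary).
#' @param path Output SAM path.
#' @param read_length Reported aligned length (default 30 bp).
#' @return The path, invisibly.
#' @export
write_sam <- function(ends, genome, path, read_length = 30L) {
  genome <- as_genome_index(genome)
  mapq <- if ("mapq" %in% names(ends)) ends$mapq else rep(60L, nrow(ends))
  left <- ifelse(ends$strand == "+", ends$pos, ends$pos - read_length + 1L)
  if (any(left < 1L)) stop("read extends past chromosome start")
  flag <- ifelse(ends$strand == "+", 0L, 16L)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom,
                      as.integer(genome$length)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                  ends$read, flag, ends$chrom, as.integer(left),
                  as.integer(mapq), as.integer(read_length))
  writeLines(c(header, body), path)
  invisible(path)
}

sample_pos5 <- function(start, end, chrom_len, read_length) {
  # 5' position uniform in the fragment; strand chosen so the aligned read
  # stays inside the chromosome
  pos <- start + floor(stats::runif(length(start)) * (end - start + 1))
  can_plus <- pos <= chrom_len - read_length + 1L
  can_minus <- pos >= read_length
  strand <- ifelse(stats::runif(length(pos)) < 0.5, "+", "-")
  strand[!can_minus] <- "+"
  strand[!can_plus] <- "-"
  list(pos = as.integer(pos), strand = strand)
}

#' Simulate Hi-C read pairs from a planted contact model
#'
#' Draws `n_pairs` fragment pairs from the contact model, places each
#' read-end uniformly within its fragment with a random strand, and
#' optionally injects short inward/outward artefact pairs (uncut DNA /
#' self-ligation mimics) that are truth-labelled. The exact expected
#' interaction matrix of the non-artefact pairs is returned, so the full
#' pairing -> filtering -> counting path can be checked against ground
#' truth.
#'
#' @param fragments A `fragment_set`.
#' @param model A [contact_model()].
#' @param n_pairs Number of genuine contact pairs (>= 1).
#' @param seed Integer seed.
#' @param artefact_fraction Artefact pairs injected as a fraction of
#'   `n_pairs` (half inward, half outward; default 0).
#' @param artefact_span_below Length-2 vector: artefact spans are drawn
#'   uniformly below these inward/outward thresholds
#'   (default c(1000, 25000)).
#' @param nonunique_fraction Fraction of genuine pairs whose forward end is
#'   written with MAPQ 0 (planted non-unique ends; default 0).
#' @param read_length Aligned length written to SAM (default 30).
#' @param dir If non-NULL, write `forward.sam` and `reverse.sam` there.
#' @return List: `pairs` (tibble with ends, `artefact` label and `mapq1`),
#'   `truth` (the expected `interaction_matrix` of genuine unique pairs),
#'   and `files` (paths, when `dir` given).
#' @export
simulate_pairs <- function(fragments, model, n_pairs, seed = 1L,
                           artefact_fraction = 0,
                           artefact_span_below = c(1000, 25000),
                           nonunique_fraction = 0,
                           read_length = 30L, dir = NULL) {
  if (nrow(fragments) == 0L) stop("empty fragment set")
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  set.seed(seed)
  gi <- fragment_genome(fragments)
  n <- nrow(fragments)
  mid <- (fragments$start + fragments$end) / 2
  bias <- model$bias %||% rep(1, n)
  blocks <- model$blocks
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- ij[, 1]
  j <- ij[, 2]
  same_chrom <- fragments$chrom[i] == fragments$chrom[j]
  d <- abs(mid[j] - mid[i])
  d[i == j] <- pmax(fragments$length[i[i == j]] / 2, 1)
  w <- bias[i] * bias[j]
  w[same_chrom] <- w[same_chrom] * d[same_chrom]^(-model$decay_exponent)
  if (!is.null(blocks)) {
    same_block <- same_chrom & blocks[i] == blocks[j]
    w[same_block] <- w[same_block] * model$block_contrast
  }
  w[!same_chrom] <- w[!same_chrom] * model$trans_weight
  draw <- stats::rmultinom(1, n_pairs, prob = w)[, 1]
  sel <- which(draw > 0)
  pair_i <- rep(i[sel], draw[sel])
  pair_j <- rep(j[sel], draw[sel])
  truth <- interaction_matrix(
    tibble::tibble(id1 = i[sel], id2 = j[sel], count = draw[sel]),
    fragments)

  len1 <- gi$length[match(fragments$chrom[pair_i], gi$chrom)]
  len2 <- gi$length[match(fragments$chrom[pair_j], gi$chrom)]
  e1 <- sample_pos5(fragments$start[pair_i], fragments$end[pair_i],
                    len1, read_length)
  e2 <- sample_pos5(fragments$start[pair_j], fragments$end[pair_j],
                    len2, read_length)
  pairs <- tibble::tibble(
    read = sprintf("sim%07d", seq_along(pair_i)),
    chrom1 = fragments$chrom[pair_i], pos1 = e1$pos, strand1 = e1$strand,
    chrom2 = fragments$chrom[pair_j], pos2 = e2$pos, strand2 = e2$strand,
    artefact = "none")

  n_art <- round(artefact_fraction * n_pairs)
  if (n_art > 0L) {
    half <- floor(n_art / 2)
    kinds <- c(rep("inward", half), rep("outward", n_art - half))
    max_span <- ifelse(kinds == "inward", artefact_span_below[1],
                       artefact_span_below[2])
    ci <- sample(nrow(gi), n_art, replace = TRUE,
                 prob = gi$length / sum(gi$length))
    span <- floor(stats::runif(n_art) * pmin(max_span - read_length,
                                             gi$length[ci] / 2)) +
      read_length
    lo <- read_length +
      floor(stats::runif(n_art) * (gi$length[ci] - 2 * read_length - span))
    art <- tibble::tibble(
      read = sprintf("art%07d", seq_len(n_art)),
      chrom1 = gi$chrom[ci], pos1 = as.integer(lo),
      strand1 = ifelse(kinds == "inward", "+", "-"),
      chrom2 = gi$chrom[ci], pos2 = as.integer(lo + span),
      strand2 = ifelse(kinds == "inward", "-", "+"),
      artefact = kinds)
    pairs <- dplyr::bind_rows(pairs, art)
  }
  pairs$mapq1 <- 60L
  n_nu <- round(nonunique_fraction * n_pairs)
  if (n_nu > 0L) {
    nu_idx <- sample(which(pairs$artefact == "none"), n_nu)
    pairs$mapq1[nu_idx] <- 0L
    # non-unique ends never enter the truth matrix
    genuine <- pairs$artefact == "none" & pairs$mapq1 > 0L
    gp <- pairs[genuine, ]
    ti <- locate_fragments(fragments, gp$chrom1, gp$pos1)
    tj <- locate_fragments(fragments, gp$chrom2, gp$pos2)
    truth <- interaction_matrix(
      tibble::tibble(id1 = pmin(ti, tj), id2 = pmax(ti, tj), count = 1),
      fragments)
  }

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    # which physical file carries which end is random per pair
    swap <- stats::runif(nrow(pairs)) < 0.5
    fwd <- tibble::tibble(
      read = pairs$read,
      chrom = ifelse(swap, pairs$chrom2, pairs$chrom1),
      pos = ifelse(swap, pairs$pos2, pairs$pos1),
      strand = ifelse(swap, pairs$strand2, pairs$strand1),
      mapq = pairs$mapq1)
    rev <- tibble::tibble(
      read = pairs$read,
      chrom = ifelse(swap, pairs$chrom1, pairs$chrom2),
      pos = ifelse(swap, pairs$pos1, pairs$pos2),
      strand = ifelse(swap, pairs$strand1, pairs$strand2),
      mapq = 60L)
    files <- list(forward = file.path(dir, "forward.sam"),
                  reverse = file.path(dir, "reverse.sam"))
    write_sam(fwd, gi, files$forward, read_length = read_length)
    write_sam(rev, gi, files$reverse, read_length = read_length)
  }
  list(pairs = pairs, truth = truth, files = files)
}

#' Simulate feature tracks correlated with planted compartments
#'
#' Emits per-fragment feature data in every supported input format, with a
#' planted between-compartment effect: "A" fragments carry `effect_size`
#' times the gene/read density of "B" fragments, while methylation is
#' elevated in "B" (heterochromatin-like). Truth intensities are returned
#' alongside the raw inputs, so the file -> track -> analysis path can be
#' validated end to end.
#'
#' @param fragments A `fragment_set`.
#' @param labels Per-fragment compartment labels ("A"/"B").
#' @param effect_size Multiplicative A-over-B contrast (default 2); 1 means
#'   no compartment effect (null tracks).
#' @param base_rate Expected genes (and reads x 10) per fragment in the "B"
#'   group (default 2).
#' @param seed Integer seed.
#' @param dir If non-NULL, write `features.gff3`, `reads.sam`,
#'   `methylation.tsv` there.
#' @return List: `features` (tibble), `reads` (tibble), `calls` (tibble),
#'   `truth` (per-fragment expected intensities), `files` (when `dir`
#'   given).
#' @export
simulate_tracks <- function(fragments, labels, effect_size = 2,
                            base_rate = 2, seed = 1L, dir = NULL) {
  stopifnot(length(labels) == nrow(fragments))
  set.seed(seed)
  gi <- fragment_genome(fragments)
  n <- nrow(fragments)
  boost <- ifelse(labels == "A", effect_size, 1)
  lam_feat <- base_rate * boost
  lam_reads <- base_rate * 10 * boost
  meth_p <- ifelse(labels == "A", 0.2, pmin(0.2 * effect_size, 0.95))

  # annotation features: contained within their fragment
  n_feat <- stats::rpois(n, lam_feat)
  features <- purrr::map_dfr(which(n_feat > 0), function(k) {
    fs <- fragments$start[k]
    fe <- fragments$end[k]
    w <- pmax(floor(fragments$length[k] / 10), 2L)
    st <- fs + floor(stats::runif(n_feat[k]) *
                       pmax(fe - fs - w, 1))
    tibble::tibble(chrom = fragments$chrom[k], start = as.integer(st),
                   end = as.integer(pmin(st + w - 1L, fe)), type = "gene")
  })

  # short reads: 5' positions within the fragment
  n_reads <- stats::rpois(n, lam_reads)
  reads <- purrr::map_dfr(which(n_reads > 0), function(k) {
    p <- fragments$start[k] +
      floor(stats::runif(n_reads[k]) * fragments$length[k])
    tibble::tibble(chrom = fragments$chrom[k], pos = as.integer(p),
                   strand = "+")
  })

  # methylation calls: ~10 covered cytosines per fragment
  n_call <- stats::rpois(n, 10)
  calls <- purrr::map_dfr(which(n_call > 0), function(k) {
    p <- fragments$start[k] +
      floor(stats::runif(n_call[k]) * fragments$length[k])
    tot <- stats::rpois(n_call[k], 20) + 1L
    m <- stats::rbinom(n_call[k], tot, meth_p[k])
    tibble::tibble(chrom = fragments$chrom[k], pos = as.integer(p),
                   methylated = m, total = tot)
  })

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(gff = file.path(dir, "features.gff3"),
                  sam = file.path(dir, "reads.sam"),
                  methylation = file.path(dir, "methylation.tsv"))
    gff_lines <- c("##gff-version 3",
                   sprintf("%s\tsim\t%s\t%d\t%d\t.\t+\t.\tID=f%06d",
                           features$chrom, features$type, features$start,
                           features$end, seq_len(nrow(features))))
    writeLines(gff_lines, files$gff)
    rd <- reads
    rd$read <- sprintf("trk%07d", seq_len(nrow(rd)))
    rd$mapq <- 60L
    # 1M cigar keeps the 5' base the leftmost base regardless of strand
    write_sam(rd[, c("read", "chrom", "pos", "strand", "mapq")], gi,
              files$sam, read_length = 1L)
    utils::write.table(as.data.frame(calls), files$methylation, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(features = features, reads = reads, calls = calls,
       truth = tibble::tibble(fragment_id = fragments$fragment_id,
                              label = labels, lambda_features = lam_feat,
                              lambda_reads = lam_reads,
                              methylation_p = meth_p),
       files = files)
}
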