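#' Interaction matrix container
#'
#' Symmetric fragment-by-fragment contact counts in sparse triplet form
#' (upper triangle: `id1 <= id2`), keyed to a `fragment_set`.
#'
#' @param counts Tibble with columns `id1`, `id2`, `count` (unordered pairs
#'   stored with `id1 <= id2`; duplicates are summed).
#' @param fragments The `fragment_set` the IDs refer to.
#' @return An `interaction_matrix` object.
#' @export
interaction_matrix <- function(counts, fragments) {
  validate_fragment_set(fragments)
  counts <- tibble::as_tibble(counts)
  if (nrow(counts) == 0L) {
    counts <- tibble::tibble(id1 = integer(), id2 = integer(),
                             count = numeric())
  }
  stopifnot(all(c("id1", "id2", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("negative interaction counts")
  n <- nrow(fragments)
  if (nrow(counts) > 0L) {
    if (any(counts$id1 < 1L | counts$id2 < 1L |
            counts$id1 > n | counts$id2 > n)) {
      stop("fragment IDs outside the fragment set")
    }
    lo <- pmin(counts$id1, counts$id2)
    hi <- pmax(counts$id1, counts$id2)
    counts$id1 <- lo
    counts$id2 <- hi
    counts <- dplyr::summarise(dplyr::group_by(counts, .data$id1, .data$id2),
                               count = sum(.data$count), .groups = "drop")
    counts <- dplyr::arrange(counts, .data$id1, .data$id2)
  }
  structure(list(counts = counts, fragments = fragments,
                 total = sum(counts$count)),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf(
    "<interaction_matrix> %d fragments, %d non-zero pairs, total count %g\n",
    nrow(x$fragments), nrow(x$counts), x$total))
  invisible(x)
}

#' Total stored count of an interaction matrix
#' @param x An `interaction_matrix`.
#' @return The sum of all stored pair counts (= read pairs mapped).
#' @export
interaction_total <- function(x) x$total

#' Dense symmetric view of an interaction matrix
#'
#' @param x An `interaction_matrix` or `normalized_matrix`.
#' @param chrom Optional chromosome name: restrict to the intra-chromosomal
#'   block of that chromosome. Default: genome-wide matrix.
#' @return A dense symmetric numeric matrix with fragment IDs as dimnames.
#' @export
dense_matrix <- function(x, chrom = NULL) {
  UseMethod("dense_matrix")
}

#' @export
dense_matrix.interaction_matrix <- function(x, chrom = NULL) {
  frags <- x$fragments
  ids <- if (is.null(chrom)) frags$fragment_id else
    frags$fragment_id[frags$chrom == chrom]
  if (length(ids) == 0L) stop("no fragments on chromosome ", chrom)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  cc <- x$counts
  keep <- cc$id1 %in% ids & cc$id2 %in% ids
  cc <- cc[keep, ]
  if (nrow(cc) > 0L) {
    i <- match(cc$id1, ids)
    j <- match(cc$id2, ids)
    m[cbind(i, j)] <- cc$count
    m[cbind(j, i)] <- cc$count
  }
  m
}

#' @export
dense_matrix.normalized_matrix <- function(x, chrom = NULL) {
  m <- x$matrix
  if (is.null(chrom)) return(m)
  frags <- x$fragments
  ids <- as.character(frags$fragment_id[frags$chrom == chrom])
  if (length(ids) == 0L) stop("no fragments on chromosome ", chrom)
  m[ids, ids, drop = FALSE]
}

#' Write / read an interaction matrix as a triplet table
#'
#' Plain-text sparse format: tab-separated `id1 id2 count` with `id1 <= id2`
#' and a header line.
#'
#' @param x An `interaction_matrix`.
#' @param path TSV path.
#' @param fragments For the reader: the `fragment_set` the IDs refer to.
#' @return The path (writer, invisibly) or an `interaction_matrix` (reader).
#' @export
write_interaction_matrix <- function(x, path) {
  utils::write.table(as.data.frame(x$counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_interaction_matrix
#' @export
read_interaction_matrix <- function(path, fragments) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  interaction_matrix(tab, fragments)
}
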