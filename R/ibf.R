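#' Bloom filter false-positive rate
#'
#' Probability that a non-inserted element is reported present by a Bloom
#' filter of `n` bits holding `m` elements under `hash_count` hash
#' functions:
#' \deqn{p = (1 - (1 - 1/n)^{Hm})^H}
#'
#' @param n filter size in bits (>= 1).
#' @param m number of inserted elements (>= 0).
#' @param hash_count number of hash functions H (>= 1).
#' @return The predicted false-positive probability.
#' @examples
#' false_positive_rate(2, 1, 1)          # 0.5
#' false_positive_rate(12365, 1000, 3)   # just under 0.01
#' @export
false_positive_rate <- function(n, m, hash_count = 3L) {
  if (any(n < 1)) stop("n must be >= 1 (a filter with no bits is degenerate)")
  if (any(m < 0)) stop("m must be >= 0")
  if (any(hash_count < 1)) stop("hash_count must be >= 1")
  # log1p keeps precision for large n where 1 - 1/n is close to 1
  (1 - exp(hash_count * m * log1p(-1 / n)))^hash_count
}

#' Optimal Bloom filter bin size for a target false-positive rate
#'
#' Inverts the false-positive formula: for a bin that must hold up to
#' `max_kmers` distinct k-mers, the smallest bit count keeping the rate at
#' or below `target_fpr` is
#' \deqn{n = \lceil -1 / (r^{1/(H\,maxKmers)} - 1) \rceil, \quad
#'       r = 1 - p^{1/H}.}
#' Within one interleaved filter every bin shares the size computed for the
#' most loaded bin.
#'
#' @param max_kmers largest number of distinct k-mers any bin must hold.
#'   A value of 0 (an empty bin) returns 1 by convention.
#' @param target_fpr desired false-positive probability, in (0, 1).
#' @param hash_count number of hash functions H.
#' @return Bin size in bits (numeric; may exceed the integer range).
#' @examples
#' optimal_bin_size(1, 0.5, 1)        # 2
#' optimal_bin_size(1000, 0.01, 3)    # 12365
#' @export
optimal_bin_size <- function(max_kmers, target_fpr = 0.01, hash_count = 3L) {
  if (target_fpr <= 0 || target_fpr >= 1)
    stop("target_fpr must lie strictly between 0 and 1")
  if (max_kmers < 0) stop("max_kmers must be >= 0")
  if (max_kmers == 0) return(1)
  r <- 1 - target_fpr^(1 / hash_count)
  # r^(1/(H m)) - 1 = expm1(log(r) / (H m)), kept in log space for precision
  ceiling(-1 / expm1(log(r) / (hash_count * max_kmers)))
}

#' Construct an empty interleaved Bloom filter
#'
#' An interleaved Bloom filter (IBF) packs `b` equal-size Bloom filters —
#' one per user bin — into a single bit matrix in which each of the `n` bit
#' positions holds a `b`-bit sub-vector, so one set of hash probes queries
#' every bin simultaneously.
#'
#' @param n bits per bin (shared by all bins; size the most loaded bin with
#'   [optimal_bin_size()]).
#' @param bin_labels character vector of distinct bin labels; its length
#'   sets the bin count b.
#' @param hash_seeds integer seeds of the H hash functions.
#' @param target_fpr the false-positive rate the size was chosen for
#'   (recorded in the object; informational).
#' @return An object of class `ibf` with fields `bits` (raw vector,
#'   position-major), `n`, `b`, `bin_labels`, `hash_seeds`, `target_fpr`.
#' @examples
#' f <- ibf(n = 64, bin_labels = c("taxA", "taxB"))
#' f <- ibf_insert(f, "taxA", encode_kmer(c("PEPTI", "EPTID")))
#' ibf_query(f, encode_kmer(c("PEPTI", "AAAAA")))
#' @export
ibf <- function(n, bin_labels, hash_seeds = DEFAULT_HASH_SEEDS[1:3],
                target_fpr = 0.01) {
  n <- as.numeric(n)
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a single value >= 1")
  bin_labels <- as.character(bin_labels)
  if (length(bin_labels) < 1L) stop("at least one bin is required")
  if (anyDuplicated(bin_labels)) stop("bin labels must be unique")
  b <- length(bin_labels)
  structure(list(
    bits = raw(ceiling(n * b / 8)),
    n = n, b = b,
    bin_labels = bin_labels,
    hash_seeds = as.numeric(hash_seeds),
    target_fpr = target_fpr
  ), class = "ibf")
}

#' @export
print.ibf <- function(x, ...) {
  cat(sprintf("Interleaved Bloom filter: %d bins x %s bits, %d hash functions\n",
              x$b, format(x$n, big.mark = ","), length(x$hash_seeds)))
  invisible(x)
}

#' Insert encoded k-mers into one bin of an IBF
#'
#' Each code is hashed with every seed; the bit at (position, bin) is set
#' for each probe. Insertion is idempotent: re-inserting the same codes
#' leaves the bit matrix unchanged.
#'
#' @param filter an [ibf()].
#' @param bin a bin label or 1-based bin index.
#' @param codes numeric vector of encoded k-mers (deduplicated internally).
#' @return The updated filter.
#' @export
ibf_insert <- function(filter, bin, codes) {
  stopifnot(inherits(filter, "ibf"))
  bin_idx <- resolve_bin(filter, bin)
  codes <- unique(as.numeric(codes))
  filter$bits <- cpp_insert_codes(filter$bits, filter$n, filter$b,
                                  bin_idx - 1L, codes, filter$hash_seeds)
  filter
}

#' Count k-mer membership across all bins of an IBF
#'
#' For each bin, counts how many of the distinct query codes have all H
#' probed bits set. Inserted codes are always found in their own bin (no
#' false negatives); other bins report a code present only with the
#' filter's false-positive probability.
#'
#' @param filter an [ibf()].
#' @param codes numeric vector of encoded k-mers; duplicates count once.
#' @return Named integer vector of per-bin counts in `[0, length(unique(codes))]`.
#' @export
ibf_query <- function(filter, codes) {
  stopifnot(inherits(filter, "ibf"))
  if (length(codes) == 0L)
    return(structure(integer(filter$b), names = filter$bin_labels))
  counts <- cpp_query_counts(filter$bits, filter$n, filter$b,
                             as.numeric(codes), filter$hash_seeds)
  names(counts) <- filter$bin_labels
  counts
}

resolve_bin <- function(filter, bin) {
  if (is.character(bin)) {
    idx <- match(bin, filter$bin_labels)
    if (is.na(idx)) stop("unknown bin label: ", bin)
    return(idx)
  }
  bin <- as.integer(bin)
  if (is.na(bin) || bin < 1L || bin > filter$b)
    stop("bin index out of range 1..", filter$b)
  bin
}
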