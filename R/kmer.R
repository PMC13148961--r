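#' K-mer configuration
#'
#' Bundles the parameters that define how amino-acid sequences are
#' k-merized and encoded: the k-mer length, the optional forward-strand
#' minimizer window, and whether the isobaric residues isoleucine and
#' leucine are collapsed to a single symbol (de novo sequencing cannot
#' distinguish them; collapsing trades specificity for robustness).
#'
#' Each residue is encoded in 5 bits, so a k-mer must fit a 64-bit word:
#' k is limited to 12.
#'
#' @param k k-mer length in residues (1--12; default 5).
#' @param minimizer_window number of consecutive k-mers per minimizer
#'   window; 0 disables minimizer sketching (the default). When enabled it
#'   must be at least 2 and is applied identically at index build and at
#'   query time.
#' @param collapse_il logical; map L to I before encoding (default FALSE).
#' @return An object of class `kmer_config`.
#' @examples
#' kmer_config(k = 5)
#' kmer_config(k = 4, minimizer_window = 3, collapse_il = TRUE)
#' @export
kmer_config <- function(k = 5L, minimizer_window = 0L, collapse_il = FALSE) {
  k <- as.integer(k)
  minimizer_window <- as.integer(minimizer_window)
  if (is.na(k) || k < 1L || k > 12L)
    stop("k must be an integer in 1..12 (5-bit encoding of 12 residues fills 64 bits)")
  if (is.na(minimizer_window) || (minimizer_window != 0L && minimizer_window < 2L))
    stop("minimizer_window must be 0 (disabled) or >= 2")
  structure(list(k = k, minimizer_window = minimizer_window,
                 collapse_il = isTRUE(collapse_il)),
            class = "kmer_config")
}

#' @export
print.kmer_config <- function(x, ...) {
  cat("k-mer configuration: k =", x$k,
      if (x$minimizer_window > 0) paste0("| minimizer window = ", x$minimizer_window)
      else "| minimizers off",
      if (x$collapse_il) "| I/L collapsed" else "", "\n")
  invisible(x)
}

#' Extract canonical k-mers from an amino-acid sequence
#'
#' Slides a window of length `k` over the sequence and returns every window
#' whose residues are all in the 20-letter canonical alphabet. Windows that
#' contain a non-canonical residue (X, B, Z, U, O, J, `*`, ...) are dropped;
#' the number dropped is attached as the `"dropped"` attribute so callers
#' can log it. Positions are 0-based.
#'
#' @param sequence a single amino-acid string.
#' @param config a [kmer_config()].
#' @return A data frame with columns `position` (0-based start) and `kmer`;
#'   attribute `dropped` carries the count of excluded windows. A sequence
#'   shorter than k (or empty) yields zero rows.
#' @examples
#' kmerize("PEPTIDE", kmer_config(k = 5))
#' kmerize("PEXTIDE", kmer_config(k = 3))  # windows containing X are dropped
#' @export
kmerize <- function(sequence, config = kmer_config()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- cpp_kmerize(toupper(sequence), config$k, config$collapse_il)
  out <- data.frame(position = res$position, kmer = res$kmer,
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- res$dropped
  out
}

#' Encode k-mers as 64-bit integer codes
#'
#' Packs a canonical k-mer into an integer: each residue maps to its
#' alphabetical ordinal (A=0, C=1, ..., Y=19) occupying 5 bits, first
#' residue most significant, i.e. `code = sum ord(residue_i) * 32^(k-1-i)`.
#' Codes are returned as R doubles; they are exact for k <= 10 (codes below
#' 2^50). For k of 11 or 12 the index pipeline keeps codes in native 64-bit
#' words internally and this numeric view may round.
#'
#' @param kmers character vector of equal-length canonical k-mers.
#' @param config a [kmer_config()]; only `collapse_il` is consulted.
#' @return Numeric vector of codes, one per k-mer.
#' @examples
#' encode_kmer(c("AA", "AC", "CA"))  # 0, 1, 32
#' decode_kmer(encode_kmer("PEPTI"), k = 5)
#' @export
encode_kmer <- function(kmers, config = kmer_config()) {
  stopifnot(is.character(kmers))
  if (length(kmers) == 0L) return(numeric(0))
  cpp_encode(kmers, config$collapse_il)
}

#' @rdname encode_kmer
#' @param codes numeric vector of k-mer codes.
#' @param k the k-mer length the codes were produced with.
#' @export
decode_kmer <- function(codes, k) {
  stopifnot(is.numeric(codes))
  k <- as.integer(k)
  if (any(codes < 0 | codes >= 32^k))
    stop("code out of range for k = ", k)
  cpp_decode(codes, k)
}

#' Forward-strand minimizers of an ordered k-mer stream
#'
#' For every run of `window` consecutive k-mers the numerically smallest
#' code is selected; the union of the selections is returned. If fewer than
#' `window` k-mers are supplied the single overall minimum is returned.
#' Ordering is plain numeric order of the encoded value; protein sequences
#' have no reverse strand, so only the forward direction is considered.
#'
#' @param codes numeric vector of encoded k-mers in sequence order.
#' @param window integer window length in k-mers (>= 2).
#' @return Numeric vector of the distinct selected codes, sorted ascending.
#' @examples
#' minimizers(c(5, 3, 9), window = 3)     # 3
#' minimizers(c(5, 3, 9, 1), window = 3)  # 3 1
#' @export
minimizers <- function(codes, window) {
  window <- as.integer(window)
  if (is.na(window) || window < 2L) stop("window must be >= 2")
  if (length(codes) == 0L) return(numeric(0))
  cpp_minimizers(as.numeric(codes), window)
}
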