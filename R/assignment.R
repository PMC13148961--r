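#' Filter and deduplicate a de novo peptide list
#'
#' De novo sequencing engines attach a confidence score in [0, 1] to each
#' predicted peptide (the average of the residue-level confidences).
#' Records below `min_confidence` are dropped, as are peptides too short to
#' yield a single k-mer; duplicated sequences are collapsed to one record
#' keeping the maximum confidence (first-occurrence order preserved). A
#' conservative default of 0.70 suits most searches; 0.50 is the
#' documented relaxed setting for mutation-rich samples where recall of
#' variant peptides matters more than maximal precision.
#'
#' @param peptides a data frame with columns `sequence` and `confidence`
#'   (a `source_tag` column, if present, is carried through).
#' @param min_confidence minimum confidence retained (default 0.7,
#'   inclusive).
#' @param k minimum peptide length (peptides shorter than the k-mer length
#'   produce no k-mers; default 5).
#' @return The filtered data frame; attribute `dropped` records how many
#'   records each rule removed.
#' @examples
#' p <- data.frame(sequence = c("PEPTIDES", "SHRT", "PEPTIDES"),
#'                 confidence = c(0.8, 0.99, 0.95))
#' filter_peptides(p, min_confidence = 0.7, k = 5)
#' @export
filter_peptides <- function(peptides, min_confidence = 0.7, k = 5L) {
  peptides <- as.data.frame(peptides)
  if (!all(c("sequence", "confidence") %in% names(peptides)))
    stop("peptides must have columns 'sequence' and 'confidence'")
  if (any(peptides$confidence < 0 | peptides$confidence > 1, na.rm = TRUE))
    stop("confidence scores must lie in [0, 1]")
  n0 <- nrow(peptides)
  peptides$sequence <- toupper(peptides$sequence)
  keep_conf <- peptides$confidence >= min_confidence
  keep_len <- nchar(peptides$sequence) >= k
  out <- peptides[keep_conf & keep_len, , drop = FALSE]
  # collapse duplicate sequences to the highest-confidence record
  if (nrow(out) > 1L) {
    ord <- order(match(out$sequence, out$sequence), -out$confidence)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out$sequence), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- c(low_confidence = sum(!keep_conf),
                            too_short = sum(keep_conf & !keep_len),
                            duplicate = n0 - sum(!keep_conf) -
                              sum(keep_conf & !keep_len) - nrow(out))
  out
}

#' Read a peptide list from a delimited file
#'
#' Accepts TSV or CSV with a header; the sequence column may be named
#' `sequence` or `peptide`, the confidence column `confidence` or `score`.
#'
#' @param path file path.
#' @return A data frame with columns `sequence` and `confidence`.
#' @export
read_peptides <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  seq_col <- intersect(c("sequence", "peptide"), names(d))[1]
  conf_col <- intersect(c("confidence", "score"), names(d))[1]
  if (is.na(seq_col) || is.na(conf_col))
    stop("peptide table needs a sequence/peptide and a confidence/score column")
  data.frame(sequence = toupper(d[[seq_col]]),
             confidence = as.numeric(d[[conf_col]]),
             stringsAsFactors = FALSE)
}

#' Classify peptides against a peptide index
#'
#' Runs the assignment pipeline: each peptide's distinct k-mer codes
#' (minimized the same way as the index, when enabled) are counted against
#' every bin of every IBF, giving the count matrix C with entries
#' \eqn{c_{uv}} (k-mer hits of peptide u in bin v) and the per-peptide
#' distinct-k-mer totals \eqn{y_u}. The assignment threshold D (a
#' percentage) sets the per-peptide cutoff \eqn{x_u = y_u D / 100}
#' (real-valued, no rounding); the lookup matrix has
#' \eqn{l_{uv} = 1} iff \eqn{c_{uv} \ge x_u}. The per-bin assignment score
#' is the column mean \eqn{S_B = \sum_u l_{uB} / z} over the z peptides.
#' D = 100 (the default) is the full-coverage criterion: every k-mer of the
#' peptide must be supported by the bin.
#'
#' @param object a [peptide_index()].
#' @param peptides a data frame with columns `sequence` and `confidence`,
#'   or a path readable by [read_peptides()].
#' @param D assignment threshold as a percentage in (0, 100].
#' @param min_confidence confidence filter applied first (default 0.7);
#'   set to 0 to keep everything.
#' @param filter logical; apply [filter_peptides()] (default TRUE).
#' @param ... unused.
#' @return An object of class `peptide_assignment` with fields `counts`
#'   (u x v integer matrix), `y`, `lookup` (u x v 0/1 matrix), `scores`
#'   (named per-bin S), `D`, and the filtered `peptides`.
#' @examples
#' bins <- list(taxA = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
#'              taxB = "MSDNPLLTWQEFARLEKQVVWLAHDNAQLRAEV")
#' idx <- peptide_index(bins)
#' q <- data.frame(sequence = c("MKTAYIAK", "QRQISFVK"), confidence = 0.9)
#' res <- predict(idx, q)
#' res$scores
#' @export
predict.peptide_index <- function(object, peptides, D = 100,
                                  min_confidence = 0.7, filter = TRUE, ...) {
  if (is.character(peptides) && length(peptides) == 1L)
    peptides <- read_peptides(peptides)
  if (filter)
    peptides <- filter_peptides(peptides, min_confidence, object$config$k)
  if (nrow(peptides) == 0L)
    stop("no peptides after filtering")
  res <- count_matrix(object, peptides)
  res <- assignment_threshold(res, D)
  res
}

#' Count matrix of k-mer hits per peptide and bin
#'
#' Lower-level entry point behind [predict.peptide_index()]: queries each
#' IBF of the index and stitches the per-IBF counts into the global
#' peptide x bin count matrix via the bin directory. No thresholding is
#' applied; follow with [assignment_threshold()].
#'
#' @param index a `peptide_index`.
#' @param peptides filtered peptide data frame.
#' @return A partially filled `peptide_assignment` (counts and y only).
#' @export
count_matrix <- function(index, peptides) {
  stopifnot(inherits(index, "peptide_index"))
  cfg <- index$config
  seqs <- toupper(peptides$sequence)
  u <- length(seqs)
  v <- nrow(index$bin_directory)
  counts <- matrix(0L, u, v, dimnames = list(seqs, index$bin_directory$label))
  y <- NULL
  for (bi in seq_along(index$ibfs)) {
    f <- index$ibfs[[bi]]
    q <- cpp_query_peptides(f$bits, f$n, f$b, seqs, cfg$k, cfg$collapse_il,
                            cfg$minimizer_window, f$hash_seeds)
    cols <- which(index$bin_directory$ibf == bi)
    counts[, cols] <- q$counts
    y <- q$y
  }
  if (is.null(y))
    y <- cpp_peptide_y(seqs, cfg$k, cfg$collapse_il, cfg$minimizer_window)
  structure(list(counts = counts, y = y, lookup = NULL, scores = NULL,
                 D = NULL, peptides = peptides,
                 bin_labels = index$bin_directory$label),
            class = "peptide_assignment")
}

#' Apply the assignment threshold and score bins
#'
#' Recomputes the lookup matrix and per-bin scores of an assignment for a
#' (new) threshold D without re-querying the index: \eqn{x_u = y_u D/100},
#' \eqn{l_{uv} = [c_{uv} \ge x_u]}, \eqn{S_B = \mathrm{mean}_u\, l_{uB}}.
#'
#' @param result a `peptide_assignment` (from [count_matrix()] or
#'   [predict.peptide_index()]).
#' @param D percentage threshold in (0, 100].
#' @return The updated `peptide_assignment`.
#' @export
assignment_threshold <- function(result, D) {
  stopifnot(inherits(result, "peptide_assignment"))
  if (!is.numeric(D) || length(D) != 1L || D <= 0 || D > 100)
    stop("D must be a percentage in (0, 100]")
  x <- result$y * D / 100            # real-valued cutoff, no rounding
  result$lookup <- 1L * (result$counts >= x)
  z <- nrow(result$counts)
  if (z == 0L) stop("no peptides after filtering")
  result$scores <- colMeans(result$lookup)
  result$D <- D
  result
}

#' @export
print.peptide_assignment <- function(x, ...) {
  z <- nrow(x$counts)
  cat(sprintf("Peptide assignment: %d peptide(s) x %d bin(s), D = %g%%\n",
              z, ncol(x$counts), x$D))
  top <- sort(x$scores, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top)) {
    cat("  top bins by assignment score S:\n")
    show <- utils::head(top, 5L)
    for (i in seq_along(show))
      cat(sprintf("    %-24s S = %.4f (%d peptide(s))\n", names(show)[i],
                  show[i], as.integer(round(show[i] * z))))
  } else cat("  no bin received any assignment\n")
  invisible(x)
}

#' Per-bin summary of an assignment
#'
#' One row per bin: the number of peptides assigned (column sum of the
#' lookup matrix), the assignment score S, and the number of uniquely
#' assigned peptides (peptides whose lookup row has exactly this one bin
#' set). Rows are ordered by descending S, ties in bin order.
#'
#' @param object a `peptide_assignment`.
#' @param ... unused.
#' @return A data frame with columns `bin_label`, `peptides_passing`,
#'   `score_S`, `unique_peptides`.
#' @export
summary.peptide_assignment <- function(object, ...) {
  L <- object$lookup
  uniq_rows <- rowSums(L) == 1L
  out <- data.frame(
    bin_label = colnames(L),
    peptides_passing = colSums(L),
    score_S = object$scores,
    unique_peptides = colSums(L[uniq_rows, , drop = FALSE]),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score_S, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.peptide_assignment <- function(x, ...) summary(x)

#' Write assignment reports
#'
#' Writes the two standard tab-separated reports into `dir`:
#' `bins.tsv`, the per-bin summary (see [summary.peptide_assignment()]),
#' and `peptides.tsv` with one row per peptide: sequence, confidence, the
#' distinct-k-mer count y, the best matching bin(s) (highest count among
#' bins with the lookup bit set, `;`-separated), that count, and whether
#' the peptide is uniquely assigned.
#'
#' @param result a `peptide_assignment`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_assignment <- function(result, dir) {
  stopifnot(inherits(result, "peptide_assignment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bins_path <- file.path(dir, "bins.tsv")
  pep_path <- file.path(dir, "peptides.tsv")
  write.table(summary(result), bins_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  L <- result$lookup
  best <- vapply(seq_len(nrow(L)), function(i) {
    hit <- which(L[i, ] == 1L)
    if (!length(hit)) return(NA_character_)
    cmax <- max(result$counts[i, hit])
    paste(colnames(L)[hit[result$counts[i, hit] == cmax]], collapse = ";")
  }, character(1))
  best_count <- vapply(seq_len(nrow(L)), function(i) {
    hit <- which(L[i, ] == 1L)
    if (!length(hit)) return(NA_integer_)
    as.integer(max(result$counts[i, hit]))
  }, integer(1))
  pep <- data.frame(
    peptide = rownames(result$counts),
    confidence = result$peptides$confidence,
    y = result$y,
    best_bins = best,
    best_count = best_count,
    assigned_bins = rowSums(L),
    unique = rowSums(L) == 1L,
    stringsAsFactors = FALSE
  )
  write.table(pep, pep_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bins = bins_path, peptides = pep_path))
}
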