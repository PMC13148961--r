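#' Load a substitution matrix in NCBI text layout
#'
#' Parses the standard NCBI/EMBOSS scoring-matrix text format (`#`
#' comments, a header row of residues, one scored row per residue) into a
#' substitution model over the 20 canonical amino acids. Ambiguity columns
#' (B, Z, X, `*`) are ignored. The matrix must contain every canonical
#' residue and be symmetric. BLOSUM62 — built from alignment blocks of at
#' least 62% identity, where higher scores mark substitutions frequently
#' observed between related proteins — ships with the package and is the
#' default used for error-tolerant indexing.
#'
#' @param path path to a matrix file; defaults to the bundled BLOSUM62.
#' @return An object of class `substitution_model`: a 20x20 integer score
#'   matrix (`scores`, rows/columns in alphabetical residue order) and, for
#'   each residue, the full alphabet ordered by descending score
#'   (`sorted_candidates`, ties alphabetical) — the order in which variant
#'   enumeration tries replacements.
#' @examples
#' m <- read_blosum()
#' m$scores["W", "W"]  # 11
#' @export
read_blosum <- function(path = system.file("extdata", "BLOSUM62.txt",
                                           package = "peptax")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a scoring matrix: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  row_res <- vapply(rows, `[`, character(1), 1L)
  vals <- lapply(rows, function(r) suppressWarnings(as.integer(r[-1])))
  if (any(lengths(vals) != length(header)))
    stop("malformed matrix row(s): column count does not match the header")
  full <- do.call(rbind, vals)
  rownames(full) <- row_res
  colnames(full) <- header
  missing <- setdiff(AA_ALPHABET, intersect(row_res, header))
  if (length(missing))
    stop("matrix is missing canonical residue(s): ",
         paste(missing, collapse = ", "))
  scores <- full[AA_ALPHABET, AA_ALPHABET, drop = FALSE]
  asym <- which(scores != t(scores), arr.ind = TRUE)
  if (nrow(asym))
    stop(sprintf("asymmetric matrix: S(%s,%s) = %d but S(%s,%s) = %d",
                 AA_ALPHABET[asym[1, 1]], AA_ALPHABET[asym[1, 2]],
                 scores[asym[1, , drop = FALSE]],
                 AA_ALPHABET[asym[1, 2]], AA_ALPHABET[asym[1, 1]],
                 t(scores)[asym[1, , drop = FALSE]]))
  substitution_model(scores)
}

#' @rdname read_blosum
#' @param scores a symmetric 20x20 integer matrix with the canonical
#'   residues as dimnames (any order; it is reindexed alphabetically).
#' @export
substitution_model <- function(scores) {
  scores <- as.matrix(scores)
  if (is.null(dimnames(scores)) ||
      !setequal(rownames(scores), AA_ALPHABET) ||
      !setequal(colnames(scores), AA_ALPHABET))
    stop("scores must be a 20x20 matrix named by the canonical residues")
  scores <- scores[AA_ALPHABET, AA_ALPHABET]
  storage.mode(scores) <- "integer"
  if (!isTRUE(all.equal(scores, t(scores))))
    stop("substitution matrix must be symmetric")
  cand_idx <- cpp_sorted_candidates(scores)
  sorted_candidates <- apply(cand_idx, 1L, function(i) AA_ALPHABET[i])
  sorted_candidates <- t(sorted_candidates)
  rownames(sorted_candidates) <- AA_ALPHABET
  structure(list(scores = scores, sorted_candidates = sorted_candidates),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("Substitution model over the 20 canonical amino acids\n")
  cat("  score range:", min(x$scores), "..", max(x$scores), "\n")
  invisible(x)
}

#' Mutation (error-tolerant expansion) configuration
#'
#' @param enabled logical; expand reference k-mers into substitution
#'   variants at index build time.
#' @param score_threshold minimum cumulative substitution score
#'   `sum_i S(original_i, variant_i)` a variant must reach (default 25).
#' @param model a [substitution_model()]; defaults to bundled BLOSUM62
#'   (loaded lazily at build time when enabled).
#' @return An object of class `mutation_config`.
#' @export
mutation_config <- function(enabled = FALSE, score_threshold = 25L,
                            model = NULL) {
  structure(list(enabled = isTRUE(enabled),
                 score_threshold = as.integer(score_threshold),
                 model = model),
            class = "mutation_config")
}

#' Enumerate substitution variants of a k-mer
#'
#' Returns every k-mer `v` whose cumulative substitution score against the
#' original, `sum_i S(kmer_i, v_i)`, reaches `threshold`. Enumeration is a
#' depth-first search over per-residue candidate lists pre-sorted by
#' descending score with branch-and-bound pruning: a branch is abandoned as
#' soon as its partial score plus the best possible completion falls below
#' the threshold, and because candidates are sorted, all later siblings are
#' skipped with it. The original k-mer is always included in the result,
#' even when its self-score is below the threshold, so indexed references
#' always represent their own exact sequence.
#'
#' @param kmer a canonical k-mer string.
#' @param model a [substitution_model()].
#' @param threshold integer cumulative score threshold.
#' @return Character vector of variant k-mers (sorted; includes `kmer`).
#'   Attribute `nodes` records the number of search-tree nodes visited.
#' @examples
#' m <- read_blosum()
#' generate_variants("W", m, threshold = 11)  # only W scores 11 against W
#' @export
generate_variants <- function(kmer, model, threshold) {
  stopifnot(inherits(model, "substitution_model"),
            is.character(kmer), length(kmer) == 1L)
  res <- cpp_generate_variants(kmer, model$scores, as.integer(threshold))
  structure(res$variants, nodes = res$nodes)
}

#' Expand a k-mer set with substitution variants
#'
#' Union of [generate_variants()] over the input set; always a superset of
#' the input. With mutation disabled the input is returned unchanged.
#'
#' @param kmers character vector of canonical k-mers.
#' @param model a [substitution_model()].
#' @param config a [mutation_config()].
#' @return Character vector of distinct k-mers.
#' @export
expand_kmers <- function(kmers, model, config = mutation_config(enabled = TRUE)) {
  kmers <- unique(as.character(kmers))
  if (!config$enabled) return(kmers)
  out <- unlist(lapply(kmers, function(km)
    generate_variants(km, model, config$score_threshold)))
  sort(unique(c(out, kmers)))
}
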