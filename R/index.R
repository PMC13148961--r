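#' Load reference protein sequences into user bins
#'
#' Reads a protein FASTA and optionally merges records into bins
#' (proteomes, taxa) via a two-column grouping table. Without grouping,
#' every record is its own bin, labelled by the first whitespace-delimited
#' token of its header. With grouping, records sharing a label are merged
#' in order of first appearance; records absent from the grouping table
#' stay as singleton bins with a warning. Grouping rows that reference a
#' missing record ID are ignored with a warning.
#'
#' @param fasta path to a protein FASTA file.
#' @param grouping optional path to a tab-separated, headerless table
#'   mapping record ID to bin label.
#' @return A named list of user bins; each element is a character vector of
#'   amino-acid sequences and the name is the bin label.
#' @export
load_bins <- function(fasta, grouping = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate record ID(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seq_chr <- as.character(seqs)
  names(seq_chr) <- ids
  if (is.null(grouping)) {
    bins <- as.list(seq_chr)
  } else {
    g <- read.delim(grouping, header = FALSE, sep = "\t",
                    colClasses = "character")
    if (ncol(g) < 2L) stop("grouping table needs two tab-separated columns")
    g <- g[, 1:2]
    names(g) <- c("record_id", "bin")
    missing <- setdiff(g$record_id, ids)
    if (length(missing)) {
      warning("grouping references ", length(missing),
              " record ID(s) absent from the FASTA; ignored")
      g <- g[g$record_id %in% ids, , drop = FALSE]
    }
    label_of <- structure(g$bin, names = g$record_id)
    ungrouped <- setdiff(ids, g$record_id)
    if (length(ungrouped)) {
      warning(length(ungrouped),
              " record(s) absent from the grouping table form singleton bins")
      label_of <- c(label_of, structure(ungrouped, names = ungrouped))
    }
    labels <- unname(label_of[ids])    # bin order = first appearance in FASTA
    bins <- split(unname(seq_chr), factor(labels, levels = unique(labels)))
  }
  lapply(bins, as.character)
}

#' Read a blacklist of reference labels
#'
#' One label per line; blank lines and `#` comments are skipped. Labels
#' match bin labels exactly (after grouping).
#'
#' @param path path to the blacklist file, or NULL for an empty blacklist.
#' @return Character vector of labels.
#' @export
read_blacklist <- function(path = NULL) {
  if (is.null(path)) return(character(0))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Partition user bins into index batches
#'
#' Blacklisted bins are removed first; the remaining bins, in input order,
#' are chunked into batches of `split_size` (the last batch takes the
#' remainder). Each batch becomes one independently sized IBF.
#'
#' @param bin_labels character vector of bin labels in input order.
#' @param split_size maximum bins per IBF (M >= 1; default 64).
#' @param blacklist character vector of labels to exclude.
#' @return A list of character vectors (one per batch).
#' @examples
#' plan_splits(paste0("bin", 1:10), split_size = 4)
#' @export
plan_splits <- function(bin_labels, split_size = 64L, blacklist = character(0)) {
  split_size <- as.integer(split_size)
  if (is.na(split_size) || split_size < 1L) stop("split_size must be >= 1")
  keep <- setdiff(bin_labels, blacklist)
  if (length(keep) == 0L)
    stop("empty index: every bin is blacklisted (or no bins were given)")
  unname(split(keep, ceiling(seq_along(keep) / split_size)))
}

#' Sizing load of one index batch
#'
#' The number of bits per bin of an IBF is driven by the most loaded bin it
#' holds: for each bin the distinct encoded k-mers over all its sequences
#' are counted — after minimizer selection and mutation expansion when
#' those modes are enabled — and the maximum over bins is returned (at
#' least 1, so empty bins still get a valid filter).
#'
#' @param bins named list of bins (character vectors of sequences).
#' @param config a [kmer_config()].
#' @param mutation a [mutation_config()].
#' @return The maximum distinct-k-mer count over the bins (numeric).
#' @export
estimate_max_kmers <- function(bins, config = kmer_config(),
                               mutation = mutation_config()) {
  stopifnot(length(bins) >= 1L)
  model <- resolve_model(mutation)
  counts <- vapply(bins, function(seqs) {
    cpp_bin_distinct_count(toupper(as.character(seqs)), config$k,
                           config$collapse_il, config$minimizer_window,
                           mutation$enabled,
                           if (mutation$enabled) model$scores else NULL,
                           mutation$score_threshold)
  }, numeric(1))
  max(counts, 1)
}

resolve_model <- function(mutation) {
  if (!mutation$enabled) return(NULL)
  if (!is.null(mutation$model)) mutation$model else read_blosum()
}

#' Build a partitioned interleaved Bloom filter index over protein bins
#'
#' The main constructor: k-merizes every reference bin, optionally expands
#' k-mers into BLOSUM-scored substitution variants (error-tolerant mode)
#' and/or sketches them with forward-strand minimizers, sizes one
#' interleaved Bloom filter per batch of `split_size` bins from the
#' batch's own maximum distinct-k-mer load, and inserts each bin's k-mers
#' into its column. The result is deterministic for a given configuration:
#' hash seeds are fixed constants recorded in the index.
#'
#' @param x path to a protein FASTA file, or a named list of bins (each a
#'   character vector of amino-acid sequences).
#' @param grouping optional grouping TSV path (see [load_bins()]); only
#'   used when `x` is a FASTA path.
#' @param blacklist optional blacklist file path or character vector of bin
#'   labels to exclude.
#' @param config a [kmer_config()].
#' @param mutation a [mutation_config()].
#' @param target_fpr Bloom filter false-positive rate per bin (default 0.01).
#' @param hash_count number of hash functions H (default 3).
#' @param split_size bins per IBF (default 64).
#' @param hash_seeds optional explicit hash seeds (length `hash_count`).
#' @return An object of class `peptide_index`; query it with
#'   [predict.peptide_index()].
#' @examples
#' bins <- list(taxA = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
#'              taxB = "MSDNPLLTWQEFARLEKQVVWLAHDNAQLRAEV")
#' idx <- peptide_index(bins, config = kmer_config(k = 5))
#' idx
#' @export
peptide_index <- function(x, grouping = NULL, blacklist = NULL,
                          config = kmer_config(),
                          mutation = mutation_config(),
                          target_fpr = 0.01, hash_count = 3L,
                          split_size = 64L, hash_seeds = NULL) {
  if (is.character(x) && length(x) == 1L) {
    bins <- load_bins(x, grouping)
  } else if (is.list(x)) {
    bins <- lapply(x, as.character)
    if (is.null(names(bins)) || any(!nzchar(names(bins))))
      stop("bins supplied as a list must be named by bin label")
  } else stop("x must be a FASTA path or a named list of bins")
  if (anyDuplicated(names(bins))) stop("bin labels must be unique")

  black <- if (is.character(blacklist) && length(blacklist) == 1L &&
               file.exists(blacklist)) read_blacklist(blacklist)
           else as.character(blacklist %||% character(0))
  hash_count <- as.integer(hash_count)
  if (is.null(hash_seeds)) hash_seeds <- DEFAULT_HASH_SEEDS[seq_len(hash_count)]
  if (length(hash_seeds) != hash_count)
    stop("need exactly hash_count hash seeds")
  model <- resolve_model(mutation)

  batches <- plan_splits(names(bins), split_size, black)
  ibfs <- vector("list", length(batches))
  directory <- list()
  for (bi in seq_along(batches)) {
    labels <- batches[[bi]]
    batch_bins <- bins[labels]
    mk <- estimate_max_kmers(batch_bins, config, mutation)
    n <- optimal_bin_size(mk, target_fpr, hash_count)
    f <- ibf(n, labels, hash_seeds, target_fpr)
    empty <- character(0)
    for (j in seq_along(labels)) {
      seqs <- toupper(as.character(batch_bins[[j]]))
      cnt <- cpp_bin_distinct_count(seqs, config$k, config$collapse_il,
                                    config$minimizer_window, FALSE, NULL, 0L)
      if (cnt == 0) empty <- c(empty, labels[j])
      f$bits <- cpp_insert_bin(f$bits, f$n, f$b, j - 1L, seqs,
                               config$k, config$collapse_il,
                               config$minimizer_window, f$hash_seeds,
                               mutation$enabled,
                               if (mutation$enabled) model$scores else NULL,
                               mutation$score_threshold)
    }
    if (length(empty))
      warning("bin(s) with no valid k-mers retained as empty: ",
              paste(empty, collapse = ", "))
    f$max_kmers <- mk
    ibfs[[bi]] <- f
    directory[[bi]] <- data.frame(label = labels, ibf = bi,
                                  local_bin = seq_along(labels),
                                  stringsAsFactors = FALSE)
  }
  structure(list(
    ibfs = ibfs,
    bin_directory = do.call(rbind, directory),
    config = config,
    mutation = mutation_config(mutation$enabled, mutation$score_threshold),
    target_fpr = target_fpr,
    hash_count = hash_count,
    hash_seeds = as.numeric(hash_seeds),
    split_size = as.integer(split_size),
    blacklist = sort(black),
    format_version = 1L
  ), class = "peptide_index")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.peptide_index <- function(x, ...) {
  cat("Partitioned interleaved Bloom filter index\n")
  cat(sprintf("  %d bin(s) across %d IBF(s); k = %d, H = %d, target FPR = %g\n",
              nrow(x$bin_directory), length(x$ibfs), x$config$k,
              x$hash_count, x$target_fpr))
  if (x$mutation$enabled)
    cat("  mutation expansion on, score threshold", x$mutation$score_threshold, "\n")
  if (x$config$minimizer_window > 0)
    cat("  minimizer window", x$config$minimizer_window, "\n")
  invisible(x)
}

#' @export
summary.peptide_index <- function(object, ...) {
  sizes <- vapply(object$ibfs, function(f) f$n, numeric(1))
  bins <- vapply(object$ibfs, function(f) f$b, numeric(1))
  loads <- vapply(object$ibfs, function(f) f$max_kmers %||% NA_real_, numeric(1))
  out <- data.frame(ibf = seq_along(object$ibfs), bins = bins,
                    bits_per_bin = sizes, max_kmers = loads)
  print(object)
  print(out, row.names = FALSE)
  invisible(out)
}

#' Serialize / restore a peptide index
#'
#' The index is written as a single versioned RDS archive: the header
#' (k-mer and mutation configuration, hash count and seeds, target
#' false-positive rate, split size, bin directory) together with each
#' IBF's raw bit matrix. A rebuild from identical inputs produces a
#' byte-identical file.
#'
#' @param index a `peptide_index`.
#' @param path output file path.
#' @return `write_index` returns `path` invisibly; `read_index` returns
#'   the restored `peptide_index`.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "peptide_index"))
  saveRDS(unclass(index), path, version = 3L)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported index format version")
  class(obj$config) <- "kmer_config"
  class(obj$mutation) <- "mutation_config"
  for (i in seq_along(obj$ibfs)) class(obj$ibfs[[i]]) <- "ibf"
  structure(obj, class = "peptide_index")
}
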