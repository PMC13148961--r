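#' Specification for a synthetic reference + query fixture
#'
#' Parameters of the seeded generator that emulates the structure of a
#' defined-composition metaproteomic evaluation: a reference database of
#' bins (taxa/proteomes) with known protein membership, and a de
#' novo-style query peptide list with known bin of origin, optional
#' single-substitution noise, decoys, and sampled confidence scores.
#'
#' @param n_bins number of reference bins (default 10).
#' @param proteins_per_bin proteins per bin (default 3).
#' @param protein_length integer range `c(min, max)` of protein lengths
#'   (default 120--240 residues).
#' @param residue_distribution probability weights over the 20-residue
#'   alphabet in alphabetical order (default uniform).
#' @param n_query_peptides number of query peptides (default 200).
#' @param peptide_length tryptic peptide length range retained
#'   (default 5--30).
#' @param substitution_rate per-peptide probability of one BLOSUM-guided
#'   substitution (default 0).
#' @param decoy_fraction fraction of query peptides drawn from no bin
#'   (random composition; default 0).
#' @param confidence_shape `c(alpha, beta)` of the Beta distribution the
#'   confidence scores are sampled from (default c(8, 2), mean 0.8 —
#'   a high-confidence de novo regime).
#' @param seed integer RNG seed; every generator output is a pure function
#'   of the spec including this seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_bins = 10L, proteins_per_bin = 3L,
                         protein_length = c(120L, 240L),
                         residue_distribution = rep(1 / 20, 20),
                         n_query_peptides = 200L,
                         peptide_length = c(5L, 30L),
                         substitution_rate = 0,
                         decoy_fraction = 0,
                         confidence_shape = c(8, 2),
                         seed = 1L) {
  stopifnot(n_bins >= 1, proteins_per_bin >= 1, n_query_peptides >= 1,
            length(protein_length) == 2L, length(peptide_length) == 2L,
            length(residue_distribution) == 20L,
            all(residue_distribution >= 0),
            substitution_rate >= 0, substitution_rate <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1)
  structure(list(
    n_bins = as.integer(n_bins),
    proteins_per_bin = as.integer(proteins_per_bin),
    protein_length = as.integer(protein_length),
    residue_distribution = residue_distribution / sum(residue_distribution),
    n_query_peptides = as.integer(n_query_peptides),
    peptide_length = as.integer(peptide_length),
    substitution_rate = substitution_rate,
    decoy_fraction = decoy_fraction,
    confidence_shape = confidence_shape,
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

random_protein <- function(len, weights) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = weights),
        collapse = "")
}

#' Generate a synthetic reference database
#'
#' Deterministic in the spec's seed. Bins are labelled `bin01`, `bin02`,
#' ... and proteins `<bin>_p<i>`.
#'
#' @param spec a [fixture_spec()].
#' @return A list: `fasta` (named character vector of protein sequences,
#'   names = record IDs), `grouping` (data frame record_id/bin), and
#'   `truth` (identical mapping, the ground-truth bin of every protein).
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    wd <- max(2L, nchar(as.character(spec$n_bins)))
    bins <- sprintf(paste0("bin%0", wd, "d"), seq_len(spec$n_bins))
    ids <- character(0)
    seqs <- character(0)
    bin_of <- character(0)
    for (b in bins) {
      for (p in seq_len(spec$proteins_per_bin)) {
        len <- sample(spec$protein_length[1]:spec$protein_length[2], 1L)
        ids <- c(ids, sprintf("%s_p%d", b, p))
        seqs <- c(seqs, random_protein(len, spec$residue_distribution))
        bin_of <- c(bin_of, b)
      }
    }
    names(seqs) <- ids
    grouping <- data.frame(record_id = ids, bin = bin_of,
                           stringsAsFactors = FALSE)
    list(fasta = seqs, grouping = grouping, truth = grouping)
  })
}

#' Tryptic digestion of a protein sequence
#'
#' Cleaves after K or R except when the next residue is P; fragments
#' outside the retained length range (default 5--30 residues, the typical
#' tryptic peptide range) are discarded.
#'
#' @param protein a canonical amino-acid string.
#' @param min_length,max_length retained fragment length range.
#' @return Character vector of retained peptides (possibly empty).
#' @examples
#' digest_tryptic("AAAKGGGRCCCCC")  # "GGGR" "CCCCC" ("AAAK" is too short)
#' digest_tryptic("AAKPGGR")        # no cleavage before proline
#' @export
digest_tryptic <- function(protein, min_length = 5L, max_length = 30L) {
  protein <- toupper(protein)
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  if (n == 0L) return(character(0))
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  frags <- substring(protein, starts, ends)
  frags[nchar(frags) >= min_length & nchar(frags) <= max_length]
}

#' Generate a synthetic de novo-style query peptide list
#'
#' Samples tryptic peptides from the reference (uniformly over the pooled
#' digest, with replacement if more are requested than exist, which is
#' logged as a message), optionally applies at most one BLOSUM62-guided
#' substitution per peptide (replacement residue drawn among residues
#' scoring >= 0 against the original, excluding the original itself),
#' appends decoy peptides of random composition, and attaches
#' Beta-sampled confidence scores.
#'
#' @param spec a [fixture_spec()].
#' @param reference output of [generate_reference()] for the same spec.
#' @param bins optional character vector restricting source bins (e.g. a
#'   single planted bin); default all bins.
#' @return A list: `peptides` (data frame sequence/confidence) and `truth`
#'   (data frame sequence/bin/substituted, bin `"decoy"` for decoys).
#' @export
generate_queries <- function(spec, reference, bins = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  model <- read_blosum()
  with_seed(spec$seed + 1L, {
    src <- reference$truth
    if (!is.null(bins)) src <- src[src$bin %in% bins, , drop = FALSE]
    pool_pep <- character(0)
    pool_bin <- character(0)
    for (i in seq_len(nrow(src))) {
      frags <- digest_tryptic(reference$fasta[[src$record_id[i]]],
                              spec$peptide_length[1], spec$peptide_length[2])
      pool_pep <- c(pool_pep, frags)
      pool_bin <- c(pool_bin, rep(src$bin[i], length(frags)))
    }
    if (length(pool_pep) == 0L) stop("reference yields no tryptic peptides")
    n_decoy <- round(spec$n_query_peptides * spec$decoy_fraction)
    n_real <- spec$n_query_peptides - n_decoy
    replace <- n_real > length(pool_pep)
    if (replace)
      message("requested ", n_real, " peptides from a pool of ",
              length(pool_pep), "; sampling with replacement")
    idx <- if (n_real > 0)
      sample.int(length(pool_pep), n_real, replace = replace)
    else integer(0)
    peps <- pool_pep[idx]
    origins <- pool_bin[idx]
    substituted <- logical(length(peps))
    if (spec$substitution_rate > 0 && length(peps)) {
      do_sub <- runif(length(peps)) < spec$substitution_rate
      for (i in which(do_sub)) {
        peps[i] <- substitute_residue(peps[i], model)
        substituted[i] <- TRUE
      }
    }
    if (n_decoy > 0) {
      lens <- sample(spec$peptide_length[1]:spec$peptide_length[2], n_decoy,
                     replace = TRUE)
      decoys <- vapply(lens, random_protein, character(1),
                       weights = spec$residue_distribution)
      peps <- c(peps, decoys)
      origins <- c(origins, rep("decoy", n_decoy))
      substituted <- c(substituted, logical(n_decoy))
    }
    conf <- rbeta(length(peps), spec$confidence_shape[1],
                  spec$confidence_shape[2])
    list(
      peptides = data.frame(sequence = peps, confidence = round(conf, 4),
                            stringsAsFactors = FALSE),
      truth = data.frame(sequence = peps, bin = origins,
                         substituted = substituted, stringsAsFactors = FALSE)
    )
  })
}

# replace one random position with a plausible (BLOSUM score >= 0,
# different) residue; positions with no such neighbour fall back to any
# other residue scoring the maximum available
substitute_residue <- function(peptide, model) {
  chars <- strsplit(peptide, "")[[1]]
  pos <- sample.int(length(chars), 1L)
  orig <- chars[pos]
  sc <- model$scores[orig, ]
  cand <- names(sc)[sc >= 0 & names(sc) != orig]
  if (!length(cand)) {
    alt <- sc[names(sc) != orig]
    cand <- names(alt)[alt == max(alt)]
  }
  chars[pos] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  paste(chars, collapse = "")
}

#' Write a complete fixture to disk
#'
#' Materializes a [fixture_spec()] as the four standard files:
#' `reference.fasta`, `grouping.tsv` (record_id, bin; no header),
#' `peptides.tsv` (sequence, confidence; with header) and `truth.tsv`.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if absent).
#' @return Invisibly, a named vector of the four paths.
#' @export
simulate_fixture <- function(spec, dir) {
  ref <- generate_reference(spec)
  qry <- generate_queries(spec, ref)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "reference.fasta")
  writeLines(paste0(">", names(ref$fasta), "\n", unname(ref$fasta)), fasta)
  grouping <- file.path(dir, "grouping.tsv")
  write.table(ref$grouping, grouping, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  peptides <- file.path(dir, "peptides.tsv")
  write.table(qry$peptides, peptides, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- file.path(dir, "truth.tsv")
  write.table(qry$truth, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, grouping = grouping, peptides = peptides,
              truth = truth))
}
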