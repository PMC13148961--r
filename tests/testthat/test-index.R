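make_fasta3 <- function() {
  seqs <- c(p1 = "MKTAYIAKQRQISFVKSHFSRQ", p2 = "MSDNPLLTWQEFARLEKQ",
            p3 = "GGHHEEWWLLKKMMNNPPQQ")
  write_temp_fasta(seqs)
}

test_that("load_bins maps records to bins with and without grouping", {
  fa <- make_fasta3()
  bins <- load_bins(fa)
  expect_length(bins, 3L)
  expect_named(bins, c("p1", "p2", "p3"))

  g <- tempfile()
  writeLines(c("p1\ttaxA", "p2\ttaxA", "p3\ttaxA"), g)
  bins <- load_bins(fa, g)
  expect_length(bins, 1L)
  expect_length(bins$taxA, 3L)

  g2 <- tempfile()
  writeLines(c("p1\ttaxA", "p2\ttaxA", "ghost\ttaxB"), g2)
  expect_warning(expect_warning(bins <- load_bins(fa, g2), "absent"),
                 "singleton")
  expect_named(bins, c("taxA", "p3"))

  dup <- write_temp_fasta(c(a = "MKTA", a = "MSDN"))
  expect_error(load_bins(dup), "duplicate")
})

test_that("splits chunk bins in order after blacklist removal", {
  labs <- paste0("bin", 1:10)
  expect_equal(lengths(plan_splits(labs, 4)), c(4L, 4L, 2L))
  expect_equal(plan_splits(labs, 4)[[3]], c("bin9", "bin10"))
  expect_equal(lengths(plan_splits(labs, 4, blacklist = c("bin2", "bin7"))),
               c(4L, 4L))
  expect_length(plan_splits(labs, 64), 1L)
  expect_error(plan_splits(labs, 4, blacklist = labs), "empty index")
})

test_that("sizing load is the per-bin maximum of distinct k-mer counts", {
  expect_equal(estimate_max_kmers(list(b = "PEPTIDE")), 3)
  bins <- list(small = "PEPTIDE", big = "MKTAYIAKQRQ")  # 3 vs 7 k-mers
  expect_equal(estimate_max_kmers(bins), 7)
  m <- read_blosum()
  mut <- mutation_config(TRUE, 20, model = m)
  expect_gte(estimate_max_kmers(bins, mutation = mut),
             estimate_max_kmers(bins))
})

test_that("index build is deterministic and serializes bit-exactly", {
  set.seed(71)
  bins <- setNames(lapply(1:5, function(i) random_protein_str(80)),
                   paste0("bin", 1:5))
  i1 <- peptide_index(bins, split_size = 2)
  i2 <- peptide_index(bins, split_size = 2)
  expect_identical(serialize(i1, NULL), serialize(i2, NULL))

  p1 <- tempfile(fileext = ".rds")
  write_index(i1, p1)
  back <- read_index(p1)
  expect_identical(back$ibfs[[1]]$bits, i1$ibfs[[1]]$bits)
  expect_equal(back$bin_directory, i1$bin_directory)
  p2 <- tempfile(fileext = ".rds")
  write_index(i2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("every reference k-mer is found in its own bin after the build", {
  set.seed(72)
  bins <- setNames(lapply(1:4, function(i) random_protein_str(60)),
                   paste0("bin", 1:4))
  idx <- peptide_index(bins, split_size = 2)
  for (lab in names(bins)) {
    row <- idx$bin_directory[idx$bin_directory$label == lab, ]
    f <- idx$ibfs[[row$ibf]]
    codes <- unique(encode_kmer(kmerize(bins[[lab]], idx$config)$kmer))
    counts <- ibf_query(f, codes)
    expect_equal(unname(counts[row$local_bin]), length(codes))
  }
})

test_that("true-positive counts are invariant to the split size", {
  set.seed(73)
  bins <- setNames(lapply(1:10, function(i) random_protein_str(70)),
                   paste0("bin", 1:10))
  peptides <- data.frame(
    sequence = vapply(bins[1:5], function(s) substr(s, 11, 25), character(1)),
    confidence = 0.9)
  base <- NULL
  for (M in c(1L, 3L, 64L, 10L)) {
    idx <- peptide_index(bins, split_size = M)
    res <- predict(idx, peptides, D = 100, min_confidence = 0)
    tp <- res$counts[cbind(1:5, match(paste0("bin", 1:5),
                                      colnames(res$counts)))]
    expect_equal(tp, unname(res$y))
    if (is.null(base)) base <- tp else expect_equal(tp, base)
  }
})

test_that("each IBF is sized by its own batch and records its load", {
  set.seed(74)
  bins <- list(a = random_protein_str(40), b = random_protein_str(40),
               c = random_protein_str(200), d = random_protein_str(200))
  idx <- peptide_index(bins, split_size = 2)
  expect_length(idx$ibfs, 2L)
  for (f in idx$ibfs)
    expect_equal(f$n, optimal_bin_size(f$max_kmers, idx$target_fpr,
                                       idx$hash_count))
  expect_gt(idx$ibfs[[2]]$n, idx$ibfs[[1]]$n)
})

test_that("blacklisted bins never enter the directory", {
  set.seed(75)
  bins <- setNames(lapply(1:6, function(i) random_protein_str(50)),
                   paste0("bin", 1:6))
  bl <- tempfile()
  writeLines(c("# outliers", "bin2", "bin5"), bl)
  idx <- peptide_index(bins, blacklist = bl, split_size = 3)
  expect_false(any(c("bin2", "bin5") %in% idx$bin_directory$label))
  expect_equal(nrow(idx$bin_directory), 4L)
})

test_that("bins with no valid k-mers are retained empty with a warning", {
  bins <- list(good = "MKTAYIAKQRQISFVK", bad = "XXXXXXXX")
  expect_warning(idx <- peptide_index(bins), "empty")
  expect_equal(idx$bin_directory$label, c("good", "bad"))
  q <- data.frame(sequence = "MKTAYIAK", confidence = 0.9)
  res <- predict(idx, q, min_confidence = 0)
  expect_equal(unname(res$scores["bad"]), 0)
})

test_that("minimizer mode is applied identically at build and query", {
  set.seed(76)
  seqs <- setNames(lapply(1:3, function(i) random_protein_str(60)),
                   paste0("bin", 1:3))
  cfg <- kmer_config(k = 5, minimizer_window = 4)
  idx <- peptide_index(seqs, config = cfg)
  # a peptide identical to a full reference sequence selects the same
  # minimizers, so every selected k-mer must be found
  q <- data.frame(sequence = seqs$bin2, confidence = 0.9)
  res <- predict(idx, q, D = 100, min_confidence = 0)
  expect_equal(unname(res$lookup[1, "bin2"]), 1L)
  codes <- encode_kmer(kmerize(seqs$bin2, kmer_config(k = 5))$kmer)
  expect_equal(unname(res$y), length(minimizers(codes, 4)))
})
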