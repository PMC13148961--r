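toy_assignment <- function(counts, y) {
  structure(list(counts = counts, y = y, lookup = NULL, scores = NULL,
                 D = NULL,
                 peptides = data.frame(sequence = rownames(counts),
                                       confidence = 0.9),
                 bin_labels = colnames(counts)),
            class = "peptide_assignment")
}

test_that("confidence filtering keeps the boundary and deduplicates", {
  p <- data.frame(sequence = c("PEPTIDES", "AAAAAGGG"),
                  confidence = c(0.9, 0.69))
  expect_equal(nrow(filter_peptides(p, 0.70)), 1L)
  expect_equal(nrow(filter_peptides(p, 0.0)), 2L)

  short <- data.frame(sequence = c("AAA", "PEPTIDES"), confidence = 0.99)
  f <- filter_peptides(short, 0.7, k = 5)
  expect_equal(f$sequence, "PEPTIDES")
  expect_equal(unname(attr(f, "dropped")["too_short"]), 1L)

  dup <- data.frame(sequence = c("PEPTIDES", "PEPTIDES", "AGAGAGAG"),
                    confidence = c(0.8, 0.95, 0.75))
  f <- filter_peptides(dup, 0.7)
  expect_equal(f$sequence, c("PEPTIDES", "AGAGAGAG"))
  expect_equal(f$confidence, c(0.95, 0.75))
  expect_error(filter_peptides(data.frame(sequence = "AA", confidence = 1.2)))
})

test_that("the lookup threshold x = y D / 100 is applied unrounded", {
  counts <- matrix(c(4L, 3L), 1, 2,
                   dimnames = list("PEP", c("b1", "b2")))
  res <- assignment_threshold(toy_assignment(counts, y = 5L), D = 80)
  expect_equal(unname(res$lookup[1, ]), c(1L, 0L))  # x = 4.0

  # D = 100: only full coverage passes
  res100 <- assignment_threshold(toy_assignment(counts, y = 5L), D = 100)
  expect_equal(unname(res100$lookup[1, ]), c(0L, 0L))
  counts[1, 1] <- 5L
  expect_equal(unname(assignment_threshold(toy_assignment(counts, 5L),
                                           100)$lookup[1, 1]), 1L)
  expect_error(assignment_threshold(toy_assignment(counts, 5L), 0))
  expect_error(assignment_threshold(toy_assignment(counts, 5L), 101))
})

test_that("lowering D never clears a set lookup bit", {
  set.seed(81)
  y <- sample(3:12, 30, replace = TRUE)
  counts <- matrix(0L, 30, 6)
  for (i in 1:30) counts[i, ] <- sample(0:y[i], 6, replace = TRUE)
  dimnames(counts) <- list(paste0("p", 1:30), paste0("b", 1:6))
  a <- toy_assignment(counts, y)
  l80 <- assignment_threshold(a, 80)$lookup
  l70 <- assignment_threshold(a, 70)$lookup
  expect_true(all(l70 >= l80))
})

test_that("bin scores are column means of the lookup matrix", {
  counts <- matrix(c(5L, 5L, 0L, 1L), 4, 1,
                   dimnames = list(paste0("p", 1:4), "b1"))
  res <- assignment_threshold(toy_assignment(counts, y = rep(5L, 4)), 100)
  expect_equal(unname(res$scores), 0.5)  # column bits (1,1,0,0)

  ones <- matrix(5L, 4, 2, dimnames = list(paste0("p", 1:4), c("a", "b")))
  res <- assignment_threshold(toy_assignment(ones, rep(5L, 4)), 100)
  expect_equal(unname(res$scores), c(1, 1))
  # conservation: sum_B S_B * z = number of set bits
  expect_equal(sum(res$scores) * 4, sum(res$lookup))
})

test_that("count matrix equals per-IBF queries stitched by the directory", {
  set.seed(82)
  bins <- setNames(lapply(1:6, function(i) random_protein_str(60)),
                   paste0("bin", 1:6))
  idx <- peptide_index(bins, split_size = 2)  # 3 IBFs
  peptides <- data.frame(
    sequence = c(substr(bins$bin1, 5, 18), substr(bins$bin4, 20, 33),
                 random_protein_str(12)),
    confidence = 0.9)
  res <- predict(idx, peptides, min_confidence = 0)
  # oracle: query each IBF directly with each peptide's distinct codes
  for (u in seq_len(nrow(res$counts))) {
    codes <- unique(encode_kmer(kmerize(peptides$sequence[u],
                                        idx$config)$kmer))
    expect_equal(unname(res$y[u]), length(codes))
    for (bi in seq_along(idx$ibfs)) {
      oracle <- ibf_query(idx$ibfs[[bi]], codes)
      cols <- idx$bin_directory$label[idx$bin_directory$ibf == bi]
      expect_equal(res$counts[u, cols], oracle)
    }
  }
})

test_that("a peptide whose k-mers are all indexed reaches full coverage", {
  set.seed(83)
  bins <- setNames(lapply(1:3, function(i) random_protein_str(50)),
                   c("src", "o1", "o2"))
  idx <- peptide_index(bins)
  pep <- substr(bins$src, 10, 24)
  res <- predict(idx, data.frame(sequence = pep, confidence = 1),
                 D = 100, min_confidence = 0)
  expect_equal(unname(res$counts[1, "src"]), unname(res$y[1]))
  expect_equal(unname(res$lookup[1, "src"]), 1L)
})

test_that("scores are invariant to peptide input order", {
  set.seed(84)
  bins <- setNames(lapply(1:4, function(i) random_protein_str(60)),
                   paste0("bin", 1:4))
  idx <- peptide_index(bins)
  peptides <- data.frame(
    sequence = vapply(bins, function(s) substr(s, 3, 17), character(1)),
    confidence = 0.9)
  r1 <- predict(idx, peptides, min_confidence = 0)
  r2 <- predict(idx, peptides[rev(seq_len(nrow(peptides))), ],
                min_confidence = 0)
  expect_equal(r1$scores, r2$scores)
})

test_that("configuration mismatches and empty inputs are rejected", {
  bins <- list(a = "MKTAYIAKQRQISFVK")
  idx <- peptide_index(bins)
  expect_error(predict(idx, data.frame(sequence = "PEPTIDES",
                                       confidence = 0.2)),
               "no peptides")
})

test_that("assignment reports round-trip through the TSV writers", {
  set.seed(85)
  bins <- setNames(lapply(1:3, function(i) random_protein_str(60)),
                   paste0("bin", 1:3))
  idx <- peptide_index(bins)
  peptides <- data.frame(
    sequence = c(substr(bins$bin1, 4, 18), substr(bins$bin1, 20, 34),
                 substr(bins$bin3, 7, 21)),
    confidence = c(0.9, 0.8, 0.95))
  res <- predict(idx, peptides, min_confidence = 0)
  dir <- tempfile()
  paths <- write_assignment(res, dir)
  bins_tbl <- read.delim(paths[["bins"]])
  expect_equal(sort(bins_tbl$bin_label), sort(colnames(res$lookup)))
  expect_equal(bins_tbl$score_S[1], max(res$scores))
  pep_tbl <- read.delim(paths[["peptides"]])
  expect_equal(nrow(pep_tbl), 3L)
  expect_equal(pep_tbl$y, unname(res$y))
  # summary ranks by descending score and counts unique assignments
  s <- summary(res)
  expect_true(all(diff(s$score_S) <= 0))
  expect_true(all(s$unique_peptides <= s$peptides_passing))
})
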