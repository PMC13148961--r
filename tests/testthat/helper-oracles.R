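# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths except where sharing is part of the contract
# (the hash positions, which implementation and scalar-Bloom oracle must
# agree on by construction).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_kmers <- function(n, k) {
  vapply(seq_len(n), function(i)
    paste(sample(AA20, k, replace = TRUE), collapse = ""), character(1))
}

random_protein_str <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# least n with (1 - (1 - 1/n)^(H m))^H <= p, by binary search on the
# false-positive formula written out directly
oracle_bin_size <- function(m, p, H) {
  fpr <- function(n) (1 - (1 - 1 / n)^(H * m))^H
  lo <- 1
  hi <- 2
  while (fpr(hi) > p) hi <- hi * 2
  while (lo < hi) {
    mid <- floor((lo + hi) / 2)
    if (fpr(mid) <= p) hi <- mid else lo <- mid + 1
  }
  lo
}

# brute-force substitution-variant enumeration over the full 20^k space
brute_force_variants <- function(kmer, scores, threshold) {
  chars <- strsplit(kmer, "")[[1]]
  grid <- do.call(expand.grid,
                  c(rep(list(AA20), length(chars)),
                    list(stringsAsFactors = FALSE)))
  total <- rowSums(mapply(function(col, orig) scores[orig, grid[[col]]],
                          seq_along(chars), chars))
  hits <- apply(grid[total >= threshold, , drop = FALSE], 1L, paste,
                collapse = "")
  sort(unique(c(hits, kmer)))
}

# independent per-bin scalar Bloom filters sharing the package's hash
# positions; returns membership counts for the query codes
scalar_bloom_counts <- function(n, inserted_by_bin, query_codes, seeds) {
  counts <- integer(length(inserted_by_bin))
  query_codes <- unique(query_codes)
  qpos <- peptax:::cpp_hash_positions(query_codes, seeds, n)
  for (j in seq_along(inserted_by_bin)) {
    bits <- logical(n)
    codes <- unique(inserted_by_bin[[j]])
    if (length(codes)) {
      pos <- peptax:::cpp_hash_positions(codes, seeds, n)
      bits[as.vector(pos) + 1L] <- TRUE
    }
    counts[j] <- sum(apply(qpos, 1L, function(p) all(bits[p + 1L])))
  }
  counts
}

write_temp_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# distinct random 64-bit-range codes kept within exact-double range
random_codes <- function(n, max_code = 2^50) {
  unique(floor(runif(n * 1.2, 0, max_code)))[seq_len(n)]
}
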