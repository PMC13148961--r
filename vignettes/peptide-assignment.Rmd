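---
title: "Indexing and assigning de novo peptides with interleaved Bloom filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexing and assigning de novo peptides with interleaved Bloom filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptax)
```

## The model

`peptax` classifies peptide sequences against a protein reference database
by approximate k-mer membership. Each reference entity — a protein, a
proteome, or a taxon-level group of proteins (a *user bin*) — is reduced to
the set of its distinct amino-acid k-mers, and those k-mers are inserted
into one column of an interleaved Bloom filter (IBF): `b` equal-size Bloom
filters stored position-major, so that each of the `n` bit positions holds
a `b`-bit sub-vector and one set of `H` hash probes answers the membership
question for every bin simultaneously.

A Bloom filter is a probabilistic set: it never misses an inserted element
(no false negatives), but reports absent elements present with probability

$$p = \left(1 - \left(1 - \tfrac{1}{n}\right)^{Hm}\right)^H$$

for `n` bits, `m` inserted elements, `H` hash functions. The package sizes
each IBF by inverting this for the smallest `n` meeting a target rate at
the load of its *most loaded* bin (`maxKmers`, counted after variant
expansion and minimizer selection, since that is what the filter must
hold):

$$n = \left\lceil \frac{-1}{r^{1/(H\,\mathrm{maxKmers})} - 1} \right\rceil,
\qquad r = 1 - p^{1/H}.$$

Interleaving forces all bins of one IBF to share that `n`; bins with very
uneven k-mer content therefore waste bits, which is exactly why large
databases are partitioned: batches of `split_size` bins get their own,
independently sized IBF, and query results are stitched back together
through a global bin directory. The partitioning changes memory and
false-positive behaviour per batch but never true positives — an invariant
the test suite checks across split sizes.

Assignment is a two-threshold procedure. For each query peptide `u` the
distinct-k-mer hits per bin form the count matrix entry `c_uv`; with `y_u`
distinct k-mers in the peptide and an assignment threshold `D` (a
percentage), the peptide is assigned to bin `v` when
`c_uv >= x_u = y_u * D / 100`. The per-bin assignment score is the fraction
of peptides assigned: `S_B = sum_u l_uB / z`. Both the raw assigned-peptide
count and `S` are reported, so bins can be ranked by either.

## Error-tolerant mode

De novo peptides carry sequencing errors and genuine sequence variation,
most of it substitutions between biochemically similar residues. In
mutation mode every reference k-mer is expanded, at index build time, into
all variants whose *cumulative* substitution score against the original,
`sum_i S(kmer_i, variant_i)` under BLOSUM62, reaches a user threshold. Two
details matter:

* **Cumulative, not per-position, scoring.** A per-substitution threshold
  cannot be reconciled with useful thresholds around 25 for 5-mers
  (BLOSUM62's largest single entry is 11); summing over positions makes the
  threshold a budget shared across the k-mer, so one dissimilar
  substitution must be paid for by similar residues elsewhere.
* **Originals are unconditional.** The original k-mer is always indexed,
  even when its self-score misses the threshold, so exact matching never
  degrades.

Enumeration is depth-first over per-residue candidate lists pre-sorted by
descending score (ties alphabetical, for reproducible indexes), with
branch-and-bound pruning: a branch is cut as soon as its partial score plus
the best possible completion cannot reach the threshold, and the sort order
lets the cut discard all remaining siblings at once. The suite verifies the
pruned enumeration against brute-force enumeration of the full `20^k`
space for k up to 3.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 5 | k-mer length (residues). Short enough that tryptic peptides (5–30 residues) yield several k-mers; 5-bit encoding caps k at 12. |
| `target_fpr` | 0.01 | per-bin Bloom false-positive rate the sizing rule guarantees at full load. |
| `hash_count` | 3 | number of hash functions H. |
| `split_size` | 64 | user bins per IBF; aligns sub-vectors with machine words. |
| `D` | 100 | assignment threshold (percent of a peptide's k-mers that must hit a bin). 100 is the full-coverage criterion; 80 and 70 are useful relaxations. |
| `min_confidence` | 0.70 | de novo confidence filter; 0.50 is the relaxed preset for mutation-rich samples where variant recall is prioritized. |
| `score_threshold` | 25 | cumulative BLOSUM62 score a variant must reach in mutation mode. |
| `minimizer_window` | 0 (off) | forward-strand minimizer sketching; proteins have no reverse complement, and protein sequences are short, so sketching is optional. |
| `collapse_il` | FALSE | map I/L (isobaric, indistinguishable de novo) to one symbol. Off by default to match the literal reference alphabet. |

## Numerical and design choices

* **Encoding.** 5-bit alphabetical ordinals, first residue most
  significant: codes are order-preserving per position and fit 64 bits for
  k ≤ 12. R doubles are exact for codes up to 2^53 (k ≤ 10); the build and
  query pipelines keep codes in native 64-bit integers inside the compiled
  core throughout, so k of 11–12 remains exact end to end.
* **Hashing.** H independent functions realized as a splitmix64 finalizer
  of the code XORed with a mixed seed; the H seeds are fixed constants
  recorded in the index header, making rebuilds byte-identical and indexes
  portable across platforms.
* **Set semantics everywhere.** k-mers are deduplicated per bin before
  sizing and insertion, and per peptide before querying; a repeated k-mer
  within one peptide counts once. This keeps the count matrix consistent
  with the sizing load and avoids double-counting bits.
* **Unrounded threshold.** `x = y*D/100` is compared as a real number;
  with `y = 5, D = 80` the cutoff is exactly 4.0 and a count of 4 passes.
* **Non-canonical residues** (X, B, Z, U, O, J, `*`) invalidate only the
  k-mer windows containing them, not the whole sequence; dropped-window
  counts are reported. Bins left with no valid k-mers are retained (with a
  warning) so bin indices stay aligned with the input.
* **Minimizers with mutation.** Minimizers need an ordered k-mer stream,
  variant expansion produces unordered sets; when both are enabled the
  package selects minimizers on the original stream first and expands only
  the selected k-mers. The two modes are therefore composable but their
  combination weakens the coverage guarantee for substituted queries, and
  they are tested separately.
* **Empty-bin convention.** `optimal_bin_size(0, ...)` returns 1 bit so an
  IBF of empty bins is still well-formed.
* **Ties in bin ranking** are broken by input bin order; bin order is
  first-appearance order in the FASTA/grouping input, never sorted.

## The synthetic fixture generator

`fixture_spec()` / `generate_reference()` / `generate_queries()` emulate a
defined-composition evaluation: bins of random proteins (uniform residue
composition by default, configurable), tryptic digestion (cleave after K/R
except before P, retain 5–30 residue fragments), query peptides sampled
from known bins with Beta(8, 2)-distributed confidence scores (mean 0.8, a
high-confidence de novo regime), optional decoys of random composition, and
an optional single BLOSUM62-guided substitution per peptide — one plausible
error, drawn among replacements scoring ≥ 0 against the original, which
isolates the substitution mechanism that mutation mode is designed to
absorb. Everything is a pure function of the spec's seed.

What the generator does **not** emulate: real proteome homology and shared
conserved peptides across taxa, realistic residue composition unless
configured, missed cleavages, insertions/deletions, modified residues, and
de novo error models beyond single substitutions. Passing the planted-bin
recovery tests therefore demonstrates the correctness of the index and
scoring machinery, not classification accuracy on real communities, where
closely related taxa legitimately share peptides and multi-assignment is
expected.

## Problem sizes in the test suite

The suite runs entirely on generated data: filters up to ~124 kbit (a bin
sized for 10 000 k-mers, probed 100 000 times for the empirical
false-positive check), databases of 10 bins × 3 proteins of 120–240
residues, query sets of 40–100 peptides, and exhaustive variant oracles up
to k = 3 (8 000 variants). These sizes exercise every code path — multiple
IBFs, both modes, all thresholds — while keeping a full run in the tens of
seconds.

## Known limitations

* Assignment is bin-level; there is no lowest-common-ancestor rollup
  across taxonomic ranks, no FDR estimation, and no protein inference
  beyond the per-bin score.
* Mutation mode models substitutions only — no insertions, deletions, or
  mass-shift (PTM) awareness.
* Bloom filters cannot delete: a changed reference requires a rebuild.
* Interleaving reserves the largest bin's size for every bin in a batch;
  grouping references of similar k-mer content into the same split keeps
  memory tight.
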