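# peptax

Peptide-to-protein and taxon assignment with partitioned interleaved
Bloom filter (IBF) indexes over amino-acid k-mers.

## The problem

De novo peptide sequencing predicts peptide sequences directly from MS/MS
spectra, without a database — which means the question "which protein, which
organism?" still has to be answered afterwards, often against reference
databases far too large for exact search. `peptax` answers it with
approximate membership counting: every reference entity (a protein, a
proteome, or a taxon — a *user bin*) is represented by the set of its
amino-acid k-mers in one column of an interleaved Bloom filter, and a query
peptide is assigned to the bins that contain (enough of) its k-mers. The
intended users are metaproteomics and proteogenomics analysts who need fast,
memory-bounded taxonomic or protein-level classification of large de novo
peptide lists.

## The method

**Bloom filter sizing.** A Bloom filter of `n` bits holding `m` elements
under `H` hash functions has false-positive rate

    p = (1 − (1 − 1/n)^(H·m))^H

Inverting for the smallest `n` meeting a target rate `p` at load `maxKmers`
(the largest distinct-k-mer count over the bins of one IBF):

    n = ⌈ −1 / (r^(1/(H·maxKmers)) − 1) ⌉,   r = 1 − p^(1/H)

Defaults: `p = 0.01`, `H = 3`, `k = 5`. An IBF stores `b` such filters
interleaved — each bit position holds a `b`-bit sub-vector — so one set of
hash probes queries all bins at once. Large databases are partitioned into
batches of `M` bins (default 64), one independently sized IBF per batch,
with an optional blacklist removing over-represented references up front.

**Error tolerance.** In mutation mode each reference k-mer is expanded at
build time into every variant whose cumulative BLOSUM62 score against the
original, `Σᵢ S(kmerᵢ, varᵢ)`, meets a user threshold — enumerated over
per-residue candidate lists pre-sorted by descending score with
branch-and-bound pruning. Originals are always indexed, so exact matching is
never lost.

**Assignment.** For `u` filtered query peptides and `v` bins the count
matrix `C` holds the distinct-k-mer hits `c_uv`; with `y_u` the number of
distinct k-mers of peptide `u` and an assignment threshold `D` (percent),
peptide `u` is assigned to bin `v` when `c_uv ≥ x_u = y_u·D/100` (lookup
matrix `L`), and each bin's assignment score is the fraction of peptides
assigned to it, `S_B = Σ_u l_uB / z`. `D = 100` demands full k-mer coverage.

## Worked example

```r
library(peptax)

# a seeded synthetic community: 6 bins, known peptide origins
spec <- fixture_spec(n_bins = 6, proteins_per_bin = 3,
                     n_query_peptides = 40, substitution_rate = 0, seed = 42)
ref  <- generate_reference(spec)
bins <- split(unname(ref$fasta), ref$grouping$bin)

idx <- peptide_index(bins, split_size = 3)
idx
#> Partitioned interleaved Bloom filter index
#>   6 bin(s) across 2 IBF(s); k = 5, H = 3, target FPR = 0.01

# query peptides drawn only from bin02, full-coverage criterion
qry <- generate_queries(spec, ref, bins = "bin02")
res <- predict(idx, qry$peptides, D = 100, min_confidence = 0.7)
res
#> Peptide assignment: 36 peptide(s) x 6 bin(s), D = 100%
#>   top bins by assignment score S:
#>     bin02                    S = 1.0000 (36 peptide(s))

head(summary(res), 3)
#>   bin_label peptides_passing score_S unique_peptides
#> 1     bin02               36       1              36
#> 2     bin01                0       0               0
#> 3     bin03                0       0               0
```

Every one of the 36 peptides surviving the 70% confidence filter is
assigned to its true source bin (`S = 1`), none to any other bin: at
`D = 100` an off-target assignment would need every k-mer of a peptide to
false-positive simultaneously. `write_assignment(res, dir)` writes the
per-bin and per-peptide TSV reports; a command-line front end for the
same pipeline ships as `inst/scripts/peptax` (subcommands `build`,
`query`, `simulate`).

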