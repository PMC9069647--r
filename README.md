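# crossBeta

Geometric detection of amyloid-characteristic parallel β-sheets from
Cα coordinates, and analysis of their length-5 boundary prefixes.

## What this is for

Amyloids are misfolded protein aggregates whose defining feature is the
cross-β architecture: in-register parallel β-strands on *separate*
polypeptide chains, stacked at ≈ 4.8 Å. Several soluble, globular
proteins contain substructures satisfying the same strict geometry, which
makes the short sequences at the *borders* of those sheets candidates for
modulating amyloid transitions. crossBeta is for structural
bioinformaticians who want to:

* detect parallel β-sheet segment pairs in PDB/mmCIF files from
  coordinates alone (no DSSP, no annotation text);
* harvest the boundary 5-mers of those sheets — the **XXYYY prefix**,
  where `YYY` are the first three sheet residues and `XX` the two
  residues immediately preceding the sheet, plus the mirrored suffix;
* tally the raw multiplicities of these k-mers across a structure
  collection, split into NMR- and X-ray-derived entries;
* search any protein sequence set (e.g. `pdb_seqres.txt`) for exact
  occurrences of the harvested k-mers.

## The detector

A pair of equal-length residue runs on two distinct chains, paired
index-to-index (in register), is accepted when

1. every per-position Cα–Cα distance d_k satisfies 2 Å ≤ d_k ≤ 15 Å and
   the standard deviation of the profile is < 1.5 Å;
2. neither run is strongly curved — operationalised as the straightness
   ratio (end-to-end / contour length) ≥ 0.9, and the runs point the same
   way (normalised direction dot product ≥ 0.5, which excludes
   anti-parallel sheets);
3. the segment covers ≥ 1/7 of the resolved length of at least one
   parent chain.

Reported pairs are maximal (no one-residue extension stays valid). The
separate-chain rule excludes hairpins and β-barrels by construction. All
thresholds live in `GeometryParams()`.

## Worked example

The generator plants a known sheet, so the expected answer is known in
advance. A stand-in for an amyloid-β(1–40) fibril (three chains, strand
planted at L17):

```r
library(crossBeta)

spec <- standInSheetSpec("2MPZ")          # synthetic stand-in, Aβ(1–40)
s    <- generateParallelSheet(spec)
pp   <- findParallelPairs(s)
pp[, c("chain_a","chain_b","start_a","end_a","length",
       "mean_distance","distance_sd")]
#>   chain_a chain_b start_a end_a length mean_distance distance_sd
#> 1       A       B      17    25      9           4.8           0
#> 2       A       C      17    25      9           9.6           0
#> 3       B       C      17    25      9           4.8           0

tallyKmers(boundaryKmers(s, pp, sides = "prefix"))
#>    kmer   side method_class count n_entries entries
#> 1 QKLVF prefix          NMR     6         1    2MPZ
```

All three in-band chain pairs (adjacent at 4.8 Å, next-nearest at 9.6 Å)
report the planted strand 17–25, and each segment's boundary reads
QK|LVF: glutamine–lysine flanking the leucine–valine–phenylalanine start
of the β-strand — six occurrences because each of the three pairs
contributes both of its chains. Searching a sequence collection for a
harvested k-mer:

```r
searchKmer("GGERA", standInSequenceCollection())
#>    kmer source_id chain_id position     context
#> 1 GGERA      1TCP        A       20 SNEGGERAYFR
```

To run the same pipeline over your own structure files:

```r
res <- runPipeline(c("dir/with/pdbs"), GeometryParams())
res$counts                     # k-mer tally with entry lists
prefixSurveyReport("dir/with/pdbs")   # comparison against the published
                                      # reference prefix counts
```

A thin command-line front end with `detect`, `count`, `search`,
`simulate` and `survey` subcommands is at `exec/crossbeta`
(`Rscript exec/crossbeta simulate --help`).

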