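---
title: "Geometric detection of parallel beta-sheets and their boundary prefixes"
author: "crossBeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric detection of parallel beta-sheets and their boundary prefixes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossBeta)
```

## The problem

Amyloids are protein aggregates built from stacked, in-register parallel
beta-sheets (the cross-beta architecture). Because several globular,
soluble proteins contain substructures that satisfy the same strict
geometry, the short sequences at the *borders* of such sheets are
interesting: they may modulate the transition into the amyloid state.
crossBeta implements the corresponding analysis chain from coordinates
alone, with no secondary-structure annotation and no hydrogen-bond
assignment:

1. detect parallel beta-sheet segment pairs in a structure from C-alpha
   coordinates (`findParallelPairs`);
2. extract the length-5 boundary *prefix* of each detected segment — the
   two residues immediately N-terminal of the sheet (`XX`) plus the first
   three sheet residues (`YYY`) — and the mirrored *suffix*
   (`boundaryKmers`);
3. tally raw multiplicities of these k-mers, partitioned into NMR-derived
   and X-ray-derived entries (`tallyKmers`, `topKmers`);
4. search arbitrary protein sequence collections for exact occurrences of
   the k-mers (`searchKmer`, `batchKmerReport`).

A synthetic generator (`generateParallelSheet`, `generateDecoy`) produces
ground-truth fibrils and negative controls so that every stage is testable
without downloading anything.

## The detection model

Two equal-length residue runs, on *distinct* polypeptide chains, form a
parallel segment pair when, under index-registered pairing (residue *k*
of one run against residue *k* of the other):

* every per-position C-alpha distance lies in `[dMin, dMax]` = [2, 15] Å,
  and the standard deviation of the distance profile is below
  `sigmaMax` = 1.5 Å;
* both runs are straight: end-to-end distance over contour length at
  least `straightnessMin` = 0.9 (the curvature exclusion);
* the runs point the same way: normalised end-to-end dot product at least
  `parallelDotMin` = 0.5 (anti-parallel arrangements score near −1);
* the segment covers at least `coverageMin` = 1/7 of the resolved length
  of at least one parent chain.

Reported pairs are *maximal*: extending them by one residue at either end
violates a constraint. The separate-chain requirement by itself excludes
hairpins and beta-barrels.

### Parameter choices that were genuinely open

**Curvature.** The exclusion of strongly curved "parallel" runs needs an
operational measure. We use the straightness ratio (end-to-end /
contour), which is 1 for a straight strand, ≈ 0.64 for a semicircle and
< 0.5 for an ideal alpha-helix C-alpha trace. The 0.9 default cleanly
separates extended strands (> 0.97 even at 0.3 Å coordinate noise) from
helical and arc decoys; it is exposed in `GeometryParams` because any
reproduction of published counts can be sensitive to it.

**Registration.** Only index-aligned pairings are enumerated by default
(offset 0 between residue indices), because in-register stacking is the
amyloid hallmark. `offsetScan = k` widens the scan to ±k index offsets for
structures whose chains carry extra terminal residues.

**Distance band and variance.** The band applies per position (every
distance in [2, 15] Å), not merely to the mean; the standard deviation
uses the population form (denominator L). Both conventions are recorded
here because the alternatives (band on the mean; sample sd) are defensible
and would change borderline windows.

**Coverage.** The denominator is the number of residues with a resolved
C-alpha in the parent chain, and the filter passes when *either* chain
satisfies it; `coverageBoth = TRUE` gives the stricter both-chain variant.
The boundary is inclusive: length 2 on a 14-residue chain (exactly 1/7)
passes.

**Chain breaks.** A gap in author numbering > 1 or a consecutive C-alpha
step above 4.5 Å terminates every run; residues without a C-alpha stay in
the derived sequence but cannot join a segment.

**Ties and ordering.** Output is sorted by (chain_a, start_a, chain_b,
start_b) with chain_a earlier in file order, so each physical pair appears
exactly once; ranking ties in count tables break lexicographically by
k-mer.

## Boundary k-mers and counting

A prefix exists only when two flank residues precede the segment with no
numbering break across the five positions, and all five letters are
standard residues; 5-mers containing `X` (unknown or unmapped residues)
are discarded rather than wildcarded, because the surveyed boundaries are
ordinary amino-acid 5-mers. Selenomethionine maps to `M` by default.

Counting is raw and uncorrected: the same 5-mer arising on both chains of
one pair, in several pairs, in several models, or in several (possibly
homologous) entries counts once per occurrence. No homology correction or
enrichment statistic is applied — such counts are informal by nature.
Because the published per-entry multiplicities do not say whether each
model of an NMR ensemble counts separately, both modes are computed: the
default counts every model, `firstModelOnly` restricts to model 1, and
`prefixSurveyReport` reports both side by side with a per-entry
breakdown.

Sequence search counts overlapping matches, is case-insensitive, and an
`X` in a target sequence never matches; hits carry entry/chain/position
provenance and an 11-residue context window.

## What the generator emulates — and what it does not

`generateParallelSheet` builds `nChains` copies of one sequence with the
planted strand as an ideal extended run (rise 3.4 Å per residue), chains
stacked perpendicular to the strand axis at 4.8 Å — the canonical
cross-beta inter-strand spacing — optionally twisted. Flanking residues
form a coil of fixed 3.8 Å virtual bonds whose directions are
perpendicular-to-slightly-folded-back relative to the strand axis and
rotate by 1.1 rad per step with golden-angle phasing per chain. This coil
design is deliberate: it guarantees that any window reaching even one
residue into the coil loses straightness decisively, so the planted
segment is the unique maximal detection, and neighbouring chains' coils
diverge instead of forming accidental strand pairs.

Coordinate noise is Gaussian with the requested per-coordinate marginal
sd, drawn once per model and *smoothed along the chain* (3-residue moving
average, rescaled). Real ensemble disorder is spatially correlated;
uncorrelated per-residue noise of 0.3 Å would occasionally stretch a
virtual C-alpha bond past the 4.5 Å break threshold, which no physical
fluctuation of that size does.

The decoys each violate exactly one constraint: a single-chain ideal
alpha-helix and a hairpin (separate-chain rule), two strands at 20 Å
(distance band), two long concentric arcs at constant 4.8 Å separation
(every window long enough for coverage is too curved — the arc turns
0.25 rad per residue over 61 residues, so windows of ≥ 9 residues turn
≥ 2 rad and fall below 0.9 straightness while shorter windows fail
coverage), and an anti-parallel two-strand sheet (direction). The
diagnostic `rejectionReason` examines direction before the distance
constraints, because under index registration an anti-parallel
arrangement violates the distance band as a side effect of its reversed
direction, and the orientation is the informative diagnosis.

What the generator does **not** emulate: side chains and steric zippers,
hydrogen-bonding geometry, real fibril polymorph mixtures within one
entry, alternate locations, missing density, or SEQRES/ATOM
discrepancies. Passing the planted-recovery and decoy tests therefore
shows the *detector logic* is correct under the stated geometry; it does
not show that any particular threshold matches the curation behaviour of
a specific published pipeline on deposited structures.

## Synthetic stand-ins for named reference entries

The worked examples of the boundary analysis concern specific deposited
entries (the amyloid-beta fibrils 2MPZ/2LMN/..., the p53 tetramerization
domain 1OLG/..., the cyanase crystals 1DW9/..., and the sequence-level
hits 1TCP and 2FIC). The package ships no coordinates for them; instead,
`standInSheetSpec` builds generator-based *stand-ins* keyed by those PDB
codes: synthetic in-register sheets whose chains carry the biologically
relevant sequence (amyloid-beta(1–40); the p53 tetramerization region)
with the strand planted at the documented boundary, e.g. L17 for the
QK|LVF boundary of the amyloid-beta fibrils. The TAP-like and BIN1-like
records of `standInSequenceCollection` are synthetic sequences carrying
the GGERA and HQKLV motifs. Tests and the acceptance script run the full
file-based pipeline on these stand-ins; checks against the deposited
coordinates themselves require the user to supply the files (any mix of
PDB/mmCIF paths works with `prefixSurveyReport`).

For the same reason, the published reference counts in
`referencePrefixCounts` (QKLVF 77, GEYFT 48, HHQKL 36, HQKLV 25, GGERA
106) are carried as comparison targets only; nothing in the package
claims to recompute them without the deposited inputs, and the survey
report marks absent reference entries as missing rather than guessing.
One spelling discrepancy in the published GGERA entry list (2Y42 vs 4Y42)
is accepted in either form during entry-list comparison.

## Numerical choices

* Window statistics use prefix sums over each contiguous stretch, with
  the distance profile centred on the stretch mean first to avoid
  catastrophic cancellation on near-constant profiles; the moments of
  *reported* pairs are recomputed two-pass, so an exactly rigid
  translation reports a distance sd of exactly 0.
* Degenerate direction vectors (zero end-to-end length) fail the
  direction test rather than dividing by zero.
* The straightness of a run whose contour length is 0 is defined as 0.
* Author ordering: residues sort by (author number, insertion code)
  within a chain; chains keep file order.
* Alternate locations resolve to the highest-occupancy conformer, ties by
  altloc identifier.

## Validation sizes

The test suite and the acceptance script validate, at fixed seeds: exact
agreement of `findParallelPairs` with a brute-force enumeration oracle on
200 random structures of up to 2 chains × 15 residues; 100 % recovery of
the planted boundary prefix on 50 noisy sheets (noise sd 0.3 Å, 2–3
chains); rejection of all five decoy classes with the intended
diagnostics; agreement of `searchKmer` with a naive scan on 1000 random
sequences; PDB round-trips at 10⁻³ Å; and reproduction of
construction-known counts and entry lists on an 18-entry stand-in corpus
under both model-counting modes. These sizes were chosen so the whole
suite exercises every code path many times while remaining quick to run
routinely.

## Known limitations

* Reproducing published per-entry multiplicity counts on the real
  PDB_Amyloid entries depends on the exact curvature measure and the
  NMR-model counting convention of the original curation pipeline, which
  are not fully specified; the survey report therefore shows per-entry
  breakdowns under both counting modes so discrepancies are attributable.
* Whole-PDB hit counts for a k-mer are not stable claims (the PDB grows
  daily); only presence in named entries is asserted.
* The mmCIF reader handles coordinate sections and the experiment method;
  exotic mmCIF dialects beyond `_atom_site`/`_exptl` are untested.
* Only C-alpha geometry is used; no all-atom or hydrogen-bond criteria.
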