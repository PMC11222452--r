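---
title: "Models and methods behind plastidkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plastidkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`plastidkit` reconstructs a complete comparative-plastome workflow: from
annotated circular genomes to a ranked list of phylogenetic markers that
best substitute for the whole plastome. This vignette explains the models
and conventions each stage uses, the tunable parameters that matter, what
the synthetic-data generator does and does not emulate, and the design
choices made where more than one defensible option existed.

## Coordinates and records

All internal coordinates are 0-based half-open; GenBank's 1-based
inclusive intervals are converted at the I/O boundary and converted back
on write. A feature may span the origin of the circular molecule, in
which case it is stored (and emitted) as a two-segment `join`. Only the
feature kinds the analyses consume are modelled: `gene`, `CDS`, `tRNA`,
`rRNA`, and `pseudogene` (a GenBank `gene` carrying `/pseudo`).
Pseudogenes are included in the gene and CDS tallies of
`feature_counts()`, matching the reporting convention of plastome feature
tables, and IR-duplicated loci count once per annotated occurrence.
Ambiguity codes other than the four bases are preserved on read but are
treated as missing data in every downstream statistic, whose definitions
(π, likelihoods) assume `{A,C,G,T}`.

When a locus is duplicated in the inverted repeats, `extract_locus()`
returns the copy with the smaller start coordinate by default
(`copies = "both"` returns both); the marker analyses treat a duplicated
gene as one marker.

## Quadripartite detection

`detect_quadripartite()` finds the inverted-repeat pair as the
maximal-length pair of disjoint reverse-complementary repeats. The search
seeds 25-mers of the doubled sequence (doubling handles repeats spanning
the origin) against its reverse complement; hits belonging to one repeat
pair fall on a single diagonal of that comparison, so maximal exact
repeats are maximal runs of consecutive seed positions per diagonal. With
`max_mismatch_frac = 0` (the default) the repeat is exact; a tolerant
mode chains near-adjacent runs on the same diagonal for real records
whose IRs differ by a few bases. The longer single-copy region is
labelled LSC, which is the universal plastome convention. The k-mer
length of 25 makes chance seed collisions negligible at the 20–160 kb
scale while keeping the scan linear.

`canonicalize()` rotates (and if necessary reflects) the genome to the
order LSC, IRb, SSC, IRa with position 0 at the first LSC base. Both
orientations admit that order; the lexicographically smaller canonical
sequence is chosen, which makes the result invariant to rotation and to
reverse complementation of the input and makes the function idempotent.

Junction positions are reported as the coordinate of the first base of
the downstream region, fixing the off-by-one convention: a gene ending
exactly at a junction has left-distance 0. `compare_junctions()` reports
each accession's IR length minus the set median, so lineage-specific
expansions and contractions appear as signed deltas in bp.

## Nucleotide diversity and identity profiles

`sliding_window_pi()` computes, per window, the mean over sequence pairs
of the per-site difference fraction, with the DnaSP-style defaults of a
600 bp window and 200 bp step. Windows are anchored in alignment columns
(as DnaSP anchors them), with reference coordinates carried along for
naming. Two gap policies are provided: complete deletion per window (the
default; columns containing any gap are dropped before computing π) and
pairwise deletion. Ambiguity codes are always missing per pair. The
estimator is the direct mean pairwise difference without an n/(n−1)
correction; the chosen policy is recorded in the profile object so a
profile is self-describing. A window with no usable columns yields `NA`
rather than 0.

Hotspots (`top_k_regions`) are grown greedily: windows are visited in
decreasing π; a window overlapping or abutting an existing region merges
into it (touching regions coalesce), otherwise it founds a new region,
until *k* regions exist. A region is *named after its peak window* — the
feature(s) the highest-π window overlaps, or `geneA-geneB` for a spacer —
so a hotspot centred on one locus keeps that locus's name even when
merging absorbs flanking windows.

The identity profile is an mVISTA-style percent-identity track computed
from a supplied alignment (window 100, step 40): gap-vs-base counts as a
mismatch, gap-vs-gap is skipped, and windows are labelled coding or
non-coding by the majority of their reference positions.

The size-variation test compares |length difference| over all
within-species accession pairs against all between-species pairs with a
Welch two-sample t-test, per region (whole, LSC, SSC, IR). The pairwise
|Δ| construction is this package's definition of the "variation" samples;
degenerate (zero-variance) inputs report p = 1 when the means agree.

Alignment computation is deliberately outside the package: profiles
consume alignments produced by an external MAFFT-compatible tool (a thin
`mafft` hook is used when extracted loci are unaligned) or exact
simulator truth. The package never aligns.

## Site rates and phylogenetic informativeness

Per-site rates come from one of two estimators, both normalized to mean 1
over all sites of a locus, with invariant sites at rate 0:

* `fitch_norm` (default): λ_i proportional to the Fitch parsimony step
  count of site i on the guide tree — fast and deterministic;
* `ml_jc`: λ_i maximizes the site's Jukes–Cantor pruning likelihood with
  all branch lengths scaled by λ_i — slower, closer to a full
  rates-from-ML workflow.

The guide tree is rescaled to unit maximum root-to-tip depth before
estimation, so rates are in substitutions per unit tree depth and time
axes are comparable across loci.

Per-site informativeness uses the quartet form
ρ(t; λ) = 16 λ² t e^(−4λt), which peaks at t = 1/(4λ); the constant 16
is immaterial to ranking. The *net* profile sums over sites, so longer
loci legitimately score higher — the quantity the marker pipeline
consumes. A locus's summary score is the trapezoid area of the net
profile on t ∈ [0, 1], i.e. integrated utility over the whole depth of
the reference tree; no single epoch is privileged. Because rates are
normalized within a locus, cross-locus ranking is driven by how many
sites vary and how their rates are distributed, which is exactly what the
integral rewards.

A practical note on per-site ML rates: resolving rates site-by-site
requires substantial divergence. The parameter-recovery check in the test
suite therefore uses a deep tree (0.8 expected substitutions per site
root-to-tip) and strong heterogeneity (gamma shape 0.5); at shallow
plastome-like divergence most sites carry 0–1 changes and per-site
estimates are dominated by Poisson noise, although locus-level mean rates
remain accurately ranked.

## Trees and tree distances

Distances (p, JC69, K2P) use pairwise deletion; a saturated Jukes–Cantor
pair (p ≥ 3/4) is an error by default rather than a silent cap, because
capped distances quietly distort neighbor joining (a cap mode exists for
exploratory use). Neighbor joining and tree containers come from `ape`,
with negative branch lengths clamped to zero.

`log_likelihood()` is a self-contained Felsenstein pruning implementation
under GTR with 4 equal-probability discrete-gamma categories
(mean-of-bin rates, the standard convention); gaps and ambiguities are
missing data. It exists to make the likelihood auditable — the test suite
checks it against the two-taxon closed form and against brute-force
summation over internal states — and to power per-site work. The tree
*search* (`optimize_tree`) delegates to `phangorn::optim.pml`
(GTR+Γ, NNI rearrangements, branch-length and model optimization),
the same practitioner engine class as the RAxML runs this kind of study
uses; the two implementations agree on the returned model to numerical
precision.

`bootstrap_consensus()` resamples alignment columns, infers one tree per
replicate (NJ replicates by default; full ML optionally), and keeps the
splits present in more than the threshold fraction (default 50%),
annotated with percentage support.

Robinson–Foulds distances are computed after pruning both trees to their
shared tip set, mirroring per-locus accession exclusion. The generalized
distance pairs the two trees' splits by maximum-weight bipartite matching
(Hungarian algorithm) where a pair's weight is the mutual clustering
information, in bits, of the two bipartitions; the distance is
1 − 2S/(H₁+H₂) with S the matching score and H the summed clustering
entropies. This is the clustering-information variant of the
generalized-RF family; other variants (matching-split,
phylogenetic-information) weight partial agreement differently, so
numerical values are comparable only within one variant.

## The marker-selection pipeline

`run_pipeline()` chains: whole-plastome alignment → reference ML tree and
bootstrap majority-rule consensus → interspecific π profile → top-5
hotspot regions → per-CDS site rates and net PI → top-10 loci → candidate
union (duplicates tagged `both`) → per-candidate tree and generalized-RF
congruence → exhaustive combination search (all 2³−1 subsets of the top
3). Design choices that were genuinely open:

* **Congruence is scored against the bootstrap consensus**, not the fully
  resolved ML tree, whenever bootstrapping is enabled. Splits without
  majority support are simply absent from the reference, so candidate
  loci are not rewarded or punished for agreeing with arbitrarily
  resolved edges; the split-based distances handle the resulting
  polytomies natively.
* **Per-locus trees are the single best tree** per locus set by default
  (`locus_tree = "consensus"` switches to each set's own bootstrap
  consensus).
* **Multi-locus concatenation is intersection-of-accessions**: an
  accession must carry every locus in the set; excluded accessions are
  listed in the evaluation object.
* **Ties**: equally congruent single loci are ordered by their candidate
  evidence (best rank across the diversity and informativeness sources),
  then by name — if two markers are indistinguishable on congruence, the
  more informative one is preferred. Combination-search ties prefer fewer
  loci, then alphabetical order.
* Intergenic hotspot candidates are extracted in intergenic mode (the
  sequence strictly between the flanking features); coding candidates in
  feature mode.

All stochastic steps (bootstrap, any tree-search randomness) run under
the configuration seed; two runs with the same inputs and seed produce
identical reports.

## The synthetic-data generator

`simulate_dataset()` emulates the phenomena the analyses measure:

* a pure-birth species tree rescaled to unit depth, with accession-level
  "star" tips grafted at 3% of depth, so intraspecific divergence is far
  below interspecific divergence;
* HKY+Γ substitutions (κ = 2, AT-rich frequencies A=T=0.325, C=G=0.175,
  gamma shape 1 over 4 discrete categories), simulated per rate category
  so true per-site rates are known exactly;
* per-locus rate multipliers — intergenic spacers and pseudogenes at 3×,
  coding loci at 1×, and `rpoB` planted at 5× in the default scenario —
  over a ~27 kb toy genome template (a realistic ~159 kb template is also
  provided) whose locus inventory echoes real plastomes;
* a tree-depth scale of 0.008 substitutions/site at multiplier 1, which
  puts genome-wide interspecific π near 0.02, the magnitude real
  congeneric plastome comparisons show;
* intergenic deletions (events on branches at 0.0015 per bp per unit
  depth, geometric lengths of mean 3 bp, inherited by descendants), the
  mechanism behind inter- vs intra-specific size variation; insertions
  are not modelled, which keeps the true multiple alignment exact (root
  coordinates with gap masks) and alignment an *input* everywhere;
* lineage-specific IR junction shifts at the LSC/IRb and IRb/SSC borders
  (the default scenario contracts and expands the IR in four species by
  180–300 bp), implemented as boundary moves that keep the two IRs
  identical — the IRa-side borders mirror automatically, and only the
  IRa copy of the sequence changes, which also keeps the single-copy +
  IRb alignment truth exact under shifts.

Two deliberate idealizations, and what they mean for the tests: the IRs
evolve as one locus and are copied (the strongest form of concerted
evolution), so IR identity is exact rather than near-exact as in real
records (the tolerant detection mode covers the latter); and species
trees are conditioned, by rejection sampling, on a minimum edge length of
5% of depth. Without that conditioning a pure-birth draw routinely
contains near-zero edges — internal splits no locus (nor the
whole-genome tree) can resolve, and near-simultaneous speciations that
erase the inter/intra-specific contrast — and recovery experiments on
such draws measure luck rather than method. Passing tests therefore show
the pipeline recovers *recoverable* structure; they do not claim real
data are free of unresolvable edges.

The generator also guarantees that the constructed IR pair is the
*maximal* reverse-complement repeat: if the single-copy base flanking a
boundary happens to complement its partner across the junction, one base
is adjusted (mirrored into the truth alignment), so structural detection
can be compared with the construction exactly.

The whole-genome alignment truth covers LSC + IRb + SSC — one IR copy,
the standard convention in plastome phylogenetics, and the portion of the
genome that junction events leave untouched.

## Problem sizes used by the checks

The reference scenario is 6 species × 2 accessions (12 taxa) on the toy
template; structural recovery is checked on ~100 simulated genomes under
random rotations and reflections; junction recovery on 20 datasets with
planted ±200–800 bp shifts; π against brute-force recomputation on 50
random alignments; tree distances against exhaustive oracles on all
unrooted 5-leaf topology pairs plus 200 random pairs; rate recovery on
10 loci × 2000 sites × 12 taxa; and marker recovery over 20 seeded
pipeline runs with 25 bootstrap replicates each. These sizes were chosen
as the smallest at which each property is sharply testable.

## Known limitations

* GenBank parsing covers the feature-table subset the analyses need
  (gene/CDS/tRNA/rRNA, `complement`, `join`, `/pseudo`); exotic location
  operators (`order`, nested per-segment `complement`) are not parsed.
* The generalized-RF values are specific to the clustering-information
  variant and should not be compared numerically against other variants.
* Per-site ML rate estimation assumes the guide tree; rate estimates at
  very shallow divergence are noisy site-by-site (locus-level means
  remain reliable).
* The simulator does not model codon structure, insertions,
  recombination, heteroplasmy, or partial IR loss.
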