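---
title: "Evolutionary feature profiling of gene families: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary feature profiling of gene families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(evoprofiler)
```

This vignette documents the models, conventions and numerical choices
behind `evoprofiler`, the assumptions of the synthetic-data generators,
and the limitations of what a green test establishes. It states no
empirical result that the test suite and acceptance script do not
themselves compute.

## Units of analysis

The orthologous group (OG) — all genes descended from a single ancestral
gene in the last common ancestor of the species set — is the unit over
which all metrics are computed. A gene family is a cataloged set of
genes; an OG belongs to a family when it contains at least one cataloged
member, so an OG may belong to several families. Missing metric values
are always `NA`: aggregation and clustering exclude them, they are never
absorbed as zeros.

## The 18 metrics

**Taxonomic spread.** AGE is the age (My) of the most recent common
ancestor of the species present, read off the ultrametric species tree
(leaves must sit at age 0 within a relative tolerance of 1e-6; a
non-ultrametric tree triggers a warning and ages are measured from the
deepest tip). A single-species OG is assigned AGE 0 — a degenerate case,
since OGs are normally defined at an ancestor of at least two species.
UNI is the fraction of the total species set present.

**Copy number.** DUP is the fraction of *present* species with ≥ 2
copies; ACN the mean copy count over present species (absent species are
excluded, not zero-filled); CNV the standard deviation of those counts
divided by ACN. The sample standard deviation (n − 1) is the default,
matching the convention of the statistical environment; population sd is
available via `sd_type`. A single-species OG has sd 0, hence CNV 0.

**Turnover (EXP/CON/STA).** When no external turnover report is
supplied, ancestral copy numbers are reconstructed by Wagner parsimony:
a Sankoff dynamic program over integer states 0..`max_count` with cost
|i − j| per branch. `max_count` defaults to the maximum leaf count + 2,
allowing ancestral overshoot. Species absent from the OG enter with
count 0 — loss is observable. Among tied minimal-cost assignments the
*smallest* state is chosen at every node (root first, then top-down),
which makes the reconstruction deterministic; note this prefers a later
gain over an earlier presence-plus-loss when both cost the same.
EXP/CON/STA are the fractions of all edges of the rooted tree labeled
gain/loss/stable by the sign of (child − parent); they always sum to 1.
An `internal_only` variant is provided because it is ambiguous whether
the original analysis counted tip branches. This parsimony substitute
replaces a birth–death likelihood model: it has no rate parameters, and
equal-cost gain/loss. Parsed report files take precedence when supplied.

**Synteny (SYN).** For each ordered pair (gene g in species s, species
s′ containing ≥ 1 ortholog of g), the pair is maintained when the OG set
of g's flanking genes (window of 1 gene per side by default) intersects
the flank OG set of at least one ortholog in s′. SYN = maintained /
evaluated pairs; genes without flanks (singleton scaffolds), and pairs
whose target species has no flanked ortholog, leave the denominator.
Neighbors not assigned to any OG are unmatchable. A per-gene variant
(maintained in ≥ 1 other species) is available by flag. The window width
is a design choice — the source analysis says only "orthologous
neighbors" — and is configurable.

**Protein divergence (EVR).** The orthology database's internal
evolutionary-rate computation is not printed anywhere we can follow, so
EVR is operationalized as a background-normalized divergence ratio: the
mean over present species pairs of (100 − mean OG member identity) /
(100 − background identity), skipping pairs with background identity
100. Identities are consumed as tables, never computed from sequence.

**Codon substitution (PDS/PDN/SEL).** Maximum-likelihood codon models
are out of scope; the built-in substitute is Nei–Gojobori (1986)
counting. Synonymous site counts per codon are the per-position
fractions of non-stop single-nucleotide changes that are synonymous,
summed over the three positions and averaged over the two sequences.
Codons with gaps, N, or a stop in either sequence are skipped pairwise.
Multi-nucleotide codon differences are averaged over all substitution
pathways (orderings of the changed positions) with equal weight,
excluding pathways through stop codons; if *every* pathway is blocked
the codon pair is treated as non-comparable, a case we have not observed
for sense–sense pairs. Proportions are Jukes–Cantor corrected,
d = −(3/4) ln(1 − (4/3)p), undefined for p ≥ 3/4 (this is why a
single-codon example with one synonymous difference has dS missing: one
difference over a third of a site saturates the correction). Per OG, PDS
and PDN are unweighted means of the defined pairwise distances and
SEL = PDN/PDS (missing when PDS = 0). A likelihood run would instead
produce one tree-wide value; the averaging difference is the price of
the desk-scale substitute. Parsed M0 output takes precedence.

**Variation (NSP/NSD/SSD) and alignment (WGA/PHC).** Per gene:
NSP = nonsyn/(syn + nonsyn) coding SNPs (missing when the gene has no
coding SNPs), NSD and SSD are counts per CDS nucleotide. WGA and PHC are
length-weighted means of per-nucleotide track values over the union of
CDS intervals; positions without track coverage take the track's default
(0, the bedGraph sparsity convention). Strand is recorded but ignored —
per-nucleotide averages are strand-symmetric. Gene models use GFF3
1-based inclusive coordinates, tracks 0-based half-open; the conversion
lives in one place (`data_model_io`). Per-OG values are unweighted means
over member genes with defined values; when the underlying data come
from a single reference species, `focal_species` restricts the averaged
genes accordingly.

## Family profiles and significance

For family F and metric x, Δx̄ = aggregate(F's OGs) −
aggregate(complement), where the OG universe is the union of all
families' OG sets. Two complement conventions exist: the default
`"exclusive"` (universe minus F's own OGs, i.e. "all other OGs that
contain an immune gene") and `"inclusive"` (the union of the *other*
families' OG sets, in which OGs shared between families also appear).
Both the mean (headline profiles) and the median (clustering input) are
always computed. Scaled deltas divide by the per-metric max |Δx̄|, so
the most deviant family is ±1; an all-zero metric scales to zeros.

Significance per family/metric: a two-sided Wilcoxon rank-sum test of
the family's OG values against the complement, and a permutation test
that redraws size-matched sets without replacement from the pooled
values. The permutation p is the plain b/m count of |Δ_perm| ≥ |Δ_obs|
(two-sided on |Δ| — profile deltas are signed in both directions; the
strictly one-sided "greater" reading is available by flag, as is a
(b + 1)/(m + 1) correction, both off by default to match the stated
counting). Stars report min(p_wilcoxon, p_perm): \*\*\* ≤ 0.01,
\*\* ≤ 0.05, \* ≤ 0.1. No multiple-testing correction is applied across
the families × metrics grid, by design. Default n_perm is 10,000; every
permutation draw is seeded and the seed recorded.

## Clustering and support

Metric columns are z-scaled (sample sd; constant columns become zeros
with a warning). Distances between family rows: 1 − r for Pearson,
Spearman or Kendall correlation across metrics, or Euclidean. Rows with
fewer than three defined metrics are rejected for correlation distances.
A zero-variance row has undefined correlation and is assigned the
neutral distance 1 — this matters only in degenerate bootstrap resamples
that draw near-constant column multisets.

Agglomeration is an in-package Lance–Williams implementation (single,
complete, average, median linkage; median operates on squared distances
with heights reported back on the original scale, and may produce
inversions, which are flagged). Ties in the minimal distance are broken
by the lexicographically smallest pair of cluster labels, making every
dendrogram deterministic. The implementation is validated against
`stats::hclust` and an independent naive O(n³) oracle in the tests.

**Multiscale bootstrap AU.** The resampling unit is the metric column —
the observations defining the family distances. At each scale
r ∈ {0.5, …, 1.4}, round(r·m) columns are drawn with replacement,
families are reclustered, and clade presence is recorded; BP is the raw
proportion at r = 1. AU comes from a weighted least-squares fit of
qnorm(1 − BP(r)) against (√r, 1/√r), giving signed distance v and
curvature c, with AU = 1 − Φ(v − c) and weights B·φ(z)²/(BP(1 − BP)).
Scales where the clade appears in no or in every replicate carry no
probit information and would flatten the fit (we measured AU ≈ 0.88 for
a clade present in ≥ 99.6% of replicates at every scale when such points
were clamped into the fit), so degenerate scales are excluded; when
fewer than two informative scales remain, proportions are clamped to
[1/(2B), 1 − 1/(2B)] and all scales are used, flagged `"clamped"`.
Clades present in every replicate at every scale (or none) are clamped
to AU 1 (or 0) and flagged. The nominal 10,000 replicates per
distance–linkage combination are interpreted as 1,000 per scale × 10
scales; both counts are configurable.

**Subtree co-occurrence.** In each replicate tree, two families co-occur
when one belongs to the other's minimal non-singleton clade (the leaf
set of the other's parent node). Counts accumulate over all replicates
of all 16 combinations and are Dice-normalized:
2·C(F1,F2) / (C(F1,·) + C(F2,·)). A pair that is sister in every
replicate — and whose cherry never absorbs a lone leaf — scores 1; a
pair never sharing a minimal clade scores 0. Alternative membership
readings were considered (any shared clade below the root; same cluster
at a k-cut) and rejected because they cannot reach both quoted extremes.

PCA of the family × metric matrix is a thin `stats::prcomp` wrapper
returning loadings, scores and variance fractions.

## Expression similarity

On a clustered expression map (R × C grid, toroidal), a family occupies
the cells holding ≥ 1 member; at supercell resolution it occupies every
center whose 3 × 3 toroidal block contains a member (one supercell per
cell). Similarity of two families is |A ∩ B| / |A ∪ B| over occupied
units. Significance: gene-to-cell assignments are shuffled as a random
bijection onto the fixed multiset of cell slots — preserving every cell
size and family size — and p is the strict count of permutation scores
greater than the observed, divided by n_perm (≥ and add-one variants by
flag). Because the score distribution is discrete, the strict count is
mildly anti-conservative when ties sit at the rejection threshold; the
calibration test quantifies this. Module-resolution scoring reuses the
same machinery with coexpression modules as units; declaring every cell
a module reproduces the cell-resolution result exactly, which the tests
assert. The lightweight module builder (hierarchical clustering of
1 − Pearson on gene expression rows, cut at k or height h, constant
genes set aside as "unclustered") is a deliberately simple substitute
for weighted correlation network analysis; externally built partitions
can be supplied instead. The real map's grid dimensions are not public;
the synthetic default is 30 × 30.

## Synthetic data: what it emulates, and what it does not

Every generator is deterministic given a seed and carries a truth
record. Copy numbers evolve by a continuous-time gain/loss process
(total rate (λ+μ)k, gain probability λ/(λ+μ), absorbing at 0); extinct
OGs are dropped with a count, since real OGs are defined by extant
members. Codon alignments evolve on a star tree from a stop-free
ancestor, with Poisson single-nucleotide proposals accepted always if
synonymous, with probability ω if nonsynonymous, never if
stop-producing — sufficient for NG86 recovery, while making no claim
about tree-shaped covariance. Gene orders start from a shared ancestral
order and apply per-species single-gene translocations; SNP counts are
Poisson at declared per-nucleotide rates; tracks are piecewise constant;
the expression map places background genes uniformly and planted family
pairs into a small shared cell subset with mixing parameter ρ.

Defaults were chosen once as desk-scale stand-ins for the source data's
regime (e.g. 30 × 30 expression grid; SNP rates 0.02/0.005 per nt giving
an expected nonsynonymous proportion of 0.2; calibration nulls on a
10 × 10 grid with two 15-gene families among 300 mapped genes, dense
enough that the Jaccard null has usable resolution). Green tests
therefore establish that the estimators recover *these* generative
processes — not that real orthology, alignments, or expression maps obey
them. In particular: the zero-rearrangement identity SYN = 1 holds only
when gene content is constant across species (differential loss alone
changes neighbors); and NG86 under the star-tree generator estimates ω
well at moderate divergence but inherits NG86's known biases at high
divergence.

## Numerical choices and degenerate inputs

- Ultrametricity tolerance 1e-6 relative; beyond it, warn and proceed.
- JC correction undefined at p ≥ 0.75 → distance missing, never Inf.
- Readers reject out-of-range or duplicated records rather than coerce.
- Permutation p-values are plain b/m by default; the b/m estimator can
  return 0, which is reported as printed, not floored.
- All tabular outputs are TSV with headers and deterministic column
  order (metrics in the canonical 18-column order).
- Pipeline stages never mutate inputs and every output directory gets a
  run log with seeds and replicate counts.

## Known limitations

Wagner parsimony has no rate model, so gain/loss proportions are
parsimony counts, not rate estimates; NG86 averages pairwise estimates
where a likelihood model would fit one tree-wide value; EVR is a
documented substitute for an unpublished internal computation; the
module builder is not a weighted correlation network; and the bootstrap
AU fit uses the standard two-parameter (signed distance, curvature)
approximation without higher-order corrections.
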