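---
title: "Methods: TCR-alpha repertoire diversity, overlap and motif clustering"
author: "tcrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TCR-alpha repertoire diversity, overlap and motif clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrep)
```

## Scope and data model

`tcrep` analyses UMI-corrected TCR-alpha clonotype tables from
multi-challenge, multi-tissue mouse studies of effector regulatory (eTreg)
and conventional effector (eCD4) CD4+ T cells. The unit of observation is a
*clonotype*: a unique receptor variant keyed by V segment plus CDR3
sequence (nucleotide or amino-acid level), carrying a UMI count — each
UMI-labelled cDNA counts one mRNA molecule — and a frequency recomputed as
count over the sample total. A *repertoire* is one sample's clonotype
table plus annotation (mouse, tissue, subset, challenge); a *cohort* is a
set of repertoires plus the study design.

Two clonotype-matching conventions are used, mirroring how the analyses
are defined:

* amino-acid level: (V gene, CDR3 amino acids) — used by diversity-style
  aggregation and the amino-acid overlap analyses;
* nucleotide level: (V gene, J gene, CDR3 nucleotides) — used by the
  conversion analysis, where only an identical rearrangement is evidence
  of a shared clone.

The asymmetry (J only at the nucleotide level) follows the analysis
definitions as stated; segment names are always matched at the gene level
with allele suffixes (`*01`) stripped. Upstream read processing (UMI
consensus, V/J alignment) is out of scope: the package consumes
already-assembled clonotype tables.

## Diversity

Depth confounds every richness and evenness estimate, so all diversity
metrics are computed on a fixed number of molecules: each sample is
downsampled to `depth = 1000` UMI-labelled molecules drawn *without
replacement* (multivariate hypergeometric — the draw models picking
physical cDNA molecules, not resampling frequencies), and samples with
fewer than `min_umi = 700` UMIs are excluded outright. Samples between
700 and 1000 UMIs are used at full depth. Three metrics are reported:

* observed diversity: the number of distinct clonotypes;
* Chao1 (bias-corrected): `S_obs + n1 (n1 - 1) / (2 (n2 + 1))` with `n1`
  singletons and `n2` doubletons — a lower bound on total richness driven
  by the representation of small clonotypes. The bias-corrected form is
  chosen because it remains defined at `n2 = 0` and always dominates
  `S_obs`;
* normalised Shannon-Wiener index: `H / ln S_obs` with
  `H = -sum p_i ln p_i` — repertoire evenness, 1 for a perfectly even
  repertoire and 0 by contract for a single clonotype. Natural logarithms
  normalised by `ln S_obs` are the only choice that makes the uniform case
  exactly 1.

Whether metrics should be averaged over repeated downsamples is exposed as
`n_resamples` (default 1, the common single-draw practice); whether they
are computed on nucleotide- or amino-acid-level clonotypes is exposed as
`level` (default `"nt"`, the resolution at which tables are extracted).
Group effects are tested with Welch's unequal-variance t-test of each
challenge against control — "parametric t-test" leaves the variant open
and Welch is the safer default — annotated with the conventional star bins
(`*` p<0.05 to `****` p<0.0001).

## Overlap (F2)

Pairwise repertoire similarity is the frequency-weighted overlap

```
F2(A, B) = sum over shared keys of sqrt(p_i * q_i)
```

the clonotype-wise sum of geometric mean frequencies, which reads as the
proportion of shared T cells between the paired repertoires. Before
computing F2, each repertoire is reduced to its `top_n = 1000` largest
clonotypes; samples with fewer than 700 clonotypes are excluded. Top-N
selection first shuffles rows with a seeded RNG and then stably sorts by
descending count, so the plentiful count-1 and count-2 clonotypes are not
selected in alphabetical order. Frequencies are renormalised within the
selection, which makes `F2(A, A) = 1` exactly; computing on the reduced,
renormalised cloneset is the interpretation adopted where the convention
was not pinned down, and it is what makes the identity case exact.

Downstream geometry uses `d = 1 - F2`: bounded, monotone and zero for
identical samples (the specific transform behind the published MDS plots
is not stated; this is the simplest map with those properties). Embeddings
use classical metric MDS (`stats::cmdscale`; deterministic) with Sammon
mapping as an option; dendrograms use average linkage (UPGMA), the common
convention for repertoire trees, serialised as newick with branch lengths.

## CDR3 motif clusters

Convergent responses appear as clusters of homologous CDR3s. The pooled
unique amino-acid CDR3s form a graph whose edges connect sequences of
equal length differing by exactly one substitution (Hamming distance 1 —
substitution only, so clusters are always length-homogeneous).
Construction uses per-position mask hashing within length buckets, which
is near-linear and verified in the tests against an all-pairs oracle.

A CDR3 is *selected* when it has more sample neighbors than expected under
the recombination null. The expectation is estimated from a baseline pool
of random V(D)J rearrangements: `expected = (neighbors of the CDR3 within
the baseline) x (|sample| / |baseline|)`. Selection tests the observed
degree with an upper-tail Poisson test at rate `max(expected,
1/|baseline|)` — the floor avoids degenerate zero-rate p-values — followed
by Benjamini-Hochberg correction at `alpha = 0.05` and an `observed >= 1`
requirement. The Poisson form, the BH correction and the threshold are
package choices (the published pipeline names only the selection
principle); they are validated by simulation: on cohorts drawn purely from
the null the selected fraction stays below `alpha` in at least 95% of
replicates, and planted motifs at realistic frequencies are recovered with
member-set Jaccard above 0.7.

Clusters are the connected components of the selected subgraph; singletons
are discarded and ids are assigned deterministically (size, then
lexicographically smallest member — published cluster numbers such as
"408" are arbitrary labels and are not reproduced). Each cluster yields a
per-sample frequency (total frequency of member CDR3s in that sample; the
matrix is ordered by average-linkage clustering of Euclidean distances on
`log10(freq + 1e-5)`) and a position weight matrix: residue-by-position
proportions weighted by pooled clonotype frequency, columns summing to 1,
with the argmax consensus — the standard input for logo renderers.
Cluster membership is defined on the CDR3 sequence alone (no V-segment
agreement requirement), following the clustering definition as stated.

## Conversion and iNKT

Clonal eCD4→eTreg conversion is read from matched pairs: for each mouse
and tissue with both subsets, the two repertoires are reduced to their
top-100 nucleotide clonotypes (samples under 100 clonotypes excluded) and
overlapped at the nucleotide level. Sharing of identical rearrangements
between subsets of the same animal is reported as the F2 statistic itself,
not as a directional rate — direction is a biological inference, not a
computational one. Challenge groups are tested against control separately
per tissue, so the challenge-site and spleen contrasts sit side by side.
As a calibration utility the test suite also re-pairs subsets across mice,
giving a permutation null for what matched-pair sharing looks like in the
absence of conversion.

The invariant NKT fraction is the summed frequency of clonotypes matching
TRAV11 + CVVGDRGSALGRLHF + TRAJ18 exactly (any nucleotide variant); it is
invariant under amino-acid aggregation and nucleotide-variant splitting.

## The synthetic cohort generator

Every downstream stage is validated on synthetic cohorts with known
ground truth; the generator is first-class, tested code.

*Recombination model.* Nucleotide CDR3s are built as V-segment 3' tail
(starting at the conserved Cys codon) + N-region + J-segment 5' head
(ending at the conserved Phe codon), with per-side trimming that never
removes the conserved codons, and rejection of out-of-frame or
stop-containing products. The packaged default is a synthetic mouse-style
locus — 24 TRAV and 22 TRAJ segments with deterministic germline
tails/heads, uniform usage — so no external germline download is needed
while the literal TRAV11/TRAJ18 genes exist for the iNKT clonotype.
Insertion lengths are uniform on 0..11 nt: all residue classes modulo 3
are equally likely, so exactly one third of raw rearrangements are
in-frame in expectation, a property the tests check by brute-force
counting. Trimming probabilities decay from 0.30 at zero to 0.02 at six
nucleotides; inserted bases are mildly GC-biased (0.28/0.22), typical of
N-regions.

*Cohorts.* The design grid is challenges x mice (3-7 per group) x tissues
x subsets. Per-sample depths are log-normal with medians 1360 (eTreg) and
3740 (eCD4) UMIs — the printed per-sample orders of magnitude scaled down
tenfold, a desk-scale choice; background clone sizes follow a discrete
power law with exponent 2 (truncated at sample depth), which produces the
strong clonal skew the diversity metrics must detect — no specific
distribution is prescribed by the study, and exponent 2 is the common
repertoire regime. Planted structure:

* *challenge motifs*: a consensus CDR3 with per-position alternative
  residues; every mouse of the challenge carries the same amino-acid
  members, but each (mouse, subset) realises them with its own
  synonymous-codon back-translation — convergent recombination made
  explicit (identical amino acids, distinct nucleotides), so amino-acid
  motif sharing never masquerades as the nucleotide-identical sharing
  that defines conversion;
* *tissue-resident motifs*: the same construction keyed to a tissue,
  injected across all challenges;
* *conversion*: identical (V, J, nucleotide CDR3) clonotypes injected
  into both subsets of the same mouse at the designated challenge and
  tissue only;
* *iNKT*: the literal TRAV11-CVVGDRGSALGRLHF-TRAJ18 clonotype with
  binomial sampling noise.

A cohort is a deterministic function of its design, including the seed;
identical designs serialise byte-identically.

What the generator does *not* emulate: thymic selection and real germline
sequences, realistic V/J usage skews, sequencing error, cross-reactive
background sharing beyond what the small synthetic locus induces, and
TCR-beta. The demo design also plants the same amino-acid challenge
motifs in both subsets — a simplification: in real data the two subsets
mount largely distinct responses outside the tumour challenges. Passing tests therefore demonstrate that the statistical
machinery behaves as specified under controlled conditions — level
control, planted-signal recovery, threshold contracts — not that any
biological conclusion transfers to real data.

## Numerical and engineering choices

* Clonotype tables are stored sorted by descending count with C-locale
  lexicographic CDR3 tie-break, so files round-trip byte-identically;
  analytical tie-breaking for top-N selection is random by design and
  separately seeded.
* Degenerate inputs: empty repertoires are readable objects but refuse
  diversity metrics and serialisation; a repertoire shallower than the
  requested depth raises on direct calls and is marked excluded inside
  pipelines; single-clonotype repertoires define `shannon_norm = 0`;
  degenerate recombination models (only stops) error after 1e6
  consecutive rejections.
* Rows violating the in-frame invariant (`3 x aa length != nt length`,
  stop symbols, zero counts) are dropped on read with a counted warning.
* The full pipeline (`run_pipeline()`) is driven by one seed; stages
  consume the RNG in a fixed order, so re-runs are reproducible
  checksum-for-checksum.

## Problem sizes used in the test suite

The suite exercises the pipeline at desk scale: cohorts of 3-6 groups x
3-4 mice with per-sample depths of roughly 300-1500 UMIs, baselines of
2e4 rearrangements, 100-replicate null calibrations and 20-seed
specificity sweeps. These sizes were chosen as the smallest at which the
planted effects are comfortably detectable by construction; the same code
paths run unchanged at the published scale (hundreds of samples, 1e4-1e5
UMIs per sample).

## Known limitations

* The synthetic locus is a stand-in: absolute diversity values and
  baseline sharing rates are not calibrated to real mouse TRA data.
* The enrichment null assumes neighbor counts are Poisson under random
  rearrangement; heavy convergence in very small synthetic loci can make
  the null conservative.
* Amino-acid-level exclusion thresholds are applied at the analysis level
  (after aggregation), one of two defensible readings of the exclusion
  rule.
* No indel (Levenshtein) neighborhoods, no unweighted overlap metrics,
  no specificity prediction.
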