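---
title: "Methods: multi-pool ED scans, marker diversity, trees and introgression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-pool ED scans, marker diversity, trees and introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcampr)
```

# Overview

`pcampr` implements the computational core of a bulked-segregant mapping and
population-genetics workflow for structured plant populations such as wild
rice: a pair-wise comparison analysis for multiple pool-seq (PCAMP) that
scans for trait-associated genomic regions between phenotype bulks, and the
marker-based side of the same study design — per-locus diversity statistics,
Nei's standard genetic distance with UPGMA clustering, minimum-spanning
haplotype networks, and ABBA-BABA introgression tests. A set of synthetic
generators emulates each input so the whole pipeline can be exercised and
validated at desk scale.

# The PCAMP model

## Per-site statistic

Two DNA bulks are compared site by site through the Euclidean distance
between their base-frequency vectors,

$$\mathrm{ED} = \sqrt{(A_1-A_2)^2 + (C_1-C_2)^2 + (G_1-G_2)^2 + (T_1-T_2)^2},$$

where $A_i, \dots, T_i$ are the frequencies of reads supporting each base in
pool $i$ at the site. ED is symmetric, zero iff the pools agree, and at most
$\sqrt 2$ (opposite fixation). A site where either pool has zero read depth
has no defined frequency vector and is excluded from that comparison rather
than scored zero — zero would assert agreement the data cannot show.

InDel alleles cannot occupy literal base slots, so biallelic InDel sites map
REF to slot 1 and ALT to slot 2 of the 4-vector, leaving the formula — and
its $\sqrt 2$ geometry — unchanged. SNPs and InDels are analysed as separate
association scans throughout.

## Noise suppression, smoothing, threshold

Raw ED at a null site is dominated by binomial sampling noise of order
$1/\sqrt{\mathrm{depth}}$. Raising ED to the 5th power (`ed_power`, `power =
5`) shrinks that noise floor towards zero while leaving near-maximal signals
large. The powered values are then smoothed along each chromosome by
tricube distance-weighted local averaging (`fit_ed_profile`): a site at
physical distance $d$ from the focal site gets weight
$(1-(d/w)^3)^3$ for $d < w$ and zero otherwise. The window $w$ defaults to
1 Mb — the scale of the candidate intervals this class of scan reports
(a few hundred kb to ~1 Mb); it is the main tunable and should shrink for
denser designs. The smoother is linear and preserves constants; a moving
median is available (`method = "median"`) for heavy-tailed profiles.

The significance threshold is the genome-wide median of the fitted values
plus three standard deviations (`ed_threshold`). The SD uses the population
(n-denominator) form: at genome-wide site counts the n/(n−1) distinction is
far below numerical relevance, and the simpler definition is exactly
reproducible. The threshold is computed per comparison and per variant
class, genome-wide rather than per chromosome, because the null noise level
is a property of pool depth and pool size, not of the chromosome. Sites
qualify only strictly above the threshold; runs of qualifying sites closer
than `merge_gap_bp` (default 100 kb) merge into one candidate interval.

## Multi-pool orchestration

With $k$ pools, `run_pcamp` runs all $\binom k2$ unordered comparisons. In
each comparison the SNP and InDel scans are intersected — a region supported
by only one variant class is treated as unconfirmed. Across comparisons the
merged regions are annotated with a recurrence count, and regions recurring
in at least `min_recurrence` (default 2) comparisons are flagged final
candidates. The intersection-within, recurrence-across structure reflects
that each pair shares the same causal locus if the two phenotypes straddle
it, so a real locus should reappear in several pairs.

# Synthetic pool-seq: what it emulates

`simulate_pool_seq` generates the minimal sufficient structure the ED scan
can see: per-pool allele frequencies and reads. Site frequencies are drawn
from a symmetric Beta(0.5, 0.5) spectrum (a resequencing-like U-shaped SFS).
Inside a causal region the two contrasted pools' target frequencies are
displaced by ±effect/2 (clipped to [0, 1]); each pool then samples its
2 × 30 allele copies binomially (finite-bulk sampling), read depth is
Poisson with mean 48.5, and alt-supporting reads are binomial in the pool
frequency. Defaults — four pools of 30 individuals, ~48.5× depth, 5 000
sites on a 25-Mb chromosome with one 1-Mb planted region of effect 0.8 and
25% InDel sites — mirror a four-bulk field design at desk scale.

What it does **not** emulate: linkage disequilibrium decay around the causal
locus (displacement is uniform inside the region and absent outside, rather
than decaying), mapping and calling artefacts, depth heterogeneity between
bulks, and polygenic architecture. Passing the recovery tests therefore
shows the scan machinery is correct and well calibrated under its own model,
not that any particular real dataset will yield the same intervals.

# Marker diversity

For co-dominant SSR/InDel genotypes the package reports, per locus: allele
frequencies over typed individuals (two copies each), observed
heterozygosity (share of typed individuals with two distinct alleles),
unbiased expected heterozygosity $\frac{2n}{2n-1}(1-\sum p_i^2)$, Nei's gene
diversity $1-\sum p_i^2$, effective allele number $1/\sum p_i^2$, and the
Shannon–Weaver index $-\sum p_i \ln p_i$ (natural log, the POPGENE
convention — confirmed by back-solving printed reference rows: gene
diversity 0.4962 implies biallelic frequencies 0.5436/0.4564 and a Shannon
index of 0.6893, matching the published 0.6894). The summary row is the
unweighted arithmetic mean over loci, matching how such tables are printed.

Two caveats are worth documenting. First, published tables from this
tradition often label the $\approx 1 - \text{gene diversity}$ column "He"
and its complement "Ho" — swapped relative to standard usage; the package
reports `ho_obs`, `he_exp` and `nei` under unambiguous names and leaves the
mapping to the caller. Second, in such printed tables the Ae column is not
always exactly $1/(1-\mathrm{Nei})$; where both columns are printed, the
identity should be checked before treating either as authoritative —
`locus_report` output satisfies it to 1e-9 by construction.

Nucleotide diversity π uses the unbiased frequency form
$\sum_s 2p_s(1-p_s)\frac n{n-1}$ divided by total assayed sites, which
equals the mean pairwise per-site difference — the package tests this
equality against a brute-force pairwise oracle.

The marker-population generator draws subpopulation allele frequencies from
a Balding–Nichols Dirichlet around global frequencies (an Fst-like
`divergence` parameter, default 0.1 across 5 subpopulations of 184
individuals at 40 loci) and genotypes with the partial-selfing equilibrium
inbreeding coefficient $F = s/(2-s)$. The default selfing rate 0.5 puts the
simulated population in the heterozygote-deficient regime typical of
selfing-prone wild rice while keeping enough heterozygotes to exercise both
estimator branches; `selfing_rate = 0` recovers Hardy–Weinberg (tested
within 3 SE) and 1 drives observed heterozygosity to zero.

# Trees and networks

Nei's standard distance between populations is
$D = -\ln\!\left(J_{xy}/\sqrt{J_xJ_y}\right)$ with the J's averaged over
loci on the union allele alphabet; no shared alleles anywhere gives an
explicit `Inf` rather than a capped number, and `upgma` refuses infinite
entries with instructions to prune (silently capping would distort every
downstream merge height). UPGMA merges the closest pair, with new distances
the size-weighted mean and node height d/2; ties merge the pair whose leaf
labels sort first, making dendrograms reproducible. Output is ultrametric
by construction and is cross-checked in tests against average-linkage
`hclust` and against cophenetic round-trips on ultrametric inputs.

Haplotype networks collapse identical aligned sequences into nodes after
masking, network-wide, every column containing a gap or ambiguity character
(the conservative reading of how network programs treat partial data;
disable with `mask_ambiguous = FALSE`). Edges are Hamming distances; the
default `epsilon = 0` yields a pure minimum spanning tree via Kruskal with
deterministic (weight, label) ordering, and `epsilon > 0` adds
alternative edges whose weight is within epsilon of the distance class at
which their endpoints first connected — the usual minimum-spanning-network
extension. The MST weight is verified against exhaustive enumeration over
all spanning trees for up to 7 nodes.

# ABBA-BABA

Because the compared panels are populations, the D statistic uses the
frequency-weighted form: per site, ABBA mass $(1-p_1)p_2p_3(1-p_4)$ and
BABA mass $p_1(1-p_2)p_3(1-p_4)$, with the outgroup entering through its
own frequency rather than being forced ancestral. $D =
(\mathrm{ABBA}-\mathrm{BABA})/(\mathrm{ABBA}+\mathrm{BABA})$; significance
comes from a delete-one block jackknife over physical blocks (default 1 Mb).
The four-taxon generator drifts each population's frequency around a shared
ancestral Beta(0.5, 0.5) draw (Balding–Nichols, drift 0.2) and models gene
flow as mixing P3's frequency into P2 with fraction m; at m = 0, P1 and P2
are exchangeable so E[ABBA] = E[BABA], and the null calibration test
requires |Z| < 3 in at least 95% of 50 seeded runs.

# Numerical choices and scale

Problem sizes in the tests were chosen as the smallest that make each
statistical check stable: 5 000 sites per simulated genome for the
planted-region and false-positive suites (30 replicates), 500 sites for the
exact brute-force oracle comparison, 20 000 sites per ABBA-BABA panel, and
≤ 7 nodes for exhaustive spanning-tree enumeration. All generators are pure
functions of their config and seed; identical seeds give byte-identical
outputs. Degenerate inputs are contracts, not crashes: empty VCF bodies give
empty tables, a single site smooths to itself, an empty fitted profile or an
all-missing locus raises an informative error, and zero informative
ABBA-BABA mass returns NA with a warning.

# Known limitations

The scan assumes biallelic sites and two-entry AD fields; multiallelic
records are dropped rather than decomposed. The smoother's bandwidth is a
design parameter, not estimated from the data; interval boundaries inherit
its scale and should be read as ~window-resolution. Recurrence counting
treats any physical overlap across comparisons as the same region; partial
overlaps are not split. The diversity module does not compute F-statistics,
HWE tests, or linkage disequilibrium, and the network module builds minimum
spanning (not median-joining) networks.
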