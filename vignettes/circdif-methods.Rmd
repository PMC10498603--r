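---
title: "Methods: differential eccDNA circulome analysis with circdif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential eccDNA circulome analysis with circdif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circdif)
```

## The problem

Extrachromosomal circular DNA (eccDNA) is shed from the linear genome at
sizes from a few hundred bp to beyond 100 kbp. Under genotoxic stress —
for instance in the spinal cord of ALS-model animals carrying a mutant
SOD1 transgene — both the overall circle load and the set of genes that
shed circles change. `circdif` implements a complete split-read based
analysis of such two-group circulome experiments: circle junction calling,
merging and filtering, per-gene quantification, differential and
commonality analysis, size-periodicity profiling, telomeric-circle (ECTR)
estimation, differential proteomics, and the integration of the three
evidence layers. A synthetic cohort generator with a ground-truth ledger
makes every stage testable without access to sequencing data.

## From split reads to circles

A read sequenced across a circle junction aligns as two segments in
*inverted* genomic order: the read prefix maps downstream of the read
suffix. `call_junctions()` emits a circle `(chrom, min(starts),
max(ends))` for every such read whose two segments each contribute at
least `min_non_overlap = 10` bp of genomic span not shared with the other
segment; collinear reads are ignored and inter-chromosomal reads are
skipped and counted (multi-fragment chimeric circles are out of scope).
Identical junctions within a sample aggregate, one supporting read adding
one split read.

`merge_circles()` coalesces near-duplicate junctions: two circles link
when both breakpoints differ by less than `d_min = 10` bp (strict), and
clusters are connected components under single linkage. With a 10 bp
radius, chaining across unrelated circles is negligible. The merged
circle keeps the coordinates of the member with the highest split-read
support — a real observed junction rather than a min/max envelope — with
deterministic tie-breaks (smallest start, then smallest end), and sums
the split reads, so split-read mass is conserved. We chose the
two-breakpoint distance rule over a single-endpoint rule because a
single-endpoint interpretation would chain circles sharing one breakpoint
but differing at the other.

`filter_circles()` retains circles with at least 2 split reads, length at
most 100 kbp, and a chromosome outside the mitochondrial alias set
`{chrM, MT, chrMT}`.

## PpGC: per-gene circle production

Circles are annotated against gene models by strand-blind interval
overlap of at least 1 bp under half-open (BED) coordinates; GTF input is
converted on read. A circle spanning several genes contributes its full
split-read count to each of them — the quantity is "circles carrying this
gene or a fragment of it", so no apportioning is performed.

For gene $i$ with length $L_i$ in sample $s$:

$$\mathrm{PpGC}_{i,s} = \log_2\!\left(\mathrm{raw}_{i,s} \cdot
\frac{L_{\max}}{L_i} + 1\right)$$

where $\mathrm{raw}_{i,s}$ is the split-read sum over circles overlapping
gene $i$, and $L_{\max}$ is the length of the longest gene *found in the
dataset* — by default the longest gene with at least one circle
assignment in the run (`l_max_source = "detected"`), switchable to the
whole annotation. The length scaling removes the trivial advantage of
long genes; the $\log_2(x+1)$ equalization compresses the heavy right
tail and leaves undetected genes at exactly 0. Final PpGC values are
invariant under a global rescaling of all gene lengths.

## DifCir: differential production

Per gene, group means of final PpGC values give
$\Delta_i = \bar{x}^{case}_i - \bar{x}^{ctrl}_i$ (the log2 fold change)
and a two-sided two-sample t-test gives $p_i$. The default is the classic
pooled-variance Student test (a Welch switch exists); the calling rule is

- up-DPpGC: $\Delta_i > \theta$ **and** $p_i \le \alpha$,
- down-DPpGC: $\Delta_i < -\theta$ **and** $p_i \le \alpha$,

with $\theta = 1$ (one fold change in log2 scale, strict inequality:
"more than" the threshold) and $\alpha = 0.01$ (inclusive: a
$-\log_{10} p \ge 2$ boundary). No multiple-testing correction enters the
default call — the thresholds are on raw p — but a Benjamini–Hochberg
column is always emitted for transparency. Degenerate genes are handled
without inventing a prior: both groups constant and equal gives $p = 1$;
both constant but unequal gives the minimum representable positive p with
a warning, so the mean difference decides the call.

Two genome-level companions: `chromosome_enrichment()` scores each
chromosome's up-DPpGC count with an upper-tail hypergeometric test
$P(X \ge k)$, and `gene_length_regression()` fits OLS of
$-\log_{10} p$ on gene length over the up-DPpGCs (constant response
defines $R^2 = 0$) to probe whether shedding propensity merely tracks
gene size.

## Democratic method: common circles

Within one group, the vote threshold is the *ceiling of the mode* of the
group's empirical PpGC distribution. The mode is estimated as the argmax
of a Gaussian kernel density (Silverman's bandwidth, 1024-point grid over
$[0, \max]$) over the group's **positive** gene–sample values — zeros are
excluded because the spike of undetected genes would otherwise always
dominate. A sample votes for a gene when its final PpGC reaches the
threshold ($\ge$), and genes with at least 3 votes are the group's
CPpGCs. Thresholds are computed independently per group; modes of 7.0476
and 8.00402 yield thresholds 8 and 9. Whether the distribution should
pool all gene–sample values or per-gene means is an open choice; we pool
all positive gene–sample values of the group.

## Size profiles and the exact rank-sum test

`size_profile()` bins circle lengths at 1 bp up to 10 kbp, smooths with a
centered 31 bp moving average under reflect padding (mass is conserved up
to boundary handling), and detects local maxima with a topographic
prominence floor of 5% of the global smoothed maximum; bin-level jitter
within one smoothing window collapses to a single summit. The median
spacing of consecutive maxima estimates the ~200 bp length periodicity
that nucleosome-associated circle cohorts display. The smoothing method
and bin width are explicit, configurable choices; spectral estimation is
deliberately out of scope.

`unique_count_comparison()` and `ectr_group_compare()` use
`exact_wilcoxon()`: for combined sample sizes up to 25 the two-sided
p-value comes from the *full* null distribution of the rank-sum statistic
(mid-ranks under ties), enumerated by dynamic programming over the
doubled ranks; the two-sided p doubles the smaller tail, capped at 1.
Complete separation at $n_1 = 10$ vs $n_2 = 9$ gives
$p = 2/\binom{19}{9} = 2.165 \times 10^{-5}$, the smallest value this
design can produce. Beyond 25 the tie-corrected normal approximation with
continuity correction is used. `stats::wilcox.test` cannot compute exact
p-values under ties, which is why the enumeration is implemented here and
cross-checked against both `wilcox.test` (tie-free cases) and brute-force
rank enumeration in the tests.

## ECTR: telomeric repeats on circles

The estimator works directly on circle consensus sequences: count
non-overlapping TTAGGG and CCCTAA occurrences per sequence, take the
orientation maximum (a repeat tract and its complement are never summed),
qualify sequences with at least $k$ motifs, and report
$\mathrm{ECTR} = 6 \cdot \text{(motif count over qualifying sequences)}$
bp in kbp. The default $k = 4$ reflects the repeat count most samples
reach; the k-sweep (1–12) is non-increasing by construction. Read-based
estimation with coverage normalization is a non-goal: the sequence-level
definition is deterministic and sidesteps amplification-depth
normalization, which rolling-circle amplification leaves ill-defined.

## Differential proteins

Protein abundances per subcellular fraction (CP, ME, sNE, cNE, Cysk) are
compared with a paired t-test on per-pair log2 differences; the average
log2 ratio is the mean of per-pair log2 ratios, consistent with the
paired test. Multiple testing uses Storey q-values: $\hat\pi_0$ from the
$\lambda$ grid 0.05–0.95 (step 0.05) with a cubic smoothing-spline
extrapolation to $\lambda \to 1$, clamped to $(0, 1]$; for fewer than 100
tests a fixed $\lambda = 0.5$ estimate is used for stability. With
$\hat\pi_0 = 1$ the q-values coincide exactly with Benjamini–Hochberg. A
protein is a DEP when $q < 0.05$ **and** $|$average log2 ratio$| > 0.38$;
fractions are analyzed independently and a protein's overall status is
its any-fraction call.

## Integration

`match_tandems()` pairs up-DPpGC genes with DEPs (identity gene–protein
mapping by default; a two-column mapping table is accepted, collisions
rejected). Direction is taken from the most significant fraction;
concordance means the eccDNA and protein changes share a sign.
`risk_overlap()` intersects gene sets with user-supplied risk lists after
case-folding (mouse symbols match human lists case-insensitively; no
ortholog mapping). `rdc_compare()` pools PpGC values of a reference
fragile-gene panel (e.g. recurrent double-strand-break cluster genes) per
group and reports the fold change of group means with a rank-sum p.
Risk lists ship as plain one-symbol-per-line files because database
snapshots are dated; the package bundles only list contents printed in
primary literature plus clearly labelled synthetic fillers.

## The synthetic cohort generator

`simulate_cohort()` emulates the data structure the analysis assumes, and
its defaults are the study conditions: 10 control and 9 case samples; a
Poisson circle load of 480 per control sample with a 6-fold case
multiplier; circle lengths from an equal-weight mixture at 200, 400, …,
1000 bp (SD 20 bp, truncated positive) plus a 10% log-uniform tail capped
below 100 kbp; 5% mitochondrial circles; five hotspot genes shedding 5
extra circles per case sample at a guaranteed split-read floor of 4 (plus
Poisson(1) variation, giving the between-sample variance real cohorts
show); telomeric circles planting 35.1 kbp (control) and 30.5 kbp (case)
of TTAGGG per sample on average, with Poisson variability in per-sample
circle counts mirroring the high inter-sample spread of real ECTR
estimates; and a 1000-protein panel (named after the gene models where
the panel sizes allow, so gene–protein tandems can arise) with 50 planted
differential proteins (log2 shift 1.0, replicate noise SD 0.2, 5 matched
pairs). Gene lengths are log-normal with median 30 kbp and a heavy right
tail, so megabase neural-like genes occur. `simulate_split_reads()`
realizes each circle as split reads with ±2 bp junction jitter — small
enough that the 10 bp merge radius coalesces one circle's reads, large
enough to exercise the merge rule.

What the generator does **not** emulate: sequence content and sequencing
errors, rolling-circle amplification bias, coverage structure within
circles, chimeric multi-fragment circles, and realistic gene density or
chromatin context. Passing tests therefore demonstrate the correctness
and calibration of the *algorithms* under the assumed statistical
structure, not performance on real sequencing data.

## Numerical choices and problem sizes

Determinism: every stochastic step runs under an explicit seed and the
generator restores the caller's RNG state; identical configurations give
byte-identical outputs, which the pipeline manifest (parameter values and
file checksums) makes verifiable. Coordinates are 0-based half-open
everywhere internally. Ties are broken deterministically in the merge
representative; the exact rank-sum enumeration switches to the normal
approximation above 25 combined samples; KDE grids are fixed at 1024
points. The test suite runs on reduced cohorts (60 baseline circles per
sample, 50 genes, 200 proteins) and calibration checks use 50 null
simulations of 2000 genes and 20 replicate cohorts — sizes at which every
distributional property under test is already stable.

## Known limitations

The junction caller works on abstract split-read records, not BAM
alignments; converting supplementary alignments into the 8-column TSV is
the user's (straightforward) responsibility. The democratic mode is a
KDE argmax and inherits bandwidth sensitivity near integer boundaries.
ECTR ignores variant telomeric motifs and cannot separate interstitial
from terminal repeats. The DEP module starts from an abundance matrix;
upstream spectral processing is out of scope. Group comparisons assume
independent samples within groups and matched pairs across the protein
panel.
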