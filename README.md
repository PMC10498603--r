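# circdif

Differential analysis of extrachromosomal circular DNA (eccDNA)
circulomes between two groups of samples — for instance a genotoxic
disease model versus healthy controls — from split-read circle evidence
through per-gene quantification to the integration with proteomic and
risk-gene evidence.

eccDNA molecules are circles excised from the linear genome. A
sequencing read that crosses the circle junction aligns as two segments
in inverted genomic order; `circdif` calls circles from such records,
coalesces near-duplicate junctions (both breakpoints within D_min = 10
bp, split reads summed), and filters to circles with ≥ 2 split reads,
length ≤ 100 kbp, outside the mitochondrial chromosome.

The core quantity is the **produced-per-gene circles (PpGC)** value: for
gene *i* in sample *s*,

    PpGC_i,s = log2( raw_i,s * L_Max / L_i + 1 )

where `raw` sums the split reads of all circles carrying gene *i* or a
fragment of it, `L_i` is the gene length and `L_Max` the longest gene
found in the dataset. On the PpGC matrix the package provides:

- **DifCir** — per-gene two-sample Student t-test; a gene is an
  up-DPpGC when the log2 mean difference exceeds θ = 1 and p ≤ α = 0.01;
  with hypergeometric chromosome enrichment and a gene-length OLS
  companion (R² of −log10 p vs gene length).
- **Democratic method** — per group, the vote threshold is the ceiling
  of the mode of the positive PpGC distribution (KDE argmax); genes with
  ≥ 3 votes are the group's common circles (CPpGCs).
- **Size profiling** — 1 bp histograms, 31 bp moving-average smoothing,
  prominence-filtered peaks and their median spacing (the ~200 bp
  periodicity), plus an exact Wilcoxon rank-sum comparison of per-sample
  unique circle counts (full enumeration with mid-ranks up to n1+n2 = 25).
- **ECTR** — extrachromosomal telomere repeat content per sample from
  circle sequences: non-overlapping TTAGGG/CCCTAA motifs (orientation
  maximum), sequences qualifying at ≥ k = 4 repeats, reported in kbp.
- **DEP calling** — paired t-tests with Storey q-values per subcellular
  fraction; a protein is differential at q < 0.05 and |average log2
  ratio| > 0.38.
- **Integration** — DPpGC–DEP tandems with concordance, overlap with
  user-supplied risk-gene lists, and fold-change comparison over a
  reference fragile-gene panel.

A synthetic cohort generator (`simulate_cohort()`) emulates the study
structure — 10 control vs 9 case samples, six-fold case circle
enrichment, 200 bp length periodicity, mitochondrial contamination,
planted hotspot genes, telomeric circles, paired protein panel — and
returns a ground-truth ledger, so the whole pipeline is testable without
external data.

## Worked example

```r
library(circdif)

co  <- simulate_cohort(simulation_config(seed = 1))
run <- run_pipeline(co)

run
#> circdif run: 25388 circles after filtering, 26 up-DPpGC(s), count ratio 5.89 (p = 2.17e-05)

head(run$difcir[order(run$difcir$p_value), c("gene_id", "delta", "p_value")], 5)
#>      gene_id delta  p_value
#> 84  Gene0084 11.40 1.70e-34
#> 57  Gene0057  9.47 6.79e-34
#> 6   Gene0006 10.32 1.08e-33
#> 54  Gene0054 10.80 4.72e-33
#> 104 Gene0104  8.57 1.51e-30

co$truth$hotspot_genes$gene_id
#> "Gene0104" "Gene0057" "Gene0084" "Gene0006" "Gene0054"
```

The five most significant up-DPpGCs are exactly the five planted hotspot
genes. The per-sample unique-circle comparison shows the planted
six-fold case enrichment at the smallest p this design can produce
(complete separation of 10 vs 9 samples):

```r
run$count_comparison$ratio     #> 5.89
run$count_comparison$p_value   #> 2.165018e-05   (= 2 / choose(19, 9))
```

Democratic voting derives each group's threshold from its PpGC
distribution mode (here 4.59 → 5 for control, 5.11 → 6 for case; 15 case
CPpGCs), the size profile of sample A1 shows peaks at 204, 399, 605,
800, 1000 bp with a median spacing of 198 bp, and the ECTR estimates
recover the planted telomeric content (control 32.8 ± 2.1 kbp vs case
31.9 ± 2.9 kbp, Wilcoxon p = 0.765 — comparable groups, as planted).

`run_pipeline(co, out_dir = "run1")` additionally writes every stage
table plus a `manifest.json` with parameter values and file checksums;
reruns with the same seed are byte-identical.

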