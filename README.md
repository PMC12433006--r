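# nanomsp

Discovery and validation of **methylation-specific PCR (MSP) biomarkers**
from per-CpG nanopore 5mC methylation calls.

## The problem

Cancer cells hypermethylate specific CpG islands early in tumorigenesis, and
a qPCR assay on bisulfite-converted DNA (MSP) can detect that
hypermethylation cheaply in a clinical lab. The hard part is the discovery
step: finding, genome-wide, small regions that are (a) methylated in tumor
tissue, (b) unmethylated in healthy tissue, and (c) shaped so that a
bisulfite-specific primer pair can actually be designed on them. Nanopore
sequencing with adaptive sampling gives per-CpG methylation over all CpG
islands from just a handful of tissue samples; `nanomsp` turns those pileups
into ranked, designable MSP assays and validates them from qPCR CT tables.

## What the package computes

**Region calling.** Per CpG site (strand-aggregated), a site is *eligible*
when every control sample has `meth_pct <= maxMethControl` (default 10%), at
least one tumor sample has `meth_pct >= minMethTumor` (default 50%), and all
samples cover the site with `>= minSiteDepth` reads. Maximal windows of
18–24 nt holding `>= 3` eligible CpGs are candidate primer sites; two
non-overlapping sites whose outer span is 60–400 nt form a candidate
amplicon, scored as

```
score = sum over tumor samples s, site CpGs c of  (meth_pct(s,c)/100) * depth(s,c)
```

(monotone in tumor methylation and coverage). Scored regions are
thresholded and greedily reduced to the highest-scoring representative of
each overlapping cluster.

**Assay design.** The region ± flank is bisulfite-converted in silico
(methylated allele: non-CpG C → T, CpG C retained) and all 14–22-mers are
screened: per primer ≥ 1 CpG and ≥ 1 converted C, GC 50–70%, Wallace-rule
Tm band; per pair amplicon 80–400 bp with ≥ 3 CpGs, Tm difference < 5 °C,
and ungapped-complementarity dimer screens (run > 8 overall, > 4 anchored
at a 3' end). Hydrolysis probes (20–30 nt, no 5' G, no ≥ 6 nt palindrome,
Tm 5–10 °C above the primers) are placed just downstream of the forward
primer.

**Marker validation.** From CT tables, `ΔCT = CT_target − CT_ACTB`;
Welch tests with Bonferroni correction across markers; ROC AUC with the
orientation "lower ΔCT = tumor"; and the Youden-optimal cutpoint maximizing
`J = sensitivity + specificity − 1` over margin-midpoint candidates.

**Synthetic data.** `simulate_msp_dataset()` generates every input the
pipeline consumes — a reference with GC-rich CpG islands (mean 777 nt, 67%
GC), strand-split bedmethyl files with negative-binomial coverage and
tumor-purity-diluted methylation, and CT tables with
methylation-dependent signal — so the whole workflow is testable without
restricted patient data.

## Worked example

Six MSP markers assayed on three tumor and three control samples ship with
the package:

```r
library(nanomsp)
dct <- example_delta_ct()
summarize_markers(dct)[, c("marker", "mean_tumor", "mean_control",
                           "cutpoint", "youden_j", "auc", "separated")]
```

```
  marker mean_tumor mean_control cutpoint youden_j   auc separated
1   FLI1       3.60        17.26     9.54    1.000 1.000      TRUE
2  KCNB1       7.52        13.75     5.96    0.667 0.667     FALSE
3   LHX8       1.28        10.51     4.48    1.000 1.000      TRUE
4   URAD       1.94         7.41     3.40    1.000 1.000      TRUE
5  USP44       3.60         9.26     7.95    1.000 1.000      TRUE
6 ZNF529       4.14        14.86     7.45    1.000 1.000      TRUE
```

Five of the six markers separate tumor from control perfectly in this small
cohort (J = AUC = 1; the classifier "tumor if ΔCT ≤ cutpoint" places the
threshold at the midpoint of the separating margin). KCNB1 misclassifies
one tumor sample whose ΔCT of 19.80 sits above all controls, giving
sensitivity 2/3 at specificity 1 (J = AUC = 2/3). ZNF529's control ΔCT
values span 10.9 cycles (20.82 − 9.92), KCNB1's tumor values 19.62 cycles
— the `range_*` columns of the same summary.

End-to-end on simulated data:

```r
sim  <- simulate_msp_dataset("demo_data", simulation_config(), seed = 42)
man  <- read_sample_manifest(sim$paths$manifest)
pred <- predict_msp_regions(man, prediction_config(),
                            islands = read_bed_intervals(sim$paths$islands))
pred$report                     # per-stage funnel counts
pairs <- design_primer_pairs(pred$regions[1, ], sim$paths$reference)
design_probe(pairs[1, ], attr(pairs, "template"))
```

Or as one pipeline run from a JSON config (see `run_pipeline()` /
`inst/cli/nanomsp.R` with subcommands `simulate`, `predict`, `design`,
`validate`, `run`).

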