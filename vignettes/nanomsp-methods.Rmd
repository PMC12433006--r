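---
title: "nanomsp: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nanomsp: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanomsp)
```

This vignette explains what `nanomsp` computes and why its defaults are set
the way they are. It is the package's methods reference: every statement
about behavior here is checked by the test suite or the acceptance script;
nothing below reports an empirical result the code does not itself compute.

## 1. Input model

The discovery input is one bedmethyl file per tissue sample — the extended
BED dialect written by nanopore modified-base pileup tools, where column 10
is the count of valid modification calls at a position and column 11 the
percent of those calls read as 5mC. A record is one cytosine on one strand.
Because CpG methylation is symmetric in somatic tissue to a good
approximation, `aggregate_cpg_strands()` merges the `+` record at position
p with the `-` record at p+1 into one site (summed depth, depth-weighted
mean percent); strand-specific analysis remains available with
`aggregate_strands = FALSE` in `predict_msp_regions()`, since per-strand
averages are occasionally informative for assay interpretation. All genomic
coordinates are 0-based half-open internally (BED-native); string positions
inside templates are 1-based like `substr()`.

Depth filtering happens twice, deliberately: `read_bedmethyl(min_depth = 1)`
drops only empty rows at parse time, while the analysis-level threshold
(`min_site_depth`, default 5 reads) lives in `prediction_config()` so that
the same parsed records can be re-analyzed under different stringencies.

## 2. Region calling

A CpG site is *eligible* for MSP primer placement when three conditions
hold across the cohort:

* every control sample is at most `max_meth_control` percent methylated
  (default 10%),
* at least one tumor sample is at least `min_meth_tumor` percent methylated
  (default 50%),
* every sample covers the site with at least `min_site_depth` valid calls.

The 50% tumor threshold deserves a flag: "methylated in at least one tumor
sample" is not a quantified criterion, and 50% is the conventional
hemimethylation midpoint rather than a fitted value. It interacts with
tumor purity — at 70% purity a fully methylated clone reads ~65% — so
cohorts with low purity should lower it. It is exposed in
`prediction_config()` for exactly that reason.

`find_primer_sites()` reports every *maximal* group of at least `min_cpgs`
(default 3) eligible CpGs whose dinucleotides fit inside one window of at
most `max_primer_len` (default 24) nt. Maximality makes the output
canonical: shifted duplicates of the same CpG group are not reported, and
each window is anchored at its first CpG and extended to cover its last
(padded to `min_primer_len`, default 18 nt). Two non-overlapping sites
whose *outer span* (forward-site start to reverse-site end) lies in
`[min_amplicon_len, max_amplicon_len]` = [60, 400] nt form a candidate
region. The alternative — measuring the *inner gap* between
sites — was considered and rejected: the outer span is the amplicon length
an MSP assay would actually produce, which is what the length bounds mean
in PCR terms.

### Scoring

The published tooling this package re-implements describes its score only
as "based on sequencing depth and methylation in the tumor samples", so the
formula here is this package's own, chosen to be the simplest statistic
with the stated dependencies:

$$\mathrm{score} = \sum_{s \in \text{tumor}} \sum_{c \in \text{site CpGs}}
  \frac{\text{meth\_pct}(s,c)}{100} \cdot \text{depth}(s,c)$$

It is non-negative, monotone non-decreasing in every methylation percentage
and every depth, and linear in depth (property-tested). Its scale is
data-dependent — it grows with coverage, CpG count and tumor sample count —
so published score ranges from other implementations are **not**
reproduction targets, and `score_threshold` defaults to 0; users should set
thresholds from their own empirical score distribution (e.g. an upper
quantile).

### Cluster selection

CpG islands are internally homogeneous, so candidate regions overlap
heavily. Instead of manual curation, `cluster_and_select()` applies a
deterministic greedy rule: process regions in descending score (ties:
longer span, then smaller start) and suppress any region overlapping an
already-selected one. This is reproducible and, on disjoint clusters,
provably selects each cluster's maximum.

## 3. In-silico bisulfite conversion and assay design

Bisulfite treatment deaminates unmethylated C to U (read as T), while 5mC
is protected. The methylated-allele template therefore converts every
non-CpG C to T and retains CpG Cs; the unmethylated-allele template
converts every C. MSP primers are designed on the methylated-allele
template because the assay detects the methylated allele; the unmethylated
conversion is exposed for specificity screening against negative controls.
`OB` designs operate on the reverse complement (the two strands are no
longer complementary after conversion, so they are independent design
spaces); on a reverse-complement-palindromic fixture the two strands
provably yield identical genomic amplicons, which the tests exploit as a
coordinate-mapping oracle.

Primer constraints (all in `design_constraints()`):

| parameter | default | rationale |
|---|---|---|
| primer length | 14–22 nt | bisulfite primers run short and AT-rich |
| CpGs per primer | ≥ 1 | the primer must discriminate methylation; the amplicon-level "≥ 3 CpGs" rule alone would allow methylation-blind primers |
| converted Cs per primer | ≥ 1 | distinguishes converted from unconverted DNA |
| GC | 50–70% | band around the ~60% target |
| Tm (Wallace) | 50–70 °C | `2(A+T)+4(G+C)`; exact and unit-testable |
| pair Tm difference | < 5 °C | co-amplification |
| amplicon | 80–400 bp, ≥ 3 CpGs | detection specificity |
| amplicon converted Cs | ≥ 4 *rewarded* | "ideally four" is a preference, so it is a ranking bonus, not a filter |
| dimer runs | ≤ 8 overall, ≤ 4 at 3' ends | complementarity-run heuristic |

The dimer/hairpin screen is a longest ungapped complementary run (longest
common substring against the partner's reverse complement), not
thermodynamic folding: no folding method is specified by the constraint
set, the run heuristic is deterministic and oracle-testable, and 3'-anchored
runs — the polymerase-extensible ones — get the tighter threshold.
CpG-overlapping primer bases are emitted as the methylated-allele base
(C/G), not degenerate codes, matching the methylated-allele assay design.

Probes: 20–30 nt on the forward strand, starting within
`probe_max_offset = 10` nt of the forward primer's 3' end — "close to the
forward primer" is not quantified further, and 10 nt keeps the reporter
near the amplification start without constraining the search to nothing.
Hard filters: no 5' G (quenches FAM), no reverse-complement palindrome of
6+ nt, Tm 5–10 °C above the hotter primer, dimer runs against primers and
self ≤ 8. Ranking is GC proximity to 50%.

The nearest-neighbor Tm option uses the SantaLucia (1998) unified table at
500 nM oligo and 50 mM monovalent salt; it is provided for users who want
a thermodynamic estimate but is not the default because its parameter
choices would dominate test tolerances.

## 4. Validation statistics

ΔCT is the *difference* `CT_target − CT_ACTB`. The describing literature
uses both "ratio" and "delta" for this normalization; the magnitudes of
published per-sample tables are consistent with a difference, and a
difference in cycles is the standard log-scale normalization (a ratio of
CTs has no physical interpretation). Censored targets (no amplification
within the run) are imputed at the cycle count — 43 by default, matching
the thermal protocol — and flagged; this is conservative for
tumor-detection, since a censored ΔCT lands at the unmethylated extreme.

Group comparison is a two-sided Welch t-test (the unequal-variance default
of the usual convenience wrappers) with Bonferroni adjustment
`p_adj = min(1, m·p)` over the marker family. The ROC convention is "lower
ΔCT indicates tumor"; AUC is the Mann–Whitney pair-counting form with ties
at 0.5, and the test suite verifies exact equality with the rank-sum
formulation. Cutpoints maximize Youden's `J = sensitivity + specificity − 1`
over candidates at the midpoints between adjacent distinct ΔCT values plus
±∞ — midpoints rather than observed values so the reported threshold is
centered in the separating margin rather than sitting on a patient's
measurement. Ties break toward higher specificity (a screening assay
prefers fewer false positives), then the lower cutpoint. These choices make
J and AUC invariant under strictly increasing transforms of ΔCT
(property-tested).

## 5. The synthetic world

`simulation_config()` defaults state the world the package is tested in:

* 3 tumor + 3 control samples — the minimal recommended discovery design;
* CpG islands: mean length 777 nt (minimum 200), 67% GC, one CpG per 8 nt,
  in AT-rich background with 0.6–2.5 kb gaps; half the islands planted DM;
* methylation: per-read probability 0.9 at DM-island CpGs in pure tumor,
  0.02 elsewhere and in controls; tumor purity per sample uniform on
  0.70–0.80, mixing linearly:
  `p = purity·p_tumor + (1 − purity)·p_control` (the standard
  two-population model for tumor cell percentage);
* coverage: negative-binomial with mean 15 and size 10 — overdispersed, as
  nanopore coverage is, spanning the ~12–29× per-sample island depths a
  small adaptive-sampling run produces; split across strands binomially;
* qPCR: `ct_ref ~ N(20, 0.5)`,
  `ct_target = ct_ref + 20 − 18·meth_fraction + N(0, 1)`, censored at 43
  cycles — chosen so that fully methylated templates give ΔCT ≈ 2 and
  unmethylated ones ≈ 20, the order of magnitude real marker panels show.

What a green test on this world establishes: the caller recovers planted
DM islands at ≥ 95% sensitivity with zero calls in non-DM islands, and the
cutpoint machinery reaches J ≥ 0.9 on the simulated CT signal. What it
does not establish: performance under basecaller-correlated errors,
mapping artifacts, copy-number variation, inter-island methylation
heterogeneity, or purity below ~0.5 — none of which the generator models.
Real cohort performance must be established on real cohorts.

## 6. Numerical and engineering choices

* All randomness is seed-driven; simulation outputs are byte-identical for
  identical seed and configuration.
* Ranking orders are deterministic total orders with documented tie-breaks,
  so repeated runs produce byte-identical outputs.
* Weighted means with zero total weight (two zero-depth strand records)
  fall back to the unweighted mean.
* The BED writer clamps column 5 to the 0–1000 BED convention and carries
  the raw score in an extra column; round-tripping is exact to 10
  significant digits.
* The pipeline configuration is a single declarative JSON file (nested
  blocks per stage, unknown keys rejected, relative paths resolved against
  the config file); JSON was chosen over YAML because the JSON parser is a
  hard dependency of the package already.
* A textbook-looking corner case is worth naming: a differential island of
  8 CpGs spaced 6 nt can never yield a region, because such an island is at
  most ~48 nt wide — below the 60 nt minimum amplicon span. The end-to-end
  tests therefore plant wider islands; the eligibility and windowing
  behavior of narrow islands is still covered by the unit tests.

## 7. Known limitations

* Primer thermodynamics are heuristic; shortlisted assays should still be
  checked with a thermodynamic folding tool and wet-lab gradient PCR.
* The region score is package-specific; scores are comparable within a run,
  not across datasets or with other callers.
* `validate` assumes one CT measurement per sample × marker; technical
  replicates should be aggregated upstream.
* Genome-scale inputs are processed by linear scans per chromosome; the
  package targets adaptive-sampling-sized data (CpG islands ± 2 kb), not
  whole-genome bedmethyl files at full depth.
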