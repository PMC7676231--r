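---
title: "Methods: from shotgun reads to imidazole propionate associations"
author: "imppipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from shotgun reads to imidazole propionate associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scientific background

Imidazole propionate (ImP) is produced by gut bacteria from dietary
histidine: histidine ammonia-lyase (*hutH*, KEGG ortholog K01745)
converts histidine to urocanate, and urocanate reductase (*urdA*)
reduces urocanate to ImP. Elevated serum ImP impairs insulin signalling
and is associated with type 2 diabetes, with lower microbial gene
richness, and with the low-richness, Bacteroides-dominated community
type ("Bacteroides 2"). `imppipe` implements the complete computational
chain needed to study these links in a shotgun-metagenomics cohort —
gene quantification, community typing, functional-marker quantification
and cohort statistics — and pairs it with a synthetic cohort generator
that plants that exact statistical structure, so that every stage can be
validated end to end without access-restricted subject-level data.

## The synthetic world

`synthetic_world_config()` fixes the study conditions. The defaults are
the reference scenario used by the tests and the acceptance script:

* **Cohort**: 500 subjects in proportions 27.5 / 33.4 / 39.1% across
  healthy, prediabetes and type 2 diabetes — the class mix of a
  1958-subject cardiometabolic cohort scaled to desk size. Clinical
  covariates (age, sex, BMI, ethnicity, creatinine clearance, fasting
  and 2-h OGTT analytes, HbA1c, triglycerides) are drawn from truncated
  normal / log-normal scenario distributions whose medians follow the
  published cohort description. These distributional forms are scenario
  choices, not inferences: the source cohort reports medians and
  quartiles only.
* **Catalog and taxa**: 5000 genes of 300–1500 nt grouped into 60
  metagenomic species (MGS) of 80 genes (50 marker genes each) across 20
  genera; three community types with Dirichlet parameters giving a
  diverse Bacteroides-dominated type, a low-diversity strongly
  Bacteroides-dominated type (the "Bacteroides 2" analog) and a
  Prevotella-dominated type.
* **Gene richness**: each subject retains a Beta-distributed fraction of
  every MGS's genes (mean 0.85, or 0.55 in the Bacteroides-2-like
  type; concentration 60). Retention drives both the planted richness
  and its bimodality in each diagnosis stratum.
* **The ImP model** (log-nM scale):
  `log ImP = log 20 + shift(group) + beta * z(richness) +
  0.25 * urdA-carrier + N(0, 0.6)` with shifts 0 / 0.35 / 0.60 and
  `beta = -0.25`. The baseline of 20 nM and the group ordering echo the
  reported healthy-vs-diabetes medians; the noise SD reproduces the wide
  interquartile spread of serum ImP.
* **urdA carriage**: true (non-His-373) urdA carriage probability 0.25 /
  0.75 / 0.25 by enterotype, contributing a read share of about 0.1%
  (0.4% in the Bacteroides-2 analog); inactive His-373 homologs are
  carried independently at 50%.
* **Reads**: 5×10⁴ single-end 150-bp reads per subject, drawn
  proportionally to abundance × gene length with uniform start
  positions and substitution errors at 0.5% per base. The read model is
  deliberately minimal — substitution-only, constant quality, no
  platform error profile — because the mapping stage only needs
  identity-threshold behaviour.
* **Nutrition**: a 37-group food-frequency table with per-group gamma
  intakes, 20% zero-inflation, energy from scenario energy densities
  with log-normal self-report error plus 3% gross under- and 2% gross
  over-reporters (for the 0.5–3.5×BMR plausibility screen), and
  histidine computed from per-group contents. Histidine is generated
  independent of ImP by default — the planted null — and can be tied to
  ImP via `histidine_imp_beta` for power studies.

What the generator does **not** emulate: sequencing error profiles,
paired ends, host/food contamination, strain-level variation,
compositional coupling between clinical covariates and the microbiome
beyond the planted terms, and item-level FFQ granularity. Passing tests
therefore demonstrate that the pipeline recovers structure it is pointed
at, under a clean read model — not that it is robust to every artefact
of real data.

## Gene quantification

Reads are mapped with an exact 31-mer seed and ungapped extension over
the full overlapping span, on both strands; every alignment tying the
best match count with identity ≥ 0.95 is kept. Ties are deliberately
retained as *shared* hits: they feed smart shared counting, where
uniquely-mapping reads are attributed first and each shared read is then
split across its candidates proportionally to their unique counts. A
shared read whose candidates all have zero unique counts is split
equally — the symmetric choice that preserves read conservation
(`sum(counts) = mapped reads`, an invariant tested to 1e-9).

Downsizing to a common depth (default 10⁴ reads at desk scale; 10⁷ in
cohort practice) and rarefaction richness (mean detected genes over 10
independent rarefactions) operate on *reads*, not on fractional counts:
fractional smart-shared counts are first rounded to integer read
assignments by largest-remainder rounding, because subsampling is only
defined on reads. Samples below the target depth are excluded and
reported, never silently kept. FPKM is
`count / (length/10³) / (depth/10⁶)`.

The low/high gene-count split is a strict `<` threshold. On synthetic
data the threshold is estimated as the density crossing of a
2-component Gaussian mixture fitted to log-richness of the healthy
stratum, mirroring the practice of reading the threshold off the
bimodal richness distribution of healthy controls; it can be fixed via
configuration instead.

## Community profiling and enterotypes

MGS abundance follows the 50-marker rule: the mean FPKM of the marker
panel if strictly more than 10% of markers have positive signal, else
exactly 0 (the discontinuity at 5/50 vs 6/50 is tested). Genus-level
pseudo-counts (largest-remainder rounding to 10⁴ per sample — the
Dirichlet multinomial needs integers, and the integer nature of the
original taxon counts is not reproducible here) enter a Dirichlet
multinomial mixture fitted by EM: responsibilities in the E-step,
mixture weights by responsibility means and each component's Dirichlet
parameters by L-BFGS-B ascent in log-alpha space (analytic gradient,
floor 10⁻⁶, started at the current value so the EM objective is
monotone to 10⁻⁸; the multinomial coefficient is omitted throughout as
it is constant per sample). Initialization is seeded k-means on
proportion vectors with restarts. K is chosen by BIC with
`p = KJ + (K-1)` free parameters — the selection criterion is our
choice, as the original enterotype scheme is inherited rather than
re-derived.

"Bacteroides 2" is identified *operationally*: among components whose
largest Dirichlet share belongs to the configured Bacteroides-like
genus, the one with the lowest member mean richness is tagged as the
Bacteroides-2 analog. This is an analog by construction, not a claim of
nomenclature equivalence with published enterotype taxonomies.

## Functional markers

A urdA homolog is *functional* iff protein position 373 (1-based) is
not histidine; classification is a pure function of that residue.
Quantification windows are the annotated FAD active-site span ±90 nt,
clipped to the gene. A read counts toward a window iff its overlap with
the window matches exactly — zero mismatches, no gaps — over strictly
more than 100 nt; "larger than 100 bp" is read as strict, making 101 nt
the smallest accepted overlap (configurable). Reads may overhang window
edges; only the overlap must match; matching is strand-agnostic because
shotgun reads are unstranded. Samples with fewer than 10 qualifying
reads are excluded with a recorded reason. Counts are reported as reads
per million sample reads, separately for true and false urdA. *hutH*
abundance is the FPKM sum over catalog genes annotated to K01745, with
the annotation supplied as an input table. Position 373 is taken as the
raw (ungapped) sequence position on the synthetic references; with
user-supplied references an aligned position can be provided in the
sidecar instead.

## Cohort statistics

* **Exclusions** apply in a fixed order (CVD etiology → Grubbs ImP
  outliers → incomplete biochemistry); a record hit by several rules is
  counted under the first, so per-rule counts always sum to input minus
  output. Grubbs is the iterative one-at-a-time test with the
  `t`-based critical value, run on log ImP.
* **Derived indices**: TyG, QUICKI, and closed-form HOMA surrogates
  (÷22.5 and 20·I/(G−3.5)) — labelled surrogates because the iterative
  HOMA2 computer model is a program, not a formula; Stumvoll ISI and
  MDRD eGFR use published coefficients stored in an overridable
  configuration, with mmol/l→mg/dl conversions applied internally.
* **Quartiles** cut at type-7 percentiles with ties to the lower
  quartile. Odds ratios come from a maximum-likelihood multinomial
  logit (healthy and Q1 as references; Wald CIs; separation flagged,
  never silently reported), fitted with tight convergence so the
  covariate-free binary case reproduces the 2×2 cross-product to 1e-6.
* **Partial correlations** correlate least-squares residuals after
  projection on the covariates (+ intercept); the Spearman variant
  ranks first. The nested adjustment sets are Model 1 (age, sex, BMI,
  ethnicity), Model 2 (+ creatinine clearance), Model 3 (+ diabetes
  status). Aliased or constant covariates are dropped by the pivoted QR,
  so adding a zero-variance covariate cannot change the result. The
  cohort also computes MDRD eGFR, but the kidney covariate exposed to
  the models is creatinine clearance; only one kidney-function covariate
  enters any model.
* **Transform policy**: Shapiro–Wilk at 0.05 gates a natural-log
  transform; degenerate inputs pass through flagged.
* **FDR** is Benjamini–Hochberg within each analysis block (one family
  per heatmap-equivalent block, matching per-panel adjustment practice).
* **Random-forest importance** regresses covariate-adjusted ImP
  residuals on taxon abundances (configurable `mtry`, 50 max nodes),
  averaging node-purity importance over resampling folds, with a
  BH-adjusted Spearman screen per taxon.

## Numerical choices and degenerate inputs

Alpha floor 10⁻⁶ in the DMM keeps gamma functions finite; EM stops on a
log-likelihood gain below `tol` (10⁻⁶ by default; the pipeline driver
uses 10⁻⁴, where BIC differences are orders of magnitude larger).
Zero-variance samples yield no Grubbs outliers; all-tied values fall in
Q1; samples with zero genus mass yield all-zero pseudo-count rows;
largest-remainder rounding breaks ties by index. Derived child seeds
are kept below 2³¹.

## Problem sizes

The reference scenario (500 subjects × 5×10⁴ reads over a 5000-gene
catalog, downsizing depth 10⁴, 10 rarefactions, DMM over K ∈ 2..4) was
chosen so a complete end-to-end run finishes in minutes on a laptop
core while keeping per-sample read counts large enough for the
binomial-scale checks (a 0.8/0.2 abundance split is recovered to ±0.01
at 5×10⁴ reads). Oracle tests run at enumeration scale: all shared-read
instances with ≤5 reads × ≤3 genes, all rarefaction instances with ≤6
reads, DMM recovery at 200 samples × 30 genera over 10 seeds.

## Known limitations

The mapper is a desk-scale exact-seed matcher, not a production
aligner: gapped alignments, quality-aware mapping and contaminant
screening are out of scope. Diet-quality scores are simplified
percentile-rank analogs of aHEI/DASH/Mediterranean, suitable for
testing the statistical plumbing but not for nutritional inference.
The hutH–richness association is not planted by the generator, so its
sign on synthetic data is uninformative. Reported cohort-scale estimates
(odds ratios near 1.75/2.76, correlations near −0.3) cannot be
reproduced from synthetic data; what the package validates is sign and
significance recovery of planted structure plus exact agreement with
small-scale oracles.
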