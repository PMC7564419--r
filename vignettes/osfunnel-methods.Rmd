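---
title: "osfunnel: statistical methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{osfunnel: statistical methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind each stage of the
`osfunnel` pipeline, the meaning and rationale of every tuning parameter,
what the synthetic generator does and does not emulate, and the numerical
and edge-case decisions a user should know before trusting the output.

# 1. Copy-number segmentation and calling

## Model

A marker-level track is a per-sample, per-chromosome series of linear-scale
copy-number measurements at strictly increasing genomic positions (1-based,
as printed in array annotations). `segment_track()` applies recursive binary
splitting: every admissible breakpoint of a segment is scored by a Welch
two-sample *t* statistic between the left and right flanks, and the
strongest split is accepted when three gates all pass, then both flanks are
segmented recursively. The result tiles the markers exactly.

This is a transparent stand-in for proprietary segmentation engines. It
honours the same three published tuning parameters and is validated on
synthetic tracks with known breakpoints, but it is not a reimplementation of
any specific commercial algorithm.

## Parameters (`segmentation_params()`)

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_markers` | 10 | markers | smallest reportable event; both flanks of any split must hold at least this many markers |
| `split_p_threshold` | 0.001 | probability | two-sided Welch *t* p-value a breakpoint must beat |
| `signal_to_noise` | 0.3 | pooled SDs | minimum \|mean difference\| / pooled SD of the flanks |
| `diploid_low`, `diploid_high` | 1.72, 2.78 | copies | the diploid window for three-state calling |

Calls are made on **segment means**: a gene inherits the mean copy number of
the segment with the largest base-pair overlap (ties go to the upstream
segment), and that mean is called deletion (−1) below `diploid_low`, gain
(+1) above `diploid_high`, normal (0) in the closed interval between them —
the boundary values 1.72 and 2.78 themselves are normal. Gene intervals are
BED (0-based, half-open); segment positions are 1-based inclusive, so a
segment spans `[start_pos − 1, end_pos)` in BED space. Genes overlapped by
no segment are absent from the matrix and listed in an attribute rather than
imputed.

## Numerical notes

The breakpoint scan uses cumulative sums for O(n) evaluation of all flank
means and variances. On exactly constant data this shortcut suffers
catastrophic cancellation (variances of order 1e−16 masquerading as signal),
so flank variances below `(1e-9 · scale)^2` and mean differences below
`1e-9 · scale` are snapped to zero, where `scale = max(|x|, 1)`. A zero
pooled variance with a nonzero mean difference is treated as an infinitely
strong split (p = 0), and a zero difference as no split.

# 2. Per-gene survival screens

## Model

For each gene *g*, a Cox proportional-hazards model

\[ h(t \mid x) = h_0(t)\,\exp\{\beta_g\,\text{feature}_g + \gamma'\,z\} \]

where the feature is either normalized log2 expression or the gene's
−1/0/+1 copy-number state entered as a **single ordinal covariate**, and *z*
holds the clinical adjustments (default: race as treatment-coded factor and
metastasis at diagnosis as 0/1). Ties are handled by Efron's method
(survival times at yearly resolution guarantee ties); Breslow is available
behind a flag. p-values are two-sided Wald. A gene is *significant* when its
fit converged and p < α (default 0.05, per screen, deliberately
unadjusted — multiplicity is controlled downstream by the overlap FDR).

Assumptions: proportional hazards per gene, independent censoring,
log-linear effect of the feature. Rows with missing covariates are dropped
listwise with a reported count; constant features are flagged inestimable
rather than fitted; monotone-likelihood fits (perfect separation, detected
by runaway coefficients or standard errors) are flagged non-converged and
excluded from the significant set.

## Kaplan–Meier and log-rank

`km_estimate()` and `logrank()` wrap the standard product-limit estimator
and two-group log-rank test for group-level views (e.g. gain versus rest via
`dichotomize_by_cnv()`). The KM median is undefined (flagged, not NA-guessed)
when the curve never reaches 0.5.

# 3. Integration and the funnel

## Triple signature

A gene enters the signature when all three of these are significant at α:
expression~survival, copy-number~survival, and expression~copy-number
(per-gene OLS of expression on continuous copy number). The gene is
*coherent* when the directions agree: positive expression–copy-number slope
with both survival effects harmful for a gain (`gain_up`), or matching signs
for a deletion (`deletion_down`). Mixed-direction genes are reported but
flagged incoherent.

## Overlap FDR

For an intersection of *k* independent screens over `n_common` genes with
levels α₁…α_k and a direction-coherence requirement that accepts
`2 / 2^k = 2/direction_levels · …` of sign patterns, the expected chance
overlap is

\[ E = n_\text{common} \cdot \prod_i \alpha_i \,/\, \text{direction\_levels} \]

and the reported FDR is `E / observed`, capped at 1. Pairwise replication
uses `direction_levels = 2` (two of four sign patterns agree); the triple
signature uses `direction_levels = 4` (two coherent patterns of eight). This
is an expected-proportion-of-chance-hits estimate, not a BH-style adjusted
p-value; it assumes approximate independence of the screens under the null.

## Fold change versus normal

Tumor-versus-normal differential expression uses the geometric-mean ratio
`base^(mean_t − mean_n)` on log-scale input (base 2 by default), a
Wilcoxon rank-sum test per gene, and Benjamini–Hochberg adjustment. Note the
*arithmetic* mean of a null geometric-mean ratio exceeds 1 (Jensen's
inequality); the log of the fold change is the unbiased-centered quantity.

## Funnel

`apply_funnel()` keeps coherent signature genes whose risk-state prevalence
is at least `prevalence_threshold` (strict boundary: exactly at threshold
passes) and whose curated flags (`targetable_network`,
`inhibitor_available`, `model_available`) are all true, ranked by the
copy-number–survival p-value.

# 4. Chromosome enrichment

Per chromosome: `a` significant genes on the chromosome, `b` its remaining
genes, `c` significant genes elsewhere, `d` the rest. The enrichment odds
ratio is `(a/b)/(c/d)`; the p-value is a one-sided Pearson chi-square (no
continuity correction) in the direction OR > 1:
`z = sign(ad − bc) · sqrt(χ²)`, `p = 1 − Φ(z)`. Depleted chromosomes
therefore have p near 1 by construction. `neg_ln_p` is the natural-log
`−ln p`, computed via `pnorm(..., log.p = TRUE)` so it stays finite when p
underflows double precision. Counts are accumulated in double precision
(the chi-square cross-products overflow 32-bit integers on genome-scale
tables). Grand totals are always computed from the input table. Edge cases:
`a = 0` gives OR 0 with a computed (near-1) p; `b = 0` or `d = 0` gives OR
NA. The bundled `os_chromosome_cnv_counts()` table is a worked example from
a published 85-patient pediatric/AYA osteosarcoma cohort.

# 5. Drug-combination scoring

## Median-effect (Chou–Talalay)

Single-agent checkerboard margins are fit by least squares on the
log-linearized median-effect equation
`log(fa/(1−fa)) = m·log D − m·log Dm`, giving the half-effect dose `Dm` (the
IC50 for growth inhibition) and sigmoidicity `m`. Points with fa exactly 0
or 1 carry no information on the log-odds scale and are excluded with a
count; a non-positive slope is an error (the dose response must be
monotone increasing). The combination index at effect level fa for a dose
pair (d1, d2) is the **non-constant-ratio** form
`CI = d1/Dx_1(fa) + d2/Dx_2(fa)` with `Dx(fa) = Dm·(fa/(1−fa))^(1/m)`,
evaluated by default on fa = 0.20…0.80 in steps of 0.05. Whether the
original CalcuSyn analyses used constant-ratio or non-constant-ratio mode is
not documented; non-constant-ratio (per dose pair) is implemented.

## Bliss independence

Expected combination effect `A + B − A·B` for single-agent
fraction-affected A and B; each cell is scored by
`delta_pct = 100·(observed − expected)`, replicates averaged with the SEM of
the delta reported. Bands: delta < −10 antagonism; −10…10 (inclusive)
additive; 10 < delta ≤ 20 synergistic; > 20 markedly synergistic. The
−10/+10 boundaries belong to Additive and +20 to Synergistic — conservative
toward additivity, since the published band key leaves the boundaries
ambiguous. Raw growth signal is normalized as `1 − treated/vehicle`,
clipped to [0, 1], before any scoring.

# 6. The synthetic generator

## What it emulates

- Discrete copy-number gains (3 or 4 copies) in planted risk genes at a
  configurable prevalence; sporadic survival-neutral gains/deletions in
  background genes (prevalence 0.1) so screens face a realistic null.
- Expression linearly coupled to copy number
  (`baseline + slope·(copies − 2) + noise`).
- Exponential survival under proportional hazards,
  `h = h₀·exp(met_lh·met + Σ_g β_g (expr_g − baseline_g))`, with independent
  exponential censoring tuned to the target censoring fraction.
- Marker tracks with known breakpoints, normal-tissue expression panels, and
  Hill-curve checkerboards with a planted Bliss interaction.

## What it does not emulate

Genomic waviness and GC artifacts, subclonality and tumor purity, correlated
gene–gene expression structure, informative censoring, batch effects, and
chromosome-scale spatial correlation of copy number. Conclusions about those
phenomena cannot be drawn from these simulations.

## Defaults and their rationale

400 patients × 400 genes, three planted risk genes (`RISK1..RISK3`) with
gain prevalence 0.4, expression slope 1.5 log2-units per copy, and
per-unit-expression log hazard 0.7 (HR ≈ 2); baseline hazard 0.15/yr,
censoring 0.3, metastasis prevalence 0.2 at log-HR 1.5; expression noise
SD 0.5, marker noise SD 0.1. One subtlety drove the cohort sizing: because
*every* planted gene's expression enters the hazard, the genes a marginal
per-gene screen omits act as a shared lognormal frailty that attenuates the
remaining genes' marginal effects (a well-known property of
omitted-covariate Cox models). The defaults were chosen by power analysis so
that each planted gene clears the copy-number screen with per-gene Wald
z ≈ 8, making full recovery of the planted signature the overwhelmingly
probable outcome of any run, rather than a coin flip on screen power.

## Determinism

`run_pipeline()` derives per-stage seeds from the single top-level seed via
fixed substream offsets (`(seed·7919 + offset) mod 2^31−1`), so identical
configurations give byte-identical reports and any stage can be re-run in
isolation from the written tables.

# 7. Decisions on under-specified points

- **Adjusted screens by default**: the per-gene screens adjust for race and
  metastasis at diagnosis; pass `adjust = character(0)` for univariate
  screening.
- **Diploid window applies to segment means**, not raw markers, since calls
  are segment-level properties.
- **Overlap-FDR direction levels**: 2 for pairwise replication, 4 for the
  triple signature, from counting coherent sign patterns.
- **Fold change** is the geometric-mean ratio (difference of log-scale
  means, exponentiated), log base 2 by default.
- **Gene↦segment ties** (equal overlap) resolve to the upstream segment,
  deterministically.
- **OR edge cases**: `a = 0` reports OR 0 with its computed one-sided p
  rather than a hard-coded 1.

# 8. Limitations

- The segmentation is a validated stand-in, not a circular-binary-
  segmentation reimplementation; breakpoint behavior on heavy-tailed noise
  is not characterized.
- The overlap FDR assumes independent screens under the null; correlated
  expression would make it optimistic.
- Wald inference in the per-gene Cox screens is asymptotic; at small n or
  few events, use the log-rank path instead.
- The combination index inherits the median-effect model; dose responses
  that are non-monotone or poorly described by a Hill curve will produce
  misleading CIs (inspect the fit's `r` before trusting them).
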