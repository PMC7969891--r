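---
title: "Methods: two-sample Mendelian randomization of iron status on ALS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization of iron status on ALS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironmr)
```

## The causal question and the design

Observational studies have repeatedly associated elevated systemic iron
status with amyotrophic lateral sclerosis (ALS), but such associations are
vulnerable to reverse causation (early disease altering iron biomarkers) and
residual confounding. Two-sample Mendelian randomization (MR) sidesteps both
by using germline variants as instruments: allele assignment is randomized
at conception and fixed before disease onset. `ironmr` implements the
complete summary-statistics workflow for this question, from instrument
selection through sensitivity analysis, with the per-SNP association
estimates of the two source GWAS shipped as plain-text fixtures:

* **Exposure**: 12 SNPs associated at genome-wide significance
  (p < 5×10⁻⁸) with at least one of four iron-status biomarkers — serum
  iron, ferritin (log-transformed), transferrin saturation, transferrin —
  in a European meta-analysis of N = 48,972 (`iron_associations()`).
* **Outcome**: the same 12 SNPs' associations with ALS in a European
  case-control meta-analysis of 20,806 cases and 59,804 controls
  (`als_associations()`).

Ferritin effects stay on the log scale throughout; results for it are
reported per SD of log ferritin, and the pipeline labels it accordingly.

All estimation assumes the three instrumental-variable conditions:
relevance (enforced quantitatively via F statistics), independence from
confounders, and exclusion (no effect on ALS except through the biomarker).
The sensitivity battery (MR-Egger, weighted median, MR-PRESSO,
leave-one-out) probes violations of the third.

## Instrument selection

`significance_filter()`, `ld_prune()` and the set constructors implement
the three selection criteria: genome-wide significance (strict
p < 5×10⁻⁸; the exposure fixture's rows carry no numeric p, their presence
in the source table *is* the significance flag), linkage equilibrium
(pairwise r² ≤ 0.01, pruning greedily by ascending p with input order as
tie-break — the packaged 12 SNPs are already mutually independent, so the
order rule only matters for user data), and instrument strength.

Two analysis modes mirror the study design:

* **Conservative** (`conservative_set()`): SNPs significant for *all four*
  biomarkers whose signs are concordant with a single iron-status axis —
  iron, ferritin and transferrin saturation moving together, transferrin
  opposite (transferrin rises when iron stores fall). The rule is
  direction-symmetric, so relabelling any SNP's effect allele does not
  change membership. On the fixture it returns rs1800562, rs1799945 and
  rs855791, the two *HFE* variants and the *TMPRSS6* variant.
* **Liberal** (`liberal_set()`): all SNPs significant for the requested
  biomarker (5 iron, 6 ferritin, 5 transferrin saturation, 9 transferrin).

Strength uses R² = 2·β²·EAF·(1−EAF), valid for a standardized phenotype
(no allele-count correction is added), and
F = R²(N−k−1)/[(1−R²)k]. Per-SNP F uses k = 1 — the only convention that
reproduces the published per-SNP range of 39 to 3,340 over the 25 nonblank
biomarker-SNP cells of the exposure table — while
`instrument_strength()` also reports the set-level F with k equal to the
set size and R² summed.

## Harmonization

The two source tables happen to print identical allele pairs, so on the
fixtures harmonization is the identity; `harmonize()` nonetheless
implements the full alignment logic needed for arbitrary GWAS exports:
swapped alleles (negate the outcome beta, complement its frequency), strand
complements, and palindromic A/T and C/G SNPs, which allele labels alone
cannot orient. Palindromes are resolved by frequency concordance with a
±0.08 ambiguity window around 0.5: both frequencies outside the window and
on the same side keeps the orientation, opposite sides flips it, either
inside drops the SNP. The window default is conventional practice; the one
packaged palindrome (rs1799945, C/G) sits at frequencies 0.85/0.849, far
from ambiguity, so the fixture result is insensitive to the choice.
Indels and multi-allelic records are dropped rather than guessed.
Exposure/outcome frequency gaps above 0.2 after alignment warn but do not
drop — the fixtures' small cross-study differences (e.g. 0.45 vs 0.433)
pass silently.

## Estimators

All pooled estimates are on the log odds-ratio scale per SD of exposure,
reported as OR with 95% CI `exp(β ± 1.96·se)`.

* **Wald ratio**: β_j = by_j / bx_j, SE by the first-order delta method
  (se_y / |bx_j|). With all fixture F ≥ 39 the exposure-side uncertainty
  is negligible; a second-order SE is available via `second_order = TRUE`.
* **IVW** (`mr_ivw()`): the inverse-variance-weighted mean of Wald ratios,
  weights w_j = bx_j²/se_yj². The default SE is multiplicative
  random-effects — the fixed-effect SE times max(1, √(Q/(J−1))) — which
  never deflates below the fixed-effect SE and leaves the point estimate
  unchanged; `effects_model = "fe"` selects the fixed-effect SE.
* **MR-Egger** (`mr_egger()`): weighted regression of by on bx with a free
  intercept after orienting every instrument to bx ≥ 0 (making the fit
  invariant to allele coding). The intercept estimates average directional
  pleiotropy; the slope is causal under the InSIDE assumption. SEs carry
  the max(1, σ̂) dispersion floor. P-values default to a t reference on
  J−2 df, the original formulation's convention: with three to nine
  instruments the normal reference is materially anti-conservative (on the
  fixture's transferrin-saturation set it would turn a borderline
  intercept, p ≈ 0.07 under t on 3 df, into p ≈ 0.004), and the t
  convention is also what the tooling used for analyses of this design
  reports. `dist = "normal"` restores the normal test.
* **Weighted median** (`mr_weighted_median()`): linear interpolation of
  the cumulative-weight midpoints of the ordered ratios at 0.5; consistent
  when valid instruments carry ≥ 50% of the weight. The SE is a parametric
  bootstrap (default `n_boot = 1000`, `seed = 0`, recorded in the fit) that
  leaves the global RNG state untouched.
* **MR-PRESSO** (`mr_presso()`): observed residual sum of squares against
  leave-one-out IVW expectations, compared with `n_sim` (default 5000,
  minimum 1000) parametric replicates in which both bx and by are
  resampled and the leave-one-out slopes refitted. The global p uses the
  +1 correction, so it is never exactly zero and is bounded below by
  1/(n_sim+1). Per-SNP outlier p-values are Bonferroni-multiplied by J and
  capped at 1; following the published two-stage procedure the outlier
  test fires only when the global test is significant (configurable via
  `outlier_gate`), and the outlier-corrected IVW estimate is reported only
  when something was removed. A signed-distortion summary was considered
  and omitted: the corrected-vs-uncorrected comparison is already exposed
  through the two estimates themselves.

Numerical conventions: zero exposure betas are errors (the Wald ratio is
undefined), exactly equal ratios give Q = 0 and identical fixed/random SEs,
ties in the weighted-median interpolation are handled by ordered
interpolation, and estimator minimums (1 SNP for IVW, 3 for Egger and the
weighted median, 4 for PRESSO, 2 for leave-one-out) are enforced as errors
while the pipeline skips — and records — methods whose minimum exceeds the
harmonized set.

## What the fixture analysis can and cannot reproduce

The study's published conservative IVW ORs (1.00, 0.96, 0.99, 1.04) were
computed from unrounded consortium data; the packaged tables print betas to
two decimals. The package therefore asserts reproduction as properties:
fixture log-ORs within 0.15 of the printed ones, confidence intervals
spanning the null, non-significant Egger intercepts, and a clean PRESSO.
One rounding artifact is worth knowing about: in the liberal transferrin
set the pooled estimate is dominated by rs8177240 (weight 1444 of 1872),
and two-decimal rounding of its outcome beta pushes the IVW and
weighted-median CIs marginally past the null (IVW OR 0.951, 0.909–0.995).
The corresponding acceptance test states the property the unrounded data
satisfy and is allowed to fail on those two rows rather than being widened.
For conservative transferrin the printed OR (1.04) is the reciprocal of
what the printed inputs give (0.961); the package reports per SD increase
of the biomarker itself and leaves reorientation to the reader.

## Power

`mr_power()` implements the standard normal-approximation for a binary
outcome: power = Φ(|ln OR|·√(N·R²·cf·(1−cf)) − z₁₋α/₂), with N the outcome
GWAS size, cf its case fraction and R² the instrument set's summed variance
explained; `detectable_or()` inverts it. At OR = 1 power equals α/2, the
one-tail rejection probability. `power_table()` reports the detectable OR
at 80% power per biomarker — about 1.12 per SD of iron for the
conservative set against this outcome GWAS — quantifying why a null result
here excludes only moderate-to-large effects.

## The synthetic generator and calibration

`simulate_mr_dataset()` emulates exactly the data shape the estimators
consume: true exposure effects γ_j uniform on `bx_range` (default
0.05–0.3 SD, the span of the packaged instruments), allele frequencies
uniform on 0.1–0.9, standard errors from the GWAS sampling formulas at the
source studies' sample sizes (so simulated instruments have realistic
strength), direct effects α_j ~ N(μ_α, σ_α) optionally correlated with γ_j
through a Gaussian copula (`inside_violation`) to break InSIDE, and
observed effects drawn around γ_j and θγ_j + α_j. An optional outlier
shifts one outcome beta in units of its SE, keeping injected contamination
scale-free.

What it does *not* emulate: LD between instruments, winner's-curse bias in
exposure effects selected from the same GWAS, sample overlap between the
two studies, non-normal effect distributions, and binary-trait
non-collapsibility. Passing calibration therefore demonstrates that the
estimators are implemented correctly under their stated assumptions, not
that those assumptions hold in any given application.

`run_calibration_experiment()` drives replicate simulations and reports
per-method rejection rates, bias, RMSE and Monte-Carlo SEs. The packaged
calibration settings — 500 replicates, 30 instruments, IVW under its
default multiplicative random-effects SE — give Monte-Carlo bands of about
±0.02 on a nominal 0.05 rejection rate; the IVW and PRESSO-global type-I
errors land inside [0.03, 0.07], the IVW mean recovers θ = 0.1 within two
Monte-Carlo SEs, and the Egger intercept recovers μ_α = 0.02 (σ_α = 0.01,
a small realistic spread) within two Monte-Carlo SEs. At small instrument
counts (J ≈ 10) the PRESSO global test is mildly conservative — a known
property of the simulation construction, in which the null distribution
carries exposure-resampling noise that the observed statistic does not.

## Interfaces and reproducibility

Everything is callable as pipe-friendly functions returning tibbles;
fitted objects carry `tidy()`/`glance()` methods and the analysis object
has an `autoplot()` forest plot. `run_full_analysis()` orchestrates the
whole study (selection → strength → harmonization → estimators →
diagnostics), writes TSVs plus a JSON manifest when given `out_dir`, and is
byte-reproducible under a fixed seed; the published sensitivity re-run
that removes rs1800562 (whose iron-raising allele also lowers LDL) is
`exclude_snps = "rs1800562"`. No multiplicity correction is applied across
biomarkers, matching the source study's per-biomarker reporting.

## Limitations

European-ancestry summary data only; no proxy-SNP search, liftover or
LD-from-reference computation (pairwise r² is an input); the weighted
median and PRESSO are simulation-based, so their SEs/p-values carry seed
metadata rather than closed forms; and a null MR here speaks to lifetime
average iron status and ALS *incidence*, not to iron's role in progression.
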