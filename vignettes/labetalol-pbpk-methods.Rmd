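---
title: "Methods: whole-body PBPK modeling of labetalol in healthy and diseased populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body PBPK modeling of labetalol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

labetapbpk implements a whole-body PBPK model for labetalol with
perfusion-limited tissues. For each organ $i$ with volume $V_i$, blood flow
$Q_i$ and tissue:plasma partition coefficient $K_{p,i}$,

$$V_i \frac{dC_i}{dt} = Q_i \left(C_\mathrm{art} - \frac{C_i}{K_{p,i}}\right),$$

with the lung in series with the cardiac output between the venous and
arterial pools. The liver receives the hepatic arterial flow plus the portal
outflow of the gut compartment and eliminates drug at
$f_u\,CL_\mathrm{int}\,C_\mathrm{liver}/K_{p,\mathrm{liver}}$; at steady
state this reproduces the well-stirred organ clearance
$CL_h = Q_h f_u CL_\mathrm{int}/(Q_h + f_u CL_\mathrm{int})$. The kidney
eliminates with an extraction-corrected intrinsic rate chosen so the
systemic renal clearance equals its target exactly, which makes the linear
identity $AUC_{0-\infty} = \mathrm{Dose}/CL$ hold to the precision of the
integrator — this identity is the engine's primary test oracle.

Oral doses enter a gastric compartment that empties with first-order
half-time equal to the gastric emptying time (healthy default 15 min),
followed by seven intestinal transit segments in series whose total mean
transit equals the small-intestine transit time (default 3.3 h). Each
segment absorbs drug at
$k_a = P_\mathrm{eff} \cdot (2/r) \cdot A_\mathrm{mucosa}$, with effective
permeability $P_\mathrm{eff} = 4.67\times10^{-5}$ cm/min, lumen radius
$r = 1.25$ cm and a mucosal amplification factor of 600
(plicae × villi × microvilli, 3 × 10 × 20), giving $k_a \approx 2.7\,h^{-1}$
and near-complete absorption — consistent with a BCS class 1 drug that is
described clinically as readily absorbed with ~25% absolute bioavailability
set by first pass. Absorbed drug enters the gut tissue and reaches the liver
through the portal flow, so first-pass extraction is mechanistic rather than
imposed: the healthy oral bioavailability that *emerges* from the model
(~0.32 in the test suite) is an output, not an input.

Because clearances and transit are linear, the entire system is a linear
time-invariant ODE with piecewise-constant infusion input. The engine
therefore propagates the state **exactly** with matrix exponentials over
each constant-input interval (`Matrix::expm`), caching the propagator per
step size. This is unconditionally stable and free of truncation error; the
`rtol`/`atol` arguments are retained for interface compatibility and guard
the (theoretically impossible, numerically tiny) negative states. Mass
balance closes to ~1e-13 in the test suite. The output grid is refined
tenfold through each infusion and its immediate washout so that the
*trapezoidal integral of the sampled profile* resolves the venous peak; this
affects only sampling, never the states.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| total body clearance | 15 | mL/min/kg | published model input; split into renal + hepatic |
| fraction unbound | 0.45 | – | published; disease scales the *bound* fraction |
| log P / pKa | 2.79 / 9.38 | – | partition scheme input (log D at pH 7.4, monoprotic base) |
| Vss calibration target | 11 | L/kg | midpoint of the clinical 9–15.7 L/kg window |
| GFR (healthy) | 120 | mL/min | conventional adult value; baseline for CKD deltas |
| hematocrit (healthy) | 0.45 | – | conventional; carried for disease tables and manifests |
| GET / SITT (healthy) | 15 min / 3.3 h | | conventional GI transit baselines |
| infusion duration | 0.0833 | h | 5-min slow IV injection; an explicit knob (see below) |
| t_end | 8 (IV) / 12 (oral) | h | matches the magnitude of the published truncated AUCs |
| intestinal segments K | 7 | – | transit-compartment convention |

Composition-based partition schemes underpredict the distribution of
lysosomally trapped bases like labetalol (raw implied Vss ≈ 1.8 L/kg), so a
single global multiplicative factor on all $K_p$ maps the implied Vss onto
the clinical window. The calibration is closed-form (Vss is affine in the
scale) and is verified against a bisection oracle in the tests.

The clearance split is deliberately conservative: renal clearance of
*unchanged* drug is glomerular filtration of unbound drug
($f_u \cdot GFR = 3.24$ L/h at the healthy reference), and the remaining
59.76 L/h is hepatic, consistent with glucuronidation being the dominant
elimination route for the parent drug while the large urinary recovery
reported clinically refers to drug-related material including conjugates.
This choice has a consequence discussed under *Known limitations*.

Two published quantities — "specific organ permeability 0.1 L/min" and
"specific clearance 6 L/h" — are simulator-internal optimized values whose
operational meaning is not reproducible outside that platform; they are
stored as metadata and do not drive the engine.

## Disease models

Child-Pugh classes apply a monotone modifier table (liver volume 0.9/0.8/0.7,
hematocrit 0.41/0.38/0.35, protein-binding factor 0.95/0.90/0.85, GFR
100/70/40 mL/min, hepatic intrinsic clearance 0.60/0.40/0.25 for A/B/C; a
liver-flow factor slot ships at 1.0). The magnitudes follow published
cirrhosis PBPK parameterizations; because no single printed source fixes
them, every cirrhosis acceptance claim in this package is an *ordering*
claim, never an absolute-value claim.

Severe CKD applies the five published changes exactly: GET 24.375 min,
SITT 2.94 h, hematocrit 0.398, protein binding factor 0.843 (on the bound
fraction: $f_{u,\mathrm{dis}} = 1 - 0.843\,(1-f_u) = 0.536$), and GFR 11.
The printed GFR unit (mL/min/kg) would exceed any healthy GFR and is treated
as a typographical artifact; the default reading is 11 mL/min absolute, the
literal per-kg reading is available via `gfr_unit = "mL/min/kg"`, both are
tested, and the active interpretation is recorded in every run manifest.
Moderate CKD has no printed values and interpolates midway between healthy
and severe (configurable). Disease application requires a healthy baseline
and refuses to stack (applying modifiers twice is an error, by design).

## The synthetic-data generator

The generator emulates the *structure* of the clinical datasets the analysis
assumes: sparse sampling (5–90 min dense, then hourly), mean-one
multiplicative log-normal residual error (default CV 20%, a typical
bioanalytical plus biological variability), and small cohorts with the
published age/weight/sex descriptors. It does not emulate assay
quantification limits, dropout, dosing-history errors or between-subject
variability beyond body-weight scaling — so a green parameter-recovery test
establishes that the NCA pipeline is consistent and approximately unbiased
under the stated error model, not that it is robust to real bioanalytical
pathologies.

Two recovery findings are worth recording. First, with the post-dose
sampling grid (first sample 5 min after dosing) the cohort NCA clearance
carries a systematic ≈ +10% bias from the missing rising limb of the IV
peak; this is a property of the sampling design, sits inside the 15%
recovery band, and was left as-is. Second, a 3-point terminal regression is
fine for dense noise-free profiles but leaves the terminal slope inestimable
in ~40% of CV-20% synthetic subjects (the decay across a 2-h window is
smaller than the noise), so the recovery experiment uses a 12-point terminal
window and summarizes over subjects with an estimable terminal phase,
reporting the estimable count — standard sparse-data NCA practice.

## Numerical and statistical conventions

- Linear trapezoid AUC by default; the lin-log rule is available by flag.
- $\lambda_z$ by unweighted log-linear regression on the last 3 positive
  samples (configurable), flagged when $R^2 < 0.9$ or inestimable.
- Percentiles use linear interpolation between order statistics (R type 7);
  the 1..100 check value is p5 = 5.95, p95 = 95.05.
- Median confidence intervals by seeded percentile bootstrap (default
  10,000 resamples) because the published CI method is unstated — and some
  printed intervals exclude their own medians, so no numeric claim is made
  against them.
- Two-fold flags are inclusive at both boundaries.
- AFE has two modes: full-precision ratios, and "as printed" (the published
  rounded ratio column), because the source's own AFE values for the oral
  parameters (1.193, 0.84) reproduce only from its printed ratios. The mode
  is recorded on the qualification table. Note the printed ratios are not
  always half-up roundings of the printed observed/predicted pairs.
- All randomness (population sampling, residual error, bootstrap) flows
  through explicit seeds and restores the caller's RNG state.
- Scenario configs and run manifests are JSON (`jsonlite`); no YAML parser
  is part of the guaranteed dependency stack.

## Known limitations

**CKD severity ordering (a deliberate red test).** The published
box-whisker comparison shows exposure rising from healthy through moderate
to severe renal failure. Under this package's stated clearance split that
ordering cannot emerge: labetalol's filtration clearance is only ~5% of
total (3.24 of 63 L/h), and the uremic fall in protein binding *raises*
the free fraction, which raises the well-stirred hepatic clearance by more
than the GFR collapse removes. Net total clearance is nearly flat (within
~1%), and the healthy → moderate step inverts. Reproducing the published
+28% AUC rise would require suppressing nonrenal (hepatic/UGT) clearance in
uremia — a real phenomenon, but not among the five printed CKD parameters,
and inventing a factor for it would turn an ordering claim into a fitted
result. The acceptance test for the CKD leg therefore asserts the published
direction and fails, with this section as the analysis. The
`hepatic_intrinsic_clearance_factor` field exists on the modifier object for
users who wish to impose a literature value.

**IV Cmax and the infusion convention.** The venous peak at the end of a
5-minute infusion is an order of magnitude above the published "observed
Cmax" values, which are first-sample concentrations measured after the
(very fast, CO-driven) distribution phase; by 15 minutes the simulated
venous concentration is in the observed range. Peak comparisons for IV
dosing are therefore meaningful only once an infusion duration and sampling
convention are fixed; both are explicit configuration knobs surfaced in the
run manifest, and IV Cmax is not an acceptance quantity.

**Terminal phase.** Calibrating all $K_p$ with one global factor inflates
the adipose coefficient, producing a model terminal half-life (~22 h)
longer than the clinically reported 5.5 h while leaving truncated AUCs in
the published range. Oracle tests that need the full AUC integrate to 240 h
(>10 model half-lives).

**Other simplifications.** Blood:plasma concentration ratio fixed at 1 (no
published value); hematocrit therefore has no kinetic effect and is carried
for disease bookkeeping. No saturable kinetics, transporters, metabolites,
enterohepatic recirculation, or multiple-dose regimens (all modeled studies
are single-dose). Population variability is body-weight scaling plus
uniform demographics only — the published ranges give no basis for richer
covariance. Drug–drug and food interactions are exposed only as the
clearance/bioavailability hooks implicit in the parameter objects, with no
quantitative claims.
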