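---
title: "In silico screening of prognostic scarring biomarkers: models and methods"
author: "scarscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico screening of prognostic scarring biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Hypertrophic scarring is a common outcome of traumatic and surgical skin
wounds, characterized by excess collagen deposition, and there are few
validated molecular markers that *predict* — weeks before the scar is
fully developed — whether a healing wound will scar pathologically.
Prospective human studies of candidate markers are expensive and slow, so
a useful complement is to screen candidates *in silico*: simulate many
plausible wound-healing trajectories, label each simulated wound's
outcome, and ask which measurable wound proteins separate the
prospectively-normal from the prospectively-pathological wounds at early
time points.

`scarscreen` implements that strategy as a reusable, tested pipeline with
four stages:

1. **Virtual cohort** — simulate a kinetic model of wound healing once
   with default parameters (the normal-healing reference) and thousands of
   times with every parameter independently perturbed within a 0.5–2×
   range of its default, emulating inter-individual variability.
2. **Outcome classification** — compute day-40 collagen and fibroblast
   fold changes of each simulation against the reference and label each
   wound normal (both ≤ 1), mild pathological (both in [5, 10]), severe
   pathological (both > 10) or excluded (anything else, e.g. fold changes
   in the ambiguous 1–5 range). A collagen-only binary label
   (pathological iff collagen fold change > 10) over *all* simulations
   feeds the regression stage.
3. **Overlap screening** — for each screened wound protein, day and
   outcome-group pair, build 50-bin concentration histograms and compute
   the Bhattacharyya coefficient BC = Σᵢ √(pᵢqᵢ) ∈ [0, 1] between the
   normal group and each pathological group; small BC means the protein's
   concentration separates the groups. Day-40 screens identify
   *diagnostic* markers; day-7/14/21 screens identify *prognostic*
   candidates.
4. **Predictive evaluation** — logistic-regression panels over the three
   prognostic markers (all 7 non-empty subsets) at days 14 and 21, each
   with its ROC curve, Mann–Whitney AUC, DeLong 95% CI, all 21 pairwise
   DeLong paired AUC tests per day, and stratified tenfold
   cross-validation of the triple panel with pooled out-of-fold
   probabilities.

## The reference surrogate model

The pipeline is model-agnostic: any `kinetic_model()` that names its
states and positive parameters, supplies an initial state and a
derivative function, and maps the collagen, fibroblast and screened-protein
roles can be plugged in. The package ships a twelve-state reference
surrogate capturing the canonical coupling structure of injury-initiated
healing:

* platelets `P` decay after injury (`P(0) = 1`, the injury signal) and
  recruit inflammatory cells `I`, amplified by CXCL8 (`C8`) and inhibited
  by IL-10 (`I10`);
* repair macrophages `M` differentiate from `I` and produce IL-10 and
  TGF-β (`T`);
* fibroblasts `F` are recruited by TGF-β, grow logistically with capacity
  `Fmax` and die at rate `aF`; they produce TGF-β, TIMP-1 (`T1`),
  fibronectin (`FN`) and collagen (`COL`);
* collagen is produced at rate `pC·F·T/(KT+T)` and degraded by MMP-9
  (`M9`) with TIMP-1 inhibition, `dC·COL·M9/(1 + T1/KT1)`;
* IL-10 enhances TIMP-1 production (factor `1 + e10·I10/(K10e+I10)`) and
  suppresses IL-6 (`C6`) production and inflammatory recruitment.

Every loss term is proportional to its own state, so trajectories stay
non-negative; all states except platelets start at zero, so the all-zero
state is a fixed point (no constitutive production). Concentrations are in
arbitrary units — classification and screening only use fold changes and
within-cohort distributions, so absolute units are immaterial. The system
is a delay-free ODE model integrated with `deSolve::lsoda` at relative
tolerance 1e-6 and sampled on the daily grid t = 1, …, 40 (the t = 0
initial state is stored separately and never screened; whether a published
40-point grid includes day 0 is ambiguous, and day 1–40 is this package's
convention). A plug-in model with explicit delays would need a different
integrator contract and is out of scope; the `rhs(t, state, params)`
signature is where a lagged-state argument would attach.

## Calibration of the shipped defaults

The surrogate's coupling structure is fixed, but its ~30 default rate
constants are a calibration choice. They were frozen after a seeded
constrained random search (`calibrate_defaults()`) requiring, at the
defaults (see `check_calibration()`):

* **C1** inflammation resolves: `I(40) < 0.1 · max I(t)`;
* **C2** collagen plateaus: < 5% relative change between days 35 and 40;
* **C3** `aF/2 < gF < aF`: normal healing resolves fibroblasts, while
  halving apoptosis (the pathological scenario) flips net growth positive;
* **C4** the two-parameter pathological scenario (`aF/2`, `1.5·pC`)
  produces ≥ 5-fold day-40 collagen and fibroblast changes;
* **C5** a seeded 5,000-draw cohort populates the normal, mild and severe
  classes with ≥ 0.5% of draws each and excludes < 90%.

Within those constraints, the defaults were additionally chosen so the
demo cohort exhibits the qualitative behaviour the screening method is
designed to surface: the prognostic trio (IL-10, TIMP-1, fibronectin
analogs) separates normal from severe wounds progressively better from
day 7 through day 21, and day-21 regression panels outperform their
day-14 counterparts. Two structural choices matter here and are worth
recording. First, fibroblast growth and apoptosis rates are large in
absolute terms, so pathological ("runaway") fibroblast trajectories
saturate at the carrying capacity well before day 40; this keeps the
day-40 outcome from being dominated entirely by the growth-apoptosis race
and lets production, TGF-β drive and degradation parameters shape the
collagen outcome. Second, IL-10's two causal routes to collagen — via
enhanced TIMP-1 (inhibiting MMP-9-mediated degradation) and via
suppression of the late inflammatory tail (reducing MMP-9 supply) — act
late in the simulation, and macrophage (hence IL-10) kinetics are slow,
so IL-10's association with the outcome strengthens from day 7 to day 21,
as required of a prognostic rather than an instantaneous marker. In this
surrogate the IL-10 analog's *direction* of association arises from these
two routes jointly; the screening method itself is direction-agnostic
(it measures distribution overlap, not signed fold change).

One honest caveat: because IL-10's rate equation is driven only by the
inflammatory cascade (there is no fibroblast input to it in this model),
its achievable separation between normal and severe outcomes is weak —
single-marker AUCs around 0.52–0.55 — and its Bhattacharyya-coefficient
decrements from day 7 to 14 to 21, while real in expectation, are of the
same order (~1e-3) as 50-bin histogram sampling noise at 5,000 draws. The
strict day-by-day ordering of the IL-10 coefficients therefore holds at
the packaged demo seed but should not be expected to survive arbitrary
reseeding, unlike the TIMP-1 and fibronectin orderings and all the
AUC-based panel orderings, which are comfortably seed-robust. A surrogate
in which fibroblast-derived IL-10 production fed back into the marker
(as is biologically documented for skin cells) would strengthen this
channel; that coupling is deliberately outside this model's fixed
equation set.

## Statistical methods and numerical conventions

**Parameter sampling.** Each parameter is drawn independently and
uniformly on [θ/2, 2θ] (a log-uniform option exists with the same
bounds). Uniform-on-the-interval is the minimal reading of
"randomly selected within a 0.5–2-fold range"; no correlation structure
is imposed. Draws are a deterministic function of `(defaults, n, seed)`.

**Classification thresholds.** The literal inequalities are used with no
epsilon slack: normal requires both fold changes ≤ 1, mild both in
[5, 10] inclusive, severe both strictly > 10. Mixed pairs (e.g. collagen
12, fibroblast 4) are excluded: the class rules are stated jointly on
both variables, and anything not matching one of the three rules is
ambiguous by construction. Boundary cases follow: (10, 10) is mild, not
severe. The binary rule is collagen-only and strict (> 10).

**Histograms and overlap.** Plotting histograms bin each group over its
own min–max range (50 bins), matching the usual presentation of
percentage-of-simulations curves. The Bhattacharyya coefficient, however,
is only defined on a *shared* partition, so overlap computations re-bin
both groups over the pooled min–max of the two groups being compared.
These are deliberately distinct artifacts. Degenerate ranges (min = max)
are widened by a relative epsilon so single-valued groups remain
representable. "X% smaller overlap on day d than day 7" is defined as the
relative BC reduction `100·(BC₇ − BC_d)/BC₇`; per-day candidate rankings
average the normal-vs-mild and normal-vs-severe coefficients, and both
raw coefficients are always reported so users can re-rank.

**Regression and ROC.** Marker concentrations are min–max normalized per
day before fitting — an affine reparameterization that changes
coefficients but provably not fitted probabilities or AUCs; it is done
only so coefficients are comparable across markers. Fits use
`stats::glm` (binomial, IRLS, tolerance 1e-8); complete separation is
detected and flagged rather than silently reported. AUC is the
Mann–Whitney statistic with midranks for ties, identical to the
trapezoidal area under the empirical ROC. AUC variance, confidence
intervals (Wald on the AUC scale, clipped to [0, 1]) and paired AUC tests
use DeLong placement values; degenerate cases (perfect separation,
identical scores) are flagged, with `p = 1` by convention for a zero
difference with zero variance. The 21 pairwise DeLong p-values per day
are reported raw, without multiplicity correction — a documented choice,
since the panel comparison is descriptive here. Cross-validation is
stratified by outcome with a fixed seed; the CV ROC is computed on the
*pooled* out-of-fold probabilities, not averaged per fold.

**Failure handling.** Integration failures (non-finite values, blow-up,
values below −1e-9) are recorded per draw and excluded, never re-drawn;
a > 1% failure rate raises a warning. Values in (−1e-9, 0) are clamped to
zero as integrator round-off.

## What the synthetic cohort does and does not emulate

The generator emulates: graded scarring severity arising from continuous
parameter variation; a mixture of resolving and collagen-elevated
outcomes; markers whose early concentrations carry genuine (causal,
model-mediated) information about the late outcome; and realistic
nuisance variation, since all ~30 parameters vary, not only the
outcome-driving ones. It does not emulate: measurement noise or assay
variability (concentrations are exact model outputs); correlated
parameter variation across individuals; delayed regulatory interactions;
spatial wound structure; or the 28-species richness of full wound-healing
models — the surrogate has one collagen species and seven screened
proteins. Passing the packaged checks therefore demonstrates that the
*pipeline* correctly discovers and quantifies prognostic structure where
it exists; it does not validate any specific clinical marker. AUC values
obtained on this synthetic cohort depend on the calibration and should
not be quoted as clinical performance estimates.

## Problem sizes

The packaged demo profile simulates 5,000 draws (master seed 4242), a
desk-scale cohort that keeps the full pipeline in the minutes range on a
single CPU while leaving hundreds of draws in the rarest outcome class;
cohort sizes into the hundreds of thousands are a config change
(`n_simulations`). Unit tests use smaller seeded cohorts (400–800 draws)
where only structure, not precision, is under test.

## Running the pipeline

```{r}
library(scarscreen)
cfg <- system.file("extdata", "demo_config.yaml", package = "scarscreen")
report <- run_pipeline(cfg, out_dir = "results/demo")
report
```

The numbered scripts under `analysis/` run the same four stages
step-by-step with intermediate artifacts on disk, and
`scripts/acceptance.R` recomputes the headline quantities from scratch
into a flat JSON.

## Known limitations

* The surrogate is a calibrated stand-in with invented rate constants; it
  reproduces qualitative healing behaviour, not any measured time course.
* Only two pathological outcome groups (mild, severe) are screened
  against normal; the excluded class is discarded by design in the
  overlap stage, which mirrors the screening strategy but discards
  borderline phenotypes.
* The DeLong test's normal approximation is used at all sample sizes; at
  very small cohorts its type-I error calibration degrades.
* Parallel execution is not implemented; cohort simulation is a simple
  deterministic loop (results are independent of any execution order by
  construction).
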