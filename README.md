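# scarscreen

In silico screening of prognostic biomarkers of pathological scarring in
skin wounds.

Hypertrophic scars — raised, fibrotic scars with excess collagen — are a
common outcome of traumatic and surgical skin wounds, and there are
essentially no molecular markers in clinical use that *predict*, weeks in
advance, whether a healing wound will scar pathologically. `scarscreen`
implements a computational strategy for discovering candidate prognostic
markers: simulate a large virtual cohort of wound-healing trajectories
from a kinetic model under random parameter perturbation, classify each
simulated wound's outcome, screen wound proteins for early-time-point
separation between outcome groups, and quantify predictive accuracy with
regression panels.

The package is aimed at computational/systems biologists studying wound
healing and fibrosis, and more generally at anyone who wants a tested,
seeded, reproducible implementation of the virtual-cohort biomarker
screening pattern with a pluggable kinetic model.

## Method at its core

1. **Virtual cohort.** A kinetic model (a shipped 12-state surrogate of
   injury-initiated healing: platelets, inflammatory cells, macrophages,
   fibroblasts, TGF-β, IL-6, CXCL8, IL-10, MMP-9, TIMP-1, fibronectin,
   collagen) is simulated daily over 40 days with default parameters
   (normal-healing reference) and for *n* draws with every parameter θ
   sampled uniformly on [θ/2, 2θ].
2. **Outcome labels.** Day-40 fold changes versus the reference,
   FC = x(40)/x_ref(40), for collagen and fibroblasts give the four-way
   class — normal (both ≤ 1), mild (both ∈ [5, 10]), severe (both > 10),
   excluded otherwise — and the collagen-only binary label
   (pathological ⇔ FC_col > 10).
3. **Overlap screen.** Per protein, day and group pair, 50-bin
   concentration histograms on shared support give the Bhattacharyya
   coefficient BC = Σᵢ√(pᵢqᵢ) ∈ [0, 1]; low BC = strong separation.
   Day 40 ranks *diagnostic* markers, days 7/14/21 rank *prognostic*
   candidates.
4. **Predictive evaluation.** Logistic-regression panels over the
   IL-10/TIMP-1/fibronectin analogs (3 singles, 3 pairs, 1 triple) at
   days 14 and 21, each with ROC, Mann–Whitney AUC, DeLong 95% CI; all 21
   pairwise DeLong paired AUC tests per day; stratified tenfold
   cross-validation of the triple panel on pooled out-of-fold
   probabilities.

See `vignettes/biomarker-screening-methods.Rmd` for the model equations,
calibration constraints, statistical conventions and limitations.

## Worked example

```r
library(scarscreen)

cfg <- system.file("extdata", "demo_config.yaml", package = "scarscreen")
report <- run_pipeline(cfg, out_dir = "results/demo")
report
```

This simulates the demo cohort (5,000 draws, seed 4242) and prints, among
other things (abridged output, see `results/demo/` for the full tables):

```
class counts: normal=2213, mild=42, severe=1179, excluded=1566
top-ranked prognostic candidates per day:
 day       role rank protein mean_bc
  21 prognostic    1       T   0.246
  21 prognostic    2      FN   0.326
  21 prognostic    3      T1   0.385
panel AUCs:
 day     panel n_markers   auc
  14 I10+T1+FN         3 0.948
  21 I10+T1+FN         3 0.977
day21 CV (I10+T1+FN): AUC 0.977 [0.973, 0.980]
```

Reading this: about 44% of the perturbed simulations heal normally, a
graded minority scar mildly or severely, and ~31% fall in the ambiguous
1–5 fold-change band that the screen excludes. The TGF-β, fibronectin and
TIMP-1 analogs show the least day-21 normal-vs-pathological distribution
overlap (smallest mean Bhattacharyya coefficients); day-21 concentrations
predict the day-40 binary outcome better than day-14 concentrations for
every panel; and the triple-marker panel's cross-validated AUC is within
a few ten-thousandths of its in-sample AUC, i.e. the panel generalizes
within the cohort.

The same stages can be run step-by-step with intermediate artifacts via
the numbered scripts:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_classify_outcomes.R
Rscript analysis/03_overlap_screen.R
Rscript analysis/04_predictive_accuracy.R
```

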