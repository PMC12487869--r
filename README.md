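# petkin

Tracer-kinetic quantification of dynamic PET studies with arterial blood
sampling, built for slowly equilibrating reversible radiotracers — the
regime where the tissue clearance half-life (ln 2 / k₂) rivals the scan
length, no reference region exists, and every binding endpoint must come
from full compartmental modeling against a metabolite-corrected arterial
input function. It is aimed at PET modelers evaluating novel radiotracers
(e.g. neurotransmitter-transporter ligands in nonhuman primates) and at
anyone who needs a tested, scriptable implementation of the standard
blood-input quantification chain.

## What it computes

* **Input function** — total plasma and whole blood fitted with a sum of
  decaying exponentials (piecewise-linear pre-peak rise), parent fraction
  fitted with an integrated-gamma model
  PF(t) = 1 − a·G(t; α, β); the model input is the product
  C_p(t) = plasma(t) × PF(t).
* **Compartment models** — 1TCM, reversible 2TCM (k₄ > 0) and
  irreversible 2TiCM (k₄ = 0), each with a fractional blood-volume term
  V_b and a time delay Δt estimated from the first 10 min of the
  whole-brain curve:
  C_model(t) = (1 − V_b)·C_T(t) + V_b·C_wb(t − Δt).
  Weighted bounded Levenberg–Marquardt with a fixed multistart design;
  covariance from the Gauss–Newton Hessian; macroparameters
  V_T = K₁/k₂ (1TCM), V_T = (K₁/k₂)(1 + k₃/k₄) (2TCM),
  K_i = K₁k₃/(k₂+k₃) (2TiCM).
* **Model selection** — AIC = n·ln(WRSS/n) + 2p, nested F-tests, and
  primary-parameter rSE reliability (≤ 10 %).
* **Binding endpoints** — Lassen occupancy plots (slope = occupancy,
  x-intercept = V_ND), BP_ND = V_T/V_ND − 1, and Guo plots for
  cross-tracer affinity ratios.
* **Protocol design** — time-stability (scan-shortening) and rest-period
  ("broken scan") analyses by truncated/gapped refits.
* **Synthetic studies** — a generator with complete ground truth
  (45-frame/180-min schedule, 11 regions, 175-min clearance half-life,
  paired baseline/blocking arms sharing one occupancy and V_ND), used by
  the whole validation suite.

## Worked example

Simulate a one-animal paired baseline/blocking study at the default
(study-like) conditions, quantify it, and estimate occupancy:

```r
library(petkin)
cfg <- synthetic_study_config(seed = 7, n_animals = 1)
run_simulate(cfg, "demo_study")
man <- read_manifest("demo_study/manifest.csv")
res <- run_quantify(man, models = "1TCM")
res$scans[["m01_baseline"]]$fits[["occipital"]][["1TCM"]]
#> <tissue_fit> roi 'occipital' 1TCM: WRSS=12.03, AIC=-53.38
#>   K1=0.01805 mL/min/cm3 (rSE 1.5%), k2=0.004096 (rSE 5.8%), V_b=0.0392, delta_t=0.012
#>   V_T=4.406 mL/cm3 (rSE 4.5%), clearance half-life 169.2 min
```

The occipital K₁ of 18.1 µL·min⁻¹·cm⁻³ and V_T of 4.41 mL/cm³ recover the
generating values (18.0 and 4.55) within their standard errors; the
169-min clearance half-life shows why 180-min scans are barely long
enough for this tracer class.

```r
occ <- run_occupancy(res)
occ
#> <occupancy_report> (1TCM V_T) 1 animal/tracer group(s)
#>          group animal_id    tracer occupancy occupancy_se     V_ND   V_ND_se n_rois
#>  m01 synthetic       m01 synthetic 0.6419435   0.03639871 1.027415 0.1359572     11
#>   single animal: across-animal SD omitted
occ$bpnd[occ$bpnd$roi %in% c("occipital", "thalamus"), ]
#>        roi V_T_baseline V_T_blocking BP_ND_baseline BP_ND_blocking
#>  occipital         4.41         2.29          3.289          1.228
#>   thalamus         1.96         1.39          0.906          0.349
```

The Lassen regression over the 11 regions estimates 64 % occupancy
(truth for this animal: 65 %) with V_ND = 1.03 mL/cm³ (truth 0.88, n = 1
animal at the study noise level); BP_ND is then tabulated per region for
both conditions against the estimated V_ND.

A thin command-line wrapper with `simulate` / `quantify` / `occupancy` /
`stability` subcommands is installed at `inst/scripts/petkin.R`.

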