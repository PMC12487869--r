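---
title: "Compartment-model quantification of slow-kinetic PET radiotracers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-model quantification of slow-kinetic PET radiotracers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petkin)
```

# Scope

petkin quantifies dynamic PET studies of reversible, slowly equilibrating
radiotracers measured with arterial blood sampling. It covers the full
chain from discrete blood samples to binding endpoints:

1. construction of a metabolite-corrected arterial plasma input function,
2. compartment-model fitting (1TCM, reversible 2TCM, irreversible 2TiCM)
   with a fractional blood-volume term and a blood-to-tissue time delay,
3. model selection by F-test, AIC and parameter reliability,
4. occupancy and nondisplaceable distribution volume from Lassen plots,
   binding potential (BP~ND~), and cross-tracer comparison by Guo plots,
5. scan-shortening (time-stability) and rest-period analyses, and
6. a synthetic-study generator with complete ground truth, so that every
   stage is testable without any scanner data.

The package was designed around the regime where these questions are
hardest: tracers whose tissue clearance half-life (ln 2 / k~2~, about
175 min by default) is comparable to the scan length, so equilibrium is
never reached within a 180-min acquisition.

# The input function

Arterial samples give whole-blood and plasma activity at discrete times.
The continuous total-plasma model is piecewise linear from (0, 0) through
the measured pre-peak samples and a sum of 1-3 decaying exponentials
fitted to the samples from the peak onward (amplitudes referenced to
t = 0). The junction value at the peak time is the fitted model value, so
the curve is continuous by construction. Fitting the pre-peak rise by
exact interpolation rather than by a parametric form is a deliberate
choice: with only a handful of samples on the rise there is nothing to
estimate, and interpolation guarantees the bolus mass seen by the model
matches the data. The whole-blood curve (needed for the vascular term)
uses the same machinery.

The unmetabolized parent fraction follows the integrated-gamma family

$$\mathrm{PF}(t) = 1 - a \, G(t;\, \alpha, \beta),$$

with $G$ the cumulative gamma distribution. This form starts at 1, is
monotone non-increasing regardless of noise in the measured fractions,
and levels off at $1 - a$, matching slow peripheral metabolism in which a
fifth or so of the tracer is eventually metabolized. The exact
parameterization of published integrated-gamma metabolite models varies;
the CDF form used here is a documented choice within that family that
satisfies all of the constraints the application needs. The default
generator truth ($a = 0.382$, $\alpha = 0.326$, $\beta = 6.87\times
10^{-4}$/min) passes through parent fractions 0.88, 0.83 and 0.79 at 30,
90 and 180 min.

The model input is the pointwise product
$C_p(t) = \text{plasma}(t)\times \mathrm{PF}(t)$; the plasma free
fraction f~p~ is carried as scan metadata (it is measured externally and
never fitted).

# Tissue models

All three compartment models share one impulse-response family. With
$s = k_2 + k_3 + k_4$ and
$\alpha_{1,2} = \tfrac12\!\left[s \mp \sqrt{s^2 - 4k_2k_4}\right]$, the
tissue response to the delayed input is

$$C_T(t) = K_1\left[\phi_1 e^{-\alpha_1 t} + \phi_2 e^{-\alpha_2 t}\right]
  \ast C_p(t - \Delta t),$$

which reduces to $K_1 e^{-k_2 t} \ast C_p$ for the 1TCM and to the
$k_4 = 0$ limit (one integrating term, $\alpha_1 = 0$) for the 2TiCM. The
measured concentration adds the vascular term:

$$C_\text{model}(t) = (1 - V_b)\,C_T(t) + V_b\,C_{wb}(t - \Delta t).$$

Whether the vascular term should also be delayed is ambiguous in common
practice; here the whole-blood curve is shifted by the same $\Delta t$ as
plasma, since both are observed at the same sampling site.

Macroparameters: $V_T = K_1/k_2$ (1TCM),
$V_T = (K_1/k_2)(1 + k_3/k_4)$ (2TCM),
$K_i = K_1 k_3/(k_2+k_3)$ (2TiCM), clearance half-life
$\ln 2 / k_2$. K~1~ is stored in mL·min^-1^·cm^-3^ and reported
additionally in µL·min^-1^·cm^-3^ (values are small for these tracers).

## Numerical scheme

Convolution is computed analytically for a piecewise-linear input sampled
on a uniform fine grid (default step 0.05 min), using the exact
per-segment integral of $e^{-\lambda u}$ against a linear segment and a
one-step recursion. This is exact for the model family given the
piecewise-linear input representation, robust at the bolus peak (where
ODE steppers need tiny steps), and fast enough for multistart fitting.
Frame averages are trapezoidal on the same grid; frame boundaries must be
multiples of the grid step (true for the default 45-frame schedule:
6 × 30 s, 3 × 1 min, 2 × 2 min, 34 × 5 min). Agreement with brute-force
ODE integration on a 0.01-min grid is better than 0.1 % of the curve
maximum over random admissible parameter draws (checked in the test
suite). The $\lambda \to 0$ limit falls back to the running trapezoidal
integral, and a repeated macro-rate root is separated by $10^{-10}$ to
keep the two-exponential decomposition well-defined.

## Fitting, weights, uncertainty

Fits are weighted nonlinear least squares by bounded
Levenberg-Marquardt from a fixed multistart design: 8 points log-spaced
over the bounds (K~1~ ∈ [0, 0.5] mL·min^-1^·cm^-3^; k~2~, k~3~, k~4~ ∈
[0, 1] min^-1^; V~b~ ∈ [0, 0.2]), each start's rate ladder rotated per
parameter, and — because the model is linear in $(K_1(1-V_b), V_b)$ once
the rates are fixed — K~1~ and V~b~ are seeded per start by solving that
linear subproblem. Ties between starts are broken by lowest WRSS, then
lowest parameter norm. Non-convergence from every start raises an
explicit error; a fit that converged from at least one start is flagged
`converged`.

Default frame weights are proportional to frame duration (uniform and
duration²/activity are available); weight vectors are scale-invariant by
construction, since the covariance
$(J^\top W J)^{-1}\,\mathrm{WRSS}/(N - p)$ cancels any common factor.
rSE is 100·SE/|estimate|; the SE of V~T~ and K~i~ follows by the delta
method from the free-parameter covariance.

The blood-to-tissue delay is estimated once per scan from the first
10 min of the whole-brain curve (unweighted mean of the regional TACs
when no whole-brain region exists) under a 3-parameter uptake-only model
(K~1~, V~b~, $\Delta t$; k~2~ = 0, washout being negligible that early),
with $\Delta t$ bounded to [-3, +3] min, and is then held fixed in all
regional fits — including truncated and gapped refits, whose early frames
are always retained.

# Model selection

AIC is the least-squares form $n \ln(\mathrm{WRSS}/n) + 2p$ (an AICc
switch exists but is off by default; at n = 45 frames the correction is
small and the plain form is the convention in this literature). A more
complex model replaces the 1TCM only if it jointly has the lowest AIC
and a significant nested F-test against the 1TCM at α = 0.05. The
irreversible 2TiCM is not nested in the 1TCM in the required direction
(k~4~ = 0 versus k~3~ = 0), so that pair is compared on AIC alone, while
the F-test is computed for the properly nested pairs (1TCM ⊂ 2TCM,
2TiCM ⊂ 2TCM). Reliability of the primary parameter (V~T~, or K~i~ for
the 2TiCM) is flagged at rSE ≤ 10 %. The default on any tie or failure
is the 1TCM.

# Occupancy, BP~ND~, Guo plots

The Lassen plot regresses $\Delta V_T = V_T^\text{base} -
V_T^\text{block}$ on $V_T^\text{base}$ across regions; the slope is the
occupancy r and the x-intercept ($-b/r$) is V~ND~, with SEs by the delta
method. OLS is the default estimator — the standard convention — but
since both axes carry estimation error a total-least-squares option
(first principal axis, jackknife SEs) is provided. A slope
indistinguishable from zero leaves V~ND~ flagged undefined rather than
propagating NaN, and negative or implausible estimates are reported,
never clipped. BP~ND~ = V~T~/V~ND~ - 1 uses the across-animal mean V~ND~
for tabulation.

The Guo plot regresses tracer A's regional baseline V~T~ on tracer B's.
The slope estimates $f_p^A K_D^B / (f_p^B K_D^A)$, so the affinity ratio
$K_D^B/K_D^A$ is slope × $f_p^B/f_p^A$. Because the standard derivation
leaves the intercept's normalization convention open, both the raw
intercept (mL/cm³) and the V~ND~-normalized form are reported when V~ND~
values are supplied.

# Time stability and rest periods

`time_stability()` truncates the TAC at each endpoint (default grid 180
down to 60 min in 30-min steps), refits with the full-scan delay, and
reports 100·(V~T~^short^ - V~T~^full^)/V~T~^full^ (the full-scan value is
always the denominator); ±10 % is the conventional feasibility band.
`rest_period_analysis()` removes the frames overlapping a gap instead.
All parameters, including V~b~, are refit freely in shortened and gapped
fits; fixing V~b~ at its full-scan value would understate the true
uncertainty of a broken-scan protocol.

# The synthetic-study generator

`synthetic_study_config()` fixes the complete ground truth; its defaults
are the study regime the package targets:

| quantity | default | meaning |
|---|---|---|
| schedule | 45 frames / 180 min | 6 × 30 s, 3 × 1 min, 2 × 2 min, 34 × 5 min |
| regions | 11, V~T~ 1.96-4.55 mL/cm³ | gray-matter set spanning the study range |
| k~2~ | ln 2 / 175 min^-1^ | 175-min clearance half-life |
| K~1~ | V~T~ × k~2~ | ~8-18 µL·min^-1^·cm^-3^ |
| V~b~ | 0.036 | fractional blood volume |
| parent fraction | 0.88 / 0.83 / 0.79 at 30 / 90 / 180 min | slow metabolism |
| f~p~ | 0.135 | plasma free fraction |
| occupancy | 0.65 / 0.70 / 0.71 per animal | blocking-arm ground truth |
| V~ND~ | 0.88 mL/cm³ | shared across regions and animals |
| blocking plasma | × 1.3 | input elevation under blocking |
| TAC noise | peak CV 0.04 | see below |

The blocking arm keeps K~1~ fixed (delivery unchanged by the blocking
drug) and raises k~2~ so that
$V_T^\text{block} = V_{ND} + (1-r)(V_T^\text{base} - V_{ND})$ — i.e.
specific binding is reduced by exactly (1 - r). The 1.3× blocking plasma
elevation is a documented, arbitrary choice: the underlying study
observed elevated plasma activity under blocking without printing the
factor.

TAC noise is zero-mean Gaussian with SD ∝ √(activity/frame duration) —
the standard count-statistics surrogate — scaled so the peak frame has a
4 % CV, a realistic region-level noise for long-frame nonhuman-primate
data; blood samples get 2 % multiplicative noise and parent fractions
2 % additive noise clipped to [0, 1]. No published noise model exists
for these data; these are one-time choices, not tuning knobs.

One top-level seed drives everything; per-scan streams are drawn from it
in a fixed order (for each animal, then each condition: blood stream,
then TAC stream), and `ground_truth.json` stores every generating
parameter and stream seed, so any generated file can be reproduced
bit-exactly.

What the generator does *not* emulate: image-level (voxel) noise and its
spatial correlation, scanner resolution and partial-volume effects,
motion, dispersion and calibration errors in blood sampling, per-animal
anatomy, and between-animal kinetic variability beyond the per-animal
occupancy. Passing the package's recovery tests therefore demonstrates
correctness of the estimators under the stated statistical model, not
performance on real scanner data.

# Validation problem sizes

The test-suite and acceptance computations use: 100 randomized noiseless
blood-model recoveries; 20 random parameter draws for the ODE
cross-check; 200 noisy replicates for V~T~ bias and rSE calibration; 220
noisy TACs for the model-selection rate; 15 seeds per kinetic regime for
the truncation-bias comparison; and a 3-animal paired study for the
end-to-end occupancy recovery. These sizes were chosen to give stable
Monte-Carlo estimates of each property at desk scale.

# Known limitations

- No reference-tissue or graphical (Logan/Patlak) estimation methods —
  the Patlak limit appears only as a test oracle. For the GAT-1
  application there is no valid reference region.
- No dispersion or delay modeling of the blood sampling line itself;
  activities are assumed decay-corrected to injection time upstream.
- The parent-fraction family is monotone by construction; tracers with
  non-monotone parent fractions (e.g. metabolite back-conversion) need a
  different model.
- Occupancy assumes one V~ND~ shared across regions (the Lassen
  premise) and a single blocking dose; dose-occupancy (EC~50~) designs
  are out of scope.
- The `.tac` reader covers the common whitespace-delimited
  `start[seconds] end[seconds]` dialect only.
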