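## Shared fixtures, all built in code.

## Noiseless study configuration (default ground truth, zero noise).
noiseless_config <- function(...) {
  synthetic_study_config(seed = 42L, blood_cv = 0, parent_sd = 0,
                         tac_peak_cv = 0, ...)
}

## Continuous truth input function of the default study.
fixture_input <- function(condition = "baseline") {
  generate_input(noiseless_config(), condition = condition)$truth
}

## A constant input function (plasma = whole blood = value, PF = 1),
## built through the public fitting surface from degenerate samples.
constant_input <- function(value = 1) {
  bl <- blood_sample_table(c(0.01, 60, 120, 180),
                           rep(value, 4), rep(value, 4))
  pf <- fit_parent_fraction(parent_fraction_table(c(5, 60, 120, 180),
                                                  rep(1, 4)))
  pl <- fit_plasma_curve(bl, n_exponentials = 1, "plasma")
  wb <- fit_plasma_curve(bl, n_exponentials = 1, "whole_blood")
  make_input_function(pl, pf, wb, f_p = 0.135)
}

## Noiseless frame-averaged TAC from a parameter set.
noiseless_tac <- function(params, input = fixture_input(),
                          schedule = default_frame_schedule(),
                          roi = "sim") {
  tac(roi, schedule, predict_tac(params, input, schedule))
}

## Noisy 1TCM TAC at the study noise model (seeded).
noisy_tac <- function(seed, K1 = 0.0135, k2 = log(2) / 175, V_b = 0.036,
                      peak_cv = 0.04, input = fixture_input(),
                      schedule = default_frame_schedule()) {
  kp <- kinetic_parameters("1TCM", K1 = K1, k2 = k2, V_b = V_b)
  pred <- predict_tac(kp, input, schedule)
  set.seed(seed)
  ipk <- which.max(pred)
  sigma0 <- peak_cv * pred[ipk] / sqrt(pred[ipk] / schedule$dur[ipk])
  act <- pred + rnorm(length(pred), 0, sigma0 * sqrt(pmax(pred, 0) / schedule$dur))
  tac("sim", schedule, act)
}

## Table-3-like default baseline V_T set (the generator's regional truth).
fixture_baseline_vt <- function() {
  rt <- noiseless_config()$roi_truth
  setNames(rt$V_T, rt$roi)
}
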