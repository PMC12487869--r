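test_that("vascular-only prediction equals the scaled whole-blood curve", {
  inp <- fixture_input()
  sched <- default_frame_schedule()
  kp <- kinetic_parameters("1TCM", K1 = 0, k2 = 0.01, V_b = 0.05)
  pred <- predict_tac(kp, inp, sched)
  ## oracle: frame-averaged whole blood by independent fine quadrature
  wb_avg <- sapply(seq_len(nrow(sched)), function(i) {
    tt <- seq(sched$frame_start[i], sched$frame_end[i], length.out = 2001)
    v <- eval_whole_blood(inp, tt)
    sum(diff(tt) * (v[-1] + v[-length(v)]) / 2) / (sched$frame_end[i] - sched$frame_start[i])
  })
  expect_equal(pred, 0.05 * wb_avg, tolerance = 1e-4)
})

test_that("1TCM matches the closed form under a constant unit input", {
  inp <- constant_input(1)
  k2 <- log(2) / 175
  kp <- kinetic_parameters("1TCM", K1 = 0.0135, k2 = k2, V_b = 0)
  got <- tissue_concentration(kp, inp, 180)
  want <- (0.0135 / k2) * (1 - exp(-k2 * 180))
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("2TCM with k3 = 0 collapses to the 1TCM prediction", {
  inp <- fixture_input()
  sched <- default_frame_schedule()
  p1 <- kinetic_parameters("1TCM", K1 = 0.02, k2 = 0.01, V_b = 0.036)
  p2 <- kinetic_parameters("2TCM", K1 = 0.02, k2 = 0.01, k3 = 0, k4 = 0.07,
                           V_b = 0.036)
  expect_equal(predict_tac(p2, inp, sched), predict_tac(p1, inp, sched),
               tolerance = 1e-8)
})

test_that("irreversible-model late slope under constant input is K_i (Patlak limit)", {
  inp <- constant_input(2)
  kp <- kinetic_parameters("2TiCM", K1 = 0.01, k2 = 0.03, k3 = 0.02, V_b = 0)
  K_i <- derive_macroparameters(kp)$K_i
  ct <- tissue_concentration(kp, inp, c(150, 180))
  slope <- (ct[2] - ct[1]) / 30 / 2  # per unit input concentration
  expect_equal(slope, K_i, tolerance = 0.01)
})

test_that("delay estimation recovers the true shift", {
  inp <- fixture_input()
  sched <- default_frame_schedule()
  mk_wb <- function(dt) {
    kp <- kinetic_parameters("1TCM", K1 = 0.015, k2 = log(2) / 175,
                             V_b = 0.036, delta_t = dt)
    tac("whole_brain", sched, predict_tac(kp, inp, sched))
  }
  est <- estimate_delay(mk_wb(0.5), inp)
  expect_lt(abs(est$delta_t - 0.5), 0.1)

  est0 <- estimate_delay(mk_wb(0), inp)
  expect_lt(abs(est0$delta_t), 0.05)

  ## scale equivariance: doubling the TAC leaves the delay unchanged
  wb <- mk_wb(0.5)
  wb2 <- tac("whole_brain", sched, 2 * wb$activity)
  est2 <- estimate_delay(wb2, inp)
  expect_lt(abs(est2$delta_t - est$delta_t), 0.05)

  short <- tac("s", frame_schedule(0:3, 1:4), rep(1, 4))
  expect_error(estimate_delay(short, inp), "at least 5 frames")
})

test_that("noiseless 1TCM data are recovered to 0.1% on the 45-frame schedule", {
  inp <- fixture_input()
  kp <- kinetic_parameters("1TCM", K1 = 0.0135, k2 = 0.004, V_b = 0.036)
  fit <- fit_tissue_model(noiseless_tac(kp, inp), inp, "1TCM")
  expect_equal(fit$parameters$K1, 0.0135, tolerance = 1e-3)
  expect_equal(fit$parameters$k2, 0.004, tolerance = 1e-3)
  expect_equal(fit$parameters$V_b, 0.036, tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("weights are scale-invariant in estimates and rSE", {
  inp <- fixture_input()
  tc <- noisy_tac(11)
  tc2 <- tac(tc$roi_name, tc$schedule, tc$activity, weights = 2 * tc$weights)
  f1 <- fit_tissue_model(tc, inp, "1TCM")
  f2 <- fit_tissue_model(tc2, inp, "1TCM")
  expect_equal(f1$parameters$K1, f2$parameters$K1, tolerance = 1e-6)
  expect_equal(f1$parameters$k2, f2$parameters$k2, tolerance = 1e-6)
  expect_equal(f1$rse, f2$rse, tolerance = 1e-4)
})

test_that("macroparameters follow their closed forms", {
  k2_175 <- log(2) / 175
  p1 <- kinetic_parameters("1TCM", K1 = 0.0135, k2 = k2_175)
  expect_equal(derive_macroparameters(p1)$V_T, 0.0135 / k2_175,
               tolerance = 1e-12)
  expect_equal(derive_macroparameters(p1)$V_T, 3.408, tolerance = 1e-3)
  expect_equal(derive_macroparameters(p1)$clearance_half_life, 175)

  p2 <- kinetic_parameters("2TCM", K1 = 0.02, k2 = 0.01, k3 = 0.03, k4 = 0.03)
  expect_equal(derive_macroparameters(p2)$V_T, 4)

  pi2 <- kinetic_parameters("2TiCM", K1 = 0.01, k2 = 0.01, k3 = 0.01)
  expect_equal(derive_macroparameters(pi2)$K_i, 0.005)
  expect_error(volume_of_distribution(pi2), "undefined")

  p0 <- kinetic_parameters("1TCM", K1 = 0.01, k2 = 0)
  expect_warning(v <- volume_of_distribution(p0), "infinite")
  expect_true(is.infinite(v))
})

test_that("model nesting orders the residual sums of squares", {
  ## WRSS(2TCM) <= WRSS(1TCM) on noisy synthetic TACs (seeded)
  inp <- fixture_input()
  skip_slow <- FALSE
  n_bad <- 0L
  for (s in 1:12) {
    tc <- noisy_tac(100 + s)
    f1 <- fit_tissue_model(tc, inp, "1TCM")
    f2 <- fit_tissue_model(tc, inp, "2TCM")
    expect_lte(f2$wrss, f1$wrss * (1 + 1e-6))
  }
})

test_that("a shifted input reproduces a delayed prediction", {
  cfg <- noiseless_config()
  dt <- 0.5
  inp <- generate_input(cfg)
  shifted_blood <- blood_sample_table(inp$blood$sample_time + dt,
                                      inp$blood$whole_blood_activity,
                                      inp$blood$plasma_activity)
  shifted_parent <- parent_fraction_table(inp$parent$sample_time + dt,
                                          inp$parent$parent_fraction)
  base_in <- make_input_function(fit_plasma_curve(inp$blood, 3),
                                 fit_parent_fraction(inp$parent),
                                 fit_plasma_curve(inp$blood, 3, "whole_blood"),
                                 0.135)
  shift_in <- make_input_function(fit_plasma_curve(shifted_blood, 3),
                                  fit_parent_fraction(shifted_parent),
                                  fit_plasma_curve(shifted_blood, 3, "whole_blood"),
                                  0.135)
  sched <- default_frame_schedule()
  kp_del <- kinetic_parameters("1TCM", K1 = 0.0135, k2 = 0.004, V_b = 0.036,
                               delta_t = dt)
  kp_0 <- kinetic_parameters("1TCM", K1 = 0.0135, k2 = 0.004, V_b = 0.036)
  a <- predict_tac(kp_del, base_in, sched)
  b <- predict_tac(kp_0, shift_in, sched)
  expect_lt(max(abs(a - b)) / max(a), 0.02)
})

test_that("K1 is reported in both mL and uL per minute per cm3", {
  p <- kinetic_parameters("1TCM", K1 = 0.0135, k2 = 0.004)
  expect_output(print(p), "13.5 uL/min/cm3")
})
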