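test_that("plasma curve fit recovers exponential ground truth", {
  ## noiseless mono-exponential after an instantaneous peak at 1 min
  t <- c(0.5, 1, seq(5, 180, by = 10))
  y <- ifelse(t < 1, 10 * t, 10 * exp(-0.01 * t))
  bl <- blood_sample_table(t, y, y)
  fit <- fit_plasma_curve(bl, n_exponentials = 1)
  expect_equal(fit$A, 10, tolerance = 1e-4)
  expect_equal(fit$lambda, 0.01, tolerance = 1e-4)

  ## degenerate flat tail: one exponential with rate -> 0
  tb <- c(1, 30, 60, 120, 180)
  bl2 <- blood_sample_table(tb, rep(5, 5), rep(5, 5))
  fit2 <- fit_plasma_curve(bl2, n_exponentials = 1)
  expect_equal(eval_plasma(fit2, c(10, 90, 180)), rep(5, 3), tolerance = 1e-5)

  ## tri-exponential forward-simulate then refit; oracle = generating model
  A <- c(5, 3, 1); lam <- c(0.5, 0.05, 0.002)
  tpost <- seq(1, 180, length.out = 30)
  truth <- function(tt) sapply(tt, function(u) sum(A * exp(-lam * u)))
  bl3 <- blood_sample_table(c(0.5, tpost), c(1, truth(tpost)), c(1, truth(tpost)))
  fit3 <- fit_plasma_curve(bl3, n_exponentials = 3)
  expect_lt(max(abs(eval_plasma(fit3, tpost) - truth(tpost)) / truth(tpost)),
            0.005)
})

test_that("plasma fit fails loudly on bad inputs", {
  bl <- blood_sample_table(c(1, 30, 60, 120), c(4, 3, 2, 1), c(4, 3, 2, 1))
  expect_error(fit_plasma_curve(bl, n_exponentials = 3), "at least 5 samples")
  blz <- blood_sample_table(c(1, 30, 60, 120), rep(0, 4), rep(0, 4))
  expect_error(fit_plasma_curve(blz, 1), "zero")
  expect_error(blood_sample_table(c(1, 1, 2, 3), 1:4, 1:4), "increasing")
  expect_error(blood_sample_table(c(1, 2, 3), 1:3, 1:3), "at least 4")
})

test_that("parent-fraction model fits and stays monotone", {
  times7 <- c(5, 15, 30, 60, 90, 120, 180)

  ## no metabolism: a = 0, PF identically 1
  pf1 <- fit_parent_fraction(parent_fraction_table(times7, rep(1, 7)))
  expect_equal(pf1$a, 0)
  expect_equal(eval_parent_fraction(pf1, c(0, 90, 180)), rep(1, 3))

  ## forward-simulate then refit (a = 0.3, shape 2, rate 0.02)
  truth <- 1 - 0.3 * pgamma(times7, shape = 2, rate = 0.02)
  pf2 <- fit_parent_fraction(parent_fraction_table(times7, truth))
  expect_equal(pf2$a, 0.3, tolerance = 1e-3)
  expect_equal(pf2$shape, 2, tolerance = 1e-3)
  expect_equal(pf2$rate, 0.02, tolerance = 1e-3)

  ## slow-metabolism profile: 0.88 / 0.83 / 0.79 at 30 / 90 / 180 min
  cfg <- noiseless_config()
  tab <- generate_input(cfg)$parent
  pf3 <- fit_parent_fraction(tab)
  expect_equal(eval_parent_fraction(pf3, 180), 0.79, tolerance = 0.02)

  ## noisy, non-monotone samples still give a monotone fitted curve
  set.seed(7)
  noisy <- pmin(pmax(truth + rnorm(7, 0, 0.03), 0), 1)
  pf4 <- fit_parent_fraction(parent_fraction_table(times7, noisy))
  grid <- seq(0, 200, by = 0.5)
  v <- eval_parent_fraction(pf4, grid)
  expect_equal(v[1], 1)
  expect_true(all(diff(v) <= 1e-12))

  expect_error(parent_fraction_table(times7, truth + 1), "\\[0, 1\\]")
})

test_that("metabolite-corrected input is the plasma x parent product", {
  inp <- fixture_input()
  tt <- seq(0, 180, by = 0.5)

  ## PF = 1 -> corrected input equals total plasma everywhere
  inp_id <- make_input_function(inp$plasma,
                                fit_parent_fraction(
                                  parent_fraction_table(c(5, 60, 120, 180),
                                                        rep(1, 4))),
                                inp$whole_blood, 0.1)
  expect_equal(eval_input(inp_id, tt), eval_plasma(inp$plasma, tt))

  ## pointwise product and plasma bound
  pf180 <- eval_parent_fraction(inp$parent, 180)
  expect_equal(eval_input(inp, 180), eval_plasma(inp$plasma, 180) * pf180)
  expect_true(all(eval_input(inp, tt) <= eval_plasma(inp$plasma, tt) + 1e-12))

  ## integral agrees with fine-grid trapezoidal quadrature within 0.1%
  coarse <- seq(0, 180, by = 0.05)
  fine <- seq(0, 180, by = 0.002)
  q1 <- sum(diff(coarse) * (eval_input(inp, coarse[-1]) +
                              eval_input(inp, coarse[-length(coarse)])) / 2)
  q2 <- sum(diff(fine) * (eval_input(inp, fine[-1]) +
                            eval_input(inp, fine[-length(fine)])) / 2)
  expect_equal(q1, q2, tolerance = 1e-3)

  expect_error(make_input_function(inp$plasma, inp$parent, inp$whole_blood,
                                   f_p = 1.2), "f_p")
})

test_that("plasma model is continuous at the peak junction", {
  cfg <- noiseless_config()
  inp <- generate_input(cfg)
  fit <- fit_plasma_curve(inp$blood, 3)
  eps <- 1e-9
  left <- eval_plasma(fit, fit$peak_time - eps)
  right <- eval_plasma(fit, fit$peak_time + eps)
  peak <- eval_plasma(fit, fit$peak_time)
  expect_lt(abs(left - right), 1e-6 * peak)
  expect_equal(eval_plasma(fit, c(-5, 0)), c(0, 0))
})

test_that("noiseless blood fits recover generating parameters within 1%", {
  ## property: randomized admissible plasma + parent truths, seeded
  set.seed(2024)
  times7 <- c(5, 15, 30, 60, 90, 120, 180)
  tb <- c(0.5, 1, 2, 3, 5, 8, 12, 20, 30, 45, 60, 90, 120, 150, 180)
  for (i in 1:100) {
    A <- c(runif(1, 10, 60), runif(1, 3, 15), runif(1, 1, 6))
    lam <- c(runif(1, 0.3, 1), runif(1, 0.03, 0.1), runif(1, 0.001, 0.01))
    truth <- sapply(tb, function(u) sum(A * exp(-lam * u)))
    truth[tb < 1] <- truth[tb >= 1][1] * tb[tb < 1]
    fit <- fit_plasma_curve(blood_sample_table(tb, truth, truth), 3)
    post <- tb[tb >= 1]
    tv <- sapply(post, function(u) sum(A * exp(-lam * u)))
    expect_lt(max(abs(eval_plasma(fit, post) - tv) / tv), 0.01)

    a <- runif(1, 0.1, 0.5); sh <- runif(1, 0.5, 3); ra <- runif(1, 0.005, 0.05)
    pftab <- parent_fraction_table(times7, 1 - a * pgamma(times7, sh, ra))
    pfit <- fit_parent_fraction(pftab)
    pv <- eval_parent_fraction(pfit, times7)
    expect_lt(max(abs(pv - pftab$parent_fraction)), 0.01)
  }
})

test_that("SUV normalizes activity by dose per gram", {
  expect_equal(suv(5, 180, 5), 5 / (180000 / 5000))
  expect_equal(suv(0, 180, 5), 0)
  a <- c(0.3, 5, 12)
  expect_equal(suv_to_activity(suv(a, 182, 10), 182, 10), a, tolerance = 1e-12)
  expect_error(suv(5, 0, 5), "positive")
  expect_error(suv(5, 180, -1), "positive")
})
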