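test_that("Lassen regression recovers constructed occupancy exactly", {
  vt <- fixture_baseline_vt()  # 11 regions, ~2.0-4.6 mL/cm3
  r <- 0.68; vnd <- 0.88
  vt_block <- vnd + (1 - r) * (vt - vnd)
  fit <- lassen_fit(vt, vt_block, roi_name = names(vt))
  expect_equal(fit$r, r, tolerance = 1e-12)
  expect_equal(fit$V_ND, vnd, tolerance = 1e-12)
  expect_true(fit$vnd_defined)

  ## full occupancy: blocking V_T pinned at V_ND -> r = 1, intercept V_ND
  fit1 <- lassen_fit(vt, rep(vnd, length(vt)))
  expect_equal(fit1$r, 1, tolerance = 1e-12)
  expect_equal(fit1$V_ND, vnd, tolerance = 1e-12)

  ## no blocking effect: r = 0 and V_ND flagged undefined, not NaN
  fit0 <- lassen_fit(vt, vt)
  expect_equal(fit0$r, 0, tolerance = 1e-12)
  expect_false(fit0$vnd_defined)
  expect_true(is.na(fit0$V_ND))

  expect_error(lassen_fit(vt[1:2], vt_block[1:2]), "at least 3")
  expect_error(lassen_fit(rep(2, 5), rep(1, 5)), "all equal")
})

test_that("Lassen fit is invariant to region order and duplication", {
  vt <- fixture_baseline_vt()
  set.seed(3)
  vt_block <- 0.9 + 0.35 * (vt - 0.9) + rnorm(length(vt), 0, 0.05)
  f <- lassen_fit(vt, vt_block)
  perm <- sample(length(vt))
  f_perm <- lassen_fit(vt[perm], vt_block[perm])
  expect_equal(f_perm$r, f$r, tolerance = 1e-12)
  expect_equal(f_perm$V_ND, f$V_ND, tolerance = 1e-12)
  f_dup <- lassen_fit(c(vt, vt), c(vt_block, vt_block))
  expect_equal(f_dup$r, f$r, tolerance = 1e-12)
  expect_equal(f_dup$V_ND, f$V_ND, tolerance = 1e-12)
})

test_that("noisy Lassen recovery stays within its sampling bands", {
  vt <- fixture_baseline_vt()
  r <- 0.68; vnd <- 0.88
  set.seed(99)
  rs <- vnds <- numeric(200)
  for (i in 1:200) {
    vb <- vt * (1 + rnorm(length(vt), 0, 0.05))
    vk <- (vnd + (1 - r) * (vt - vnd)) * (1 + rnorm(length(vt), 0, 0.05))
    f <- lassen_fit(vb, vk)
    rs[i] <- f$r; vnds[i] <- f$V_ND
  }
  expect_lt(abs(median(rs) - r), 0.03)
  expect_lt(abs(median(vnds) - vnd) / vnd, 0.15)
})

test_that("BP_ND arithmetic and guards", {
  expect_equal(compute_bpnd(2, 2), 0)
  expect_equal(compute_bpnd(c(2, 4), 2), c(0, 1))
  expect_error(compute_bpnd(2, 0), "positive")
  expect_error(compute_bpnd(2, -0.61), "positive")

  ## full-occupancy V_ND feeds straight back: (V_T - V_ND)/V_ND
  vt <- fixture_baseline_vt()
  fit <- lassen_fit(vt, rep(0.88, length(vt)))
  expect_equal(compute_bpnd(vt, fit$V_ND), (vt - fit$V_ND) / fit$V_ND,
               tolerance = 1e-10)

  ## total least squares option agrees on noiseless data
  vb <- vt; vk <- 0.88 + 0.32 * (vt - 0.88)
  tls <- lassen_fit(vb, vk, method = "tls")
  expect_equal(tls$r, 0.68, tolerance = 1e-10)
  expect_equal(tls$V_ND, 0.88, tolerance = 1e-8)
})

test_that("Guo plot recovers relative affinity from constructed tracers", {
  s <- fixture_baseline_vt() - 0.8  # shared specific-binding term

  ## identical tracers: slope 1, intercept 0, K_D ratio 1
  g0 <- guo_fit(1 + s, 1 + s, f_p_A = 0.12, f_p_B = 0.12)
  expect_equal(g0$slope, 1, tolerance = 1e-12)
  expect_equal(g0$intercept, 0, tolerance = 1e-12)
  expect_equal(g0$KD_ratio, 1, tolerance = 1e-12)

  ## linear construction: vt_A = 1 + 2 s, vt_B = 0.5 + s
  g1 <- guo_fit(1 + 2 * s, 0.5 + s, f_p_A = 0.1, f_p_B = 0.1)
  expect_equal(g1$slope, 2, tolerance = 1e-12)
  expect_equal(g1$intercept, 0, tolerance = 1e-10)

  ## affinity ratio from measured free fractions (13.5% vs 12.4%),
  ## K_D ratio (B/A) = 1.06 by construction
  f_p_A <- 13.5; f_p_B <- 12.4
  kd_ratio <- 1.06
  slope_true <- kd_ratio * f_p_A / f_p_B
  vnd_A <- 0.88; vnd_B <- 0.85
  vt_A <- vnd_A + slope_true * s
  vt_B <- vnd_B + s
  g2 <- guo_fit(vt_A, vt_B, f_p_A, f_p_B, V_ND_A = vnd_A, V_ND_B = vnd_B)
  expect_equal(g2$slope, 1.06 * 13.5 / 12.4, tolerance = 1e-6)
  expect_equal(g2$KD_ratio, 1.06, tolerance = 1e-6)
  expect_equal(g2$BP_ratio, g2$slope * vnd_B / vnd_A, tolerance = 1e-10)
  expect_equal(g2$intercept, vnd_A - g2$slope * vnd_B, tolerance = 1e-8)
  expect_equal(g2$intercept_normalized, g2$intercept / vnd_A)

  expect_error(guo_fit(1:2, 1:2, 0.1, 0.1), "at least 3")
  expect_error(guo_fit(1 + s, rep(1, length(s)), 0.1, 0.1), "unidentifiable")
})
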