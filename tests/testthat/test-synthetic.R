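test_that("generation is deterministic given the seed", {
  cfg <- synthetic_study_config(seed = 5L)
  a <- generate_input(cfg)
  b <- generate_input(cfg)
  expect_identical(a$blood, b$blood)
  expect_identical(a$parent, b$parent)
  ta <- generate_tacs(cfg)
  tb <- generate_tacs(cfg)
  expect_identical(sapply(ta$tacs, function(x) x$activity),
                   sapply(tb$tacs, function(x) x$activity))
})

test_that("zero noise reproduces the continuous truth exactly", {
  cfg <- noiseless_config()
  g <- generate_input(cfg)
  expect_equal(g$blood$plasma_activity,
               eval_plasma(g$truth$plasma, cfg$blood_times))
  expect_equal(g$parent$parent_fraction,
               eval_parent_fraction(g$truth$parent, cfg$parent_times))

  ## default parent-fraction truth matches the slow-metabolism profile
  expect_equal(eval_parent_fraction(g$truth$parent, c(30, 90, 180)),
               c(0.88, 0.83, 0.79), tolerance = 0.005)

  gt <- generate_tacs(cfg)
  kp <- kinetic_parameters("1TCM", K1 = gt$truth$K1[1], k2 = gt$truth$k2[1],
                           V_b = gt$truth$V_b[1])
  expect_equal(gt$tacs[[1]]$activity,
               predict_tac(kp, g$truth, cfg$schedule))
})

test_that("noiseless generated TACs round-trip through the fitter", {
  cfg <- noiseless_config()
  inp <- generate_input(cfg)$truth
  gt <- generate_tacs(cfg)
  for (i in c(1, 8, 11)) {
    fit <- fit_tissue_model(gt$tacs[[i]], inp, "1TCM")
    expect_equal(fit$parameters$K1, gt$truth$K1[i], tolerance = 1e-3)
    expect_equal(fit$V_T, gt$truth$V_T[i], tolerance = 1e-3)
  }
})

test_that("rSE from the covariance calibrates against the empirical spread", {
  inp <- fixture_input()
  vts <- rses <- numeric(60)
  for (s in 1:60) {
    f <- fit_tissue_model(noisy_tac(3000 + s), inp, "1TCM")
    vts[s] <- f$V_T
    rses[s] <- f$primary_rse
  }
  emp_cv <- 100 * sd(vts) / mean(vts)
  expect_lt(emp_cv / mean(rses), 2)
  expect_gt(emp_cv / mean(rses), 0.5)
})

test_that("the study writer is reproducible and conserves specific binding", {
  cfg <- synthetic_study_config(seed = 11L, n_animals = 1L)
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  unlink(c(d1, d2), recursive = TRUE)
  man <- generate_study(cfg, d1)
  generate_study(cfg, d2)
  expect_setequal(list.files(d1), list.files(d2))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  expect_equal(nrow(man), 2)  # baseline + blocking for one animal

  ## refuse to clobber without force
  expect_error(generate_study(cfg, d1), "not empty")
  expect_silent(generate_study(cfg, d1, force = TRUE))

  ## ground truth records the (1 - r)-scaled specific binding
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"),
                            simplifyVector = TRUE)
  base_vt <- gt$scans$m01_baseline$roi_truth$V_T
  block_vt <- gt$scans$m01_blocking$roi_truth$V_T
  r <- gt$scans$m01_blocking$occupancy
  vnd <- gt$scans$m01_blocking$V_ND
  expect_equal(block_vt - vnd, (1 - r) * (base_vt - vnd), tolerance = 1e-12)
})

test_that("a zero-occupancy study shows no baseline/blocking V_T separation", {
  cfg <- synthetic_study_config(seed = 21L, occupancy = 0, n_animals = 1L,
                                blocking_input_scale = 1)
  inp_b <- generate_input(cfg, seed = 1, condition = "baseline")
  inp_k <- generate_input(cfg, seed = 2, condition = "blocking")
  fit_in <- function(g) make_input_function(fit_plasma_curve(g$blood, 3),
                                            fit_parent_fraction(g$parent),
                                            fit_plasma_curve(g$blood, 3, "whole_blood"),
                                            cfg$f_p)
  tac_b <- generate_tacs(cfg, seed = 31, condition = "baseline")
  tac_k <- generate_tacs(cfg, seed = 32, condition = "blocking")
  vt_b <- sapply(names(tac_b$tacs), function(r)
    fit_tissue_model(tac_b$tacs[[r]], fit_in(inp_b), "1TCM")$V_T)
  vt_k <- sapply(names(tac_k$tacs), function(r)
    fit_tissue_model(tac_k$tacs[[r]], fit_in(inp_k), "1TCM")$V_T)
  expect_gt(t.test(vt_b, vt_k, paired = TRUE)$p.value, 0.01)
})
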