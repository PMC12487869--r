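## Synthetic-study generator. Emulates a long-scan (180 min, 45 frames)
## nonhuman-primate study of a slow, reversible radiotracer: tissue
## clearance half-life about 175 min, fractional blood volume 0.036,
## eleven gray-matter regions with baseline V_T spanning about 2.0-4.6
## mL/cm3, slow peripheral metabolism (parent fraction 0.88/0.83/0.79 at
## 30/90/180 min), and paired baseline/blocking scans sharing one
## occupancy and one V_ND per animal.

## Default regional ground truth: 11 gray-matter regions with baseline
## V_T values spanning the study range.
default_roi_truth <- function() {
  data.frame(
    roi = c("brain_stem", "caudate", "cerebellum", "cingulate", "frontal",
            "hippocampus", "insula", "occipital", "putamen", "temporal",
            "thalamus"),
    V_T = c(2.61, 2.25, 3.36, 4.30, 3.73, 2.98, 4.46, 4.55, 2.71, 4.48, 1.96))
}

#' Configuration of a synthetic PET study
#'
#' Holds the complete ground truth for the generator: frame schedule,
#' regional kinetic parameters, input-function shape, parent-fraction
#' model, blocking-arm occupancy, noise levels and seed. Defaults follow
#' the long-scan slow-kinetics study the package is designed around:
#' one-tissue kinetics with k2 = ln(2)/175 per min, K1 = V_T * k2,
#' V_b = 0.036, per-animal occupancies 0.65/0.70/0.71 (recycled) sharing
#' V_ND = 0.88 mL/cm3, and a 1.3-fold plasma elevation in the blocking
#' condition.
#'
#' @param seed Top-level integer seed. Per-component streams are drawn
#'   from it in a fixed documented order (for each animal, then each
#'   condition: blood-sampling stream, then TAC-noise stream).
#' @param schedule A [frame_schedule()].
#' @param roi_truth Data frame with columns `roi`, `V_T` (and optionally
#'   `K1`, `V_b`); missing `K1` is derived as `V_T * k2_default`.
#' @param k2_default 1/min; default ln(2)/175 (175-min clearance
#'   half-life).
#' @param V_b Fractional blood volume ground truth.
#' @param delta_t True blood-to-tissue delay, minutes.
#' @param plasma_A,plasma_lambda Amplitudes (kBq/cm3, referenced to t = 0)
#'   and rates (1/min) of the tri-exponential plasma decay.
#' @param peak_time Plasma bolus peak time, minutes.
#' @param wb_ratio Whole-blood-to-plasma amplitude ratio.
#' @param parent_a,parent_shape,parent_rate Integrated-gamma
#'   parent-fraction truth; defaults hit PF(30) = 0.88, PF(90) = 0.83,
#'   PF(180) = 0.79.
#' @param f_p Plasma free fraction.
#' @param injected_dose_MBq,body_weight_kg Scan metadata.
#' @param blood_times Arterial sampling times, minutes.
#' @param parent_times Metabolite sampling times, minutes (the 7-sample
#'   protocol).
#' @param occupancy,V_ND Blocking-arm ground truth: scalar or per-animal
#'   occupancy fraction(s) and the shared nondisplaceable volume.
#' @param blocking_input_scale Plasma/whole-blood elevation factor in the
#'   blocking condition.
#' @param blood_cv Multiplicative CV of blood-sample noise.
#' @param parent_sd Additive SD of parent-fraction noise (clipped to
#'   `[0, 1]`).
#' @param tac_peak_cv Target coefficient of variation of the peak frame;
#'   per-frame noise SD scales as sqrt(activity / frame duration).
#' @param n_animals Number of animals.
#' @return Object of class `synthetic_study_config` (a list).
#' @export
synthetic_study_config <- function(seed = 1L,
                                   schedule = default_frame_schedule(),
                                   roi_truth = default_roi_truth(),
                                   k2_default = log(2) / 175,
                                   V_b = 0.036,
                                   delta_t = 0,
                                   plasma_A = c(40, 10, 5),
                                   plasma_lambda = c(0.5, 0.05, 0.002),
                                   peak_time = 1,
                                   wb_ratio = 0.9,
                                   parent_a = 0.3823401,
                                   parent_shape = 0.3261512,
                                   parent_rate = 0.0006872786,
                                   f_p = 0.135,
                                   injected_dose_MBq = 182,
                                   body_weight_kg = 10,
                                   blood_times = c(0.25, 0.5, 0.75, 1, 1.5, 2,
                                                   3, 5, 8, 12, 15, 20, 30, 45,
                                                   60, 90, 120, 150, 180),
                                   parent_times = c(5, 15, 30, 60, 90, 120, 180),
                                   occupancy = c(0.65, 0.70, 0.71),
                                   V_ND = 0.88,
                                   blocking_input_scale = 1.3,
                                   blood_cv = 0.02,
                                   parent_sd = 0.02,
                                   tac_peak_cv = 0.04,
                                   n_animals = 3L) {
  if (tac_peak_cv < 0 || blood_cv < 0 || parent_sd < 0)
    stop_petkin("noise levels must be non-negative")
  if (n_animals < 1L) stop_petkin("n_animals must be at least 1")
  if (!all(c("roi", "V_T") %in% names(roi_truth)))
    stop_petkin("roi_truth needs columns 'roi' and 'V_T'")
  if (is.null(roi_truth$K1)) roi_truth$K1 <- roi_truth$V_T * k2_default
  if (is.null(roi_truth$V_b)) roi_truth$V_b <- V_b
  occ <- rep_len(occupancy, n_animals)
  structure(list(seed = as.integer(seed), schedule = schedule,
                 roi_truth = roi_truth, k2_default = k2_default, V_b = V_b,
                 delta_t = delta_t, plasma_A = plasma_A,
                 plasma_lambda = plasma_lambda, peak_time = peak_time,
                 wb_ratio = wb_ratio, parent_a = parent_a,
                 parent_shape = parent_shape, parent_rate = parent_rate,
                 f_p = f_p, injected_dose_MBq = injected_dose_MBq,
                 body_weight_kg = body_weight_kg, blood_times = blood_times,
                 parent_times = parent_times, occupancy = occ, V_ND = V_ND,
                 blocking_input_scale = blocking_input_scale,
                 blood_cv = blood_cv, parent_sd = parent_sd,
                 tac_peak_cv = tac_peak_cv, n_animals = as.integer(n_animals)),
            class = "synthetic_study_config")
}

#' @export
print.synthetic_study_config <- function(x, ...) {
  cat(sprintf("<synthetic_study_config> seed %d, %d animals, %d ROIs, %d frames\n",
              x$seed, x$n_animals, nrow(x$roi_truth), nrow(x$schedule)))
  cat(sprintf("  occupancy %s, V_ND %.3g mL/cm3, tac peak CV %.3g\n",
              paste(signif(x$occupancy, 3), collapse = "/"), x$V_ND,
              x$tac_peak_cv))
  invisible(x)
}

## Construct the continuous truth input function for one condition.
truth_input <- function(config, condition = c("baseline", "blocking")) {
  condition <- match.arg(condition)
  scale <- if (condition == "blocking") config$blocking_input_scale else 1
  A <- config$plasma_A * scale
  tp <- config$peak_time
  mk <- function(A, col) structure(
    list(peak_time = tp, pre_times = c(0, tp),
         pre_values = c(0, sum_exp(tp, A, config$plasma_lambda)),
         A = A, lambda = config$plasma_lambda, rss = 0, column = col),
    class = "plasma_curve")
  parent <- structure(list(a = config$parent_a, shape = config$parent_shape,
                           rate = config$parent_rate, rss = 0),
                      class = "parent_fraction_model")
  make_input_function(mk(A, "plasma_activity"), parent,
                      mk(A * config$wb_ratio, "whole_blood_activity"),
                      config$f_p)
}

#' Generate synthetic blood and parent-fraction tables
#'
#' Draws blood samples at the configured times from the continuous truth
#' curves (linear rise to the bolus peak, then tri-exponential decay)
#' with multiplicative Gaussian noise, and parent-fraction samples from
#' the integrated-gamma truth with additive noise clipped to `[0, 1]`.
#'
#' @param config A [synthetic_study_config()].
#' @param seed Stream seed (defaults to the config's top-level seed).
#' @param condition `"baseline"` or `"blocking"` (the blocking plasma is
#'   elevated by `blocking_input_scale`).
#' @return List with `blood` ([blood_sample_table()]), `parent`
#'   ([parent_fraction_table()]), and `truth` (the generating
#'   `input_function`).
#' @export
generate_input <- function(config, seed = config$seed,
                           condition = c("baseline", "blocking")) {
  condition <- match.arg(condition)
  truth <- truth_input(config, condition)
  set.seed(seed)
  tb <- config$blood_times
  pl <- eval_plasma(truth$plasma, tb)
  wb <- eval_plasma(truth$whole_blood, tb)
  if (config$blood_cv > 0) {
    pl <- pmax(pl * (1 + rnorm(length(tb), 0, config$blood_cv)), 0)
    wb <- pmax(wb * (1 + rnorm(length(tb), 0, config$blood_cv)), 0)
  }
  tp <- config$parent_times
  pf <- eval_parent_fraction(truth$parent, tp)
  if (config$parent_sd > 0)
    pf <- pmin(pmax(pf + rnorm(length(tp), 0, config$parent_sd), 0), 1)
  list(blood = blood_sample_table(tb, wb, pl),
       parent = parent_fraction_table(tp, pf),
       truth = truth)
}

## Regional kinetic truth for one condition. Blocking keeps K1 (and hence
## delivery) fixed and raises k2 so that
## V_T_block = V_ND + (1 - r) * (V_T_base - V_ND).
roi_truth_condition <- function(config, animal = 1L,
                                condition = c("baseline", "blocking")) {
  condition <- match.arg(condition)
  rt <- config$roi_truth
  if (condition == "blocking") {
    r <- config$occupancy[animal]
    rt$V_T <- config$V_ND + (1 - r) * (rt$V_T - config$V_ND)
  }
  rt$k2 <- rt$K1 / rt$V_T
  rt
}

#' Generate noisy regional time-activity curves
#'
#' Forward-models each region's TAC from its ground-truth kinetic
#' parameters through [predict_tac()] and adds zero-mean Gaussian noise
#' with SD proportional to sqrt(activity / frame duration) — the standard
#' count-statistics surrogate — scaled so the peak frame has the target
#' CV.
#'
#' @param config A [synthetic_study_config()].
#' @param input Generating `input_function` (defaults to the truth curve
#'   for the chosen condition).
#' @param seed Stream seed.
#' @param condition `"baseline"` or `"blocking"`.
#' @param animal Animal index (selects the per-animal occupancy).
#' @return List with `tacs` (named list of [tac()]) and `truth` (data
#'   frame of generating parameters per region).
#' @export
generate_tacs <- function(config, input = NULL, seed = config$seed,
                          condition = c("baseline", "blocking"),
                          animal = 1L) {
  condition <- match.arg(condition)
  if (is.null(input)) input <- truth_input(config, condition)
  rt <- roi_truth_condition(config, animal, condition)
  sched <- config$schedule
  set.seed(seed)
  tacs <- vector("list", nrow(rt))
  for (i in seq_len(nrow(rt))) {
    kp <- kinetic_parameters("1TCM", K1 = rt$K1[i], k2 = rt$k2[i],
                             V_b = rt$V_b[i], delta_t = config$delta_t)
    pred <- predict_tac(kp, input, sched)
    act <- pred
    if (config$tac_peak_cv > 0) {
      ipk <- which.max(pred)
      sigma0 <- config$tac_peak_cv * pred[ipk] /
        sqrt(pred[ipk] / sched$dur[ipk])
      sd_i <- sigma0 * sqrt(pmax(pred, 0) / sched$dur)
      act <- pred + rnorm(length(pred), 0, sd_i)
    }
    tacs[[i]] <- tac(rt$roi[i], sched, act)
  }
  names(tacs) <- rt$roi
  list(tacs = tacs, truth = rt, condition = condition)
}

#' Generate a complete multi-animal baseline/blocking study on disk
#'
#' Writes, per animal and condition, a TAC CSV, a blood CSV and a
#' parent-fraction CSV; a study manifest (`manifest.csv`) with scan
#' metadata (free fraction, dose, weight, condition); and a
#' `ground_truth.json` sufficient to recompute every generated curve
#' bit-exactly given the seed.
#'
#' @param config A [synthetic_study_config()].
#' @param outdir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return The manifest as a data frame (invisibly: paths are relative to
#'   `outdir`).
#' @export
generate_study <- function(config, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !force)
    stop_petkin("output directory '%s' is not empty (use force = TRUE)", outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ## stream order: for each animal, for each condition: blood, then TACs
  seeds <- child_seeds(config$seed, config$n_animals * 4L)
  manifest <- list()
  truth_rec <- list(config = unclass_config(config), scans = list())
  k <- 0L
  for (a in seq_len(config$n_animals)) {
    for (cond in c("baseline", "blocking")) {
      k <- k + 1L
      seed_blood <- seeds[2L * k - 1L]
      seed_tac <- seeds[2L * k]
      scan_id <- sprintf("m%02d_%s", a, cond)
      inp <- generate_input(config, seed = seed_blood, condition = cond)
      gt <- generate_tacs(config, input = inp$truth, seed = seed_tac,
                          condition = cond, animal = a)
      tac_file <- sprintf("%s_tac.csv", scan_id)
      blood_file <- sprintf("%s_blood.csv", scan_id)
      parent_file <- sprintf("%s_parent.csv", scan_id)
      write_tac_csv(gt$tacs, file.path(outdir, tac_file), seed = seed_tac)
      write_blood_csv(inp$blood, file.path(outdir, blood_file), seed = seed_blood)
      write_parent_csv(inp$parent, file.path(outdir, parent_file), seed = seed_blood)
      manifest[[k]] <- data.frame(
        scan_id = scan_id, animal_id = sprintf("m%02d", a), tracer = "synthetic",
        condition = cond, tac_file = tac_file, blood_file = blood_file,
        parent_file = parent_file, f_p = config$f_p,
        injected_dose_MBq = config$injected_dose_MBq,
        body_weight_kg = config$body_weight_kg)
      truth_rec$scans[[scan_id]] <- list(
        animal = a, condition = cond, seed_blood = seed_blood,
        seed_tac = seed_tac,
        occupancy = config$occupancy[a], V_ND = config$V_ND,
        roi_truth = roi_truth_condition(config, a, cond))
    }
  }
  manifest <- do.call(rbind, manifest)
  write_csv_commented(manifest, file.path(outdir, "manifest.csv"),
                      seed = config$seed)
  jsonlite::write_json(truth_rec, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(manifest)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$schedule <- data.frame(frame_start = config$schedule$frame_start,
                             frame_end = config$schedule$frame_end)
  out
}
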