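## Study-level orchestration: manifest in, fit/selection/occupancy
## reports out. Per-scan failures are isolated; a run fails only when
## every scan fails.

#' Read a study manifest
#'
#' A manifest CSV has one row per scan with columns `scan_id`,
#' `animal_id`, `tracer`, `condition` (baseline/blocking), `tac_file`,
#' `blood_file`, `parent_file`, `f_p`, `injected_dose_MBq`,
#' `body_weight_kg`. File paths are resolved relative to the manifest's
#' directory.
#'
#' @param path Manifest CSV path.
#' @return Data frame with an attribute `dir` (the manifest directory).
#' @export
read_manifest <- function(path) {
  df <- read_csv_commented(path)
  need <- c("scan_id", "animal_id", "tracer", "condition", "tac_file",
            "blood_file", "parent_file", "f_p")
  if (!all(need %in% names(df)))
    stop_petkin("manifest '%s' must have columns %s", path,
                paste(need, collapse = ", "))
  if (!all(df$condition %in% c("baseline", "blocking")))
    stop_petkin("manifest conditions must be 'baseline' or 'blocking'")
  attr(df, "dir") <- dirname(normalizePath(path))
  df
}

## Unweighted mean of the regional TACs: the whole-brain surrogate used
## for delay estimation when no whole-brain region is provided.
mean_tac <- function(tacs) {
  act <- rowMeans(vapply(tacs, function(t) t$activity,
                         numeric(nrow(tacs[[1]]$schedule))))
  tac("whole_brain_mean", tacs[[1]]$schedule, act)
}

#' Quantify every scan of a study
#'
#' For each manifest row: fit the input function (plasma and whole-blood
#' sum-of-exponentials, integrated-gamma parent fraction), estimate the
#' blood-to-tissue delay from the first 10 min of the whole-brain curve
#' (the unweighted mean of the regional TACs, unless a region named in
#' `whole_brain_roi` exists), fit the requested compartment models per
#' region with that fixed delay, and run model selection. Deterministic
#' given the input files.
#'
#' @param manifest A data frame from [read_manifest()] (or a path).
#' @param models Models to fit (default all three).
#' @param n_exponentials Plasma-fit exponential order (1-3 or "auto").
#' @param whole_brain_roi Optional name of a region to use for delay
#'   estimation.
#' @param outdir Optional directory for `fits.csv` and `selection.csv`.
#' @param step Fine-grid step, minutes.
#' @param verbose Log each scan/region/model to the console.
#' @return Object of class `quantify_result`: per-scan list with the
#'   input function, delay, fits and selections, plus `fits` and
#'   `selection` data frames and a per-scan `errors` list.
#' @export
run_quantify <- function(manifest, models = c("1TCM", "2TCM", "2TiCM"),
                         n_exponentials = 3, whole_brain_roi = NULL,
                         outdir = NULL, step = 0.05, verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir <- attr(manifest, "dir") %||% "."
  scans <- list(); fit_rows <- list(); sel_rows <- list(); errors <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch(
      quantify_scan(row, dir, models, n_exponentials, whole_brain_roi,
                    step, verbose),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[row$scan_id]] <- conditionMessage(res)
      warning(sprintf("scan '%s' failed: %s", row$scan_id,
                      conditionMessage(res)), call. = FALSE)
      next
    }
    scans[[row$scan_id]] <- res
    fit_rows[[row$scan_id]] <- res$fit_table
    sel_rows[[row$scan_id]] <- res$sel_table
  }
  if (length(scans) == 0L)
    stop_petkin("all %d scans failed; first error: %s", nrow(manifest),
                errors[[1]])
  fits <- do.call(rbind, fit_rows); rownames(fits) <- NULL
  selection <- do.call(rbind, sel_rows); rownames(selection) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_csv_commented(fits, file.path(outdir, "fits.csv"))
    write_csv_commented(selection, file.path(outdir, "selection.csv"))
  }
  structure(list(scans = scans, fits = fits, selection = selection,
                 errors = errors, manifest = manifest),
            class = "quantify_result")
}

quantify_scan <- function(row, dir, models, n_exponentials, whole_brain_roi,
                          step, verbose) {
  paths <- file.path(dir, c(row$tac_file, row$blood_file, row$parent_file))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_petkin("missing input file(s): %s", paste(missing, collapse = ", "))
  tacs <- read_tac_csv(paths[1])
  blood <- read_blood_csv(paths[2])
  parent <- read_parent_csv(paths[3])
  plasma <- fit_plasma_curve(blood, n_exponentials, "plasma")
  wb <- fit_plasma_curve(blood, n_exponentials, "whole_blood")
  pf <- fit_parent_fraction(parent)
  input <- make_input_function(plasma, pf, wb, row$f_p)
  wb_tac <- if (!is.null(whole_brain_roi) && whole_brain_roi %in% names(tacs))
    tacs[[whole_brain_roi]] else mean_tac(tacs)
  delay <- estimate_delay(wb_tac, input, step = step)
  fits <- list(); frows <- list(); srows <- list(); selections <- list()
  for (roi in names(tacs)) {
    roi_fits <- list()
    for (m in models) {
      f <- fit_tissue_model(tacs[[roi]], input, m,
                            fixed_delay = delay$delta_t, step = step)
      if (verbose)
        message(sprintf("[%s] %s %s: WRSS=%.4g AIC=%.2f conv=%s",
                        row$scan_id, roi, m, f$wrss, f$aic, f$converged))
      roi_fits[[m]] <- f
      frows[[paste(roi, m)]] <- data.frame(
        scan_id = row$scan_id, roi = roi, model = m,
        K1 = f$parameters$K1, K1_uL = 1000 * f$parameters$K1,
        k2 = f$parameters$k2, k3 = f$parameters$k3, k4 = f$parameters$k4,
        V_b = f$parameters$V_b, delta_t = f$parameters$delta_t,
        K1_se = f$se[["K1"]], K1_rse = f$rse[["K1"]],
        wrss = f$wrss, aic = f$aic,
        V_T = if (is.null(f$V_T)) NA_real_ else f$V_T,
        K_i = if (is.null(f$K_i)) NA_real_ else f$K_i,
        primary_rse = f$primary_rse, converged = f$converged)
    }
    sel <- select_model(roi_fits)
    selections[[roi]] <- sel
    srows[[roi]] <- data.frame(
      scan_id = row$scan_id, roi = roi, chosen_model = sel$chosen_model,
      aic_1TCM = sel$table$aic[sel$table$model == "1TCM"],
      aic_2TCM = if ("2TCM" %in% sel$table$model)
        sel$table$aic[sel$table$model == "2TCM"] else NA_real_,
      aic_2TiCM = if ("2TiCM" %in% sel$table$model)
        sel$table$aic[sel$table$model == "2TiCM"] else NA_real_,
      f_p_value = if (!is.null(sel$f_tests[["1TCM_vs_2TCM"]]))
        sel$f_tests[["1TCM_vs_2TCM"]]$p_value else NA_real_,
      primary_rse = sel$table$primary_rse[sel$table$model == sel$chosen_model],
      f_test_significant = sel$flags$f_test_significant,
      rse_reliable = sel$flags$rSE_reliable)
    fits[[roi]] <- roi_fits
  }
  list(scan_id = row$scan_id, input = input, delay = delay, fits = fits,
       selections = selections,
       fit_table = do.call(rbind, frows), sel_table = do.call(rbind, srows))
}

#' @export
print.quantify_result <- function(x, ...) {
  cat(sprintf("<quantify_result> %d scan(s), %d fit rows, %d failed scan(s)\n",
              length(x$scans), nrow(x$fits), length(x$errors)))
  invisible(x)
}

#' Occupancy and BP_ND from paired baseline/blocking scans
#'
#' Groups a [run_quantify()] result by animal and tracer, requires one
#' baseline and one blocking scan per group, runs a Lassen occupancy
#' regression per animal on the chosen model's regional V_T values,
#' averages V_ND across animals, and tabulates BP_ND for both conditions
#' using that averaged V_ND.
#'
#' @param quantified A `quantify_result`.
#' @param model Model whose V_T feeds the occupancy plot (default 1TCM).
#' @param outdir Optional directory for `occupancy.csv` and `bpnd.csv`.
#' @return Object of class `occupancy_report`: per-animal `occupancy_fit`
#'   list, `occupancy` and `bpnd` data frames, `mean_V_ND`.
#' @export
run_occupancy <- function(quantified, model = "1TCM", outdir = NULL) {
  fits <- quantified$fits
  man <- quantified$manifest
  man <- man[man$scan_id %in% names(quantified$scans), ]
  groups <- split(man, paste(man$animal_id, man$tracer))
  unpaired <- names(groups)[!vapply(groups, function(g)
    all(c("baseline", "blocking") %in% g$condition), logical(1))]
  if (length(unpaired))
    stop_petkin("unpaired scans for: %s", paste(unpaired, collapse = ", "))
  occ_fits <- list(); occ_rows <- list()
  vt_tables <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    vt_of <- function(cond) {
      sid <- g$scan_id[g$condition == cond][1]
      sub <- fits[fits$scan_id == sid & fits$model == model, ]
      setNames(sub$V_T, sub$roi)
    }
    vb <- vt_of("baseline"); vk <- vt_of("blocking")
    rois <- intersect(names(vb), names(vk))
    lf <- lassen_fit(vb[rois], vk[rois], roi_name = rois)
    occ_fits[[gname]] <- lf
    occ_rows[[gname]] <- data.frame(
      group = gname, animal_id = g$animal_id[1], tracer = g$tracer[1],
      occupancy = lf$r, occupancy_se = lf$r_se, V_ND = lf$V_ND,
      V_ND_se = lf$V_ND_se, n_rois = lf$n_rois)
    vt_tables[[gname]] <- data.frame(roi = rois, V_T_baseline = vb[rois],
                                     V_T_blocking = vk[rois])
  }
  occupancy <- do.call(rbind, occ_rows); rownames(occupancy) <- NULL
  mean_V_ND <- mean(occupancy$V_ND, na.rm = TRUE)
  sd_V_ND <- if (nrow(occupancy) > 1L) sd(occupancy$V_ND, na.rm = TRUE) else NA_real_
  ## BP_ND tables against the across-animal mean V_ND, regional V_T
  ## averaged across animals per condition
  allvt <- do.call(rbind, vt_tables)
  agg <- aggregate(cbind(V_T_baseline, V_T_blocking) ~ roi, allvt, mean)
  bpnd <- data.frame(roi = agg$roi,
                     V_T_baseline = agg$V_T_baseline,
                     V_T_blocking = agg$V_T_blocking,
                     BP_ND_baseline = compute_bpnd(agg$V_T_baseline, mean_V_ND),
                     BP_ND_blocking = compute_bpnd(agg$V_T_blocking, mean_V_ND))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_csv_commented(occupancy, file.path(outdir, "occupancy.csv"))
    write_csv_commented(bpnd, file.path(outdir, "bpnd.csv"))
  }
  structure(list(fits = occ_fits, occupancy = occupancy, bpnd = bpnd,
                 mean_V_ND = mean_V_ND, sd_V_ND = sd_V_ND, model = model,
                 single_animal = nrow(occupancy) == 1L),
            class = "occupancy_report")
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat(sprintf("<occupancy_report> (%s V_T) %d animal/tracer group(s)\n",
              x$model, nrow(x$occupancy)))
  print(x$occupancy, row.names = FALSE)
  if (x$single_animal)
    cat("  single animal: across-animal SD omitted\n")
  else
    cat(sprintf("  mean V_ND = %.3f +/- %.3f mL/cm3\n", x$mean_V_ND, x$sd_V_ND))
  invisible(x)
}

#' Generate a synthetic study (pipeline wrapper)
#'
#' Thin wrapper over [generate_study()] so simulation sits beside
#' quantification in the pipeline interface; the emitted manifest is
#' directly consumable by [run_quantify()].
#'
#' @inheritParams generate_study
#' @return The manifest data frame, invisibly.
#' @export
run_simulate <- function(config, outdir, force = FALSE) {
  generate_study(config, outdir, force = force)
}

#' Time-stability analysis for every scan of a quantified study
#'
#' Reruns [time_stability()] for each scan, using that scan's fitted
#' input function and delay.
#'
#' @param quantified A `quantify_result`.
#' @param manifest_dir Directory holding the scan files (defaults to the
#'   manifest's directory).
#' @param endpoints Truncation endpoints, minutes.
#' @param model_kind Model to refit.
#' @param outdir Optional directory for `stability.csv`.
#' @param step Fine-grid step.
#' @return A `stability_report` data frame with a `scan_id` column.
#' @export
run_stability <- function(quantified, endpoints = seq(180, 60, by = -30),
                          model_kind = "1TCM", outdir = NULL, step = 0.05,
                          manifest_dir = NULL) {
  dir <- manifest_dir %||% attr(quantified$manifest, "dir") %||% "."
  out <- list()
  for (sid in names(quantified$scans)) {
    scan <- quantified$scans[[sid]]
    row <- quantified$manifest[quantified$manifest$scan_id == sid, ]
    tacs <- read_tac_csv(file.path(dir, row$tac_file))
    rep <- time_stability(tacs, scan$input, endpoints, model_kind,
                          fixed_delay = scan$delay$delta_t, step = step)
    rep$scan_id <- sid
    out[[sid]] <- rep
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_csv_commented(res, file.path(outdir, "stability.csv"))
  }
  class(res) <- c("stability_report", "data.frame")
  res
}
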