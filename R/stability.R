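## Time-stability and rest-period ("broken scan") analyses: drop frames,
## refit with the full-scan delay, and report the percent change of the
## macroparameters against the full-scan estimate. The percent-difference
## denominator is always the full-scan value.

refit_report <- function(tac, input, keep, model_kind, fixed_delay,
                         full_fit, label, step = 0.05) {
  n_free <- length(free_param_names(model_kind))
  if (sum(keep) < n_free + 2L)
    return(data.frame(roi = tac$roi_name, spec = label, ok = FALSE,
                      V_T_full = full_fit$V_T, V_T_short = NA_real_,
                      K1_full = full_fit$parameters$K1, K1_short = NA_real_,
                      pct_diff_V_T = NA_real_, pct_diff_K1 = NA_real_,
                      pass_10pct = NA,
                      note = sprintf("only %d frames left, %d required",
                                     sum(keep), n_free + 2L)))
  short <- fit_tissue_model(subset_tac(tac, keep), input, model_kind,
                            fixed_delay = fixed_delay, step = step)
  pdV <- 100 * (short$V_T - full_fit$V_T) / full_fit$V_T
  pdK <- 100 * (short$parameters$K1 - full_fit$parameters$K1) /
    full_fit$parameters$K1
  data.frame(roi = tac$roi_name, spec = label, ok = TRUE,
             V_T_full = full_fit$V_T, V_T_short = short$V_T,
             K1_full = full_fit$parameters$K1, K1_short = short$parameters$K1,
             pct_diff_V_T = pdV, pct_diff_K1 = pdK,
             pass_10pct = abs(pdV) <= 10, note = "")
}

#' Time stability of kinetic parameters under scan shortening
#'
#' Refits the model on time-activity curves truncated at each endpoint
#' (frames ending after the endpoint are dropped; the full-scan delay is
#' reused) and reports the percent difference of V_T and K1 against the
#' full-scan fit. A shortened protocol is conventionally deemed feasible
#' when V_T stays within 10 percent.
#'
#' @param tac A [tac()] (or list of them).
#' @param input An input function.
#' @param endpoints Truncation endpoints in minutes; default 180 down to
#'   60 in 30-min steps.
#' @param model_kind Compartment model to refit.
#' @param fixed_delay Delay (minutes) reused for every refit.
#' @param step Fine-grid step.
#' @return A `stability_report` data frame with one row per
#'   (roi, endpoint): V_T and K1 full/short, percent differences, a
#'   10-percent pass flag, and per-endpoint failure notes.
#' @export
time_stability <- function(tac, input, endpoints = seq(180, 60, by = -30),
                           model_kind = "1TCM", fixed_delay = 0, step = 0.05) {
  tacs <- if (inherits(tac, "tac")) list(tac) else tac
  out <- list()
  for (tc in tacs) {
    scan_end <- max(tc$schedule$frame_end)
    full <- fit_tissue_model(tc, input, model_kind, fixed_delay = fixed_delay,
                             step = step)
    for (ep in endpoints) {
      if (ep <= 0 || ep > scan_end + 1e-9) {
        out[[length(out) + 1L]] <- data.frame(
          roi = tc$roi_name, spec = sprintf("end=%g", ep), ok = FALSE,
          V_T_full = full$V_T, V_T_short = NA_real_,
          K1_full = full$parameters$K1, K1_short = NA_real_,
          pct_diff_V_T = NA_real_, pct_diff_K1 = NA_real_, pass_10pct = NA,
          note = "endpoint outside (0, scan length]")
        next
      }
      keep <- tc$schedule$frame_end <= ep + 1e-9
      out[[length(out) + 1L]] <-
        refit_report(tc, input, keep, model_kind, fixed_delay, full,
                     sprintf("end=%g", ep), step)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("stability_report", "data.frame")
  res
}

#' Rest-period ("broken scan") analysis
#'
#' Removes the frames overlapping a gap `[gap_start, gap_start +
#' gap_duration]`, refits with the full-scan delay, and reports percent
#' differences of V_T and K1 against the full-scan fit.
#'
#' @inheritParams time_stability
#' @param gap_start Gap start, minutes post injection.
#' @param gap_duration Gap length in minutes (0 is a no-op).
#' @return A `stability_report` data frame.
#' @export
rest_period_analysis <- function(tac, input, gap_start, gap_duration,
                                 model_kind = "1TCM", fixed_delay = 0,
                                 step = 0.05) {
  tacs <- if (inherits(tac, "tac")) list(tac) else tac
  out <- list()
  for (tc in tacs) {
    scan_end <- max(tc$schedule$frame_end)
    if (gap_start < 0 || gap_start + gap_duration > scan_end + 1e-9)
      stop_petkin("gap [%g, %g] must lie inside the scan (0-%g min)",
                  gap_start, gap_start + gap_duration, scan_end)
    full <- fit_tissue_model(tc, input, model_kind, fixed_delay = fixed_delay,
                             step = step)
    gap_end <- gap_start + gap_duration
    keep <- tc$schedule$frame_end <= gap_start + 1e-9 |
      tc$schedule$frame_start >= gap_end - 1e-9
    out[[length(out) + 1L]] <-
      refit_report(tc, input, keep, model_kind, fixed_delay, full,
                   sprintf("gap=%g+%g", gap_start, gap_duration), step)
  }
  res <- do.call(rbind, out)
  class(res) <- c("stability_report", "data.frame")
  res
}
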