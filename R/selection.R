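## Model selection among 1TCM / 2TCM / 2TiCM fits of one TAC.
##
## A more complex model is preferred over the one-tissue model only when
## it wins jointly: nested F-test p <= alpha AND lowest AIC. The
## irreversible model is not nested in the one-tissue model in the
## required direction (k4 = 0 vs k3 = 0), so that comparison uses AIC
## alone; the F-test is computed for the nested pairs 1TCM in 2TCM and
## 2TiCM in 2TCM. Reliability of the primary macroparameter (V_T or K_i)
## is flagged by its relative standard error.

#' Akaike information criterion from a weighted residual sum of squares
#'
#' AIC = n * ln(WRSS / n) + 2p. With `correct = TRUE` the small-sample
#' correction 2p(p + 1)/(n - p - 1) is added (AICc).
#'
#' @param wrss Positive weighted residual sum of squares.
#' @param n Number of frames.
#' @param p Number of free parameters (n > p).
#' @param correct Use the AICc small-sample correction (default FALSE).
#' @return Unitless AIC.
#' @export
aic <- function(wrss, n, p, correct = FALSE) {
  if (!is.finite(wrss) || wrss <= 0) stop_petkin("WRSS must be positive, got %g", wrss)
  if (n <= p) stop_petkin("AIC requires n > p (n = %d, p = %d)", n, p)
  out <- n * log(wrss / n) + 2 * p
  if (correct) out <- out + 2 * p * (p + 1) / (n - p - 1)
  out
}

#' F-test between two nested least-squares fits
#'
#' @param wrss_simple,wrss_complex Weighted residual sums of squares of
#'   the simpler and the more complex model.
#' @param p_simple,p_complex Free-parameter counts (p_complex > p_simple).
#' @param n Number of frames (n > p_complex).
#' @return List with `F` and `p_value` (F distribution with
#'   `(p_complex - p_simple, n - p_complex)` degrees of freedom). When the
#'   complex fit is worse (larger WRSS), F is clipped to 0 and p = 1.
#' @export
f_test_nested <- function(wrss_simple, p_simple, wrss_complex, p_complex, n) {
  if (p_complex <= p_simple) stop_petkin("p_complex must exceed p_simple")
  if (n <= p_complex) stop_petkin("F-test requires n > p_complex")
  df1 <- p_complex - p_simple
  df2 <- n - p_complex
  if (wrss_complex > wrss_simple)
    return(list(F = 0, p_value = 1, df1 = df1, df2 = df2))
  Fv <- ((wrss_simple - wrss_complex) / df1) / (wrss_complex / df2)
  list(F = Fv, p_value = pf(Fv, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Select the best compartment model for a time-activity curve
#'
#' @param fits Named list of `tissue_fit` objects; must contain `"1TCM"`,
#'   optionally `"2TCM"` and/or `"2TiCM"`, all fitted to the same frames.
#' @param alpha F-test significance level (default 0.05).
#' @param rse_threshold Reliability threshold on the primary-parameter
#'   relative standard error, percent (default 10).
#' @return Object of class `model_comparison`: the chosen model label, a
#'   per-model table (WRSS, AIC, primary rSE, flags), and the F-tests.
#' @export
select_model <- function(fits, alpha = 0.05, rse_threshold = 10) {
  if (length(fits) == 0L) stop_petkin("empty fit set")
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$parameters$model_kind, character(1))
  if (!"1TCM" %in% names(fits)) stop_petkin("a 1TCM fit is required")
  kinds <- names(fits)
  n <- fits[["1TCM"]]$n_frames
  tab <- data.frame(
    model = kinds,
    wrss = vapply(fits, function(f) f$wrss, numeric(1)),
    n_free = vapply(fits, function(f) f$n_free, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    primary = vapply(fits, function(f) f$primary_parameter, character(1)),
    primary_rse = vapply(fits, function(f) f$primary_rse %||% NA_real_, numeric(1)),
    row.names = NULL)
  tab$rse_reliable <- !is.na(tab$primary_rse) & tab$primary_rse <= rse_threshold
  tab$lowest_aic <- tab$aic <= min(tab$aic) + 1e-12

  ftests <- list()
  for (cx in intersect(c("2TCM"), kinds)) {
    ftests[["1TCM_vs_2TCM"]] <- f_test_nested(fits[["1TCM"]]$wrss, fits[["1TCM"]]$n_free,
                                              fits[[cx]]$wrss, fits[[cx]]$n_free, n)
  }
  if (all(c("2TiCM", "2TCM") %in% kinds))
    ftests[["2TiCM_vs_2TCM"]] <- f_test_nested(fits[["2TiCM"]]$wrss, fits[["2TiCM"]]$n_free,
                                               fits[["2TCM"]]$wrss, fits[["2TCM"]]$n_free, n)

  chosen <- "1TCM"
  f_flag <- FALSE
  if ("2TCM" %in% kinds) {
    p2 <- ftests[["1TCM_vs_2TCM"]]$p_value
    if (p2 <= alpha && tab$lowest_aic[tab$model == "2TCM"]) {
      chosen <- "2TCM"; f_flag <- TRUE
    }
  }
  if (chosen == "1TCM" && "2TiCM" %in% kinds) {
    ## non-nested against 1TCM: AIC-only rule
    if (tab$lowest_aic[tab$model == "2TiCM"]) chosen <- "2TiCM"
  }
  structure(list(chosen_model = chosen, table = tab, f_tests = ftests,
                 alpha = alpha, rse_threshold = rse_threshold,
                 n_frames = n,
                 flags = list(
                   f_test_significant = f_flag,
                   lowest_AIC = tab$lowest_aic[tab$model == chosen],
                   rSE_reliable = tab$rse_reliable[tab$model == chosen])),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> chosen: %s (alpha=%.3g, rSE threshold %.3g%%)\n",
              x$chosen_model, x$alpha, x$rse_threshold))
  print(x$table, row.names = FALSE)
  invisible(x)
}
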