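## Occupancy (Lassen) plots, BP_ND, and cross-tracer Guo plots.

#' Lassen occupancy plot
#'
#' Regresses the blocking-induced decrease in the total volume of
#' distribution on its baseline value across regions:
#' `V_T_baseline - V_T_blocking = r * (V_T_baseline - V_ND)`. The slope is
#' the target occupancy `r` of the blocking drug; the x-intercept is the
#' nondisplaceable distribution volume `V_ND`, assumed shared across
#' regions. Standard errors come from the regression, V_ND's by the delta
#' method. Ordinary least squares is the default; `method = "tls"` fits
#' by total least squares (first principal axis), since both axes carry
#' estimation error.
#'
#' @param vt_baseline,vt_blocking Paired regional V_T values, mL/cm3.
#' @param roi_name Optional region labels.
#' @param method `"ols"` (default) or `"tls"`.
#' @return Object of class `occupancy_fit`: `r`, `V_ND`, `r_se`,
#'   `V_ND_se`, `n_rois`, `vnd_defined`, and the underlying regression.
#' @export
lassen_fit <- function(vt_baseline, vt_blocking, roi_name = NULL,
                       method = c("ols", "tls")) {
  method <- match.arg(method)
  if (length(vt_baseline) != length(vt_blocking))
    stop_petkin("baseline and blocking V_T vectors must be paired")
  n <- length(vt_baseline)
  if (n < 3L) stop_petkin("occupancy regression needs at least 3 regions, got %d", n)
  if (diff(range(vt_baseline)) < 1e-12)
    stop_petkin("baseline V_T values are all equal; occupancy slope is unidentifiable")
  x <- as.numeric(vt_baseline)
  y <- x - as.numeric(vt_blocking)
  if (method == "ols") {
    fit <- lm(y ~ x)
    b <- unname(coef(fit)[1]); r <- unname(coef(fit)[2])
    V <- suppressWarnings(vcov(fit))  # degenerate (noiseless) fits warn here
    r_se <- sqrt(V[2, 2]); b_se <- sqrt(V[1, 1]); cov_rb <- V[1, 2]
  } else {
    mx <- mean(x); my <- mean(y)
    sv <- svd(cbind(x - mx, y - my))
    v <- sv$v[, 1]
    r <- v[2] / v[1]
    b <- my - r * mx
    ## jackknife SEs for the principal-axis slope/intercept
    rs <- bs <- numeric(n)
    for (i in seq_len(n)) {
      xi <- x[-i]; yi <- y[-i]
      svi <- svd(cbind(xi - mean(xi), yi - mean(yi)))
      vi <- svi$v[, 1]
      rs[i] <- vi[2] / vi[1]
      bs[i] <- mean(yi) - rs[i] * mean(xi)
    }
    r_se <- sqrt((n - 1) / n * sum((rs - mean(rs))^2))
    b_se <- sqrt((n - 1) / n * sum((bs - mean(bs))^2))
    cov_rb <- (n - 1) / n * sum((rs - mean(rs)) * (bs - mean(bs)))
    fit <- NULL
  }
  vnd_defined <- abs(r) > 1e-8
  if (vnd_defined) {
    V_ND <- -b / r
    ## delta method: V_ND = -b/r, d/db = -1/r, d/dr = b/r^2
    g <- c(-1 / r, b / r^2)
    V_ND_se <- sqrt(max(g[1]^2 * b_se^2 + g[2]^2 * r_se^2 +
                          2 * g[1] * g[2] * cov_rb, 0))
  } else {
    V_ND <- NA_real_
    V_ND_se <- NA_real_
  }
  structure(list(r = r, V_ND = V_ND, r_se = r_se, V_ND_se = V_ND_se,
                 intercept = b, intercept_se = b_se, n_rois = n,
                 vnd_defined = vnd_defined, method = method,
                 roi_name = roi_name, vt_baseline = x, delta_vt = y,
                 lm_fit = fit),
            class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("<occupancy_fit> (%s, %d ROIs) occupancy r = %.3f (SE %.3f)",
              x$method, x$n_rois, x$r, x$r_se))
  if (x$vnd_defined)
    cat(sprintf("; V_ND = %.3f mL/cm3 (SE %.3f)\n", x$V_ND, x$V_ND_se))
  else cat("; V_ND undefined (no measurable blocking effect)\n")
  invisible(x)
}

#' Nondisplaceable binding potential
#'
#' `BP_ND = V_T / V_ND - 1`.
#'
#' @param V_T Total volume of distribution, mL/cm3 (vector allowed).
#' @param V_ND Nondisplaceable volume of distribution, mL/cm3, > 0.
#' @return Unitless BP_ND.
#' @export
compute_bpnd <- function(V_T, V_ND) {
  if (!is.numeric(V_ND) || length(V_ND) != 1L || !is.finite(V_ND) || V_ND <= 0)
    stop_petkin("V_ND must be a single positive number, got %s",
                paste(V_ND, collapse = ","))
  V_T / V_ND - 1
}

#' Guo plot: cross-tracer comparison from baseline V_T values
#'
#' Regresses tracer A's regional baseline V_T on tracer B's. Under shared
#' specific binding the slope equals `f_p^A K_D^B / (f_p^B K_D^A)`, so
#' the affinity ratio `K_D^B / K_D^A = slope * f_p^B / f_p^A`. When V_ND
#' values for both tracers are supplied, the BP_ND ratio (A/B) is derived
#' as `slope * V_ND^B / V_ND^A`, and the intercept is additionally
#' reported normalized by tracer A's V_ND.
#'
#' @param vt_A,vt_B Baseline V_T per region for the two tracers (paired).
#' @param f_p_A,f_p_B Plasma free fractions (same units for both; percent
#'   or fraction).
#' @param V_ND_A,V_ND_B Optional nondisplaceable volumes, mL/cm3.
#' @return Object of class `guo_fit`: `slope`, `intercept`, their SEs,
#'   `KD_ratio` (K_D^B / K_D^A), `BP_ratio` (A/B, or NA),
#'   `intercept_normalized` (intercept / V_ND_A, or NA).
#' @export
guo_fit <- function(vt_A, vt_B, f_p_A, f_p_B, V_ND_A = NULL, V_ND_B = NULL) {
  if (length(vt_A) != length(vt_B))
    stop_petkin("the two tracers must share the same region set")
  if (length(vt_A) < 3L) stop_petkin("Guo plot needs at least 3 regions")
  if (diff(range(vt_B)) < 1e-12)
    stop_petkin("tracer-B V_T values are all equal; slope is unidentifiable")
  fit <- lm(vt_A ~ vt_B)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  ses <- sqrt(diag(suppressWarnings(vcov(fit))))
  KD_ratio <- slope * f_p_B / f_p_A
  BP_ratio <- if (!is.null(V_ND_A) && !is.null(V_ND_B))
    slope * mean(V_ND_B) / mean(V_ND_A) else NA_real_
  intercept_normalized <- if (!is.null(V_ND_A)) intercept / mean(V_ND_A) else NA_real_
  structure(list(slope = slope, intercept = intercept,
                 slope_se = unname(ses[2]), intercept_se = unname(ses[1]),
                 KD_ratio = KD_ratio, BP_ratio = BP_ratio,
                 intercept_normalized = intercept_normalized,
                 f_p_A = f_p_A, f_p_B = f_p_B, n_rois = length(vt_A),
                 lm_fit = fit),
            class = "guo_fit")
}

#' @export
print.guo_fit <- function(x, ...) {
  cat(sprintf("<guo_fit> (%d ROIs) slope = %.3f (SE %.3f), intercept = %.3f mL/cm3\n",
              x$n_rois, x$slope, x$slope_se, x$intercept))
  cat(sprintf("  K_D ratio (B/A) = %.3f", x$KD_ratio))
  if (!is.na(x$BP_ratio)) cat(sprintf("; BP_ND ratio (A/B) = %.3f", x$BP_ratio))
  cat("\n")
  invisible(x)
}
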