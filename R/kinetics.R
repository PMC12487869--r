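## Compartment-model forward prediction and fitting.
##
## All three models share one impulse-response family: the tissue response
## to the metabolite-corrected plasma input C_p is a sum of (at most two)
## convolution terms K1 * phi_j * exp(-alpha_j t) (*) C_p, with
##   alpha_{1,2} = 0.5 * [(k2 + k3 + k4) -/+ sqrt((k2 + k3 + k4)^2 - 4 k2 k4)]
## for the two-tissue models, and a single term exp(-k2 t) for the
## one-tissue model. The measured PET concentration adds a fractional
## blood-volume term:
##   C_model(t) = (1 - V_b) * C_T(t) + V_b * C_wb(t - delta_t),
## with C_T driven by C_p(t - delta_t). Convolution is computed
## analytically for a piecewise-linear input sampled on a fine grid
## (default 0.05 min), then averaged over each frame by the trapezoid rule.

#' Kinetic parameter set for a compartment model
#'
#' @param model_kind One of `"1TCM"`, `"2TCM"`, `"2TiCM"`.
#' @param K1 Influx rate constant, mL plasma per min per cm3 tissue.
#' @param k2,k3,k4 Tissue rate constants, 1/min. `k3 = k4 = 0` for 1TCM;
#'   `k4 = 0` for the irreversible 2TiCM.
#' @param V_b Fractional blood volume in `[0, 0.2]`.
#' @param delta_t Blood-to-tissue time delay, minutes, in `[-3, 3]`.
#' @return Object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(model_kind = c("1TCM", "2TCM", "2TiCM"),
                               K1, k2, k3 = 0, k4 = 0, V_b = 0, delta_t = 0) {
  model_kind <- match.arg(model_kind)
  if (any(c(K1, k2, k3, k4) < 0)) stop_petkin("rate constants must be non-negative")
  if (V_b < 0 || V_b > 0.2) stop_petkin("V_b must lie in [0, 0.2], got %g", V_b)
  if (model_kind == "1TCM" && (k3 != 0 || k4 != 0))
    stop_petkin("1TCM requires k3 = k4 = 0")
  if (model_kind == "2TiCM" && k4 != 0)
    stop_petkin("2TiCM requires k4 = 0")
  structure(list(model_kind = model_kind, K1 = K1, k2 = k2, k3 = k3, k4 = k4,
                 V_b = V_b, delta_t = delta_t),
            class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat(sprintf("<kinetic_parameters> %s: K1=%.4g mL/min/cm3 (%.3g uL/min/cm3), k2=%.4g, k3=%.4g, k4=%.4g 1/min, V_b=%.3g, delta_t=%.3g min\n",
              x$model_kind, x$K1, 1000 * x$K1, x$k2, x$k3, x$k4, x$V_b, x$delta_t))
  invisible(x)
}

## Impulse-response decomposition: list of (amplitude phi_j, rate alpha_j)
## such that C_T = K1 * sum_j phi_j exp(-alpha_j t) (*) C_p.
impulse_terms <- function(model_kind, k2, k3, k4) {
  if (model_kind == "1TCM") return(list(phi = 1, alpha = k2))
  s <- k2 + k3 + k4
  disc <- sqrt(max(s^2 - 4 * k2 * k4, 0))
  a1 <- (s - disc) / 2
  a2 <- (s + disc) / 2
  if (a2 - a1 < 1e-10) a2 <- a1 + 1e-10  # repeated-root guard
  list(phi = c((k3 + k4 - a1) / (a2 - a1), (a2 - k3 - k4) / (a2 - a1)),
       alpha = c(a1, a2))
}

## Convolution of exp(-lambda t) with a piecewise-linear signal c on a
## uniform grid of step h: exact per-segment integrals accumulated by the
## recursion y[i+1] = E * y[i] + q[i], E = exp(-lambda h).
conv_exp_grid <- function(cvals, h, lambda) {
  n <- length(cvals)
  if (n < 2L) return(numeric(n))
  if (lambda * h < 1e-12) {
    ## lambda -> 0 limit: running trapezoidal integral
    q <- h * (cvals[-n] + cvals[-1]) / 2
    return(c(0, cumsum(q)))
  }
  E <- exp(-lambda * h)
  I0 <- (1 - E) / lambda
  I1 <- (1 - E * (1 + lambda * h)) / lambda^2
  m <- (cvals[-1] - cvals[-n]) / h
  q <- cvals[-1] * I0 - m * I1
  c(0, as.numeric(stats::filter(q, E, method = "recursive")))
}

## Fine evaluation grid covering a schedule; step must divide every frame
## boundary (0.05 min divides the 30-s frames of the default protocol).
model_grid <- function(schedule, step = 0.05) {
  tmax <- max(schedule$frame_end)
  seq(0, tmax, by = step)
}

## Instantaneous model concentration on a grid, given precomputed input
## values (cp, cwb already delayed). Used by the fitting objective.
model_curve_from_grids <- function(model_kind, K1, k2, k3, k4, V_b,
                                   cp, cwb, h) {
  terms <- impulse_terms(model_kind, k2, k3, k4)
  ct <- numeric(length(cp))
  for (j in seq_along(terms$alpha))
    ct <- ct + terms$phi[j] * conv_exp_grid(cp, h, terms$alpha[j])
  (1 - V_b) * K1 * ct + V_b * cwb
}

## Trapezoid frame averages of a grid curve. Frame boundaries must land on
## grid points (checked to 1e-6 min).
frame_average <- function(vals, grid, schedule) {
  h <- grid[2] - grid[1]
  i0 <- round(schedule$frame_start / h)
  i1 <- round(schedule$frame_end / h)
  if (max(abs(i0 * h - schedule$frame_start), abs(i1 * h - schedule$frame_end)) > 1e-6)
    stop_petkin("frame boundaries must be multiples of the grid step (%g min)", h)
  cs <- c(0, cumsum(vals))
  vapply(seq_len(nrow(schedule)), function(k) {
    a <- i0[k] + 1L; b <- i1[k] + 1L  # grid indices of the frame edges
    integ <- h * ((cs[b + 1L] - cs[a]) - (vals[a] + vals[b]) / 2)
    integ / (schedule$frame_end[k] - schedule$frame_start[k])
  }, numeric(1))
}

#' Predict a frame-averaged time-activity curve
#'
#' Forward model: analytic convolution of the compartmental impulse
#' response with the (delayed) piecewise-linear input on a fine grid,
#' blood-volume term added, then trapezoidal averaging over each frame.
#'
#' @param params A [kinetic_parameters()] set.
#' @param input An [make_input_function()] result.
#' @param schedule A [frame_schedule()].
#' @param step Fine-grid step in minutes (default 0.05).
#' @return Numeric vector of frame-averaged kBq/cm3, one per frame.
#' @export
predict_tac <- function(params, input, schedule, step = 0.05) {
  grid <- model_grid(schedule, step)
  cp <- eval_input(input, grid - params$delta_t)
  cwb <- eval_whole_blood(input, grid - params$delta_t)
  vals <- model_curve_from_grids(params$model_kind, params$K1, params$k2,
                                 params$k3, params$k4, params$V_b, cp, cwb,
                                 step)
  frame_average(vals, grid, schedule)
}

#' Instantaneous model tissue concentration
#'
#' Evaluates the continuous-time model concentration
#' `(1 - V_b) C_T(t) + V_b C_wb(t - delta_t)` at arbitrary times (no frame
#' averaging), by interpolation on the fine convolution grid.
#'
#' @inheritParams predict_tac
#' @param times Times in minutes.
#' @export
tissue_concentration <- function(params, input, times, step = 0.05) {
  tmax <- max(times)
  grid <- seq(0, tmax + step, by = step)
  cp <- eval_input(input, grid - params$delta_t)
  cwb <- eval_whole_blood(input, grid - params$delta_t)
  vals <- model_curve_from_grids(params$model_kind, params$K1, params$k2,
                                 params$k3, params$k4, params$V_b, cp, cwb,
                                 step)
  approx(grid, vals, xout = times)$y
}

#' Estimate the blood-to-tissue time delay
#'
#' Fits the first 10 minutes of the whole-brain curve with a 3-parameter
#' irreversible uptake model (K1, V_b, delta_t; k2 fixed at 0 — washout is
#' negligible over 10 min), and returns the fitted delay.
#'
#' @param whole_brain_tac A [tac()] whose schedule covers at least 10 min.
#' @param input An input function.
#' @param t_max Early-segment cutoff in minutes (default 10).
#' @param step Fine-grid step in minutes.
#' @return List with `delta_t` (minutes), `K1`, `V_b`, `wrss`.
#' @export
estimate_delay <- function(whole_brain_tac, input, t_max = 10, step = 0.05) {
  keep <- whole_brain_tac$schedule$frame_end <= t_max + 1e-9
  if (sum(keep) < 5L)
    stop_petkin("delay estimation needs at least 5 frames ending within %g min, found %d",
                t_max, sum(keep))
  early <- subset_tac(whole_brain_tac, keep)
  sched <- early$schedule
  w <- early$weights
  y <- early$activity
  grid <- model_grid(sched, step)
  objective <- function(p) {  # p = (K1, V_b, delta_t)
    cp <- eval_input(input, grid - p[3])
    cwb <- eval_whole_blood(input, grid - p[3])
    ## k2 = 0: C_T = K1 * running integral of delayed input
    ct <- conv_exp_grid(cp, step, 0)
    pred <- frame_average((1 - p[2]) * p[1] * ct + p[2] * cwb, grid, sched)
    sqrt(w) * (y - pred)
  }
  best <- NULL
  for (dt0 in c(-2, -1, -0.5, 0, 0.5, 1, 2)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = c(0.01, 0.05, dt0), fn = objective,
                         lower = c(0, 0, -3), upper = c(0.5, 0.2, 3),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    wrss <- sum(res$fvec^2)
    if (is.null(best) || wrss < best$wrss)
      best <- list(delta_t = res$par[3], K1 = res$par[1], V_b = res$par[2],
                   wrss = wrss)
  }
  if (is.null(best)) stop_petkin("delay estimation failed from every start")
  best
}

## Free-parameter layout per model; order matters (multistart + covariance).
free_param_names <- function(model_kind) {
  switch(model_kind,
         "1TCM" = c("K1", "k2", "V_b"),
         "2TCM" = c("K1", "k2", "k3", "k4", "V_b"),
         "2TiCM" = c("K1", "k2", "k3", "V_b"))
}

param_bounds <- function(model_kind) {
  nm <- free_param_names(model_kind)
  lower <- setNames(rep(0, length(nm)), nm)
  upper <- setNames(ifelse(nm == "K1", 0.5, ifelse(nm == "V_b", 0.2, 1)), nm)
  list(lower = lower, upper = upper)
}

## Fixed multistart design: 8 points log-spaced over the bounds, each
## parameter's ladder rotated by its index so starts are spread out.
multistart_grid <- function(model_kind, n_starts = 8) {
  nm <- free_param_names(model_kind)
  lo <- c(K1 = 1e-3, k2 = 1e-3, k3 = 1e-3, k4 = 1e-3, V_b = 1e-3)
  hi <- c(K1 = 0.2, k2 = 0.5, k3 = 0.5, k4 = 0.5, V_b = 0.1)
  ladder <- function(a, b) exp(seq(log(a), log(b), length.out = n_starts))
  out <- matrix(0, n_starts, length(nm), dimnames = list(NULL, nm))
  for (j in seq_along(nm)) {
    l <- ladder(lo[[nm[j]]], hi[[nm[j]]])
    out[, j] <- l[((seq_len(n_starts) - 1 + (j - 1) * 3) %% n_starts) + 1]
  }
  out
}

#' Fit a compartment model to a time-activity curve
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt, bounded, fixed
#' 8-point log-spaced multistart) of the chosen compartment model with
#' blood-volume fraction and a fixed time delay. The covariance of the
#' estimates is the inverse Gauss-Newton Hessian scaled by
#' WRSS / (N - p); relative standard errors are 100 * SE / |estimate|.
#'
#' @param tac A [tac()].
#' @param input An input function.
#' @param model_kind `"1TCM"`, `"2TCM"` or `"2TiCM"`.
#' @param fixed_delay Delay in minutes (from [estimate_delay()]).
#' @param step Fine-grid step in minutes.
#' @param n_starts Number of multistart points.
#' @return Object of class `tissue_fit`: fitted [kinetic_parameters()],
#'   `covariance`, `se`, `rse` (percent), `wrss`, `n_frames`, `n_free`,
#'   `aic`, `converged`, plus the macroparameters `V_T` (reversible
#'   models, with `V_T_se`/`V_T_rse` by the delta method), `K_i` (2TiCM)
#'   and `clearance_half_life` (minutes, ln(2)/k2).
#' @export
fit_tissue_model <- function(tac, input, model_kind = c("1TCM", "2TCM", "2TiCM"),
                             fixed_delay = 0, step = 0.05, n_starts = 8) {
  model_kind <- match.arg(model_kind)
  nm <- free_param_names(model_kind)
  p <- length(nm)
  if (nrow(tac$schedule) < p + 2L)
    stop_petkin("%s fit needs at least %d frames, tac '%s' has %d",
                model_kind, p + 2L, tac$roi_name, nrow(tac$schedule))
  sched <- tac$schedule
  y <- tac$activity
  w <- tac$weights
  grid <- model_grid(sched, step)
  cp <- eval_input(input, grid - fixed_delay)
  cwb <- eval_whole_blood(input, grid - fixed_delay)
  sw <- sqrt(w)
  k3i <- match("k3", nm)
  k4i <- match("k4", nm)
  resid_fn <- function(par) {
    k3 <- if (is.na(k3i)) 0 else par[k3i]
    k4 <- if (is.na(k4i)) 0 else par[k4i]
    vals <- model_curve_from_grids(model_kind, par[1], par[2], k3, k4,
                                   par[p], cp, cwb, step)
    sw * (y - frame_average(vals, grid, sched))
  }
  b <- param_bounds(model_kind)
  starts <- multistart_grid(model_kind, n_starts)
  ## seed K1 and V_b per start by the linear subproblem: given the rate
  ## constants the model is linear in (K1 (1 - V_b), V_b)
  cwb_avg <- frame_average(cwb, grid, sched)
  for (i in seq_len(nrow(starts))) {
    k3 <- if (is.na(k3i)) 0 else starts[i, k3i]
    k4 <- if (is.na(k4i)) 0 else starts[i, k4i]
    ctf <- frame_average(model_curve_from_grids(model_kind, 1, starts[i, 2],
                                                k3, k4, 0, cp, cwb, step),
                         grid, sched)
    X <- cbind(sw * ctf, sw * cwb_avg)
    ab <- tryCatch(qr.solve(X, sw * y), error = function(e) c(NA, NA))
    if (all(is.finite(ab))) {
      vb0 <- min(max(ab[2], 0), 0.2)
      k10 <- min(max(ab[1] / max(1 - vb0, 0.8), 1e-4), 0.5)
      starts[i, 1] <- k10
      starts[i, p] <- max(vb0, 1e-4)
    }
  }
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn,
                         lower = b$lower, upper = b$upper,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$info %in% 1:4) n_conv <- n_conv + 1L
    wrss <- sum(res$fvec^2)
    if (is.null(best) || wrss < best_wrss * (1 - 1e-10) ||
        (wrss <= best_wrss * (1 + 1e-10) && sum(res$par^2) < sum(best$par^2))) {
      best <- res
      best_wrss <- wrss
    }
  }
  if (is.null(best))
    stop_petkin("compartment-model fit failed from every start (tac '%s', %s)",
                tac$roi_name, model_kind)
  par <- setNames(as.numeric(best$par), nm)
  wrss <- sum(best$fvec^2)
  n <- length(y)
  ## Gauss-Newton covariance from a central-difference Jacobian of the
  ## weighted residuals at the optimum.
  J <- fd_jacobian(resid_fn, par)
  cov <- pseudo_solve(crossprod(J)) * wrss / max(n - p, 1)
  dimnames(cov) <- list(nm, nm)
  se <- sqrt(pmax(diag(cov), 0))
  rse <- 100 * se / pmax(abs(par), .Machine$double.eps)
  kp <- kinetic_parameters(model_kind, K1 = par[["K1"]], k2 = par[["k2"]],
                           k3 = if (is.na(k3i)) 0 else par[["k3"]],
                           k4 = if (is.na(k4i)) 0 else par[["k4"]],
                           V_b = par[["V_b"]], delta_t = fixed_delay)
  out <- list(parameters = kp, covariance = cov, se = se, rse = rse,
              wrss = wrss, n_frames = n, n_free = p,
              aic = aic(wrss, n, p),
              converged = n_conv > 0L, n_converged_starts = n_conv,
              roi_name = tac$roi_name)
  macro <- derive_macroparameters(kp)
  out$V_T <- macro$V_T
  out$K_i <- macro$K_i
  out$clearance_half_life <- macro$clearance_half_life
  prim <- primary_parameter_se(kp, cov)
  out$primary_parameter <- prim$name
  out$primary_value <- prim$value
  out$primary_se <- prim$se
  out$primary_rse <- prim$rse
  if (!is.null(out$V_T) && !is.na(out$V_T)) {
    if (identical(prim$name, "V_T")) { out$V_T_se <- prim$se; out$V_T_rse <- prim$rse }
  }
  class(out) <- "tissue_fit"
  out
}

## Delta-method SE of the primary macroparameter (V_T for reversible
## models, K_i for the irreversible model).
primary_parameter_se <- function(params, cov) {
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3; k4 <- params$k4
  kind <- params$model_kind
  if (kind == "2TiCM") {
    val <- K1 * k3 / (k2 + k3)
    g <- c(K1 = k3 / (k2 + k3),
           k2 = -K1 * k3 / (k2 + k3)^2,
           k3 = K1 * k2 / (k2 + k3)^2,
           V_b = 0)
    name <- "K_i"
  } else if (kind == "1TCM") {
    val <- if (k2 > 0) K1 / k2 else Inf
    g <- c(K1 = 1 / k2, k2 = -K1 / k2^2, V_b = 0)
    name <- "V_T"
  } else {
    val <- if (k2 > 0 && k4 > 0) (K1 / k2) * (1 + k3 / k4) else Inf
    g <- c(K1 = val / max(K1, .Machine$double.eps),
           k2 = -val / k2,
           k3 = K1 / (k2 * k4),
           k4 = -K1 * k3 / (k2 * k4^2),
           V_b = 0)
    name <- "V_T"
  }
  if (!is.finite(val)) return(list(name = name, value = val, se = NA_real_, rse = NA_real_))
  g <- g[colnames(cov)]
  v <- as.numeric(t(g) %*% cov %*% g)
  se <- sqrt(max(v, 0))
  list(name = name, value = val, se = se,
       rse = 100 * se / max(abs(val), .Machine$double.eps))
}

#' Macroparameters of a fitted compartment model
#'
#' Total volume of distribution `V_T` (K1/k2 for 1TCM,
#' (K1/k2)(1 + k3/k4) for 2TCM; undefined for the irreversible model),
#' net influx constant `K_i = K1 k3 / (k2 + k3)` (2TiCM only), and the
#' tissue clearance half-life ln(2)/k2.
#'
#' @param params A [kinetic_parameters()] set.
#' @return List with `V_T` (mL/cm3 or NA), `K_i` (mL/min/cm3 or NA),
#'   `clearance_half_life` (minutes), and `V_T_defined`.
#' @export
derive_macroparameters <- function(params) {
  kind <- params$model_kind
  half_life <- if (params$k2 > 0) log(2) / params$k2 else Inf
  if (kind == "2TiCM") {
    K_i <- if (params$k2 + params$k3 > 0)
      params$K1 * params$k3 / (params$k2 + params$k3) else 0
    return(list(V_T = NA_real_, V_T_defined = FALSE, K_i = K_i,
                clearance_half_life = half_life))
  }
  V_T <- if (params$k2 > 0) {
    if (kind == "1TCM") params$K1 / params$k2
    else if (params$k4 > 0) (params$K1 / params$k2) * (1 + params$k3 / params$k4)
    else Inf
  } else Inf
  list(V_T = V_T, V_T_defined = TRUE, K_i = NA_real_,
       clearance_half_life = half_life)
}

#' Total volume of distribution of a fit or parameter set
#'
#' Explicit accessor that errors for the irreversible model, where V_T is
#' undefined, and flags an infinite V_T when k2 = 0.
#'
#' @param x A `kinetic_parameters` or `tissue_fit` object.
#' @return V_T in mL/cm3.
#' @export
volume_of_distribution <- function(x) {
  params <- if (inherits(x, "tissue_fit")) x$parameters else x
  if (params$model_kind == "2TiCM")
    stop_petkin("V_T is undefined for the irreversible 2TiCM (use K_i)")
  m <- derive_macroparameters(params)
  if (!is.finite(m$V_T))
    warning("k2 = 0: V_T is infinite", call. = FALSE)
  m$V_T
}

#' @export
print.tissue_fit <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<tissue_fit> roi '%s' %s: WRSS=%.4g, AIC=%.2f%s\n",
              x$roi_name, p$model_kind, x$wrss, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  K1=%.4g mL/min/cm3 (rSE %.1f%%), k2=%.4g (rSE %.1f%%), V_b=%.3g, delta_t=%.3g\n",
              p$K1, x$rse[["K1"]], p$k2, x$rse[["k2"]], p$V_b, p$delta_t))
  if (p$model_kind == "2TiCM")
    cat(sprintf("  K_i=%.4g mL/min/cm3 (rSE %.1f%%)\n", x$K_i, x$primary_rse))
  else
    cat(sprintf("  V_T=%.4g mL/cm3 (rSE %.1f%%), clearance half-life %.1f min\n",
                x$V_T, x$primary_rse, x$clearance_half_life))
  invisible(x)
}
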