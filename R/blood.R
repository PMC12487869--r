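## Blood processing: discrete arterial samples -> continuous-time models.
##
## The plasma (and whole-blood) curve is piecewise linear from t = 0
## through the measured pre-peak samples, then a sum of decaying
## exponentials fitted to the post-peak samples; the junction value at the
## peak time is the fitted model value, so the curve is continuous by
## construction. The unmetabolized parent fraction follows an
## integrated-gamma model PF(t) = 1 - a * G(t; shape, rate) with G the
## gamma CDF, which starts at 1, decreases monotonically and levels off at
## 1 - a. The metabolite-corrected input is the pointwise product.

#' Arterial blood sample table
#'
#' @param sample_time Minutes post injection, strictly increasing.
#' @param whole_blood_activity,plasma_activity kBq/cm3, non-negative.
#' @return Object of class `blood_sample_table` (a data frame).
#' @export
blood_sample_table <- function(sample_time, whole_blood_activity, plasma_activity) {
  n <- length(sample_time)
  if (length(whole_blood_activity) != n || length(plasma_activity) != n)
    stop_petkin("blood table columns must have equal length")
  if (is.unsorted(sample_time, strictly = TRUE))
    stop_petkin("blood sample times must be strictly increasing")
  if (any(whole_blood_activity < 0) || any(plasma_activity < 0))
    stop_petkin("blood activities must be non-negative")
  if (n < 4L)
    stop_petkin("at least 4 blood samples are required, got %d", n)
  structure(data.frame(sample_time = as.numeric(sample_time),
                       whole_blood_activity = as.numeric(whole_blood_activity),
                       plasma_activity = as.numeric(plasma_activity)),
            class = c("blood_sample_table", "data.frame"))
}

#' Parent (unmetabolized) fraction table
#'
#' @param sample_time Minutes post injection, increasing. The long-scan
#'   metabolite protocol draws 7 samples at 5, 15, 30, 60, 90, 120 and
#'   180 min.
#' @param parent_fraction Unitless fractions in `[0, 1]`.
#' @return Object of class `parent_fraction_table` (a data frame).
#' @export
parent_fraction_table <- function(sample_time, parent_fraction) {
  if (length(sample_time) != length(parent_fraction))
    stop_petkin("parent fraction columns must have equal length")
  if (is.unsorted(sample_time, strictly = TRUE))
    stop_petkin("parent fraction times must be increasing")
  if (any(parent_fraction < 0 | parent_fraction > 1))
    stop_petkin("parent fractions must lie in [0, 1]")
  structure(data.frame(sample_time = as.numeric(sample_time),
                       parent_fraction = as.numeric(parent_fraction)),
            class = c("parent_fraction_table", "data.frame"))
}

## Evaluate sum_j A_j exp(-lambda_j t) (amplitudes referenced to t = 0).
sum_exp <- function(t, A, lambda) {
  v <- numeric(length(t))
  for (j in seq_along(A)) v <- v + A[j] * exp(-lambda[j] * t)
  v
}

#' Fit a plasma (or whole-blood) activity curve
#'
#' Piecewise-linear rise from (0, 0) through the measured pre-peak samples,
#' then a sum of `n_exponentials` decaying exponentials fitted by least
#' squares to the samples from the peak onward. Amplitudes are referenced
#' to t = 0, i.e. the post-peak model is sum A_j exp(-lambda_j t).
#' With `n_exponentials = "auto"` the 1-, 2- and 3-exponential fits are
#' compared by AIC.
#'
#' @param samples A [blood_sample_table()] or a data frame with columns
#'   `sample_time` and one activity column; `which` chooses the column.
#' @param n_exponentials 1, 2, 3 or "auto".
#' @param which `"plasma"` or `"whole_blood"`.
#' @return Object of class `plasma_curve`, with fields `peak_time`,
#'   `pre_times`, `pre_values` (interpolation nodes), `A`, `lambda`, `rss`.
#' @export
fit_plasma_curve <- function(samples, n_exponentials = 3, which = c("plasma", "whole_blood")) {
  which <- match.arg(which)
  col <- if (which == "plasma") "plasma_activity" else "whole_blood_activity"
  t <- samples$sample_time
  y <- samples[[col]]
  if (all(y == 0)) stop_petkin("all %s activities are zero; cannot fit a curve", which)
  if (identical(n_exponentials, "auto")) {
    fits <- lapply(1:3, function(k)
      try(fit_plasma_curve(samples, k, which), silent = TRUE))
    ok <- !vapply(fits, inherits, logical(1), "try-error")
    if (!any(ok)) stop_petkin("no exponential order could be fitted")
    fits <- fits[ok]
    aics <- vapply(fits, function(f) {
      npost <- sum(t >= f$peak_time)
      npost * log(max(f$rss, 1e-300) / npost) + 2 * (2 * length(f$A))
    }, numeric(1))
    return(fits[[which.min(aics)]])
  }
  n_exp <- as.integer(n_exponentials)
  ipk <- which.max(y)
  tpost <- t[ipk:length(t)]
  ypost <- y[ipk:length(y)]
  need <- n_exp + 2L
  if (length(tpost) < need)
    stop_petkin("fitting %d exponentials requires at least %d samples at/after the peak, got %d",
                n_exp, need, length(tpost))

  fit <- fit_sum_exp(tpost, ypost, n_exp)
  pre_t <- c(0, t[seq_len(ipk - 1L)])
  pre_v <- c(0, y[seq_len(ipk - 1L)])
  ## junction node: fitted value at the peak time (continuity by construction)
  structure(list(peak_time = t[ipk],
                 pre_times = c(pre_t, t[ipk]),
                 pre_values = c(pre_v, sum_exp(t[ipk], fit$A, fit$lambda)),
                 A = fit$A, lambda = fit$lambda, rss = fit$rss,
                 column = col),
            class = "plasma_curve")
}

## Multistart least-squares fit of y ~ sum A_j exp(-lambda_j t), A, lambda >= 0.
## Starts: log-spaced rate ladders spanning the sampled time range; for each
## rate start the amplitudes are seeded by bounded linear least squares.
fit_sum_exp <- function(t, y, n_exp) {
  tspan <- max(t) - min(t)
  base_rates <- if (tspan > 0) 10^seq(log10(5 / max(tspan, 1)), log10(0.002), length.out = 4)
                else rep(0.01, 4)
  starts <- lapply(seq_len(4), function(i) {
    lam <- base_rates[i] * (10^seq(1, -1, length.out = n_exp))
    lam <- sort(pmax(lam, 1e-6), decreasing = TRUE)
    X <- vapply(seq_len(n_exp), function(j) exp(-lam[j] * t), numeric(length(t)))
    A <- tryCatch(qr.solve(X, y), error = function(e) rep(max(y) / n_exp, n_exp))
    A <- pmax(A, max(y) * 1e-3)
    list(A = A, lambda = lam)
  })
  ## plus a near-constant start for degenerate (flat) tails
  starts <- c(starts, list(list(A = rep(max(y) / n_exp, n_exp),
                                lambda = rep(1e-6, n_exp) * 10^(seq_len(n_exp) - 1))))
  resid_fn <- function(p) {
    A <- p[seq_len(n_exp)]
    lam <- p[n_exp + seq_len(n_exp)]
    y - sum_exp(t, A, lam)
  }
  best <- NULL
  for (s in starts) {
    p0 <- c(s$A, s$lambda)
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         lower = rep(0, 2 * n_exp),
                         upper = c(rep(Inf, n_exp), rep(10, n_exp)),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12 * best$rss ||
        (abs(rss - best$rss) <= 1e-12 * max(best$rss, 1e-300) &&
         sum(res$par^2) < sum(c(best$A, best$lambda)^2)))
      best <- list(A = res$par[seq_len(n_exp)],
                   lambda = res$par[n_exp + seq_len(n_exp)], rss = rss)
  }
  if (is.null(best)) stop_petkin("sum-of-exponentials fit failed from every start")
  ord <- order(best$lambda, decreasing = TRUE)
  list(A = best$A[ord], lambda = best$lambda[ord], rss = best$rss)
}

#' Evaluate a fitted plasma curve
#'
#' @param model A `plasma_curve`.
#' @param t Times in minutes; values at t <= 0 are 0.
#' @return kBq/cm3 at each time.
#' @export
eval_plasma <- function(model, t) {
  out <- numeric(length(t))
  pre <- t > 0 & t < model$peak_time
  post <- t >= model$peak_time
  if (any(pre))
    out[pre] <- approx(model$pre_times, model$pre_values, xout = t[pre], rule = 2)$y
  if (any(post))
    out[post] <- sum_exp(t[post], model$A, model$lambda)
  out
}

#' @export
print.plasma_curve <- function(x, ...) {
  cat(sprintf("<plasma_curve> (%s) peak at %.3g min; %d exponentials\n",
              x$column, x$peak_time, length(x$A)))
  cat(sprintf("  A      = %s kBq/cm3\n", paste(signif(x$A, 4), collapse = ", ")))
  cat(sprintf("  lambda = %s 1/min\n", paste(signif(x$lambda, 4), collapse = ", ")))
  invisible(x)
}

#' Fit the unmetabolized parent-fraction model
#'
#' Integrated-gamma model PF(t) = 1 - a * G(t; shape, rate), with G the
#' cumulative gamma distribution: PF(0) = 1, monotone non-increasing,
#' asymptote 1 - a. Fitted by least squares; noisy non-monotone samples are
#' allowed, the fitted curve is monotone by construction.
#'
#' @param samples A [parent_fraction_table()].
#' @return Object of class `parent_fraction_model` with fields `a`,
#'   `shape`, `rate`, `rss`.
#' @export
fit_parent_fraction <- function(samples) {
  t <- samples$sample_time
  y <- samples$parent_fraction
  if (any(y < 0 | y > 1)) stop_petkin("parent fractions must lie in [0, 1]")
  if (length(t) < 4L) stop_petkin("at least 4 parent-fraction samples are required, got %d", length(t))
  if (all(y >= 1 - 1e-12))
    return(structure(list(a = 0, shape = 1, rate = 0.01, rss = 0),
                     class = "parent_fraction_model"))
  resid_fn <- function(p) y - (1 - p[1] * pgamma(t, shape = p[2], rate = p[3]))
  a0 <- min(1, max(0.01, 1 - min(y)))
  best <- NULL
  for (shape0 in c(0.3, 1, 2, 5)) for (rate0 in c(0.002, 0.02, 0.1)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = c(a0, shape0, rate0), fn = resid_fn,
                         lower = c(0, 1e-3, 1e-6), upper = c(1, 100, 10),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(a = res$par[1], shape = res$par[2], rate = res$par[3], rss = rss)
  }
  if (is.null(best)) stop_petkin("parent-fraction fit failed from every start")
  structure(best, class = "parent_fraction_model")
}

#' Evaluate a parent-fraction model
#'
#' @param model A `parent_fraction_model`.
#' @param t Times in minutes.
#' @return PF(t) in `[0, 1]`.
#' @export
eval_parent_fraction <- function(model, t) {
  1 - model$a * pgamma(pmax(t, 0), shape = model$shape, rate = model$rate)
}

#' @export
print.parent_fraction_model <- function(x, ...) {
  cat(sprintf("<parent_fraction_model> PF(t) = 1 - %.4g * G(t; shape=%.4g, rate=%.4g); asymptote %.3f\n",
              x$a, x$shape, x$rate, 1 - x$a))
  invisible(x)
}

#' Assemble a metabolite-corrected input function
#'
#' The input to the tissue model is the product of the fitted total-plasma
#' curve and the parent-fraction model; the whole-blood curve supplies the
#' vascular term, and the plasma free fraction is carried as metadata.
#'
#' @param plasma,whole_blood `plasma_curve` objects.
#' @param parent A `parent_fraction_model`.
#' @param f_p Plasma free fraction in (0, 1].
#' @return Object of class `input_function`.
#' @export
make_input_function <- function(plasma, parent, whole_blood, f_p = NA_real_) {
  stopifnot(inherits(plasma, "plasma_curve"),
            inherits(parent, "parent_fraction_model"),
            inherits(whole_blood, "plasma_curve"))
  if (!is.na(f_p) && (f_p <= 0 || f_p > 1))
    stop_petkin("f_p must lie in (0, 1], got %g", f_p)
  structure(list(plasma = plasma, parent = parent, whole_blood = whole_blood,
                 f_p = f_p),
            class = "input_function")
}

#' Evaluate the metabolite-corrected plasma input
#'
#' @param input An [make_input_function()] result.
#' @param t Times in minutes.
#' @return Unchanged-tracer plasma concentration, kBq/cm3.
#' @export
eval_input <- function(input, t) {
  eval_plasma(input$plasma, t) * eval_parent_fraction(input$parent, t)
}

#' Evaluate the whole-blood curve of an input function
#'
#' @inheritParams eval_input
#' @export
eval_whole_blood <- function(input, t) eval_plasma(input$whole_blood, t)

#' @export
print.input_function <- function(x, ...) {
  cat("<input_function>\n  plasma: "); print(x$plasma)
  cat("  parent: "); print(x$parent)
  cat(sprintf("  f_p = %s\n", ifelse(is.na(x$f_p), "NA", sprintf("%.3f", x$f_p))))
  invisible(x)
}
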