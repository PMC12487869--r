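## Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_petkin <- function(...) stop(sprintf(...), call. = FALSE)

## Finite-difference Jacobian of a vector-valued function, central
## differences with relative step. Used for the Gauss-Newton covariance.
fd_jacobian <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1e-4)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

## Pseudo-inverse via SVD; tolerates rank deficiency from parameters
## pinned at bounds (their variance is then effectively unidentified).
pseudo_solve <- function(A) {
  s <- svd(A)
  tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) return(matrix(NA_real_, nrow(A), ncol(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

## Deterministic child seeds from one top-level seed. Streams are drawn
## in a fixed documented order: stream k is the k-th integer drawn after
## seeding the generator with the parent seed.
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

## Trapezoidal integral of y over x (both vectors, x increasing).
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Standardized uptake value
#'
#' Normalizes a tissue activity concentration by the injected dose per gram
#' of body weight, assuming a tissue density of 1 g/cm3:
#' SUV = activity / (dose_kBq / weight_g).
#'
#' @param activity Activity concentration in kBq/cm3 (vector allowed).
#' @param injected_dose Injected dose in MBq (scalar, > 0).
#' @param body_weight Body weight in kg (scalar, > 0).
#' @return Unitless SUV, same length as `activity`.
#' @examples
#' suv(5, injected_dose = 180, body_weight = 5)
#' @export
suv <- function(activity, injected_dose, body_weight) {
  if (!is.numeric(injected_dose) || length(injected_dose) != 1L || injected_dose <= 0)
    stop_petkin("`injected_dose` must be a single positive number (MBq), got %s",
                paste(injected_dose, collapse = ","))
  if (!is.numeric(body_weight) || length(body_weight) != 1L || body_weight <= 0)
    stop_petkin("`body_weight` must be a single positive number (kg), got %s",
                paste(body_weight, collapse = ","))
  ## dose in kBq divided by weight in grams: kBq injected per gram
  activity / (injected_dose * 1000 / (body_weight * 1000))
}

## Inverse of suv(): activity concentration from an SUV.
#' @rdname suv
#' @param value SUV value(s) to convert back to kBq/cm3.
#' @export
suv_to_activity <- function(value, injected_dose, body_weight) {
  value * (injected_dose * 1000 / (body_weight * 1000))
}
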