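#' Normalise a binding profile to unit area
#'
#' @param b numeric vector, [binding_kernel()] or `deconvolved_profile`
#'   (the `"mean"` strand solution is taken unless `which` says otherwise).
#' @param which strand solution for a deconvolved profile.
#' @return numeric vector summing to 1 (within 1e-12).
#' @export
normalize_area <- function(b, which = c("mean", "crick", "watson")) {
  which <- match.arg(which)
  if (inherits(b, "deconvolved_profile")) {
    b <- switch(which, mean = b$b_mean, crick = b$b_crick, watson = b$b_watson)
  } else if (inherits(b, "binding_kernel")) {
    b <- b$mass
  }
  total <- sum(b)
  if (total <= 0) stop("profile has zero (or negative) total mass", call. = FALSE)
  b / total
}

#' Decompose an RPA binding shape into DMC1 and RAD51 components
#'
#' Ordinary least squares of the unit-area RPA profile on the unit-area
#' DMC1 and RAD51 profiles with an intercept: `P = alpha + beta*D +
#' gamma*R`.  The relative filament proportions are `beta / (beta + gamma)`
#' and `gamma / (beta + gamma)`; because all three profiles have area 1,
#' proportions are invariant to the overall scale of each assay.
#'
#' @param P,D,R unit-area profiles on a common binning (numeric vectors or
#'   objects accepted by [normalize_area()]; vectors must already sum to 1).
#' @param condition_threshold warn when the (D, R) design is closer to
#'   collinear than this condition number.
#' @return object of class `mixture_fit`: list with `alpha`, `beta`,
#'   `gamma`, `prop_dmc1`, `prop_rad51`, `residual_sse`, `fit` (the `lm`
#'   object).  Negative `beta` or `gamma` triggers a warning and undefined
#'   (NA) proportions.
#' @export
fit_mixture <- function(P, D, R, condition_threshold = 1e8) {
  P <- as_unit_profile(P); D <- as_unit_profile(D); R <- as_unit_profile(R)
  if (length(P) != length(D) || length(P) != length(R)) {
    stop("P, D, R must share binning", call. = FALSE)
  }
  X <- cbind(D = D - mean(D), R = R - mean(R))
  sv <- svd(X)$d
  if (sv[2] <= 0 || sv[1] / max(sv[2], .Machine$double.eps) > condition_threshold) {
    warning("D and R are near-collinear; mixture proportions are unstable")
  }
  fit <- stats::lm(P ~ D + R)
  cf <- stats::coef(fit)
  beta <- unname(cf["D"]); gamma <- unname(cf["R"])
  if (is.na(beta) || is.na(gamma)) {
    warning("degenerate design: a coefficient could not be estimated")
    beta <- ifelse(is.na(beta), 0, beta); gamma <- ifelse(is.na(gamma), 0, gamma)
  }
  ## numerically-zero coefficients are clamped; genuinely negative fits are
  ## reported as-is with undefined proportions
  tol0 <- 1e-8 * max(abs(beta), abs(gamma), 1e-12)
  if (beta < 0 && beta > -tol0) beta <- 0
  if (gamma < 0 && gamma > -tol0) gamma <- 0
  neg <- beta < 0 || gamma < 0
  if (neg) warning("negative fitted mixture coefficient; proportions undefined")
  denom <- beta + gamma
  structure(
    list(
      alpha = unname(cf[1]), beta = beta, gamma = gamma,
      prop_dmc1 = if (!neg && denom > 0) beta / denom else NA_real_,
      prop_rad51 = if (!neg && denom > 0) gamma / denom else NA_real_,
      residual_sse = sum(stats::residuals(fit)^2),
      fit = fit
    ),
    class = "mixture_fit"
  )
}

as_unit_profile <- function(x) {
  if (inherits(x, c("deconvolved_profile", "binding_kernel"))) {
    return(normalize_area(x))
  }
  x <- as.numeric(x)
  if (abs(sum(x) - 1) > 1e-6) {
    stop("profiles must be normalised to unit area (see normalize_area())",
         call. = FALSE)
  }
  x
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> alpha %.3g, beta %.3f, gamma %.3f -> DMC1 %.1f%% / RAD51 %.1f%% (SSE %.3g)\n",
    x$alpha, x$beta, x$gamma, 100 * x$prop_dmc1, 100 * x$prop_rad51, x$residual_sse
  ))
  invisible(x)
}

#' Mixture fit at fixed DMC1/RAD51 proportions
#'
#' Constrains the relative proportions to `weights` and fits only an
#' intercept and a common scale by least squares:
#' `P ~ alpha + s * (w_d * D + w_r * R)`.  The residual sum of squares is
#' comparable with the free fit's (the free fit is the nested minimum).
#'
#' @param P,D,R unit-area profiles as in [fit_mixture()].
#' @param weights length-2 nonnegative weights `(w_d, w_r)` summing to 1.
#' @return list with `weights`, `alpha`, `scale`, `predicted`,
#'   `residual_sse`.
#' @export
fixed_mixture_fit <- function(P, D, R, weights) {
  stopifnot(length(weights) == 2, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-8)
  P <- as_unit_profile(P); D <- as_unit_profile(D); R <- as_unit_profile(R)
  M <- weights[1] * D + weights[2] * R
  fit <- stats::lm(P ~ M)
  list(
    weights = weights,
    alpha = unname(stats::coef(fit)[1]),
    scale = unname(stats::coef(fit)[2]),
    predicted = unname(stats::fitted(fit)),
    residual_sse = sum(stats::residuals(fit)^2)
  )
}
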