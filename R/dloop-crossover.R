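#' Equal-signal hotspot bins ordered by centromere distance
#'
#' Sorts hotspots by distance to the centromere and splits them into
#' `n_bins` groups holding (as nearly as possible) equal total DSB-proxy
#' signal: hotspot `i` goes to the bin containing the midpoint of its
#' cumulative-weight interval, so every bin's weight is within one
#' hotspot's weight of `total / n_bins`.
#'
#' @param weight nonnegative DSB-proxy signal per hotspot (e.g. RPA on the
#'   DSB-initiating homolog, or H3K4me3).
#' @param order_by ordering covariate (centromere distance); default keeps
#'   the given order.
#' @param n_bins number of bins (default 4: bin 1 centromere-proximal,
#'   bin `n_bins` telomere-proximal).
#' @return integer bin assignment (1..n_bins) in the input hotspot order.
#' @export
equal_signal_bins <- function(weight, order_by = NULL, n_bins = 4) {
  stopifnot(n_bins >= 1, all(weight >= 0))
  total <- sum(weight)
  if (total <= 0) stop("total DSB-proxy weight must be > 0", call. = FALSE)
  if (any(weight > total / n_bins)) {
    warning("a single hotspot holds more than a full bin's share of signal")
  }
  ord <- if (is.null(order_by)) seq_along(weight) else order(order_by)
  w <- weight[ord]
  mid <- cumsum(w) - w / 2
  bin_sorted <- pmin(pmax(ceiling(mid / (total / n_bins)), 1L), n_bins)
  bins <- integer(length(weight))
  bins[ord] <- bin_sorted
  bins
}

#' Per-bin event fractions with bootstrap confidence intervals
#'
#' The share of all events (crossovers, non-crossovers, or repair-template
#' RPA signal) falling in each hotspot bin.  Confidence intervals come from
#' resampling hotspots with replacement from the full set and recomputing
#' the fractions.
#'
#' @param bins integer bin assignment per hotspot (1..n_bins).
#' @param events nonnegative event count (or signal) per hotspot.
#' @param n_boot bootstrap iterations (default 100000).
#' @param conf confidence level.
#' @param seed optional RNG seed.
#' @return data.frame with `bin`, `events`, `fraction`, `lo`, `hi`.
#' @export
bin_fractions <- function(bins, events, n_boot = 1e5, conf = 0.95, seed = NULL) {
  stopifnot(length(bins) == length(events), all(events >= 0))
  if (sum(events) <= 0) stop("total events must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(bins)
  n_bins <- max(bins)
  per_bin <- vapply(seq_len(n_bins), function(b) sum(events[bins == b]), numeric(1))
  frac <- per_bin / sum(per_bin)

  ## hotspot-level bootstrap via multinomial resampling weights, chunked so
  ## the weight matrix stays small
  E <- vapply(seq_len(n_bins), function(b) events * (bins == b), numeric(n))
  boots <- matrix(NA_real_, n_boot, n_bins)
  chunk <- max(1L, min(n_boot, floor(2e6 / n)))
  done <- 0L
  while (done < n_boot) {
    sz <- min(chunk, n_boot - done)
    W <- stats::rmultinom(sz, n, rep(1 / n, n))  # n x sz resample counts
    tot <- crossprod(W, E)                       # sz x n_bins
    boots[done + seq_len(sz), ] <- tot / rowSums(tot)
    done <- done + sz
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boots, 2, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  data.frame(
    bin = seq_len(n_bins), events = per_bin, fraction = frac,
    lo = ci[1, ], hi = ci[2, ]
  )
}

#' Rescale per-bin crossover rates to an absolute per-DSB probability
#'
#' Raw crossover-per-DSB-proxy ratios are only relative; this multiplies
#' all bins by the single constant that makes the DSB-weighted mean rate
#' equal `mean_rate` (default 0.10, i.e. one DSB in ten resolves as a
#' crossover).  Between-bin ratios are preserved exactly.
#'
#' @param co_events crossover count per bin.
#' @param dsb_proxy DSB-proxy total per bin.
#' @param mean_rate target weighted-mean crossover probability per DSB.
#' @return data.frame with `bin`, `raw_ratio`, `rate`.
#' @export
rescale_crossover_rate <- function(co_events, dsb_proxy, mean_rate = 0.10) {
  stopifnot(length(co_events) == length(dsb_proxy))
  if (any(dsb_proxy <= 0)) stop("DSB-proxy totals must be > 0", call. = FALSE)
  if (sum(co_events) <= 0) stop("no crossovers to rescale", call. = FALSE)
  raw <- co_events / dsb_proxy
  scale <- mean_rate * sum(dsb_proxy) / sum(co_events)
  data.frame(bin = seq_along(raw), raw_ratio = raw, rate = raw * scale)
}

#' Relative lifespans of crossover- and non-crossover-destined intermediates
#'
#' Models repair-template RPA per DSB in bin `b` as a mixture of the two
#' intermediate lifespans weighted by the resolution probabilities:
#' `R_b = (1 - sister_fraction) * (c_b * L_co + (1 - c_b) * L_nco)`
#' (sister-chromatid repair contributes no repair-template RPA), and solves
#' for `(L_co, L_nco)` by least squares.  Lifespans are relative (the
#' template-RPA units are arbitrary); the ratio `L_co / L_nco` is the
#' scale-free quantity of interest.
#'
#' @param co_rate absolute crossover probability per DSB in each bin
#'   (`c_b`, e.g. from [rescale_crossover_rate()]).
#' @param template_rpa repair-template RPA per DSB in each bin (`R_b`).
#' @param sister_fraction assumed probability of sister repair (default 0).
#' @param co_share assumed mean crossover share among inter-homolog
#'   intermediates (recorded assumption; default 0.10).
#' @param weights optional per-bin least-squares weights (default equal).
#' @return object of class `lifespan_estimate`: list with `L_co`, `L_nco`,
#'   `ratio`, `co_share`, `sister_fraction`, `fitted`, `residual_sse`.
#' @export
estimate_lifespans <- function(co_rate, template_rpa, sister_fraction = 0,
                               co_share = 0.10, weights = NULL) {
  stopifnot(length(co_rate) == length(template_rpa),
            sister_fraction >= 0, sister_fraction < 1)
  if (length(co_rate) < 2) stop("need >= 2 bins", call. = FALSE)
  if (diff(range(co_rate)) < 1e-12) {
    stop("all bins have the same crossover rate: system is singular", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, length(co_rate)) else weights
  X <- (1 - sister_fraction) * cbind(co = co_rate, nco = 1 - co_rate)
  fit <- stats::lm.wfit(X, template_rpa, w)
  L <- stats::coef(fit)
  structure(
    list(
      L_co = unname(L["co"]), L_nco = unname(L["nco"]),
      ratio = unname(L["co"] / L["nco"]),
      co_share = co_share, sister_fraction = sister_fraction,
      fitted = as.numeric(X %*% L),
      residual_sse = sum(w * fit$residuals^2)
    ),
    class = "lifespan_estimate"
  )
}

#' @export
print.lifespan_estimate <- function(x, ...) {
  cat(sprintf(
    "<lifespan_estimate> L_co %.3f, L_nco %.3f, ratio %.2f (sister repair %.0f%%)\n",
    x$L_co, x$L_nco, x$ratio, 100 * x$sister_fraction
  ))
  invisible(x)
}

#' Crossover-count regression on eight recombination measures
#'
#' Ordinary least squares of the per-hotspot crossover count on the
#' standardised measures of H3K4me3, RPA, DMC1 and RAD51 on the
#' DSB-initiating (`_d`) and repair-template (`_r`) homologs:
#' `C ~ H_d + H_r + P_d + P_r + D_d + D_r + R_d + R_r`.
#'
#' @param data data.frame containing the response column and predictor
#'   columns.
#' @param response name of the crossover-count column (default `"C"`).
#' @param predictors character vector of predictor column names (default
#'   the eight standard measures present in `data`).
#' @return object of class `crossover_model`: list with `fit` (the `lm`),
#'   `coefficients`, `predictors`, `dropped` (perfectly collinear columns
#'   removed with a warning).
#' @export
crossover_feature_model <- function(data, response = "C", predictors = NULL) {
  if (is.null(predictors)) {
    std <- c("H_d", "H_r", "P_d", "P_r", "D_d", "D_r", "R_d", "R_r")
    predictors <- intersect(std, names(data))
  }
  stopifnot(response %in% names(data), length(predictors) >= 1)
  if (nrow(data) < 50) stop("need >= 50 hotspots", call. = FALSE)
  X <- data[predictors]
  keep <- vapply(X, function(v) stats::sd(v) > 0, logical(1))
  if (any(!keep)) {
    warning(sprintf("dropping constant predictor(s): %s",
                    paste(predictors[!keep], collapse = ", ")))
  }
  predictors <- predictors[keep]
  df <- data.frame(scale(data[predictors]))
  df[[response]] <- data[[response]]
  fml <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(fml, data = df)
  dropped <- character(0)
  if (anyNA(stats::coef(fit))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    warning(sprintf("perfectly collinear predictor(s) dropped: %s",
                    paste(dropped, collapse = ", ")))
    predictors <- setdiff(predictors, dropped)
    fit <- stats::lm(stats::reformulate(predictors, response = response), data = df)
  }
  ## embed the data in the call so stats::step() can re-evaluate the model
  ## from any frame
  fit$call$data <- df
  structure(
    list(fit = fit, coefficients = stats::coef(fit), predictors = predictors,
         response = response, data = df, dropped = dropped),
    class = "crossover_model"
  )
}

#' @export
print.crossover_model <- function(x, ...) {
  cat("<crossover_model>\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Stepwise AIC feature selection for the crossover model
#'
#' Bidirectional stepwise search (default) starting from the full model,
#' minimising the Akaike Information Criterion.
#'
#' @param model a `crossover_model`.
#' @param direction search direction passed to [stats::step()].
#' @return list with `fit` (selected `lm`), `selected` (retained predictor
#'   names) and `aic`.
#' @export
select_features <- function(model, direction = c("both", "backward", "forward")) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "crossover_model"))
  scope <- list(
    lower = stats::reformulate("1", response = model$response),
    upper = stats::formula(model$fit)
  )
  sel <- stats::step(model$fit, scope = scope, direction = direction, trace = 0)
  list(
    fit = sel,
    selected = setdiff(names(stats::coef(sel)), "(Intercept)"),
    aic = stats::AIC(sel)
  )
}
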