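## Fragment-size measurement-error calibration.
##
## Gel estimates of fragment length are noisy: the error grows with fragment
## size (heteroscedasticity) and neighbouring bands in one lane are measured
## on the same fitted migration curve, so their errors are serially
## correlated. Two calibration models are offered:
##   "lm"     ordinary least squares, iid errors;
##   "varpow" generalized least squares with Var(e_i) propto |mu_i|^(2*delta)
##            (power-of-mean variance) and AR(1) correlation within a lane,
##            ordered by migration rank.
## Both regress measured on expected size; a measured size is converted back
## to a range of plausible true sizes by inverting the prediction band.

#' Drop fragments below the gel detection limit
#'
#' Short fragments run off the gel or fall below the stain detection limit
#' and cannot be observed or sized reliably; the default limit is 100 bp
#' (the boundary itself is kept).
#'
#' @param lengths numeric vector of fragment lengths.
#' @param min_detectable detection limit in nt (default 100).
#' @return the retained lengths.
#' @export
filter_detectable <- function(lengths, min_detectable = 100) {
  lengths[lengths >= min_detectable]
}

.new_calibration_model <- function(kind, beta0, beta1, sigma, delta, phi,
                                   level, min_detectable, loglik, n,
                                   converged = TRUE) {
  stopifnot(abs(phi) < 1, sigma >= 0, level > 0, level < 1)
  structure(list(kind = kind, beta0 = beta0, beta1 = beta1, sigma = sigma,
                 delta = delta, phi = phi, level = level,
                 min_detectable = min_detectable, loglik = loglik, n = n,
                 converged = converged),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> kind=", x$kind,
      sprintf("\n  measured = %.4g + %.4g * expected", x$beta0, x$beta1),
      sprintf("\n  sigma=%.4g delta=%.3g phi=%.3g", x$sigma, x$delta, x$phi),
      sprintf("\n  level=%.2f min_detectable=%g logLik=%.2f (n=%d)\n",
              x$level, x$min_detectable, x$loglik, x$n),
      sep = "")
  invisible(x)
}

.check_points <- function(points) {
  need <- c("expected", "measured")
  if (!is.data.frame(points) || !all(need %in% names(points)))
    stop("calibration points need columns 'expected' and 'measured'")
  stopifnot(all(points$expected > 0), all(points$measured > 0))
  points
}

#' Fit the ordinary least-squares calibration model
#'
#' @param points data frame with columns `expected` and `measured`
#'   (`lane_id` and `rank` are ignored by this model).
#' @param level prediction-band confidence level for [permissive_range()].
#' @param min_detectable gel detection limit carried into the model.
#' @return a `calibration_model` of kind `"lm"` (delta and phi fixed at 0).
#'   The reported log-likelihood is the Gaussian ML value, comparable with
#'   [fit_varpow()].
#' @export
fit_lm <- function(points, level = 0.95, min_detectable = 100) {
  points <- .check_points(points)
  if (nrow(points) < 3L || length(unique(points$expected)) < 2L)
    stop("need >= 3 points with >= 2 distinct expected sizes")
  fit <- stats::lm(measured ~ expected, data = points)
  res <- stats::residuals(fit)
  n <- length(res)
  sigma_ml <- sqrt(sum(res^2) / n)
  .new_calibration_model(
    kind = "lm",
    beta0 = unname(stats::coef(fit)[1]),
    beta1 = unname(stats::coef(fit)[2]),
    sigma = sigma_ml,
    delta = 0, phi = 0,
    level = level, min_detectable = min_detectable,
    loglik = as.numeric(stats::logLik(fit)), n = n)
}

#' Fit the heteroscedastic AR(1) ("varpow") calibration model
#'
#' Maximizes the Gaussian likelihood of
#' `measured_i = beta0 + beta1 * expected_i + e_i` with
#' `Var(e_i) = sigma^2 * |mu_i|^(2*delta)` (variance a power of the fitted
#' mean) and `cor(e_i, e_j) = phi^|rank_i - rank_j|` within a lane, via
#' [nlme::gls()] with `varPower` and `corAR1` structures (ML, so the fit is
#' directly comparable with, and never worse than, [fit_lm()], which it
#' nests at `delta = phi = 0`).
#'
#' @param points data frame with columns `expected`, `measured`, `lane_id`,
#'   `rank` (migration order within the lane, by descending size).
#' @param level,min_detectable as in [fit_lm()].
#' @return a `calibration_model` of kind `"varpow"`.
#' @export
fit_varpow <- function(points, level = 0.95, min_detectable = 100) {
  points <- .check_points(points)
  if (!all(c("lane_id", "rank") %in% names(points)))
    stop("varpow calibration needs 'lane_id' and 'rank' columns")
  sizes <- table(points$lane_id)
  if (length(sizes) < 2L || sum(sizes >= 3L) < 2L)
    stop("need >= 2 lanes with >= 3 points each")
  d <- points[order(points$lane_id, points$rank), , drop = FALSE]
  d$lane_id <- factor(d$lane_id)
  fit <- tryCatch(
    nlme::gls(measured ~ expected, data = d,
              correlation = nlme::corAR1(form = ~ rank | lane_id),
              weights = nlme::varPower(form = ~ fitted(.)),
              method = "ML",
              control = nlme::glsControl(maxIter = 200, msMaxIter = 200,
                                         tolerance = 1e-8)),
    error = function(e)
      stop("varpow fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  cf <- stats::coef(fit)
  delta <- unname(stats::coef(fit$modelStruct$varStruct,
                              unconstrained = FALSE))
  phi <- unname(stats::coef(fit$modelStruct$corStruct,
                            unconstrained = FALSE))
  .new_calibration_model(
    kind = "varpow",
    beta0 = unname(cf[1]), beta1 = unname(cf[2]),
    sigma = fit$sigma, delta = delta, phi = phi,
    level = level, min_detectable = min_detectable,
    loglik = as.numeric(stats::logLik(fit)), n = nrow(d))
}

#' Gaussian log-likelihood of a calibration model on a dataset
#'
#' Evaluates the block-diagonal (per-lane AR(1), power-variance) Gaussian
#' log-likelihood of a fitted model on calibration points. Used to compare
#' nested fits; independent of the fitting machinery.
#'
#' @param model a `calibration_model`.
#' @param points calibration data frame (`expected`, `measured`, and for
#'   phi != 0 also `lane_id`, `rank`).
#' @return log-likelihood value.
#' @export
calibration_loglik <- function(model, points) {
  points <- .check_points(points)
  mu <- model$beta0 + model$beta1 * points$expected
  sd_i <- model$sigma * abs(mu)^model$delta
  r <- (points$measured - mu) / sd_i
  if (abs(model$phi) < .Machine$double.eps) {
    return(sum(stats::dnorm(points$measured, mu, sd_i, log = TRUE)))
  }
  stopifnot(all(c("lane_id", "rank") %in% names(points)))
  ll <- 0
  for (lane in unique(points$lane_id)) {
    i <- which(points$lane_id == lane)
    i <- i[order(points$rank[i])]
    k <- length(i)
    R <- model$phi^abs(outer(points$rank[i], points$rank[i], "-"))
    ll <- ll - 0.5 * (k * log(2 * pi) + determinant(R)$modulus +
                        2 * sum(log(sd_i[i])) +
                        drop(r[i] %*% solve(R, r[i])))
  }
  as.numeric(ll)
}

#' Invert the prediction band: plausible true sizes for a measurement
#'
#' The permissive range of a measured size `m` is the closed interval of
#' true sizes `x` such that `m` lies within the level-`level` band
#' `beta0 + beta1*x +/- z * sigma * |beta0 + beta1*x|^delta`. The band edges
#' are monotone in `x` (for `beta1 > 0`), so the interval is found by root
#' bracketing; with `sigma = 0` it collapses to the point
#' `(m - beta0)/beta1`.
#'
#' @param model a `calibration_model`.
#' @param measured measured size in nt (vectorized).
#' @return for one measurement, `c(lo, hi)`; for several, a 2-column matrix.
#' @export
permissive_range <- function(model, measured) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$beta1 <= 0)
    stop("calibration slope must be positive to invert the band")
  z <- stats::qnorm(1 - (1 - model$level) / 2)
  one <- function(m) {
    if (model$sigma == 0) {
      x <- (m - model$beta0) / model$beta1
      return(c(lo = x, hi = x))
    }
    g <- function(x) model$beta0 + model$beta1 * x
    half <- function(x) z * model$sigma * abs(g(x))^model$delta
    upper_edge <- function(x) g(x) + half(x) - m   # root: lower end of range
    lower_edge <- function(x) g(x) - half(x) - m   # root: upper end of range
    x0 <- max((m - model$beta0) / model$beta1, 1e-6)
    bracket <- c(1e-9, max(10 * x0, 1e4))
    lo <- tryCatch(stats::uniroot(upper_edge, bracket, extendInt = "upX",
                                  tol = 1e-8)$root,
                   error = function(e) 0)
    hi <- stats::uniroot(lower_edge, bracket, extendInt = "upX",
                         tol = 1e-8)$root
    c(lo = max(lo, 0), hi = hi)
  }
  if (length(measured) == 1L) return(one(measured))
  t(vapply(measured, one, numeric(2)))
}
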