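#' Fit a sigmoid dose-response curve
#'
#' Least-squares fit of the inducer dose-response
#' \deqn{f(x) = f_{max} / (1 + \exp(-(x - x_{1/2})/\gamma))}
#' (the rising logistic: signal grows with inducer concentration, as an
#' arabinose-inducible promoter does). The literal falling form
#' \eqn{f_{max} / (1 + \exp((x - x_{1/2})/\gamma))} is available via
#' `form = "falling"`. Initialisation is taken from the data: `f_max` from
#' the maximum signal, `x_half` from the concentration whose signal is
#' closest to half-maximum, `gamma_rate` from a tenth of the concentration
#' range.
#'
#' @param data Data frame with numeric columns `x` (inducer concentration,
#'   e.g. % w/v arabinose) and `y` (mean signal).
#' @param form `"rising"` (default) or `"falling"`.
#' @return An object of class `sigmoid_fit` with elements `f_max`, `x_half`,
#'   `gamma_rate`, `residual_norm`, `form`, `fit` (the underlying `nls`
#'   object, or `NULL` for the degenerate all-zero case), `data`.
#' @examples
#' x <- exp(seq(log(0.001), log(0.1), length.out = 8))
#' y <- 100 / (1 + exp(-(x - 0.03) / 0.01))
#' fit_sigmoid(data.frame(x = x, y = y))
#' @export
fit_sigmoid <- function(data, form = c("rising", "falling")) {
  form <- match.arg(form)
  x <- data$x; y <- data$y
  if (length(x) < 4L) abort("fit_sigmoid() needs at least 4 points")
  if (any(x < 0)) abort("concentrations must be non-negative")
  if (length(unique(x)) < 2L) abort("concentrations must not all be equal")
  if (max(y) <= 0) {
    # degenerate flat-zero response: f_max -> 0, shape parameters moot
    out <- structure(list(f_max = 0, x_half = median(x),
                          gamma_rate = NA_real_, residual_norm = sqrt(sum(y^2)),
                          form = form, fit = NULL, data = as_tibble(data)),
                     class = "sigmoid_fit")
    return(out)
  }
  sign_ <- if (form == "rising") -1 else 1
  fmax0 <- max(y)
  xhalf0 <- x[which.min(abs(y - fmax0 / 2))]
  gam0 <- diff(range(x)) / 10
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ f_max / (1 + exp(sign_ * (x - x_half) / gamma_rate)),
      data = data.frame(x = x, y = y),
      start = list(f_max = fmax0, x_half = xhalf0, gamma_rate = gam0),
      lower = c(0, -Inf, .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(sprintf(
        "sigmoid fit failed to converge (start: f_max=%g, x_half=%g, gamma_rate=%g): %s",
        fmax0, xhalf0, gam0, conditionMessage(e)))
    })
  cf <- coef(fit)
  structure(list(f_max = unname(cf["f_max"]), x_half = unname(cf["x_half"]),
                 gamma_rate = unname(cf["gamma_rate"]),
                 residual_norm = sqrt(sum(resid(fit)^2)),
                 form = form, fit = fit, data = as_tibble(data)),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit %s> f_max=%.6g  x_half=%.6g  gamma_rate=%.6g  residual_norm=%.3g\n",
              x$form, x$f_max, x$x_half, x$gamma_rate, x$residual_norm))
  invisible(x)
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$x
  if (is.null(object$fit)) return(rep(0, length(x)))
  sign_ <- if (object$form == "rising") -1 else 1
  object$f_max / (1 + exp(sign_ * (x - object$x_half) / object$gamma_rate))
}

#' @exportS3Method
tidy.sigmoid_fit <- function(x, ...) {
  tibble(term = c("f_max", "x_half", "gamma_rate"),
         estimate = c(x$f_max, x$x_half, x$gamma_rate))
}

#' @exportS3Method
glance.sigmoid_fit <- function(x, ...) {
  tibble(residual_norm = x$residual_norm, n = nrow(x$data), form = x$form,
         converged = is.null(x$fit) || x$fit$convInfo$isConv)
}

#' Maximum-likelihood gamma fit of per-cell fluorescence
#'
#' Per-cell fluorescence of a constitutively expressed reporter is
#' well described by a gamma distribution whose shape parameter sets the
#' noise: the predicted coefficient of variation is \eqn{1/\sqrt{shape}}
#' (shape 25 gives CV 0.2, the regime seen in the linear induction range).
#' Fitting is by maximum likelihood (moment-based start, bounded
#' optimisation, fixed iteration cap).
#'
#' @param values Numeric vector of per-cell fluorescence values (n >= 50,
#'   all > 0).
#' @return An object of class `gamma_fit`: `shape`, `scale`, `cv_predicted`,
#'   `loglik`, `n`, `fit` (the `fitdistrplus::fitdist` object), `values`.
#' @export
fit_gamma <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 50L) abort("fit_gamma() needs at least 50 values")
  if (any(values <= 0)) abort("fluorescence values must all be positive")
  if (stats::sd(values) == 0) abort("constant values: zero variance, gamma fit undefined")
  fd <- fitdistrplus::fitdist(values, "gamma", method = "mle",
                              control = list(maxit = 500))
  shape <- unname(fd$estimate["shape"])
  scale <- 1 / unname(fd$estimate["rate"])
  structure(list(shape = shape, scale = scale,
                 cv_predicted = 1 / sqrt(shape),
                 loglik = fd$loglik, n = length(values), fit = fd,
                 values = values),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("<gamma_fit> shape=%.4g  scale=%.4g  predicted CV=%.3g  (n=%d)\n",
              x$shape, x$scale, x$cv_predicted, x$n))
  invisible(x)
}

#' @exportS3Method
tidy.gamma_fit <- function(x, ...) {
  tibble(term = c("shape", "scale"), estimate = c(x$shape, x$scale),
         std.error = unname(x$fit$sd[c("shape", "rate")]) *
           c(1, x$scale^2))  # delta method for scale = 1/rate
}

#' @exportS3Method
glance.gamma_fit <- function(x, ...) {
  tibble(cv_predicted = x$cv_predicted, logLik = x$loglik, n = x$n)
}

#' Exponential decay rate and half-life
#'
#' Fits `log(y) ~ t` by least squares, for signal dilution by growth after
#' induction is withdrawn: with no degradation, the half-life equals the
#' culture doubling time. A flat series gives rate 0 and infinite half-life.
#'
#' @param data Data frame with numeric columns `t` (time) and `y` (signal,
#'   all > 0; >= 3 points).
#' @return An object of class `decay_fit`: `rate` (per unit time),
#'   `half_time` (`log(2)/rate`), `fit` (the `lm`), `data`.
#' @examples
#' d <- data.frame(t = seq(0, 160, by = 32), y = 100 * 2^(-seq(0, 160, by = 32) / 32))
#' decay_halflife(d)
#' @export
decay_halflife <- function(data) {
  t <- data$t; y <- data$y
  if (length(t) < 3L) abort("decay_halflife() needs at least 3 points")
  if (any(y <= 0)) abort("signals must all be positive for a log-linear fit")
  fit <- lm(log(y) ~ t)
  rate <- -unname(coef(fit)[2])
  # a numerically flat series (|slope| below machine-level noise) is no decay
  if (abs(rate) < 1e-12) rate <- 0
  structure(list(rate = rate,
                 half_time = if (rate == 0) Inf else log(2) / rate,
                 fit = fit, data = as_tibble(data)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> rate=%.6g per unit time, half-life=%.6g\n",
              x$rate, x$half_time))
  invisible(x)
}

#' @exportS3Method
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("rate", "half_time"), estimate = c(x$rate, x$half_time))
}

#' @exportS3Method
glance.decay_fit <- function(x, ...) {
  tibble(r.squared = summary(x$fit)$r.squared, n = nrow(x$data))
}
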