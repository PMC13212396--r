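#' Normalized quantile residuals
#'
#' For each observation, the standard-normal quantile of its fitted
#' conditional BCPE distribution function:
#' \eqn{r_i = \Phi^{-1}(F(y_i \mid \hat\theta(x_i)))}. Under a correctly
#' specified model the residuals are standard normal. Works against a
#' fitted model ([fit_centiles()]) or a generating truth ([build_truth()]),
#' which makes calibration checks under the true model possible.
#'
#' @param object A `centile_fit` or `generator_truth`.
#' @param data Data frame holding the covariate and response columns.
#' @param response Response column name.
#' @return Numeric vector of residuals, one per row of `data`.
#' @export
quantile_residuals <- function(object, data, response = "liver_length_cm") {
  x <- data[[covariate_of(object)]]
  y <- data[[response]]
  pars <- params_of(object, x)
  u <- pbcpe(y, pars$mu, pars$sigma, pars$nu, pars$tau)
  n_clamped <- sum(u < 1e-10 | u > 1 - 1e-10)
  if (n_clamped > 0) {
    warning(n_clamped, " residual(s) at the cdf boundary clamped")
  }
  stats::qnorm(pmin(pmax(u, 1e-10), 1 - 1e-10))
}

covariate_of <- function(object) {
  stopifnot(inherits(object, c("centile_fit", "generator_truth")))
  object$covariate
}

params_of <- function(object, x) {
  if (inherits(object, "centile_fit")) {
    predict_params(object, x)
  } else {
    truth_params(object, x)
  }
}

#' LOESS smooth of residuals against the covariate
#'
#' Local linear regression with tricube weights over the span-nearest
#' neighbors (no robustness iterations), evaluated on a 100-point grid.
#' Used to reveal systematic trends the model failed to absorb.
#'
#' @param points Data frame with columns `x` and `r`.
#' @param span Neighborhood fraction in (0, 1].
#' @return A tibble `(x, smoothed)` on an equally spaced grid.
#' @export
loess_smooth <- function(points, span = 0.5) {
  n <- nrow(points)
  if (n < 20) stop("need at least 20 points for a LOESS residual smooth")
  if (span <= 0 || span > 1) stop("`span` must be in (0, 1]")
  if (span * n < 5) stop("`span` too small: fewer than 5 points in the neighborhood")
  fit <- stats::loess(
    r ~ x,
    data = points, span = span, degree = 1,
    family = "gaussian",
    control = stats::loess.control(surface = "direct")
  )
  grid <- seq(min(points$x), max(points$x), length.out = 100)
  tibble::tibble(x = grid, smoothed = stats::predict(fit, newdata = data.frame(x = grid)))
}

#' Normal quantile-quantile points
#'
#' Sorted residuals against \eqn{\Phi^{-1}((i - 0.5)/n)}.
#'
#' @param residuals Numeric vector (at least 20 values).
#' @return A tibble `(theoretical, sample)`.
#' @export
qq_normal <- function(residuals) {
  n <- length(residuals)
  if (n < 20) stop("need at least 20 residuals for a Q-Q plot")
  tibble::tibble(
    theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
    sample = sort(residuals)
  )
}

# Kolmogorov-Smirnov distance from the standard normal
ks_normal <- function(r) {
  n <- length(r)
  u <- stats::pnorm(sort(r))
  max(pmax(abs(seq_len(n) / n - u), abs((seq_len(n) - 1) / n - u)))
}

sample_skewness <- function(r) {
  m <- mean(r)
  mean((r - m)^3) / (mean((r - m)^2))^1.5
}

sample_excess_kurtosis <- function(r) {
  m <- mean(r)
  mean((r - m)^4) / (mean((r - m)^2))^2 - 3
}

#' Residual diagnostics report
#'
#' Computes the three model-adequacy checks on normalized quantile
#' residuals: the residual-versus-covariate trend (LOESS), the normal
#' Q-Q points, and the residual histogram (Freedman-Diaconis bins),
#' together with summary moments and the Kolmogorov-Smirnov distance from
#' the standard normal. Pure function of (model, data): repeated calls
#' give identical output.
#'
#' @param object A `centile_fit` or `generator_truth`.
#' @param data Data frame with covariate and response columns.
#' @param span LOESS span.
#' @param response Response column name.
#' @return An object of class `centile_diagnostics`.
#' @export
residual_diagnostics <- function(object, data, span = 0.5,
                                 response = "liver_length_cm") {
  x <- data[[covariate_of(object)]]
  r <- quantile_residuals(object, data, response = response)
  h <- graphics::hist(r, breaks = "FD", plot = FALSE)
  structure(
    list(
      residuals = tibble::tibble(x = x, r = r),
      mean = mean(r),
      sd = stats::sd(r),
      skewness = sample_skewness(r),
      excess_kurtosis = sample_excess_kurtosis(r),
      ks_distance = ks_normal(r),
      loess_curve = loess_smooth(tibble::tibble(x = x, r = r), span = span),
      qq_points = qq_normal(r),
      histogram = tibble::tibble(
        mid = h$mids, count = h$counts,
        lo = utils::head(h$breaks, -1), hi = utils::tail(h$breaks, -1)
      ),
      span = span,
      covariate = covariate_of(object)
    ),
    class = "centile_diagnostics"
  )
}

#' @export
print.centile_diagnostics <- function(x, ...) {
  cat(sprintf(
    "<centile_diagnostics> n = %d residuals: mean %.3f, sd %.3f, skew %.3f, excess kurtosis %.3f, KS %.4f\n",
    nrow(x$residuals), x$mean, x$sd, x$skewness, x$excess_kurtosis,
    x$ks_distance
  ))
  invisible(x)
}

#' Write a diagnostics report to JSON
#'
#' @param diag A [residual_diagnostics()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagnostics_json <- function(diag, path) {
  jsonlite::write_json(
    list(
      covariate = diag$covariate,
      n = nrow(diag$residuals),
      moments = list(
        mean = diag$mean, sd = diag$sd, skewness = diag$skewness,
        excess_kurtosis = diag$excess_kurtosis
      ),
      ks_distance = diag$ks_distance,
      loess_span = diag$span,
      loess_curve = diag$loess_curve,
      qq_points = diag$qq_points,
      histogram = diag$histogram
    ),
    path,
    digits = 10, auto_unbox = TRUE
  )
  invisible(path)
}
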