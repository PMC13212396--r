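#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy centile_fit
#' @export
tidy.centile_fit <- function(x, ...) {
  purrr::imap_dfr(
    x$coef,
    function(b, nm) {
      tibble::tibble(
        parameter = nm, term = seq_along(b), estimate = b,
        link = unname(x$links[nm]), lambda = unname(x$lambda[nm])
      )
    }
  ) |>
    dplyr::bind_rows(tibble::tibble(
      parameter = "tau", term = 1L, estimate = log(x$tau),
      link = "log", lambda = NA_real_
    ))
}

#' @method glance centile_fit
#' @export
glance.centile_fit <- function(x, ...) {
  tibble::tibble(
    covariate = x$covariate,
    n_obs = x$n_obs,
    deviance = x$deviance,
    gaic = x$gaic,
    edf = sum(x$edf, na.rm = TRUE),
    tau = x$tau,
    converged = x$converged,
    iterations = x$iterations
  )
}

#' @method augment centile_fit
#' @export
augment.centile_fit <- function(x, data, ...) {
  pars <- predict_params(x, data[[x$covariate]])
  dplyr::bind_cols(
    data,
    tibble::tibble(
      .mu = pars$mu, .sigma = pars$sigma, .nu = pars$nu, .tau = pars$tau,
      .resid = quantile_residuals(x, data, ...)
    )
  )
}

#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) x$flags

#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(
    n_retained = nrow(x$retained),
    n_hard_excluded = nrow(x$hard_excluded),
    n_review = length(unique(x$review$exam_id)),
    review_dropped = x$drop_review
  )
}

#' @method tidy centile_diagnostics
#' @export
tidy.centile_diagnostics <- function(x, ...) x$residuals

#' @method glance centile_diagnostics
#' @export
glance.centile_diagnostics <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$residuals),
    mean = x$mean, sd = x$sd,
    skewness = x$skewness, excess_kurtosis = x$excess_kurtosis,
    ks_distance = x$ks_distance
  )
}

#' Centile fan chart
#'
#' Plots the fitted centile curves (P5/P15/P50/P85/P95 by default) over the
#' covariate range, optionally over the data points.
#'
#' @param object A [fit_centiles()] object.
#' @param data Optional data frame to underlay as points.
#' @param p Centiles to draw.
#' @param n_grid Grid resolution.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot centile_fit
#' @export
autoplot.centile_fit <- function(object, data = NULL,
                                 p = c(0.05, 0.15, 0.5, 0.85, 0.95),
                                 n_grid = 200, ...) {
  grid <- seq(object$range[1], object$range[2], length.out = n_grid)
  cent <- predict_centile(object, grid, p)
  cent$centile_label <- factor(
    sprintf("P%g", cent$p * 100),
    levels = sprintf("P%g", sort(p) * 100)
  )
  gg <- ggplot2::ggplot()
  if (!is.null(data)) {
    gg <- gg + ggplot2::geom_point(
      data = data,
      ggplot2::aes(
        x = .data[[object$covariate]],
        y = .data[[object$response]]
      ),
      alpha = 0.15, size = 0.4, colour = "grey40"
    )
  }
  gg +
    ggplot2::geom_line(
      data = cent,
      ggplot2::aes(x = .data$x, y = .data$centile, colour = .data$centile_label)
    ) +
    ggplot2::labs(
      x = if (object$covariate == "age_years") "Age (years)" else "Height (cm)",
      y = "Liver length (cm)", colour = "Centile"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.centile_fit
#' @param fit A `centile_fit`.
#' @export
plot_centiles <- function(fit, data = NULL, ...) autoplot(fit, data = data, ...)

#' Diagnostic panels
#'
#' One ggplot per adequacy check: residuals against the covariate with the
#' LOESS trend, the normal Q-Q plot, or the residual histogram. With the
#' patchwork package installed, `which = "all"` composes the three panels.
#'
#' @param object A [residual_diagnostics()] object.
#' @param which `"residuals"`, `"qq"`, `"histogram"` or `"all"`.
#' @param ... Unused.
#' @return A ggplot (or patchwork composition).
#' @method autoplot centile_diagnostics
#' @export
autoplot.centile_diagnostics <- function(object,
                                         which = c("residuals", "qq", "histogram", "all"),
                                         ...) {
  which <- match.arg(which)
  xlab <- if (object$covariate == "age_years") "Age (years)" else "Height (cm)"
  panels <- list(
    residuals = ggplot2::ggplot() +
      ggplot2::geom_point(
        data = object$residuals,
        ggplot2::aes(x = .data$x, y = .data$r),
        alpha = 0.15, size = 0.4
      ) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_line(
        data = object$loess_curve,
        ggplot2::aes(x = .data$x, y = .data$smoothed),
        colour = "red"
      ) +
      ggplot2::labs(x = xlab, y = "Normalized quantile residual") +
      ggplot2::theme_minimal(),
    qq = ggplot2::ggplot(
      object$qq_points,
      ggplot2::aes(x = .data$theoretical, y = .data$sample)
    ) +
      ggplot2::geom_abline(linetype = 2) +
      ggplot2::geom_point(size = 0.4, alpha = 0.4) +
      ggplot2::labs(x = "Theoretical quantile", y = "Sample quantile") +
      ggplot2::theme_minimal(),
    histogram = ggplot2::ggplot(object$histogram) +
      ggplot2::geom_col(
        ggplot2::aes(x = .data$mid, y = .data$count),
        width = object$histogram$hi - object$histogram$lo,
        fill = "grey70", colour = "white"
      ) +
      ggplot2::labs(x = "Normalized quantile residual", y = "Count") +
      ggplot2::theme_minimal()
  )
  if (which != "all") {
    return(panels[[which]])
  }
  if (requireNamespace("patchwork", quietly = TRUE)) {
    Reduce(`+`, panels)
  } else {
    panels$residuals
  }
}

#' @rdname autoplot.centile_diagnostics
#' @param diag A `centile_diagnostics`.
#' @export
plot_diagnostics <- function(diag, which = "all", ...) {
  autoplot(diag, which = which, ...)
}
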