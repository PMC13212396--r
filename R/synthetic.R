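#' Published anchor centile tables
#'
#' Loads the packaged transcription of the published liver-length percentile
#' tables (P5/P15/P50/P85/P95 by age or height bin, overall or sex
#' stratified). These printed values anchor the synthetic-cohort generator:
#' at every bin midpoint the generating BCPE parameters are solved so that
#' the simulated conditional distribution reproduces the printed P5/P50/P95.
#'
#' @param covariate `"age_years"` or `"height_cm"`.
#' @param sex `"all"` (default) for the overall table, or `"male"` /
#'   `"female"` for the sex-stratified tables (no per-bin counts are
#'   published for those).
#' @return A tibble with columns `bin`, `lo`, `hi`, `midpoint`, `n` (only
#'   for `sex = "all"`), and `P5`, `P15`, `P50`, `P85`, `P95` in cm.
#' @export
#' @examples
#' liver_anchors("age_years")
liver_anchors <- function(covariate = c("age_years", "height_cm"),
                          sex = c("all", "male", "female")) {
  covariate <- match.arg(covariate)
  sex <- match.arg(sex)
  stem <- if (covariate == "age_years") "anchors_age" else "anchors_height"
  if (sex != "all") stem <- paste0(stem, "_by_sex")
  path <- system.file("extdata", paste0(stem, ".csv"), package = "hepanorm")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (sex != "all") tab <- dplyr::filter(tab, .data$sex == !!sex)
  dplyr::mutate(tab, midpoint = (lo + hi) / 2, .after = "hi")
}

#' Published cohort demographics
#'
#' Summary counts of the source cohort (sex split, age median and quartiles,
#' height availability) as published; used by the `cohort_like` covariate
#' sampling law and for demographic arithmetic.
#'
#' @return A named numeric vector.
#' @export
cohort_demographics <- function() {
  path <- system.file("extdata", "cohort_demographics.csv", package = "hepanorm")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stats::setNames(tab$value, tab$characteristic)
}

#' Solve BCPE parameters from three printed centiles
#'
#' Given printed 5th, 50th and 95th percentiles and a fixed tail-heaviness
#' `tau`, returns the BCPE parameters whose quantiles reproduce them:
#' `mu` equals `q50` (the BCPE median), and `(sigma, nu)` solve the two
#' remaining quantile equations. The system is solved by profiling:
#' for a trial `nu`, `sigma` follows in closed form from the upper quantile
#' equation, and the lower equation becomes a one-dimensional root-finding
#' problem in `nu`.
#'
#' @param q5,q50,q95 Centiles in cm with `0 < q5 < q50 < q95`.
#' @param tau Tail heaviness (default 2, the Box-Cox normal family).
#' @param tol Required reproduction accuracy of the three quantiles.
#' @return A one-row tibble with columns `mu`, `sigma`, `nu`, `tau`.
#' @export
#' @examples
#' solve_bcpe_quantiles(8, 10, 12) # symmetric: nu = 1, sigma = 0.2/1.6449
solve_bcpe_quantiles <- function(q5, q50, q95, tau = 2, tol = 1e-6) {
  stopifnot(q5 > 0, q5 < q50, q50 < q95, tau > 0)
  mu <- q50
  z95 <- pe_quantile(0.95, tau)
  z05 <- -z95
  sigma_of <- function(nu) {
    if (abs(nu) < .NU_EPS) {
      log(q95 / mu) / z95
    } else {
      expm1(nu * log(q95 / mu)) / (nu * z95)
    }
  }
  gap <- function(nu) {
    s <- sigma_of(nu)
    if (!is.finite(s) || s <= 1e-4 || s >= 1) {
      return(NA_real_)
    }
    q5_hat <- if (abs(nu) < .NU_EPS) {
      mu * exp(s * z05)
    } else {
      arg <- 1 + s * nu * z05
      if (arg <= 0) {
        return(NA_real_)
      }
      mu * arg^(1 / nu)
    }
    q5_hat - q5
  }
  nus <- seq(-5, 5, by = 0.1)
  gs <- vapply(nus, gap, numeric(1))
  ok <- which(!is.na(gs))
  hit <- ok[which(diff(sign(gs[ok])) != 0)]
  if (length(hit) == 0) {
    stop("no BCPE parameters with sigma in (1e-4, 1), nu in (-5, 5) reproduce these centiles")
  }
  i <- hit[1]
  j <- ok[which(ok > i)][1]
  root <- stats::uniroot(gap, lower = nus[i], upper = nus[j], tol = 1e-13)$root
  nu <- root
  sigma <- sigma_of(nu)
  out <- tibble::tibble(mu = mu, sigma = sigma, nu = nu, tau = tau)
  got <- qbcpe(c(0.05, 0.5, 0.95), mu, sigma, nu, tau)
  if (max(abs(got - c(q5, q50, q95))) > tol) {
    stop("quantile solver did not reach the requested accuracy")
  }
  out
}

#' Build a covariate-indexed generating truth from an anchor table
#'
#' Solves BCPE parameters at every bin midpoint of a printed centile table
#' and interpolates `(log mu, log sigma, nu)` linearly between midpoints
#' (constant beyond the first and last midpoint). The result is the exact
#' conditional law the synthetic generator simulates from, and the target
#' against which pipeline recovery is scored.
#'
#' @param anchors An anchor table as returned by [liver_anchors()]; any
#'   tibble with columns `midpoint`, `lo`, `hi`, `P5`, `P50`, `P95` works.
#' @param tau Tail heaviness of the generating law, constant across the
#'   covariate (default 2).
#' @param covariate Name of the covariate the anchors are indexed by.
#' @return An object of class `generator_truth`.
#' @export
build_truth <- function(anchors, tau = 2,
                        covariate = c("age_years", "height_cm")) {
  covariate <- match.arg(covariate)
  stopifnot(all(diff(anchors$midpoint) > 0))
  sol <- purrr::pmap_dfr(
    anchors[, c("P5", "P50", "P95")],
    function(P5, P50, P95) solve_bcpe_quantiles(P5, P50, P95, tau = tau)
  )
  structure(
    list(
      covariate = covariate,
      tau = tau,
      anchors = dplyr::bind_cols(anchors, sol[, c("mu", "sigma", "nu")]),
      range = c(min(anchors$lo), max(anchors$hi))
    ),
    class = "generator_truth"
  )
}

#' @export
print.generator_truth <- function(x, ...) {
  cat(
    "<generator_truth> BCPE truth over", x$covariate,
    sprintf("[%g, %g), tau = %g, %d anchors\n", x$range[1], x$range[2],
      x$tau, nrow(x$anchors))
  )
  invisible(x)
}

#' Evaluate the generating truth
#'
#' `truth_params()` returns the interpolated BCPE parameters at covariate
#' values `x`; `truth_quantile()` the corresponding true centiles.
#'
#' @param truth A [build_truth()] object.
#' @param x Covariate values inside the truth range.
#' @param p Probabilities in (0, 1).
#' @return `truth_params()` a tibble `(x, mu, sigma, nu, tau)`;
#'   `truth_quantile()` a tibble `(x, p, centile)`.
#' @export
truth_params <- function(truth, x) {
  a <- truth$anchors
  interp <- function(v) stats::approx(a$midpoint, v, xout = x, rule = 2)$y
  tibble::tibble(
    x = x,
    mu = exp(interp(log(a$mu))),
    sigma = exp(interp(log(a$sigma))),
    nu = interp(a$nu),
    tau = truth$tau
  )
}

#' @rdname truth_params
#' @export
truth_quantile <- function(truth, x, p) {
  grid <- tidyr::expand_grid(x = x, p = p)
  pars <- truth_params(truth, grid$x)
  tibble::tibble(
    x = grid$x, p = grid$p,
    centile = qbcpe(grid$p, pars$mu, pars$sigma, pars$nu, pars$tau)
  )
}

# rough median height (cm) for a given age, used only to fabricate
# plausible ages for height-sampled cohorts and heights for age-sampled ones
age_height_curve <- function() {
  list(
    age = c(0, 0.5, 1, 2, 3, 5, 7, 9, 11, 13, 15, 17, 18),
    height = c(50, 66, 75, 87, 95, 109, 122, 133, 144, 156, 166, 172, 174)
  )
}

height_from_age <- function(age) {
  cv <- age_height_curve()
  stats::approx(cv$age, cv$height, xout = age, rule = 2)$y
}

age_from_height <- function(height) {
  cv <- age_height_curve()
  stats::approx(cv$height, cv$age, xout = height, rule = 2)$y
}

window_days <- function(age_years) {
  ifelse(age_years < 2, 90,
    ifelse(age_years < 9, 180,
      ifelse(age_years < 14, 90, 180)
    )
  )
}

#' Simulate a synthetic ultrasound cohort
#'
#' Draws a cohort of liver-length exam records whose conditional
#' distribution given the covariate is the BCPE `truth`, then dresses it up
#' with the artifacts the ingest and screening stages must handle: a share
#' of measurements rendered as free-text report strings (cm, mm and
#' unitless variants in 70/20/10 proportions), injected gross measurement
#' errors outside the physical 3-25 cm range, height observations at
#' realistic date gaps (including some outside the matching window),
#' and patients carrying exclusion-triggering diagnosis codes or abnormal
#' transaminase flags.
#'
#' @param truth A [build_truth()] object.
#' @param n Number of exam records.
#' @param covariate_sampling `"uniform"` over the truth range (default), or
#'   `"cohort_like"`: bins drawn with probability proportional to the
#'   published per-bin counts, uniform within bin.
#' @param outlier_rate Fraction of records replaced by gross errors drawn
#'   uniformly from \eqn{[0.5, 3) \cup (25, 60]} cm.
#' @param report_frac Fraction of records whose measurement is delivered
#'   only as free text.
#' @param height_frac Fraction of exams given a usable in-window height
#'   observation when the truth covariate is age (height-covariate truths
#'   always get one, since the height is the modeling covariate).
#' @param abnormal_lab_rate,excluded_dx_rate Per-patient probabilities of
#'   an abnormal AST/ALT flag and of carrying an excludable diagnosis code.
#' @param repeat_frac Fraction of patients contributing two exams.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return An object of class `synthetic_cohort`: a list with tibbles
#'   `exams` and `heights` (matching the on-disk CSV interface),
#'   `injected_outlier_ids`, `excluded_code_prefixes`, and the `truth`.
#' @export
simulate_cohort <- function(truth, n,
                            covariate_sampling = c("uniform", "cohort_like"),
                            outlier_rate = 0.01,
                            report_frac = 0.5,
                            height_frac = 0.7,
                            abnormal_lab_rate = 0.02,
                            excluded_dx_rate = 0.02,
                            repeat_frac = 0.04,
                            seed = NULL) {
  covariate_sampling <- match.arg(covariate_sampling)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)

  # patients first: a fraction contribute two exams, and a patient's exams
  # share one growth trajectory (covariate drifts with the date offset)
  a <- truth$anchors
  n_pat <- max(1, round(n / (1 + repeat_frac)))
  owner <- c(seq_len(n_pat), sample.int(n_pat, n - n_pat, replace = TRUE))
  x_base <- if (covariate_sampling == "uniform" || !("n" %in% names(a))) {
    stats::runif(n_pat, truth$range[1], truth$range[2])
  } else {
    bin <- sample.int(nrow(a), n_pat, replace = TRUE, prob = a$n)
    stats::runif(n_pat, a$lo[bin], a$hi[bin])
  }
  date_base <- as.Date("2014-01-01") + sample.int(4017, n_pat, replace = TRUE) - 1
  offset_days <- c(rep(0, n_pat), round(stats::runif(n - n_pat, -270, 270)))
  exam_date <- date_base[owner] + offset_days

  clip <- function(v) {
    pmin(pmax(v, truth$range[1]), truth$range[2] - 1e-3)
  }
  if (truth$covariate == "age_years") {
    age <- clip(x_base[owner] + offset_days / 365.25)
    x <- age
    height <- height_from_age(age) * exp(stats::rnorm(n, 0, 0.035))
  } else {
    # ~6 cm/year average pediatric growth for the date drift
    height <- clip(x_base[owner] + offset_days / 365.25 * 6)
    x <- height
    age <- pmin(pmax(age_from_height(height) +
      stats::rnorm(n, 0, 0.6), 0), 17.99)
  }

  pars <- truth_params(truth, x)
  y <- rbcpe(n, pars$mu, pars$sigma, pars$nu, pars$tau)

  n_out <- round(outlier_rate * n)
  injected <- if (n_out > 0) sample.int(n, n_out) else integer(0)
  if (n_out > 0) {
    # kept clear of the 3/25 cm bounds by half a rounding step so a gross
    # error is still gross after values are rendered to 0.1 cm
    low <- stats::runif(n_out) < 0.5
    y[injected] <- ifelse(low,
      stats::runif(n_out, 0.5, 2.9499),
      stats::runif(n_out, 25.05, 60)
    )
  }

  patient <- sprintf("P%05d", owner)
  exam_id <- sprintf("E%06d", seq_len(n))

  # patient-level exclusion attributes
  pat_tab <- tibble::tibble(patient_id = unique(patient))
  m <- nrow(pat_tab)
  pat_tab$abn_lab <- stats::runif(m) < abnormal_lab_rate
  pat_tab$abn_lab[stats::runif(m) < 0.05] <- NA
  dx_pool_excl <- c("K76.0", "B18.2", "E74.04", "I50.9")
  dx_pool_ok <- c("Z00.129", "R10.9", "J06.9", "")
  pat_tab$dx <- ifelse(stats::runif(m) < excluded_dx_rate,
    sample(dx_pool_excl, m, replace = TRUE),
    sample(dx_pool_ok, m, replace = TRUE, prob = c(0.1, 0.1, 0.1, 0.7))
  )

  # free-text rendering: cm / mm / unitless in 70/20/10 proportions
  y_round <- round(y, 1)
  as_report <- stats::runif(n) < report_frac
  style <- sample(c("cm", "mm", "plain"), n, replace = TRUE,
    prob = c(0.7, 0.2, 0.1))
  style[style == "plain" & (y_round < 3 | y_round > 25)] <- "cm"
  report_text <- dplyr::case_when(
    !as_report ~ NA_character_,
    style == "cm" ~ sprintf("Liver length: %.1f cm.", y_round),
    style == "mm" ~ sprintf("The liver measures %.0f mm in length.", y_round * 10),
    TRUE ~ sprintf("Liver length %.1f, normal echotexture.", y_round)
  )

  exams <- tibble::tibble(
    patient_id = patient,
    exam_id = exam_id,
    exam_date = exam_date,
    age_years = round(age, 3),
    sex = sample(c("male", "female"), n, replace = TRUE,
      prob = c(2055, 2556) / 4611
    ),
    liver_length_cm = ifelse(as_report, NA_real_, y_round),
    report_text = report_text,
    diagnosis_codes = pat_tab$dx[match(patient, pat_tab$patient_id)],
    abnormal_ast_alt = pat_tab$abn_lab[match(patient, pat_tab$patient_id)]
  )

  # height observations: one usable in-window value per selected exam,
  # plus occasional decoys outside the window
  gets_height <- if (truth$covariate == "height_cm") {
    rep(TRUE, n)
  } else {
    stats::runif(n) < height_frac
  }
  w <- window_days(age)
  gap_in <- round(stats::runif(n, -1, 1) * w)
  idx <- which(gets_height)
  heights <- tibble::tibble(
    patient_id = patient[idx],
    obs_date = exam_date[idx] + gap_in[idx],
    height_cm = round(height[idx], 1)
  )
  decoy <- which(stats::runif(n) < 0.05)
  if (length(decoy) > 0) {
    heights <- dplyr::bind_rows(heights, tibble::tibble(
      patient_id = patient[decoy],
      obs_date = exam_date[decoy] +
        (w[decoy] + round(stats::runif(length(decoy), 30, 400))) *
          sample(c(-1, 1), length(decoy), replace = TRUE),
      height_cm = round(height[decoy] + stats::rnorm(length(decoy), 0, 2), 1)
    ))
  }
  heights <- dplyr::arrange(heights, patient_id, obs_date)

  structure(
    list(
      exams = exams,
      heights = heights,
      injected_outlier_ids = exam_id[sort(injected)],
      excluded_code_prefixes = c("K76", "B18", "E74", "I50"),
      truth = truth
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d exams, %d height observations, %d injected outliers (%s truth)\n",
    nrow(x$exams), nrow(x$heights), length(x$injected_outlier_ids),
    x$truth$covariate
  ))
  invisible(x)
}

#' Write a synthetic cohort to CSV
#'
#' Writes `exams.csv` and `heights.csv` in the formats [read_exams()] and
#' [read_heights()] consume, plus `truth.json` describing the generating
#' parameters.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$exams, file.path(dir, "exams.csv"), na = "")
  readr::write_csv(cohort$heights, file.path(dir, "heights.csv"), na = "")
  truth <- cohort$truth
  jsonlite::write_json(
    list(
      covariate = truth$covariate, tau = truth$tau,
      range = truth$range,
      anchors = truth$anchors,
      injected_outlier_ids = cohort$injected_outlier_ids,
      excluded_code_prefixes = cohort$excluded_code_prefixes
    ),
    file.path(dir, "truth.json"),
    digits = I(17), auto_unbox = TRUE
  )
  invisible(dir)
}
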