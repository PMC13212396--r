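#' Stratification bins for outlier screening
#'
#' Age strata: year one in four 3-month bins, year two in two 6-month bins,
#' then annual bins up to 18 years. Height strata: 10-cm increments. Bins
#' are half-open `[lo, hi)`.
#'
#' @param x Covariate values (age in years or height in cm).
#' @param stratification `"age"` or `"height"`.
#' @return Character vector of bin labels (e.g. `"0.25-0.49"`, `"90-99"`).
#' @export
#' @examples
#' assign_screen_bin(c(0.3, 1.6), "age")
#' assign_screen_bin(95, "height")
assign_screen_bin <- function(x, stratification = c("age", "height")) {
  stratification <- match.arg(stratification)
  if (any(!is.finite(x))) stop("out of modeled range: non-finite covariate")
  if (stratification == "age") {
    if (any(x < 0 | x >= 18)) stop("out of modeled range: age must be in [0, 18)")
    edges <- c(0, 0.25, 0.5, 0.75, 1, 1.5, 2:18)
    i <- findInterval(x, edges, rightmost.closed = FALSE)
    lo <- edges[i]
    hi <- edges[i + 1]
    sprintf("%g-%g", lo, hi - 0.01)
  } else {
    if (any(x <= 0)) stop("out of modeled range: height must be positive")
    lo <- floor(x / 10) * 10
    sprintf("%g-%g", lo, lo + 9)
  }
}

#' Robust MAD z-scores
#'
#' Standardizes values within a stratum using the median and the median
#' absolute deviation scaled by the normal-consistency constant 1.4826:
#' \eqn{z_r = (x - median) / (1.4826 \cdot MAD)}. When the MAD is zero (or
#' the stratum has fewer than 2 values) the rule abstains and `NA` scores
#' are returned.
#'
#' @param values Numeric vector (one stratum).
#' @return Numeric vector of robust z-scores, or `NA`s when abstaining.
#' @export
mad_z <- function(values) {
  if (length(values) == 0) stop("empty stratum")
  if (length(values) < 2) {
    return(rep(NA_real_, length(values)))
  }
  med <- stats::median(values)
  mad0 <- stats::median(abs(values - med))
  if (mad0 == 0) {
    return(rep(NA_real_, length(values)))
  }
  (values - med) / (1.4826 * mad0)
}

mad_severity <- function(z) {
  dplyr::case_when(
    is.na(z) ~ NA_character_,
    abs(z) >= 3.5 ~ "extreme",
    abs(z) >= 3 ~ "moderate",
    TRUE ~ NA_character_
  )
}

#' Tukey-fence severities
#'
#' Flags values strictly outside the quartile fences: beyond
#' `1.5 * IQR` is moderate, beyond `3 * IQR` extreme. Quartiles use linear
#' interpolation of order statistics (R quantile type 7). The rule abstains
#' (all `NA`) for strata with fewer than 4 values or zero IQR.
#'
#' @param values Numeric vector (one stratum).
#' @return A tibble with `severity` (`"moderate"`, `"extreme"` or `NA`) and
#'   `score` (distance beyond the nearer quartile in IQR multiples).
#' @export
tukey_severity <- function(values) {
  n <- length(values)
  if (n < 4) {
    return(tibble::tibble(
      severity = rep(NA_character_, n),
      score = rep(NA_real_, n)
    ))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) {
    return(tibble::tibble(
      severity = rep(NA_character_, n),
      score = rep(NA_real_, n)
    ))
  }
  score <- pmax((values - q[2]) / iqr, (q[1] - values) / iqr, 0)
  severity <- dplyr::case_when(
    score > 3 ~ "extreme",
    score > 1.5 ~ "moderate",
    TRUE ~ NA_character_
  )
  tibble::tibble(severity = severity, score = score)
}

#' Hard physical bounds filter
#'
#' Liver lengths below 3 cm or above 25 cm are physically implausible at
#' any pediatric age and are excluded outright (bounds inclusive for
#' retention).
#'
#' @param records Exam tibble with `liver_length_cm`.
#' @return A list with `kept` (tibble) and `excluded_ids` (character).
#' @export
hard_bounds_filter <- function(records) {
  stopifnot(all(!is.na(records$liver_length_cm)))
  ok <- records$liver_length_cm >= 3 & records$liver_length_cm <= 25
  list(
    kept = records[ok, , drop = FALSE],
    excluded_ids = records$exam_id[!ok]
  )
}

flags_for <- function(records, stratification) {
  cov <- if (stratification == "age") {
    records$age_years
  } else if ("height_cm" %in% names(records)) {
    records$height_cm
  } else {
    rep(NA_real_, nrow(records))
  }
  present <- !is.na(cov)
  if (!any(present)) {
    return(tibble::tibble(
      exam_id = character(0), rule = character(0),
      stratification = character(0), severity = character(0),
      score = numeric(0)
    ))
  }
  df <- tibble::tibble(
    exam_id = records$exam_id[present],
    value = records$liver_length_cm[present],
    bin = assign_screen_bin(cov[present], stratification)
  )
  df |>
    dplyr::group_by(.data$bin) |>
    dplyr::reframe(
      exam_id = .data$exam_id,
      mad_score = mad_z(.data$value),
      mad_sev = mad_severity(.data$mad_score),
      tk = tukey_severity(.data$value)
    ) |>
    tidyr::unpack("tk", names_sep = "_") |>
    (\(d) dplyr::bind_rows(
      tibble::tibble(
        exam_id = d$exam_id, rule = "mad_z",
        severity = d$mad_sev, score = d$mad_score
      ),
      tibble::tibble(
        exam_id = d$exam_id, rule = "tukey",
        severity = d$tk_severity, score = d$tk_score
      )
    ))() |>
    dplyr::filter(!is.na(.data$severity)) |>
    dplyr::mutate(stratification = stratification, .after = "rule")
}

#' Two-step outlier screen
#'
#' Applies the hard physical bounds, then runs the two distribution-agnostic
#' rules (MAD z-scores and Tukey fences) within age-stratified and (for
#' records with a matched height) height-stratified bins. A record lands on
#' the review list when it carries at least one extreme flag or at least two
#' moderate flags across distinct (rule, stratification) pairs. Review
#' records are retained in the modeling set by default — an automated
#' pipeline exports them for audit instead of adjudicating them — and can
#' be dropped with `drop_review = TRUE`.
#'
#' @param records Height-matched exam tibble with `liver_length_cm` present.
#' @param drop_review Remove review-listed records from `retained`.
#' @return An object of class `screen_result`: list with `retained`,
#'   `hard_excluded` (tibble of exam_id, liver_length_cm), `review`
#'   (flag tibble restricted to review-triggering exams), and `flags`
#'   (all flags).
#' @export
screen_outliers <- function(records, drop_review = FALSE) {
  hb <- hard_bounds_filter(records)
  kept <- hb$kept
  flags <- dplyr::bind_rows(
    flags_for(kept, "age"),
    flags_for(kept, "height")
  )
  trigger <- flags |>
    dplyr::group_by(.data$exam_id) |>
    dplyr::summarise(
      n_extreme = sum(.data$severity == "extreme"),
      n_moderate = sum(.data$severity == "moderate"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_extreme >= 1 | .data$n_moderate >= 2)
  review <- dplyr::semi_join(flags, trigger, by = "exam_id")
  retained <- if (drop_review) {
    kept[!(kept$exam_id %in% trigger$exam_id), , drop = FALSE]
  } else {
    kept
  }
  structure(
    list(
      retained = retained,
      hard_excluded = records[
        records$exam_id %in% hb$excluded_ids,
        intersect(c("exam_id", "liver_length_cm"), names(records)),
        drop = FALSE
      ],
      review = review,
      flags = flags,
      drop_review = drop_review
    ),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "<screen_result> %d retained, %d hard-excluded, %d on review list%s\n",
    nrow(x$retained), nrow(x$hard_excluded),
    length(unique(x$review$exam_id)),
    if (x$drop_review) " (dropped)" else " (retained, exported for audit)"
  ))
  invisible(x)
}

#' Write the review report
#'
#' One row per (exam, rule, stratification) flag for exams that triggered
#' review, with the measurement and covariates for the human auditor.
#'
#' @param screen A [screen_outliers()] result.
#' @param records The records passed to the screen (for covariates).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_review_csv <- function(screen, records, path) {
  cols <- intersect(
    c("exam_id", "liver_length_cm", "age_years", "height_cm"),
    names(records)
  )
  out <- dplyr::left_join(
    screen$review,
    records[, cols, drop = FALSE],
    by = "exam_id"
  ) |>
    dplyr::select(
      dplyr::all_of(cols),
      "rule", "stratification", "severity", "score"
    )
  readr::write_csv(out, path)
  invisible(path)
}
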