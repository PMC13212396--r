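#' Standard reporting bins
#'
#' The published binning: for age, year one in four 3-month bins, year two
#' in two 6-month bins, then annual bins; for height, 10-cm bins. Bins are
#' half-open `[lo, hi)` and labeled `"3-3.99"` / `"50-59"` with the
#' percentiles evaluated at the arithmetic midpoint.
#'
#' @param covariate `"age_years"` or `"height_cm"`.
#' @param range Numeric length-2; bins whose midpoint falls outside are
#'   dropped. Default the full published span.
#' @return A tibble `(bin, lo, hi, midpoint)`.
#' @export
standard_bins <- function(covariate = c("age_years", "height_cm"),
                          range = NULL) {
  covariate <- match.arg(covariate)
  if (covariate == "age_years") {
    edges <- c(0, 0.25, 0.5, 0.75, 1, 1.5, 2:18)
    lo <- utils::head(edges, -1)
    hi <- utils::tail(edges, -1)
    bin <- sprintf("%g-%g", lo, hi - 0.01)
  } else {
    lo <- seq(20, 240, by = 10)
    hi <- lo + 10
    bin <- sprintf("%g-%g", lo, lo + 9)
  }
  out <- tibble::tibble(bin = bin, lo = lo, hi = hi, midpoint = (lo + hi) / 2)
  if (!is.null(range)) {
    out <- dplyr::filter(out, .data$midpoint >= range[1], .data$midpoint <= range[2])
  }
  out
}

#' Percentile reference table at bin midpoints
#'
#' Evaluates the fitted P5/P15/P50/P85/P95 centiles at the midpoint of each
#' reporting bin and applies the minimum-count reporting rule: bins with
#' fewer than `min_n` observations are omitted (100 by default overall,
#' 50 for sex-stratified tables). Displayed centiles are rounded to 0.1 cm;
#' the unrounded values are kept in an attribute and used by
#' [classify_band()] via [choose_reference()], so rounding stays
#' display-only.
#'
#' @param fit A [fit_centiles()] object.
#' @param data The modeling data (used to count observations per bin); a
#'   `bins` tibble with an `n` column may be given instead.
#' @param bins Optional tibble `(bin, lo, hi, midpoint[, n])`; default
#'   [standard_bins()] restricted to the fitted range.
#' @param sex_stratum `"all"`, `"male"` or `"female"` (metadata; also sets
#'   the `min_n` default).
#' @param min_n Minimum per-bin count for reporting.
#' @param probs Centile probabilities reported.
#' @return A `centile_table`: tibble `(bin, lo, hi, midpoint, n, P5, P15,
#'   P50, P85, P95)` with attributes `raw` (unrounded centiles),
#'   `covariate`, `sex_stratum`, `min_n`.
#' @export
centile_table <- function(fit, data = NULL, bins = NULL,
                          sex_stratum = c("all", "male", "female"),
                          min_n = NULL,
                          probs = c(0.05, 0.15, 0.5, 0.85, 0.95)) {
  stopifnot(inherits(fit, "centile_fit"))
  sex_stratum <- match.arg(sex_stratum)
  if (is.null(min_n)) min_n <- if (sex_stratum == "all") 100 else 50
  if (is.null(bins)) {
    bins <- standard_bins(fit$covariate, range = fit$range)
  }
  if (!("n" %in% names(bins))) {
    if (is.null(data)) stop("supply `data` (to count bins) or `bins` with an `n` column")
    x <- data[[fit$covariate]]
    x <- x[is.finite(x)]
    bins$n <- vapply(
      seq_len(nrow(bins)),
      function(i) sum(x >= bins$lo[i] & x < bins$hi[i]),
      numeric(1)
    )
  }
  drop <- bins$n < min_n
  if (all(drop)) stop("no reportable bins: all counts below min_n = ", min_n)
  if (any(drop)) {
    message(
      sum(drop), " bin(s) below min_n = ", min_n, " omitted: ",
      paste(bins$bin[drop], collapse = ", ")
    )
  }
  bins <- bins[!drop, , drop = FALSE]
  cent <- predict_centile(fit, bins$midpoint, probs)
  wide <- matrix(cent$centile, nrow = nrow(bins), byrow = TRUE)
  colnames(wide) <- paste0("P", round(probs * 100))
  raw <- dplyr::bind_cols(bins, tibble::as_tibble(wide))
  out <- raw
  out[, colnames(wide)] <- round(out[, colnames(wide)], 1)
  structure(
    out,
    raw = raw,
    covariate = fit$covariate,
    sex_stratum = sex_stratum,
    min_n = min_n,
    class = c("centile_table", class(out))
  )
}

#' Classify a measurement into reference bands
#'
#' Bands: below P5 abnormal low; \[P5, P15) low normal; \[P15, P85\] normal;
#' (P85, P95\] high normal; above P95 abnormal high. The P5-P95 interval is
#' the reference (normal) range; P5-P15 and P85-P95 are gray zones.
#'
#' @param y Measurements (cm).
#' @param p5,p15,p85,p95 Centiles of the applicable reference row
#'   (unrounded values preferred), recycled against `y`.
#' @return Factor with levels `abnormal_low`, `low_normal`, `normal`,
#'   `high_normal`, `abnormal_high`.
#' @export
#' @examples
#' classify_band(11.5, 8.7, 9.2, 11.2, 11.8) # high_normal
classify_band <- function(y, p5, p15, p85, p95) {
  if (any(!(p5 < p15 & p15 < p85 & p85 < p95))) {
    stop("non-monotone centile row")
  }
  bands <- c("abnormal_low", "low_normal", "normal", "high_normal", "abnormal_high")
  out <- dplyr::case_when(
    y < p5 ~ "abnormal_low",
    y < p15 ~ "low_normal",
    y <= p85 ~ "normal",
    y <= p95 ~ "high_normal",
    TRUE ~ "abnormal_high"
  )
  factor(out, levels = bands)
}

#' Pick the applicable reference row
#'
#' Liver size correlates more strongly with height than with age, so the
#' height-based row is preferred whenever a height is available and covered
#' by a reported bin; otherwise the age-based row is used (with a warning
#' if an uncovered height had to be passed over).
#'
#' @param age Age in years, or `NA`.
#' @param height Height in cm, or `NA`.
#' @param age_table,height_table [centile_table()] objects (either may be
#'   `NULL` when unavailable).
#' @return One-row tibble: the chosen (unrounded) reference row plus a
#'   `reference` column (`"height"` or `"age"`).
#' @export
choose_reference <- function(age = NA, height = NA,
                             age_table = NULL, height_table = NULL) {
  row_in <- function(tab, v) {
    if (is.null(tab) || is.na(v)) {
      return(NULL)
    }
    raw <- attr(tab, "raw")
    i <- which(raw$lo <= v & v < raw$hi)
    if (length(i) == 0) {
      return(NULL)
    }
    raw[i[1], , drop = FALSE]
  }
  h_row <- row_in(height_table, height)
  if (!is.null(h_row)) {
    return(dplyr::mutate(h_row, reference = "height"))
  }
  if (!is.na(height) && !is.null(height_table)) {
    warning("height ", height, " cm not covered by a reported bin; falling back to age")
  }
  a_row <- row_in(age_table, age)
  if (!is.null(a_row)) {
    return(dplyr::mutate(a_row, reference = "age"))
  }
  stop("no applicable reference: neither covariate is covered by a reported bin")
}

#' Classify a table of measurements
#'
#' Adds `reference` (which table was used) and `band` columns to a
#' measurements data frame, row by row, preferring height-based rows.
#'
#' @param data Data frame with `liver_length_cm` and `age_years` and/or
#'   `height_cm`.
#' @param age_table,height_table [centile_table()] objects.
#' @return `data` with `reference` and `band` appended.
#' @export
classify_measurements <- function(data, age_table = NULL, height_table = NULL) {
  rows <- purrr::pmap(
    list(
      data$liver_length_cm,
      if ("age_years" %in% names(data)) data$age_years else rep(NA_real_, nrow(data)),
      if ("height_cm" %in% names(data)) data$height_cm else rep(NA_real_, nrow(data))
    ),
    function(y, a, h) {
      ref <- choose_reference(a, h, age_table, height_table)
      tibble::tibble(
        reference = ref$reference,
        band = classify_band(y, ref$P5, ref$P15, ref$P85, ref$P95)
      )
    }
  )
  dplyr::bind_cols(data, dplyr::bind_rows(rows))
}

#' Write a centile table to CSV or JSON
#'
#' @param table A [centile_table()].
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_centile_table <- function(table, path) {
  out <- dplyr::select(
    tibble::as_tibble(table),
    "bin", "midpoint", "n", dplyr::starts_with("P")
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(
        covariate = attr(table, "covariate"),
        sex_stratum = attr(table, "sex_stratum"),
        min_n = attr(table, "min_n"),
        rows = out
      ),
      path,
      digits = 10, auto_unbox = TRUE
    )
  } else {
    readr::write_csv(out, path)
  }
  invisible(path)
}
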