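#' Parse liver length from free-text report snippets
#'
#' Extracts the first liver-length mention from free text and standardizes
#' it to centimeters. A number with an explicit unit wins (`cm` as is,
#' `mm` divided by 10). A unitless number is interpreted by plausibility:
#' values in \[3, 25\] are taken as cm, values in \[30, 250\] as mm; anything
#' else returns `NA`. Absence of a measurement is a value, not an error;
#' malformed numerics yield `NA` with a warning.
#'
#' @param text Character vector of report snippets.
#' @return Numeric vector of lengths in cm (`NA` where no measurement).
#' @export
#' @examples
#' parse_liver_length(c(
#'   "Liver length: 10.2 cm", # 10.2
#'   "liver measures 102 mm in length", # 10.2
#'   "Liver normal in echotexture." # NA
#' ))
parse_liver_length <- function(text) {
  num <- "([0-9]+(?:[.,][0-9]+)?)"
  with_unit <- stringr::str_match(
    stringr::str_to_lower(text),
    paste0(num, "\\s*(cm|mm)\\b")
  )
  bare <- stringr::str_match(stringr::str_to_lower(text), num)

  to_num <- function(s) {
    v <- suppressWarnings(as.numeric(sub(",", ".", s, fixed = TRUE)))
    bad <- !is.na(s) & is.na(v)
    if (any(bad)) {
      warning(sum(bad), " malformed numeric value(s) could not be parsed")
    }
    v
  }
  v_unit <- to_num(with_unit[, 2])
  unit <- with_unit[, 3]
  v_bare <- to_num(bare[, 2])

  out <- ifelse(!is.na(v_unit),
    ifelse(unit == "mm", v_unit / 10, v_unit),
    ifelse(is.na(v_bare), NA_real_,
      ifelse(v_bare >= 3 & v_bare <= 25, v_bare,
        ifelse(v_bare >= 30 & v_bare <= 250, v_bare / 10, NA_real_)
      )
    )
  )
  out[is.na(text) | !nzchar(trimws(ifelse(is.na(text), "", text)))] <- NA_real_
  out
}

#' Read an exam table
#'
#' Reads the exams CSV (columns `patient_id, exam_id, exam_date, age_years,
#' sex, liver_length_cm, report_text, diagnosis_codes, abnormal_ast_alt`;
#' `diagnosis_codes` semicolon-separated, dates ISO-8601) and standardizes
#' it: missing numeric lengths are filled by parsing `report_text`, records
#' still lacking a measurement or aged 18 years or more are dropped with a
#' message, and `sex` is normalized to `male`/`female`/`unknown`.
#'
#' @param path Path to the exams CSV.
#' @return A tibble of exam records with `liver_length_cm` present on every
#'   row and `age_years < 18`.
#' @export
read_exams <- function(path) {
  ex <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = "c", exam_id = "c", exam_date = readr::col_date(),
      age_years = "d", sex = "c", liver_length_cm = "d",
      report_text = "c", diagnosis_codes = "c", abnormal_ast_alt = "l"
    ),
    progress = FALSE
  )
  if (anyDuplicated(ex$exam_id) > 0) stop("duplicate exam_id in ", path)
  if (any(!is.na(ex$age_years) & ex$age_years < 0)) stop("negative age_years in ", path)
  ex <- dplyr::mutate(ex,
    sex = dplyr::if_else(.data$sex %in% c("male", "female"), .data$sex, "unknown"),
    liver_length_cm = dplyr::coalesce(
      .data$liver_length_cm,
      parse_liver_length(.data$report_text)
    )
  )
  n0 <- nrow(ex)
  ex <- dplyr::filter(
    ex,
    !is.na(.data$liver_length_cm),
    !is.na(.data$age_years), .data$age_years < 18
  )
  if (nrow(ex) < n0) {
    message(n0 - nrow(ex), " exam(s) dropped (no parseable measurement or age >= 18)")
  }
  ex
}

#' Read a height-observation table
#'
#' Reads the heights CSV (`patient_id, obs_date, height_cm`), rejecting
#' implausible heights outside (20, 250) cm at read time.
#'
#' @param path Path to the heights CSV.
#' @return A tibble of height observations.
#' @export
read_heights <- function(path) {
  ht <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = "c", obs_date = readr::col_date(), height_cm = "d"
    ),
    progress = FALSE
  )
  n0 <- nrow(ht)
  ht <- dplyr::filter(ht, .data$height_cm > 20, .data$height_cm < 250)
  if (nrow(ht) < n0) {
    message(n0 - nrow(ht), " height observation(s) outside (20, 250) cm rejected")
  }
  ht
}

#' Read an ICD-10 exclusion prefix list
#'
#' One prefix per line; blank lines and `#` comments ignored.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of prefixes.
#' @export
read_exclusion_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Attach the closest in-window height to each exam
#'
#' Heights count only when observed within an age-specific window around
#' the exam date: under 2 years, 90 days; 2 to under 9 years, 180 days;
#' 9 to under 14 years, 90 days; 14 years and over, 180 days (all
#' inclusive, in whole days, on either side). Among in-window observations
#' the one closest to the exam date is attached; equidistant ties go to the
#' earlier observation.
#'
#' @param exams Exam tibble ([read_exams()]).
#' @param heights Height tibble ([read_heights()]).
#' @return The exams with columns `height_cm` and `height_gap_days` added
#'   (`NA` when no observation falls inside the window).
#' @export
match_heights <- function(exams, heights) {
  cand <- dplyr::inner_join(
    dplyr::select(exams, "exam_id", "patient_id", "exam_date", "age_years"),
    heights,
    by = "patient_id", relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      gap = as.integer(.data$obs_date - .data$exam_date),
      height_gap_days = abs(.data$gap)
    ) |>
    dplyr::filter(.data$height_gap_days <= window_days(.data$age_years)) |>
    dplyr::arrange(.data$exam_id, .data$height_gap_days, .data$obs_date) |>
    dplyr::distinct(.data$exam_id, .keep_all = TRUE)
  dplyr::left_join(
    exams,
    dplyr::select(cand, "exam_id", "height_cm", "height_gap_days"),
    by = "exam_id"
  )
}

split_codes <- function(codes) {
  strsplit(ifelse(is.na(codes), "", codes), ";", fixed = TRUE) |>
    lapply(trimws) |>
    lapply(function(x) x[nzchar(x)])
}

#' Apply patient-level exclusion criteria
#'
#' Removes every exam of any patient who has a documented abnormal AST/ALT
#' result (regardless of date, i.e. on any of their exams) or whose
#' diagnosis codes include a code starting with one of the supplied ICD-10
#' prefixes. Exclusion is patient-level: all of an excluded patient's exams
#' are dropped, and all exams of retained patients are kept (no collapsing
#' to one exam per patient).
#'
#' @param records Exam tibble (possibly height-matched).
#' @param excluded_codes Character vector of ICD-10 prefixes (the published
#'   list is institutional; callers supply their own).
#' @return The subset of `records` belonging to retained patients.
#' @export
apply_exclusions <- function(records, excluded_codes = character(0)) {
  codes <- split_codes(records$diagnosis_codes)
  hit_dx <- vapply(codes, function(cs) {
    length(cs) > 0 && length(excluded_codes) > 0 &&
      any(vapply(
        cs,
        function(cd) any(startsWith(cd, excluded_codes)),
        logical(1)
      ))
  }, logical(1))
  abn <- !is.na(records$abnormal_ast_alt) & records$abnormal_ast_alt
  excluded_patients <- unique(records$patient_id[hit_dx | abn])
  out <- records[!(records$patient_id %in% excluded_patients), , drop = FALSE]
  if (length(excluded_patients) > 0) {
    message(
      length(excluded_patients), " patient(s) excluded (",
      nrow(records) - nrow(out), " exams)"
    )
  }
  out
}
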