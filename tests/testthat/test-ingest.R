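# Measurement parsing, height matching, exclusion filters

test_that("liver lengths are parsed from free text and standardized to cm", {
  expect_equal(parse_liver_length("Liver length: 10.2 cm"), 10.2)
  expect_equal(parse_liver_length("liver measures 102 mm in length"), 10.2)
  expect_true(is.na(parse_liver_length("Liver normal in echotexture.")))
  # unitless plausibility heuristic
  expect_equal(parse_liver_length("Liver length 9.8, normal."), 9.8)
  expect_equal(parse_liver_length("length 98 craniocaudal"), 9.8)
  expect_true(is.na(parse_liver_length("measurement 500 noted")))
  expect_true(is.na(parse_liver_length("value 27 recorded"))) # between ranges
  # unit wins over plausibility; first mention wins
  expect_equal(parse_liver_length("spleen 8.1 cm; liver 12.3 cm"), 8.1)
  expect_true(is.na(parse_liver_length(NA_character_)))
  expect_true(is.na(parse_liver_length("")))
})

test_that("parsing a standardized value string is idempotent", {
  vals <- c(3.0, 5.7, 10.2, 24.9)
  once <- parse_liver_length(sprintf("%.1f", vals))
  expect_equal(once, vals)
  expect_equal(parse_liver_length(sprintf("%.1f cm", once)), vals)
})

make_exam <- function(age, exam_date = as.Date("2020-06-01"), id = "E1") {
  tibble::tibble(
    patient_id = "P1", exam_id = id, exam_date = exam_date,
    age_years = age, sex = "female", liver_length_cm = 10,
    report_text = NA_character_, diagnosis_codes = NA_character_,
    abnormal_ast_alt = FALSE
  )
}

make_height <- function(days_offset, height = 80,
                        exam_date = as.Date("2020-06-01")) {
  tibble::tibble(
    patient_id = "P1", obs_date = exam_date + days_offset, height_cm = height
  )
}

test_that("height matching respects the age-specific windows", {
  # age 1.5: window 90 days; 80 days before the exam is attached
  m <- match_heights(make_exam(1.5), make_height(-80))
  expect_equal(m$height_cm, 80)
  expect_equal(m$height_gap_days, 80L)
  # age 10: window 90 days; 120 days after is NOT attached
  m <- match_heights(make_exam(10), make_height(120, 140))
  expect_true(is.na(m$height_cm))
  # age 5: window 180 days, closest of 30 and 60 wins
  hts <- dplyr::bind_rows(make_height(30, 101), make_height(60, 115))
  m <- match_heights(make_exam(5), hts)
  expect_equal(m$height_cm, 101)
  # age 14: window back to 180 days
  m <- match_heights(make_exam(14.5), make_height(150, 160))
  expect_equal(m$height_cm, 160)
  # boundary gap exactly at the window is inclusive
  m <- match_heights(make_exam(1.0), make_height(90, 78))
  expect_equal(m$height_gap_days, 90L)
})

test_that("equidistant height ties go to the earlier observation", {
  hts <- dplyr::bind_rows(make_height(30, 99), make_height(-30, 95))
  m <- match_heights(make_exam(3), hts)
  expect_equal(m$height_cm, 95)
})

test_that("attached heights never exceed the window (property)", {
  set.seed(42)
  for (i in 1:25) {
    n_ex <- 8
    exams <- tibble::tibble(
      patient_id = sample(c("A", "B"), n_ex, replace = TRUE),
      exam_id = sprintf("E%d", seq_len(n_ex)),
      exam_date = as.Date("2018-01-01") + sample.int(2000, n_ex),
      age_years = runif(n_ex, 0, 17.9),
      liver_length_cm = 10
    )
    hts <- tibble::tibble(
      patient_id = sample(c("A", "B"), 12, replace = TRUE),
      obs_date = as.Date("2018-01-01") + sample.int(2000, 12),
      height_cm = runif(12, 50, 180)
    )
    m <- match_heights(exams, hts)
    w <- ifelse(m$age_years < 2, 90,
      ifelse(m$age_years < 9, 180, ifelse(m$age_years < 14, 90, 180))
    )
    ok <- is.na(m$height_gap_days) | m$height_gap_days <= w
    expect_true(all(ok))
  }
})

test_that("exclusions are patient-level and prefix-matched", {
  recs <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P3", "P3", "P4"),
    exam_id = sprintf("E%d", 1:6),
    diagnosis_codes = c(NA, NA, "K76.0", "Z00.1;J06.9", NA, "B18.2;Z00.1"),
    abnormal_ast_alt = c(TRUE, NA, FALSE, FALSE, NA, FALSE)
  )
  out <- suppressMessages(apply_exclusions(recs, c("K76", "B18")))
  # P1 abnormal labs (both exams), P2 code K76.0, P4 code B18.2 all dropped
  expect_setequal(out$exam_id, c("E4", "E5"))
  # subset property and all-or-none per patient
  expect_true(all(out$exam_id %in% recs$exam_id))
  kept_p <- unique(out$patient_id)
  expect_true(all(table(recs$patient_id[recs$patient_id %in% kept_p]) ==
    table(out$patient_id)))
  # no exclusion list: only the lab rule applies, exams per patient retained
  out2 <- suppressMessages(apply_exclusions(recs, character(0)))
  expect_setequal(out2$exam_id, c("E3", "E4", "E5", "E6"))
})

test_that("exam and height CSV round trips through read functions", {
  f <- small_cohort_files()
  ex <- suppressMessages(read_exams(file.path(f$dir, "exams.csv")))
  expect_true(all(!is.na(ex$liver_length_cm)))
  expect_true(all(ex$age_years < 18))
  expect_false(any(duplicated(ex$exam_id)))
  ht <- suppressMessages(read_heights(file.path(f$dir, "heights.csv")))
  expect_true(all(ht$height_cm > 20 & ht$height_cm < 250))
  # all text-only records recovered their measurement by parsing
  raw <- f$cohort$exams
  text_only <- raw$exam_id[is.na(raw$liver_length_cm) & !is.na(raw$report_text)]
  expect_true(all(text_only %in% ex$exam_id))
})

test_that("implausible heights are rejected at read time", {
  tf <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    patient_id = c("A", "B", "C"),
    obs_date = as.Date("2020-01-01") + 0:2,
    height_cm = c(15, 120, 260)
  ), tf)
  ht <- suppressMessages(read_heights(tf))
  expect_equal(ht$height_cm, 120)
})
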