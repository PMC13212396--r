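# Percentile tables, reporting rules, band classification

test_that("bins below the reporting floor are omitted", {
  fit <- small_constant_fit()
  bins <- tibble::tibble(
    bin = c("3-3.99", "4-4.99", "5-5.99"),
    lo = 3:5, hi = 4:6, midpoint = c(3.5, 4.5, 5.5),
    n = c(99, 100, 250)
  )
  tab <- suppressMessages(centile_table(fit, bins = bins))
  expect_setequal(tab$bin, c("4-4.99", "5-5.99"))
  # sex-stratified floor is 50
  tab2 <- centile_table(fit,
    bins = dplyr::mutate(bins, n = c(49, 50, 60)),
    sex_stratum = "male"
  ) |> suppressMessages()
  expect_setequal(tab2$bin, c("4-4.99", "5-5.99"))
  expect_error(
    centile_table(fit, bins = dplyr::mutate(bins, n = c(10, 20, 30))),
    "no reportable bins"
  )
})

test_that("midpoints are arithmetic centers and rows are monotone", {
  sb <- standard_bins("age_years")
  expect_equal(sb$midpoint[sb$bin == "3-3.99"], 3.5)
  expect_equal(sb$midpoint[sb$bin == "0-0.24"], 0.125)
  expect_equal(standard_bins("height_cm")$midpoint[
    standard_bins("height_cm")$bin == "50-59"
  ], 55)

  fit <- small_constant_fit()
  d <- constant_truth_data()
  tab <- suppressMessages(centile_table(fit, d))
  raw <- attr(tab, "raw")
  expect_true(all(
    raw$P5 < raw$P15 & raw$P15 < raw$P50 & raw$P50 < raw$P85 & raw$P85 < raw$P95
  ))
  # displayed values are the raw ones rounded to 0.1
  expect_equal(tab$P50, round(raw$P50, 1))
  # deterministic: regenerating gives an identical table
  tab2 <- suppressMessages(centile_table(fit, d))
  expect_identical(tibble::as_tibble(tab), tibble::as_tibble(tab2))
})

test_that("band classification follows the published boundary conventions", {
  # published age row 3-3.99: P5 8.7, P15 9.2, P85 11.2, P95 11.8
  expect_equal(
    as.character(classify_band(11.5, 8.7, 9.2, 11.2, 11.8)),
    "high_normal"
  )
  expect_equal(
    as.character(classify_band(12.0, 8.7, 9.2, 11.2, 11.8)),
    "abnormal_high"
  )
  expect_equal(as.character(classify_band(10.2, 8.7, 9.2, 11.2, 11.8)), "normal")
  # boundaries: P5 and P85 belong to the band below/at, P15 to normal
  expect_equal(as.character(classify_band(8.7, 8.7, 9.2, 11.2, 11.8)), "low_normal")
  expect_equal(as.character(classify_band(9.2, 8.7, 9.2, 11.2, 11.8)), "normal")
  expect_equal(as.character(classify_band(11.2, 8.7, 9.2, 11.2, 11.8)), "normal")
  expect_equal(as.character(classify_band(11.8, 8.7, 9.2, 11.2, 11.8)), "high_normal")
  expect_equal(as.character(classify_band(8.0, 8.7, 9.2, 11.2, 11.8)), "abnormal_low")
  expect_error(classify_band(10, 9, 8, 11, 12), "non-monotone")
})

test_that("height-based references are preferred, with fallback and warning", {
  fit <- small_constant_fit()
  d <- constant_truth_data()
  age_tab <- suppressMessages(centile_table(fit, d, min_n = 50))
  # a fake height table over 50-180 built from the same fit via custom bins
  hbins <- tibble::tibble(
    bin = c("100-109", "110-119"), lo = c(100, 110), hi = c(110, 120),
    midpoint = c(105, 115), n = c(500, 500)
  )
  hfit <- fit
  hfit$covariate <- "height_cm" # same smooth, relabeled covariate
  hfit$range <- c(50, 180)
  hfit$range_t <- hfit$range_t # transform untouched (power of age)
  # build the height table through the public API with explicit bins
  h_tab <- suppressMessages(
    centile_table(small_constant_fit(), bins = dplyr::mutate(hbins, midpoint = c(10, 12)))
  )
  h_tab$lo <- hbins$lo
  h_tab$hi <- hbins$hi
  attr(h_tab, "raw")$lo <- hbins$lo
  attr(h_tab, "raw")$hi <- hbins$hi

  both <- choose_reference(
    age = 12, height = 105,
    age_table = age_tab, height_table = h_tab
  )
  expect_equal(both$reference, "height")
  only_age <- choose_reference(age = 12, height = NA, age_table = age_tab)
  expect_equal(only_age$reference, "age")
  expect_warning(
    fb <- choose_reference(
      age = 15, height = 185,
      age_table = age_tab, height_table = h_tab
    ),
    "not covered"
  )
  expect_equal(fb$reference, "age")
  suppressWarnings(expect_error(
    choose_reference(age = NA, height = 30, height_table = h_tab),
    "no applicable reference"
  ))
})

test_that("classification uses unrounded centiles (rounding is display-only)", {
  fit <- small_constant_fit()
  d <- constant_truth_data()
  tab <- suppressMessages(centile_table(fit, d))
  raw <- attr(tab, "raw")
  i <- 3
  # a measurement between the raw and the rounded P95 must be classified
  # against the raw value
  raw_p95 <- raw$P95[i]
  disp_p95 <- tab$P95[i]
  if (abs(raw_p95 - disp_p95) > 1e-6) {
    y <- (raw_p95 + disp_p95) / 2
    want <- if (y <= raw_p95) "high_normal" else "abnormal_high"
    got <- classify_band(y, raw$P5[i], raw$P15[i], raw$P85[i], raw$P95[i])
    expect_equal(as.character(got), want)
  }
  # end-to-end classification over a measurements frame
  meas <- tibble::tibble(
    liver_length_cm = c(9, 10, 13),
    age_years = c(4, 8, 12)
  )
  cl <- classify_measurements(meas, age_table = tab)
  expect_equal(nrow(cl), 3)
  expect_true(all(cl$reference == "age"))
  expect_s3_class(cl$band, "factor")
})

test_that("tables serialize to CSV and JSON", {
  fit <- small_constant_fit()
  tab <- suppressMessages(centile_table(fit, constant_truth_data()))
  fc <- tempfile(fileext = ".csv")
  fj <- tempfile(fileext = ".json")
  write_centile_table(tab, fc)
  write_centile_table(tab, fj)
  back <- readr::read_csv(fc, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(tab))
  doc <- jsonlite::read_json(fj)
  expect_equal(doc$min_n, 100)
  expect_equal(length(doc$rows), nrow(tab))
})
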