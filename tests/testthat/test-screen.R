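# Two-step outlier screening: hard bounds, MAD-z, Tukey fences, review rule

test_that("hard bounds keep exactly the 3-25 cm range, inclusive", {
  recs <- tibble::tibble(
    exam_id = sprintf("E%d", 1:6),
    liver_length_cm = c(2.9, 3.0, 10.0, 25.0, 25.1, 24.999)
  )
  hb <- hard_bounds_filter(recs)
  expect_setequal(hb$excluded_ids, c("E1", "E5"))
  expect_setequal(hb$kept$exam_id, c("E2", "E3", "E4", "E6"))
})

test_that("screening bins follow the published stratification", {
  expect_equal(assign_screen_bin(0.3, "age"), "0.25-0.49")
  expect_equal(assign_screen_bin(1.6, "age"), "1.5-1.99")
  expect_equal(assign_screen_bin(0, "age"), "0-0.24")
  expect_equal(assign_screen_bin(17.99, "age"), "17-17.99")
  expect_equal(assign_screen_bin(95, "height"), "90-99")
  expect_equal(assign_screen_bin(50, "height"), "50-59")
  expect_error(assign_screen_bin(18, "age"), "out of modeled range")
  expect_error(assign_screen_bin(NaN, "age"), "out of modeled range")
})

test_that("MAD z-scores match the robust definition", {
  # stratum {1..7, 10}: median 4.5, MAD 2 -> z(10) = 5.5 / (1.4826 * 2)
  z <- mad_z(c(1:7, 10))
  expect_equal(z[8], (10 - 4.5) / (1.4826 * 2), tolerance = 1e-6)
  expect_equal(round(z[8], 4), 1.8548)
  # scored against the {1..7} reference statistics (median 4, MAD 2) the
  # value 10 standardizes to 2.0234 - still below the moderate threshold
  expect_equal((10 - 4) / (1.4826 * 2), 2.0234, tolerance = 1e-4)
  # no flag at that score
  expect_true(is.na(mad_severity(z[8])))
  # identical values: MAD = 0, rule abstains
  expect_true(all(is.na(mad_z(rep(5, 10)))))
  # centering: median element scores 0 on symmetric data
  expect_equal(mad_z(1:9)[5], 0)
  expect_error(mad_z(numeric(0)), "empty stratum")
})

test_that("MAD-z is monotone for values above the median", {
  set.seed(9)
  base <- rnorm(30, 10, 1)
  base[30] <- 13 # above the median
  for (i in 1:20) {
    bumped <- base
    bumped[30] <- base[30] + runif(1, 0, 5)
    # other values fixed: score of the bumped value cannot decrease
    expect_gte(mad_z(bumped)[30], mad_z(base)[30] - 1e-12)
  }
})

test_that("Tukey fences use type-7 quartiles with strict inequalities", {
  # quartiles of 1..100: Q1 = 25.75, Q3 = 75.25, IQR = 49.5,
  # extreme fence = Q3 + 3 * IQR = 223.75, so 300 is extreme
  expect_equal(
    unname(quantile(1:100, c(.25, .75), type = 7)),
    c(25.75, 75.25)
  )
  tk <- tukey_severity(c(1:100, 300))
  expect_equal(tk$severity[101], "extreme")
  expect_true(all(is.na(tk$severity[1:100])))
  # a value exactly at the 1.5 fence is not flagged (strict)
  x <- c(1, 2, 3, 4)
  q <- quantile(x, c(.25, .75), type = 7)
  at_fence <- unname(q[2] + 1.5 * (q[2] - q[1]))
  tk2 <- tukey_severity(c(x, at_fence))
  expect_true(is.na(tk2$severity[5]))
  # degenerate spread or tiny stratum: abstain
  expect_true(all(is.na(tukey_severity(rep(7, 8))$severity)))
  expect_true(all(is.na(tukey_severity(c(1, 2, 100))$severity)))
})

test_that("flags equal a brute-force oracle on random strata", {
  brute <- function(x) {
    med <- median(x)
    mad0 <- median(abs(x - med))
    mz <- if (length(x) >= 2 && mad0 > 0) (x - med) / (1.4826 * mad0) else rep(NA_real_, length(x))
    msev <- ifelse(is.na(mz), NA,
      ifelse(abs(mz) >= 3.5, "extreme", ifelse(abs(mz) >= 3, "moderate", NA))
    )
    q1 <- quantile(x, 0.25, type = 7)
    q3 <- quantile(x, 0.75, type = 7)
    iqr <- q3 - q1
    tsev <- rep(NA_character_, length(x))
    if (length(x) >= 4 && iqr > 0) {
      lo_m <- q1 - 1.5 * iqr
      hi_m <- q3 + 1.5 * iqr
      lo_e <- q1 - 3 * iqr
      hi_e <- q3 + 3 * iqr
      tsev[(x < lo_m & x >= lo_e) | (x > hi_m & x <= hi_e)] <- "moderate"
      tsev[x < lo_e | x > hi_e] <- "extreme"
    }
    list(m = msev, t = tsev)
  }
  set.seed(55)
  for (i in 1:60) {
    n <- sample(2:50, 1)
    x <- round(rbcpe(n, 10, 0.15, 0.5, 2), 1)
    if (runif(1) < 0.3) x[sample(n, 1)] <- runif(1, 3, 25) # shove in a wild value
    o <- brute(x)
    expect_identical(mad_severity(mad_z(x)), as.character(o$m))
    expect_identical(tukey_severity(x)$severity, as.character(o$t))
  }
})

test_that("false-positive rate of |z_r| >= 3.5 on normal data is tiny", {
  set.seed(3)
  x <- rnorm(10000)
  expect_lt(mean(abs(mad_z(x)) >= 3.5), 0.001)
})

test_that("review triggers on one extreme or two moderate flags", {
  # stratum of 60 near-identical values, one record pushed to a moderate
  # score in BOTH rules under the age stratification, moderate under height
  set.seed(8)
  base <- tibble::tibble(
    exam_id = sprintf("E%03d", 1:61),
    patient_id = sprintf("P%03d", 1:61),
    age_years = runif(61, 3, 3.9),
    height_cm = runif(61, 95, 99),
    liver_length_cm = c(rnorm(60, 10, 0.3), 11.6)
  )
  sc <- screen_outliers(base)
  fl <- sc$flags[sc$flags$exam_id == "E061", ]
  expect_gte(nrow(fl), 2)
  expect_true("E061" %in% sc$review$exam_id)
  # review records are retained by default, dropped on request
  expect_true("E061" %in% sc$retained$exam_id)
  sc2 <- screen_outliers(base, drop_review = TRUE)
  expect_false("E061" %in% sc2$retained$exam_id)
  # a single moderate flag must NOT trigger review
  one_mod <- sc$flags |>
    dplyr::group_by(exam_id) |>
    dplyr::summarise(
      n_ext = sum(severity == "extreme"),
      n_mod = sum(severity == "moderate")
    ) |>
    dplyr::filter(n_ext == 0, n_mod == 1)
  expect_true(!any(one_mod$exam_id %in% sc$review$exam_id))
})

test_that("records without height get only age-stratified flags", {
  set.seed(14)
  recs <- tibble::tibble(
    exam_id = sprintf("E%03d", 1:41),
    age_years = runif(41, 5, 5.9),
    height_cm = NA_real_,
    liver_length_cm = c(rnorm(40, 11, 0.4), 20)
  )
  sc <- screen_outliers(recs)
  expect_true(all(sc$flags$stratification == "age"))
  # an extreme age-only flag still reaches review
  expect_true("E041" %in% sc$review$exam_id)
})
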