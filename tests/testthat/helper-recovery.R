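# Full-pipeline recovery experiment, shared by the acceptance tests.
# One cohort of n = 20,000 per covariate at a fixed seed, pushed through
# CSV ingest, height matching, exclusions, screening and the default fit.
recovery_run <- function(covariate, seed) {
  key <- paste0("recovery_", covariate, "_", seed)
  memo(key, {
    anchors <- liver_anchors(covariate)
    truth <- build_truth(anchors, tau = 2, covariate = covariate)
    cohort <- simulate_cohort(truth, 20000, seed = seed)
    dir <- file.path(tempdir(), paste0("recovery-", covariate, "-", seed))
    write_cohort(cohort, dir)
    exams <- suppressMessages(read_exams(file.path(dir, "exams.csv")))
    exams <- match_heights(
      exams,
      suppressMessages(read_heights(file.path(dir, "heights.csv")))
    )
    exams <- suppressMessages(
      apply_exclusions(exams, cohort$excluded_code_prefixes)
    )
    screen <- screen_outliers(exams)
    data <- screen$retained
    if (covariate == "height_cm") {
      data <- data[!is.na(data$height_cm), , drop = FALSE]
    }
    fit <- fit_centiles(data, covariate = covariate)
    list(
      anchors = anchors, truth = truth, cohort = cohort,
      screen = screen, data = data, fit = fit
    )
  })
}

age_recovery <- function() recovery_run("age_years", seed = 1)
height_recovery <- function() recovery_run("height_cm", seed = 1)
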