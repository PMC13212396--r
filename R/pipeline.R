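#' Run the full reference-range pipeline
#'
#' Executes ingest, exclusion, outlier screening, model fitting, residual
#' diagnostics and table generation in one reproducible call, writing the
#' standard outputs (tables CSV/JSON, model JSON, diagnostics JSON, review
#' CSV, run manifest). All results are computed before anything is written,
#' so a failing stage leaves no partial output.
#'
#' @param exams_file Path to the exams CSV ([read_exams()] format).
#' @param output_dir Directory for outputs (created if needed).
#' @param heights_file Optional heights CSV; required when
#'   `covariate = "height_cm"`.
#' @param exclusion_file Optional plain-text ICD-10 prefix list.
#' @param covariate Modeling covariate.
#' @param sex_stratified Also fit per-sex models and tables.
#' @param drop_review Drop review-flagged records from the modeling set.
#' @param min_n,min_n_sex Reporting count floors (overall / per sex).
#' @param seed Integer seed recorded in the manifest and applied before
#'   fitting (the fit is deterministic; the seed guards any downstream
#'   stochastic additions).
#' @param ... Passed to [fit_centiles()] (e.g. `n_knots`, `lambda`).
#' @return Invisibly, a list with `screen`, `fits`, `tables`,
#'   `diagnostics`, and `manifest`.
#' @export
run_pipeline <- function(exams_file, output_dir,
                         heights_file = NULL,
                         exclusion_file = NULL,
                         covariate = c("age_years", "height_cm"),
                         sex_stratified = FALSE,
                         drop_review = FALSE,
                         min_n = 100, min_n_sex = 50,
                         seed = NULL,
                         ...) {
  covariate <- match.arg(covariate)
  if (!file.exists(exams_file)) stop("exams file not found: ", exams_file)
  if (covariate == "height_cm" && is.null(heights_file)) {
    stop("`heights_file` is required for the height-based model")
  }
  if (!is.null(heights_file) && !file.exists(heights_file)) {
    stop("heights file not found: ", heights_file)
  }
  if (!is.null(exclusion_file) && !file.exists(exclusion_file)) {
    stop("exclusion file not found: ", exclusion_file)
  }
  if (!is.null(seed)) set.seed(seed)

  exams <- read_exams(exams_file)
  if (!is.null(heights_file)) {
    exams <- match_heights(exams, read_heights(heights_file))
  }
  prefixes <- if (is.null(exclusion_file)) {
    character(0)
  } else {
    read_exclusion_list(exclusion_file)
  }
  exams <- apply_exclusions(exams, prefixes)

  screen <- screen_outliers(exams, drop_review = drop_review)
  model_data <- screen$retained
  if (covariate == "height_cm") {
    model_data <- dplyr::filter(model_data, !is.na(.data$height_cm))
  }

  strata <- list(all = model_data)
  if (sex_stratified) {
    strata$male <- dplyr::filter(model_data, .data$sex == "male")
    strata$female <- dplyr::filter(model_data, .data$sex == "female")
  }
  fits <- list()
  tables <- list()
  diagnostics <- list()
  for (nm in names(strata)) {
    d <- strata[[nm]]
    fits[[nm]] <- fit_centiles(d, covariate = covariate, ...)
    tables[[nm]] <- centile_table(
      fits[[nm]], d,
      sex_stratum = nm,
      min_n = if (nm == "all") min_n else min_n_sex
    )
    diagnostics[[nm]] <- residual_diagnostics(fits[[nm]], d)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hepanorm")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = list(
      exams_file = exams_file, heights_file = heights_file,
      exclusion_file = exclusion_file, covariate = covariate,
      sex_stratified = sex_stratified, drop_review = drop_review,
      min_n = min_n, min_n_sex = min_n_sex,
      fit_options = list(...)
    ),
    input_md5 = as.list(tools::md5sum(stats::na.omit(c(
      exams_file, heights_file, exclusion_file
    )))),
    n_exams_ingested = nrow(exams),
    n_retained = nrow(screen$retained),
    n_hard_excluded = nrow(screen$hard_excluded),
    n_review = length(unique(screen$review$exam_id)),
    n_model = vapply(strata, nrow, numeric(1))
  )

  # all computed: write outputs
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(strata)) {
    suffix <- if (nm == "all") "" else paste0("_", nm)
    write_centile_table(
      tables[[nm]],
      file.path(output_dir, paste0("centile_table", suffix, ".csv"))
    )
    write_centile_table(
      tables[[nm]],
      file.path(output_dir, paste0("centile_table", suffix, ".json"))
    )
    write_centile_model(
      fits[[nm]],
      file.path(output_dir, paste0("model", suffix, ".json"))
    )
    write_diagnostics_json(
      diagnostics[[nm]],
      file.path(output_dir, paste0("diagnostics", suffix, ".json"))
    )
  }
  write_review_csv(screen, exams, file.path(output_dir, "review.csv"))
  jsonlite::write_json(
    manifest,
    file.path(output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = 10
  )

  invisible(list(
    screen = screen, fits = fits, tables = tables,
    diagnostics = diagnostics, manifest = manifest
  ))
}
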