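# Shared fixtures, computed once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a small cohort drawn from a constant BCPE law: fast fits in unit tests
constant_truth_data <- function(n = 2000, seed = 301,
                                mu = 10, sigma = 0.1, nu = 1, tau = 2) {
  set.seed(seed)
  tibble::tibble(
    age_years = runif(n, 0, 18),
    liver_length_cm = rbcpe(n, mu, sigma, nu, tau)
  )
}

# quick fixed-lambda fit on constant-truth data
small_constant_fit <- function() {
  memo("small_constant_fit", {
    fit_centiles(
      constant_truth_data(),
      covariate = "age_years",
      n_knots = 8, lambda = c(10, 10, 10)
    )
  })
}

# small synthetic cohort written to disk and read back through ingest
small_cohort_files <- function() {
  memo("small_cohort_files", {
    tr <- build_truth(liver_anchors("age_years"), covariate = "age_years")
    coh <- simulate_cohort(tr, 1500, seed = 77)
    dir <- file.path(tempdir(), "hepanorm-small-cohort")
    write_cohort(coh, dir)
    list(dir = dir, cohort = coh, truth = tr)
  })
}

# a smooth BCPE truth (no interpolation corners): gentle logistic-style
# growth in mu, slowly varying sigma and nu
smooth_truth_params <- function(x) {
  tibble::tibble(
    x = x,
    mu = 6 + 9 * (x / 18)^0.7,
    sigma = 0.14 - 0.003 * x,
    nu = 0.5 + 0.05 * x,
    tau = 2
  )
}

smooth_truth_data <- function(n = 20000, seed = 91) {
  set.seed(seed)
  x <- runif(n, 0, 18)
  p <- smooth_truth_params(x)
  tibble::tibble(
    age_years = x,
    liver_length_cm = rbcpe(n, p$mu, p$sigma, p$nu, p$tau)
  )
}
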