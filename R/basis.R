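#' Penalized B-spline (P-spline) basis
#'
#' Builds a B-spline design matrix on `n_knots` equal-width segments
#' spanning `range`, with the knot sequence extended `degree` knots beyond
#' each boundary so that the basis forms a partition of unity (rows sum to
#' one) on the whole range. The basis dimension is `n_knots + degree`.
#' Values outside `range` are refused: the fitted centile curves are never
#' extrapolated.
#'
#' @param x Covariate values within `range`.
#' @param range Numeric length-2 vector, the covariate range the basis spans.
#' @param n_knots Number of equal-width segments between the boundary knots.
#' @param degree Spline degree (3 = cubic).
#' @return The design matrix with attributes `knots`, `degree`, `range`.
#' @export
#' @examples
#' B <- pspline_basis(seq(0, 18, by = 3), c(0, 18), n_knots = 10)
#' rowSums(B) # all 1
pspline_basis <- function(x, range, n_knots = 12, degree = 3) {
  stopifnot(length(range) == 2, range[2] > range[1], n_knots >= 1, degree >= 1)
  if (any(!is.finite(x))) stop("covariate out of modeled range: non-finite value")
  eps <- 1e-8 * diff(range)
  if (any(x < range[1] - eps | x > range[2] + eps)) {
    stop("covariate outside the training range: extrapolation refused")
  }
  x <- pmin(pmax(x, range[1]), range[2])
  h <- diff(range) / n_knots
  knots <- range[1] + ((-degree):(n_knots + degree)) * h
  # pin the boundary knots so x at the range limits is always admissible
  knots[degree + 1] <- range[1]
  knots[degree + 1 + n_knots] <- range[2]
  B <- splines::splineDesign(knots, x, ord = degree + 1, outer.ok = FALSE)
  attr(B, "knots") <- knots
  attr(B, "degree") <- degree
  attr(B, "range") <- range
  B
}

# difference penalty matrix t(D) %*% D for a basis of dimension k
penalty_matrix <- function(k, order = 2) {
  stopifnot(k >= order + 1)
  D <- diff(diag(k), differences = order)
  crossprod(D)
}

# covariate transforms: spline smoothing is done on the transformed scale
apply_transform <- function(x, transform) {
  switch(transform$type,
    identity = x,
    power = x^transform$exponent,
    log = log(x + transform$offset),
    stop("unknown transform type: ", transform$type)
  )
}

default_transform <- function(covariate) {
  if (covariate == "age_years") {
    list(type = "power", exponent = 0.4)
  } else {
    list(type = "identity")
  }
}
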