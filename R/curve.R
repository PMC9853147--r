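#' Construct a reference curve
#'
#' @param ages strictly increasing age grid in months.
#' @param mu median D-score at each age (strictly increasing).
#' @param sigma SD of the D-score at each age (positive); recycled if scalar.
#' @return A [ReferenceCurve-class].
#' @export
ReferenceCurve <- function(ages, mu, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, length(ages))
  new("ReferenceCurve", ages = as.numeric(ages), mu = as.numeric(mu),
      sigma = as.numeric(sigma))
}

#' Default synthetic reference curve
#'
#' Median ability grows as `mu(a) = 20 * log2(a + 1) + 10` D-score units with
#' constant spread `sigma(a) = 5`: a monotone, concave trajectory resembling
#' early development (fast gains in infancy, slowing towards 36 months) that is
#' analytically invertible, which keeps closed-form checks of pass-age
#' quantiles possible.
#'
#' @param ages age grid in months (default 0 to 36 by 0.25).
#' @param sigma constant SD in D-score units (default 5).
#' @return A [ReferenceCurve-class].
#' @export
defaultReferenceCurve <- function(ages = seq(0, 36, by = 0.25), sigma = 5) {
  ReferenceCurve(ages, 20 * log2(ages + 1) + 10, sigma)
}

#' Evaluate a reference curve
#'
#' `curveMedian()` / `curveSD()` interpolate the median and SD of ability at
#' arbitrary ages within the grid span (linear interpolation); `ageSpan()`
#' returns the covered age interval in months.
#'
#' @param curve A `ReferenceCurve`.
#' @param age numeric vector of ages in months; must lie within `ageSpan(curve)`.
#' @name ReferenceCurve-eval
NULL

checkAges <- function(curve, age) {
  rng <- range(curve@ages)
  bad <- age < rng[1] - 1e-9 | age > rng[2] + 1e-9
  if (any(bad)) {
    stop(sprintf(
      "age(s) outside the reference curve span [%g, %g]: %s",
      rng[1], rng[2], paste(format(age[bad][seq_len(min(3, sum(bad)))]), collapse = ", ")
    ), call. = FALSE)
  }
}

#' @rdname ReferenceCurve-eval
#' @export
setMethod("curveMedian", "ReferenceCurve", function(curve, age) {
  checkAges(curve, age)
  approx(curve@ages, curve@mu, xout = age, rule = 2)$y
})

#' @rdname ReferenceCurve-eval
#' @export
setMethod("curveSD", "ReferenceCurve", function(curve, age) {
  checkAges(curve, age)
  approx(curve@ages, curve@sigma, xout = age, rule = 2)$y
})

#' @rdname ReferenceCurve-eval
#' @export
setMethod("ageSpan", "ReferenceCurve", function(curve) range(curve@ages))

setMethod("show", "ReferenceCurve", function(object) {
  cat(sprintf(
    "ReferenceCurve over [%g, %g] months: mu in [%.2f, %.2f], sigma in [%.2f, %.2f]\n",
    min(object@ages), max(object@ages), min(object@mu), max(object@mu),
    min(object@sigma), max(object@sigma)
  ))
  invisible(object)
})

# Invert the median curve: age at which the median child has ability d.
# Returns NA outside the curve's ability range.
invertCurveMedian <- function(curve, d) {
  out <- approx(curve@mu, curve@ages, xout = d, rule = 1)$y
  out
}

#' Read / write a reference curve as JSON
#'
#' @param curve A `ReferenceCurve`.
#' @param path file path.
#' @return `readReferenceCurve()` returns a `ReferenceCurve`;
#'   `writeReferenceCurve()` returns `path` invisibly.
#' @export
writeReferenceCurve <- function(curve, path) {
  obj <- list(
    ages = curve@ages, mu = curve@mu, sigma = curve@sigma,
    units = "months / D-score"
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeReferenceCurve
#' @export
readReferenceCurve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ReferenceCurve(obj$ages, obj$mu, obj$sigma)
}
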