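#' The three classical growth-law families
#'
#' Growth of indeterminate growers is commonly described by one of three
#' two-parameter laws relating instantaneous growth rate (GR, mm/day) to
#' current body length `L` (snout--vent length, mm):
#'
#' * Von Bertalanffy: `GR = A1 * r * (1 - L / A1)` -- growth rate declines
#'   linearly with length, so the smallest animals grow fastest.
#' * logistic-by-length: `GR = L * r * (1 - L / A1)` -- sigmoid growth with
#'   maximum rate at `A1 / 2`.
#' * logistic-by-weight: `GR = (r * L / 3) * (1 - L^3 / A1^3)` -- the
#'   logistic law expressed on the weight (length-cubed) scale but fitted to
#'   length; maximum rate at `A1 * 4^(-1/3)`.
#'
#' `A1` is the asymptotic length (mm) and `r` the characteristic growth
#' parameter (per day).
#'
#' @return Character vector of the three family names.
#' @export
growth_families <- function() {
  c("von_bertalanffy", "logistic_by_length", "logistic_by_weight")
}

match_family <- function(family) {
  match.arg(family, growth_families())
}

#' Instantaneous growth rate as a function of body length
#'
#' Evaluates the differential form of a growth-law family: the expected
#' growth rate (mm/day) of an animal of length `length` mm.
#'
#' @param family One of [growth_families()].
#' @param length Body length(s), mm; must be non-negative.
#' @param A1 Asymptotic length, mm (> 0).
#' @param r Characteristic growth parameter, per day (> 0).
#' @return Numeric vector of growth rates, mm/day. Zero at `length = A1`
#'   for every family.
#' @examples
#' gr_rate("von_bertalanffy", 37.455, A1 = 52.81, r = 0.0017)
#' @export
gr_rate <- function(family, length, A1, r) {
  family <- match_family(family)
  if (any(length < 0)) abort("`length` must be non-negative.")
  if (A1 <= 0 || r <= 0) abort("`A1` and `r` must be positive.")
  switch(family,
    von_bertalanffy    = A1 * r * (1 - length / A1),
    logistic_by_length = length * r * (1 - length / A1),
    logistic_by_weight = (r * length / 3) * (1 - length^3 / A1^3)
  )
}

#' Shape constant anchoring a growth curve at hatchling size
#'
#' Each family's integrated solution carries a dimensionless constant `b`
#' chosen so that the curve passes through the hatchling length `L0` at age
#' zero: `1 - L0/A1` (Von Bertalanffy), `A1/L0 - 1` (logistic-by-length) and
#' `A1^3/L0^3 - 1` (logistic-by-weight).
#'
#' @inheritParams gr_rate
#' @param L0 Hatchling length, mm, with `0 < L0 <= A1`.
#' @return The shape constant `b` (0 when `L0 == A1`).
#' @export
b_param <- function(family, A1, L0) {
  family <- match_family(family)
  if (L0 <= 0) abort("`L0` must be positive.")
  if (L0 > A1) abort("Hatchling length `L0` cannot exceed the asymptote `A1`.")
  switch(family,
    von_bertalanffy    = 1 - L0 / A1,
    logistic_by_length = A1 / L0 - 1,
    logistic_by_weight = A1^3 / L0^3 - 1
  )
}

#' Construct an integrated growth curve
#'
#' Combines a family and its parameters with a hatchling length `L0` into a
#' length-at-age curve. The integrated solutions are
#' `L(t) = A1 (1 - b e^{-rt})` (Von Bertalanffy),
#' `L(t) = A1 / (1 + b e^{-rt})` (logistic-by-length) and
#' `L(t) = (A1^3 / (1 + b e^{-rt}))^{1/3}` (logistic-by-weight),
#' with `b = b_param(family, A1, L0)` so that `L(0) = L0` exactly.
#'
#' @inheritParams b_param
#' @param L0 Hatchling length, mm, with `0 < L0 < A1`.
#' @return An object of class `growth_curve`.
#' @seealso [length_at_age()], [time_to_length()], [build_growth_curve()]
#' @export
growth_curve <- function(family, A1, r, L0) {
  family <- match_family(family)
  if (A1 <= 0 || r <= 0) abort("`A1` and `r` must be positive.")
  if (L0 <= 0 || L0 >= A1) {
    abort("`L0` must satisfy 0 < L0 < A1 for an integrable growth curve.")
  }
  structure(
    list(family = family, A1 = A1, r = r, L0 = L0,
         b = b_param(family, A1, L0)),
    class = "growth_curve"
  )
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf(
    "<growth_curve: %s>\n  A1 = %.3f mm, r = %.5f /day, L0 = %.2f mm, b = %.5f\n",
    x$family, x$A1, x$r, x$L0, x$b
  ))
  invisible(x)
}

#' Length at age along a growth curve
#'
#' Closed-form evaluation of the integrated growth law; `t` is age in days
#' post-hatching.
#'
#' @param curve A [growth_curve()].
#' @param t Age(s), days; non-negative.
#' @return Length(s), mm. `length_at_age(curve, 0)` equals `L0` exactly and
#'   the curve increases monotonically towards `A1`.
#' @export
length_at_age <- function(curve, t) {
  stopifnot(inherits(curve, "growth_curve"))
  if (any(t < 0)) abort("Age `t` must be non-negative.")
  e <- curve$b * exp(-curve$r * t)
  switch(curve$family,
    von_bertalanffy    = curve$A1 * (1 - e),
    logistic_by_length = curve$A1 / (1 + e),
    logistic_by_weight = (curve$A1^3 / (1 + e))^(1 / 3)
  )
}

#' Age at which a growth curve reaches a target length
#'
#' Closed-form inversion of [length_at_age()]. The target must lie in
#' `[L0, A1)`: lengths at or above the asymptote are never reached.
#'
#' @param curve A [growth_curve()].
#' @param length Target length, mm.
#' @return Age in days (0 for `length = L0`).
#' @export
time_to_length <- function(curve, length) {
  stopifnot(inherits(curve, "growth_curve"))
  # tolerate round-trip floating-point error: length_at_age(curve, 0) can
  # land a hair below L0 (cube root in the weight family)
  eps <- 1e-8 * curve$A1
  if (any(length < curve$L0 - eps)) {
    abort("Target length below hatchling length `L0`.")
  }
  length <- pmax(length, curve$L0)
  if (any(length >= curve$A1)) {
    abort("Target length at or above the asymptote `A1` is unreachable.")
  }
  q <- switch(curve$family,
    von_bertalanffy    = (1 - length / curve$A1),
    logistic_by_length = (curve$A1 / length - 1),
    logistic_by_weight = (curve$A1^3 / length^3 - 1)
  )
  -log(q / curve$b) / curve$r
}

#' Length of maximum growth rate
#'
#' The length at which the differential growth law peaks: interior for the
#' two logistic families (`A1/2` and `A1 * 4^(-1/3)`), but at the lower
#' boundary for Von Bertalanffy, whose rate decreases monotonically with
#' length -- for that family `NA` is returned and the maximum observable
#' rate occurs at the smallest length.
#'
#' @inheritParams gr_rate
#' @return Length in mm, or `NA_real_` for Von Bertalanffy.
#' @export
inflection_length <- function(family, A1) {
  family <- match_family(family)
  if (A1 <= 0) abort("`A1` must be positive.")
  switch(family,
    von_bertalanffy    = NA_real_,
    logistic_by_length = A1 / 2,
    logistic_by_weight = A1 * 4^(-1 / 3)
  )
}

#' Tabulate a growth curve for export or plotting
#'
#' @param curve A [growth_curve()].
#' @param t Ages (days) at which to evaluate the curve.
#' @return A tibble with columns `t_days` and `svl_mm`.
#' @export
curve_table <- function(curve, t = seq(0, 5 / curve$r, length.out = 200)) {
  tibble::tibble(t_days = t, svl_mm = length_at_age(curve, t))
}

#' @exportS3Method ggplot2::autoplot
autoplot.growth_curve <- function(object, t = NULL, ...) {
  tab <- if (is.null(t)) curve_table(object) else curve_table(object, t)
  ggplot2::ggplot(tab, ggplot2::aes(.data$t_days, .data$svl_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$A1, linetype = "dashed") +
    ggplot2::labs(
      x = "Age (days post-hatching)", y = "SVL (mm)",
      title = sprintf("%s growth curve", object$family),
      subtitle = sprintf("A1 = %.1f mm, r = %.4f /day, L0 = %.1f mm",
                         object$A1, object$r, object$L0)
    )
}
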