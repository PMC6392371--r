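#' Fit a growth-law family to growth-rate data
#'
#' Nonlinear least squares of the differential growth law on per-individual
#' growth intervals: parameters `(A1, r)` minimise
#' `sum((gr_i - gr_rate(family, l_ref_i, A1, r))^2)` over the intervals.
#' Fitting uses Levenberg--Marquardt ([minpack.lm::nlsLM()]) started from the
#' exact linear least-squares back-transformation (each family is linear in
#' transformed coefficients: e.g. Von Bertalanffy rate is `r*A1 - r*L`),
#' falling back to `A1 = 1.1 * max(l_ref)`, `r = 0.005`/day when the linear
#' solution does not imply positive parameters.
#'
#' Goodness of fit is reported as the mean squared residual
#' `MSR = SSres / (n - 2)` (residual degrees of freedom) and
#' `R2 = 1 - SSres / SStot`, the criteria used for model selection by
#' [compare_models()].
#'
#' @param intervals Interval tibble with columns `l_ref_mm` and
#'   `gr_mm_per_day` (see [extract_intervals()]); at least 3 rows.
#' @param family One of [growth_families()].
#' @param start Optional named list/vector with `A1` and `r` starting values.
#' @return An object of class `growth_fit` with elements `family`, `A1`,
#'   `r`, `se_A1`, `se_r`, `n`, `msr`, `r2`, `converged`, `residuals`,
#'   `fitted` and `data`.
#' @export
fit_growth <- function(intervals, family, start = NULL) {
  family <- match_family(family)
  check_columns(intervals, c("l_ref_mm", "gr_mm_per_day"), "interval")
  df <- dplyr::filter(intervals,
                      is.finite(.data$l_ref_mm), is.finite(.data$gr_mm_per_day))
  if (nrow(df) < 3) abort("At least 3 finite growth intervals are required.")
  l <- df$l_ref_mm
  gr <- df$gr_mm_per_day
  if (diff(range(l)) < sqrt(.Machine$double.eps)) {
    abort("Non-identifiable data: all reference lengths are equal.")
  }
  if (var(gr) == 0) abort("R2 is undefined: observed rates have zero variance.")

  if (is.null(start)) start <- linear_start(family, l, gr)
  # Bound A1 to a biologically plausible multiple of the largest observed
  # length. Without it the Von Bertalanffy family is unidentifiable on
  # rate-length data with near-zero slope: r -> 0, A1 -> Inf with r*A1
  # constant, an endless ridge the optimizer would chase to the iteration
  # limit. At the bound the estimate reads "asymptote beyond the observable
  # range" and the MSR is still well-defined.
  lower <- c(A1 = 1e-6, r = 1e-12)
  upper <- c(A1 = 10 * max(l), r = 1)
  start <- pmin(pmax(unlist(start)[c("A1", "r")], lower * 2), upper / 2)
  fit <- minpack.lm::nlsLM(
    gr ~ gr_rate(family, l, A1, r),
    data = data.frame(l = l, gr = gr),
    start = as.list(start),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      maxiter = 1000, maxfev = 10000, ftol = 1e-10, ptol = 1e-12
    )
  )
  est <- coef(fit)
  sm <- summary(fit)
  res <- gr - gr_rate(family, l, est[["A1"]], est[["r"]])
  gd <- goodness(gr, gr - res, n_params = 2)
  converged <- isTRUE(fit$convInfo$isConv) ||
    is.null(fit$convInfo) # nlsLM always populates convInfo; be defensive
  if (!converged) {
    warn(sprintf("Fit of the %s model did not converge.", family))
  }
  structure(
    list(
      family = family,
      A1 = unname(est[["A1"]]), r = unname(est[["r"]]),
      se_A1 = unname(sm$coefficients["A1", "Std. Error"]),
      se_r = unname(sm$coefficients["r", "Std. Error"]),
      n = length(gr), msr = gd$msr, r2 = gd$r2,
      converged = converged,
      residuals = res, fitted = gr - res,
      data = tibble::tibble(l_ref_mm = l, gr_mm_per_day = gr)
    ),
    class = "growth_fit"
  )
}

# Exact linear least-squares back-transformation used as starting values:
#   VB: gr = r*A1 - r*L             (intercept + slope)
#   LL: gr = r*L - (r/A1)*L^2       (no intercept)
#   LW: gr = (r/3)*L - (r/(3*A1^3))*L^4
linear_start <- function(family, l, gr) {
  cand <- switch(family,
    von_bertalanffy = {
      b <- coef(lm(gr ~ l))
      c(A1 = -b[[1]] / b[[2]], r = -b[[2]])
    },
    logistic_by_length = {
      b <- coef(lm(gr ~ 0 + l + I(l^2)))
      c(A1 = -b[[1]] / b[[2]], r = b[[1]])
    },
    logistic_by_weight = {
      b <- coef(lm(gr ~ 0 + l + I(l^4)))
      c(A1 = (-b[[1]] / b[[2]])^(1 / 3), r = 3 * b[[1]])
    }
  )
  if (any(!is.finite(cand)) || any(cand <= 0) || cand[["A1"]] <= max(l)) {
    cand <- c(A1 = 1.1 * max(l), r = 0.005)
  }
  cand
}

#' Goodness-of-fit measures for rate predictions
#'
#' @param observed,predicted Equal-length numeric vectors of growth rates.
#' @param n_params Number of fitted parameters (2 for all families here).
#' @return A list with `msr = SSres / (n - n_params)` and
#'   `r2 = 1 - SSres / SStot` (total sum of squares about the observed mean).
#' @export
goodness <- function(observed, predicted, n_params = 2) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal length.")
  }
  n <- length(observed)
  if (n <= n_params) abort("Need more observations than parameters.")
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) abort("R2 is undefined: observed rates have zero variance.")
  ssres <- sum((observed - predicted)^2)
  list(msr = ssres / (n - n_params), r2 = 1 - ssres / sstot)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit: %s, n = %d>\n  A1 = %.3f +/- %.3f mm, r = %.5f +/- %.5f /day\n  MSR = %.5g, R2 = %.4f%s\n",
    x$family, x$n, x$A1, x$se_A1, x$r, x$se_r, x$msr, x$r2,
    if (x$converged) "" else "  [NOT CONVERGED]"
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A1", "r"),
    estimate = c(x$A1, x$r),
    std.error = c(x$se_A1, x$se_r)
  )
}

#' @exportS3Method generics::glance
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, msr = x$msr, r2 = x$r2, n = x$n,
    A1 = x$A1, se_A1 = x$se_A1, r = x$r, se_r = x$se_r,
    converged = x$converged
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.growth_fit <- function(object, ...) {
  grid <- tibble::tibble(
    l_ref_mm = seq(min(object$data$l_ref_mm), max(object$data$l_ref_mm),
                   length.out = 200)
  )
  grid$gr_mm_per_day <- gr_rate(object$family, grid$l_ref_mm,
                                object$A1, object$r)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$l_ref_mm, .data$gr_mm_per_day)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "Reference SVL (mm)", y = "Growth rate (mm/day)",
                  title = sprintf("%s fit (R2 = %.3f)", object$family,
                                  object$r2))
}

#' Fit all three growth-law families to the same intervals
#'
#' @inheritParams fit_growth
#' @return A named list of [fit_growth()] results, one per family.
#' @export
fit_all_models <- function(intervals) {
  fits <- purrr::map(setNames(growth_families(), growth_families()),
                     \(f) fit_growth(intervals, f))
  fits
}

#' Select the best-fitting growth law
#'
#' Selection follows the classical rule for these growth analyses: the
#' family with the lowest mean squared residual (MSR) wins; the coefficient
#' of determination is reported alongside, and when MSR and R2 rank
#' different families first the conflict is recorded (MSR decides). Exact
#' MSR ties break by higher R2, then by family order (Von Bertalanffy,
#' logistic-by-length, logistic-by-weight).
#'
#' @param fits Either a named list of `growth_fit` objects (one per family,
#'   fitted to identical intervals) or a data frame with columns `family`,
#'   `msr` and `r2` -- e.g. a published model-comparison table.
#' @return An object of class `model_comparison`: a list with the ranked
#'   `table`, the `selected` family and a `criterion_conflict` flag.
#' @export
compare_models <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- tibble::as_tibble(fits)
    check_columns(tab, c("family", "msr", "r2"), "model-comparison")
    if (!"converged" %in% names(tab)) tab$converged <- TRUE
  } else {
    stopifnot(all(purrr::map_lgl(fits, inherits, "growth_fit")))
    tab <- purrr::map(fits, glance) |> dplyr::bind_rows()
  }
  if (!all(tab$family %in% growth_families())) {
    abort("Unknown model family in comparison table.")
  }
  if (any(!tab$converged)) {
    warn("Model comparison includes unconverged fit(s).")
  }
  tab <- dplyr::mutate(
    tab,
    msr_rank = rank(.data$msr, ties.method = "min"),
    r2_rank = rank(-.data$r2, ties.method = "min")
  )
  tab <- tab[order(tab$msr, -tab$r2,
                   as.integer(factor(tab$family, levels = growth_families()))), ]
  selected <- tab$family[1]
  conflict <- tab$r2_rank[1] != 1L
  structure(
    list(table = tab, selected = selected, criterion_conflict = conflict),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> selected: %s%s\n", x$selected,
              if (x$criterion_conflict) " (MSR and R2 rankings disagree; MSR decides)" else ""))
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.model_comparison <- function(x, ...) x$table

#' Per-sex fit report in the layout of a growth-parameter summary table
#'
#' Fits all three families within each sex (pooling juveniles and adults,
#' as population-level growth analyses do) and selects a model per sex.
#'
#' @param intervals Interval tibble including a `sex` column.
#' @return A list with `report` (tibble: sex, family, msr, r2, A1, se_A1,
#'   r, se_r, n, selected) and `fits` (nested list by sex).
#' @export
fit_by_sex <- function(intervals) {
  check_columns(intervals, c("sex", interval_columns[6:10]), "interval")
  sexes <- sort(unique(intervals$sex))
  fits <- purrr::map(setNames(sexes, sexes), \(s) {
    fit_all_models(dplyr::filter(intervals, .data$sex == s))
  })
  report <- purrr::imap(fits, \(fl, s) {
    cmp <- compare_models(fl)
    purrr::map(fl, glance) |>
      dplyr::bind_rows() |>
      dplyr::mutate(sex = s, selected = .data$family == cmp$selected,
                    .before = 1)
  }) |> dplyr::bind_rows()
  list(report = report, fits = fits)
}
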