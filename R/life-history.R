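#' Growth curve from a fitted model and hatchling size
#'
#' Anchors the integrated solution of a fitted growth law at the average
#' hatchling SVL `L0`, yielding a length-at-age curve from which ages at any
#' size (e.g. sexual maturity) can be read off.
#'
#' @param fit A converged [fit_growth()] result.
#' @param L0 Hatchling SVL, mm; must lie below the fitted asymptote.
#' @return A [growth_curve()].
#' @export
build_growth_curve <- function(fit, L0) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!fit$converged) abort("Cannot build a curve from an unconverged fit.")
  if (L0 >= fit$A1) abort("`L0` must be below the fitted asymptote `A1`.")
  growth_curve(fit$family, fit$A1, fit$r, L0)
}

#' Age at sexual maturity from a growth curve
#'
#' Inverts the growth curve at the sex-specific SVL at which animals become
#' sexually mature (here 35 mm for males and 37 mm for females by default
#' elsewhere in the pipeline). Reported in days post-hatching and in months
#' (30-day months).
#'
#' @param curve A [growth_curve()].
#' @param svl_at_maturity Maturity threshold SVL, mm, within `(L0, A1)`.
#' @return One-row tibble: `maturity_svl_mm`, `age_days`, `age_months`.
#' @export
age_at_maturity <- function(curve, svl_at_maturity) {
  days <- time_to_length(curve, svl_at_maturity)
  tibble::tibble(
    maturity_svl_mm = svl_at_maturity,
    age_days = days,
    age_months = days / 30
  )
}

#' Group means and standard errors of growth rate
#'
#' Per-cell sample size, mean and standard error (sd / sqrt(n)) of the
#' growth rate, grouped by any subset of the interval factors (typically
#' sex, age class, season and year). Empty cells are omitted; singleton
#' cells report `NA` standard error.
#'
#' @param intervals Interval tibble (see [extract_intervals()]).
#' @param by Character vector of grouping columns.
#' @return Tibble with the grouping columns plus `n`, `mean_gr`, `se_gr`.
#' @export
summarize_growth <- function(intervals,
                             by = c("sex", "age_class", "season", "year")) {
  unknown <- setdiff(by, names(intervals))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown grouping factor(s): %s.",
                  paste0("'", unknown, "'", collapse = ", ")))
  }
  check_columns(intervals, "gr_mm_per_day", "interval")
  intervals |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_gr = mean(.data$gr_mm_per_day),
      se_gr = sd(.data$gr_mm_per_day) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Fixed-effects ANOVA on growth rates
#'
#' Fits a fixed-effects analysis of variance of growth rate on the given
#' factors (sequential, type-I sums of squares via [stats::aov()]) and
#' returns the F tests. Every factor must have at least two levels and the
#' rates must vary.
#'
#' @param intervals Interval tibble.
#' @param factors Character vector of factor columns, subset of
#'   `c("sex", "season", "year", "age_class")` (or any interval column).
#' @return An object of class `growth_anova`: list with `table` (tibble:
#'   `term, df, sumsq, meansq, statistic, p.value`) and `group_means`
#'   (from [summarize_growth()]).
#' @export
anova_growth <- function(intervals, factors) {
  unknown <- setdiff(factors, names(intervals))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown factor(s): %s.",
                  paste0("'", unknown, "'", collapse = ", ")))
  }
  check_columns(intervals, "gr_mm_per_day", "interval")
  df <- dplyr::mutate(
    intervals,
    dplyr::across(dplyr::all_of(factors), as.factor)
  )
  nlev <- purrr::map_int(factors, \(f) nlevels(df[[f]]))
  if (any(nlev < 2)) {
    abort(sprintf("Factor '%s' has a single level.",
                  factors[which(nlev < 2)[1]]))
  }
  if (var(df$gr_mm_per_day) == 0) {
    abort("F is undefined: all growth rates are identical.")
  }
  form <- stats::reformulate(factors, response = "gr_mm_per_day")
  fit <- aov(form, data = df)
  an <- as.data.frame(anova(fit))
  tab <- tibble::tibble(
    term = rownames(an),
    df = an$Df,
    sumsq = an$`Sum Sq`,
    meansq = an$`Mean Sq`,
    statistic = an$`F value`,
    p.value = an$`Pr(>F)`
  )
  structure(
    list(table = tab,
         group_means = summarize_growth(intervals, by = factors)),
    class = "growth_anova"
  )
}

#' @export
print.growth_anova <- function(x, ...) {
  cat("<growth_anova>\n")
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.growth_anova <- function(x, ...) x$table

#' Monthly mean growth-rate series
#'
#' Aggregates intervals to a monthly series for correlation with monthly
#' environmental covariates: each interval is assigned to the calendar month
#' of its midpoint date and cell means are taken.
#'
#' @param intervals Interval tibble carrying `date_first` and `date_last`.
#' @return Tibble: `year, month, n, mean_gr`.
#' @export
monthly_growth <- function(intervals) {
  check_columns(intervals, c("date_first", "date_last", "gr_mm_per_day"),
                "interval")
  mid <- as.Date(intervals$date_first) +
    floor(as.numeric(as.Date(intervals$date_last) -
                       as.Date(intervals$date_first)) / 2)
  intervals |>
    dplyr::mutate(
      year = as.integer(format(mid, "%Y")),
      month = as.integer(format(mid, "%m"))
    ) |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(n = dplyr::n(), mean_gr = mean(.data$gr_mm_per_day),
                     .groups = "drop")
}

#' Pearson correlation between growth and an environmental covariate
#'
#' Two-sided Pearson correlation between an aligned pair of series --
#' typically monthly mean growth rate against monthly prey count, prey
#' category richness, mean temperature or total precipitation.
#'
#' @param growth Numeric growth series.
#' @param covariate Numeric covariate series, same length (>= 3).
#' @param name Covariate label carried into the output.
#' @return One-row tibble: `covariate, n, estimate, p.value`.
#' @export
correlate_growth_env <- function(growth, covariate, name = "covariate") {
  if (length(growth) != length(covariate)) {
    abort("Series must be aligned (equal length).")
  }
  keep <- is.finite(growth) & is.finite(covariate)
  growth <- growth[keep]; covariate <- covariate[keep]
  if (length(growth) < 3) abort("Need at least 3 aligned observations.")
  if (sd(covariate) == 0 || sd(growth) == 0) {
    abort("Correlation is undefined for a zero-variance series.")
  }
  ct <- cor.test(growth, covariate, method = "pearson",
                 alternative = "two.sided")
  tibble::tibble(
    covariate = name, n = length(growth),
    estimate = unname(ct$estimate), p.value = ct$p.value
  )
}

#' Correlations of monthly growth with all environmental covariates
#'
#' Joins the monthly growth series ([monthly_growth()]) with the monthly
#' environment table ([monthly_env_table()]) and reports the Pearson
#' correlation of mean growth rate with each covariate, optionally per year.
#'
#' @param intervals Interval tibble.
#' @param env Monthly environment table with columns `year, month,
#'   prey_count, prey_categories, temp_c, precip_mm`.
#' @param by_year Correlate within each year separately (as well as pooled).
#' @return Tibble: `year` ("all" for pooled rows), `covariate`, `n`,
#'   `estimate`, `p.value`.
#' @export
env_growth_correlations <- function(intervals, env, by_year = TRUE) {
  g <- monthly_growth(intervals)
  joined <- dplyr::inner_join(g, env, by = c("year", "month"))
  covars <- c("prey_count", "prey_categories", "temp_c", "precip_mm")
  check_columns(joined, covars, "environment")
  one_block <- function(d, label) {
    purrr::map(covars, \(v) {
      correlate_growth_env(d$mean_gr, d[[v]], name = v)
    }) |>
      dplyr::bind_rows() |>
      dplyr::mutate(year = label, .before = 1)
  }
  out <- one_block(joined, "all")
  if (by_year) {
    yearly <- joined |>
      dplyr::group_by(.data$year) |>
      dplyr::group_split() |>
      purrr::map(\(d) one_block(d, as.character(d$year[1]))) |>
      dplyr::bind_rows()
    out <- dplyr::bind_rows(out, yearly)
  }
  out
}
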