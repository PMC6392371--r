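#' Fit stage of the growth-analysis pipeline
#'
#' Extracts growth intervals from a capture table, fits all three growth-law
#' families within each sex and selects a model per sex by lowest mean
#' squared residual. Optionally writes the fit report and intervals as CSV.
#'
#' @param captures Capture tibble or path to a capture CSV.
#' @param window Admissible recapture interval, days.
#' @param l_ref Reference-length definition, see [extract_intervals()].
#' @param out_dir Optional output directory for `fit_report.csv` and
#'   `intervals.csv`.
#' @return A list with `intervals`, `report` (per sex and family: MSR, R2,
#'   parameter estimates and standard errors, selection flag) and `fits`.
#' @export
run_fit <- function(captures, window = c(30, 100),
                    l_ref = c("midpoint", "first"), out_dir = NULL) {
  if (is.character(captures)) captures <- read_captures(captures)
  check_columns(captures, capture_columns, "capture")
  intervals <- extract_intervals(captures, window = window,
                                 l_ref = match.arg(l_ref))
  res <- fit_by_sex(intervals)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(res$report, file.path(out_dir, "fit_report.csv"))
    write_intervals(intervals, file.path(out_dir, "intervals.csv"))
  }
  list(intervals = intervals, report = res$report, fits = res$fits)
}

#' Full growth-ecology analysis
#'
#' The complete pipeline: interval extraction, per-sex model fitting and
#' selection, growth curves anchored at hatchling size, ages at sexual
#' maturity, group summaries of growth rate by sex/age class/season/year,
#' ANOVAs on the main factors, and correlations of monthly growth with prey
#' and climate. All outputs are returned and, when `out_dir` is given,
#' written as CSVs together with a JSON run manifest (package version, seed
#' and parameters) so runs are reproducible.
#'
#' @inheritParams run_fit
#' @param prey Prey tibble (with `month` column) or CSV path; optional.
#' @param climate Climate tibble or CSV path; optional.
#' @param L0 Hatchling SVL anchoring the growth curves, mm.
#' @param maturity_svl Named vector of maturity thresholds, mm.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic given its inputs).
#' @return A list with `intervals`, `report`, `selected`, `curves`,
#'   `maturity`, `group_summary`, `anova`, `correlations` and `manifest`.
#' @export
run_full_analysis <- function(captures, prey = NULL, climate = NULL,
                              L0 = 22.1,
                              maturity_svl = c(male = 35, female = 37),
                              window = c(30, 100),
                              l_ref = c("midpoint", "first"),
                              out_dir = NULL, seed = NULL) {
  if (is.character(prey)) prey <- read_prey(prey)
  if (is.character(climate)) climate <- read_climate(climate)
  fit_stage <- run_fit(captures, window = window, l_ref = l_ref)
  intervals <- fit_stage$intervals
  report <- fit_stage$report

  selected <- report |>
    dplyr::filter(.data$selected) |>
    dplyr::select("sex", "family")
  curves <- purrr::map(
    setNames(selected$sex, selected$sex),
    \(s) build_growth_curve(
      fit_stage$fits[[s]][[selected$family[selected$sex == s]]], L0
    )
  )
  maturity <- purrr::imap(curves, \(crv, s) {
    age_at_maturity(crv, unname(maturity_svl[[s]])) |>
      dplyr::mutate(sex = s, family = crv$family, .before = 1)
  }) |> dplyr::bind_rows()

  group_summary <- summarize_growth(intervals)

  anova_tabs <- list(
    year = tidy(anova_growth(intervals, "year")),
    season = tidy(anova_growth(intervals, "season")),
    sex = tidy(anova_growth(intervals, "sex"))
  )

  correlations <- NULL
  env <- NULL
  if (!is.null(prey) && !is.null(climate)) {
    env <- monthly_env_table(prey, climate)
    gm <- monthly_growth(intervals)
    if (nrow(dplyr::inner_join(gm, env, by = c("year", "month"))) < 3) {
      abort("Alignment error: environmental series do not overlap the capture months.")
    }
    correlations <- env_growth_correlations(intervals, env)
  }

  manifest <- list(
    package = "lizgrowth",
    version = as.character(utils::packageVersion("lizgrowth")),
    seed = seed,
    parameters = list(
      L0 = L0, maturity_svl = as.list(maturity_svl),
      window = window, l_ref = match.arg(l_ref)
    ),
    n_captures = if (is.character(captures)) NA_integer_ else nrow(captures),
    n_intervals = nrow(intervals)
  )

  out <- list(
    intervals = intervals, report = report, selected = selected,
    curves = curves, maturity = maturity, group_summary = group_summary,
    anova = anova_tabs, correlations = correlations, env = env,
    manifest = manifest
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_intervals(intervals, file.path(out_dir, "intervals.csv"))
    readr::write_csv(report, file.path(out_dir, "fit_report.csv"))
    readr::write_csv(maturity, file.path(out_dir, "maturity.csv"))
    readr::write_csv(group_summary, file.path(out_dir, "group_summary.csv"))
    readr::write_csv(
      purrr::imap(anova_tabs,
                  \(t, nm) dplyr::mutate(t, factor_set = nm, .before = 1)) |>
        dplyr::bind_rows(),
      file.path(out_dir, "anova.csv")
    )
    if (!is.null(correlations)) {
      readr::write_csv(correlations, file.path(out_dir, "correlations.csv"))
    }
    purrr::iwalk(curves, \(crv, s) {
      readr::write_csv(curve_table(crv),
                       file.path(out_dir, sprintf("growth_curve_%s.csv", s)))
    })
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
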