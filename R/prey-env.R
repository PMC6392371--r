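#' Read prey-sweep and climate tables
#'
#' Prey CSVs use the schema `year, season, category, life_stage, count`
#' (a `month` column is accepted and kept when present, as produced by the
#' simulator); climate CSVs use `year, month, temp_c, precip_mm`.
#'
#' @param path File path.
#' @export
read_prey <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("year", "season", "category", "life_stage", "count"),
                "prey")
  if (any(df$count < 0)) abort("Prey counts must be non-negative.")
  tibble::as_tibble(df)
}

#' @rdname read_prey
#' @export
read_climate <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("year", "month", "temp_c", "precip_mm"), "climate")
  if (any(df$precip_mm < 0)) abort("Precipitation must be non-negative.")
  tibble::as_tibble(df)
}

#' Sweep-net prey counts from the Chamela study seasons
#'
#' The packaged table of arthropods collected by sweep netting at the
#' Chamela biological station across the wet and dry seasons of 1989 and
#' 1990, by prey category. Categories are arthropod orders, with beetles and
#' lepidopterans split into adult and larval forms (each stage is its own
#' prey category). Season totals are 341 (wet) + 84 (dry) = 425 items in
#' 1989 and 356 + 155 = 511 in 1990.
#'
#' @return A prey tibble (see [read_prey()]).
#' @export
chamela_prey <- function() {
  read_prey(system.file("extdata", "chamela_prey_sweeps.csv",
                        package = "lizgrowth", mustWork = TRUE))
}

#' Total prey items for a year and optional season
#'
#' @param samples Prey tibble.
#' @param year Calendar year filter (optional).
#' @param season `"wet"` or `"dry"` (optional).
#' @return Total count (0 for an empty selection).
#' @export
aggregate_prey <- function(samples, year = NULL, season = NULL) {
  df <- samples
  if (!is.null(year)) df <- dplyr::filter(df, .data$year %in% !!year)
  if (!is.null(season)) df <- dplyr::filter(df, .data$season %in% !!season)
  sum(df$count)
}

#' Number of distinct prey categories present
#'
#' Counts distinct (order, life stage) combinations with a positive summed
#' count in the selection; the adult and larval forms of an order are
#' separate prey categories.
#'
#' @inheritParams aggregate_prey
#' @return Integer richness (0 for an empty selection).
#' @export
category_richness <- function(samples, year = NULL, season = NULL) {
  df <- samples
  if (!is.null(year)) df <- dplyr::filter(df, .data$year %in% !!year)
  if (!is.null(season)) df <- dplyr::filter(df, .data$season %in% !!season)
  df |>
    dplyr::group_by(.data$category, .data$life_stage) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$total > 0) |>
    nrow()
}

#' Monthly environment table aligned for growth correlations
#'
#' Builds one row per year-month with the total prey count, prey-category
#' richness, mean temperature and total precipitation, for joining against
#' the monthly growth series. Prey samples must carry a `month` column
#' (season-level tables such as [chamela_prey()] cannot be aligned
#' monthly). Months present in only one source are kept and flagged
#' incomplete.
#'
#' @param prey Prey tibble with a `month` column.
#' @param climate Climate tibble (`year, month, temp_c, precip_mm`).
#' @return Tibble: `year, month, prey_count, prey_categories, temp_c,
#'   precip_mm, complete`.
#' @export
monthly_env_table <- function(prey, climate) {
  check_columns(prey, c("year", "month", "category", "life_stage", "count"),
                "prey")
  check_columns(climate, c("year", "month", "temp_c", "precip_mm"), "climate")
  if (anyDuplicated(climate[, c("year", "month")]) > 0) {
    abort("Duplicate climate records for a year-month.")
  }
  prey_m <- prey |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(
      prey_count = sum(.data$count),
      prey_categories = dplyr::n_distinct(
        paste(.data$category, .data$life_stage)[.data$count > 0]
      ),
      .groups = "drop"
    )
  out <- dplyr::full_join(prey_m, climate, by = c("year", "month")) |>
    dplyr::arrange(.data$year, .data$month) |>
    dplyr::mutate(
      complete = !is.na(.data$prey_count) & !is.na(.data$temp_c) &
        !is.na(.data$precip_mm)
    )
  out
}
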