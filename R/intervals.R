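#' Per-interval growth rate
#'
#' The elementary growth datum of a mark-recapture study: the change in
#' snout--vent length between two captures of the same individual divided by
#' the elapsed days, `GR = (SVL2 - SVL1) / days`, in mm/day. Negative values
#' are permitted -- apparent shrinkage arises from measurement error -- and
#' are flagged downstream rather than discarded.
#'
#' @param l1,l2 SVL at the first and second capture, mm (> 0).
#' @param days Elapsed days between captures (> 0).
#' @return Growth rate(s), mm/day.
#' @examples
#' growth_rate(25, 28, 60) # 0.05 mm/day
#' @export
growth_rate <- function(l1, l2, days) {
  if (any(days <= 0)) abort("Invalid interval: `days` must be positive.")
  if (any(l1 <= 0) || any(l2 <= 0)) abort("SVL measurements must be positive.")
  (l2 - l1) / days
}

#' Calendrical wet/dry season of a date
#'
#' The tropical dry-forest year at the study site splits into a wet season
#' (July--November, the rainy months) and a dry season (December--June).
#' The split is calendrical: it does not depend on realised rainfall.
#'
#' @param date A `Date` vector (or anything coercible via [as.Date()]).
#' @return Character vector, `"wet"` or `"dry"`.
#' @export
assign_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  ifelse(m >= 7L & m <= 11L, "wet", "dry")
}

#' Default sex-specific age-class thresholds
#'
#' Juvenile SVL ranges and adult thresholds, mm: juvenile males
#' 25.0--31.0 mm and adult males above 32.0 mm; juvenile females
#' 25.0--34.0 mm and adult females above 35.0 mm. Lengths in the unassigned
#' gap between the juvenile upper bound and the adult threshold are classed
#' juvenile (any animal not strictly above the adult threshold is).
#'
#' @return A tibble with columns `sex`, `juvenile_min`, `juvenile_max`,
#'   `adult_threshold` (all mm).
#' @export
default_age_class_rule <- function() {
  tibble::tibble(
    sex = c("male", "female"),
    juvenile_min = c(25, 25),
    juvenile_max = c(31, 34),
    adult_threshold = c(32, 35)
  )
}

#' Assign juvenile/adult age class from SVL and sex
#'
#' @param svl SVL, mm (> 0).
#' @param sex `"male"` or `"female"` (recycled against `svl`).
#' @param rule Threshold table as produced by [default_age_class_rule()].
#' @return Character vector, `"juvenile"` or `"adult"`.
#' @export
assign_age_class <- function(svl, sex, rule = default_age_class_rule()) {
  if (any(svl <= 0)) abort("`svl` must be positive.")
  if (!all(sex %in% rule$sex)) {
    abort("Age-class bounds are sex-specific; `sex` must be 'male' or 'female'.")
  }
  thr <- rule$adult_threshold[match(sex, rule$sex)]
  ifelse(svl > thr, "adult", "juvenile")
}

capture_columns <- c("id", "sex", "date", "svl_mm", "mass_g")

#' Read and write capture tables
#'
#' The capture CSV schema is `id, sex, date, svl_mm, mass_g` with an ISO-8601
#' date column; `mass_g` may be missing.
#'
#' @param path File path.
#' @param captures A capture tibble.
#' @return `read_captures()` returns a tibble; `write_captures()` returns
#'   `captures` invisibly.
#' @export
read_captures <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, capture_columns, "capture")
  df$date <- as.Date(df$date)
  tibble::as_tibble(df)
}

#' @rdname read_captures
#' @export
write_captures <- function(captures, path) {
  check_columns(captures, capture_columns, "capture")
  readr::write_csv(captures, path)
  invisible(captures)
}

check_columns <- function(df, needed, what) {
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Malformed %s table: missing column(s) %s.",
                  what, paste0("'", missing, "'", collapse = ", ")))
  }
  invisible(df)
}

#' Flag implausible capture records
#'
#' Adds a logical `valid` column: `FALSE` where SVL falls outside plausible
#' bounds or the date falls outside the study window.
#'
#' @param captures A capture tibble.
#' @param svl_bounds Plausible SVL range, mm.
#' @param study_window Optional `Date` pair; records outside it are flagged.
#' @return The capture tibble with a `valid` column.
#' @export
validate_captures <- function(captures, svl_bounds = c(10, 80),
                              study_window = NULL) {
  check_columns(captures, capture_columns, "capture")
  ok <- captures$svl_mm >= svl_bounds[1] & captures$svl_mm <= svl_bounds[2]
  if (!is.null(study_window)) {
    d <- as.Date(captures$date)
    ok <- ok & d >= study_window[1] & d <= study_window[2]
  }
  dplyr::mutate(captures, valid = ok)
}

#' Extract growth intervals from capture histories
#'
#' Converts repeated captures of marked individuals into growth intervals.
#' By default one interval per individual is formed from its first to its
#' last capture (so each marked animal contributes a single growth-rate
#' datum); `per_pair = TRUE` instead forms an interval from every
#' consecutive capture pair. Intervals whose elapsed days fall outside
#' `window` (default 30--100 days) are dropped, as are individuals captured
#' only once and records with unknown sex (age classes are sex-specific).
#'
#' Each interval carries the reference length `l_ref_mm` used as the model
#' predictor -- the midpoint `(L1 + L2)/2` by default, since the increment
#' measures growth around the interval's centre -- together with the age
#' class, season and year of its first capture, and a `shrinkage` flag for
#' negative growth (retained by default; drop with
#' `keep_negative = FALSE`).
#'
#' @param captures A capture tibble (see [read_captures()]).
#' @param window Admissible elapsed days, `c(min, max)`.
#' @param l_ref `"midpoint"` or `"first"`: reference length definition.
#' @param per_pair Form intervals from consecutive capture pairs instead of
#'   first-to-last.
#' @param keep_negative Retain (flagged) negative-growth intervals.
#' @param rule Age-class thresholds, see [default_age_class_rule()].
#' @return A tibble with columns `id, sex, year, season, age_class, l1_mm,
#'   l2_mm, days, gr_mm_per_day, l_ref_mm, shrinkage, date_first,
#'   date_last`.
#' @export
extract_intervals <- function(captures, window = c(30, 100),
                              l_ref = c("midpoint", "first"),
                              per_pair = FALSE, keep_negative = TRUE,
                              rule = default_age_class_rule()) {
  check_columns(captures, capture_columns, "capture")
  l_ref <- match.arg(l_ref)
  if (length(window) != 2 || window[1] <= 0 || window[2] < window[1]) {
    abort("`window` must be positive increasing bounds on elapsed days.")
  }
  df <- captures |>
    dplyr::filter(.data$sex %in% c("male", "female")) |>
    dplyr::mutate(date = as.Date(.data$date)) |>
    dplyr::arrange(.data$id, .data$date)

  pair_up <- function(g, ...) {
    n <- nrow(g)
    if (n < 2) {
      return(tibble::tibble(
        sex = character(), date_first = as.Date(character()),
        date_last = as.Date(character()), l1_mm = double(), l2_mm = double()
      ))
    }
    if (per_pair) {
      i1 <- seq_len(n - 1); i2 <- i1 + 1L
    } else {
      i1 <- 1L; i2 <- n
    }
    tibble::tibble(
      sex = g$sex[i1],
      date_first = g$date[i1], date_last = g$date[i2],
      l1_mm = g$svl_mm[i1], l2_mm = g$svl_mm[i2]
    )
  }

  out <- df |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(pair_up) |>
    dplyr::ungroup()

  if (nrow(out) == 0) return(empty_intervals())

  out <- out |>
    dplyr::mutate(
      days = as.integer(.data$date_last - .data$date_first),
      gr_mm_per_day = growth_rate(.data$l1_mm, .data$l2_mm, pmax(.data$days, 1L)),
      l_ref_mm = if (l_ref == "midpoint") (.data$l1_mm + .data$l2_mm) / 2
                 else .data$l1_mm,
      year = as.integer(format(.data$date_first, "%Y")),
      season = assign_season(.data$date_first),
      age_class = assign_age_class(.data$l1_mm, .data$sex, rule),
      shrinkage = .data$gr_mm_per_day < 0
    ) |>
    dplyr::filter(.data$days >= window[1], .data$days <= window[2])
  if (!keep_negative) out <- dplyr::filter(out, !.data$shrinkage)
  dplyr::select(
    out, "id", "sex", "year", "season", "age_class", "l1_mm", "l2_mm",
    "days", "gr_mm_per_day", "l_ref_mm", "shrinkage", "date_first", "date_last"
  )
}

empty_intervals <- function() {
  tibble::tibble(
    id = character(), sex = character(), year = integer(),
    season = character(), age_class = character(), l1_mm = double(),
    l2_mm = double(), days = integer(), gr_mm_per_day = double(),
    l_ref_mm = double(), shrinkage = logical(),
    date_first = as.Date(character()), date_last = as.Date(character())
  )
}

interval_columns <- c(
  "id", "sex", "year", "season", "age_class", "l1_mm", "l2_mm", "days",
  "gr_mm_per_day", "l_ref_mm"
)

#' Read and write growth-interval tables
#'
#' Interval CSVs use the schema `id, sex, year, season, age_class, l1_mm,
#' l2_mm, days, gr_mm_per_day, l_ref_mm` (plus any extra columns present,
#' such as the capture dates and the shrinkage flag).
#'
#' @param path File path.
#' @param intervals An interval tibble from [extract_intervals()].
#' @export
read_intervals <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, interval_columns, "interval")
  tibble::as_tibble(df)
}

#' @rdname read_intervals
#' @export
write_intervals <- function(intervals, path) {
  check_columns(intervals, interval_columns, "interval")
  readr::write_csv(intervals, path)
  invisible(intervals)
}
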