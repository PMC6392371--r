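test_that("growth_rate computes SVL increment per day and keeps sign", {
  expect_equal(growth_rate(25, 28, 60), 0.05)
  expect_equal(growth_rate(30, 30, 45), 0)
  expect_equal(growth_rate(33, 32.5, 50), -0.01)
  expect_error(growth_rate(25, 28, 0), "days")
  expect_error(growth_rate(25, 28, -3), "days")
  expect_error(growth_rate(0, 28, 10), "positive")
})

test_that("season assignment is calendrical: July-November wet, rest dry", {
  expect_equal(assign_season(as.Date("1989-08-15")), "wet")
  expect_equal(assign_season(as.Date("1989-03-10")), "dry")
  expect_equal(assign_season(as.Date("1989-12-01")), "dry")
  months <- assign_season(as.Date(sprintf("1989-%02d-01", 1:12)))
  expect_equal(sum(months == "wet"), 5)
  expect_equal(sum(months == "dry"), 7)
})

test_that("age classes follow sex-specific thresholds with gap -> juvenile", {
  expect_equal(assign_age_class(30, "male"), "juvenile")
  expect_equal(assign_age_class(36, "female"), "adult")
  expect_equal(assign_age_class(31.5, "male"), "juvenile")  # gap 31-32
  expect_equal(assign_age_class(34.5, "female"), "juvenile") # gap 34-35
  expect_equal(assign_age_class(32.5, "male"), "adult")
  expect_error(assign_age_class(30, "unknown"), "sex")
})

test_that("extract_intervals takes one first-to-last interval per individual", {
  cap <- make_captures(
    list("a", "male", "1989-02-01", 25.0),
    list("a", "male", "1989-03-15", 26.5),   # intermediate capture
    list("a", "male", "1989-04-02", 28.0),   # 60 days after first
    list("b", "female", "1989-05-01", 30.0), # single capture
    list("c", "female", "1989-06-01", 33.0),
    list("c", "female", "1989-06-21", 33.5)  # 20 days, below the floor
  )
  iv <- extract_intervals(cap)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$id, "a")
  expect_equal(iv$days, 60L)
  expect_equal(iv$gr_mm_per_day, 0.05)
  expect_equal(iv$l_ref_mm, 26.5)
  expect_equal(iv$age_class, "juvenile")
  expect_equal(iv$season, "dry")
  expect_equal(iv$year, 1989L)
  # at most one interval per individual over any dataset
  expect_lte(max(table(iv$id)), 1)
})

test_that("per-pair mode yields consecutive intervals, each window-filtered", {
  cap <- make_captures(
    list("a", "male", "1989-02-01", 25.0),
    list("a", "male", "1989-03-15", 26.5),  # 42 days
    list("a", "male", "1989-04-02", 28.0)   # 18 days: dropped
  )
  iv <- extract_intervals(cap, per_pair = TRUE)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$days, 42L)
})

test_that("negative growth is retained but flagged, and can be excluded", {
  cap <- make_captures(
    list("a", "male", "1989-02-01", 30.0),
    list("a", "male", "1989-04-02", 29.5),
    list("b", "male", "1989-02-01", 25.0),
    list("b", "male", "1989-04-02", 27.0)
  )
  iv <- extract_intervals(cap)
  expect_equal(iv$shrinkage, c(TRUE, FALSE))
  iv2 <- extract_intervals(cap, keep_negative = FALSE)
  expect_equal(iv2$id, "b")
})

test_that("stored growth rates are reproducible from the interval fields", {
  cfg <- sim_config(n_individuals = 150, seed = 11)
  iv <- extract_intervals(simulate_captures(cfg))
  expect_gt(nrow(iv), 5)
  expect_equal(iv$gr_mm_per_day, (iv$l2_mm - iv$l1_mm) / iv$days,
               tolerance = 1e-12)
  expect_true(all(iv$days >= 30 & iv$days <= 100))
  expect_true(all(iv$l_ref_mm >= pmin(iv$l1_mm, iv$l2_mm) &
                    iv$l_ref_mm <= pmax(iv$l1_mm, iv$l2_mm)))
})

test_that("capture and interval tables round-trip through CSV", {
  cfg <- sim_config(n_individuals = 80, seed = 4)
  cap <- simulate_captures(cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_captures(cap, f1)
  cap2 <- read_captures(f1)
  expect_equal(as.data.frame(cap2), as.data.frame(cap))
  expect_equal(extract_intervals(cap2), extract_intervals(cap))

  iv <- extract_intervals(cap)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_intervals(iv, f2)
  iv2 <- read_intervals(f2)
  expect_equal(iv2$gr_mm_per_day, iv$gr_mm_per_day)
  expect_equal(iv2$season, iv$season)
})

test_that("schema violations are reported by column name", {
  expect_error(extract_intervals(tibble::tibble(id = "a")), "sex")
  expect_error(write_captures(tibble::tibble(id = "a"), tempfile()), "svl_mm")
})

test_that("validate_captures flags implausible SVL and out-of-window dates", {
  cap <- make_captures(
    list("a", "male", "1989-02-01", 30.0),
    list("b", "male", "1989-02-01", 95.0),
    list("c", "male", "1995-02-01", 30.0)
  )
  v <- validate_captures(cap, study_window = as.Date(c("1989-01-01",
                                                       "1990-12-31")))
  expect_equal(v$valid, c(TRUE, FALSE, FALSE))
})
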