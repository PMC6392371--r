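test_that("simulation is reproducible under a fixed seed", {
  cfg <- sim_config(n_individuals = 60, seed = 42)
  expect_identical(simulate_individuals(cfg), simulate_individuals(cfg))
  expect_identical(simulate_captures(cfg), simulate_captures(cfg))
  ec <- env_config(seed = 42)
  expect_identical(simulate_env(ec), simulate_env(ec))
})

test_that("latent trajectories follow the configured growth law exactly", {
  cfg <- sim_config(family = "logistic_by_length", A1 = 46.46, r = 0.0053,
                    n_individuals = 25, seed = 3)
  ind <- simulate_individuals(cfg)
  at100 <- latent_svl(ind, 100)
  expected <- purrr::map_dbl(ind$l0, \(l0) {
    length_at_age(growth_curve("logistic_by_length", 46.46, 0.0053, l0), 100)
  })
  expect_equal(at100, expected, tolerance = 1e-9)
  # zero hatchling variance pins length at age zero to the mean exactly
  cfg0 <- sim_config(l0_sd = 0, n_individuals = 10, seed = 3)
  ind0 <- simulate_individuals(cfg0)
  expect_equal(latent_svl(ind0, 0), rep(22.1, 10))
})

test_that("hatchling sizes stay positive and below the asymptote", {
  cfg <- sim_config(n_individuals = 400, l0_sd = 6, seed = 17)
  ind <- simulate_individuals(cfg)
  expect_true(all(ind$l0 > 0 & ind$l0 < cfg$A1))
  expect_true(all(as.integer(format(ind$hatch_date, "%m")) %in% 9:11))
})

test_that("observation respects capture probability and measurement error", {
  cfg0 <- sim_config(n_individuals = 40, p_capture = 0, seed = 5)
  expect_equal(nrow(simulate_captures(cfg0)), 0)

  # perfect detection, no error, no death: two sessions a month apart give
  # a growth rate matching the instantaneous law at the interval midpoint
  cfg <- sim_config(
    family = "von_bertalanffy", A1 = 50.36, r = 0.0028,
    n_individuals = 200, n_months = 2, study_start = "1989-01-01",
    p_capture = 1, measurement_sd = 0, monthly_survival = 1, seed = 6
  )
  cap <- simulate_captures(cfg)
  iv <- extract_intervals(cap)
  expect_gt(nrow(iv), 50)
  # recorded SVLs are rounded to 0.01 mm, so a 30-day chord can deviate
  # from the instantaneous midpoint rate by up to ~0.01 mm / 30 d
  expect_lt(
    max(abs(iv$gr_mm_per_day -
              gr_rate("von_bertalanffy", iv$l_ref_mm, 50.36, 0.0028))),
    7.5e-4
  )
  expect_true(all(cap$svl_mm > 0))
})

test_that("default design yields the target scale of marked individuals", {
  cap <- simulate_captures(sim_config(seed = 1))
  marked <- length(unique(cap$id))
  expect_lt(abs(marked - 702) / 702, 0.10)
})

test_that("direct interval generator honours its ranges and noise law", {
  iv <- simulate_growth_intervals(500, "logistic_by_length", 46.46, 0.0053,
                                  seed = 2)
  expect_true(all(iv$days >= 30 & iv$days <= 100))
  expect_true(all(iv$l1_mm >= 25 & iv$l1_mm <= 0.9 * 46.46))
  expect_equal(iv$l_ref_mm, (iv$l1_mm + iv$l2_mm) / 2)
  resid <- iv$gr_mm_per_day - (iv$l2_mm - iv$l1_mm) / iv$days
  expect_equal(sd(resid), 0.02, tolerance = 0.15)
  expect_equal(mean(resid), 0, tolerance = 3 * 0.02 / sqrt(500))
})

test_that("generated data identify the generating family by lowest MSR", {
  # Von Bertalanffy configuration; the two logistic families are much
  # harder to tell apart over the observable size range (see vignette)
  hits <- purrr::map_lgl(1:100, \(s) {
    iv <- simulate_growth_intervals(
      300, "von_bertalanffy", A1 = 50.36, r = 0.0028,
      l1_range = c(22.1, 0.9 * 50.36), seed = 3000 + s
    )
    compare_models(fit_all_models(iv))$selected == "von_bertalanffy"
  })
  expect_gte(mean(hits), 0.80)
})

test_that("semelparous option caps lifespan at one year", {
  cfg <- sim_config(n_individuals = 200, semelparous = TRUE,
                    monthly_survival = 1, seed = 9)
  ind <- simulate_individuals(cfg)
  expect_true(all(as.numeric(ind$death_date - ind$hatch_date) <= 365))
})

test_that("wet-season growth boost accelerates only wet-month growth", {
  base <- sim_config(n_individuals = 150, seed = 12, measurement_sd = 0,
                     p_capture = 1, monthly_survival = 1)
  boosted <- sim_config(n_individuals = 150, seed = 12, measurement_sd = 0,
                        p_capture = 1, monthly_survival = 1,
                        wet_gr_boost = 2.5)
  iv_b <- extract_intervals(observe(simulate_individuals(base), base))
  iv_x <- extract_intervals(observe(simulate_individuals(boosted), boosted))
  mg_b <- summarize_growth(iv_b, by = "season")
  mg_x <- summarize_growth(iv_x, by = "season")
  gain <- function(s, season) s$mean_gr[s$season == season]
  expect_gt(gain(mg_x, "wet") / gain(mg_b, "wet"), 1.5)
})
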