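test_that("growth curves built from fits carry the family shape constant", {
  iv <- simulate_growth_intervals(200, "von_bertalanffy", 52.81, 0.0017,
                                  noise_sd = 0, seed = 8)
  iv$gr_mm_per_day <- gr_rate("von_bertalanffy", iv$l_ref_mm, 52.81, 0.0017)
  fit <- fit_growth(iv, "von_bertalanffy")
  crv <- build_growth_curve(fit, L0 = 22.1)
  expect_equal(crv$b, 0.58152, tolerance = 1e-4)

  iv2 <- simulate_growth_intervals(200, "logistic_by_length", 46.46, 0.0053,
                                   noise_sd = 0, seed = 8)
  iv2$gr_mm_per_day <- gr_rate("logistic_by_length", iv2$l_ref_mm,
                               46.46, 0.0053)
  crv2 <- build_growth_curve(fit_growth(iv2, "logistic_by_length"), 22.1)
  expect_equal(crv2$b, 1.10226, tolerance = 1e-4)

  expect_error(build_growth_curve(fit, L0 = fit$A1), "below")
})

test_that("age at maturity inverts the curve and reports months", {
  male <- growth_curve("logistic_by_length", 46.46, 0.0053, 22.1)
  am <- age_at_maturity(male, 35)
  expect_equal(am$age_days, 229.03, tolerance = 1e-4)
  expect_equal(am$age_months, am$age_days / 30)
  female <- growth_curve("von_bertalanffy", 52.81, 0.0017, 22.1)
  expect_equal(age_at_maturity(female, 37)$age_days, 390.56, tolerance = 1e-4)
  # maturity at hatchling size is day zero; at the asymptote unreachable
  expect_equal(age_at_maturity(male, male$L0)$age_days, 0)
  expect_error(age_at_maturity(male, male$A1), "unreachable")
  # strictly increasing in the threshold
  ages <- purrr::map_dbl(seq(25, 44, by = 1),
                         \(s) age_at_maturity(male, s)$age_days)
  expect_true(all(diff(ages) > 0))
})

test_that("group summaries report n, mean and standard error per cell", {
  iv <- tibble::tibble(
    sex = c("f", "f", "f", "m"),
    gr_mm_per_day = c(0.04, 0.05, 0.06, 0.08)
  )
  s <- summarize_growth(iv, by = "sex")
  f <- s[s$sex == "f", ]
  expect_equal(f$n, 3L)
  expect_equal(f$mean_gr, 0.05)
  expect_equal(f$se_gr, 0.00577, tolerance = 1e-3)
  expect_equal(nrow(summarize_growth(iv[0, ], by = "sex")), 0)
  expect_error(summarize_growth(iv, by = "habitat"), "habitat")
})

test_that("cell means weighted by n reconstruct the overall mean", {
  cfg <- sim_config(n_individuals = 300, seed = 21)
  iv <- extract_intervals(simulate_captures(cfg))
  s <- summarize_growth(iv)
  expect_equal(sum(s$n * s$mean_gr) / sum(s$n), mean(iv$gr_mm_per_day),
               tolerance = 1e-12)
})

test_that("two-group ANOVA equals the squared pooled-variance t statistic", {
  set.seed(31)
  for (rep in 1:5) {
    iv <- tibble::tibble(
      sex = rep(c("m", "f"), each = 20),
      gr_mm_per_day = rnorm(40, 0.05, 0.01)
    )
    a <- tidy(anova_growth(iv, "sex"))
    tt <- t.test(gr_mm_per_day ~ sex, data = iv, var.equal = TRUE)
    expect_equal(a$statistic[1], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p.value[1], tt$p.value, tolerance = 1e-10)
  }
})

test_that("ANOVA rejects degenerate designs", {
  iv <- tibble::tibble(sex = rep("m", 10), gr_mm_per_day = rnorm(10))
  expect_error(anova_growth(iv, "sex"), "single level")
  iv2 <- tibble::tibble(sex = rep(c("m", "f"), 5),
                        gr_mm_per_day = rep(0.05, 10))
  expect_error(anova_growth(iv2, "sex"), "identical")
})

test_that("ANOVA detects a strong group difference", {
  set.seed(99)
  hits <- purrr::map_lgl(1:50, \(i) {
    iv <- tibble::tibble(
      sex = rep(c("m", "f"), each = 30),
      gr_mm_per_day = c(rnorm(30, 0.08, 0.01), rnorm(30, 0.04, 0.01))
    )
    tidy(anova_growth(iv, "sex"))$p.value[1] < 0.001
  })
  expect_gte(mean(hits), 0.99)
})

test_that("correlations are exact on proportional series and affine-invariant", {
  gr <- c(0.02, 0.05, 0.03, 0.07, 0.04, 0.06)
  out <- correlate_growth_env(gr, 2 * gr)
  expect_equal(out$estimate, 1.0)
  x <- rnorm(12)
  base <- correlate_growth_env(gr2 <- rnorm(12), x)
  shifted <- correlate_growth_env(3 * gr2 + 10, 0.5 * x - 2)
  expect_equal(shifted$estimate, base$estimate, tolerance = 1e-12)
  expect_equal(shifted$p.value, base$p.value, tolerance = 1e-12)
  expect_error(correlate_growth_env(gr, rep(1, 6)), "zero-variance")
  expect_error(correlate_growth_env(gr, x), "aligned")
})

test_that("correlation of independent series is centred on zero", {
  set.seed(123)
  r <- purrr::map_dbl(1:500, \(i) {
    correlate_growth_env(rnorm(12), rnorm(12))$estimate
  })
  expect_lt(abs(mean(r)), 2 * sd(r) / sqrt(length(r)))
})

test_that("monthly growth series uses interval midpoint months", {
  iv <- extract_intervals(make_captures(
    list("a", "male", "1989-01-10", 25.0),
    list("a", "male", "1989-03-11", 28.0),  # midpoint 1989-02-09
    list("b", "male", "1989-07-01", 30.0),
    list("b", "male", "1989-08-10", 31.0)   # midpoint 1989-07-21
  ))
  mg <- monthly_growth(iv)
  expect_equal(mg$month, c(2L, 7L))
  expect_equal(mg$n, c(1L, 1L))
})
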