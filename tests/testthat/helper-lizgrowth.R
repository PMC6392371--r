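# Small in-code fixtures and independent oracles shared across tests.

# A capture table built from (id, sex, date, svl) rows.
make_captures <- function(...) {
  rows <- list(...)
  tibble::tibble(
    id = purrr::map_chr(rows, 1),
    sex = purrr::map_chr(rows, 2),
    date = as.Date(purrr::map_chr(rows, 3)),
    svl_mm = purrr::map_dbl(rows, 4),
    mass_g = NA_real_
  )
}

# Independent inversion oracle: bisection on length_at_age.
bisect_time_to_length <- function(curve, target, hi = 20 / curve$r,
                                  tol = 1e-10) {
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (length_at_age(curve, mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Exact linear least-squares back-transformations, the fitting oracle.
linear_oracle <- function(family, l, gr) {
  switch(family,
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
}

# Richardson-extrapolated (5-point) derivative of length_at_age; O(h^4)
# accurate, so closed-form rate laws can be checked to tight tolerances.
# Requires t >= 2h.
numeric_gr <- function(curve, t, h = 0.25) {
  f <- function(u) length_at_age(curve, u)
  (8 * (f(t + h) - f(t - h)) - (f(t + 2 * h) - f(t - 2 * h))) / (12 * h)
}

# Interval tibble straight from (l_ref, gr) vectors.
rate_data <- function(l_ref, gr) {
  tibble::tibble(l_ref_mm = l_ref, gr_mm_per_day = gr)
}
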