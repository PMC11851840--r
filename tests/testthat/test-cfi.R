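test_that("CFI series is the per-animal running sum", {
  d <- data.frame(pig_id = c("A", "A", "A", "B"), day = c(1, 2, 3, 1),
                  dfi_kg = c(2, 2, 3, 5), bw_kg = c(30, 31, 32, 40))
  s <- build_cfi_series(d)
  expect_equal(s$cfi_kg, c(2, 4, 7, 5))
  one <- build_cfi_series(d[4, ])
  expect_equal(one$cfi_kg, 5)
  expect_error(build_cfi_series(d[c(1, 1, 2), ]), "duplicate")
})

test_that("an exactly linear animal gives CF = 1 and A = -slope*bw_in", {
  s <- linear_animal(bw0 = 30, adg = 1, slope = 2.5, days = 0:110)
  f <- fit_cfi_line(s)
  expect_equal(f$slope_best, 2.5, tolerance = 1e-9)
  expect_equal(f$intercept_a, -75, tolerance = 1e-9)
  expect_equal(f$cf, 1, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_true(f$retained)
})

test_that("curvature moves CF away from 1 (OLS oracle)", {
  days <- 0:110
  bw <- 30 + days
  cfi <- 0.015 * (bw - 30)^2 + 1.0 * (bw - 30)  # slope rises with weight
  s <- data.frame(pig_id = "Q", day = days, cfi_kg = cfi, bw_kg = bw)
  f <- fit_cfi_line(s)
  sel <- (bw >= 25 & bw <= 50) | (bw >= 100 & bw <= 140)
  slope_oracle <- unname(coef(lm(cfi[sel] ~ bw[sel]))[2])
  chord <- cfi[length(cfi)] / (bw[length(bw)] - bw[1])
  expect_equal(f$cf, slope_oracle / chord, tolerance = 1e-9)
  expect_gt(abs(f$cf - 1), 0.02)
})

test_that("too few window points raise an informative error", {
  s <- linear_animal(days = 30:110)   # bw 60..140: start window empty
  expect_error(fit_cfi_line(s), "start window")
  s2 <- linear_animal(days = 0:60)    # bw 30..90: end window empty
  expect_error(fit_cfi_line(s2), "end window")
})

test_that("population coefficients average the retained animals", {
  fits <- data.frame(pig_id = c("A", "B"), cf = c(1.0, 1.2),
                     intercept_a = c(-80, -90), retained = TRUE)
  co <- population_coefficients(fits)
  expect_equal(co$cf_mean, 1.1)
  expect_equal(co$a_mean, -85)
  expect_equal(co$n, 2)
  one <- population_coefficients(fits[1, ])
  expect_equal(one$cf_mean, 1.0)
  expect_equal(one$a_mean, -80)
  expect_error(population_coefficients(fits[fits$cf > 2, ]), "retained")
})

test_that("CF-model formula matches hand arithmetic", {
  r <- correct_cfi_cf(200, 30, 110, 1.03)
  expect_equal(r$cfi_120_cf, 225.75)
  expect_equal(r$cfi_30_cf, 0)
  expect_equal(r$cfi_30_120_cf, 225.75)

  r2 <- correct_cfi_cf(230, 28, 121, 1)
  expect_equal(r2$cfi_120_cf, 230 - 230 / 93, tolerance = 1e-9)
  expect_equal(r2$cfi_30_cf, 2 * 230 / 93, tolerance = 1e-9)
  expect_error(correct_cfi_cf(200, 110, 110, 1), "exceed")
})

test_that("A-model formula matches hand arithmetic", {
  r <- correct_cfi_a(200, 30, 110, -103.52)
  slope <- (200 + 103.52) / 110
  expect_equal(r$cfi_120_a, 200 + 10 * slope, tolerance = 1e-9)
  expect_lt(abs(r$cfi_120_a - 227.59), 0.01)
  expect_equal(r$cfi_30_a, 0)
  expect_error(correct_cfi_a(200, 30, 0, -100), "nonzero")
})

test_that("regression-based CFI is the entry-anchored line", {
  fit <- data.frame(slope_best = 2.5, bw_in = 30)
  r <- cfi_reg_values(fit)
  expect_equal(r$cfi_reg_30_120, 225)
  expect_equal(r$cfi_reg_120, 225)
  expect_equal(r$cfi_reg_30, 0)
  expect_equal(cfi_reg_values(data.frame(slope_best = 0,
                                         bw_in = 28))$cfi_reg_30_120, 0)
})

test_that("both corrections reduce to CFI_end at BW_end = 120", {
  set.seed(41)
  for (i in 1:100) {
    cfi_end <- runif(1, 150, 300)
    bw_in <- runif(1, 25, 32)
    cf <- runif(1, 0.8, 1.2)
    a <- runif(1, -150, -50)
    expect_equal(correct_cfi_cf(cfi_end, bw_in, 120, cf)$cfi_120_cf, cfi_end)
    expect_equal(correct_cfi_a(cfi_end, bw_in, 120, a)$cfi_120_a, cfi_end)
  }
})

test_that("on linear data CF- and A-models agree with the regression", {
  s <- linear_animal(bw0 = 28, adg = 0.95, slope = 2.3, days = 0:118)
  f <- fit_cfi_line(s)
  reg <- cfi_reg_values(f)
  cf <- correct_cfi_cf(f$cfi_end, f$bw_in, f$bw_end, 1)
  a <- correct_cfi_a(f$cfi_end, f$bw_in, f$bw_end, f$intercept_a)
  expect_equal(cf$cfi_30_120_cf, reg$cfi_reg_30_120, tolerance = 1e-9)
  expect_equal(a$cfi_30_120_a, reg$cfi_reg_30_120, tolerance = 1e-9)
  # equals the true between-weights intake on the line
  expect_equal(reg$cfi_reg_30_120, 2.3 * 90, tolerance = 1e-9)
})

test_that("corrected CFI is strictly increasing in CFI_end", {
  ends <- seq(180, 260, 10)
  v <- correct_cfi_cf(ends, 28, 115, 1.03)$cfi_30_120_cf
  expect_true(all(diff(v) > 0))
})

test_that("correction report flags degenerate input and scores identity", {
  tab <- data.frame(cfi_30_120_cf = c(200, 210, 220),
                    cfi_30_120_a = c(201, 211, 221),
                    cfi_reg_30_120 = c(200, 210, 220))
  r <- evaluate_correction(tab)
  expect_equal(r$correlations["cfi_30_120_cf", "cfi_reg_30_120"], 1)
  expect_equal(r$mad_cf_reg, 0)
  expect_equal(r$mad_a_reg, 1)
  tab$cfi_30_120_a <- 5
  expect_warning(r2 <- evaluate_correction(tab), "zero-variance")
  expect_true(is.na(r2$correlations["cfi_30_120_a", "cfi_reg_30_120"]))
  expect_error(evaluate_correction(tab[1:2, ]), ">= 3")
})
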