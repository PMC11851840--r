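test_that("CFI interpolation at a weight follows the line", {
  s <- linear_animal(bw0 = 30, adg = 1, slope = 2.5, days = 0:110)
  g <- linear_gfit(bw0 = 30, adg = 1, days = 0:110)
  # at an observed day's weight: that day's CFI
  expect_equal(cfi_at_weight(s, g, 75), s$cfi_kg[s$day == 45])
  # anywhere on the line: the line value
  for (w in c(33.3, 87.5, 119.9))
    expect_equal(cfi_at_weight(s, g, w), 2.5 * (w - 30), tolerance = 1e-9)
  expect_error(cfi_at_weight(s, g, 145), "outside")
})

test_that("interpolated CFI is close to generator truth", {
  sim <- simulate_population(sim_config(n_pigs = 6, seed = 51,
                                        anomaly_rates = rep(0, 8)))
  daily <- daily_records(sim$events)
  gfits <- fit_growth_all(daily)
  series <- build_cfi_series(daily)
  for (id in sim$truth$pig_id) {
    got <- cfi_at_weight(series[series$pig_id == id, ],
                         gfits[gfits$pig_id == id, ], 80)
    want <- true_cfi_at(sim$truth, id, 80)
    one_day_feed <- sim$truth$true_fcr[sim$truth$pig_id == id] *
      sim$truth$true_adg[sim$truth$pig_id == id]
    # interpolation day error and intake noise both stay within about a
    # day's worth of feed
    expect_lt(abs(got - want), 3 * one_day_feed)
  }
})

test_that("module FCR is feed over gain within the window", {
  s <- linear_animal(slope = 2.5)
  g <- linear_gfit()
  expect_equal(module_fcr(s, g, c(50, 90)), 2.5, tolerance = 1e-9)
  expect_equal(module_fcr(s, g, c(30, 120)), 2.5, tolerance = 1e-9)

  # two-phase animal: 2 kg feed per kg below 70 kg, 3 above
  days <- 0:110
  bw <- 30 + days
  cfi <- ifelse(bw <= 70, 2 * (bw - 30), 2 * 40 + 3 * (bw - 70))
  s2 <- data.frame(pig_id = "T", day = days, cfi_kg = cfi, bw_kg = bw)
  expect_equal(module_fcr(s2, g, c(80, 110)), 3, tolerance = 1e-9)
  expect_equal(module_fcr(s2, g, c(40, 60)), 2, tolerance = 1e-9)
})

test_that("rank-preserving populations give correlation 1 everywhere", {
  pop <- linear_population(slopes = seq(2.0, 3.0, length.out = 8))
  ws <- sliding_window_summary(pop$series, pop$gfits, pop$cfi_fits)
  expect_true(all(abs(ws$per_window$spearman - 1) < 1e-9))
  expect_equal(ws$summary$mean_spearman, rep(1, 8), tolerance = 1e-9)
  # the full-range window is the overall FCR itself
  full <- sliding_window_summary(pop$series, pop$gfits, pop$cfi_fits,
                                 sizes = 90)
  expect_equal(full$per_window$spearman, 1, tolerance = 1e-12)
  expect_equal(nrow(full$per_window), 1)
})

test_that("module FCR equals overall FCR exactly for the full window", {
  pop <- linear_population(slopes = c(2.1, 2.4, 2.8))
  for (i in seq_len(3)) {
    id <- sprintf("L%02d", i)
    m <- module_fcr(pop$series[pop$series$pig_id == id, ],
                    pop$gfits[pop$gfits$pig_id == id, ], c(30, 120))
    f <- pop$cfi_fits[pop$cfi_fits$pig_id == id, ]
    expect_equal(m, cfi_reg_values(f)$cfi_reg_30_120 / 90, tolerance = 1e-9)
  }
})

test_that("spearman matches a rank-then-pearson oracle", {
  set.seed(53)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.5)   # ties-free
  expect_equal(cor(x, y, method = "spearman"),
               cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("breakpoint search recovers a constructed elbow", {
  sizes <- seq(10, 80, 10)
  y <- ifelse(sizes <= 30, 0.3 + 0.04 * sizes,
              0.3 + 0.04 * 30 + 0.005 * (sizes - 30))
  bp <- fit_breakpoint(sizes, y)
  expect_lt(abs(bp$breakpoint - 30), 0.1 + 1e-9)
  expect_equal(bp$left_slope, 0.04, tolerance = 1e-6)
  expect_equal(bp$right_slope, 0.005, tolerance = 1e-6)
  expect_false(bp$no_elbow)
  expect_equal(select_optimal_module(bp), 30)
})

test_that("breakpoint fit equals the brute-force oracle", {
  y <- c(0.2, 0.4, 0.6, 0.62, 0.64, 0.66, 0.68, 0.70)
  sizes <- seq(10, 80, 10)
  bp <- fit_breakpoint(sizes, y)
  oracle <- breakpoint_oracle(sizes, y, bp$candidates)
  expect_equal(bp$breakpoint, oracle$bp)
  expect_equal(bp$rss, oracle$rss, tolerance = 1e-12)
  expect_lt(abs(bp$breakpoint - 30), 0.1 + 1e-9)
  expect_lte(bp$rss, bp$rss_line)
})

test_that("collinear points are reported as elbow-free", {
  sizes <- seq(10, 80, 10)
  bp <- fit_breakpoint(sizes, 0.1 + 0.01 * sizes)
  expect_true(bp$no_elbow)
  expect_equal(bp$rss, bp$rss_line, tolerance = 1e-10)
  expect_error(fit_breakpoint(c(10, 20, 30), c(1, 2, 3)), ">= 4")
})

test_that("optimal module size rounds to the 10-kg grid", {
  mk <- function(b) structure(list(breakpoint = b), class = "breakpoint_fit")
  expect_equal(select_optimal_module(mk(30.0)), 30)
  expect_equal(select_optimal_module(mk(27.3)), 30)
  expect_equal(select_optimal_module(mk(44.9)), 40)
})
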