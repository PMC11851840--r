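test_that("fixed seed gives identical output, distinct seeds differ", {
  a <- simulate_population(sim_config(n_pigs = 5, days = 40, seed = 9))
  b <- simulate_population(sim_config(n_pigs = 5, days = 40, seed = 9))
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
  c <- simulate_population(sim_config(n_pigs = 5, days = 40, seed = 10))
  expect_false(identical(a$events, c$events))
})

test_that("anomaly-free output passes every QC rule", {
  sim <- simulate_population(sim_config(n_pigs = 5, seed = 2,
                                        anomaly_rates = rep(0, 8)))
  qc <- apply_qc(sim$events)
  expect_equal(sum(qc$report$removed_by_rule), 0)
  expect_equal(qc$report$incomplete, 0)
  expect_equal(nrow(qc$clean), nrow(sim$events))
})

test_that("anomaly injection count matches the binomial rate", {
  rates <- c(0, 0.02, rep(0, 6))
  sim <- simulate_population(sim_config(n_pigs = 15, days = 85, seed = 4,
                                        anomaly_rates = rates))
  n <- nrow(sim$events)
  expect_gt(n, 10000)
  expected <- 0.02 * n
  tol <- 3 * sqrt(n * 0.02 * 0.98)
  expect_lt(abs(nrow(sim$anomalies) - expected), tol)
  expect_true(all(sim$anomalies$class == 2))
})

test_that("visit intakes conserve the drawn daily feed exactly", {
  sim <- simulate_population(sim_config(n_pigs = 8, days = 60, seed = 5,
                                        anomaly_rates = rep(0, 8)))
  by_day <- rowsum(sim$events$fiv_g,
                   paste(sim$events$pig_id, sim$events$day)) / 1000
  key <- paste(sim$daily_truth$pig_id, sim$daily_truth$day)
  got <- by_day[match(key, rownames(by_day)), 1]
  expect_lt(max(abs(got - sim$daily_truth$dfi_kg)), 1e-9)
})

test_that("generator moments match the configured herd parameters", {
  cfg <- sim_config(n_pigs = 500, seed = 6)
  sim <- simulate_population(cfg)
  dt <- sim$daily_truth
  # realized traits over each animal's 30-120 kg span, from the emitted
  # daily data (not the drawn parameters)
  stats <- do.call(rbind, lapply(split(dt, dt$pig_id), function(d) {
    k <- d$bw_true >= 30 & d$bw_true <= 120
    data.frame(adg = diff(range(d$bw_true[k])) / diff(range(d$day[k])),
               adfi = mean(d$dfi_kg[k]))
  }))
  se <- function(s) 3 * s / sqrt(nrow(stats))
  expect_lt(abs(mean(stats$adg) - cfg$adg_mean), se(cfg$adg_sd))
  adfi_target <- cfg$fcr_mean * cfg$adg_mean
  expect_lt(abs(mean(stats$adfi) - adfi_target), se(0.35))
  expect_lt(abs(mean(stats$adfi / stats$adg) - cfg$fcr_mean),
            se(cfg$fcr_sd))
  expect_lt(abs(mean(sim$truth$true_fcr) - cfg$fcr_mean), se(cfg$fcr_sd))
})

test_that("ground-truth CFI is nondecreasing, zero at entry, day inverse", {
  sim <- simulate_population(sim_config(n_pigs = 3, seed = 7))
  tr <- sim$truth
  for (id in tr$pig_id) {
    e <- tr$entry_bw[tr$pig_id == id]
    expect_equal(true_cfi_at(tr, id, e), 0)
    w <- seq(e, 120, length.out = 20)
    expect_true(all(diff(true_cfi_at(tr, id, w)) >= 0))
    d <- true_day_at(tr, id, 80)
    i <- match(id, tr$pig_id)
    expect_equal(logistic_bw(tr$bw_max[i], tr$xmid[i], tr$scal[i],
                             tr$age_offset[i] + d), 80, tolerance = 1e-9)
  }
  expect_error(true_cfi_at(tr, tr$pig_id[1], 10), "entry")
})

test_that("event files round-trip losslessly and report bad rows", {
  sim <- simulate_population(sim_config(n_pigs = 2, days = 10, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(sim$events, path)
  back <- read_events(path)
  expect_equal(back$fiv_g, sim$events$fiv_g, tolerance = 1e-12)
  expect_equal(back$pig_id, sim$events$pig_id)
  expect_equal(back$day, sim$events$day)

  empty <- sim$events[0, ]
  write_events(empty, path)
  expect_equal(nrow(read_events(path)), 0)

  path <- withr::local_tempfile(fileext = ".csv")
  write_events(sim$events[1:100, ], path)
  lines <- readLines(path)
  lines[51] <- "P0001,5,oops,12.0,100.0,30.0"
  writeLines(lines, path)
  expect_error(read_events(path), "51")
})

test_that("config validation rejects bad parameters", {
  expect_error(sim_config(n_pigs = 0))
  expect_error(sim_config(anomaly_rates = rep(0.2, 8)))
  expect_error(sim_config(anomaly_rates = c(-0.1, rep(0, 7))))
  expect_error(sim_config(bw_entry_sd = -1), "standard deviations")
})
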