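# exact intake surface used by several cases
intake_surface <- function(bw, otv) 5 * bw + 0.4 * otv + 0.01 * bw * otv + 20

make_intake_events <- function(n_pigs = 5, per_pig = 40, seed = 1,
                               pig_shift = 0, noise = 0) {
  set.seed(seed)
  ev <- do.call(rbind, lapply(seq_len(n_pigs), function(i) {
    bw <- runif(per_pig, 30, 120)
    otv <- runif(per_pig, 60, 900)
    shift <- if (pig_shift > 0) rnorm(1, 0, pig_shift) else 0
    data.frame(pig_id = sprintf("P%02d", i), day = seq_len(per_pig),
               visit = 1L, otv_s = otv,
               fiv_g = intake_surface(bw, otv) + shift +
                 rnorm(per_pig, 0, noise),
               bw_kg = bw, stringsAsFactors = FALSE)
  }))
  ev
}

test_that("outlier flagging uses strict 3-SD population bounds", {
  same <- data.frame(fiv_g = rep(250, 50))
  expect_false(any(flag_intake_outliers(same)))

  set.seed(3)
  fiv <- c(rnorm(1000, 250, 50), 5000)
  ev <- data.frame(fiv_g = fiv)
  fl <- flag_intake_outliers(ev)
  # hand oracle
  expect_identical(which(fl), which(abs(fiv - mean(fiv)) > 3 * sd(fiv)))
  expect_true(fl[1001])

  # a point exactly at mean + 3 sd is not flagged: for c(-v, 0 x 17, v)
  # the sd is v/3, so the extremes sit exactly on the boundary
  x <- c(-6, rep(0, 17), 6)
  expect_equal(sd(x), 2)
  expect_false(any(flag_intake_outliers(data.frame(fiv_g = x))))
})

test_that("intake model recovers an exact surface", {
  ev <- make_intake_events(noise = 0, pig_shift = 0)
  m <- fit_intake_model(ev)
  expect_equal(m$coef_bw, 5, tolerance = 1e-6)
  expect_equal(m$coef_t, 0.4, tolerance = 1e-6)
  expect_equal(m$coef_bw_t, 0.01, tolerance = 1e-6)
  expect_equal(m$intercept, 20, tolerance = 1e-4)
  expect_gte(m$marginal_r2, 1 - 1e-9)
  expect_gte(m$conditional_r2, m$marginal_r2)
})

test_that("animal-level intercepts raise conditional above marginal R2", {
  ev <- make_intake_events(n_pigs = 12, pig_shift = 30, noise = 5, seed = 4)
  m <- fit_intake_model(ev)
  expect_gt(m$conditional_r2, m$marginal_r2)
  expect_lte(m$conditional_r2, 1)
  expect_gte(m$marginal_r2, 0)
  expect_equal(length(m$random_intercepts), 12)
})

test_that("constant feeding time is rejected as singular", {
  ev <- make_intake_events()
  ev$otv_s <- 300
  expect_error(fit_intake_model(ev), "otv_s")
})

test_that("imputation restores clean values on noise-free data", {
  ev <- make_intake_events(pig_shift = 0, noise = 0, seed = 5)
  clean_fiv <- ev$fiv_g
  ev$fiv_g[c(7, 99)] <- c(9000, 12000)
  fl <- flag_intake_outliers(ev)
  expect_true(all(c(7, 99) %in% which(fl)))
  m <- fit_intake_model(ev[!fl, ])
  imp <- impute_flagged(m, ev, fl)
  expect_equal(imp$fiv_g[c(7, 99)], clean_fiv[c(7, 99)], tolerance = 1e-6)
  expect_identical(imp$fiv_g[!fl], ev$fiv_g[!fl])
  expect_identical(imp[, c("pig_id", "day", "otv_s", "bw_kg")],
                   ev[, c("pig_id", "day", "otv_s", "bw_kg")])
  # nothing newly flagged among imputed records
  expect_false(any(flag_intake_outliers(imp)[c(7, 99)]))
})

test_that("imputation uses the animal's random intercept when known", {
  ev <- make_intake_events(n_pigs = 10, per_pig = 60, pig_shift = 30,
                           noise = 3, seed = 6)
  clean_fiv <- ev$fiv_g
  hit <- c(11, 222, 480)
  ev$fiv_g[hit] <- c(8000, 9000, 10000)
  fl <- flag_intake_outliers(ev)
  expect_true(all(hit %in% which(fl)))
  m <- fit_intake_model(ev[!fl, ])
  imp <- impute_flagged(m, ev, fl)
  err_mixed <- abs(imp$fiv_g[hit] - clean_fiv[hit])
  # fixed-effects-only predictions miss by roughly the animal shift
  fixed_only <- m$intercept + m$coef_bw * ev$bw_kg[hit] +
    m$coef_t * ev$otv_s[hit] + m$coef_bw_t * ev$bw_kg[hit] * ev$otv_s[hit]
  expect_lt(mean(err_mixed), mean(abs(fixed_only - clean_fiv[hit])))
  expect_lt(max(err_mixed), 5 * m$sigma)
})

test_that("no flagged events means identity; unknown animals fall back", {
  ev <- make_intake_events()
  m <- fit_intake_model(ev)
  expect_identical(impute_flagged(m, ev, rep(FALSE, nrow(ev))), ev)

  stranger <- ev[1, ]
  stranger$pig_id <- "ZZ99"
  expect_message(
    imp <- impute_flagged(m, rbind(ev, stranger),
                          c(rep(FALSE, nrow(ev)), TRUE)),
    "unseen")
  want <- m$intercept + m$coef_bw * stranger$bw_kg +
    m$coef_t * stranger$otv_s + m$coef_bw_t * stranger$bw_kg * stranger$otv_s
  expect_equal(imp$fiv_g[nrow(imp)], want, tolerance = 1e-9)
})

test_that("end-to-end correction has bounded imputation error", {
  sim <- simulate_population(sim_config(n_pigs = 20, days = 60, seed = 23,
                                        anomaly_rates = rep(0.003, 8)))
  qc <- apply_qc(sim$events)
  out <- correct_intakes(qc$clean)
  # generator truth for surviving flagged visits
  key <- function(d) paste(d$pig_id, d$day, d$visit)
  imp_idx <- which(out$flagged)
  if (length(imp_idx) > 0) {
    truth_map <- setNames(sim$anomalies$clean_fiv, key(sim$anomalies))
    tv <- truth_map[key(out$events[imp_idx, ])]
    keep <- !is.na(tv)
    if (any(keep)) {
      mae <- mean(abs(out$events$fiv_g[imp_idx][keep] - tv[keep]))
      expect_lt(mae, 2 * out$model$sigma)
    }
  }
  succeed()
})
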