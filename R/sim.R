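#' Configuration for the synthetic AFS herd generator
#'
#' Builds the parameter set for [simulate_population()]. Defaults are
#' calibrated to a growing Yorkshire boar population on an automatic feeding
#' station (AFS): entry body weight 28.30 +/- 1.02 kg, average daily gain
#' (ADG, the 30-120 kg chord) 1.02 +/- 0.12 kg/d, feed conversion ratio
#' (FCR) 2.31 +/- 0.27 kg/kg, 7.93 visits per day and a feed rate of
#' 45.65 +/- 23.94 g/min.
#'
#' Per-animal growth follows a three-parameter logistic
#' \eqn{BW = BW_{max} / (1 + e^{(x_{mid} - age)/scal})}. Rather than drawing
#' \eqn{scal} independently, each animal's ADG and \eqn{BW_{max}} are drawn
#' and \eqn{scal} is derived from the 30-to-120 kg transit time
#' \eqn{90/ADG}, so the realized ADG distribution matches the configured
#' moments exactly.
#'
#' @param n_pigs number of animals.
#' @param days test duration in days (day 0 = entry).
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @param bw_entry_mean,bw_entry_sd entry body weight distribution (kg).
#' @param adg_mean,adg_sd 30-120 kg average daily gain distribution (kg/d).
#' @param bwmax_mean,bwmax_sd logistic asymptote distribution (kg).
#' @param fcr_mean,fcr_sd feed conversion ratio distribution (kg feed / kg gain).
#' @param visits_per_day_mean Poisson mean of feeder visits per day.
#' @param feed_rate_mean,feed_rate_sd per-animal feed rate distribution (g/min),
#'   truncated to 25-340 g/min so clean visits satisfy all QC rules.
#' @param bw_noise_sd daily body-weight observation noise (kg).
#' @param bw_jitter_sd within-day body-weight jitter across visits (kg).
#' @param dfi_noise_sd daily feed intake noise (kg/d).
#' @param age_offset age in days at test entry (so xmid is an age).
#' @param anomaly_rates numeric length 8: per-visit probability of injecting
#'   an anomaly of each QC error class 1-8.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_pigs = 150L, days = 130L, seed = 1L,
                       bw_entry_mean = 28.30, bw_entry_sd = 1.02,
                       adg_mean = 1.02, adg_sd = 0.12,
                       bwmax_mean = 170, bwmax_sd = 10,
                       fcr_mean = 2.31, fcr_sd = 0.27,
                       visits_per_day_mean = 7.93,
                       feed_rate_mean = 45.65, feed_rate_sd = 23.94,
                       bw_noise_sd = 1.0, bw_jitter_sd = 0.2,
                       dfi_noise_sd = 0.35,
                       age_offset = 70,
                       anomaly_rates = rep(0.0015, 8)) {
  stopifnot(n_pigs >= 1, days >= 3,
            length(anomaly_rates) == 8,
            all(anomaly_rates >= 0), all(anomaly_rates <= 1),
            sum(anomaly_rates) <= 1)
  sds <- c(bw_entry_sd, adg_sd, bwmax_sd, fcr_sd, feed_rate_sd,
           bw_noise_sd, bw_jitter_sd, dfi_noise_sd)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  cfg <- list(n_pigs = as.integer(n_pigs), days = as.integer(days),
              seed = as.integer(seed),
              bw_entry_mean = bw_entry_mean, bw_entry_sd = bw_entry_sd,
              adg_mean = adg_mean, adg_sd = adg_sd,
              bwmax_mean = bwmax_mean, bwmax_sd = bwmax_sd,
              fcr_mean = fcr_mean, fcr_sd = fcr_sd,
              visits_per_day_mean = visits_per_day_mean,
              feed_rate_mean = feed_rate_mean, feed_rate_sd = feed_rate_sd,
              bw_noise_sd = bw_noise_sd, bw_jitter_sd = bw_jitter_sd,
              dfi_noise_sd = dfi_noise_sd, age_offset = age_offset,
              anomaly_rates = as.numeric(anomaly_rates))
  class(cfg) <- "sim_config"
  cfg
}

# truncated-normal draw by resampling; never emits out-of-range values
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# per-visit feed cap (g); paired with the 25 g/min rate floor this keeps
# every clean visit inside all eight QC rule regions (fiv < 2000 g,
# otv < 3600 s)
.visit_cap_g <- 1400
.rate_floor <- 25
.rate_ceiling <- 340

#' Simulate a visit-level AFS dataset with ground truth
#'
#' Generates per-animal logistic body-weight trajectories, daily feed intake
#' tied to gain through each animal's FCR, a Poisson visit structure that
#' splits daily feed across visits (exact conservation), occupation times
#' from per-animal feed rates, and injected anomalies of the eight QC error
#' classes at configured rates. With all anomaly rates zero the output
#' passes every QC rule by construction.
#'
#' Day 0 intake is zero (entry day), so the noise-free cumulative intake at
#' body weight w equals `true_fcr * (w - entry_bw)` exactly.
#'
#' @param config a [sim_config()].
#' @return list of class `pigfcr_sim` with elements
#'   * `events`: data.frame `pig_id, day, visit, otv_s, fiv_g, bw_kg`
#'   * `truth`: per-animal ground truth (`true_adg`, `true_fcr`, `bw_max`,
#'     `xmid`, `scal`, `entry_bw`, `true_slope` = least-squares slope of the
#'     noise-free trajectory over the test period, `feed_rate`, `age_offset`)
#'   * `daily_truth`: noise-free daily body weight and drawn daily feed
#'   * `anomalies`: injected anomaly labels with the clean field values
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_pigs
  days <- config$days
  d <- 0:days

  entry_bw <- rnorm_trunc(n, config$bw_entry_mean, config$bw_entry_sd, 24, 34)
  adg   <- rnorm_trunc(n, config$adg_mean, config$adg_sd, 0.5, 1.7)
  bwmax <- rnorm_trunc(n, config$bwmax_mean, config$bwmax_sd, 145, Inf)
  fcr   <- rnorm_trunc(n, config$fcr_mean, config$fcr_sd, 1.2, Inf)
  rate  <- rnorm_trunc(n, config$feed_rate_mean, config$feed_rate_sd,
                       .rate_floor, .rate_ceiling)

  # scal from the 30->120 kg transit time 90/adg on the logistic
  Lfun <- log(120 * (bwmax - 30) / (30 * (bwmax - 120)))
  scal <- 90 / (adg * Lfun)
  xmid <- config$age_offset + scal * log(bwmax / entry_bw - 1)

  # noise-free trajectories: n x (days+1)
  age <- config$age_offset + d
  bw_true <- bwmax / (1 + exp((xmid - rep(age, each = n)) / scal))
  dim(bw_true) <- c(n, days + 1)

  # least-squares slope of the noise-free trajectory (the regression estimand)
  dc <- d - mean(d)
  true_slope <- as.vector(bw_true %*% dc) / sum(dc^2)

  gain <- cbind(0, t(diff(t(bw_true))))             # day 0 intake = 0
  dfi <- fcr * gain +
    matrix(stats::rnorm(n * (days + 1), 0, config$dfi_noise_sd), n)
  dfi[, 1] <- 0
  dfi <- pmax(dfi, 0)                               # kg/day

  bw_day <- bw_true + matrix(stats::rnorm(n * (days + 1), 0,
                                          config$bw_noise_sd), n)
  bad <- bw_day <= 0
  while (any(bad)) {                                # never emit nonpositive BW
    bw_day[bad] <- bw_true[bad] + stats::rnorm(sum(bad), 0, config$bw_noise_sd)
    bad <- bw_day <= 0
  }

  # long pig-day table
  pig <- rep(seq_len(n), times = days + 1)
  day <- rep(d, each = n)
  daily_g <- as.vector(dfi) * 1000
  nv <- stats::rpois(n * (days + 1), config$visits_per_day_mean)
  nv <- pmax(nv, ceiling(daily_g / .visit_cap_g * 2), 1L)

  # expand to visits; order by (pig, day)
  o <- order(pig, day)
  pig <- pig[o]; day <- day[o]; daily_g <- daily_g[o]; nv <- nv[o]
  bw_day_long <- as.vector(bw_day)[o]

  m <- sum(nv)
  row_id <- rep(seq_along(nv), times = nv)
  visit <- sequence(nv)

  # split daily feed: equal base +/- bounded uniform jitter (sum exact,
  # each share in (0, 2*base) so shares stay below the visit cap)
  base <- daily_g[row_id] / nv[row_id]
  r <- stats::runif(m, 0, base)
  rbar <- rep(as.vector(rowsum(r, row_id)) / nv, times = nv)
  fiv <- base + (r - rbar)
  fiv[base == 0] <- 0

  rate_v <- pmin(.rate_ceiling,
                 pmax(.rate_floor, rate[pig[row_id]] + stats::rnorm(m, 0, 5)))
  otv <- fiv / rate_v * 60
  otv[fiv == 0] <- stats::runif(sum(fiv == 0), 30, 120)

  bw_v <- bw_day_long[row_id] + stats::rnorm(m, 0, config$bw_jitter_sd)

  events <- data.frame(pig_id = sprintf("P%04d", pig[row_id]),
                       day = day[row_id], visit = visit,
                       otv_s = otv, fiv_g = fiv, bw_kg = bw_v,
                       stringsAsFactors = FALSE)

  # anomaly injection: one class at most per visit, class drawn by
  # partitioning [0,1) with the per-class rates
  rates <- config$anomaly_rates
  cls <- integer(m)
  if (sum(rates) > 0) {
    u <- stats::runif(m)
    edges <- cumsum(rates)
    cls <- findInterval(u, c(0, edges), left.open = TRUE)
    cls[cls > 8] <- 0L   # beyond the last edge: clean
    cls[u >= edges[8]] <- 0L
  }
  idx <- which(cls > 0)
  anomalies <- data.frame(pig_id = events$pig_id[idx],
                          day = events$day[idx], visit = events$visit[idx],
                          class = cls[idx],
                          clean_fiv = events$fiv_g[idx],
                          clean_otv = events$otv_s[idx],
                          stringsAsFactors = FALSE)
  if (length(idx) > 0) {
    k <- cls[idx]
    nf <- events$fiv_g[idx]; no <- events$otv_s[idx]
    u1 <- stats::runif(length(idx)); u2 <- stats::runif(length(idx))
    # class regions sit strictly inside the violating set of the matching
    # rule and avoid lower-index rules, so attribution is unambiguous
    nf[k == 1] <- -1 - 499 * u1[k == 1]                       # FIV < 0
    nf[k == 2] <- 2001 + 2999 * u1[k == 2]                    # FIV > 2000
    nf[k == 3] <- 21 + 479 * u1[k == 3]; no[k == 3] <- 0      # FIV>20, OTV=0
    no[k == 4] <- -1 - 599 * u1[k == 4]                       # OTV < 0
    no[k == 5] <- 3601 + 16399 * u1[k == 5]                   # OTV > 3600
    sel <- k == 6                                             # FRV>500, FIV<50
    nf[sel] <- 1 + 48 * u1[sel]
    no[sel] <- nf[sel] / (501 + 1499 * u2[sel]) * 60
    sel <- k == 7                                             # FRV>350, FIV>50
    nf[sel] <- 51 + 1449 * u1[sel]
    no[sel] <- nf[sel] / (351 + 649 * u2[sel]) * 60
    sel <- k == 8                                             # FRV=0, OTV>500
    nf[sel] <- 0
    no[sel] <- 501 + 3099 * u1[sel]
    events$fiv_g[idx] <- nf
    events$otv_s[idx] <- no
  }

  truth <- data.frame(pig_id = sprintf("P%04d", seq_len(n)),
                      true_adg = adg, true_fcr = fcr, bw_max = bwmax,
                      xmid = xmid, scal = scal, entry_bw = entry_bw,
                      true_slope = true_slope, feed_rate = rate,
                      age_offset = config$age_offset,
                      stringsAsFactors = FALSE)
  daily_truth <- data.frame(pig_id = sprintf("P%04d", pig),
                            day = day, bw_true = as.vector(bw_true)[o],
                            dfi_kg = daily_g / 1000,
                            stringsAsFactors = FALSE)
  out <- list(events = events, truth = truth, daily_truth = daily_truth,
              anomalies = anomalies, config = config)
  class(out) <- "pigfcr_sim"
  out
}

#' @export
print.pigfcr_sim <- function(x, ...) {
  cat("Synthetic AFS herd:", nrow(x$truth), "pigs,",
      x$config$days, "days,", nrow(x$events), "visits,",
      nrow(x$anomalies), "injected anomalies\n")
  invisible(x)
}

#' Ground-truth cumulative feed intake at a body weight
#'
#' Noise-free cumulative intake accumulated from test entry to body weight
#' `w`: `true_fcr * (w - entry_bw)`. Nondecreasing in `w`, zero at entry.
#'
#' @param truth the `truth` data.frame from [simulate_population()].
#' @param pig_id animal identifier.
#' @param w body weight (kg), at or above the animal's entry weight.
#' @return kg of feed.
#' @export
true_cfi_at <- function(truth, pig_id, w) {
  i <- match(pig_id, truth$pig_id)
  if (is.na(i)) stop("unknown pig_id: ", pig_id)
  if (any(w < truth$entry_bw[i] - 1e-9))
    stop("weight below entry weight for ", pig_id)
  truth$true_fcr[i] * (w - truth$entry_bw[i])
}

#' Ground-truth day (since entry) at which a body weight is reached
#'
#' Inverts the animal's noise-free logistic trajectory.
#'
#' @inheritParams true_cfi_at
#' @return fractional days since test entry.
#' @export
true_day_at <- function(truth, pig_id, w) {
  i <- match(pig_id, truth$pig_id)
  if (is.na(i)) stop("unknown pig_id: ", pig_id)
  if (any(w <= 0 | w >= truth$bw_max[i]))
    stop("weight outside (0, bw_max) for ", pig_id)
  truth$xmid[i] + truth$scal[i] * log(w / (truth$bw_max[i] - w)) -
    truth$age_offset[i]
}

#' Write / read visit-level feeding events
#'
#' Comma-separated with header `pig_id,day,visit,otv_s,fiv_g,bw_kg`.
#' `read_events()` validates every row and reports malformed rows with
#' their file line numbers.
#'
#' @param events events data.frame.
#' @param path file path.
#' @return `write_events()` the path invisibly; `read_events()` the events.
#' @export
write_events <- function(events, path) {
  cols <- c("pig_id", "day", "visit", "otv_s", "fiv_g", "bw_kg")
  stopifnot(all(cols %in% names(events)))
  utils::write.csv(events[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  cols <- c("pig_id", "day", "visit", "otv_s", "fiv_g", "bw_kg")
  if (!identical(names(raw), cols))
    stop("bad header: expected ", paste(cols, collapse = ","))
  num <- raw[, -1]
  conv <- suppressWarnings(lapply(num, as.numeric))
  bad <- Reduce(`|`, lapply(conv, is.na)) & !Reduce(`|`, lapply(num, is.na))
  bad <- bad | Reduce(`|`, lapply(num, function(x) x == "" | is.na(x)))
  if (any(bad))
    stop("malformed rows at file line(s): ",
         paste(which(bad) + 1L, collapse = ", "))
  out <- data.frame(pig_id = raw$pig_id, conv, stringsAsFactors = FALSE)
  names(out) <- cols
  out$day <- as.integer(out$day)
  out$visit <- as.integer(out$visit)
  out
}
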