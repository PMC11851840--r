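#' Aggregate visit-level events into per-animal daily records
#'
#' Daily feed intake is the sum of visit intakes (kg); the representative
#' body weight is the mean of the visit weights for that day.
#'
#' @param events clean visit-level events.
#' @return data.frame `pig_id, day, dfi_kg, bw_kg, n_visits`, sorted by
#'   animal and day.
#' @export
daily_records <- function(events) {
  key <- paste(events$pig_id, sprintf("%06d", events$day), sep = "|")
  f <- factor(key)
  sums <- rowsum(cbind(fiv = events$fiv_g, bw = events$bw_kg),
                 f, reorder = TRUE)
  n <- as.vector(table(f))
  parts <- strsplit(levels(f), "|", fixed = TRUE)
  out <- data.frame(
    pig_id = vapply(parts, `[`, "", 1L),
    day = as.integer(vapply(parts, `[`, "", 2L)),
    dfi_kg = sums[, "fiv"] / 1000,
    bw_kg = sums[, "bw"] / n,
    n_visits = n,
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$pig_id, out$day), , drop = FALSE]
}

#' Robust regression of body weight on day for one animal
#'
#' Huber M-estimation (tuning constant 1.345, iteratively reweighted least
#' squares, up to 100 iterations) of `bw ~ day`; the slope is the animal's
#' average daily gain estimate and the pseudo-R-squared is the squared
#' Pearson correlation between fitted and observed weights.
#'
#' @param daily per-animal daily records (`day`, `bw_kg`; optionally
#'   `pig_id`).
#' @param threshold pseudo-R-squared retention threshold.
#' @return one-row data.frame `pig_id, slope, intercept, pseudo_r2, n_days,
#'   day_min, day_max, retained, valid`.
#' @export
fit_robust_growth <- function(daily, threshold = 0.8) {
  pig <- if (!is.null(daily$pig_id)) daily$pig_id[1] else NA_character_
  day <- daily$day
  bw <- daily$bw_kg
  n_days <- length(unique(day))
  no_fit <- data.frame(pig_id = pig, slope = NA_real_, intercept = NA_real_,
                       pseudo_r2 = NA_real_, n_days = n_days,
                       day_min = suppressWarnings(min(day)),
                       day_max = suppressWarnings(max(day)),
                       retained = FALSE, valid = FALSE,
                       stringsAsFactors = FALSE)
  if (n_days < 3) return(no_fit)
  if (stats::sd(bw) == 0) {
    # degenerate flat trajectory: exact fit with zero slope
    return(data.frame(pig_id = pig, slope = 0, intercept = bw[1],
                      pseudo_r2 = 1, n_days = n_days,
                      day_min = min(day), day_max = max(day),
                      retained = TRUE, valid = TRUE,
                      stringsAsFactors = FALSE))
  }
  ols <- stats::lm(bw ~ day)
  if (max(abs(stats::resid(ols))) < 1e-8) {
    # exact line: the M-estimate coincides with OLS (zero-scale guard)
    fit <- ols
  } else {
    fit <- tryCatch(
      MASS::rlm(bw ~ day, maxit = 100),
      error = function(e) ols)
  }
  fitted <- stats::fitted(fit)
  r2 <- if (stats::sd(fitted) == 0) {
    if (all(abs(bw - fitted) < 1e-8)) 1 else 0
  } else stats::cor(fitted, bw)^2
  co <- stats::coef(fit)
  data.frame(pig_id = pig, slope = unname(co[2]), intercept = unname(co[1]),
             pseudo_r2 = r2, n_days = n_days,
             day_min = min(day), day_max = max(day),
             retained = r2 >= threshold, valid = TRUE,
             stringsAsFactors = FALSE)
}

#' Robust growth fits for every animal
#'
#' @param daily_df daily records for the whole population.
#' @inheritParams fit_robust_growth
#' @return data.frame with one [fit_robust_growth()] row per animal.
#' @export
fit_growth_all <- function(daily_df, threshold = 0.8) {
  parts <- split(daily_df, daily_df$pig_id)
  out <- do.call(rbind, lapply(parts, fit_robust_growth,
                               threshold = threshold))
  row.names(out) <- NULL
  out
}

#' Gate animals on growth-fit quality
#'
#' Retains animals whose pseudo-R-squared is at or above the threshold
#' (boundary inclusive), in input order.
#'
#' @param fits growth-fit table from [fit_growth_all()].
#' @param threshold retention threshold.
#' @return character vector of retained animal ids.
#' @export
gate_animals <- function(fits, threshold = 0.8) {
  keep <- fits$valid & !is.na(fits$pseudo_r2) & fits$pseudo_r2 >= threshold
  ids <- fits$pig_id[keep]
  if (length(ids) == 0 && nrow(fits) > 0)
    warning("no animals passed the growth-fit gate (threshold ",
            threshold, ")")
  ids
}

#' Three-parameter logistic growth curve
#'
#' `BW(day) = bw_max / (1 + exp((xmid - day) / scal))`: `bw_max` is the
#' mature-weight asymptote, `xmid` the age at half `bw_max`, and `scal`
#' the steepness (strictly increasing in `day` when `scal > 0`).
#'
#' @param bw_max asymptotic body weight (kg).
#' @param xmid age at half the asymptote (days).
#' @param scal steepness parameter (days), nonzero.
#' @param day age (days); vectorized.
#' @return predicted body weight (kg).
#' @export
logistic_bw <- function(bw_max, xmid, scal, day) {
  if (any(scal == 0)) stop("scal must be nonzero")
  bw_max / (1 + exp((xmid - day) / scal))
}

#' Fit the population logistic growth model
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the three-parameter
#' logistic on pooled daily records. Initialization: asymptote at 1.05 x
#' the maximum observed weight, midpoint at the day whose weight is nearest
#' half that asymptote, steepness at one eighth of the day range.
#'
#' @param daily_df pooled daily records (`day`, `bw_kg`).
#' @return list of class `logistic_fit`: `bw_max`, `xmid`, `scal`, `rss`,
#'   `converged`.
#' @export
fit_logistic <- function(daily_df) {
  day <- daily_df$day
  bw <- daily_df$bw_kg
  if (length(unique(day)) < 3) stop("need >= 3 distinct days")
  bw_max0 <- 1.05 * max(bw)
  xmid0 <- day[which.min(abs(bw - bw_max0 / 2))]
  scal0 <- diff(range(day)) / 8
  start <- list(bw_max = bw_max0, xmid = xmid0, scal = scal0)
  fit <- tryCatch(
    minpack.lm::nlsLM(bw ~ bw_max / (1 + exp((xmid - day) / scal)),
                      data = data.frame(day = day, bw = bw), start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    res <- bw - logistic_bw(start$bw_max, start$xmid, start$scal, day)
    out <- list(bw_max = start$bw_max, xmid = start$xmid, scal = start$scal,
                rss = sum(res^2), converged = FALSE)
  } else {
    co <- stats::coef(fit)
    conv <- isTRUE(fit$convInfo$isConv) &&
      stats::sd(bw) > 0          # honest flag: flat data never "converges"
    out <- list(bw_max = unname(co["bw_max"]), xmid = unname(co["xmid"]),
                scal = unname(co["scal"]),
                rss = sum(stats::resid(fit)^2), converged = conv)
  }
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic growth fit: bw_max = %.2f kg, xmid = %.2f d, scal = %.2f d (rss %.2f, %s)\n",
    x$bw_max, x$xmid, x$scal, x$rss,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Day at which an animal's fitted growth line crosses a target weight
#'
#' Inverts the robust-fit line (not the raw noisy weights): fractional
#' `day = (target - intercept) / slope`, required to lie within the
#' animal's observed day span.
#'
#' @param fit one row of the growth-fit table.
#' @param target body weight (kg).
#' @return fractional days since entry.
#' @export
day_at_weight <- function(fit, target) {
  if (!isTRUE(fit$valid) || is.na(fit$slope) || fit$slope == 0)
    stop("no valid growth line for ", fit$pig_id)
  d <- (target - fit$intercept) / fit$slope
  lo <- fit$day_min; hi <- fit$day_max
  if (any(d < lo - 1e-9 | d > hi + 1e-9))
    stop(sprintf(
      "target %.1f kg outside the fitted span of %s (days %g-%g, %.1f-%.1f kg)",
      target[which(d < lo - 1e-9 | d > hi + 1e-9)][1], fit$pig_id, lo, hi,
      fit$intercept + fit$slope * lo, fit$intercept + fit$slope * hi))
  d
}
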