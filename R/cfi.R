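#' Build per-animal cumulative feed intake series
#'
#' Running sum of daily feed per animal, paired with that day's body
#' weight. CFI at the entry day equals that day's intake.
#'
#' @param daily_df daily records (`pig_id, day, dfi_kg, bw_kg`), sorted by
#'   animal and day.
#' @return data.frame `pig_id, day, cfi_kg, bw_kg`.
#' @export
build_cfi_series <- function(daily_df) {
  key <- paste(daily_df$pig_id, daily_df$day)
  if (anyDuplicated(key))
    stop("duplicate (pig, day) record(s): ", key[anyDuplicated(key)])
  o <- order(daily_df$pig_id, daily_df$day)
  d <- daily_df[o, , drop = FALSE]
  cfi <- stats::ave(d$dfi_kg, d$pig_id, FUN = cumsum)
  data.frame(pig_id = d$pig_id, day = d$day, cfi_kg = cfi,
             bw_kg = d$bw_kg, stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit the body-weight to CFI line for one animal
#'
#' Ordinary least squares of CFI on BW over the records whose weight lies
#' in the start window (default 25-50 kg) or the end window (default
#' 100-140 kg). Reports the best-fit slope and intercept (the coefficient
#' A), the R-squared, the endpoint quantities (entry weight, final weight,
#' final CFI), and CF = best-fit slope / endpoint-chord slope, where the
#' chord slope is `cfi_end / (bw_end - bw_in)` (CFI accumulates from zero
#' at entry).
#'
#' @param series per-animal CFI series (`day, cfi_kg, bw_kg`; optionally
#'   `pig_id`), sorted by day.
#' @param start_window,end_window weight ranges (kg) contributing points.
#' @param threshold R-squared retention threshold.
#' @return one-row data.frame `pig_id, slope_best, intercept_a, r2, bw_in,
#'   bw_end, cfi_end, cf, n_start, n_end, retained`.
#' @export
fit_cfi_line <- function(series, start_window = c(25, 50),
                         end_window = c(100, 140), threshold = 0.9) {
  pig <- if (!is.null(series$pig_id)) series$pig_id[1] else NA_character_
  bw <- series$bw_kg
  cfi <- series$cfi_kg
  in_start <- bw >= start_window[1] & bw <= start_window[2]
  in_end <- bw >= end_window[1] & bw <= end_window[2]
  if (sum(in_start) < 2)
    stop("animal ", pig, ": fewer than 2 points in the start window [",
         start_window[1], ", ", start_window[2], "] kg")
  if (sum(in_end) < 2)
    stop("animal ", pig, ": fewer than 2 points in the end window [",
         end_window[1], ", ", end_window[2], "] kg")
  sel <- in_start | in_end
  fit <- stats::lm(cfi[sel] ~ bw[sel])
  co <- stats::coef(fit)
  tss <- sum((cfi[sel] - mean(cfi[sel]))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  bw_in <- bw[1]
  bw_end <- bw[length(bw)]
  cfi_end <- cfi[length(cfi)]
  if (bw_end == bw_in)
    stop("animal ", pig, ": endpoint weights equal, chord slope undefined")
  chord <- cfi_end / (bw_end - bw_in)
  data.frame(pig_id = pig, slope_best = unname(co[2]),
             intercept_a = unname(co[1]), r2 = r2,
             bw_in = bw_in, bw_end = bw_end, cfi_end = cfi_end,
             cf = unname(co[2]) / chord,
             n_start = sum(in_start), n_end = sum(in_end),
             retained = r2 >= threshold,
             stringsAsFactors = FALSE)
}

#' BW-CFI line fits for every animal
#'
#' Animals whose series cannot support a fit (too few points in a window,
#' degenerate endpoints) are dropped with a message.
#'
#' @param series_df population CFI series.
#' @inheritParams fit_cfi_line
#' @return data.frame of [fit_cfi_line()] rows.
#' @export
fit_cfi_lines <- function(series_df, start_window = c(25, 50),
                          end_window = c(100, 140), threshold = 0.9) {
  parts <- split(series_df, series_df$pig_id)
  rows <- lapply(parts, function(s)
    tryCatch(fit_cfi_line(s, start_window, end_window, threshold),
             error = function(e) NULL))
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    message(dropped, " animal(s) dropped from the BW-CFI line fit")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  row.names(out) <- NULL
  out
}

#' Population correction coefficients
#'
#' Arithmetic means and standard deviations of CF and A over retained
#' animals (R-squared at or above the retention threshold).
#'
#' @param fits BW-CFI line fits from [fit_cfi_lines()].
#' @return list of class `correction_coefficients`: `cf_mean, cf_sd,
#'   a_mean, a_sd, n, cf_min, cf_max, a_min, a_max`.
#' @export
population_coefficients <- function(fits) {
  f <- fits[fits$retained, , drop = FALSE]
  if (nrow(f) == 0) stop("no retained animals")
  out <- list(cf_mean = mean(f$cf), cf_sd = stats::sd(f$cf),
              a_mean = mean(f$intercept_a), a_sd = stats::sd(f$intercept_a),
              cf_min = min(f$cf), cf_max = max(f$cf),
              a_min = min(f$intercept_a), a_max = max(f$intercept_a),
              n = nrow(f))
  class(out) <- "correction_coefficients"
  out
}

#' @export
print.correction_coefficients <- function(x, ...) {
  cat(sprintf("CFI correction coefficients (n = %d retained):\n", x$n))
  cat(sprintf("  CF %.3f +/- %.3f  [%.3f, %.3f]\n",
              x$cf_mean, x$cf_sd, x$cf_min, x$cf_max))
  cat(sprintf("  A  %.2f +/- %.2f kg  [%.2f, %.2f]\n",
              x$a_mean, x$a_sd, x$a_min, x$a_max))
  invisible(x)
}

#' CF-model standardization of cumulative feed intake to 30-120 kg
#'
#' \deqn{CFI_{120CF} = CFI_{end} - (BW_{end} - 120) \cdot
#'   \frac{CFI_{end}}{BW_{end} - BW_{in}} \cdot CF}
#' \deqn{CFI_{30CF} = (30 - BW_{in}) \cdot
#'   \frac{CFI_{end}}{BW_{end} - BW_{in}} \cdot CF}
#' When `bw_end` is exactly 120 the 120-kg value equals `cfi_end` for any
#' CF. Vectorized over animals.
#'
#' @param cfi_end cumulative feed intake at the end of measurement (kg).
#' @param bw_in,bw_end body weight at start and end of measurement (kg),
#'   `bw_end > bw_in`.
#' @param cf the CF correction coefficient.
#' @return data.frame `cfi_120_cf, cfi_30_cf, cfi_30_120_cf`.
#' @export
correct_cfi_cf <- function(cfi_end, bw_in, bw_end, cf) {
  if (any(bw_end <= bw_in)) stop("bw_end must exceed bw_in")
  s <- cfi_end / (bw_end - bw_in) * cf
  cfi_120 <- cfi_end - (bw_end - 120) * s
  cfi_30 <- (30 - bw_in) * s
  data.frame(cfi_120_cf = cfi_120, cfi_30_cf = cfi_30,
             cfi_30_120_cf = cfi_120 - cfi_30)
}

#' A-model standardization of cumulative feed intake to 30-120 kg
#'
#' \deqn{CFI_{120A} = CFI_{end} + (120 - BW_{end}) \cdot
#'   \frac{CFI_{end} - A}{BW_{end}}}
#' \deqn{CFI_{30A} = (30 - BW_{in}) \cdot \frac{CFI_{end} - A}{BW_{end}}}
#' A is the intercept of the BW-CFI regression line (kg of feed).
#'
#' @inheritParams correct_cfi_cf
#' @param a the A correction coefficient (kg).
#' @return data.frame `cfi_120_a, cfi_30_a, cfi_30_120_a`.
#' @export
correct_cfi_a <- function(cfi_end, bw_in, bw_end, a) {
  if (any(bw_end == 0)) stop("bw_end must be nonzero")
  s <- (cfi_end - a) / bw_end
  cfi_120 <- cfi_end + (120 - bw_end) * s
  cfi_30 <- (30 - bw_in) * s
  data.frame(cfi_120_a = cfi_120, cfi_30_a = cfi_30,
             cfi_30_120_a = cfi_120 - cfi_30)
}

#' Regression-based CFI for 30-120 kg (the unbiased reference)
#'
#' Values of each animal's fitted BW-CFI line, anchored at the entry
#' weight (line value minus line value at `bw_in`), so that
#' `cfi_reg_120 - cfi_reg_30 = slope * 90` identically.
#'
#' @param fit one or more rows of the BW-CFI line-fit table.
#' @return data.frame `cfi_reg_30_120, cfi_reg_120, cfi_reg_30`.
#' @export
cfi_reg_values <- function(fit) {
  data.frame(cfi_reg_30_120 = fit$slope_best * 90,
             cfi_reg_120 = fit$slope_best * (120 - fit$bw_in),
             cfi_reg_30 = fit$slope_best * (30 - fit$bw_in))
}

#' Apply population-mean corrections to every animal
#'
#' Combines the CF-model, the A-model (population-mean coefficients
#' applied uniformly, as a breeding program would publish a single
#' correction factor) and the per-animal regression reference into one
#' table.
#'
#' @param fits BW-CFI line fits (retained animals are used).
#' @param coefs [population_coefficients()] output, or a list with
#'   `cf_mean` and `a_mean`.
#' @return data.frame with `pig_id`, the CF-model, A-model and regression
#'   30/120 kg values.
#' @export
correct_population <- function(fits, coefs) {
  f <- fits[fits$retained, , drop = FALSE]
  cf <- correct_cfi_cf(f$cfi_end, f$bw_in, f$bw_end, coefs$cf_mean)
  a <- correct_cfi_a(f$cfi_end, f$bw_in, f$bw_end, coefs$a_mean)
  reg <- cfi_reg_values(f)
  cbind(data.frame(pig_id = f$pig_id, stringsAsFactors = FALSE), cf, a, reg)
}

#' Correlation and error report for the corrected CFI values
#'
#' Pairwise Pearson correlations among the CF-model, A-model and
#' regression-based 30-120 kg values, with mean absolute differences and
#' their standard deviations. Zero-variance columns give NA correlations
#' with a warning.
#'
#' @param corrected table from [correct_population()] (needs
#'   `cfi_30_120_cf`, `cfi_30_120_a`, `cfi_reg_30_120`), at least 3 rows.
#' @return list of class `correction_report`.
#' @export
evaluate_correction <- function(corrected) {
  if (nrow(corrected) < 3) stop("need >= 3 animals")
  v <- corrected[, c("cfi_30_120_cf", "cfi_30_120_a", "cfi_reg_30_120")]
  if (any(vapply(v, stats::sd, 0) == 0)) {
    warning("zero-variance column: correlations undefined")
    cors <- matrix(NA_real_, 3, 3, dimnames = list(names(v), names(v)))
  } else {
    cors <- stats::cor(v)
  }
  out <- list(
    correlations = cors,
    mad_cf_reg = mean(abs(v$cfi_30_120_cf - v$cfi_reg_30_120)),
    sd_cf_reg = stats::sd(v$cfi_30_120_cf - v$cfi_reg_30_120),
    mad_a_reg = mean(abs(v$cfi_30_120_a - v$cfi_reg_30_120)),
    sd_a_reg = stats::sd(v$cfi_30_120_a - v$cfi_reg_30_120),
    n = nrow(v))
  class(out) <- "correction_report"
  out
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf("CFI correction accuracy (n = %d):\n", x$n))
  cat(sprintf("  r(CF, reg) = %.3f  |  mean |diff| %.2f kg (sd %.2f)\n",
              x$correlations["cfi_30_120_cf", "cfi_reg_30_120"],
              x$mad_cf_reg, x$sd_cf_reg))
  cat(sprintf("  r(A,  reg) = %.3f  |  mean |diff| %.2f kg (sd %.2f)\n",
              x$correlations["cfi_30_120_a", "cfi_reg_30_120"],
              x$mad_a_reg, x$sd_a_reg))
  cat(sprintf("  r(CF, A)   = %.3f\n",
              x$correlations["cfi_30_120_cf", "cfi_30_120_a"]))
  invisible(x)
}
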