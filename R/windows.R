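#' Cumulative feed intake at an exact body weight
#'
#' The crossing day of weight `w` is taken from the animal's robust-fit
#' growth line (monotone by construction); the CFI is then linearly
#' interpolated between the two series days bracketing that crossing.
#'
#' @param series per-animal CFI series (`day, cfi_kg`), sorted by day.
#' @param gfit the animal's growth-fit row (for the line inversion).
#' @param w target body weight (kg), within the fitted span.
#' @return interpolated CFI (kg); vectorized over `w`.
#' @export
cfi_at_weight <- function(series, gfit, w) {
  d <- day_at_weight(gfit, w)
  stats::approx(series$day, series$cfi_kg, xout = d, rule = 1)$y
}

#' Stage-specific FCR over a body-weight window
#'
#' Feed consumed between the window's weight bounds divided by the weight
#' gained: `(cfi_at(end) - cfi_at(start)) / (end - start)` in kg feed per
#' kg gain.
#'
#' @inheritParams cfi_at_weight
#' @param window numeric length 2, `c(start, end)` in kg.
#' @return kg feed / kg gain.
#' @export
module_fcr <- function(series, gfit, window) {
  v <- cfi_at_weight(series, gfit, window)
  (v[2] - v[1]) / (window[2] - window[1])
}

#' Sliding-window summary of module-FCR informativeness
#'
#' For every window of each module size on the 10-kg grid inside
#' 30-120 kg, computes the Spearman correlation across animals between the
#' window's FCR and the overall 30-120 kg FCR (defined as
#' `cfi_reg_30_120 / 90`). Animals whose fitted span does not cover a
#' window are excluded from that window (counted in the output). Per-size
#' summaries are unweighted means over the size's windows.
#'
#' @param series_df population CFI series.
#' @param gfits growth-fit table (one row per animal).
#' @param cfi_fits BW-CFI line-fit table (supplies the overall FCR).
#' @param sizes module sizes (kg).
#' @param stride window grid step (kg).
#' @param range overall weight range (kg).
#' @return list of class `window_summary`: `summary` (size,
#'   mean_spearman), `per_window` (size, start, end, spearman, n_animals).
#' @export
sliding_window_summary <- function(series_df, gfits, cfi_fits,
                                   sizes = seq(10, 80, 10), stride = 10,
                                   range = c(30, 120)) {
  fits <- cfi_fits[cfi_fits$retained, , drop = FALSE]
  ids <- intersect(fits$pig_id, gfits$pig_id[gfits$valid])
  if (length(ids) < 3) stop("need >= 3 animals spanning the weight range")
  overall <- stats::setNames(
    cfi_reg_values(fits)$cfi_reg_30_120 / diff(range), fits$pig_id)[ids]

  # precompute CFI at every grid weight once per animal (NA = not spanned)
  grid <- seq(range[1], range[2], stride)
  parts <- split(series_df, series_df$pig_id)
  cfi_grid <- vapply(ids, function(id) {
    g <- gfits[gfits$pig_id == id, , drop = FALSE]
    vapply(grid, function(w)
      tryCatch(cfi_at_weight(parts[[id]], g, w),
               error = function(e) NA_real_), 0)
  }, numeric(length(grid)))

  per <- do.call(rbind, lapply(sizes, function(sz) {
    starts <- seq(range[1], range[2] - sz, stride)
    do.call(rbind, lapply(starts, function(st) {
      i0 <- match(st, grid); i1 <- match(st + sz, grid)
      fcr_w <- (cfi_grid[i1, ] - cfi_grid[i0, ]) / sz
      ok <- !is.na(fcr_w)
      rho <- if (sum(ok) >= 3)
        stats::cor(fcr_w[ok], overall[ok], method = "spearman")
      else NA_real_
      data.frame(size = sz, start = st, end = st + sz,
                 spearman = rho, n_animals = sum(ok))
    }))
  }))
  excl <- sum(per$n_animals < length(ids))
  if (excl > 0)
    message(excl, " window(s) had animals excluded for not spanning them")
  summ <- data.frame(
    size = sizes,
    mean_spearman = vapply(sizes, function(sz)
      mean(per$spearman[per$size == sz], na.rm = TRUE), 0))
  out <- list(summary = summ, per_window = per, n_animals = length(ids))
  class(out) <- "window_summary"
  out
}

#' @export
print.window_summary <- function(x, ...) {
  cat("Sliding-window module analysis (", x$n_animals, " animals):\n",
      sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Two-segment breakpoint fit of correlation vs module size
#'
#' Continuous piecewise-linear model with one breakpoint, fit by
#' exhaustive search on a 0.1-kg grid over the open interior of the size
#' range; each candidate is scored by the residual sum of squares of the
#' constrained two-segment least-squares fit, ties broken toward the
#' smaller breakpoint.
#'
#' @param sizes module sizes (kg), at least 4.
#' @param means per-size mean correlations.
#' @param grid_step candidate spacing (kg).
#' @return list of class `breakpoint_fit`: `breakpoint`, `left_slope`,
#'   `right_slope`, `intercept`, `rss`, `rss_line` (single-line fit),
#'   `no_elbow` (TRUE when the two-segment fit does not improve on the
#'   single line), `candidates`.
#' @export
fit_breakpoint <- function(sizes, means, grid_step = 0.1) {
  if (length(sizes) < 4) stop("need >= 4 points")
  stopifnot(length(sizes) == length(means))
  o <- order(sizes)
  x <- as.numeric(sizes[o]); y <- as.numeric(means[o])
  cands <- seq(min(x) + grid_step, max(x) - grid_step, by = grid_step)
  best <- list(rss = Inf, bp = NA_real_, coef = NULL)
  for (cp in cands) {
    X <- cbind(1, x, pmax(x - cp, 0))
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    if (rss < best$rss - 1e-12) best <- list(rss = rss, bp = cp,
                                             coef = f$coefficients)
  }
  line <- stats::lm.fit(cbind(1, x), y)
  rss_line <- sum(line$residuals^2)
  no_elbow <- best$rss >= rss_line - 1e-10
  out <- list(breakpoint = best$bp,
              left_slope = unname(best$coef[2]),
              right_slope = unname(best$coef[2] + best$coef[3]),
              intercept = unname(best$coef[1]),
              rss = best$rss, rss_line = rss_line,
              no_elbow = no_elbow, candidates = cands)
  class(out) <- "breakpoint_fit"
  out
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(
    "Breakpoint at %.1f kg (slopes %.4f -> %.4f per kg, rss %.3g%s)\n",
    x$breakpoint, x$left_slope, x$right_slope, x$rss,
    if (x$no_elbow) "; no elbow detected" else ""))
  invisible(x)
}

#' Optimal module size from a breakpoint fit
#'
#' The breakpoint rounded to the nearest size on the 10-kg grid.
#'
#' @param bp a `breakpoint_fit`.
#' @param grid grid spacing (kg).
#' @return module size (kg).
#' @export
select_optimal_module <- function(bp, grid = 10) {
  round(bp$breakpoint / grid) * grid
}
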