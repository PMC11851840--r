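#' Build the window-prediction design table
#'
#' One row per animal spanning the measurement window: `bw_in`/`bw_out`
#' are the window's weight bounds (the crossing weights), `cfi_window` is
#' the feed consumed inside the window, and the target is the animal's
#' regression-based 30-120 kg CFI. Animals not spanning the window (or
#' not retained by the BW-CFI gate) are dropped with a message; zero-
#' variance predictor columns are flagged with a warning.
#'
#' @param series_df population CFI series.
#' @param gfits growth-fit table.
#' @param cfi_fits BW-CFI line-fit table.
#' @param window numeric length 2, window weight bounds (kg).
#' @return data.frame `pig_id, bw_in, bw_out, cfi_window, target`.
#' @export
build_design <- function(series_df, gfits, cfi_fits, window = c(80, 110)) {
  stopifnot(window[2] > window[1])
  fits <- cfi_fits[cfi_fits$retained, , drop = FALSE]
  ids <- intersect(fits$pig_id, gfits$pig_id[gfits$valid])
  parts <- split(series_df, series_df$pig_id)
  rows <- lapply(ids, function(id) {
    g <- gfits[gfits$pig_id == id, , drop = FALSE]
    v <- tryCatch(cfi_at_weight(parts[[id]], g, window),
                  error = function(e) NULL)
    if (is.null(v) || anyNA(v)) return(NULL)
    f <- fits[fits$pig_id == id, , drop = FALSE]
    data.frame(pig_id = id, bw_in = window[1], bw_out = window[2],
               cfi_window = v[2] - v[1],
               target = cfi_reg_values(f)$cfi_reg_30_120,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    message(dropped, " animal(s) dropped: window [", window[1], ", ",
            window[2], "] kg outside their fitted span")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  row.names(out) <- NULL
  zv <- vapply(out[, c("bw_in", "bw_out", "cfi_window")], stats::sd, 0) == 0
  if (any(zv))
    warning("zero-variance predictor column(s): ",
            paste(names(zv)[zv], collapse = ", "))
  out
}

#' Bayesian ridge regression by evidence maximization
#'
#' Gaussian linear model with an isotropic Gaussian prior (precision
#' `lam`) on the standardized coefficients and noise precision `alpha`,
#' both estimated by type-II maximum likelihood with the MacKay
#' fixed-point iteration (flat hyperpriors). The intercept is
#' unpenalized. Predictors are internally centered and scaled (constant
#' columns are dropped and get a zero coefficient) and coefficients are
#' reported on the original scale.
#'
#' Either hyperparameter may be frozen by passing a value; with both
#' frozen the fit is the closed-form ridge solution.
#'
#' @param X numeric predictor matrix (or the design table from
#'   [build_design()], from which `bw_in`, `bw_out`, `cfi_window` are
#'   taken).
#' @param y numeric response; defaults to the design table's `target`.
#' @param alpha,lam optional frozen noise / prior precision.
#' @param standardize scale predictors to unit variance (predictors are
#'   always centered).
#' @param max_iter,tol fixed-point iteration control.
#' @return list of class `brr_model`: `beta` (original scale, named),
#'   `intercept`, `alpha`, `lam`, `n_iter`, `converged`, `fitted`,
#'   `predictors`.
#' @export
fit_brr <- function(X, y = NULL, alpha = NULL, lam = NULL,
                    standardize = TRUE, max_iter = 300, tol = 1e-8) {
  if (is.data.frame(X)) {
    if (is.null(y)) y <- X$target
    X <- as.matrix(X[, c("bw_in", "bw_out", "cfi_window")])
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (n < 5) stop("need >= 5 rows")
  if (stats::sd(y) == 0) stop("constant target: nothing to fit")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- scl > 0
  if (!any(keep)) stop("no predictor with nonzero variance")
  Xs <- sweep(X[, keep, drop = FALSE], 2, ctr[keep])
  if (standardize) Xs <- sweep(Xs, 2, scl[keep], "/")
  ybar <- mean(y)
  yc <- y - ybar
  p <- ncol(Xs)

  sv <- svd(Xs)
  d2 <- sv$d^2
  Uty <- crossprod(sv$u, yc)

  alpha_fixed <- !is.null(alpha)
  lam_fixed <- !is.null(lam)
  a <- if (alpha_fixed) alpha else 1 / stats::var(yc)
  l <- if (lam_fixed) lam else 1
  converged <- alpha_fixed && lam_fixed
  it <- 0L
  repeat {
    it <- it + 1L
    m <- sv$v %*% ((sv$d * as.vector(Uty)) / (d2 + l / a))
    if (alpha_fixed && lam_fixed) break
    gam <- sum(a * d2 / (l + a * d2))
    rss <- sum((yc - Xs %*% m)^2)
    l_new <- if (lam_fixed) l else gam / max(sum(m^2), 1e-300)
    a_new <- if (alpha_fixed) a else max(n - gam, 1e-12) / max(rss, 1e-300)
    delta <- abs(l_new - l) / max(l, 1e-300) +
      abs(a_new - a) / max(a, 1e-300)
    l <- l_new; a <- a_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  m <- as.vector(sv$v %*% ((sv$d * as.vector(Uty)) / (d2 + l / a)))

  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta[keep] <- if (standardize) m / scl[keep] else m
  intercept <- ybar - sum(beta * ctr)
  out <- list(beta = beta, intercept = intercept, alpha = a, lam = l,
              n_iter = it, converged = converged,
              fitted = as.vector(X %*% beta) + intercept,
              predictors = colnames(X))
  class(out) <- "brr_model"
  out
}

#' @export
print.brr_model <- function(x, ...) {
  cat("Bayesian ridge regression (evidence maximization):\n")
  cat("  CFI_p =", sprintf("%.4f", x$intercept), "+",
      paste(sprintf("%.4f*%s", x$beta, names(x$beta)), collapse = " + "),
      "\n")
  cat(sprintf("  alpha (noise) %.4g, lambda (prior) %.4g, %d iterations%s\n",
              x$alpha, x$lam, x$n_iter,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Predict 30-120 kg CFI from a fitted ridge model
#'
#' @param model a `brr_model`.
#' @param rows design table (or matrix with the model's predictor
#'   columns).
#' @return predicted CFI (kg) per row.
#' @export
predict_cfi <- function(model, rows) {
  X <- if (is.data.frame(rows)) as.matrix(rows[, model$predictors])
  else as.matrix(rows)
  as.vector(X %*% model$beta) + model$intercept
}

#' K-fold cross-validation of the CFI prediction model
#'
#' Animals are shuffled under the given seed and partitioned into k
#' disjoint folds. Each fold is predicted by a model trained on the
#' others; per-fold MSE, RMSE and R-squared are reported along with the
#' Spearman and Pearson correlations of the pooled out-of-fold
#' predictions against the target.
#'
#' @param rows design table from [build_design()].
#' @param k number of folds (k = n gives leave-one-out).
#' @param seed integer seed for the fold assignment.
#' @param ... passed to [fit_brr()].
#' @return list of class `cv_report`: `k`, `seed`, `per_fold`, `mse_mean`,
#'   `mse_sd`, `rmse_mean`, `rmse_sd`, `r2_mean`, `r2_sd`, `spearman`,
#'   `pearson`, `oof` (pig_id, target, predicted).
#' @export
cross_validate <- function(rows, k = 5, seed = 1, ...) {
  n <- nrow(rows)
  if (k > n) stop("k (", k, ") exceeds the number of animals (", n, ")")
  if (k < 2) stop("k must be >= 2")
  set.seed(seed)
  # folds assigned over animals in id order, then shuffled: the partition
  # depends on the animal set and seed only, not on row order
  fold <- integer(n)
  fold[order(rows$pig_id)] <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  per <- data.frame(fold = seq_len(k), mse = NA_real_, rmse = NA_real_,
                    r2 = NA_real_)
  for (f in seq_len(k)) {
    test <- fold == f
    m <- fit_brr(rows[!test, , drop = FALSE], ...)
    p <- predict_cfi(m, rows[test, , drop = FALSE])
    pred[test] <- p
    res <- rows$target[test] - p
    per$mse[f] <- mean(res^2)
    per$rmse[f] <- sqrt(per$mse[f])
    sst <- sum((rows$target[test] - mean(rows$target[test]))^2)
    per$r2[f] <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  }
  out <- list(k = k, seed = seed, per_fold = per,
              mse_mean = mean(per$mse), mse_sd = stats::sd(per$mse),
              rmse_mean = mean(per$rmse), rmse_sd = stats::sd(per$rmse),
              r2_mean = mean(per$r2, na.rm = TRUE),
              r2_sd = stats::sd(per$r2, na.rm = TRUE),
              spearman = stats::cor(pred, rows$target, method = "spearman"),
              pearson = stats::cor(pred, rows$target),
              oof = data.frame(pig_id = rows$pig_id, target = rows$target,
                               predicted = pred, fold = fold,
                               stringsAsFactors = FALSE))
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d):\n", x$k, x$seed))
  cat(sprintf("  MSE %.2f +/- %.2f, RMSE %.2f +/- %.2f, R2 %.2f +/- %.2f\n",
              x$mse_mean, x$mse_sd, x$rmse_mean, x$rmse_sd,
              x$r2_mean, x$r2_sd))
  cat(sprintf("  out-of-fold Spearman %.3f, Pearson %.3f\n",
              x$spearman, x$pearson))
  invisible(x)
}

#' Derive FCR from a 30-120 kg cumulative feed intake
#'
#' Default: feed per kg of gain over the standardized 90-kg range
#' (kg/kg). The per-day variant (feed per day of measurement) is also
#' available.
#'
#' @param cfi_30_120 cumulative feed intake for 30-120 kg (kg).
#' @param mode `"per-kg-gain"` (default) or `"per-day"`.
#' @param gain weight gained over the range (kg).
#' @param days measurement days (required for `"per-day"`).
#' @return kg/kg or kg/day.
#' @export
derive_fcr <- function(cfi_30_120, mode = c("per-kg-gain", "per-day"),
                       gain = 90, days = NULL) {
  mode <- match.arg(mode)
  if (mode == "per-kg-gain") {
    if (any(gain <= 0)) stop("gain must be positive")
    cfi_30_120 / gain
  } else {
    if (is.null(days) || any(days <= 0)) stop("days must be positive")
    cfi_30_120 / days
  }
}
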