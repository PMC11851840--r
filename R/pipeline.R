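#' Pipeline configuration
#'
#' Seeds, population sizes, thresholds and window settings for
#' [run_pipeline()]. The validation population uses a distinct seed and
#' slightly perturbed generator means (a batch effect: different batches
#' raised on the same farm).
#'
#' @param n_train,n_valid training / validation population sizes.
#' @param train_seed,valid_seed generator seeds (must differ).
#' @param cv_seed fold-assignment seed.
#' @param growth_threshold pseudo-R2 gate for the growth fits.
#' @param cfi_threshold R2 gate for the BW-CFI line fits.
#' @param window prediction window weight bounds (kg).
#' @param ks cross-validation fold counts.
#' @param sim_args extra arguments for [sim_config()] (both populations).
#' @param valid_shift additive tweaks to generator means for the
#'   validation batch (named list, e.g. `list(bw_entry_mean = 0.4)`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_train = 987, n_valid = 150,
                            train_seed = 20250211, valid_seed = 20250212,
                            cv_seed = 11, growth_threshold = 0.8,
                            cfi_threshold = 0.9, window = c(80, 110),
                            ks = c(5, 10), sim_args = list(),
                            valid_shift = list(bw_entry_mean = 0.4,
                                               adg_mean = -0.02,
                                               fcr_mean = 0.03)) {
  if (train_seed == valid_seed)
    stop("train and validation seeds must differ")
  cfg <- list(n_train = n_train, n_valid = n_valid,
              train_seed = train_seed, valid_seed = valid_seed,
              cv_seed = cv_seed, growth_threshold = growth_threshold,
              cfi_threshold = cfi_threshold, window = window, ks = ks,
              sim_args = sim_args, valid_shift = valid_shift)
  class(cfg) <- "pipeline_config"
  cfg
}

# simulate -> qc -> intake correction -> daily -> growth -> cfi for one
# population; returns every intermediate plus stage record counts
process_population <- function(sim, growth_threshold = 0.8,
                               cfi_threshold = 0.9) {
  t0 <- proc.time()[3]
  qc <- apply_qc(sim$events)
  t1 <- proc.time()[3]
  corr <- correct_intakes(qc$clean)
  t2 <- proc.time()[3]
  daily <- daily_records(corr$events)
  gfits <- fit_growth_all(daily, threshold = growth_threshold)
  retained <- gate_animals(gfits, threshold = growth_threshold)
  t3 <- proc.time()[3]
  daily_g <- daily[daily$pig_id %in% retained, , drop = FALSE]
  series <- build_cfi_series(daily_g)
  cfi_fits <- fit_cfi_lines(series, threshold = cfi_threshold)
  t4 <- proc.time()[3]
  list(qc_report = qc$report, intake_model = corr$model,
       n_flagged = sum(corr$flagged), daily = daily, gfits = gfits,
       retained = retained, series = series, cfi_fits = cfi_fits,
       counts = c(visits_raw = nrow(sim$events),
                  visits_clean = nrow(qc$clean),
                  animals = nrow(sim$truth),
                  animals_growth_gate = length(retained),
                  animals_cfi_fit = nrow(cfi_fits),
                  animals_cfi_retained = sum(cfi_fits$retained)),
       elapsed = c(qc = t1 - t0, intake = t2 - t1, growth = t3 - t2,
                   cfi = t4 - t3))
}

#' Run the full phenotyping pipeline with grouped validation
#'
#' Training population: simulate, QC, intake correction, growth fits,
#' CFI series and line fits, population correction coefficients,
#' CF/A-model standardization, sliding-window analysis with breakpoint
#' selection, window design, Bayesian ridge fit and cross-validation.
#' The learned correction coefficients and ridge model are then applied,
#' frozen, to an independently seeded validation population; validation
#' animals never influence the training fits.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pigfcr_run` with `train`, `valid`, `coefs`,
#'   `brr`, `cv` (one [cross_validate()] report per k), `windows`,
#'   `breakpoint`, `optimal_module`, correlation summaries and per-stage
#'   timings.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  w <- config$window

  sim_tr <- do.call(sim_config, c(list(n_pigs = config$n_train,
                                       seed = config$train_seed),
                                  config$sim_args))
  train_sim <- simulate_population(sim_tr)
  tr <- process_population(train_sim, config$growth_threshold,
                           config$cfi_threshold)

  coefs <- population_coefficients(tr$cfi_fits)
  tr_corr <- correct_population(tr$cfi_fits, coefs)
  tr_eval <- evaluate_correction(tr_corr)

  win <- sliding_window_summary(tr$series, tr$gfits, tr$cfi_fits)
  bp <- fit_breakpoint(win$summary$size, win$summary$mean_spearman)
  opt <- select_optimal_module(bp)

  design <- build_design(tr$series, tr$gfits, tr$cfi_fits, window = w)
  brr <- fit_brr(design)
  cv <- lapply(config$ks, function(k)
    cross_validate(design, k = k, seed = config$cv_seed))
  names(cv) <- paste0("k", config$ks)

  # validation batch: new seed, slightly shifted generator means, frozen
  # coefficients and model
  base <- sim_config(n_pigs = config$n_valid, seed = config$valid_seed)
  args <- c(list(n_pigs = config$n_valid, seed = config$valid_seed),
            config$sim_args)
  for (nm in names(config$valid_shift))
    args[[nm]] <- (if (!is.null(args[[nm]])) args[[nm]] else base[[nm]]) +
      config$valid_shift[[nm]]
  valid_sim <- simulate_population(do.call(sim_config, args))
  va <- process_population(valid_sim, config$growth_threshold,
                           config$cfi_threshold)
  va_corr <- correct_population(va$cfi_fits, coefs)   # frozen coefficients
  va_eval <- evaluate_correction(va_corr)
  va_design <- build_design(va$series, va$gfits, va$cfi_fits, window = w)
  va_pred <- predict_cfi(brr, va_design)              # frozen model
  va_fcr_pred <- derive_fcr(va_pred)
  va_fcr_true <- derive_fcr(va_design$target)

  out <- list(
    config = config,
    train = tr, valid = va,
    coefs = coefs,
    train_correction = tr_corr, train_correction_report = tr_eval,
    windows = win, breakpoint = bp, optimal_module = opt,
    design = design, brr = brr, cv = cv,
    valid_correction = va_corr, valid_correction_report = va_eval,
    valid_prediction = data.frame(
      pig_id = va_design$pig_id, bw_in = va_design$bw_in,
      bw_out = va_design$bw_out, cfi_window = va_design$cfi_window,
      cfi_target = va_design$target, cfi_pred = va_pred,
      fcr_pred = va_fcr_pred, stringsAsFactors = FALSE),
    valid_pred_cor = c(
      spearman = stats::cor(va_pred, va_design$target, method = "spearman"),
      pearson = stats::cor(va_pred, va_design$target)),
    valid_fcr_cor = c(
      spearman = stats::cor(va_fcr_pred, va_fcr_true, method = "spearman"),
      pearson = stats::cor(va_fcr_pred, va_fcr_true)))
  class(out) <- "pigfcr_run"
  out
}

#' @export
print.pigfcr_run <- function(x, ...) {
  cat("Feed-efficiency phenotyping run\n")
  cat("-- training population --\n")
  print(data.frame(count = x$train$counts))
  print(x$coefs)
  print(x$train_correction_report)
  print(x$breakpoint)
  cat("optimal module size:", x$optimal_module, "kg; prediction window",
      paste(x$config$window, collapse = "-"), "kg\n")
  print(x$brr)
  for (cv in x$cv) print(cv)
  cat("-- validation population (frozen coefficients & model) --\n")
  print(data.frame(count = x$valid$counts))
  print(x$valid_correction_report)
  cat(sprintf("  predicted vs reference CFI: Spearman %.3f, Pearson %.3f\n",
              x$valid_pred_cor["spearman"], x$valid_pred_cor["pearson"]))
  cat(sprintf("  predicted vs reference FCR: Spearman %.3f, Pearson %.3f\n",
              x$valid_fcr_cor["spearman"], x$valid_fcr_cor["pearson"]))
  invisible(x)
}

#' Pairwise correlation summary with significance
#'
#' Pearson and Spearman correlations with two-sided p-values for every
#' pair of columns. Zero-variance columns yield NA entries with a
#' warning.
#'
#' @param df numeric data.frame (>= 3 rows).
#' @return data.frame `var1, var2, pearson, pearson_p, spearman,
#'   spearman_p`.
#' @export
summarize_correlations <- function(df) {
  stopifnot(nrow(df) >= 3)
  nm <- names(df)
  pairs <- utils::combn(nm, 2)
  out <- do.call(rbind, apply(pairs, 2, function(p) {
    x <- df[[p[1]]]; y <- df[[p[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero-variance column in pair ", p[1], "/", p[2])
      return(data.frame(var1 = p[1], var2 = p[2], pearson = NA_real_,
                        pearson_p = NA_real_, spearman = NA_real_,
                        spearman_p = NA_real_))
    }
    pe <- stats::cor.test(x, y)
    sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    data.frame(var1 = p[1], var2 = p[2],
               pearson = unname(pe$estimate), pearson_p = pe$p.value,
               spearman = unname(sp$estimate), spearman_p = sp$p.value,
               stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}
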