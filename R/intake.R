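#' Flag abnormal single-visit intakes
#'
#' A visit is flagged iff its intake deviates from the population mean by
#' strictly more than three standard deviations (single pass; mean and sd
#' over all events).
#'
#' @param events visit-level events (`fiv_g`).
#' @return logical vector, TRUE = flagged.
#' @export
flag_intake_outliers <- function(events) {
  fiv <- events$fiv_g
  if (length(fiv) < 2) stop("need >= 2 events")
  s <- stats::sd(fiv)
  if (s == 0) return(rep(FALSE, length(fiv)))
  abs(fiv - mean(fiv)) > 3 * s
}

#' Fit the visit-intake prediction model
#'
#' Linear mixed model `fiv ~ bw + otv + bw:otv + (1 | pig_id)` (REML):
#' intake predicted from body weight, feeding time and their interaction,
#' with a per-animal random intercept. Marginal and conditional
#' R-squared follow the Nakagawa variance decomposition
#' (fixed / fixed + random + residual). If the random-effect fit is
#' degenerate (e.g. noise-free data), falls back to the fixed-effects
#' model with zero random variance.
#'
#' @param events unflagged visit-level events (`pig_id, otv_s, fiv_g,
#'   bw_kg`), at least 10 events from at least 2 animals.
#' @return list of class `intake_model`: `coef_bw`, `coef_t`, `coef_bw_t`,
#'   `intercept`, `random_intercepts` (named, g), `marginal_r2`,
#'   `conditional_r2`, `sigma`.
#' @export
fit_intake_model <- function(events) {
  if (nrow(events) < 10) stop("need >= 10 events")
  if (length(unique(events$pig_id)) < 2) stop("need events from >= 2 animals")
  for (v in c("bw_kg", "otv_s")) {
    if (stats::sd(events[[v]]) == 0)
      stop("singular design: column '", v, "' is constant")
  }
  dat <- data.frame(fiv = events$fiv_g, bw = events$bw_kg,
                    otv = events$otv_s, pig_id = events$pig_id)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fiv ~ bw + otv + bw:otv + (1 | pig_id), data = dat,
                 REML = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate mixed fit: fixed effects only, zero random variance
    lf <- stats::lm(fiv ~ bw + otv + bw:otv, data = dat)
    fe <- stats::coef(lf)
    var_r <- 0
    var_e <- stats::sigma(lf)^2
    ran <- numeric(0)
    pred_fix <- stats::fitted(lf)
  } else {
    fe <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_r <- vc$vcov[vc$grp == "pig_id"]
    var_e <- stats::sigma(fit)^2
    re <- lme4::ranef(fit)$pig_id
    ran <- stats::setNames(re[, 1], rownames(re))
    pred_fix <- as.vector(stats::model.matrix(fit) %*% fe)
  }
  var_f <- stats::var(pred_fix)
  tot <- var_f + var_r + var_e
  out <- list(coef_bw = unname(fe["bw"]), coef_t = unname(fe["otv"]),
              coef_bw_t = unname(fe["bw:otv"]),
              intercept = unname(fe["(Intercept)"]),
              random_intercepts = ran,
              marginal_r2 = if (tot > 0) var_f / tot else 1,
              conditional_r2 = if (tot > 0) (var_f + var_r) / tot else 1,
              sigma = sqrt(var_e))
  class(out) <- "intake_model"
  out
}

#' @export
print.intake_model <- function(x, ...) {
  cat(sprintf(
    "Visit-intake model: FI = %.3f + %.3f BW + %.3f T + %.4f BW:T (g)\n",
    x$intercept, x$coef_bw, x$coef_t, x$coef_bw_t))
  cat(sprintf("  marginal R2 %.3f, conditional R2 %.3f, %d animal intercepts\n",
              x$marginal_r2, x$conditional_r2, length(x$random_intercepts)))
  invisible(x)
}

#' Predict visit intake from the intake model
#'
#' Fixed effects plus the animal's random intercept when the animal was in
#' the training data, fixed effects only otherwise.
#'
#' @param model an `intake_model`.
#' @param events events with `pig_id, otv_s, bw_kg`.
#' @return predicted intake (g) per event.
#' @export
predict_intake <- function(model, events) {
  pred <- model$intercept + model$coef_bw * events$bw_kg +
    model$coef_t * events$otv_s +
    model$coef_bw_t * events$bw_kg * events$otv_s
  if (length(model$random_intercepts) > 0) {
    r <- model$random_intercepts[events$pig_id]
    r[is.na(r)] <- 0
    pred <- pred + unname(r)
  }
  pred
}

#' Replace flagged visit intakes with model predictions
#'
#' All other fields are unchanged; negative predictions are clipped to
#' zero with a warning. Events from animals unseen by the model get the
#' fixed-effects prediction only.
#'
#' @param model an `intake_model`.
#' @param events full events table.
#' @param flagged logical vector from [flag_intake_outliers()].
#' @return events with flagged `fiv_g` imputed.
#' @export
impute_flagged <- function(model, events, flagged) {
  if (!any(flagged)) return(events)
  pred <- predict_intake(model, events[flagged, , drop = FALSE])
  if (any(pred < 0)) {
    warning(sum(pred < 0), " negative imputed intake(s) clipped to 0")
    pred <- pmax(pred, 0)
  }
  unknown <- !(events$pig_id[flagged] %in% names(model$random_intercepts)) &
    length(model$random_intercepts) > 0
  if (any(unknown))
    message(sum(unknown), " flagged event(s) from animals unseen by the ",
            "intake model: fixed-effects prediction used")
  events$fiv_g[flagged] <- pred
  events
}

#' Flag, fit and impute in one pass
#'
#' Flags 3-SD intake outliers, fits the intake model on the unflagged
#' events only, and imputes the flagged ones.
#'
#' @param events clean (post-QC) visit-level events.
#' @return list: `events` (imputed), `model`, `flagged` (logical).
#' @export
correct_intakes <- function(events) {
  flagged <- flag_intake_outliers(events)
  model <- fit_intake_model(events[!flagged, , drop = FALSE])
  list(events = impute_flagged(model, events, flagged),
       model = model, flagged = flagged)
}
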