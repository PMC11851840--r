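# deterministic fixtures shared across tests

# an animal whose CFI is exactly linear in BW: bw = bw0 + adg*day,
# cfi = slope * (bw - bw0)
linear_animal <- function(pig_id = "L1", bw0 = 30, adg = 1, slope = 2.5,
                          days = 0:110) {
  bw <- bw0 + adg * days
  data.frame(pig_id = pig_id, day = days, cfi_kg = slope * (bw - bw0),
             bw_kg = bw, stringsAsFactors = FALSE)
}

# matching growth-fit row for a noise-free linear trajectory
linear_gfit <- function(pig_id = "L1", bw0 = 30, adg = 1, days = 0:110) {
  data.frame(pig_id = pig_id, slope = adg, intercept = bw0, pseudo_r2 = 1,
             n_days = length(days), day_min = min(days), day_max = max(days),
             retained = TRUE, valid = TRUE, stringsAsFactors = FALSE)
}

# daily records for a population of exactly linear animals with distinct
# feed slopes
linear_population <- function(slopes, bw0 = 30, adg = 1, days = 0:110) {
  series <- do.call(rbind, lapply(seq_along(slopes), function(i)
    linear_animal(sprintf("L%02d", i), bw0, adg, slopes[i], days)))
  gfits <- do.call(rbind, lapply(seq_along(slopes), function(i)
    linear_gfit(sprintf("L%02d", i), bw0, adg, days)))
  cfi_fits <- fit_cfi_lines(series)
  list(series = series, gfits = gfits, cfi_fits = cfi_fits)
}

# independent brute-force evaluation of the eight QC predicates, one
# record at a time (no shared code with apply_qc's vectorized matrix)
qc_oracle_violates <- function(fiv, otv) {
  frv <- if (otv > 0) fiv / (otv / 60) else if (fiv == 0) 0 else Inf * sign(fiv)
  which(c(fiv < 0,
          fiv > 2000,
          otv == 0 && (fiv > 20 || fiv < -20),
          otv < 0,
          otv > 3600,
          frv > 500 && fiv > 0 && fiv < 50,
          frv > 350 && fiv > 50,
          frv == 0 && otv > 500))
}

# brute-force two-segment fit: for every candidate breakpoint solve the
# constrained least-squares by hand via the normal equations
breakpoint_oracle <- function(x, y, cands) {
  best <- list(rss = Inf, bp = NA_real_)
  for (cp in cands) {
    X <- cbind(1, x, pmax(x - cp, 0))
    beta <- solve(crossprod(X), crossprod(X, y))
    rss <- sum((y - X %*% beta)^2)
    if (rss < best$rss - 1e-12) best <- list(rss = rss, bp = cp)
  }
  best
}
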