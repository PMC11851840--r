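#' Feed intake rate of a visit
#'
#' FRV in g/min: `fiv / (otv/60)`. A zero-time visit with nonzero intake
#' gets a signed infinite sentinel (so the rate-based rules also catch
#' zero-time intakes); a zero-intake visit has rate 0. Total function,
#' vectorized.
#'
#' @param fiv feed intake per visit (g).
#' @param otv occupation time per visit (s).
#' @return feed rate (g/min).
#' @export
feed_rate <- function(fiv, otv) {
  out <- fiv / (otv / 60)
  zero_t <- otv == 0
  out[zero_t & fiv != 0] <- Inf * sign(fiv[zero_t & fiv != 0])
  out[fiv == 0] <- 0
  out
}

# the eight visit-level rules; logical n x 8 matrix, TRUE = violated
qc_rule_matrix <- function(events) {
  fiv <- events$fiv_g
  otv <- events$otv_s
  frv <- feed_rate(fiv, otv)
  cbind(
    r1 = fiv < 0,                                  # FIV-low
    r2 = fiv > 2000,                               # FIV-high
    r3 = otv == 0 & (fiv > 20 | fiv < -20),        # FIV-0
    r4 = otv < 0,                                  # OTV-low
    r5 = otv > 3600,                               # OTV-high
    r6 = frv > 500 & fiv > 0 & fiv < 50,           # FRV-high-FIV-low
    r7 = frv > 350 & fiv > 50,                     # FRV-high
    r8 = frv == 0 & otv > 500                      # FRV-0
  )
}

qc_rule_definitions <- c(
  r1 = "FIV < 0 g for all visits",
  r2 = "FIV > 2000 g for all visits",
  r3 = "FIV > 20 g or FIV < -20 g for visits with OTV = 0 s",
  r4 = "OTV < 0 s for all visits",
  r5 = "OTV > 3600 s for all visits",
  r6 = "FRV > 500 g/min for visits with 0 < FIV < 50 g",
  r7 = "FRV > 350 g/min for visits with FIV > 50 g",
  r8 = "FRV = 0 g/min for visits with OTV > 500 s"
)

#' Apply the eight visit-level quality-control rules
#'
#' Records with incomplete information (missing occupation time, intake or
#' body weight) are dropped before rule evaluation and counted separately.
#' A remaining record is removed iff it violates at least one rule; for
#' reporting, removal is attributed to the lowest-index violated rule.
#' Clean records are untouched and order is preserved.
#'
#' @param events visit-level events data.frame
#'   (`pig_id, day, visit, otv_s, fiv_g, bw_kg`).
#' @return list with `clean` (retained events) and `report` (a `qc_report`:
#'   `total`, `incomplete`, `kept`, `removed_by_rule`, `rule_definitions`,
#'   and the per-record `rule` attribution for removed complete records).
#' @export
apply_qc <- function(events) {
  total <- nrow(events)
  complete <- !(is.na(events$otv_s) | is.na(events$fiv_g) |
                  is.na(events$bw_kg) | is.na(events$day) |
                  is.na(events$pig_id))
  ev <- events[complete, , drop = FALSE]
  viol <- qc_rule_matrix(ev)
  removed <- rowSums(viol) > 0
  first_rule <- integer(nrow(ev))
  for (r in 8:1) first_rule[viol[, r]] <- r
  counts <- tabulate(first_rule[removed], nbins = 8)
  names(counts) <- paste0("r", 1:8)
  clean <- ev[!removed, , drop = FALSE]
  report <- structure(
    list(total = total,
         incomplete = sum(!complete),
         kept = nrow(clean),
         removed_by_rule = counts,
         rule_definitions = qc_rule_definitions,
         removed_rule = first_rule[removed],
         removed_index = which(complete)[removed]),
    class = "qc_report")
  stopifnot(report$kept + sum(counts) + report$incomplete == total)
  list(clean = clean, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Visit-level QC:", x$total, "records;",
      x$incomplete, "incomplete;", sum(x$removed_by_rule), "removed;",
      x$kept, "kept\n")
  for (r in 1:8)
    cat(sprintf("  rule %d (%s): %d\n", r, x$rule_definitions[r],
                x$removed_by_rule[r]))
  invisible(x)
}

#' Write a QC report as structured text
#'
#' @param report a `qc_report` from [apply_qc()].
#' @param path file path.
#' @export
write_qc_report <- function(report, path) {
  lines <- c(sprintf("total\t%d", report$total),
             sprintf("incomplete\t%d", report$incomplete),
             sprintf("kept\t%d", report$kept),
             sprintf("rule_%d\t%d\t%s", 1:8, report$removed_by_rule,
                     report$rule_definitions))
  writeLines(lines, path)
  invisible(path)
}
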