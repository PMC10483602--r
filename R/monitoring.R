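#' Select the monitoring-eligible cohort
#'
#' A patient enters the serial-monitoring comparison when ctDNA was detected
#' in the baseline sample, at least two blood samples were collected, and at
#' least one sample was drawn less than one month (31 days) before or after
#' the day of radiologically confirmed progression.
#'
#' @param tables a `ctmon_cohort` or list with `samples` (with `ddcq`,
#'   `draw_day`) and `radiology`.
#' @param window_days half-width of the sample-near-progression window.
#' @return data frame `patient_id`, `radiology_day` for eligible patients.
#' @export
select_monitoring_cohort <- function(tables, window_days = 31) {
  s <- tables$samples
  rad <- tables$radiology
  prog <- rad[rad$progression, ]
  prog_day <- tapply(prog$scan_day, prog$patient_id, min)
  ids <- unique(s$patient_id)
  ok <- vapply(ids, function(p) {
    rows <- s[s$patient_id == p, ]
    base <- rows[rows$draw_day == 0, ]
    if (!nrow(base) || base$ddcq[1] <= 0) return(FALSE)
    if (nrow(rows) < 2) return(FALSE)
    pd <- prog_day[p]
    if (is.na(pd)) return(FALSE)
    any(abs(rows$draw_day - pd) < window_days)
  }, logical(1))
  data.frame(patient_id = ids[ok],
             radiology_day = as.numeric(prog_day[ids[ok]]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify one serial ctDNA sample against its predecessor
#'
#' Categories on the ddCq (log2) scale, applied in order: negative when the
#' current level is 0; increase when the preceding sample was negative and
#' the current is positive, or when the level rose by at least 1 Cq (at
#' least a doubling); decrease when the level fell by more than 1 Cq (more
#' than a 50% reduction) or dropped below ddCq = 1; persistence otherwise.
#'
#' @param prev,curr ddCq of the preceding and current sample (floored at 0).
#' @return one of `"negative"`, `"increase"`, `"decrease"`, `"persistence"`.
#' @export
classify_sample <- function(prev, curr) {
  if (curr <= 0) return("negative")
  if (prev <= 0) return("increase")
  if (curr - prev >= 1) return("increase")
  if (prev - curr > 1) return("decrease")
  if (curr < 1 && curr < prev) return("decrease")
  "persistence"
}

#' Patient-level monitoring call
#'
#' Applies the serial-sample categories of the post-baseline samples up to
#' one month after radiological progression. Under the
#' `increase_or_persistence` rule the monitoring succeeds if any sample is
#' an increase (call day = first such sample) or if every sample shows
#' persistence (persistently high ctDNA; call day = first post-baseline
#' sample day). Under `increase_only` only an increase counts.
#'
#' @param calls data frame `day`, `category` of post-baseline samples
#'   ordered by day (already restricted to `radiology_day + window`).
#' @param radiology_day day of radiologically confirmed progression.
#' @param rule `"increase_or_persistence"` or `"increase_only"`.
#' @return list with `eligible`, `success`, `ctdna_call_day`, `radiology_day`,
#'   `lead_time`, `rule`.
#' @export
call_patient <- function(calls, radiology_day,
                         rule = c("increase_or_persistence",
                                  "increase_only")) {
  rule <- match.arg(rule)
  if (!nrow(calls))
    return(list(eligible = FALSE, success = FALSE,
                ctdna_call_day = NA_real_, radiology_day = radiology_day,
                lead_time = NA_real_, rule = rule))
  success <- FALSE
  call_day <- NA_real_
  inc <- which(calls$category == "increase")
  if (length(inc)) {
    success <- TRUE
    call_day <- calls$day[inc[1]]
  } else if (rule == "increase_or_persistence" &&
             all(calls$category == "persistence")) {
    success <- TRUE
    call_day <- calls$day[1]
  }
  list(eligible = TRUE, success = success, ctdna_call_day = call_day,
       radiology_day = radiology_day,
       lead_time = if (success) radiology_day - call_day else NA_real_,
       rule = rule)
}

#' Run ctDNA monitoring over a cohort
#'
#' Classifies every post-baseline sample of the monitoring-eligible patients
#' and produces patient-level outcomes and per-sample calls (swimmer-plot
#' data).
#'
#' @param tables cohort tables (see [select_monitoring_cohort()]).
#' @param rule patient-level success rule.
#' @param window_days the "1 month" window (days).
#' @return list with `outcomes` (one row per eligible patient), `calls`
#'   (per-sample categories), `eligible` (the selection table).
#' @export
monitor_ctdna <- function(tables, rule = c("increase_or_persistence",
                                           "increase_only"),
                          window_days = 31) {
  rule <- match.arg(rule)
  elig <- select_monitoring_cohort(tables, window_days)
  s <- tables$samples
  out <- vector("list", nrow(elig))
  calls_all <- vector("list", nrow(elig))
  for (i in seq_len(nrow(elig))) {
    p <- elig$patient_id[i]
    rd <- elig$radiology_day[i]
    rows <- s[s$patient_id == p & s$draw_day <= rd + window_days, ]
    rows <- rows[order(rows$draw_day), ]
    cats <- character(nrow(rows) - 1)
    for (j in 2:nrow(rows))
      cats[j - 1] <- classify_sample(rows$ddcq[j - 1], rows$ddcq[j])
    calls <- data.frame(patient_id = p, day = rows$draw_day[-1],
                        category = cats, stringsAsFactors = FALSE)
    calls_all[[i]] <- calls
    res <- call_patient(calls, rd, rule)
    out[[i]] <- data.frame(patient_id = p, eligible = res$eligible,
                           success = res$success,
                           ctdna_call_day = res$ctdna_call_day,
                           radiology_day = res$radiology_day,
                           lead_time = res$lead_time, rule = rule,
                           stringsAsFactors = FALSE)
  }
  list(outcomes = do.call(rbind, out), calls = do.call(rbind, calls_all),
       eligible = elig)
}

#' CA19-9 monitoring call for one patient
#'
#' The call day is the first day whose CA19-9 value exceeds the running
#' on-treatment nadir by more than 50%; monitoring succeeds when that day is
#' at or before radiological progression (no one-month grace window, per the
#' "at or before" convention).
#'
#' @param series data frame `day`, `value` (kU/L), ordered by day.
#' @param radiology_day day of radiological progression.
#' @param window_days grace window after radiology (0 by default).
#' @return list with `success`, `call_day`, `lead_time`.
#' @export
call_ca199 <- function(series, radiology_day, window_days = 0) {
  if (nrow(series) < 2)
    return(list(success = FALSE, call_day = NA_real_, lead_time = NA_real_))
  series <- series[order(series$day), ]
  nadir <- series$value[1]
  call_day <- NA_real_
  for (j in 2:nrow(series)) {
    if (series$value[j] > 1.5 * nadir) { call_day <- series$day[j]; break }
    nadir <- min(nadir, series$value[j])
  }
  success <- !is.na(call_day) && call_day <= radiology_day + window_days
  list(success = success,
       call_day = if (success) call_day else NA_real_,
       lead_time = if (success) radiology_day - call_day else NA_real_)
}

#' CA19-9 monitoring over the eligible cohort
#'
#' @param tables cohort tables with a `ca199` table.
#' @param eligible selection table from [select_monitoring_cohort()].
#' @param window_days grace window (days) after radiology.
#' @return data frame of per-patient CA19-9 outcomes.
#' @export
monitor_ca199 <- function(tables, eligible, window_days = 0) {
  ca <- tables$ca199
  out <- lapply(seq_len(nrow(eligible)), function(i) {
    p <- eligible$patient_id[i]
    rd <- eligible$radiology_day[i]
    ser <- ca[ca$patient_id == p & ca$draw_day <= rd + max(window_days, 0), ]
    res <- call_ca199(data.frame(day = ser$draw_day,
                                 value = ser$ca199_kU_per_L),
                      rd, window_days)
    data.frame(patient_id = p, success = res$success,
               call_day = res$call_day, radiology_day = rd,
               lead_time = res$lead_time, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Lead-time summary
#'
#' Median lead time among monitoring successes and a two-sided Wilcoxon
#' signed-rank test of the lead times against zero (zeros dropped; exact
#' enumeration when n <= 25 with no ties, otherwise normal approximation
#' with 0.5 continuity correction).
#'
#' @param outcomes data frame with `success` and `lead_time`.
#' @return list of class `ctmon_leadtime`: `n_eligible`, `n_success`,
#'   `median_lead`, `p_value`.
#' @export
lead_time_summary <- function(outcomes) {
  leads <- outcomes$lead_time[outcomes$success]
  n_success <- sum(outcomes$success)
  if (n_success == 0)
    return(structure(list(n_eligible = nrow(outcomes), n_success = 0,
                          median_lead = NA_real_, p_value = NA_real_),
                     class = "ctmon_leadtime"))
  nz <- leads[leads != 0]
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  p <- if (length(nz) == 0) 1 else
    suppressWarnings(wilcox.test(leads, mu = 0, exact = exact,
                                 correct = TRUE)$p.value)
  structure(list(n_eligible = nrow(outcomes), n_success = n_success,
                 median_lead = median(leads), p_value = p),
            class = "ctmon_leadtime")
}

#' @export
print.ctmon_leadtime <- function(x, ...) {
  cat(sprintf(
    "Monitoring success in %d of %d patients; median lead time %.1f days (P = %.3g)\n",
    x$n_success, x$n_eligible, x$median_lead, x$p_value))
  invisible(x)
}

#' Marker concordance
#'
#' Cross-tabulates ctDNA and CA19-9 monitoring success over the same
#' eligible patients and reports the fraction in whom either marker
#' indicated progression.
#'
#' @param ctdna_outcomes,ca199_outcomes per-patient outcome tables with
#'   `patient_id` and `success`.
#' @return list with `table` (2x2), `union_fraction`.
#' @export
marker_concordance <- function(ctdna_outcomes, ca199_outcomes) {
  a <- ctdna_outcomes[order(ctdna_outcomes$patient_id), ]
  b <- ca199_outcomes[order(ca199_outcomes$patient_id), ]
  if (!identical(a$patient_id, b$patient_id))
    stop("mismatched patient sets between markers")
  tab <- table(factor(ifelse(a$success, "ctDNA+", "ctDNA-"),
                      levels = c("ctDNA+", "ctDNA-")),
               factor(ifelse(b$success, "CA19-9+", "CA19-9-"),
                      levels = c("CA19-9+", "CA19-9-")))
  list(table = unclass(tab),
       union_fraction = mean(a$success | b$success))
}
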