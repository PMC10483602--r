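#' Kaplan-Meier estimate with log-log confidence intervals
#'
#' Product-limit estimate of the survival function with Greenwood variance,
#' pointwise 95% CI on the log(-log) scale, and the median with a
#' Brookmeyer-Crowley style CI obtained by inverting the pointwise CI.
#'
#' @param records data frame with columns `event_time`, `event` (0/1) and
#'   optionally `entry_time` (delayed entry, default 0).
#' @return list of class `ctmon_km`: `time`, `surv`, `var_greenwood`,
#'   `lower`, `upper`, `median`, `median_ci`, `n`, and the underlying
#'   `survfit` object.
#' @export
km_fit <- function(records) {
  stopifnot(nrow(records) >= 1)
  entry <- if ("entry_time" %in% names(records)) records$entry_time else 0
  sv <- if (any(entry > 0))
    survival::survfit(survival::Surv(entry, records$event_time,
                                     records$event) ~ 1,
                      conf.type = "log-log")
  else
    survival::survfit(survival::Surv(records$event_time, records$event) ~ 1,
                      conf.type = "log-log")
  s <- summary(sv)
  med <- unname(quantile(sv, probs = 0.5)$quantile)
  medci <- unname(c(quantile(sv, probs = 0.5)$lower,
                    quantile(sv, probs = 0.5)$upper))
  structure(list(time = s$time, surv = s$surv,
                 var_greenwood = s$std.err^2,
                 lower = s$lower, upper = s$upper,
                 median = med, median_ci = medci,
                 n = nrow(records), survfit = sv),
            class = "ctmon_km")
}

#' Log-rank test for two groups
#'
#' Standard log-rank statistic: at each event time the observed events in
#' group 1 are compared with the hypergeometric expectation given the risk
#' sets; the chi-square statistic has 1 degree of freedom.
#'
#' @param records data frame as in [km_fit()].
#' @param group vector with exactly 2 distinct values.
#' @return list with `chi2`, `p`, `obs`, `exp`.
#' @export
logrank_test <- function(records, group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("logrank_test requires exactly 2 groups")
  if (any(table(g) == 0)) stop("one group is empty")
  sd <- survival::survdiff(
    survival::Surv(records$event_time, records$event) ~ g)
  chi2 <- sd$chisq
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       obs = sd$obs, exp = sd$exp)
}

#' Cox proportional-hazards fit (Breslow ties)
#'
#' Cox regression on a covariate matrix or data-frame columns, maximising
#' the Breslow partial likelihood (the SPSS default), with Wald CIs and
#' support for delayed entry via `entry_time` (used by landmarked analyses).
#'
#' @param records data frame with `event_time`, `event`, optional
#'   `entry_time`, plus covariate columns.
#' @param covariates character vector of covariate column names. Character
#'   or factor columns are treated as categorical blocks.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list of class `ctmon_cox`: `coef`, `hr` (with 95% CI), `loglik`,
#'   `lrt_p` (per-variable likelihood-ratio p, categorical variables as
#'   whole blocks), `fit` (the `coxph` object).
#' @export
cox_fit <- function(records, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  for (v in covariates) {
    x <- records[[v]]
    if (is.null(x)) stop("covariate '", v, "' not found")
    if (length(unique(x)) < 2) stop("covariate '", v, "' is constant")
  }
  entry <- if ("entry_time" %in% names(records) &&
               any(records$entry_time > 0)) TRUE else FALSE
  lhs <- if (entry) "survival::Surv(entry_time, event_time, event)"
         else "survival::Surv(event_time, event)"
  fml <- stats::as.formula(paste(lhs, "~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = ties, x = TRUE,
                         control = survival::coxph.control(iter.max = 100))
  if (any(is.na(stats::coef(fit))))
    stop("singular information matrix: collinear covariates")
  if (!is.null(fit$iter) && fit$iter >= 100)
    stop("Cox fit did not converge in 100 iterations")
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  if (any(abs(beta) > 15))
    stop("monotone partial likelihood (complete separation?) for: ",
         paste(names(beta)[abs(beta) > 15], collapse = ", "))
  hr <- data.frame(term = names(beta), coef = beta, hr = exp(beta),
                   lower = exp(beta - 1.96 * se),
                   upper = exp(beta + 1.96 * se),
                   se = se, row.names = NULL, stringsAsFactors = FALSE)
  lrt_p <- vapply(covariates, function(v) {
    lrt_drop(records, covariates, v, ties, entry)
  }, numeric(1))
  structure(list(coef = beta, hr = hr,
                 loglik = fit$loglik[2], lrt_p = lrt_p,
                 ties = ties, fit = fit),
            class = "ctmon_cox")
}

# LRT p-value for dropping one variable (whole block for categoricals)
lrt_drop <- function(records, covariates, v, ties, entry) {
  lhs <- if (entry) "survival::Surv(entry_time, event_time, event)"
         else "survival::Surv(event_time, event)"
  full <- survival::coxph(
    stats::as.formula(paste(lhs, "~", paste(covariates, collapse = "+"))),
    data = records, ties = ties)
  rest <- setdiff(covariates, v)
  red <- if (length(rest))
    survival::coxph(
      stats::as.formula(paste(lhs, "~", paste(rest, collapse = "+"))),
      data = records, ties = ties)
  else NULL
  ll0 <- if (is.null(red)) full$loglik[1] else red$loglik[2]
  df <- length(stats::coef(full)) -
    (if (is.null(red)) 0 else length(stats::coef(red)))
  stat <- 2 * (full$loglik[2] - ll0)
  pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' Backward elimination by likelihood ratio
#'
#' Starting from the full Cox model, repeatedly removes the candidate with
#' the largest likelihood-ratio p-value above 0.1 (categorical variables
#' tested and removed as whole blocks), refitting until every remaining
#' variable has LRT p <= 0.1.
#'
#' @param records data frame as in [cox_fit()].
#' @param candidate_covariates character vector of candidate columns.
#' @param threshold removal threshold on the LRT p-value (strictly greater
#'   than this value is removed).
#' @param ties ties method.
#' @return list with `fit` (final `ctmon_cox` or `NULL` if the model
#'   emptied), `retained`, `trace` (data frame of steps).
#' @export
backward_eliminate <- function(records, candidate_covariates,
                               threshold = 0.1, ties = "breslow") {
  current <- candidate_covariates
  trace <- list()
  step <- 0
  while (length(current)) {
    fit <- cox_fit(records, current, ties = ties)
    worst <- which.max(fit$lrt_p)
    step <- step + 1
    trace[[step]] <- data.frame(step = step,
                                variable = names(fit$lrt_p),
                                lrt_p = unname(fit$lrt_p),
                                removed = FALSE,
                                stringsAsFactors = FALSE)
    if (fit$lrt_p[worst] > threshold) {
      trace[[step]]$removed[worst] <- TRUE
      current <- current[-worst]
    } else {
      return(list(fit = fit, retained = current,
                  trace = do.call(rbind, trace)))
    }
  }
  list(fit = NULL, retained = character(0), trace = do.call(rbind, trace))
}

#' Landmark a set of survival records
#'
#' Restarts the survival clock at a biomarker sampling day to avoid immortal
#' time bias: patients whose event (or censoring) occurred before the
#' landmark are excluded and the time origin is moved to the landmark day.
#'
#' @param records data frame with `event_time`, `event`.
#' @param sample_day landmark day (>= 0).
#' @return filtered records with `event_time` measured from the landmark.
#' @export
landmark <- function(records, sample_day) {
  stopifnot(sample_day >= 0)
  if (sample_day == 0) return(records)
  keep <- records$event_time > sample_day
  out <- records[keep, , drop = FALSE]
  out$event_time <- out$event_time - sample_day
  out
}

#' Proportional-hazards diagnostics
#'
#' Grambsch-Therneau score test on the scaled Schoenfeld residuals against
#' event-time rank, plus the log(-log S) curve data per group level for the
#' usual diagnostic plot. Degenerate cases (too few events) are reported as
#' `NA` rather than an error.
#'
#' @param fit a `ctmon_cox` object.
#' @param records the records the model was fitted on.
#' @param group optional column name for the log(-log) curves.
#' @return list with `ph_p` (named per-term p-values; last element `GLOBAL`)
#'   and `loglog` (data frame `group`, `time`, `loglog`) when `group` given.
#' @export
schoenfeld_check <- function(fit, records, group = NULL) {
  stopifnot(inherits(fit, "ctmon_cox"))
  ph <- tryCatch({
    z <- survival::cox.zph(fit$fit, transform = "rank")
    setNames(z$table[, "p"], rownames(z$table))
  }, error = function(e) {
    nm <- c(names(fit$coef), "GLOBAL")
    setNames(rep(NA_real_, length(nm)), nm)
  })
  loglog <- NULL
  if (!is.null(group)) {
    g <- factor(records[[group]])
    sv <- survival::survfit(
      survival::Surv(records$event_time, records$event) ~ g)
    s <- summary(sv)
    keep <- s$surv > 0 & s$surv < 1
    loglog <- data.frame(group = sub("^g=", "", as.character(s$strata)[keep]),
                         time = s$time[keep],
                         loglog = log(-log(s$surv[keep])),
                         stringsAsFactors = FALSE)
  }
  list(ph_p = ph, loglog = loglog)
}

#' Days-to-months conversion used in reports
#' @param days numeric days.
#' @return months (days / 30.4375).
#' @export
days_to_months <- function(days) days / 30.4375
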