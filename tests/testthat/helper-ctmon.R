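# shared fixtures and independent oracles

# small uncensored-emission cohort for joint-model checks
small_jm_data <- function(n = 80, seed = 5, alpha = log(1.21), ...) {
  cfg <- sim_config(n_patients = n, floor_emissions = FALSE, alpha = alpha,
                    ...)
  ch <- generate_cohort(cfg, seed = seed)
  long <- prepare_longitudinal(ch)
  surv <- data.frame(patient_id = ch$outcomes$patient_id,
                     event_time = ch$outcomes$pfs_day,
                     event = ch$outcomes$pfs_event)
  surv <- surv[surv$patient_id %in% long$patient_id, ]
  W <- surv_design(ch$patients[match(surv$patient_id,
                                     ch$patients$patient_id), ])
  list(cohort = ch, long = long, surv = surv, W = W)
}

# brute-force product-limit estimator (no package calls)
km_oracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    d <- sum(time == ut[k] & event == 1)
    r <- sum(time >= ut[k])
    s <- s * (1 - d / r)
    surv[k] <- s
  }
  list(time = ut, surv = surv)
}

# brute-force log-rank statistic for two groups
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  ut <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    r <- sum(time >= t)
    r1 <- sum(time >= t & g == 1)
    O <- O + d1
    E <- E + d * r1 / r
    if (r > 1) V <- V + d * (r1 / r) * (1 - r1 / r) * (r - d) / (r - 1)
  }
  (O - E)^2 / V
}

# Breslow partial log-likelihood for a single covariate
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(x[dead]) -
      length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# sample-category oracle transcribing the serial-classification rules
classify_oracle <- function(prev, curr) {
  if (curr <= 0) return("negative")
  if (prev <= 0 && curr > 0) return("increase")
  if (curr - prev >= 1) return("increase")
  if (prev - curr > 1) return("decrease")
  if (curr < 1 && curr < prev) return("decrease")
  "persistence"
}
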