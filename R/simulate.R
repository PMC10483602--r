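#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter set that [generate_cohort()] consumes. Defaults
#' emulate the structure of an 81-patient advanced pancreatic cancer cohort
#' under palliative chemotherapy: baseline covariate frequencies, monthly
#' blood sampling with 8-weekly CT, a decline-then-regrowth mean ctDNA
#' trajectory with subject-level random effects, transient post-infusion
#' offsets, CA19-9 log-trajectories coupled to the ctDNA level, and a
#' progression hazard that depends on the current latent ctDNA level with
#' hazard ratio 1.21 per ddCq unit.
#'
#' @param n_patients cohort size.
#' @param baseline_detect_prob probability that the baseline ddCq exceeds 0;
#'   fixes the mean latent level at treatment start.
#' @param alpha log hazard ratio of progression per ddCq unit of the current
#'   latent level.
#' @param gamma named numeric vector of covariate log hazard ratios (names
#'   must match the columns of [surv_design()]).
#' @param re_sd random-effect standard deviations (intercept + `random_df`
#'   time-basis columns).
#' @param re_corr correlation between the random intercept and the first
#'   random time-basis coefficient.
#' @param sigma residual (assay) standard deviation in ddCq cycles.
#' @param delta_infusion named offsets (ddCq cycles) for time since last
#'   infusion, categories `1-2`, `3-7`, `>7` days.
#' @param h0 constant baseline progression hazard per day.
#' @param traj_anchor_times,traj_anchor_values anchor points (days, ddCq
#'   relative to the baseline mean) through which the fixed-effect spline is
#'   fitted; the default declines over the first ~8 weeks of chemotherapy and
#'   regrows thereafter.
#' @param fixed_df,random_df spline degrees of freedom for the fixed and
#'   random time effects.
#' @param boundary boundary knots (days) of the trajectory splines.
#' @param blood_interval,ct_interval scheduled days between blood draws and
#'   CT scans.
#' @param admin_censor administrative censoring day.
#' @param death_gap_mean mean of the exponential progression-to-death gap
#'   (days).
#' @param cutoff assay wild-type delta-Cq cutoff embedded in simulated Cq
#'   values.
#' @param control_n size of the emitted non-cancer control panel.
#' @param floor_emissions floor observed ddCq at 0 (the assay behaviour);
#'   set `FALSE` for model-validation studies that require uncensored
#'   Gaussian emissions.
#' @param ca199_nonsecretor_prob fraction of patients with Lewis-negative
#'   phenotype (flat, low CA19-9).
#' @param covariates optional list overriding the categorical frequency
#'   tables (`site`, `sex`, `ecog`, `treatment`, `metastasis`,
#'   `tumour_location`) and `age_mean`/`age_sd`.
#' @return a list of class `ctmon_sim_config`.
#' @export
sim_config <- function(n_patients = 81,
                       baseline_detect_prob = 0.56,
                       alpha = log(1.21),
                       gamma = c(site_SUH = log(1.36), sex_male = log(1.43),
                                 age_c = log(0.97),
                                 ecog_1 = log(0.53), ecog_2 = log(2.05),
                                 treat_nabgem = log(2.20),
                                 treat_gem = log(4.57),
                                 met_other = log(1.80),
                                 met_liver = log(2.23)),
                       re_sd = c(2.5, 1.2, 1.2),
                       re_corr = -0.3,
                       sigma = 0.8,
                       delta_infusion = c("1-2" = 0.8, "3-7" = 0.3, ">7" = 0),
                       h0 = 0.001,
                       traj_anchor_times = c(0, 28, 56, 112, 180, 365, 540),
                       traj_anchor_values = c(0, -1.0, -1.4, -1.1, -0.4,
                                              1.2, 2.2),
                       fixed_df = 3, random_df = 2,
                       boundary = c(0, 540),
                       blood_interval = 28, ct_interval = 56,
                       admin_censor = 730,
                       death_gap_mean = 60,
                       cutoff = 11.27, control_n = 29,
                       floor_emissions = TRUE,
                       ca199_nonsecretor_prob = 0.2,
                       covariates = NULL) {
  cov_default <- list(
    site = c(SUH = 63, HUH = 18) / 81,
    sex = c(female = 32, male = 49) / 81,
    ecog = c("0" = 18, "1" = 48, "2" = 15) / 81,
    treatment = c(FOLFIRINOX = 36, NabPacGem = 38, Gemcitabine = 7) / 81,
    metastasis = c(none = 12, other = 16, liver = 53) / 81,
    tumour_location = c(head = 27, body = 15, tail = 16, unknown = 23) / 81,
    age_mean = 67, age_sd = 8)
  if (!is.null(covariates)) cov_default[names(covariates)] <- covariates
  cfg <- list(n_patients = n_patients,
              baseline_detect_prob = baseline_detect_prob,
              alpha = alpha, gamma = gamma,
              re_sd = re_sd, re_corr = re_corr, sigma = sigma,
              delta_infusion = delta_infusion, h0 = h0,
              traj_anchor_times = traj_anchor_times,
              traj_anchor_values = traj_anchor_values,
              fixed_df = fixed_df, random_df = random_df,
              boundary = boundary,
              blood_interval = blood_interval, ct_interval = ct_interval,
              admin_censor = admin_censor, death_gap_mean = death_gap_mean,
              cutoff = cutoff, control_n = control_n,
              floor_emissions = floor_emissions,
              ca199_nonsecretor_prob = ca199_nonsecretor_prob,
              covariates = cov_default)
  class(cfg) <- "ctmon_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  for (nm in c("site", "sex", "ecog", "treatment", "metastasis",
               "tumour_location")) {
    p <- cfg$covariates[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("config error: frequencies for '", nm,
           "' must be in [0,1] and sum to 1")
  }
  if (cfg$sigma <= 0) stop("config error: sigma must be > 0")
  if (cfg$h0 <= 0) stop("config error: baseline hazard must be positive")
  if (cfg$blood_interval <= 0 || cfg$ct_interval <= 0)
    stop("config error: schedule intervals must be > 0")
  D <- re_covariance(cfg)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("config error: random-effect covariance not PSD")
  if (cfg$baseline_detect_prob < 0 || cfg$baseline_detect_prob > 1)
    stop("config error: baseline_detect_prob must be in [0,1]")
  invisible(cfg)
}

re_covariance <- function(cfg) {
  q <- 1 + cfg$random_df
  if (length(cfg$re_sd) != q)
    stop("config error: re_sd must have length 1 + random_df")
  R <- diag(q)
  R[1, 2] <- R[2, 1] <- cfg$re_corr
  diag(cfg$re_sd) %*% R %*% diag(cfg$re_sd)
}

# Fixed-effect spline coefficients: intercept set so that the baseline
# detection probability matches, shape fitted through the anchor points.
resolve_trajectory <- function(cfg) {
  basis_fix <- ncs_basis(seq(cfg$boundary[1], cfg$boundary[2],
                             by = cfg$blood_interval),
                         df = cfg$fixed_df, boundary = cfg$boundary)
  basis_ran <- ncs_basis(seq(cfg$boundary[1], cfg$boundary[2],
                             by = cfg$blood_interval),
                         df = cfg$random_df, boundary = cfg$boundary)
  s_tot <- sqrt(cfg$re_sd[1]^2 + cfg$sigma^2)
  m0 <- qnorm(cfg$baseline_detect_prob) * s_tot
  X <- ncs_eval(basis_fix, cfg$traj_anchor_times)
  beta_shape <- qr.solve(crossprod(X), crossprod(X, cfg$traj_anchor_values))
  list(basis_fix = basis_fix, basis_ran = basis_ran,
       beta = c(intercept = m0, drop(beta_shape)))
}

#' Survival design matrix for cohort covariates
#'
#' Dummy-codes the baseline covariates with the reference levels used
#' throughout the analysis (HUH, female, ECOG 0, FOLFIRINOX, no metastases);
#' age is centred at 67 years.
#'
#' @param patients patients table.
#' @param age_center centring constant for age (years).
#' @return numeric matrix with named columns.
#' @export
surv_design <- function(patients, age_center = 67) {
  cbind(site_SUH = as.numeric(patients$site == "SUH"),
        sex_male = as.numeric(patients$sex == "male"),
        age_c = patients$age - age_center,
        ecog_1 = as.numeric(patients$ecog == "1"),
        ecog_2 = as.numeric(patients$ecog == "2"),
        treat_nabgem = as.numeric(patients$treatment == "NabPacGem"),
        treat_gem = as.numeric(patients$treatment == "Gemcitabine"),
        met_other = as.numeric(patients$metastasis_location == "other"),
        met_liver = as.numeric(patients$metastasis_location == "liver"))
}

#' Draw a synthetic control delta-Cq panel
#'
#' Non-cancer control delta-Cq values, uniform on `[min, max]` cycles.
#'
#' @param n panel size (>= 1).
#' @param seed integer seed.
#' @param min,max distribution bounds (cycles).
#' @return numeric vector of length `n`.
#' @export
resample_controls <- function(n, seed = NULL, min = 11, max = 16) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  runif(n, min, max)
}

#' Generate a synthetic monitoring cohort
#'
#' Simulates the full linked data structure of the study: baseline
#' covariates, a latent subject-specific ctDNA trajectory
#' \eqn{m_i(t) = x(t)'\beta + z(t)'b_i} on a natural cubic spline basis,
#' observed ddCq emissions with post-infusion offsets and assay noise
#' (floored at 0 and re-encoded as raw duplicate Cq values), CA19-9
#' log-trajectories, a latent progression time drawn by inversion from the
#' hazard \eqn{h_0 \exp(\gamma'w_i + \alpha m_i(t))}, radiological detection
#' at the first scheduled CT on or after latent progression, death after an
#' exponential gap, and administrative censoring.
#'
#' @param config a `ctmon_sim_config` from [sim_config()].
#' @param seed integer seed; the same seed and config give byte-identical
#'   tables.
#' @return list of class `ctmon_cohort` with data frames `patients`,
#'   `samples`, `ca199`, `radiology`, `outcomes`, `latent`, numeric
#'   `controls`, and a `truth` list of generating parameters.
#' @export
generate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "ctmon_sim_config"))
  validate_sim_config(config)
  set.seed(seed)
  cfg <- config
  n <- cfg$n_patients
  traj <- resolve_trajectory(cfg)
  D <- re_covariance(cfg)
  LD <- chol(D + diag(1e-12, nrow(D)))
  q <- nrow(D)

  cv <- cfg$covariates
  draw_cat <- function(p, n) names(p)[
    max.col(t(rmultinom(n, 1, p)), ties.method = "first")]
  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    site = draw_cat(cv$site, n),
    age = round(rnorm(n, cv$age_mean, cv$age_sd), 1),
    sex = draw_cat(cv$sex, n),
    ecog = draw_cat(cv$ecog, n),
    treatment = draw_cat(cv$treatment, n),
    metastasis_location = draw_cat(cv$metastasis, n),
    tumour_location = draw_cat(cv$tumour_location, n),
    stringsAsFactors = FALSE)

  W <- surv_design(patients)
  gam <- cfg$gamma[colnames(W)]
  if (any(is.na(gam))) stop("config error: gamma names must match surv_design")
  lin <- drop(W %*% gam)

  b <- matrix(rnorm(n * q), n, q) %*% LD
  step <- 0.25                          # hazard-inversion grid (days)
  grid <- seq(0, cfg$admin_censor, by = step)
  Xg <- cbind(1, ncs_eval(traj$basis_fix, grid))
  Zg <- cbind(1, ncs_eval(traj$basis_ran, grid))
  mfix_grid <- drop(Xg %*% traj$beta)

  samples_list <- vector("list", n)
  ca_list <- vector("list", n)
  rad_list <- vector("list", n)
  out_list <- vector("list", n)
  lat_list <- vector("list", n)

  inf_cat <- function(d) {
    ifelse(d <= 2, "1-2", ifelse(d <= 7, "3-7", ">7"))
  }

  for (i in seq_len(n)) {
    m_grid <- mfix_grid + drop(Zg %*% b[i, ])
    haz <- cfg$h0 * exp(lin[i] + cfg$alpha * m_grid)
    cumhaz <- cumsum(haz * step)
    E <- rexp(1)
    hit <- which(cumhaz >= E)
    latent_prog <- if (length(hit)) grid[hit[1]] else Inf
    death_day <- if (is.finite(latent_prog))
      latent_prog + rexp(1, 1 / cfg$death_gap_mean) else Inf
    censor_day <- cfg$admin_censor

    # CT schedule: baseline and 8-weekly; stop at first progressive scan,
    # death, or censoring
    scan_days <- seq(0, censor_day, by = cfg$ct_interval)
    scan_days <- scan_days[scan_days < min(death_day, censor_day) |
                             scan_days == 0]
    prog_flag <- scan_days >= latent_prog
    if (any(prog_flag)) {
      keep <- seq_len(which(prog_flag)[1])
      scan_days <- scan_days[keep]; prog_flag <- prog_flag[keep]
      rad_prog_day <- scan_days[length(scan_days)]
    } else rad_prog_day <- Inf
    rad_list[[i]] <- data.frame(patient_id = patients$patient_id[i],
                                scan_day = scan_days,
                                progression = prog_flag,
                                stringsAsFactors = FALSE)

    pfs_day <- min(rad_prog_day, death_day, censor_day)
    pfs_event <- as.integer(min(rad_prog_day, death_day) <= censor_day)
    os_day <- min(death_day, censor_day)
    os_event <- as.integer(death_day <= censor_day)
    out_list[[i]] <- data.frame(patient_id = patients$patient_id[i],
                                pfs_day = pfs_day, pfs_event = pfs_event,
                                os_day = os_day, os_event = os_event,
                                stringsAsFactors = FALSE)

    # blood draws: baseline, then 4-weekly with 1-14 day scheduling jitter,
    # until one month past radiological progression (or death/censoring)
    stop_day <- min(rad_prog_day + 31, death_day, censor_day)
    k <- seq_len(ceiling(censor_day / cfg$blood_interval))
    draw_days <- c(0, cfg$blood_interval * k +
                     sample(1:14, length(k), replace = TRUE))
    draw_days <- draw_days[draw_days <= stop_day]
    nd <- length(draw_days)
    cycle <- if (patients$treatment[i] == "FOLFIRINOX") 14 else 28
    dsli <- ifelse(draw_days == 0, 99,
                   draw_days - cycle * floor(draw_days / cycle))
    dsli[dsli == 0 & draw_days > 0] <- cycle
    cat <- inf_cat(dsli)

    Xd <- cbind(1, ncs_eval(traj$basis_fix, draw_days))
    Zd <- cbind(1, ncs_eval(traj$basis_ran, draw_days))
    m_draw <- drop(Xd %*% traj$beta) + drop(Zd %*% b[i, ])
    y_raw <- m_draw + cfg$delta_infusion[cat] + rnorm(nd, 0, cfg$sigma)
    y <- if (cfg$floor_emissions) pmax(y_raw, 0) else y_raw

    # encode as raw duplicate Cq values; quantification round-trips exactly
    delta_cq <- cfg$cutoff - y_raw
    cq_minus <- rnorm(nd, 26, 1)
    cq_plus <- cq_minus + delta_cq
    spread_m <- rnorm(nd, 0, 0.15)
    spread_p <- rnorm(nd, 0, 0.15)
    one_rep <- cq_plus > 38 & runif(nd) < 0.5
    no_amp <- cq_plus >= 45
    cq1p <- ifelse(no_amp, NA, cq_plus + ifelse(one_rep, 0, spread_p))
    cq2p <- ifelse(no_amp | one_rep, NA, cq_plus - spread_p)
    samples_list[[i]] <- data.frame(
      sample_id = sprintf("%s_S%02d", patients$patient_id[i], seq_len(nd)),
      patient_id = patients$patient_id[i],
      draw_day = draw_days,
      days_since_last_infusion = dsli,
      infusion_cat = cat,
      cq_pna_1 = round(cq1p, 3), cq_pna_2 = round(cq2p, 3),
      cq_nopna_1 = round(cq_minus + spread_m, 3),
      cq_nopna_2 = round(cq_minus - spread_m, 3),
      ddcq = y,
      stringsAsFactors = FALSE)

    # CA19-9 on log2 scale, coupled to the latent ctDNA level; ~20%
    # non-secretors (Lewis-negative) with flat low values
    nonsec <- runif(1) < cfg$ca199_nonsecretor_prob
    if (nonsec) {
      log2ca <- rnorm(nd, log2(5), 0.3)
    } else {
      a_i <- rnorm(1, 9, 1.5)
      log2ca <- a_i + 0.35 * m_draw + rnorm(nd, 0, 0.5)
    }
    ca_list[[i]] <- data.frame(patient_id = patients$patient_id[i],
                               draw_day = draw_days,
                               ca199_kU_per_L = round(2^log2ca, 1),
                               stringsAsFactors = FALSE)

    lat_list[[i]] <- data.frame(patient_id = patients$patient_id[i],
                                t(setNames(b[i, ], paste0("b", seq_len(q)))),
                                latent_prog_day = latent_prog,
                                death_day = death_day,
                                lin_pred = lin[i],
                                stringsAsFactors = FALSE)
  }

  controls <- c(cfg$cutoff,
                runif(cfg$control_n - 1, cfg$cutoff, cfg$cutoff + 4.73))
  structure(list(patients = patients,
                 samples = do.call(rbind, samples_list),
                 ca199 = do.call(rbind, ca_list),
                 radiology = do.call(rbind, rad_list),
                 outcomes = do.call(rbind, out_list),
                 latent = do.call(rbind, lat_list),
                 controls = controls,
                 truth = list(beta = traj$beta, D = D, sigma = cfg$sigma,
                              delta = cfg$delta_infusion, alpha = cfg$alpha,
                              gamma = gam, h0 = cfg$h0,
                              basis_fix = traj$basis_fix,
                              basis_ran = traj$basis_ran),
                 config = cfg, seed = seed),
            class = "ctmon_cohort")
}

#' @export
print.ctmon_cohort <- function(x, ...) {
  cat("Synthetic ctDNA monitoring cohort\n")
  cat("  patients:", nrow(x$patients),
      " samples:", nrow(x$samples),
      " events:", sum(x$outcomes$pfs_event), "PFS /",
      sum(x$outcomes$os_event), "OS\n")
  det <- x$samples$ddcq[x$samples$draw_day == 0] > 0
  cat("  baseline ctDNA detected:", sum(det), "of", length(det), "\n")
  invisible(x)
}
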