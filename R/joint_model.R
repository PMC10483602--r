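#' Joint model specification
#'
#' Settings for the joint model of the longitudinal biomarker and time to
#' first progression. The longitudinal submodel is a linear mixed model with
#' a natural cubic spline fixed effect of time (default 3 df), a random
#' intercept plus random spline effect of time (default 2 df), and optional
#' fixed offsets for time since the last chemotherapy infusion (categories
#' 1-2 / 3-7 / >7 days, reference 1-2; disabled for the log2 CA19-9
#' response). The survival submodel has a piecewise-constant baseline hazard
#' on event-time-quantile intervals and proportional covariate effects, and
#' is linked to the trajectory through its current value, slope, or scaled
#' area under the curve.
#'
#' @param association functional form linking trajectory to hazard.
#' @param fixed_df,random_df spline degrees of freedom.
#' @param infusion_adjust include infusion-timing offsets.
#' @param hazard_intervals number of baseline-hazard intervals.
#' @param nodes Gauss-Legendre nodes per hazard-interval segment of the
#'   cumulative-hazard quadrature.
#' @param chains,iter,burn,thin MCMC settings (per chain).
#' @param fix_alpha optionally fix the association coefficient (e.g. 0 for
#'   the factorized model); `NULL` estimates it.
#' @param tobit treat ddCq values of 0 as left-censored Gaussian observations
#'   instead of exact values (off by default, matching the primary analysis).
#' @return list of class `ctmon_jm_spec`.
#' @export
jm_spec <- function(association = c("current", "slope", "area"),
                    fixed_df = 3, random_df = 2,
                    infusion_adjust = TRUE,
                    hazard_intervals = 7, nodes = 15,
                    chains = 3, iter = 6000, burn = 1000, thin = 5,
                    fix_alpha = NULL, tobit = FALSE) {
  association <- match.arg(association)
  stopifnot(fixed_df >= 1, random_df >= 1, hazard_intervals >= 1, nodes >= 2,
            iter > burn)
  structure(list(association = association, fixed_df = fixed_df,
                 random_df = random_df, infusion_adjust = infusion_adjust,
                 hazard_intervals = hazard_intervals, nodes = nodes,
                 chains = chains, iter = iter, burn = burn, thin = thin,
                 fix_alpha = fix_alpha, tobit = tobit),
            class = "ctmon_jm_spec")
}

#' Assemble the longitudinal analysis set
#'
#' Links samples to radiology and keeps observations up to (and including)
#' the day of first radiological progression; later observations are
#' excluded. Patients with at least one remaining observation are retained.
#'
#' @param tables a `ctmon_cohort` or list with `samples` (needs `patient_id`,
#'   `draw_day`, `ddcq`, optionally `infusion_cat`) and `radiology`.
#' @param response `"ddcq"` or `"ca199"` (log2-transformed, taken from the
#'   `ca199` table).
#' @return data frame `patient_id`, `time`, `y`, `infusion_cat`.
#' @export
prepare_longitudinal <- function(tables, response = c("ddcq", "ca199")) {
  response <- match.arg(response)
  rad <- tables$radiology
  prog <- rad[rad$progression, ]
  prog_day <- tapply(prog$scan_day, prog$patient_id, min)
  if (response == "ddcq") {
    s <- tables$samples
    out <- data.frame(patient_id = s$patient_id, time = s$draw_day,
                      y = s$ddcq,
                      infusion_cat = if ("infusion_cat" %in% names(s))
                        s$infusion_cat else ">7",
                      stringsAsFactors = FALSE)
  } else {
    s <- tables$ca199
    out <- data.frame(patient_id = s$patient_id, time = s$draw_day,
                      y = log2(s$ca199_kU_per_L),
                      infusion_cat = ">7", stringsAsFactors = FALSE)
  }
  pd <- prog_day[out$patient_id]
  keep <- is.na(pd) | out$time <= pd
  out <- out[keep, , drop = FALSE]
  out[order(out$patient_id, out$time), , drop = FALSE]
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  k <- seq_len(n - 1)
  bsub <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- bsub
  J[cbind(k + 1, k)] <- bsub
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = 2 * e$vectors[1, ord]^2)
}

# association design: columns for [intercept, basis] transformed per form
assoc_design <- function(basis, t, form) {
  t <- as.numeric(t)
  if (form == "current") return(cbind(1, ncs_eval(basis, t)))
  if (form == "slope") return(cbind(0, ncs_eval(basis, t, deriv = 1)))
  # scaled area: (1/t) integral_0^t [1, N(s)] ds, with the t -> 0 limit
  # equal to the current value at 0
  A <- cbind(t, ncs_eval(basis, t, integral = TRUE))
  zero <- t <= 0
  A[!zero, ] <- A[!zero, , drop = FALSE] / t[!zero]
  if (any(zero)) A[zero, ] <- cbind(1, ncs_eval(basis, t[zero]))
  A
}

# quadrature nodes per patient, segmented at the hazard breakpoints
build_quadrature <- function(T_i, breaks, n_nodes) {
  gl <- gauss_legendre(n_nodes)
  edges <- c(0, breaks)
  pat <- int <- integer(0)
  tt <- wt <- numeric(0)
  off <- integer(length(T_i) + 1)
  for (i in seq_along(T_i)) {
    off[i] <- length(tt)
    for (k in seq_along(edges)) {
      lo <- edges[k]
      hi <- if (k < length(edges)) min(edges[k + 1], T_i[i]) else T_i[i]
      if (hi <= lo) next
      h2 <- (hi - lo) / 2
      tt <- c(tt, (hi + lo) / 2 + h2 * gl$x)
      wt <- c(wt, h2 * gl$w)
      pat <- c(pat, rep(i - 1L, n_nodes))
      int <- c(int, rep(k - 1L, n_nodes))
    }
  }
  off[length(T_i) + 1] <- length(tt)
  list(t = tt, w = wt, pat = pat, int = int, off = off)
}

#' Fit the joint longitudinal-survival model
#'
#' Samples the joint posterior of the trajectory fixed effects, infusion
#' offsets, residual sd, random-effect covariance, per-patient random
#' effects, survival covariate effects, association coefficient and
#' piecewise-constant baseline hazard by Metropolis-within-Gibbs with
#' adaptive proposals (hazard levels by conjugate Gibbs). The survival
#' likelihood integrates the hazard by Gauss-Legendre quadrature over each
#' patient's risk interval, segmented at the baseline-hazard breakpoints.
#'
#' @param long longitudinal analysis set from [prepare_longitudinal()]:
#'   `patient_id`, `time`, `y`, `infusion_cat`.
#' @param surv one row per patient: `patient_id`, `event_time`, `event`.
#' @param W numeric covariate matrix (rows aligned with `surv`), or `NULL`
#'   for no survival covariates.
#' @param spec a `ctmon_jm_spec`.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @return object of class `ctmon_jm` with posterior draws, summaries, the
#'   association hazard ratio (per unit for current value and area, per 0.01
#'   units for slope), convergence diagnostics and the model frame.
#' @export
fit_joint <- function(long, surv, W = NULL, spec = jm_spec(), seed = 1) {
  stopifnot(inherits(spec, "ctmon_jm_spec"))
  surv <- surv[order(surv$patient_id), , drop = FALSE]
  long <- long[order(match(long$patient_id, surv$patient_id), long$time), ,
               drop = FALSE]
  if (!all(long$patient_id %in% surv$patient_id))
    stop("longitudinal rows reference patients absent from the survival set")
  miss <- setdiff(surv$patient_id, long$patient_id)
  if (length(miss))
    stop("patients without longitudinal observations: ",
         paste(head(miss, 5), collapse = ", "))
  n <- nrow(surv)
  if (n < 20) warning("fewer than 20 patients; joint fit may be unstable")

  boundary <- c(0, max(c(long$time, surv$event_time)))
  basis_fix <- ncs_basis(long$time, spec$fixed_df, boundary)
  basis_ran <- ncs_basis(long$time, spec$random_df, boundary)

  Xt <- cbind(1, ncs_eval(basis_fix, long$time))
  Z <- cbind(1, ncs_eval(basis_ran, long$time))
  inf_levels <- c("3-7", ">7")
  Xo <- if (spec$infusion_adjust) {
    m <- sapply(inf_levels, function(l) as.numeric(long$infusion_cat == l))
    matrix(m, nrow = nrow(long), dimnames = list(NULL, inf_levels))
  } else matrix(0, nrow(long), 0)
  if (ncol(Xo) && any(colSums(Xo) == 0)) {
    keep <- colSums(Xo) > 0
    Xo <- Xo[, keep, drop = FALSE]
  }

  id <- match(long$patient_id, surv$patient_id) - 1L
  obs_off <- c(0L, cumsum(tabulate(id + 1L, nbins = n)))

  # baseline hazard breakpoints at event-time quantiles
  ev <- surv$event_time[surv$event == 1]
  if (!length(ev)) stop("no events in the survival set")
  Qn <- spec$hazard_intervals
  breaks <- unique(unname(quantile(ev, probs = seq_len(Qn - 1) / Qn)))
  Q <- length(breaks) + 1L

  quad <- build_quadrature(surv$event_time, breaks, spec$nodes)
  form <- spec$association
  Xa_nd <- assoc_design(basis_fix, quad$t, form)
  Za_nd <- assoc_design(basis_ran, quad$t, form)
  Xa_T <- assoc_design(basis_fix, surv$event_time, form)
  Za_T <- assoc_design(basis_ran, surv$event_time, form)
  int_T <- findInterval(surv$event_time, breaks)

  if (is.null(W)) W <- matrix(0, n, 0)
  W <- as.matrix(W)

  data <- list(y = long$y, id = id, Xt_obs = Xt, Xo_obs = Xo, Z_obs = Z,
               obs_off = obs_off, cens = (long$y <= 0),
               d = as.numeric(surv$event), W = W,
               Xa_T = Xa_T, Za_T = Za_T, int_T = int_T,
               node_pat = quad$pat, node_w = quad$w, node_int = quad$int,
               Xa_nd = Xa_nd, Za_nd = Za_nd, node_off = quad$off,
               Q = Q, tobit = spec$tobit)

  # initial values from a fixed-effects least-squares fit
  XX <- cbind(Xt, Xo)
  ls <- stats::lm.fit(XX, long$y)
  res_sd <- max(sd(ls$residuals), 0.1)
  q <- ncol(Z)
  A0 <- vapply(seq_len(Q) - 1L,
               function(k) sum(quad$w[quad$int == k]), numeric(1))
  dq0 <- vapply(seq_len(Q) - 1L,
                function(k) sum(surv$event[int_T == k]), numeric(1))
  init <- list(beta = ls$coefficients[seq_len(ncol(Xt))],
               delta = if (ncol(Xo))
                 ifelse(is.na(ls$coefficients[-seq_len(ncol(Xt))]), 0,
                        ls$coefficients[-seq_len(ncol(Xt))]) else numeric(0),
               gamma = rep(0, ncol(W)),
               alpha = if (is.null(spec$fix_alpha)) 0 else spec$fix_alpha,
               sigma = res_sd,
               b = matrix(0, n, q),
               re_sd = c(res_sd, rep(res_sd / 2, q - 1)),
               lambda = (dq0 + 0.1) / (A0 + 0.1))
  init$beta[is.na(init$beta)] <- 0

  control <- list(n_iter = spec$iter, n_burn = spec$burn, thin = spec$thin,
                  fix_alpha = !is.null(spec$fix_alpha))
  chains <- lapply(seq_len(spec$chains), function(ch) {
    set.seed(seed + ch - 1L)
    jm_mcmc(data, init, control)
  })

  bind_par <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  draws <- list(beta = bind_par("beta"),
                delta = bind_par("delta"),
                gamma = bind_par("gamma"),
                alpha = do.call(c, lapply(chains, `[[`, "alpha")),
                sigma = do.call(c, lapply(chains, `[[`, "sigma")),
                re_sd = bind_par("re_sd"),
                re_corr = bind_par("re_corr"),
                lambda = bind_par("lambda"))
  b_draws <- lapply(chains, `[[`, "b")
  b_mean <- Reduce(`+`, lapply(b_draws, function(a) apply(a, c(1, 2), mean))) /
    length(b_draws)
  rownames(b_mean) <- surv$patient_id

  scale <- if (form == "slope") 0.01 else 1
  a <- draws$alpha
  alpha_hr <- c(hr = exp(mean(a) * scale),
                lower = exp(unname(quantile(a, 0.025)) * scale),
                upper = exp(unname(quantile(a, 0.975)) * scale))
  rhat_alpha <- rhat_split(lapply(chains, `[[`, "alpha"))
  converged <- is.na(rhat_alpha) || rhat_alpha <= 1.1
  if (!converged)
    warning("R-hat for the association coefficient is ",
            round(rhat_alpha, 3), " (> 1.1): chains have not converged")

  colnames(draws$beta) <- c("intercept", paste0("ncs", seq_len(spec$fixed_df)))
  if (ncol(Xo)) colnames(draws$delta) <- colnames(Xo)
  if (ncol(W)) colnames(draws$gamma) <- colnames(W)

  summ <- function(x) c(mean = mean(x), sd = sd(x),
                        q2.5 = unname(quantile(x, 0.025)),
                        q97.5 = unname(quantile(x, 0.975)))
  par_mat <- cbind(draws$beta,
                   if (ncol(Xo)) draws$delta,
                   if (ncol(W)) draws$gamma,
                   alpha = draws$alpha, sigma = draws$sigma,
                   draws$re_sd)
  summary_df <- as.data.frame(t(apply(par_mat, 2, summ)))
  summary_df$term <- colnames(par_mat)
  summary_df <- summary_df[, c("term", "mean", "sd", "q2.5", "q97.5")]

  structure(list(draws = draws, b_mean = b_mean, summary = summary_df,
                 alpha_hr = alpha_hr, scale = scale,
                 rhat_alpha = rhat_alpha, converged = converged,
                 accept_alpha = mean(vapply(chains, function(ch)
                   as.numeric(ch$accept_alpha), numeric(1))),
                 spec = spec, form = form,
                 basis_fix = basis_fix, basis_ran = basis_ran,
                 breaks = breaks, inf_levels = colnames(Xo),
                 data = list(long = long, surv = surv, W = W),
                 seed = seed),
            class = "ctmon_jm")
}

# split R-hat for a scalar parameter across chains
rhat_split <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    m <- length(x) %/% 2
    if (m < 2) return(list())
    list(x[1:m], x[(m + 1):(2 * m)])
  }), recursive = FALSE)
  if (length(halves) < 2) return(NA_real_)
  m <- length(halves); nn <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- nn * stats::var(means)
  Wv <- mean(vars)
  if (Wv <= 0) return(NA_real_)
  sqrt(((nn - 1) / nn * Wv + B / nn) / Wv)
}

#' @export
print.ctmon_jm <- function(x, ...) {
  cat("Joint longitudinal-survival model (", x$form, " association)\n",
      sep = "")
  cat("  patients:", nrow(x$data$surv),
      " observations:", nrow(x$data$long), "\n")
  unit <- if (x$form == "slope") "per 0.01 units" else "per unit"
  cat(sprintf("  association HR %s: %.3f (95%% CI %.3f-%.3f)\n", unit,
              x$alpha_hr["hr"], x$alpha_hr["lower"], x$alpha_hr["upper"]))
  cat("  R-hat(alpha):", round(x$rhat_alpha, 3), "\n")
  invisible(x)
}

#' Association value of a fitted trajectory
#'
#' Evaluates the current value, slope or scaled area of a patient's
#' estimated trajectory (posterior means of the fixed effects and the
#' patient's random effects) at time `t`.
#'
#' @param fit a `ctmon_jm`.
#' @param patient_id patient identifier present in the fit.
#' @param t time (days), `>= 0`.
#' @param form association form; defaults to the fitted one.
#' @return numeric vector of values at `t`.
#' @export
association_value <- function(fit, patient_id, t,
                              form = c("current", "slope", "area")) {
  stopifnot(inherits(fit, "ctmon_jm"))
  if (any(t < 0)) stop("t must be >= 0")
  form <- match.arg(form, choices = c("current", "slope", "area"))
  i <- match(patient_id, rownames(fit$b_mean))
  if (is.na(i)) stop("unknown patient: ", patient_id)
  beta <- colMeans(fit$draws$beta)
  drop(assoc_design(fit$basis_fix, t, form) %*% beta +
         assoc_design(fit$basis_ran, t, form) %*% fit$b_mean[i, ])
}

# cumulative hazard of one patient up to each time in `times`, for one
# posterior draw
cum_hazard_draw <- function(fit, theta, b, w, times, n_nodes = 15) {
  gl <- gauss_legendre(n_nodes)
  edges <- c(0, fit$breaks)
  lam <- theta$lambda
  wg <- if (length(w)) sum(w * theta$gamma) else 0
  vapply(times, function(tmax) {
    if (tmax <= 0) return(0)
    ch <- 0
    for (k in seq_along(edges)) {
      lo <- edges[k]
      hi <- if (k < length(edges)) min(edges[k + 1], tmax) else tmax
      if (hi <= lo) next
      h2 <- (hi - lo) / 2
      tt <- (hi + lo) / 2 + h2 * gl$x
      f <- drop(assoc_design(fit$basis_fix, tt, fit$form) %*% theta$beta +
                  assoc_design(fit$basis_ran, tt, fit$form) %*% b)
      ch <- ch + lam[k] * sum(h2 * gl$w * exp(wg + theta$alpha * f))
    }
    ch
  }, numeric(1))
}

#' Dynamic prediction of progression risk
#'
#' Subject-specific conditional cumulative risk of progression
#' \eqn{\pi(u\mid t) = 1 - E[S_i(u)/S_i(t)]} for a patient event-free at `t`
#' with biomarker history up to `t`. For each retained posterior draw the
#' patient's random effects are sampled from their conditional posterior
#' given the history and survival to `t` (short Metropolis chain), and the
#' survival ratio is averaged over draws.
#'
#' @param fit a `ctmon_jm`.
#' @param patient_id patient in the fit (or new data via `newdata`: a list
#'   with `long` rows and covariate vector `w`).
#' @param t conditioning time (days); the patient must have at least one
#'   observation at or before `t`.
#' @param horizon vector of prediction times `u >= t`.
#' @param ndraw number of posterior draws used.
#' @param mh_steps Metropolis steps per draw for the random effects.
#' @param newdata optional external patient history.
#' @return data frame of class `ctmon_dynpred`: `u`, `risk`, `lower`,
#'   `upper`.
#' @export
dynamic_predict <- function(fit, patient_id, t, horizon, ndraw = 200,
                            mh_steps = 5, newdata = NULL) {
  stopifnot(inherits(fit, "ctmon_jm"), t >= 0)
  horizon <- sort(unique(pmax(horizon, t)))
  if (is.null(newdata)) {
    rows <- fit$data$long[fit$data$long$patient_id == patient_id &
                            fit$data$long$time <= t, , drop = FALSE]
    i <- match(patient_id, fit$data$surv$patient_id)
    if (is.na(i)) stop("unknown patient: ", patient_id)
    w <- if (ncol(fit$data$W)) fit$data$W[i, ] else numeric(0)
    b0 <- fit$b_mean[i, ]
  } else {
    rows <- newdata$long[newdata$long$time <= t, , drop = FALSE]
    w <- newdata$w
    b0 <- rep(0, 1 + fit$spec$random_df)
  }
  if (!nrow(rows)) stop("no observations at or before t = ", t)

  Xt <- cbind(1, ncs_eval(fit$basis_fix, rows$time))
  Z <- cbind(1, ncs_eval(fit$basis_ran, rows$time))
  Xo <- if (length(fit$inf_levels))
    sapply(fit$inf_levels, function(l) as.numeric(rows$infusion_cat == l))
  else NULL
  if (!is.null(Xo)) Xo <- matrix(Xo, nrow = nrow(rows))

  S <- length(fit$draws$alpha)
  use <- unique(round(seq(1, S, length.out = min(ndraw, S))))
  q <- ncol(fit$b_mean)
  b <- b0
  risks <- matrix(NA_real_, length(use), length(horizon))
  for (j in seq_along(use)) {
    k <- use[j]
    theta <- list(beta = fit$draws$beta[k, ],
                  delta = if (!is.null(Xo)) fit$draws$delta[k, ] else NULL,
                  gamma = if (length(w)) fit$draws$gamma[k, ] else numeric(0),
                  alpha = fit$draws$alpha[k],
                  sigma = fit$draws$sigma[k],
                  re_sd = fit$draws$re_sd[k, ],
                  re_corr = fit$draws$re_corr[k, ],
                  lambda = fit$draws$lambda[k, ])
    D <- diag(theta$re_sd, q)
    R <- diag(q)
    kk <- 0
    for (a in seq_len(q - 1)) for (bb in (a + 1):q) {
      kk <- kk + 1
      R[a, bb] <- R[bb, a] <- theta$re_corr[kk]
    }
    D <- D %*% R %*% D
    Dinv <- solve(D + diag(1e-10, q))
    logpost <- function(bv) {
      mu <- drop(Xt %*% theta$beta) + drop(Z %*% bv) +
        (if (!is.null(Xo)) drop(Xo %*% theta$delta) else 0)
      ll <- sum(stats::dnorm(rows$y, mu, theta$sigma, log = TRUE))
      ll - cum_hazard_draw(fit, theta, bv, w, t) -
        0.5 * drop(bv %*% Dinv %*% bv)
    }
    lp <- logpost(b)
    step <- 0.4 * theta$re_sd
    for (s in seq_len(mh_steps)) {
      bp <- b + rnorm(q, 0, step)
      lpp <- logpost(bp)
      if (log(runif(1)) < lpp - lp) { b <- bp; lp <- lpp }
    }
    ch <- cum_hazard_draw(fit, theta, b, w, c(t, horizon))
    risks[j, ] <- 1 - exp(-(ch[-1] - ch[1]))
  }
  out <- data.frame(u = horizon,
                    risk = colMeans(risks),
                    lower = apply(risks, 2, quantile, 0.025),
                    upper = apply(risks, 2, quantile, 0.975))
  class(out) <- c("ctmon_dynpred", "data.frame")
  out
}
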