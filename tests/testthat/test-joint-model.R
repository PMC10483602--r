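test_that("longitudinal set drops observations after first progression", {
  tabs <- list(
    samples = data.frame(patient_id = c("a", "a", "a", "b", "b"),
                         draw_day = c(0, 28, 56, 0, 28),
                         ddcq = c(2, 1, 3, 0, 0),
                         infusion_cat = ">7"),
    radiology = data.frame(patient_id = c("a", "a", "b"),
                           scan_day = c(0, 40, 56),
                           progression = c(FALSE, TRUE, FALSE)))
  long <- prepare_longitudinal(tabs)
  expect_equal(long$time[long$patient_id == "a"], c(0, 28))
  expect_equal(long$time[long$patient_id == "b"], c(0, 28))

  ch <- generate_cohort(sim_config(n_patients = 50), seed = 17)
  long <- prepare_longitudinal(ch)
  prog <- ch$radiology[ch$radiology$progression, ]
  pd <- tapply(prog$scan_day, prog$patient_id, min)
  manual <- sum(is.na(pd[ch$samples$patient_id]) |
                  ch$samples$draw_day <= pd[ch$samples$patient_id])
  expect_equal(nrow(long), manual)
})

test_that("association designs give closed-form values for constant and linear trajectories", {
  basis <- ncs_basis(seq(0, 300, 25), df = 3)
  h <- diff(basis$boundary)
  tt <- c(0, 10, 80, 150, 290)
  ad <- function(t, form) ctmon:::assoc_design(basis, t, form)
  # constant trajectory: beta = (c, 0, 0, 0)
  beta_c <- c(4.2, 0, 0, 0)
  expect_equal(drop(ad(tt, "current") %*% beta_c), rep(4.2, 5))
  expect_equal(drop(ad(tt, "slope") %*% beta_c), rep(0, 5))
  expect_equal(drop(ad(tt, "area") %*% beta_c), rep(4.2, 5))
  # linear trajectory m(t) = a + b t: first basis column is t / h
  a <- 1.5; bslope <- 0.02
  beta_l <- c(a, bslope * h, 0, 0)
  expect_equal(drop(ad(tt, "current") %*% beta_l), a + bslope * tt)
  expect_equal(drop(ad(tt, "slope") %*% beta_l), rep(bslope, 5))
  expect_equal(drop(ad(tt, "area") %*% beta_l), a + bslope * tt / 2)
})

test_that("scaled-area design matches a dense trapezoid integral for a random spline", {
  set.seed(19)
  basis <- ncs_basis(seq(0, 300, 25), df = 3)
  beta <- c(rnorm(1), rnorm(3, 0, 2))
  t1 <- 212.5
  g <- seq(0, t1, length.out = 200001)
  m <- drop(cbind(1, ncs_eval(basis, g)) %*% beta)
  trap <- (sum(m) - (m[1] + m[length(m)]) / 2) * (g[2] - g[1]) / t1
  area <- drop(ctmon:::assoc_design(basis, t1, "area") %*% beta)
  expect_equal(area, trap, tolerance = 1e-6)
})

test_that("cumulative-hazard quadrature is insensitive to doubling the nodes", {
  dat <- small_jm_data(n = 40, seed = 23)
  fit <- suppressWarnings(
    fit_joint(dat$long, dat$surv, dat$W,
              jm_spec(chains = 1, iter = 300, burn = 100, thin = 2),
              seed = 3))
  theta <- list(beta = colMeans(fit$draws$beta),
                gamma = colMeans(fit$draws$gamma),
                alpha = mean(fit$draws$alpha),
                lambda = colMeans(fit$draws$lambda))
  b <- fit$b_mean[3, ]
  w <- fit$data$W[3, ]
  tmax <- fit$data$surv$event_time[3]
  ch15 <- ctmon:::cum_hazard_draw(fit, theta, b, w, tmax, n_nodes = 15)
  ch30 <- ctmon:::cum_hazard_draw(fit, theta, b, w, tmax, n_nodes = 30)
  expect_lt(abs(log(ch15) - log(ch30)), 1e-6)
})

test_that("alpha = 0 factorizes into an independent mixed model and Cox fit", {
  dat <- small_jm_data(n = 100, seed = 29)
  spec <- jm_spec(chains = 2, iter = 1200, burn = 400, thin = 2,
                  fix_alpha = 0)
  fit <- suppressWarnings(fit_joint(dat$long, dat$surv, dat$W, spec,
                                    seed = 31))
  # longitudinal side against lme4 on the same design
  X <- ncs_eval(fit$basis_fix, dat$long$time)
  Zr <- ncs_eval(fit$basis_ran, dat$long$time)
  df <- data.frame(y = dat$long$y, X, Z1 = Zr[, 1], Z2 = Zr[, 2],
                   c37 = as.numeric(dat$long$infusion_cat == "3-7"),
                   cgt7 = as.numeric(dat$long$infusion_cat == ">7"),
                   id = dat$long$patient_id)
  lmm <- lme4::lmer(y ~ ncs1 + ncs2 + ncs3 + c37 + cgt7 +
                      (1 + Z1 + Z2 | id), data = df, REML = FALSE)
  fe <- lme4::fixef(lmm)
  post <- fit$summary
  for (term in c("intercept", "ncs1", "ncs2", "ncs3")) {
    ref <- if (term == "intercept") fe[["(Intercept)"]] else fe[[term]]
    row <- post[post$term == term, ]
    expect_lt(abs(row$mean - ref), 3.5 * row$sd + 0.05)
  }
  srow <- post[post$term == "sigma", ]
  expect_lt(abs(srow$mean - stats::sigma(lmm)), 3.5 * srow$sd + 0.05)
  # survival side against a plain Cox fit
  rec <- data.frame(event_time = dat$surv$event_time,
                    event = dat$surv$event, dat$W)
  cx <- cox_fit(rec, colnames(dat$W))
  for (term in c("met_liver", "treat_gem", "ecog_2")) {
    row <- post[post$term == term, ]
    se <- cx$hr$se[cx$hr$term == term]
    expect_lt(abs(row$mean - cx$coef[[term]]),
              3.5 * sqrt(row$sd^2 + se^2) + 0.05)
  }
})

test_that("a nearly noise-free trajectory is recovered by the fitted model", {
  # emissions generated directly from a spline in the fitted basis span
  set.seed(37)
  n <- 30
  times <- rep(seq(0, 336, by = 28), n)
  ids <- rep(sprintf("p%02d", 1:n), each = 13)
  basis <- ncs_basis(times, df = 3, boundary = c(0, 360))
  beta_true <- c(2.5, -3, 5, -2)
  m <- drop(cbind(1, ncs_eval(basis, times)) %*% beta_true)
  y <- m + rnorm(length(m), 0, 0.02)
  long <- data.frame(patient_id = ids, time = times, y = y,
                     infusion_cat = ">7")
  surv <- data.frame(patient_id = sprintf("p%02d", 1:n),
                     event_time = 360, event = rep(c(1, 0), n / 2))
  spec <- jm_spec(chains = 1, iter = 800, burn = 300, thin = 2,
                  infusion_adjust = FALSE, fix_alpha = 0,
                  hazard_intervals = 2)
  fit <- suppressWarnings(fit_joint(long, surv, NULL, spec, seed = 41))
  mhat <- vapply(unique(ids), function(p)
    mean(abs(association_value(fit, p, seq(0, 336, 28), "current") -
               drop(cbind(1, ncs_eval(fit$basis_fix, seq(0, 336, 28))) %*%
                      beta_true))), numeric(1))
  expect_lt(mean(mhat), 0.06)   # within a few residual sds of the truth
})

test_that("dynamic predictions start at zero, increase, saturate and respect level ordering", {
  dat <- small_jm_data(n = 80, seed = 43)
  fit <- suppressWarnings(
    fit_joint(dat$long, dat$surv, dat$W,
              jm_spec(chains = 1, iter = 1000, burn = 400, thin = 2),
              seed = 47))
  alive <- dat$surv$patient_id[dat$surv$event_time > 100]
  pid <- alive[1]
  t0 <- max(dat$long$time[dat$long$patient_id == pid &
                            dat$long$time <= 100])
  dp <- dynamic_predict(fit, pid, t0, horizon = t0 + c(0, 30, 60, 120, 5000),
                        ndraw = 60)
  expect_equal(dp$risk[1], 0)
  expect_true(all(diff(dp$risk) >= 0))
  expect_true(all(dp$risk >= 0 & dp$risk <= 1))

  # identical covariates, high vs zero biomarker history
  w <- dat$W[1, ]
  mk <- function(level) list(
    long = data.frame(patient_id = "new", time = c(0, 28, 56),
                      y = level, infusion_cat = ">7"),
    w = w)
  hi <- dynamic_predict(fit, "new", 56, horizon = c(84, 140, 200, 4000),
                        ndraw = 80, newdata = mk(c(6, 6.5, 7)))
  lo <- dynamic_predict(fit, "new", 56, horizon = c(84, 140, 200, 4000),
                        ndraw = 80, newdata = mk(c(0, 0, 0)))
  expect_true(all(hi$risk >= lo$risk))
  # a rising trajectory keeps the hazard proper: risk saturates far out
  expect_gt(hi$risk[4], 0.95)
  expect_error(dynamic_predict(fit, pid, -1, horizon = 10), "t >= 0")
})

test_that("slope association reports the hazard ratio per 0.01 units", {
  dat <- small_jm_data(n = 40, seed = 53)
  fit <- suppressWarnings(
    fit_joint(dat$long, dat$surv, dat$W,
              jm_spec(association = "slope", chains = 1, iter = 400,
                      burn = 150, thin = 2), seed = 59))
  expect_equal(fit$scale, 0.01)
  expect_equal(unname(fit$alpha_hr["hr"]),
               exp(mean(fit$draws$alpha) * 0.01))
})

test_that("the CA19-9 response variant fits with the same machinery", {
  ch <- generate_cohort(sim_config(n_patients = 50), seed = 61)
  long <- prepare_longitudinal(ch, response = "ca199")
  surv <- data.frame(patient_id = ch$outcomes$patient_id,
                     event_time = ch$outcomes$pfs_day,
                     event = ch$outcomes$pfs_event)
  surv <- surv[surv$patient_id %in% long$patient_id, ]
  fit <- suppressWarnings(
    fit_joint(long, surv, NULL,
              jm_spec(infusion_adjust = FALSE, chains = 1, iter = 400,
                      burn = 150, thin = 2), seed = 67))
  expect_true(is.finite(fit$alpha_hr["hr"]))
  expect_s3_class(fit, "ctmon_jm")
})
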