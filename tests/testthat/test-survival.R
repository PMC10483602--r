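test_that("Kaplan-Meier estimate matches closed forms and a brute-force oracle", {
  km <- km_fit(data.frame(event_time = c(1, 2, 3), event = 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))

  km <- km_fit(data.frame(event_time = c(5, 8, 10), event = 0))
  expect_true(all(km$surv == 1) || length(km$surv) == 0)
  expect_true(is.na(km$median))

  set.seed(61)
  rec <- data.frame(event_time = round(rexp(200, 0.01), 2),
                    event = rbinom(200, 1, 0.8))
  km <- km_fit(rec)
  oracle <- km_oracle(rec$event_time, rec$event)
  expect_equal(km$time, oracle$time, tolerance = 1e-12)
  expect_equal(km$surv, oracle$surv, tolerance = 1e-12)
})

test_that("KM with no censoring is one minus the empirical CDF", {
  set.seed(62)
  t <- sort(sample(1:500, 40))
  km <- km_fit(data.frame(event_time = t, event = 1))
  expect_equal(km$surv, 1 - seq_along(t) / length(t), tolerance = 1e-12)
})

test_that("log-rank test matches the (O-E)^2/V oracle and its degenerate cases", {
  rec <- data.frame(event_time = c(1, 2, 3, 1, 2, 3), event = 1)
  lr <- logrank_test(rec, rep(c("a", "b"), each = 3))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  rec <- data.frame(event_time = c(1, 3, 5, 2, 6, 10), event = 1)
  lr <- logrank_test(rec, rep(c("a", "b"), each = 3))
  expect_gt(lr$chi2, 0)

  set.seed(63)
  rec <- data.frame(event_time = round(c(rexp(60, 0.02), rexp(60, 0.04)), 3),
                    event = rbinom(120, 1, 0.85))
  g <- rep(c("a", "b"), each = 60)
  lr <- logrank_test(rec, g)
  expect_equal(lr$chi2, logrank_oracle(rec$event_time, rec$event, g),
               tolerance = 1e-8)
  expect_error(logrank_test(rec, rep("a", 120)), "2 groups")
})

test_that("Cox coefficient maximises the Breslow partial likelihood", {
  rec <- data.frame(event_time = c(2, 4, 6, 7, 9, 12),
                    event = c(1, 1, 0, 1, 1, 1),
                    x = c(1, 1, 0, 0, 1, 0))
  cx <- cox_fit(rec, "x")
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, breslow_loglik, numeric(1),
               time = rec$event_time, event = rec$event, x = rec$x)
  expect_equal(cx$coef[["x"]], grid[which.max(ll)], tolerance = 1e-3)
  # refined local grid for 1e-6 agreement
  g2 <- seq(grid[which.max(ll)] - 2e-4, grid[which.max(ll)] + 2e-4,
            by = 1e-7)
  ll2 <- vapply(g2, breslow_loglik, numeric(1),
                time = rec$event_time, event = rec$event, x = rec$x)
  expect_equal(cx$coef[["x"]], g2[which.max(ll2)], tolerance = 1e-6)

  rec$x2 <- rec$x
  expect_error(cox_fit(rec, c("x", "x2")), "singular|constant")
  expect_error(cox_fit(data.frame(event_time = 1:4, event = 1, x = 1),
                       "x"), "constant")
})

test_that("Cox regression recovers a generated liver-metastasis effect", {
  gamma0 <- setNames(rep(0, 9), names(sim_config()$gamma))
  gamma0["met_liver"] <- log(2)
  cover <- vapply(1:20, function(r) {
    ch <- generate_cohort(sim_config(n_patients = 800, alpha = 0,
                                     gamma = gamma0), seed = 400 + r)
    # latent progression times: the exact proportional-hazards outcome
    lat <- ch$latent$latent_prog_day
    rec <- data.frame(event_time = pmin(lat, 730),
                      event = as.numeric(is.finite(lat) & lat <= 730),
                      liver = as.numeric(
                        ch$patients$metastasis_location == "liver"))
    hr <- cox_fit(rec, "liver")$hr
    hr$lower[1] <= 2 && 2 <= hr$upper[1]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("backward elimination keeps strong effects, drops noise, and honours the 0.1 boundary", {
  set.seed(71)
  strong_kept <- vapply(1:20, function(r) {
    n <- 200
    x <- rbinom(n, 1, 0.5)
    z1 <- rnorm(n); z2 <- rnorm(n)
    t <- rexp(n, 0.01 * exp(log(3) * x))
    rec <- data.frame(event_time = t, event = 1, x = x, z1 = z1, z2 = z2)
    "x" %in% backward_eliminate(rec, c("x", "z1", "z2"))$retained
  }, logical(1))
  expect_gte(mean(strong_kept), 0.95)

  set.seed(72)
  empty <- vapply(1:20, function(r) {
    n <- 120
    rec <- data.frame(event_time = rexp(n, 0.01), event = 1,
                      z1 = rnorm(n), z2 = rbinom(n, 1, 0.5))
    length(backward_eliminate(rec, c("z1", "z2"))$retained) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.5)

  # single candidate exactly at p = 0.05 is retained (threshold is > 0.1)
  set.seed(73)
  repeat {
    n <- 80
    x <- rbinom(n, 1, 0.5)
    rec <- data.frame(event_time = rexp(n, 0.01 * exp(0.35 * x)), event = 1,
                      x = x)
    p <- cox_fit(rec, "x")$lrt_p[["x"]]
    if (p > 0.02 && p <= 0.1) break
  }
  expect_identical(backward_eliminate(rec, "x")$retained, "x")
})

test_that("landmarking excludes early events and shifts the time origin", {
  rec <- data.frame(event_time = c(20, 100, 28), event = c(1, 1, 1))
  lm28 <- landmark(rec, 28)
  expect_equal(nrow(lm28), 1L)
  expect_equal(lm28$event_time, 72)
  expect_identical(landmark(rec, 0), rec)
})

test_that("Schoenfeld diagnostics hold their size and detect converging hazards", {
  set.seed(81)
  rejections <- vapply(1:60, function(r) {
    n <- 80
    x <- rbinom(n, 1, 0.5)
    rec <- data.frame(event_time = rexp(n, 0.02 * exp(0.5 * x)), event = 1,
                      x = x)
    fit <- cox_fit(rec, "x")
    schoenfeld_check(fit, rec)$ph_p[["x"]] < 0.05
  }, logical(1))
  expect_lte(sum(rejections), qbinom(0.995, 60, 0.05))

  # converging hazards: strong early effect that vanishes later
  set.seed(82)
  n <- 500
  x <- rep(c(0, 1), each = n / 2)
  u <- runif(n)
  t <- ifelse(x == 1,
              ifelse(u > exp(-3 * 0.5), -log(u) / 3,
                     0.5 + (-log(u) - 3 * 0.5)),
              -log(u))
  rec <- data.frame(event_time = t, event = 1, x = x)
  fit <- cox_fit(rec, "x")
  chk <- schoenfeld_check(fit, rec, group = "x")
  expect_lt(chk$ph_p[["x"]], 0.05)
  expect_true(all(c("0", "1") %in% chk$loglog$group))

  # degenerate: a single event cannot support the score test
  rec1 <- data.frame(event_time = c(5, 7, 9), event = c(1, 0, 0),
                     x = c(0.5, 0, 1))
  fit1 <- cox_fit(rec1, "x")
  p1 <- schoenfeld_check(fit1, rec1)$ph_p[["x"]]
  expect_true(is.na(p1))
})

test_that("delayed entry reproduces the untruncated fit when entry is zero", {
  set.seed(83)
  rec <- data.frame(event_time = rexp(100, 0.02), event = 1,
                    x = rbinom(100, 1, 0.5))
  f1 <- cox_fit(rec, "x")
  rec$entry_time <- 0
  # force the delayed-entry code path via a negligible positive entry
  rec$entry_time[1] <- 1e-9
  f2 <- cox_fit(rec, "x")
  expect_equal(f1$coef, f2$coef, tolerance = 1e-6)
})
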