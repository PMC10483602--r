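test_that("sample classification matches its published definition", {
  expect_equal(classify_sample(3.0, 4.2), "increase")
  expect_equal(classify_sample(0.0, 0.4), "increase")
  expect_equal(classify_sample(1.4, 0.8), "decrease")
  expect_equal(classify_sample(3.0, 2.6), "persistence")
  expect_equal(classify_sample(3.0, 1.5), "decrease")
  expect_equal(classify_sample(2.0, 0.0), "negative")
})

test_that("sample classification agrees with an exhaustive truth-table oracle", {
  grid <- seq(0, 5, by = 0.1)
  for (prev in grid) for (curr in grid)
    if (classify_sample(prev, curr) != classify_oracle(prev, curr))
      fail(sprintf("mismatch at prev=%.1f curr=%.1f", prev, curr))
  succeed()
})

test_that("patient-level calls implement both success rules", {
  calls <- data.frame(day = c(28, 56, 100),
                      category = c("decrease", "decrease", "increase"))
  res <- call_patient(calls, radiology_day = 123)
  expect_true(res$success)
  expect_equal(res$lead_time, 23)

  pers <- data.frame(day = c(28, 56), category = "persistence")
  expect_true(call_patient(pers, 60, "increase_or_persistence")$success)
  expect_false(call_patient(pers, 60, "increase_only")$success)
  expect_equal(call_patient(pers, 60)$ctdna_call_day, 28)

  fails <- data.frame(day = c(28, 56, 84),
                      category = c("decrease", "negative", "negative"))
  expect_false(call_patient(fails, 90)$success)
  expect_false(call_patient(fails[0, ], 90)$eligible)
})

test_that("success under increase_only implies success under increase_or_persistence", {
  set.seed(91)
  cats <- c("increase", "persistence", "decrease", "negative")
  for (i in 1:200) {
    k <- sample(1:5, 1)
    calls <- data.frame(day = 28 * seq_len(k),
                        category = sample(cats, k, replace = TRUE))
    a <- call_patient(calls, 28 * k + 10, "increase_only")$success
    b <- call_patient(calls, 28 * k + 10, "increase_or_persistence")$success
    if (a && !b) fail("rule monotonicity violated")
  }
  succeed()
})

test_that("monitoring eligibility follows the three entry conditions", {
  tabs <- list(
    samples = data.frame(
      patient_id = c("a", "a", "a", "b", "b", "c", "d", "d"),
      draw_day = c(0, 28, 56, 0, 28, 0, 0, 200),
      ddcq = c(2, 1, 3, 0, 1, 3, 2, 2)),
    radiology = data.frame(
      patient_id = c("a", "b", "c", "d"),
      scan_day = c(60, 56, 56, 56),
      progression = TRUE))
  el <- select_monitoring_cohort(tabs)
  # a: detected, 3 samples, sample at day 56 within 31 days of scan day 60
  # b: baseline not detected; c: single sample; d: no sample near the scan
  expect_identical(el$patient_id, "a")
  expect_equal(el$radiology_day, 60)

  ch <- generate_cohort(sim_config(), seed = 42)
  el <- select_monitoring_cohort(ch)
  prog <- ch$radiology[ch$radiology$progression, ]
  pd <- tapply(prog$scan_day, prog$patient_id, min)
  brute <- vapply(unique(ch$samples$patient_id), function(p) {
    rows <- ch$samples[ch$samples$patient_id == p, ]
    !is.na(pd[p]) && nrow(rows) >= 2 &&
      any(rows$draw_day == 0 & rows$ddcq > 0) &&
      any(abs(rows$draw_day - pd[p]) < 31)
  }, logical(1))
  expect_setequal(el$patient_id, names(brute)[brute])
})

test_that("CA19-9 calls use a >50% rise over the running nadir", {
  s <- data.frame(day = c(0, 28, 56), value = c(100, 40, 70))
  expect_equal(call_ca199(s, radiology_day = 56)$call_day, 56)

  s <- data.frame(day = c(0, 28, 56), value = c(100, 80, 60))
  expect_false(call_ca199(s, radiology_day = 56)$success)

  s <- data.frame(day = c(0, 28, 56, 84), value = c(100, 80, 115, 130))
  expect_equal(call_ca199(s, radiology_day = 84)$call_day, 84)

  expect_false(call_ca199(s[1, , drop = FALSE], 84)$success)
})

test_that("lead-time summary matches exact sign-enumeration and symmetry cases", {
  out <- data.frame(success = TRUE, lead_time = c(5, 10, 15))
  s <- lead_time_summary(out)
  expect_equal(s$median_lead, 10)
  expect_equal(s$p_value, 0.25)   # 2/2^3 sign assignments as extreme

  out <- data.frame(success = TRUE, lead_time = c(-3, 3))
  s <- lead_time_summary(out)
  expect_equal(s$median_lead, 0)
  expect_equal(s$p_value, 1)

  s0 <- lead_time_summary(data.frame(success = FALSE, lead_time = NA))
  expect_equal(s0$n_success, 0)
  expect_true(is.na(s0$median_lead))
})

test_that("a constructed ctDNA-regrowth cohort yields the constructed lead time", {
  # three patients: regrowth call exactly one CT interval minus one blood
  # interval before radiology
  mk <- function(p, shift) {
    data.frame(patient_id = p,
               draw_day = c(0, shift + c(28, 56, 84)),
               ddcq = c(3, 1.5, 1.2, 2.6))  # doubling at the 4th sample
  }
  tabs <- list(samples = rbind(mk("a", 0), mk("b", 0), mk("c", 0)),
               radiology = data.frame(patient_id = c("a", "b", "c"),
                                      scan_day = 112, progression = TRUE))
  mon <- monitor_ctdna(tabs)
  expect_true(all(mon$outcomes$success))
  s <- lead_time_summary(mon$outcomes)
  expect_equal(s$median_lead, 112 - 84)

  # lead times are invariant to shifting all dates by a constant
  tabs2 <- list(samples = rbind(mk("a", 50), mk("b", 50), mk("c", 50)),
                radiology = data.frame(patient_id = c("a", "b", "c"),
                                       scan_day = 162, progression = TRUE))
  mon2 <- monitor_ctdna(tabs2)
  expect_equal(mon2$outcomes$lead_time, mon$outcomes$lead_time)
})

test_that("synthetic cohorts show a positive median lead time", {
  ch <- generate_cohort(sim_config(), seed = 42)
  mon <- monitor_ctdna(ch)
  s <- lead_time_summary(mon$outcomes)
  expect_gt(s$median_lead, 0)
  expect_gte(s$n_success, 1)
})

test_that("marker concordance cross-tabulates and reports the union fraction", {
  ct <- data.frame(patient_id = c("a", "b", "c"),
                   success = c(TRUE, TRUE, TRUE))
  ca <- data.frame(patient_id = c("a", "b", "c"),
                   success = c(TRUE, TRUE, TRUE))
  conc <- marker_concordance(ct, ca)
  expect_equal(conc$union_fraction, 1)

  ca$success <- c(FALSE, FALSE, FALSE)
  ct$success <- c(TRUE, FALSE, TRUE)
  conc <- marker_concordance(ct, ca)
  expect_equal(conc$union_fraction, 2 / 3)
  expect_equal(unname(conc$table["ctDNA+", "CA19-9-"]), 2)

  set.seed(93)
  ct$success <- runif(3) > 0.5; ca$success <- runif(3) > 0.5
  expect_equal(marker_concordance(ct, ca)$union_fraction,
               length(union(ct$patient_id[ct$success],
                            ca$patient_id[ca$success])) / 3)
  expect_error(marker_concordance(ct, ca[c(1, 2), ]), "mismatched")
})
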