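# random 2x2 cohort with both groups and both levels represented
random_2x2_records <- function(n = 200) {
  repeat {
    rec <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      ith_group = factor(sample(c("heterogeneous", "homogeneous"), n, TRUE),
                         levels = c("heterogeneous", "homogeneous")),
      status = sample(c("yes", "no"), n, TRUE),
      stringsAsFactors = FALSE)
    tab <- table(rec$ith_group, rec$status)
    if (all(dim(tab) == c(2, 2)) && all(tab >= 5)) return(rec)
  }
}

test_that("identity-link RFD equals the closed-form difference of proportions", {
  set.seed(50)
  for (rep in 1:25) {
    rec <- random_2x2_records()
    res <- rfd(rec, "status", "yes", "no")
    p1 <- mean(rec$status[rec$ith_group == "homogeneous"] == "yes")
    p0 <- mean(rec$status[rec$ith_group == "heterogeneous"] == "yes")
    expect_equal(res$estimate, 100 * (p1 - p0), tolerance = 1e-10)
    expect_equal(res$flag, "")
    expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
  }
})

test_that("identical group proportions give a null RFD spanning zero", {
  rec <- expand_counts(data.frame(
    ith_group = rep(c("heterogeneous", "homogeneous"), each = 2),
    level = rep(c("yes", "no"), 2), n = c(30, 70, 60, 140)))
  res <- rfd(rec, "level", "yes", "no")
  expect_equal(res$estimate, 0, tolerance = 1e-10)
  expect_lt(res$ci_low, 0)
  expect_gt(res$ci_high, 0)
})

test_that("published cohort counts reproduce the printed race RFD", {
  rec <- expand_counts(data.frame(
    ith_group = rep(c("heterogeneous", "homogeneous"), each = 2),
    level = rep(c("Black", "non-Black"), 2),
    n = c(313, 416, 491, 435)), characteristic = "race")
  res <- rfd(rec, "race", "Black", "non-Black")
  expect_equal(round(res$estimate, 2), 10.09)
  expect_equal(round(res$ci_low, 2), 5.27)
  expect_equal(round(res$ci_high, 2), 14.91)
})

test_that("adjusted RFD accepts covariates and reports the adjustment set", {
  set.seed(51)
  cfg <- synthetic_config(n_patients = 800, feature_dim = 2, seed = 51)
  gc <- gen_clinical(cfg, gen_features(cfg)$truth)
  rec <- merge(gc$records, gc$truth)
  rec$ith_group <- factor(ifelse(rec$regime == "homogeneous", "homogeneous",
                                 "heterogeneous"),
                          levels = c("heterogeneous", "homogeneous"))
  res <- rfd(rec, "er", "neg", "pos", adjust = c("age_group", "race"))
  expect_equal(res$adjustment, "age_group+race")
  if (res$flag == "") {
    expect_true(is.finite(res$estimate))
    # covariates independent of ER given regime: adjustment barely moves it
    unadj <- rfd(rec, "er", "neg", "pos")
    expect_lt(abs(res$estimate - unadj$estimate), 5)
  }
})

test_that("odds ratios: cross-product, Woolf CI, logistic agreement", {
  # published molecular tables (exposure = low visual ITH)
  res <- odds_ratio(counts = rbind(homogeneous = c(78, 105),
                                   heterogeneous = c(44, 117)))
  expect_equal(round(res$estimate, 2), 1.98)
  # published CIs are profile-likelihood; Woolf agrees to ~1%
  expect_equal(res$ci_low, 1.26, tolerance = 0.02)
  expect_equal(res$ci_high, 3.13, tolerance = 0.02)
  res2 <- odds_ratio(counts = rbind(homogeneous = c(113, 59),
                                    heterogeneous = c(77, 62)))
  expect_equal(round(res2$estimate, 2), 1.54)
  # symmetric table: OR exactly 1
  sym <- odds_ratio(counts = rbind(homogeneous = c(10, 10),
                                   heterogeneous = c(10, 10)))
  expect_equal(sym$estimate, 1)
  # logistic path agrees with the cross-product ratio on the same 2x2
  set.seed(52)
  for (rep in 1:10) {
    rec <- random_2x2_records()
    a <- odds_ratio(rec, "status", "yes")$estimate
    b <- odds_ratio(rec, "status", "yes", method = "logistic")$estimate
    expect_equal(a, b, tolerance = 1e-6)
  }
  # zero cell: Haldane-Anscombe correction, flagged
  z <- odds_ratio(counts = rbind(homogeneous = c(12, 0),
                                 heterogeneous = c(7, 9)))
  expect_match(z$flag, "Haldane")
  expect_true(is.finite(z$estimate))
})

test_that("Kaplan-Meier matches the empirical survival without censoring", {
  times <- c(1, 2, 3, 4, 5, 6, 7, 8)
  rec <- data.frame(patient_id = sprintf("P%d", 1:8), time = times, event = 1,
                    ith_group = factor(rep("homogeneous", 8),
                                       levels = c("heterogeneous", "homogeneous")))
  km <- km_curve(rec, horizon = 8)
  s <- summary(km$fit, times = times)$surv
  expect_equal(s, 1 - seq_along(times) / 8, tolerance = 1e-12)
  # all censored: flat curve at 1, flagged
  rec$event <- 0
  expect_length(km_curve(rec)$flags, 1)
  expect_true(all(km_curve(rec)$risk_table$survival == 1))
  # missing-recurrence records are excluded and counted
  rec$time[1] <- NA
  expect_equal(km_curve(rec)$n_excluded, 1)
})

test_that("Cox model: null under identical event patterns, flags no-event groups", {
  rec <- data.frame(
    patient_id = sprintf("P%d", 1:20),
    time = rep(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), 2),
    event = 1,
    ith_group = factor(rep(c("heterogeneous", "homogeneous"), each = 10),
                       levels = c("heterogeneous", "homogeneous")))
  res <- cox_hr(rec)
  expect_equal(res$estimate, 1, tolerance = 1e-8)
  expect_true(is.finite(attr(res, "zph_p")))
  rec$event[rec$ith_group == "homogeneous"] <- 0
  expect_match(cox_hr(rec)$flag, "monotone")
})

test_that("planted hazard ratio is recovered on a large synthetic cohort", {
  cfg <- synthetic_config(n_patients = 4000, feature_dim = 2, true_hr = 1.6,
                          seed = 60)
  gc <- gen_clinical(cfg, gen_features(cfg)$truth)
  rec <- merge(gc$records, gc$truth)
  rec$ith_group <- factor(ifelse(rec$regime == "homogeneous", "homogeneous",
                                 "heterogeneous"),
                          levels = c("heterogeneous", "homogeneous"))
  res <- cox_hr(rec)
  expect_gt(res$estimate, 1.45)
  expect_lt(res$estimate, 1.77)
  km <- km_curve(rec)
  # homogeneous curve lies below the heterogeneous one at the horizon
  rt <- km$risk_table[km$risk_table$time == 5, ]
  expect_lt(rt$survival[grepl("homogeneous", rt$group)],
            rt$survival[grepl("heterogeneous", rt$group)])
})

test_that("association battery produces the full tidy grid", {
  cfg <- synthetic_config(n_patients = 400, feature_dim = 2, seed = 61)
  gc <- gen_clinical(cfg, gen_features(cfg)$truth)
  groups <- lapply(
    list(original = 1, epithelium = 2, stroma = 3),
    function(i) data.frame(
      patient_id = gc$truth$patient_id,
      nml = 1,
      ith_group = factor(ifelse(gc$truth$regime == "homogeneous",
                                "homogeneous", "heterogeneous"),
                         levels = c("heterogeneous", "homogeneous"))))
  out <- association_battery(gc$records, groups,
                             adjustments = list(unadjusted = NULL,
                                                adjust1 = c("age_group", "race")))
  expect_equal(nrow(out), 3 * nrow(battery_variables()) * 2)
  expect_setequal(unique(out$variant), c("original", "epithelium", "stroma"))
  # skipped variable leaves a log entry, not an error
  rec2 <- gc$records
  rec2$er <- factor("pos", levels = c("pos", "neg"))
  expect_message(out2 <- association_battery(rec2, groups["original"]),
                 "skipping er")
  expect_false("er" %in% out2$variable)
  # empty cohort: empty table, no crash
  empty <- association_battery(gc$records[0, ], list())
  expect_equal(nrow(empty), 0)
})
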