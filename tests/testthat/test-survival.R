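test_that("the product-limit estimator matches hand-applied cases", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored: survival stays at 1
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  # tied events at t=1, trailing censor has no effect
  km3 <- km_estimate(c(1, 1, 2), c(1, 1, 0))
  expect_equal(km3$surv[km3$time == 1], 1 / 3)
  expect_equal(min(km3$surv), 1 / 3)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("KM equals the empirical survivor function without censoring", {
  set.seed(41)
  tt <- round(rexp(80, 0.2), 2) + 0.01
  km <- km_estimate(tt, rep(1, 80))
  emp <- vapply(km$time, function(u) mean(tt > u), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
  # invariants: S in [0,1], non-increasing; at-risk non-increasing
  expect_true(all(km$surv >= 0 & km$surv <= 1))
  expect_true(all(diff(km$surv) <= 1e-15))
  expect_true(all(diff(km$n_risk) <= 0))
})

test_that("log-rank is null on identical groups and matches the O-E oracle", {
  tt <- c(1, 2, 3, 4, 5)
  lr0 <- logrank_test(rep(tt, 2), rep(1, 10), rep(c("a", "b"), each = 5))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # separated groups: statistic positive, equal to direct tabulation
  times <- c(1, 2, 3, 4)
  events <- c(1, 1, 1, 1)
  grp <- c("g1", "g1", "g2", "g2")
  lr <- logrank_test(times, events, grp)
  expect_gt(lr$statistic, 0)
  expect_equal(lr$statistic, oracle_logrank_2g(times, events, grp),
               tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  expect_error(logrank_test(tt, rep(1, 5), rep("a", 5)), "2 groups")
})

test_that("log-rank matches the oracle on a larger censored sample", {
  set.seed(42)
  n <- 60
  times <- round(rexp(n, 0.1), 3) + 0.001
  events <- rbinom(n, 1, 0.8)
  grp <- rep(c("a", "b"), each = n / 2)
  lr <- logrank_test(times, events, grp)
  expect_equal(lr$statistic, oracle_logrank_2g(times, events, grp),
               tolerance = 1e-8)
})

test_that("Cox on a null contrast covers HR = 1", {
  set.seed(43)
  n <- 1000
  tt <- rexp(n, 0.1)
  cens <- runif(n, 0, 20)
  f <- cox_fit(pmax(pmin(tt, cens), 1e-9), as.numeric(tt <= cens),
               data.frame(arm = rep(0:1, n / 2)))
  expect_lt(f$ci_lower, 1)
  expect_gt(f$ci_upper, 1)
  expect_true(f$ci_lower < f$hr & f$hr < f$ci_upper)
})

test_that("Cox recovers a planted hazard ratio of 3", {
  set.seed(44)
  n <- 2000
  x <- rep(0:1, each = n / 2)
  tt <- rexp(n, 0.05 * 3^x)
  cens <- runif(n, 0, quantile(tt, 0.95) * 2.2)
  f <- cox_fit(pmin(tt, cens), as.numeric(tt <= cens), data.frame(x = x))
  expect_gt(f$hr, 2.6)
  expect_lt(f$hr, 3.4)
  c_idx <- attr(f, "c_index")
  expect_gt(c_idx, 0.5)
})

test_that("the 4-observation fit matches a grid-search likelihood oracle", {
  times <- c(1, 2, 3, 4)
  events <- c(1, 1, 1, 1)
  x <- c(1, 0, 1, 0)
  f <- cox_fit(times, events, data.frame(x = x))
  beta_oracle <- grid_cox_beta(times, events, x)
  expect_equal(f$beta, beta_oracle, tolerance = 1e-4)
})

test_that("monotone partial likelihood (separation) is flagged", {
  # both early events carry x = 1: the partial likelihood is monotone in
  # beta and no finite maximum exists
  w <- capture_warnings(cox_fit(c(1, 2, 3, 4), c(1, 1, 1, 1),
                                data.frame(x = c(1, 1, 0, 0))))
  expect_true(any(grepl("monotone|separation|converge", w)))
})

test_that("Breslow and Efron agree exactly when event times are untied", {
  set.seed(45)
  n <- 40
  tt <- sort(runif(n, 1, 100))          # distinct times
  ev <- rbinom(n, 1, 0.7)
  ev[1:2] <- 1
  x <- rnorm(n)
  fe <- cox_fit(tt, ev, data.frame(x = x), ties = "efron")
  fb <- cox_fit(tt, ev, data.frame(x = x), ties = "breslow")
  expect_equal(fe$beta, fb$beta, tolerance = 1e-10)
})

test_that("log-rank and the Cox score statistic agree on large untied data", {
  set.seed(46)
  n <- 800
  x <- rep(0:1, each = n / 2)
  tt <- rexp(n, 0.1 * 1.5^x) + seq_len(n) * 1e-9   # break ties
  lr <- logrank_test(tt, rep(1, n), x)
  sc <- survival::coxph(survival::Surv(tt, rep(1, n)) ~ x)
  score_chisq <- summary(sc)$sctest["test"]
  expect_lt(abs(lr$statistic - score_chisq) / lr$statistic, 0.01)
})

test_that("Cox input validation rejects degenerate designs", {
  expect_error(cox_fit(c(1, 2), c(0, 0), data.frame(x = c(0, 1))), "event")
  expect_error(cox_fit(c(1, 2, 3), c(1, 1, 0),
                       data.frame(x = c(1, 1, 1))), "rank deficient")
})

test_that("Harrell's C hits its closed-form anchor points", {
  tt <- c(5, 4, 3, 2, 1)
  ev <- rep(1, 5)
  expect_equal(concordance_index(tt, ev, risk_scores = 1:5), 1.0)
  expect_equal(concordance_index(tt, ev, risk_scores = rep(2, 5)), 0.5)
  expect_equal(concordance_index(tt, ev, risk_scores = 5:1), 0.0)
})

test_that("random risk scores give C near one half", {
  set.seed(47)
  cs <- replicate(100, {
    tt <- rexp(200, 0.1)
    concordance_index(tt, rep(1, 200), rnorm(200))
  })
  expect_lt(abs(mean(cs) - 0.5), 0.03)
})

test_that("noising a true linear predictor degrades C", {
  set.seed(48)
  n <- 500
  lp <- rnorm(n)
  tt <- rexp(n, exp(lp) * 0.05)
  c_true <- concordance_index(tt, rep(1, n), lp)
  c_noisy <- concordance_index(tt, rep(1, n), lp + rnorm(n, 0, 3))
  expect_gt(c_true, c_noisy)
})

test_that("the outcome report recovers planted subtype hazards", {
  spec <- cohort_spec(n_per_class = c(400, 400, 400),
                      hazards = list(PCSM = c(0.03, 0.01, 0.01)),
                      censoring = 0.2, gleason_assoc = 0)
  co <- generate_cohort(spec, seed = 49)
  asn <- mk_assign(names(co$labels_a), unname(co$labels_a), scheme = "PCS")
  rep <- subtype_outcome_report(asn, co$clinical,
                                class_order = c("PCS1", "PCS2", "PCS3"))
  f <- rep$PCSM$scheme   # aggressive-vs-rest binary coding, true HR 3
  expect_gt(f$hr, 2.6)
  expect_lt(f$hr, 3.4)
  # Gleason independent of subtype: adjustment leaves the HR unchanged
  fa <- rep$PCSM$scheme_adjusted
  expect_lt(abs(log(fa$hr[fa$term == "scheme"]) - log(f$hr)), 0.1)
  # pairwise: both PCS1 contrasts exceed the null PCS2 vs PCS3 contrast
  pw <- rep$PCSM$pairwise
  expect_true(all(pw$estimable))
  hr1 <- pw$hr[pw$comparison %in% c("PCS1_vs_PCS2", "PCS1_vs_PCS3")]
  expect_true(all(hr1 > pw$hr[pw$comparison == "PCS2_vs_PCS3"]))
  expect_equal(names(rep), "PCSM")
  expect_s3_class(rep$PCSM$km$PCS1, "km_curve")
  expect_lt(rep$PCSM$logrank$p_value, 0.001)
})

test_that("zero-event subtypes yield non-estimable pairwise rows, not crashes", {
  clin <- data.frame(
    sample_id = paste0("s", 1:60),
    PCSM_time = c(rexp(40, 0.1) + 0.01, runif(20, 5, 10)),
    PCSM_event = c(rbinom(40, 1, 0.8), rep(0, 20)),
    gleason_category = bin_gleason(sample(c(6, 7, 8), 60, replace = TRUE)),
    stringsAsFactors = FALSE)
  clin$PCSM_event[1:40][1:3] <- 1
  asn <- mk_assign(clin$sample_id, rep(c("A", "B", "C"), each = 20))
  rep <- subtype_outcome_report(asn, clin, class_order = c("A", "B", "C"))
  pw <- rep$PCSM$pairwise
  expect_false(any(pw$estimable[grepl("C", pw$comparison)]))
  expect_true(all(is.na(pw$hr[!pw$estimable])))
})

test_that("a single-subtype input cannot be compared", {
  clin <- data.frame(sample_id = paste0("s", 1:10),
                     PCSM_time = rexp(10, 0.1) + 0.01,
                     PCSM_event = rep(1, 10), stringsAsFactors = FALSE)
  asn <- mk_assign(clin$sample_id, rep("A", 10))
  expect_error(subtype_outcome_report(asn, clin, class_order = "A"),
               "at least 2")
})
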