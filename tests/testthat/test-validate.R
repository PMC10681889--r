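# Survival machinery: KM vs hand product-limit, log-rank vs hypergeometric
# arithmetic, Cox vs a brute-force Efron partial-likelihood oracle,
# concordance vs exhaustive pairs, Schoenfeld and Cochran's Q calibration.

test_that("KM matches the hand product-limit formula and its invariants", {
  # no events: flat at 1
  km0 <- km_estimate(c(1, 2, 3, 4, 5), rep(0, 5))
  expect_equal(km_at(km0, 5)$surv, 1)

  # all events at 1,2,3: S after t=2 is (2/3)*(1/2) = 1/3
  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km_at(km1, 2.5)$surv, 1 / 3)

  # tied events, censoring interleaved: compare to the oracle at each step
  set.seed(4)
  tm <- round(rexp(40, 0.2), 0) + 1
  st <- rbinom(40, 1, 0.6)
  km <- km_estimate(tm, st)
  for (at in c(2, 4, 7, 11))
    expect_equal(km_at(km, at)$surv, km_hand(tm, st, at), tolerance = 1e-12)

  # survival non-increasing, S(0)=1 implied, CI contains the estimate
  expect_true(all(diff(km$surv) <= 1e-12))
  expect_true(all(km$surv <= 1 & km$surv >= 0))
  ok <- !is.na(km$lower) & !is.na(km$upper)
  expect_true(all(km$lower[ok] <= km$surv[ok] + 1e-12))
  expect_true(all(km$upper[ok] >= km$surv[ok] - 1e-12))

  expect_error(km_estimate(c(0, 0), c(1, 1)), "zero")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank equals hand-computed O-E hypergeometric tables", {
  # toy: one early event in group A only
  tm <- c(1, 5); st <- c(1, 0); gr <- c("A", "B")
  lr <- logrank(tm, st, gr)
  hand <- logrank_hand(tm, st, gr)
  expect_equal(lr$statistic, hand$statistic, tolerance = 1e-10)

  set.seed(9)
  tm <- c(rexp(30, 0.3), rexp(30, 0.6))
  st <- rbinom(60, 1, 0.8)
  gr <- rep(c("A", "B"), each = 30)
  expect_equal(logrank(tm, st, gr)$statistic,
               logrank_hand(tm, st, gr)$statistic, tolerance = 1e-8)

  # identical groups: statistic ~ 0, p ~ 1
  tm2 <- rep(c(1, 2, 3, 4), 2); st2 <- rep(c(1, 0, 1, 1), 2)
  lr2 <- logrank(tm2, st2, rep(c("A", "B"), each = 4))
  expect_lt(lr2$statistic, 1e-10)
  expect_gt(lr2$p, 0.999)
  expect_error(logrank(tm2, st2, rep("A", 8)), "two groups")
})

test_that("Cox coefficient matches the brute-force Efron grid oracle to 1e-4", {
  toys <- list(
    data.frame(t = c(1, 2, 3, 4, 5, 6), s = c(1, 1, 1, 1, 0, 1),
               x = c(1, 1, 0, 1, 0, 0)),
    data.frame(t = c(2, 2, 3, 5, 5, 7), s = c(1, 1, 0, 1, 1, 1),   # ties
               x = c(1, 0, 1, 1, 0, 0)),
    data.frame(t = c(1, 1, 2, 3, 4, 4), s = c(1, 1, 1, 1, 1, 0),
               x = c(0.5, 1.2, -0.3, 0.8, -1.1, 0.2)))              # continuous
  for (d in toys) {
    fit <- cox_fit(d, "t", "s", "x")
    oracle <- efron_grid_mle(d$t, d$s, d$x)
    expect_equal(unname(fit$terms$coef), oracle, tolerance = 1e-4)
    expect_equal(fit$terms$hr, exp(fit$terms$coef))
    expect_equal(fit$terms$lower,
                 exp(fit$terms$coef - qnorm(0.975) * fit$terms$se))
  }
})

test_that("Cox guards: no events, constant covariate; exchangeable groups give HR ~ 1", {
  d <- data.frame(t = 1:6, s = rep(0, 6), x = rep(0:1, 3))
  expect_error(cox_fit(d, "t", "s", "x"), "no events")
  d2 <- data.frame(t = 1:6, s = rep(1, 6), x = rep(1, 6))
  expect_error(cox_fit(d2, "t", "s", "x"), "constant")

  d3 <- data.frame(t = rep(c(1, 2, 3, 5, 8, 9), 2), s = rep(c(1, 0, 1, 1, 0, 1), 2),
                   x = rep(0:1, each = 6))
  fit <- cox_fit(d3, "t", "s", "x")
  expect_equal(unname(fit$terms$hr), 1, tolerance = 1e-6)
})

test_that("Harrell's c: perfect ordering, exhaustive pairs, null behaviour", {
  # risk score identical to event order -> 1
  d <- data.frame(t = c(1, 2, 3, 4), s = rep(1, 4), x = c(4, 3, 2, 1))
  fit <- suppressWarnings(cox_fit(d, "t", "s", "x"))  # perfect separation
  expect_equal(harrell_c(fit), 1)

  # 4-subject worked pairs against the exhaustive oracle
  d2 <- data.frame(t = c(2, 5, 7, 9), s = c(1, 0, 1, 1), x = c(2, 1.5, 0.4, 1))
  fit2 <- cox_fit(d2, "t", "s", "x")
  risk <- d2$x * fit2$terms$coef
  expect_equal(harrell_c(fit2), harrell_c_hand(d2$t, d2$s, risk),
               tolerance = 1e-12)

  # coefficient ~ 0 on exchangeable data -> c ~ 0.5
  set.seed(31)
  d3 <- data.frame(t = rexp(600, 0.2), s = rbinom(600, 1, 0.7),
                   x = rnorm(600))
  fit3 <- cox_fit(d3, "t", "s", "x")
  expect_lt(abs(harrell_c(fit3) - 0.5), 0.06)
})

test_that("Schoenfeld check is calibrated under proportional hazards and detects violation", {
  set.seed(17)
  # type-I: 120 null replicates at alpha = 0.05
  rej <- 0L
  for (i in 1:120) {
    d <- data.frame(rbind(simulate_endpoint(150, 0.3, hr = 1),
                          simulate_endpoint(150, 0.3, hr = 2)),
                    x = rep(0:1, each = 150))
    names(d)[1:2] <- c("t", "s")
    z <- suppressWarnings(schoenfeld_check(cox_fit(d, "t", "s", "x")))
    if (z$p[z$term == "x"] < 0.05) rej <- rej + 1L
  }
  # binomial band around 0.05 with 120 draws (4 sigma ~ 0.08)
  expect_lt(rej / 120, 0.13)

  # power: hazard doubling after year 2 in the exposed arm
  set.seed(18)
  rej_tv <- 0L
  for (i in 1:20) {
    t0 <- rexp(1000, 0.15)
    t1 <- sim_time_varying(1000, 0.10, mult_after2 = 3)
    tm <- pmin(c(t0, t1), 10)
    st <- as.integer(c(t0, t1) <= 10)
    d <- data.frame(t = tm, s = st, x = rep(0:1, each = 1000))
    z <- suppressWarnings(schoenfeld_check(cox_fit(d, "t", "s", "x")))
    if (z$p[z$term == "x"] < 0.05) rej_tv <- rej_tv + 1L
  }
  expect_gt(rej_tv / 20, 0.5)

  d1 <- data.frame(t = 1:3, s = c(1, 0, 0), x = c(1, 0, 1))
  expect_error(suppressWarnings(schoenfeld_check(cox_fit(d1, "t", "s", "x"))),
               "two events")
})

test_that("Cochran's Q: zero on identical subgroups, agrees with fixed-effect meta-analysis", {
  q0 <- cochran_q(c(0.5, 0.5, 0.5), c(0.2, 0.2, 0.2))
  expect_equal(q0$Q, 0)
  expect_equal(q0$df, 2L)
  expect_gt(q0$p, 0.999)

  coefs <- c(0.3, 0.9, 1.4, 0.1); ses <- c(0.2, 0.35, 0.5, 0.25)
  q <- cochran_q(coefs, ses)
  skip_if_not_installed("metafor")
  m <- metafor::rma(yi = coefs, sei = ses, method = "FE")
  expect_equal(q$Q, unname(m$QE), tolerance = 1e-10)
  expect_equal(q$p, unname(m$QEp), tolerance = 1e-10)
  expect_equal(q$pooled, unname(coef(m)), tolerance = 1e-10)
})

test_that("Cochran's Q rejects at the nominal rate under a common hazard ratio", {
  set.seed(23)
  rej <- 0L
  n_rep <- 150L
  for (i in seq_len(n_rep)) {
    coefs <- ses <- numeric(4)
    for (g in 1:4) {
      d <- data.frame(rbind(simulate_endpoint(120, 0.25, hr = 1),
                            simulate_endpoint(120, 0.25, hr = 2.5)),
                      x = rep(0:1, each = 120))
      names(d)[1:2] <- c("t", "s")
      fit <- cox_fit(d, "t", "s", "x")
      coefs[g] <- fit$terms$coef; ses[g] <- fit$terms$se
    }
    if (cochran_q(coefs, ses)$p < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.05)
})

test_that("subgroup forest drops event-free strata and Q is zero on duplicated data", {
  set.seed(41)
  d <- data.frame(rbind(simulate_endpoint(200, 0.3, hr = 1),
                        simulate_endpoint(200, 0.3, hr = 3)),
                  merged_group = rep(c("GR", "PR"), each = 200))
  names(d)[1:2] <- c("relapse_time", "relapse_ind")
  d2 <- rbind(cbind(d, stratum = "a"), cbind(d, stratum = "b"))
  f <- subgroup_forest(d2, "relapse_time", "relapse_ind",
                       vars = list(stratum = "stratum"))
  expect_equal(f$heterogeneity$Q, 0, tolerance = 1e-10)

  # a stratum with no PR events is dropped with a warning
  empty <- data.frame(relapse_time = rep(5, 20), relapse_ind = 0,
                      merged_group = rep(c("GR", "PR"), 10), stratum = "c")
  expect_warning(
    f2 <- subgroup_forest(rbind(d2, empty), "relapse_time", "relapse_ind",
                          vars = list(stratum = "stratum")),
    "dropped")
  expect_false("c" %in% f2$estimates$level)
})

test_that("MRD adjustment leaves the group effect unchanged when MRD is independent", {
  cfg <- cohort_config(n = 5000, seed = 61,
                       group_mix = c(GR = 0.5, PR = 0.5, not_heh = 0,
                                     ph_positive = 0, masked_doubled = 0),
                       ambiguity_rates = c(mar = 0, inc = 0))
  co <- generate_cohort(cfg)
  co$pr <- as.integer(co$intended_group == "PR")
  co$log_mrd <- mrd_log10(co$mrd)
  unadj <- cox_fit(co, "relapse_time", "relapse_ind", "pr")
  adj <- cox_fit(co, "relapse_time", "relapse_ind", c("pr", "log_mrd"))
  hr_u <- unadj$terms$hr[1]
  hr_a <- adj$terms$hr[adj$terms$term == "pr"]
  expect_lt(abs(hr_a - hr_u) / hr_u, 0.05)
})

test_that("run_validation emits the full report and honours degenerate input", {
  cfg <- cohort_config(n = 600, seed = 3)
  asg <- classify_cohort(generate_cohort(cfg))
  rep1 <- run_validation(asg)
  expect_s3_class(rep1, "heh_validation_report")
  expect_equal(nrow(rep1$survival), 3L)
  expect_true(all(c("hr", "hr_adj", "surv5_GR", "surv5_PR") %in%
                    names(rep1$survival)))
  expect_true(all(rep1$survival$hr > 0))
  expect_true(!is.null(rep1$table1))
  expect_true(all(c("relapse", "event", "death") %in% names(rep1$diagnostics)))
  expect_true(nrow(rep1$definite_vs_provisional) == 3L)

  # identical input -> identical report
  rep2 <- run_validation(asg)
  expect_identical(rep1[setdiff(names(rep1), c("km", "cox"))],
                   rep2[setdiff(names(rep2), c("km", "cox"))])

  # GR-only cohort: no hazard ratios, warning emitted
  gr_only <- asg[asg$merged_group == "GR", ]
  rep3 <- run_validation(gr_only)
  expect_true(any(grepl("one merged risk group", rep3$warnings)))
  expect_false("hr" %in% names(rep3$survival))
})

test_that("report files round-trip with headers and 10-digit precision", {
  cfg <- cohort_config(n = 400, seed = 19)
  asg <- classify_cohort(generate_cohort(cfg))
  rep1 <- run_validation(asg)
  dir <- tempfile("report")
  write_validation_report(rep1, dir, seed = 19)
  files <- list.files(dir)
  expect_true(all(c("table1.csv", "survival.csv", "km_relapse.csv",
                    "forest_relapse.csv", "heterogeneity.csv",
                    "diagnostics.json") %in% files))
  for (f in grep("csv$", files, value = TRUE))
    expect_match(readLines(file.path(dir, f), n = 1), "^# hehrisk")
  surv <- read.csv(file.path(dir, "survival.csv"), comment.char = "#")
  expect_equal(surv$hr, signif(rep1$survival$hr, 10))
})
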