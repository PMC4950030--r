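test_that("replicates are exactly reproducible from (seed, rep_index)", {
  scn <- sim_scenario(k = 6, mu = 0.2, tau2 = 0.1, n_reps = 10, seed = 7)
  d1 <- simulate_meta(scn, 3)
  d2 <- simulate_meta(scn, 3)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$v, d2$v)
  expect_false(identical(simulate_meta(scn, 4)$y, d1$y))
  # out-of-order evaluation cannot change a replicate
  invisible(simulate_meta(scn, 9))
  expect_identical(simulate_meta(scn, 3)$y, d1$y)
  # fixed v: the same within-study variances in every replicate
  expect_identical(simulate_meta(scn, 1)$v, simulate_meta(scn, 8)$v)
  scn2 <- sim_scenario(k = 6, tau2 = 0.1, n_reps = 5, seed = 7,
                       fixed_v = FALSE)
  expect_false(identical(simulate_meta(scn2, 1)$v, simulate_meta(scn2, 2)$v))
})

test_that("the normal generator has the stated first two moments", {
  k <- 4
  scn <- sim_scenario(k = k, mu = 0.3, tau2 = 0.2, n_reps = 4000, seed = 11,
                      v = c(0.05, 0.1, 0.2, 0.4))
  ys <- vapply(seq_len(scn$n_reps), function(r) simulate_meta(scn, r)$y,
               numeric(k))
  for (i in seq_len(k)) {
    tot <- scn$v[i] + scn$tau2
    expect_lt(abs(mean(ys[i, ]) - 0.3), 4 * sqrt(tot / 4000))
    # variance of y_i across replicates is v_i + tau2
    expect_lt(abs(var(ys[i, ]) - tot), 4 * tot * sqrt(2 / 4000))
  }
})

test_that("E[Q] under homogeneity is k - 1", {
  scn <- sim_scenario(k = 8, mu = 0, tau2 = 0, n_reps = 3000, seed = 13)
  qs <- vapply(seq_len(3000), function(r) cochran_q(simulate_meta(scn, r)),
               numeric(1))
  se <- sd(qs) / sqrt(3000)
  expect_lt(abs(mean(qs) - 7), 3 * se)
})

test_that("binary outcome generator produces log-OR data with Woolf variances", {
  scn <- sim_scenario(k = 12, mu = 0.4, tau2 = 0.05, n_reps = 2,
                      seed = 17, outcome = "binomial_logOR", n_arm = 2000,
                      control_risk = 0.3)
  d <- simulate_meta(scn, 1)
  expect_identical(nstudies(d), 12L)
  expect_true(all(d$n == 4000L))
  # huge arms: y_i concentrates near the true effects, v_i is small
  expect_lt(mean(abs(d$y - 0.4)), 0.8)
  expect_true(all(d$v < 0.01))
  # with a rare outcome and tiny arms, continuity correction keeps
  # everything finite
  scn2 <- sim_scenario(k = 20, mu = 0, tau2 = 0, n_reps = 1, seed = 19,
                       outcome = "binomial_logOR", n_arm = 8,
                       control_risk = 0.05)
  d2 <- simulate_meta(scn2, 1)
  expect_true(all(is.finite(d2$y)) && all(d2$v > 0))
})

test_that("estimator study reports coherent bias/MSE summaries", {
  scn <- sim_scenario(k = 8, mu = 0, tau2 = 0.05, n_reps = 300, seed = 23)
  s <- run_estimator_study(scn, methods = c("DL", "HM", "SJ", "PM"))
  expect_identical(s$method, c("DL", "HM", "SJ", "PM"))
  expect_true(all(s$n_failed == 0))
  # MSE >= bias^2 is an identity
  expect_true(all(s$mse >= s$bias^2 - 1e-12))
  # positive-by-construction methods never report zeros; DL does at small
  # tau2
  expect_equal(s$prop_zero[s$method == "HM"], 0)
  expect_equal(s$prop_zero[s$method == "SJ"], 0)
  expect_gt(s$prop_zero[s$method == "DL"], 0)
  # bit-identical reruns
  s2 <- run_estimator_study(scn, methods = c("DL", "HM", "SJ", "PM"))
  expect_identical(s, s2)
})

test_that("equal-variance replicates collapse the moment family", {
  scn <- sim_scenario(k = 5, mu = 0, tau2 = 0.15, n_reps = 25, seed = 29,
                      v = rep(0.12, 5))
  for (r in seq_len(25)) {
    d <- simulate_meta(scn, r)
    dl <- tau2_dl(d)$tau2
    expect_equal(tau2_ho(d)$tau2, dl, tolerance = 1e-10)
    expect_equal(tau2_pm(d)$tau2, dl, tolerance = 1e-8)
    expect_equal(tau2_dl2(d)$tau2, dl, tolerance = 1e-10)
    expect_equal(tau2_ho2(d)$tau2, dl, tolerance = 1e-10)
    expect_equal(tau2_reml(d)$tau2, tau2_areml(d)$tau2, tolerance = 1e-8)
  }
})

test_that("interval study measures coverage and rejects bad pairings", {
  scn <- sim_scenario(k = 6, mu = 0, tau2 = 0, n_reps = 120, seed = 31)
  s <- run_interval_study(scn, intervals = list(c("SJ", "SJ")))
  # at tau2 = 0 the SJ interval can never cover the truth
  expect_equal(s$coverage, 0)
  expect_error(run_interval_study(scn, intervals = list(c("QP", "FB"))),
               "incompatible")
  expect_warning(
    run_interval_study(sim_scenario(k = 5, tau2 = 0.1, n_reps = 5,
                                    seed = 37),
                       intervals = list(c("SJ", "DL")), force = TRUE),
    "not considered")
  s2 <- run_interval_study(scn, intervals = "QP")
  expect_identical(s2$estimator, "PM")
  expect_true(all(s2$coverage >= 0 & s2$coverage <= 1))
  expect_identical(run_interval_study(scn, intervals = "QP"), s2)
})

test_that("ML is not larger than REML on average over replicates", {
  scn <- sim_scenario(k = 5, mu = 0, tau2 = 0.1, n_reps = 400, seed = 41)
  diffs <- vapply(seq_len(400), function(r) {
    d <- simulate_meta(scn, r)
    tau2_reml(d)$tau2 - tau2_ml(d)$tau2
  }, numeric(1))
  se <- sd(diffs) / sqrt(400)
  expect_gt(mean(diffs), -3 * se)
})
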