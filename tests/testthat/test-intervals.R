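f0 <- meta_fixture("F0")
f1 <- meta_fixture("F1")
f2 <- meta_fixture("F2")

test_that("Q-profile interval matches its defining equations", {
  ci <- ci_qp(f1)
  expect_equal(ci$lower, 0)
  expect_equal(q_gen(f1, ci$upper), qchisq(0.025, 2), tolerance = 1e-7)
  expect_equal(ci$upper, 0.5 / qchisq(0.025, 2) - 0.1, tolerance = 1e-6)
  expect_message(ci0 <- ci_qp(f0), "homogeneous")
  expect_true(ci0$degenerate)
  expect_identical(c(ci0$lower, ci0$upper), c(0, 0))
  # endpoint identities on random data
  for (s in 1:8) {
    d <- rand_meta(k = 4 + s %% 6, seed = 2500 + s, tau2 = 0.3)
    ci <- suppressMessages(ci_qp(d))
    k <- nstudies(d)
    if (ci$degenerate) next
    if (ci$lower > 0)
      expect_equal(q_gen(d, ci$lower), qchisq(0.975, k - 1),
                   tolerance = 1e-6)
    expect_equal(q_gen(d, ci$upper), qchisq(0.025, k - 1), tolerance = 1e-6)
    # pairing with PM: the interval always contains the PM estimate
    pm <- tau2_pm(d)$tau2
    expect_gte(pm, ci$lower)
    expect_lte(pm, ci$upper)
  }
})

test_that("profile likelihood interval satisfies the drop equation", {
  ci <- ci_pl(f1)
  expect_equal(ci$lower, 0)
  ml <- tau2_ml(f1)$tau2
  cutoff <- log_likelihood(f1, pooled_effect(f1, ml)$mu, ml) -
    qchisq(0.95, 1) / 2
  expect_equal(log_likelihood(f1, pooled_effect(f1, ci$upper)$mu, ci$upper),
               cutoff, tolerance = 1e-7)
  # nesting across levels
  ci99 <- ci_pl(f1, 0.99)
  expect_lte(ci99$lower, ci$lower)
  expect_gte(ci99$upper, ci$upper)
  expect_equal(ci_pl(f0)$lower, 0)
})

test_that("Wald intervals use the asymptotic variance and truncate at zero", {
  ci <- ci_wald(f1, kind = "ML")
  expect_equal(ci$lower, 0)
  expect_equal(ci$upper, 1 / 15 + qnorm(0.975) * sqrt(2 / 108),
               tolerance = 1e-8)
  # width scales with the z multiplier
  ci90 <- ci_wald(f2, 0.90, kind = "ML")
  ci99 <- ci_wald(f2, 0.99, kind = "ML")
  est <- tau2_ml(f2)$tau2
  v <- asymptotic_variance(f2, est, "ML")$var_tau2
  expect_equal((ci99$upper - est) / (ci90$upper - est),
               qnorm(0.995) / qnorm(0.95), tolerance = 1e-8)
  r <- ci_wald(f2, kind = "REML")
  re <- tau2_reml(f2)$tau2
  expect_equal(r$upper, re + qnorm(0.975) *
                 sqrt(asymptotic_variance(f2, re, "REML")$var_tau2),
               tolerance = 1e-8)
})

test_that("Biggerstaff-Tweedie bounds solve the gamma tail equations", {
  ci <- ci_bt(f2)
  g_up <- gamma_moments(f2, ci$upper)
  expect_equal(pgamma(cochran_q(f2) / g_up$lam, g_up$r), 0.025,
               tolerance = 1e-6)
  if (ci$lower > 0) {
    g_lo <- gamma_moments(f2, ci$lower)
    expect_equal(pgamma(cochran_q(f2) / g_lo$lam, g_lo$r,
                        lower.tail = FALSE), 0.025, tolerance = 1e-6)
  }
  expect_message(ci0 <- ci_bt(f0), "homogeneous")
  expect_true(ci0$degenerate)
})

test_that("Biggerstaff-Jackson bounds solve the mixture cdf equations", {
  ci <- ci_bj(f2)
  q <- cochran_q(f2)
  expect_equal(mixture_cdf(mixture_coefficients(f2, ci$upper, "fe"), q),
               0.025, tolerance = 1e-6)
  expect_equal(ci$lower, 0)  # 1 - F(q; 0) > alpha/2 here
  expect_gt(1 - mixture_cdf(mixture_coefficients(f2, 0, "fe"), q), 0.025)
  # the HM transformation maps the observed statistic back to the observed
  # Q, so the two BJ routes coincide
  ci_hm <- ci_bj(f2, statistic = "HM")
  expect_equal(ci_hm$lower, ci$lower, tolerance = 1e-8)
  expect_equal(ci_hm$upper, ci$upper, tolerance = 1e-8)
  # HM-statistic cdf oracle: quadratic-form transformation of F_Q
  x <- tau2_hm(f2)$tau2
  expect_equal(hetvar:::hm_statistic_cdf(f2, x, 0.1),
               mixture_cdf(mixture_coefficients(f2, 0.1, "fe"), q),
               tolerance = 1e-9)
  expect_message(expect_true(ci_bj(f0)$degenerate), "homogeneous")
})

test_that("Jackson interval generalises BJ and honours its branches", {
  # with FE weights the Jackson construction is exactly BJ
  ci_fe <- ci_jackson(f2, scheme = "fe")
  bj <- ci_bj(f2)
  expect_equal(ci_fe$lower, bj$lower, tolerance = 1e-8)
  expect_equal(ci_fe$upper, bj$upper, tolerance = 1e-8)
  # default weights: reciprocal standard errors
  ci <- ci_jackson(f2)
  a <- 1 / sqrt(f2$v)
  mu_a <- sum(a * f2$y) / sum(a)
  q_obs <- sum(a * (f2$y - mu_a)^2)
  expect_equal(mixture_cdf(mixture_coefficients(f2, ci$upper, a), q_obs),
               0.025, tolerance = 1e-6)
  expect_message(expect_true(ci_jackson(f0)$degenerate), "homogeneous")
})

test_that("Sidik-Jonkman interval is strictly positive quantile scaling", {
  ci <- ci_sj(f1)
  expect_equal(ci$lower, 2 * 0.15625 / qchisq(0.975, 2), tolerance = 1e-10)
  expect_equal(ci$upper, 2 * 0.15625 / qchisq(0.025, 2), tolerance = 1e-10)
  expect_equal(ci$lower, 0.042357, tolerance = 1e-4)
  expect_equal(ci$upper, 6.171549, tolerance = 1e-4)
  for (s in 1:10) {
    d <- rand_meta(k = 3 + s %% 6, seed = 2600 + s, tau2 = 0)
    expect_gt(ci_sj(d)$lower, 0)  # never covers tau2 = 0
  }
  # linear scaling in the point estimate
  d <- rand_meta(k = 5, seed = 2700)
  ci1 <- ci_sj(d)
  expect_equal(ci1$upper / ci1$lower,
               qchisq(0.975, 4) / qchisq(0.025, 4), tolerance = 1e-10)
})

test_that("bootstrap intervals are seeded and handle degenerate data", {
  ci0 <- ci_bootstrap(f0, mode = "nonparametric", B = 100, seed = 4)
  expect_identical(c(ci0$lower, ci0$upper), c(0, 0))
  a <- ci_bootstrap(f2, mode = "parametric", B = 300, seed = 9)
  b <- ci_bootstrap(f2, mode = "parametric", B = 300, seed = 9)
  expect_identical(c(a$lower, a$upper), c(b$lower, b$upper))
  np <- ci_bootstrap(f2, mode = "nonparametric", B = 300, seed = 9)
  expect_gte(np$lower, 0)
  expect_gte(np$upper, np$lower)
})

test_that("parametric bootstrap quantiles approach sampling quantiles", {
  d <- rand_meta(k = 8, seed = 2800, tau2 = 0.2)
  ci <- ci_bootstrap(d, mode = "parametric", B = 3000, seed = 21)
  # oracle: independent simulation from the same fitted model
  t2 <- oracle_dl(d$y, d$v)
  mu <- sum(d$y / (d$v + t2)) / sum(1 / (d$v + t2))
  set.seed(314)
  draws <- replicate(3000, {
    oracle_dl(rnorm(8, mu, sqrt(t2 + d$v)), d$v)
  })
  qs <- quantile(draws, c(0.025, 0.975), names = FALSE)
  expect_equal(ci$lower, qs[1], tolerance = 0.15)
  expect_equal(ci$upper, qs[2], tolerance = 0.1)
})

test_that("compatibility matrix reproduces the published pairings", {
  expect_identical(compatibility("PM", "QP"), "natural")
  expect_identical(compatibility("ML", "PL"), "natural")
  expect_identical(compatibility("FB", "Wt_ML"), "incompatible")
  expect_identical(compatibility("FB", "Credible"), "natural")
  expect_identical(compatibility("DL", "QP"), "in_principle")
  expect_identical(compatibility("DL", "BJ_DL"), "natural")
  expect_identical(compatibility("PM", "BT"), "in_principle")
  expect_identical(compatibility("SJ", "SJ"), "natural")
  expect_identical(compatibility("RB0", "Credible"), "natural")
  expect_identical(compatibility("RBp", "Credible"), "incompatible")
  expect_error(compatibility("XX", "QP"), "unknown estimator")
  expect_error(compatibility("DL", "XX"), "unknown interval")
  m <- compatibility_matrix()
  expect_identical(dim(m), c(17L, 12L))
  expect_false(any(is.na(m)))
  # FB pairs only with credible intervals
  expect_true(all(m["FB", colnames(m) != "Credible"] == "incompatible"))
  # every estimator admits a Wald or credible interval
  expect_true(all(m[, "Wt_ML"] != "incompatible" |
                    m[, "Credible"] != "incompatible"))
  # SJ intervals pair naturally only with the SJ estimator
  expect_identical(names(which(m[, "SJ"] == "natural")), "SJ")
})

test_that("interval dispatcher and estimator dispatcher agree with tags", {
  expect_equal(tau2_interval(f1, "QP")$upper, ci_qp(f1)$upper)
  expect_equal(tau2_estimate(f1, "PM")$tau2, tau2_pm(f1)$tau2)
  expect_error(tau2_interval(f1, "nope"), "valid tags")
  expect_error(tau2_estimate(f1, "nope"), "valid tags")
})
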