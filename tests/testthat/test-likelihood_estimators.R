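f0 <- meta_fixture("F0")
f1 <- meta_fixture("F1")
f2 <- meta_fixture("F2")

test_that("log-likelihood matches independent normal log-density sums", {
  expect_equal(log_likelihood(f0, 0.5, 0),
               -1.5 * log(2 * pi) - 1.5 * log(0.1))
  for (s in 1:10) {
    d <- rand_meta(k = 3 + s %% 5, seed = 1000 + s)
    mu <- rnorm(1); t2 <- runif(1, 0, 0.5)
    expect_equal(log_likelihood(d, mu, t2), oracle_lnL(d$y, d$v, mu, t2))
    expect_equal(restricted_log_likelihood(d, t2),
                 oracle_restricted_lnL(d$y, d$v, t2))
  }
  # quadratic penalty: moving mu away from the weighted mean lowers lnL
  mu_w <- pooled_effect(f1, 0.1)$mu
  expect_gt(log_likelihood(f1, mu_w, 0.1),
            log_likelihood(f1, mu_w + 0.7, 0.1))
  # the restriction term is exactly -0.5 log sum of RE weights
  t2 <- 0.15
  expect_equal(restricted_log_likelihood(f1, t2),
               log_likelihood(f1, pooled_effect(f1, t2)$mu, t2) -
                 0.5 * log(sum(1 / (f1$v + t2))))
})

test_that("ML/REML/AREML reproduce equal-variance closed forms", {
  expect_equal(tau2_ml(f1)$tau2, 1 / 15, tolerance = 1e-8)
  expect_equal(tau2_ml(f0)$tau2, 0)
  expect_equal(tau2_reml(f1)$tau2, 0.15, tolerance = 1e-8)
  expect_equal(tau2_reml(f0)$tau2, 0)
  expect_equal(tau2_areml(f1)$tau2, 0.15, tolerance = 1e-8)
  expect_equal(tau2_areml(f0)$tau2, 0)
  # REML and AREML agree closely but not identically on unequal variances
  r <- tau2_reml(f2)$tau2
  a <- tau2_areml(f2)$tau2
  expect_equal(a, r, tolerance = 0.1)
  expect_false(isTRUE(all.equal(a, r, tolerance = 1e-12)))
})

test_that("iterative estimates are stationary points of their likelihoods", {
  for (s in 1:10) {
    d <- rand_meta(k = 4 + s %% 5, seed = 1100 + s, tau2 = 0.2)
    ml <- tau2_ml(d)
    if (ml$tau2 > 0) {
      # numeric derivative of the profile log-likelihood vanishes
      h <- 1e-6
      slope <- (oracle_profile_lnL(d$y, d$v, ml$tau2 + h) -
                  oracle_profile_lnL(d$y, d$v, ml$tau2 - h)) / (2 * h)
      expect_lt(abs(slope), 1e-3)
    }
    re <- tau2_reml(d)
    if (re$tau2 > 0) {
      h <- 1e-6
      slope <- (oracle_restricted_lnL(d$y, d$v, re$tau2 + h) -
                  oracle_restricted_lnL(d$y, d$v, re$tau2 - h)) / (2 * h)
      expect_lt(abs(slope), 1e-3)
    }
  }
})

test_that("iterative estimates match the dense-grid likelihood maximiser", {
  for (s in 1:10) {
    d <- rand_meta(k = 3 + s %% 6, seed = 1200 + s, tau2 = 0.15)
    hi <- max(d$v) + 4 * var(d$y)
    o_ml <- oracle_max_tau2(function(t2) oracle_profile_lnL(d$y, d$v, t2), hi)
    o_re <- oracle_max_tau2(function(t2) oracle_restricted_lnL(d$y, d$v, t2),
                            hi)
    expect_equal(tau2_ml(d)$tau2, o_ml, tolerance = 1e-7)
    expect_equal(tau2_reml(d)$tau2, o_re, tolerance = 1e-7)
  }
})

test_that("REML mu-weight variants stay close and default is self-consistent", {
  d <- rand_meta(k = 6, seed = 1300, tau2 = 0.2)
  self <- tau2_reml(d, mu_weights = "self")$tau2
  mlw <- tau2_reml(d, mu_weights = "ml")$tau2
  expect_equal(self, mlw, tolerance = 0.1)
  hi <- max(d$v) + 4 * var(d$y)
  o <- oracle_max_tau2(function(t2) oracle_restricted_lnL(d$y, d$v, t2), hi)
  expect_equal(self, o, tolerance = 1e-7)
})

test_that("asymptotic variances match the Fisher-information formulas", {
  av <- asymptotic_variance(f1, 1 / 15, "ML")
  expect_equal(av$var_tau2, 2 / 108)
  # REML information is smaller, so its variance is larger
  for (s in 1:10) {
    d <- rand_meta(k = 4 + s %% 5, seed = 1400 + s)
    t2 <- runif(1, 0, 0.3)
    expect_gte(asymptotic_variance(d, t2, "REML")$var_tau2,
               asymptotic_variance(d, t2, "ML")$var_tau2)
    # direct formula re-evaluation
    w <- 1 / (d$v + t2)
    expect_equal(asymptotic_variance(d, t2, "REML")$var_tau2,
                 2 / (sum(w^2) - 2 * sum(w^3) / sum(w) +
                        (sum(w^2) / sum(w))^2))
  }
  # information accumulates: variance decreases with k
  d5 <- meta_data(y = rep(c(0, 0.5), length.out = 5), v = rep(0.1, 5))
  d20 <- meta_data(y = rep(c(0, 0.5), length.out = 20), v = rep(0.1, 20))
  expect_lt(asymptotic_variance(d20, 0.1, "ML")$var_tau2,
            asymptotic_variance(d5, 0.1, "ML")$var_tau2)
})
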