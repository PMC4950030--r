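# Independent brute-force oracles used to check the package's estimators.
# These deliberately re-derive every quantity from first principles (naive
# formula evaluation, dense-grid maximisation, Monte Carlo) and share no
# code with the implementation under test.

# Random test datasets -------------------------------------------------------

rand_meta <- function(k = 5, seed = 1, equal_v = FALSE, tau2 = 0.1,
                      with_n = FALSE) {
  set.seed(seed)
  v <- if (equal_v) rep(runif(1, 0.02, 0.3), k) else runif(k, 0.02, 0.3)
  y <- rnorm(k, 0.3, sqrt(tau2)) + rnorm(k, 0, sqrt(v))
  meta_data(y = y, v = v,
            n = if (with_n) sample(10:200, k, replace = TRUE) else NULL)
}

# Naive closed-form estimators ------------------------------------------------

oracle_q <- function(y, v) {
  m <- sum(y / v) / sum(1 / v)
  sum((y - m)^2 / v)
}

oracle_dl <- function(y, v) {
  w <- 1 / v
  max(0, (oracle_q(y, v) - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

oracle_ho <- function(y, v) {
  max(0, var(y) - mean(v))
}

oracle_hs <- function(y, v) {
  max(0, (oracle_q(y, v) - length(y)) / sum(1 / v))
}

oracle_hm <- function(y, v) {
  q <- oracle_q(y, v)
  w <- 1 / v
  q^2 / ((2 * (length(y) - 1) + q) * (sum(w) - sum(w^2) / sum(w)))
}

oracle_gmm <- function(y, v, a) {
  mu <- sum(a * y) / sum(a)
  qa <- sum(a * (y - mu)^2)
  num <- qa - (sum(a * v) - sum(a^2 * v) / sum(a))
  max(0, num / (sum(a) - sum(a^2) / sum(a)))
}

oracle_two_step <- function(y, v, step1) {
  oracle_gmm(y, v, 1 / (v + step1))
}

# Rukhin Bayes, re-evaluated independently with the same adopted grouping
oracle_rb <- function(y, v, n, prior) {
  k <- length(y)
  N <- sum(n)
  max(0, sum((y - mean(y))^2) / (k + 1) +
        (2 * k * (N - k) * prior - (k - 1) * sum(v)) / ((N + k) * (k + 1)))
}

# Log-likelihoods from scratch (sum of univariate normal log-densities) ------

oracle_lnL <- function(y, v, mu, t2) {
  sum(dnorm(y, mu, sqrt(v + t2), log = TRUE))
}

oracle_profile_lnL <- function(y, v, t2) {
  mu <- sum(y / (v + t2)) / sum(1 / (v + t2))
  oracle_lnL(y, v, mu, t2)
}

oracle_restricted_lnL <- function(y, v, t2) {
  oracle_profile_lnL(y, v, t2) - 0.5 * log(sum(1 / (v + t2)))
}

# Dense-grid maximiser with successive zoom and a final parabolic vertex
# through the best three nodes; locates a smooth interior maximum to ~1e-12.
oracle_grid_max <- function(f, lo, hi, rounds = 7, n = 201) {
  for (r in seq_len(rounds)) {
    xs <- seq(lo, hi, length.out = n)
    fs <- vapply(xs, f, numeric(1))
    i <- which.max(fs)
    lo2 <- xs[max(1, i - 2)]
    hi2 <- xs[min(n, i + 2)]
    if (hi2 - lo2 < 1e-4 * max(1, abs(xs[i]))) break
    lo <- lo2; hi <- hi2
  }
  if (i == 1 || i == n) return(xs[i])
  # parabola through (x_{i-1}, x_i, x_{i+1}); equal spacing h
  h <- xs[2] - xs[1]
  num <- fs[i - 1] - fs[i + 1]
  den <- fs[i - 1] - 2 * fs[i] + fs[i + 1]
  if (den >= 0) return(xs[i])
  xs[i] + 0.5 * h * num / den
}

oracle_max_tau2 <- function(obj, hi) {
  m <- oracle_grid_max(obj, 0, hi)
  if (obj(0) >= obj(m)) 0 else max(0, m)
}

# Monte-Carlo cdf of a positive chi-squared(1) mixture, chunked -------------

oracle_mixture_mc <- function(lambdas, xs, n = 1e7, seed = 1,
                              chunk = 1e6) {
  set.seed(seed)
  m <- length(lambdas)
  counts <- numeric(length(xs))
  done <- 0
  while (done < n) {
    nb <- min(chunk, n - done)
    q <- as.vector(lambdas %*% matrix(rchisq(m * nb, df = 1), nrow = m))
    counts <- counts + vapply(xs, function(x) sum(q <= x), numeric(1))
    done <- done + nb
  }
  counts / n
}

# Random-walk Metropolis sampler for the hierarchical model, used as the
# stochastic oracle for the deterministic-quadrature posterior.
oracle_fb_mcmc <- function(y, v, scale = 100, n_iter = 6e4, seed = 1,
                           prop_sd = 0.4) {
  set.seed(seed)
  # random walk on (mu, log tau); the log scale turns the polynomially
  # heavy upper tail of tau into an exponential one, so the chain both
  # reaches and leaves the tail (the Jacobian adds +log tau)
  lp <- function(mu, ltau) {
    tau <- exp(ltau)
    sum(dnorm(y, mu, sqrt(v + tau^2), log = TRUE)) -
      tau^2 / (2 * scale^2) + ltau
  }
  mu <- mean(y); ltau <- log(sd(y))
  out <- numeric(n_iter)
  cur <- lp(mu, ltau)
  for (i in seq_len(n_iter)) {
    s <- if (runif(1) < 0.7) prop_sd else 5 * prop_sd
    mu2 <- mu + rnorm(1, 0, s)
    ltau2 <- ltau + rnorm(1, 0, s)
    new <- lp(mu2, ltau2)
    if (log(runif(1)) < new - cur) { mu <- mu2; ltau <- ltau2; cur <- new }
    out[i] <- exp(ltau)
  }
  out[-seq_len(n_iter / 4)]
}
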