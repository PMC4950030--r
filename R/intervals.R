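new_tau2_interval <- function(method, level, lower, upper,
                              degenerate = FALSE, point_method = NA_character_) {
  if (degenerate) { lower <- 0; upper <- 0 }
  structure(list(method = method, level = level,
                 lower = max(0, lower), upper = upper,
                 degenerate = degenerate, point_method = point_method),
            class = "tau2_interval")
}

#' @export
print.tau2_interval <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("%g%% %s interval for tau2: [0, 0] (null set)\n",
                100 * x$level, x$method))
  else
    cat(sprintf("%g%% %s interval for tau2: [%.6g, %.6g]\n",
                100 * x$level, x$method, x$lower, x$upper))
  invisible(x)
}

# Internal: find the root of f on [0, cap] by doubling a bracket from
# [0, max(v)]; hitting the cap is an explicit error.
expand_uniroot <- function(f, start, cap, tol = 1e-10) {
  hi <- start
  f_hi <- f(hi)
  f0 <- f(0)
  while (sign(f_hi) == sign(f0)) {
    hi <- hi * 2
    if (hi > cap)
      stop("root search exceeded bound ", format(cap), call. = FALSE)
    f_hi <- f(hi)
  }
  uniroot(f, c(0, hi), f.lower = f0, f.upper = f_hi, tol = tol)$root
}

#' Profile likelihood confidence interval for the between-study variance
#'
#' The interval is the set of \eqn{\tilde\tau^2} whose profile
#' log-likelihood stays within \eqn{\chi^2_{1,level}/2} of the maximised
#' log-likelihood at the ML solution:
#' \eqn{\ln L(\hat\mu_{RE}(\tilde\tau^2), \tilde\tau^2) \ge
#' \ln L(\hat\mu_{ML}, \hat\tau^2_{ML}) - \chi^2_{1,level}/2.}
#' The lower bound is truncated at zero when the criterion already holds
#' there.
#'
#' @inheritParams pooled_effect
#' @param level confidence level in (0, 1).
#' @return A `tau2_interval` object.
#' @export
ci_pl <- function(data, level = 0.95) {
  stopifnot(inherits(data, "meta_data"))
  ml <- tau2_ml(data)
  lmax <- profile_log_likelihood(data, ml$tau2)
  cut <- lmax - qchisq(level, 1) / 2
  f <- function(t2) profile_log_likelihood(data, t2) - cut
  lower <- if (f(0) >= 0) 0 else uniroot(f, c(0, ml$tau2), tol = 1e-10)$root
  cap <- 1e4 * max(data$v)
  hi <- max(ml$tau2, max(data$v))
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > cap)
      stop("no upper likelihood crossing within bound ", format(cap),
           call. = FALSE)
  }
  upper <- uniroot(f, c(max(ml$tau2, lower), hi), tol = 1e-10)$root
  new_tau2_interval("PL", level, lower, upper, point_method = "ML")
}

#' Wald-type confidence interval for the between-study variance
#'
#' \eqn{\hat\tau^2 \pm z_{1-\alpha/2}\sqrt{Var(\hat\tau^2)}} with the
#' Fisher-information asymptotic variance of the ML or REML estimator; a
#' negative lower bound is truncated to zero.
#'
#' @inheritParams ci_pl
#' @param kind `"ML"` or `"REML"`: which estimator and asymptotic variance.
#' @return A `tau2_interval` object.
#' @export
ci_wald <- function(data, level = 0.95, kind = c("ML", "REML")) {
  kind <- match.arg(kind)
  est <- if (kind == "ML") tau2_ml(data) else tau2_reml(data)
  v <- asymptotic_variance(data, est$tau2, kind)$var_tau2
  z <- qnorm(1 - (1 - level) / 2)
  new_tau2_interval(paste0("Wt_", kind), level,
                    est$tau2 - z * sqrt(v), est$tau2 + z * sqrt(v),
                    point_method = kind)
}

#' Biggerstaff-Tweedie confidence interval
#'
#' Approximates the distribution of Cochran's Q at a candidate
#' \eqn{\tau^2} by a moment-matched gamma distribution (see
#' [gamma_moments()]) and inverts the two tail equations
#' \eqn{P(Q > Q_{obs}; \tilde\tau^2) = \alpha/2} (lower bound) and
#' \eqn{P(Q \le Q_{obs}; \tilde\tau^2) = \alpha/2} (upper bound).  When
#' even \eqn{\tau^2 = 0} places the observed Q below the \eqn{\alpha/2}
#' quantile, the interval is the null set `[0, 0]`.
#'
#' @inheritParams ci_pl
#' @return A `tau2_interval` object (`degenerate = TRUE` for the null set).
#' @export
ci_bt <- function(data, level = 0.95) {
  stopifnot(inherits(data, "meta_data"))
  alpha <- 1 - level
  q <- cochran_q(data)
  pupper <- function(t2) {  # P(Q > q_obs) under gamma approx at t2
    g <- gamma_moments(data, t2)
    pgamma(q / g$lam, shape = g$r, lower.tail = FALSE)
  }
  plower <- function(t2) {
    g <- gamma_moments(data, t2)
    pgamma(q / g$lam, shape = g$r)
  }
  if (plower(0) < alpha / 2) {
    message("the data appear to be highly homogeneous; reporting [0, 0]")
    return(new_tau2_interval("BT", level, 0, 0, degenerate = TRUE,
                             point_method = "DL"))
  }
  cap <- 1e4 * max(data$v)
  lower <- if (pupper(0) > alpha / 2) 0 else
    expand_uniroot(function(t2) pupper(t2) - alpha / 2, max(data$v), cap)
  upper <- expand_uniroot(function(t2) plower(t2) - alpha / 2,
                          max(data$v), cap)
  new_tau2_interval("BT", level, lower, upper, point_method = "DL")
}

# Internal: cdf in tau2 of the observed Q_a under the chi-square mixture
# law, F_{Q_a}(q_obs; tau2).
qa_cdf <- function(data, q_obs, tau2, scheme) {
  lam <- mixture_coefficients(data, tau2, scheme)
  mixture_cdf(lam, q_obs, abs_tol = 1e-9)
}

# Internal: shared driver for the BJ and Jackson interval constructions,
# which differ only in the weighting scheme defining Q_a.
generalized_q_ci <- function(data, level, scheme, method, point_method) {
  alpha <- 1 - level
  a <- resolve_weights(data, scheme)
  mu_a <- sum(a * data$y) / sum(a)
  q_obs <- sum(a * (data$y - mu_a)^2)
  Fc <- function(t2) qa_cdf(data, q_obs, t2, a)
  F0 <- Fc(0)
  if (F0 < alpha / 2) {
    message("the data appear to be highly homogeneous; reporting [0, 0]")
    return(new_tau2_interval(method, level, 0, 0, degenerate = TRUE,
                             point_method = point_method))
  }
  cap <- 1e4 * max(data$v)
  lower <- if (1 - F0 > alpha / 2) 0 else
    expand_uniroot(function(t2) (1 - Fc(t2)) - alpha / 2, max(data$v), cap,
                   tol = 1e-9)
  upper <- expand_uniroot(function(t2) Fc(t2) - alpha / 2, max(data$v), cap,
                          tol = 1e-9)
  new_tau2_interval(method, level, lower, upper, point_method = point_method)
}

#' Biggerstaff-Jackson confidence interval
#'
#' Exact inversion of the distribution of Cochran's Q, computed as a
#' positive linear combination of chi-squared(1) variables (see
#' [mixture_cdf()]).  The bounds solve
#' \eqn{1 - F_Q(Q_{obs}; \tilde\tau^2) = \alpha/2} and
#' \eqn{F_Q(Q_{obs}; \tilde\tau^2) = \alpha/2}; the lower bound is zero
#' when \eqn{1 - F_Q(Q_{obs}; 0) > \alpha/2} and the interval is the null
#' set when \eqn{F_Q(Q_{obs}; 0) < \alpha/2}.
#'
#' The `statistic` argument selects the monotone transformation of Q whose
#' distribution is inverted: the untruncated DerSimonian-Laird estimator
#' (a linear function of Q) or the Hartung-Makambi estimator.  Because the
#' observed value of either statistic maps back to the observed Q, both
#' yield identical intervals; the HM route is retained as a check of the
#' quadratic-form transformation.
#'
#' @inheritParams ci_pl
#' @param statistic `"DL"` or `"HM"`.
#' @return A `tau2_interval` object.
#' @export
ci_bj <- function(data, level = 0.95, statistic = c("DL", "HM")) {
  stopifnot(inherits(data, "meta_data"))
  statistic <- match.arg(statistic)
  generalized_q_ci(data, level, "fe",
                   method = paste0("BJ_", statistic),
                   point_method = statistic)
}

# Internal: F of the HM estimator at value x, via the quadratic-form map
# tau2_HM <= x  <=>  Q in [root_lo, root_hi]; exposed for testing.
hm_statistic_cdf <- function(data, x, tau2) {
  s <- weight_sums(data)
  sc <- s$S1 - s$S2 / s$S1
  k <- nstudies(data)
  disc <- sqrt((sc * x / 2)^2 + 2 * (k - 1) * sc * x)
  hi <- sc * x / 2 + disc
  lo <- sc * x / 2 - disc
  lam <- mixture_coefficients(data, tau2, "fe")
  p_hi <- mixture_cdf(lam, hi)
  p_lo <- if (lo > 0) mixture_cdf(lam, lo) else 0
  p_hi - p_lo
}

#' Jackson generalised-Q confidence interval
#'
#' [ci_bj()] generalised to an arbitrary positive weighting scheme for the
#' Q statistic.  The default weights are the reciprocal within-study
#' standard errors \eqn{a_i = 1/\sqrt{v_i}} (offset `x = 0`, exponent
#' `p = 1/2`), which give an exact interval under the random-effects model
#' with known within-study variances.
#'
#' @inheritParams ci_pl
#' @param scheme weighting scheme as in [generalized_q()]; default
#'   `list(x = 0, p = 1/2)`.
#' @return A `tau2_interval` object.
#' @export
ci_jackson <- function(data, level = 0.95, scheme = list(x = 0, p = 0.5)) {
  stopifnot(inherits(data, "meta_data"))
  generalized_q_ci(data, level, scheme, method = "Jackson",
                   point_method = "GMM")
}

#' Q-profile confidence interval
#'
#' Inverts the pivotal distribution \eqn{Q_{gen}(\tau^2) \sim
#' \chi^2_{k-1}}: the bounds solve
#' \eqn{Q_{gen}(\tilde\tau^2) = \chi^2_{k-1,1-\alpha/2}} (lower) and
#' \eqn{Q_{gen}(\tilde\tau^2) = \chi^2_{k-1,\alpha/2}} (upper).  Exact
#' under the random-effects model with known within-study variances.  The
#' lower bound truncates to zero when \eqn{Q_{gen}(0) <
#' \chi^2_{k-1,1-\alpha/2}}; when \eqn{Q_{gen}(0) < \chi^2_{k-1,\alpha/2}}
#' the whole interval is the null set `[0, 0]`.
#'
#' @inheritParams ci_pl
#' @return A `tau2_interval` object.
#' @export
ci_qp <- function(data, level = 0.95) {
  stopifnot(inherits(data, "meta_data"))
  alpha <- 1 - level
  k <- nstudies(data)
  q0 <- q_gen(data, 0)
  lo_crit <- qchisq(1 - alpha / 2, k - 1)
  hi_crit <- qchisq(alpha / 2, k - 1)
  if (q0 < hi_crit) {
    message("the data appear to be highly homogeneous; reporting [0, 0]")
    return(new_tau2_interval("QP", level, 0, 0, degenerate = TRUE,
                             point_method = "PM"))
  }
  cap <- 1e4 * max(data$v)
  lower <- if (q0 < lo_crit) 0 else
    expand_uniroot(function(t2) q_gen(data, t2) - lo_crit, max(data$v), cap)
  upper <- expand_uniroot(function(t2) q_gen(data, t2) - hi_crit,
                          max(data$v), cap)
  new_tau2_interval("QP", level, lower, upper, point_method = "PM")
}

#' Sidik-Jonkman confidence interval
#'
#' Scales the Sidik-Jonkman estimate by chi-squared quantiles:
#' \eqn{[(k-1)\hat\tau^2_{SJ}/\chi^2_{k-1,1-\alpha/2},\;
#' (k-1)\hat\tau^2_{SJ}/\chi^2_{k-1,\alpha/2}]}.  Both bounds are strictly
#' positive, so the interval can never cover \eqn{\tau^2 = 0}.
#'
#' @inheritParams ci_pl
#' @param variant Sidik-Jonkman variant passed to [tau2_sj()].
#' @return A `tau2_interval` object.
#' @export
ci_sj <- function(data, level = 0.95, variant = "original") {
  stopifnot(inherits(data, "meta_data"))
  alpha <- 1 - level
  k <- nstudies(data)
  sj <- tau2_sj(data, variant)$tau2
  new_tau2_interval("SJ", level,
                    (k - 1) * sj / qchisq(1 - alpha / 2, k - 1),
                    (k - 1) * sj / qchisq(alpha / 2, k - 1),
                    point_method = "SJ")
}

#' Bootstrap confidence intervals
#'
#' Percentile intervals from `B` bootstrap replicates of a base estimator.
#' The parametric mode redraws effects from the fitted random-effects model
#' \eqn{y_i^* \sim N(\hat\mu_{RE}(\hat\tau^2), \hat\tau^2 + v_i)} keeping
#' the within-study variances; the non-parametric mode resamples
#' \eqn{(y_i, v_i)} pairs with replacement.  Deterministic given `seed`.
#'
#' @inheritParams ci_pl
#' @param mode `"parametric"` or `"nonparametric"`.
#' @param base a function `meta_data -> tau2_estimate` applied per
#'   replicate (default [tau2_dl()]).
#' @param B number of bootstrap replicates.
#' @param seed integer seed for the bootstrap stream.
#' @return A `tau2_interval` object.
#' @export
ci_bootstrap <- function(data, level = 0.95,
                         mode = c("parametric", "nonparametric"),
                         base = tau2_dl, B = 1000, seed = 1) {
  stopifnot(inherits(data, "meta_data"))
  mode <- match.arg(mode)
  alpha <- 1 - level
  k <- nstudies(data)
  est0 <- base(data)$tau2
  mu0 <- pooled_effect(data, est0)$mu
  vals <- with_local_seed(seed, {
    out <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      d <- if (mode == "parametric") {
        meta_data(y = rnorm(k, mu0, sqrt(est0 + data$v)), v = data$v,
                  n = data$n)
      } else {
        i <- sample.int(k, k, replace = TRUE)
        meta_data(y = data$y[i], v = data$v[i],
                  n = if (is.null(data$n)) NULL else data$n[i])
      }
      e <- try(base(d), silent = TRUE)
      if (!inherits(e, "try-error")) out[b] <- e$tau2
    }
    out
  })
  ok <- sum(!is.na(vals))
  if (ok < B / 2)
    stop("bootstrap failed on more than half of the replicates", call. = FALSE)
  qs <- quantile(vals, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                 names = FALSE, type = 7)
  new_tau2_interval(if (mode == "parametric") "BootPar" else "BootNonpar",
                    level, qs[1], qs[2], point_method = "DL")
}

# ---------------------------------------------------------------------------
# Estimator / interval compatibility

.estimator_tags <- c("DL", "DLp", "DL2", "HO", "HO2", "PM", "HM", "HS",
                     "ML", "REML", "AREML", "SJ", "RB0", "RBp", "FB", "BM",
                     "DLb")
.interval_tags <- c("PL", "Wt_ML", "Wt_REML", "BT", "BJ_DL", "BJ_HM",
                    "Jackson", "QP", "SJ", "BootPar", "BootNonpar",
                    "Credible")

# Column families: PL | Wt | BTJ (BT/BJ/Jackson) | QP | SJ | Boot | Cred
.compat_families <- list(
  #        PL    Wt    BTJ   QP    SJ    Boot  Cred
  DL    = c("-", "v",  "v",  "p",  "-",  "v",  "-"),
  DLp   = c("-", "v",  "v",  "p",  "-",  "v",  "-"),
  DL2   = c("-", "v",  "v",  "p",  "-",  "v",  "-"),
  HO    = c("-", "v",  "v",  "p",  "-",  "v",  "-"),
  HO2   = c("-", "v",  "v",  "p",  "-",  "v",  "-"),
  PM    = c("-", "v",  "p",  "v",  "-",  "v",  "-"),
  HM    = c("-", "v",  "v",  "p",  "-",  "v",  "-"),
  HS    = c("-", "v",  "p",  "p",  "-",  "v",  "-"),
  ML    = c("v", "v",  "p",  "p",  "-",  "v",  "-"),
  REML  = c("v", "v",  "p",  "p",  "-",  "v",  "-"),
  AREML = c("v", "v",  "p",  "p",  "-",  "v",  "-"),
  SJ    = c("-", "v",  "p",  "p",  "v",  "v",  "-"),
  RB0   = c("-", "v",  "p",  "p",  "-",  "v",  "v"),
  RBp   = c("-", "v",  "p",  "p",  "-",  "v",  "-"),
  FB    = c("-", "-",  "-",  "-",  "-",  "-",  "v"),
  BM    = c("-", "v",  "p",  "p",  "-",  "v",  "-"),
  DLb   = c("-", "v",  "p",  "p",  "-",  "v",  "-")
)

interval_family <- function(interval) {
  switch(interval,
         PL = 1L, Wt_ML = 2L, Wt_REML = 2L,
         BT = 3L, BJ_DL = 3L, BJ_HM = 3L, Jackson = 3L,
         QP = 4L, SJ = 5L, BootPar = 6L, BootNonpar = 6L,
         Credible = 7L,
         stop("unknown interval tag: ", interval, call. = FALSE))
}

#' Compatibility of estimator / interval pairings
#'
#' Classifies each (point estimator, interval method) pair as `"natural"`
#' (based on the same statistical principle), `"in_principle"` (can be
#' paired, but not naturally), or `"incompatible"`.  The fully Bayesian
#' estimator pairs only with credible intervals.
#'
#' @param estimator estimator tag, one of `DL, DLp, DL2, HO, HO2, PM, HM,
#'   HS, ML, REML, AREML, SJ, RB0, RBp, FB, BM, DLb`.
#' @param interval interval tag, one of `PL, Wt_ML, Wt_REML, BT, BJ_DL,
#'   BJ_HM, Jackson, QP, SJ, BootPar, BootNonpar, Credible`.
#' @return One of `"natural"`, `"in_principle"`, `"incompatible"`.
#' @examples
#' compatibility("PM", "QP")   # natural pairing
#' compatibility("FB", "Wt_ML")  # incompatible
#' @export
compatibility <- function(estimator, interval) {
  if (!estimator %in% .estimator_tags)
    stop("unknown estimator tag: ", estimator, call. = FALSE)
  if (!interval %in% .interval_tags)
    stop("unknown interval tag: ", interval, call. = FALSE)
  cell <- .compat_families[[estimator]][interval_family(interval)]
  c(v = "natural", p = "in_principle", "-" = "incompatible")[[cell]]
}

#' Full compatibility matrix
#'
#' @return A character matrix (estimators by interval methods) of
#'   [compatibility()] classifications.
#' @export
compatibility_matrix <- function() {
  m <- outer(.estimator_tags, .interval_tags,
             Vectorize(function(e, i) compatibility(e, i)))
  dimnames(m) <- list(.estimator_tags, .interval_tags)
  m
}
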