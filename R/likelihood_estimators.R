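#' Marginal normal log-likelihood of a random-effects meta-analysis
#'
#' \deqn{\ln L(\mu, \tau^2) = -\tfrac{k}{2}\ln 2\pi - \tfrac12 \sum \ln(v_i
#'   + \tau^2) - \tfrac12 \sum (y_i - \mu)^2/(v_i + \tau^2),}
#' the log-density of \eqn{y_i \sim N(\mu, v_i + \tau^2)} independently.
#'
#' @inheritParams pooled_effect
#' @param mu candidate mean effect.
#' @return Log-likelihood value (finite scalar).
#' @export
log_likelihood <- function(data, mu, tau2) {
  stopifnot(inherits(data, "meta_data"))
  if (tau2 < 0) stop("`tau2` must be non-negative", call. = FALSE)
  s2 <- data$v + tau2
  -0.5 * nstudies(data) * log(2 * pi) - 0.5 * sum(log(s2)) -
    0.5 * sum((data$y - mu)^2 / s2)
}

# Internal: log-likelihood profiled over mu at fixed tau2.
profile_log_likelihood <- function(data, tau2) {
  log_likelihood(data, pooled_effect(data, tau2)$mu, tau2)
}

#' Restricted log-likelihood for the between-study variance
#'
#' The profiled marginal log-likelihood plus the restriction term
#' \eqn{-\tfrac12 \ln \sum 1/(v_i + \tau^2)}, which corrects for the
#' estimation of \eqn{\mu}.
#'
#' @inheritParams pooled_effect
#' @return Restricted log-likelihood value.
#' @export
restricted_log_likelihood <- function(data, tau2) {
  stopifnot(inherits(data, "meta_data"))
  if (tau2 < 0) stop("`tau2` must be non-negative", call. = FALSE)
  profile_log_likelihood(data, tau2) - 0.5 * log(sum(1 / (data$v + tau2)))
}

# Internal: generic fixed-point driver for the likelihood family.
# `update(tau2)` returns the next iterate (already truncated at 0).  On
# oscillation or iteration-cap the driver falls back to bounded scalar
# maximisation of `objective` and flags how convergence was achieved.
iterate_tau2 <- function(tau2_init, update, objective, tol, max_iter,
                         method) {
  t2 <- max(0, tau2_init)
  for (it in seq_len(max_iter)) {
    t2_new <- update(t2)
    if (abs(t2_new - t2) <= tol * (1 + t2)) {
      return(new_tau2_estimate(method, t2_new, truncate = TRUE,
                               iterations = it, converged = TRUE))
    }
    t2 <- t2_new
  }
  # Fallback: direct bounded maximisation of the profile objective.
  hi <- max(1, 10 * max(abs(t2), 1))
  while (objective(hi) > objective(hi / 2) && hi < 1e8) hi <- hi * 10
  opt <- optimize(objective, c(0, hi), maximum = TRUE,
                  tol = .Machine$double.eps^0.5)
  t2_opt <- if (objective(0) >= opt$objective) 0 else opt$maximum
  new_tau2_estimate(method, t2_opt, truncate = TRUE,
                    iterations = max_iter, converged = FALSE)
}

#' Maximum likelihood estimator of the between-study variance
#'
#' Iterates the ML fixed-point equations
#' \deqn{\hat\mu = \sum w_i y_i / \sum w_i, \qquad
#'   \hat\tau^2 = \max\left(0, \frac{\sum w_i^2 [(y_i - \hat\mu)^2 -
#'   v_i]}{\sum w_i^2}\right), \quad w_i = 1/(v_i + \hat\tau^2),}
#' from a DerSimonian-Laird start, truncating at zero in every step.  If
#' the iteration fails to settle it falls back to bounded maximisation of
#' the profile log-likelihood.
#'
#' @inheritParams pooled_effect
#' @param tau2_init starting value; defaults to the DL estimate.
#' @param tol relative-plus-absolute convergence tolerance on `tau2`.
#' @param max_iter iteration cap before the optimisation fallback.
#' @return A `tau2_estimate` object.
#' @export
tau2_ml <- function(data, tau2_init = NULL, tol = 1e-10, max_iter = 100) {
  stopifnot(inherits(data, "meta_data"))
  if (is.null(tau2_init)) tau2_init <- tau2_dl(data)$tau2
  upd <- function(t2) {
    w <- 1 / (data$v + t2)
    mu <- sum(w * data$y) / sum(w)
    max(0, sum(w^2 * ((data$y - mu)^2 - data$v)) / sum(w^2))
  }
  iterate_tau2(tau2_init, upd, function(t2) profile_log_likelihood(data, t2),
               tol, max_iter, "ML")
}

#' Restricted maximum likelihood estimator
#'
#' Iterates
#' \deqn{\hat\tau^2 = \max\left(0, \frac{\sum w_i^2 [(y_i - \hat\mu)^2 -
#'   v_i]}{\sum w_i^2} + \frac{1}{\sum w_i}\right), \quad
#'   w_i = 1/(v_i + \hat\tau^2),}
#' the stationarity condition of the restricted log-likelihood.  By default
#' the inner pooled mean \eqn{\hat\mu} is recomputed with the current
#' REML weights (self-consistent iteration, verified against a grid
#' maximiser of [restricted_log_likelihood()]); `mu_weights = "ml"` instead
#' freezes \eqn{\hat\mu} at the ML solution.
#'
#' @inheritParams tau2_ml
#' @param mu_weights `"self"` (default) or `"ml"`; which weights define the
#'   pooled mean inside the update.
#' @return A `tau2_estimate` object.
#' @export
tau2_reml <- function(data, tau2_init = NULL, tol = 1e-10, max_iter = 100,
                      mu_weights = c("self", "ml")) {
  stopifnot(inherits(data, "meta_data"))
  mu_weights <- match.arg(mu_weights)
  if (is.null(tau2_init)) tau2_init <- tau2_dl(data)$tau2
  mu_fixed <- if (mu_weights == "ml")
    pooled_effect(data, tau2_ml(data, tol = tol)$tau2)$mu else NULL
  upd <- function(t2) {
    w <- 1 / (data$v + t2)
    mu <- if (is.null(mu_fixed)) sum(w * data$y) / sum(w) else mu_fixed
    max(0, sum(w^2 * ((data$y - mu)^2 - data$v)) / sum(w^2) + 1 / sum(w))
  }
  est <- iterate_tau2(tau2_init, upd,
                      function(t2) restricted_log_likelihood(data, t2),
                      tol, max_iter, "REML")
  est
}

#' Approximate restricted maximum likelihood estimator
#'
#' Fixed point of
#' \deqn{\hat\tau^2 = \max\left(0, \frac{\sum w_i^2 [\tfrac{k}{k-1}(y_i -
#'   \hat\mu)^2 - v_i]}{\sum w_i^2}\right),}
#' a direct degrees-of-freedom adjustment to the ML update.  Identical to
#' REML when all within-study variances are equal, and very close to it
#' otherwise.
#'
#' @inheritParams tau2_ml
#' @return A `tau2_estimate` object.
#' @export
tau2_areml <- function(data, tau2_init = NULL, tol = 1e-10, max_iter = 100) {
  stopifnot(inherits(data, "meta_data"))
  if (is.null(tau2_init)) tau2_init <- tau2_dl(data)$tau2
  k <- nstudies(data)
  upd <- function(t2) {
    w <- 1 / (data$v + t2)
    mu <- sum(w * data$y) / sum(w)
    max(0, sum(w^2 * (k / (k - 1) * (data$y - mu)^2 - data$v)) / sum(w^2))
  }
  # No separate objective exists for the approximate equations; on fallback
  # use the restricted likelihood, whose maximiser AREML approximates.
  iterate_tau2(tau2_init, upd,
               function(t2) restricted_log_likelihood(data, t2),
               tol, max_iter, "AREML")
}

#' Asymptotic (Fisher-information) variance of the ML and REML estimators
#'
#' \eqn{Var(\hat\tau^2_{ML}) = 2 (\sum w_i^2)^{-1}} and
#' \eqn{Var(\hat\tau^2_{REML}) = 2 (\sum w_i^2 - 2\sum w_i^3/\sum w_i +
#' (\sum w_i^2/\sum w_i)^2)^{-1}}, with \eqn{w_i = 1/(v_i + \tau^2)}.
#'
#' @inheritParams pooled_effect
#' @param kind `"ML"` or `"REML"`.
#' @return A list with elements `kind` and `var_tau2`.
#' @export
asymptotic_variance <- function(data, tau2, kind = c("ML", "REML")) {
  stopifnot(inherits(data, "meta_data"))
  kind <- match.arg(kind)
  if (tau2 < 0) stop("`tau2` must be non-negative", call. = FALSE)
  w <- 1 / (data$v + tau2)
  info <- if (kind == "ML") sum(w^2)
          else sum(w^2) - 2 * sum(w^3) / sum(w) + (sum(w^2) / sum(w))^2
  list(kind = kind, var_tau2 = 2 / info)
}
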