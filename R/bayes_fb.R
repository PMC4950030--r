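#' Prior specification for the hierarchical Bayesian meta-analysis model
#'
#' The model is \eqn{y_i \mid \theta_i \sim N(\theta_i, v_i)},
#' \eqn{\theta_i \mid \mu, \tau \sim N(\mu, \tau^2)}, with priors
#' \eqn{\mu \sim \pi_1} and \eqn{\tau \sim \pi_2} on the between-study
#' standard deviation.  The mean prior is improper flat (the only choice
#' for which the marginalisation over \eqn{\mu} is available in closed
#' form).  The default \eqn{\pi_2} is a half-normal on \eqn{\tau \ge 0}
#' with scale 100 (variance \eqn{10^4}), an essentially flat prior on any
#' realistic effect scale; `"uniform"` gives \eqn{\tau \sim U(0, upper)}.
#'
#' @param tau_prior `"half_normal"` or `"uniform"`.
#' @param scale half-normal scale parameter (standard-deviation units).
#' @param upper upper limit of the uniform prior.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(tau_prior = c("half_normal", "uniform"),
                       scale = 100, upper = 100) {
  tau_prior <- match.arg(tau_prior)
  if (scale <= 0 || upper <= 0)
    stop("prior parameters must be positive", call. = FALSE)
  structure(list(tau_prior = tau_prior, scale = scale, upper = upper,
                 mu_prior = "flat"),
            class = "prior_spec")
}

log_prior_tau <- function(prior, tau) {
  switch(prior$tau_prior,
         half_normal = -tau^2 / (2 * prior$scale^2),
         uniform = ifelse(tau <= prior$upper, 0, -Inf))
}

#' Marginal log-posterior of the between-study standard deviation
#'
#' With the study effects and the flat mean prior integrated out
#' analytically, the unnormalised marginal log-posterior of \eqn{\tau} is
#' \deqn{\ln \pi_2(\tau) - \tfrac12 \sum \ln(v_i + \tau^2) - \tfrac12 \ln
#'   \sum w_i - \tfrac12\left[\sum w_i y_i^2 - (\sum w_i y_i)^2 / \sum
#'   w_i\right],\quad w_i = 1/(v_i + \tau^2).}
#'
#' @inheritParams pooled_effect
#' @param tau non-negative between-study standard deviation value(s).
#' @param prior a [prior_spec()] object.
#' @return Unnormalised log-density value(s).
#' @export
marginal_log_posterior <- function(data, tau, prior = prior_spec()) {
  stopifnot(inherits(data, "meta_data"), inherits(prior, "prior_spec"))
  if (!identical(prior$mu_prior, "flat"))
    stop("unsupported mean prior: only the flat prior is integrable in ",
         "closed form", call. = FALSE)
  if (any(tau < 0)) stop("`tau` must be non-negative", call. = FALSE)
  vapply(tau, function(t) {
    w <- 1 / (data$v + t^2)
    sw <- sum(w)
    log_prior_tau(prior, t) - 0.5 * sum(log(data$v + t^2)) - 0.5 * log(sw) -
      0.5 * (sum(w * data$y^2) - sum(w * data$y)^2 / sw)
  }, numeric(1))
}

# Internal: build a normalised quadrature grid over tau.  For few studies
# the marginal posterior of tau has a polynomially heavy upper tail (damped
# only by the prior), so a uniform grid in tau cannot resolve the bulk and
# the tail at once.  The nodes are instead placed uniformly in the rational
# transform s = tau/(tau + c) in [0, 1), which covers the whole half-line;
# integration is trapezoidal in s with the Jacobian dtau/ds = c/(1-s)^2 and
# log-sum-exp normalisation.  The scale c pins mid-grid near the posterior
# bulk; the mass beyond the last node is checked against a 1e-6 bound.
posterior_grid <- function(data, prior = prior_spec(), nodes = 2048) {
  f <- function(tau) marginal_log_posterior(data, tau, prior)
  c0 <- sqrt(mean(data$v) + var(data$y))
  cap <- if (prior$tau_prior == "half_normal") 3 * prior$scale else prior$upper
  cs <- min(c0, cap)
  s <- seq(0, 1 - 1 / nodes, length.out = nodes)
  tau <- cs * s / (1 - s)
  lp <- f(tau)
  jac <- cs / (1 - s)^2
  m <- max(lp)
  wts <- exp(lp - m) * jac
  wts[c(1, nodes)] <- wts[c(1, nodes)] / 2  # trapezoid ends
  h <- s[2] - s[1]
  Z <- sum(wts) * h
  if (!is.finite(Z) || Z <= 0)
    stop("posterior grid construction failed: mass does not decay",
         call. = FALSE)
  # tail bound: unnormalised mass in the last octave of the grid
  tail_mass <- sum(wts[s > 1 - 2 / nodes]) * h
  if (tail_mass > 1e-6 * Z)
    stop("posterior grid construction failed: tail mass ",
         format(tail_mass / Z), " beyond bound", call. = FALSE)
  list(tau = tau, log_post = lp, weights = wts * h / Z,
       normaliser = m + log(Z))
}

# Internal: interpolated quantile of tau from a posterior grid.
grid_quantile <- function(grid, p) {
  cdf <- cumsum(grid$weights)
  cdf <- cdf / cdf[length(cdf)]
  i <- findInterval(p, cdf) + 1L
  i <- min(max(i, 2L), length(grid$tau))
  t0 <- grid$tau[i - 1L]; t1 <- grid$tau[i]
  c0 <- cdf[i - 1L]; c1 <- cdf[i]
  if (c1 <= c0) return(t1)
  t0 + (p - c0) / (c1 - c0) * (t1 - t0)
}

#' Fully Bayesian estimate of the between-study variance
#'
#' The posterior median of \eqn{\tau^2} under the hierarchical model, with
#' the posterior computed by deterministic quadrature over the marginal
#' posterior of \eqn{\tau} (no Monte Carlo, hence exactly reproducible).
#' The median is used as the point summary because the posterior of a
#' variance is strongly right-skewed.
#'
#' @inheritParams pooled_effect
#' @param prior a [prior_spec()] object.
#' @param nodes number of quadrature nodes.
#' @return A `tau2_estimate` object (strictly positive under any
#'   continuous prior).
#' @export
tau2_fb <- function(data, prior = prior_spec(), nodes = 2048) {
  stopifnot(inherits(data, "meta_data"))
  g <- posterior_grid(data, prior, nodes)
  new_tau2_estimate("FB", grid_quantile(g, 0.5)^2, truncate = FALSE)
}

#' Bayesian credible interval for the between-study variance
#'
#' Equal-tailed posterior quantile interval for \eqn{\tau^2}, obtained by
#' squaring the \eqn{\alpha/2} and \eqn{1-\alpha/2} posterior quantiles of
#' \eqn{\tau} from the quadrature grid.
#'
#' @inheritParams tau2_fb
#' @param level credible level in (0, 1).
#' @return A `tau2_interval` object with `method = "Credible"`.
#' @export
ci_credible <- function(data, level = 0.95, prior = prior_spec(),
                        nodes = 2048) {
  stopifnot(inherits(data, "meta_data"))
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  g <- posterior_grid(data, prior, nodes)
  alpha <- 1 - level
  new_tau2_interval("Credible", level,
                    grid_quantile(g, alpha / 2)^2,
                    grid_quantile(g, 1 - alpha / 2)^2,
                    point_method = "FB")
}
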