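#' Inverse-variance pooled effect
#'
#' Pools the study effects with weights \eqn{w_i = 1/(v_i + \tau^2)}.  With
#' `tau2 = 0` this is the fixed-effect estimate \eqn{\hat\mu_{FE}}; with
#' `tau2 > 0` it is the random-effects estimate \eqn{\hat\mu_{RE}(\tau^2)}.
#'
#' @param data a [meta_data] object.
#' @param tau2 non-negative between-study variance used in the weights.
#' @return A list of class `pooled_effect` with elements `model` (`"FE"` or
#'   `"RE"`), `tau2_used`, `mu`, `var_mu` and the per-study `weights`.
#' @examples
#' pooled_effect(meta_fixture("F2"), tau2 = 0)
#' @export
pooled_effect <- function(data, tau2 = 0) {
  stopifnot(inherits(data, "meta_data"))
  if (!is.numeric(tau2) || length(tau2) != 1 || !is.finite(tau2) || tau2 < 0)
    stop("`tau2` must be a single non-negative number", call. = FALSE)
  w <- 1 / (data$v + tau2)
  sw <- sum(w)
  structure(list(model = if (tau2 == 0) "FE" else "RE",
                 tau2_used = tau2,
                 mu = sum(w * data$y) / sw,
                 var_mu = 1 / sw,
                 weights = w),
            class = "pooled_effect")
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf("%s pooled effect (tau2 = %g): mu = %.6g (SE %.6g)\n",
              x$model, x$tau2_used, x$mu, sqrt(x$var_mu)))
  invisible(x)
}

#' Cochran's Q statistic
#'
#' \eqn{Q = \sum w_{i,FE} (y_i - \hat\mu_{FE})^2} with fixed-effect weights
#' \eqn{w_{i,FE} = 1/v_i}.
#'
#' @inheritParams pooled_effect
#' @return The Q statistic (non-negative scalar).
#' @examples
#' cochran_q(meta_fixture("F1"))  # 5
#' @export
cochran_q <- function(data) {
  stopifnot(inherits(data, "meta_data"))
  w <- 1 / data$v
  mu <- sum(w * data$y) / sum(w)
  sum(w * (data$y - mu)^2)
}

# Internal: resolve a weighting scheme to a positive per-study weight vector.
# A scheme is either a numeric vector a_i, the string "fe" (a_i = 1/v_i), or
# a list(x = variance offset >= 0, p = exponent > 0) giving
# a_i = 1/(v_i + x)^p.
resolve_weights <- function(data, scheme) {
  a <- if (is.character(scheme) && length(scheme) == 1) {
    switch(scheme,
           fe = 1 / data$v,
           stop("unknown weighting scheme: ", scheme, call. = FALSE))
  } else if (is.list(scheme)) {
    x <- scheme$x
    p <- scheme$p
    if (is.null(x) || is.null(p) || x < 0 || p <= 0)
      stop("parametric scheme needs offset `x` >= 0 and exponent `p` > 0",
           call. = FALSE)
    1 / (data$v + x)^p
  } else {
    as.numeric(scheme)
  }
  if (length(a) != nstudies(data))
    stop("weighting scheme must yield one weight per study", call. = FALSE)
  if (any(!is.finite(a) | a <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  a
}

#' Generalised Cochran Q statistic
#'
#' \eqn{Q_a = \sum a_i (y_i - \hat\mu_a)^2} with
#' \eqn{\hat\mu_a = \sum a_i y_i / \sum a_i} for an arbitrary positive
#' weighting scheme.  With `scheme = "fe"` this reduces to [cochran_q()].
#'
#' @inheritParams pooled_effect
#' @param scheme a positive numeric weight vector, the string `"fe"`, or a
#'   list `list(x =, p =)` giving the parametric family
#'   \eqn{a_i = 1/(v_i + x)^p}.
#' @return The generalised Q statistic.
#' @export
generalized_q <- function(data, scheme = "fe") {
  stopifnot(inherits(data, "meta_data"))
  a <- resolve_weights(data, scheme)
  mu <- sum(a * data$y) / sum(a)
  sum(a * (data$y - mu)^2)
}

#' Profiled generalised Q statistic
#'
#' \eqn{Q_{gen}(\tau^2) = \sum (y_i - \hat\mu_{RE}(\tau^2))^2 / (v_i +
#' \tau^2)}, with the random-effects pooled mean recomputed at each candidate
#' \eqn{\tau^2} (simultaneous profiling).  Under the random-effects model
#' with known within-study variances this pivot follows a chi-squared
#' distribution on \eqn{k - 1} degrees of freedom, and it is strictly
#' decreasing in \eqn{\tau^2} whenever positive.
#'
#' @inheritParams pooled_effect
#' @return The profiled Q statistic.
#' @export
q_gen <- function(data, tau2) {
  stopifnot(inherits(data, "meta_data"))
  if (tau2 < 0) stop("`tau2` must be non-negative", call. = FALSE)
  w <- 1 / (data$v + tau2)
  mu <- sum(w * data$y) / sum(w)
  sum(w * (data$y - mu)^2)
}

#' Sums of powers of the fixed-effect weights
#'
#' \eqn{S_r = \sum (1/v_i)^r} for \eqn{r = 1, 2, 3}; the building blocks of
#' the moment estimators and the gamma approximation to the distribution
#' of Q.
#'
#' @inheritParams pooled_effect
#' @return A list with elements `S1`, `S2`, `S3`.
#' @export
weight_sums <- function(data) {
  stopifnot(inherits(data, "meta_data"))
  w <- 1 / data$v
  list(S1 = sum(w), S2 = sum(w^2), S3 = sum(w^3))
}

#' Higgins--Thompson I-squared index
#'
#' The percentage of total variation in study estimates attributable to
#' between-study heterogeneity rather than chance:
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q) \times 100}.  When \eqn{Q = 0} the
#' index is defined as 0 (package convention for perfectly homogeneous
#' data).
#'
#' @inheritParams pooled_effect
#' @return I-squared, in percent, in `[0, 100)`.
#' @export
i_squared <- function(data) {
  q <- cochran_q(data)
  if (q <= 0) return(0)
  max(0, (q - (nstudies(data) - 1)) / q) * 100
}
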