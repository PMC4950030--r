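# Internal constructor for estimator results.  `truncated` methods report
# both the signed pre-truncation value and max(0, value); positive-by-
# construction methods carry their value through unchanged.
new_tau2_estimate <- function(method, untruncated, truncate = TRUE,
                              iterations = 0L, converged = TRUE) {
  tau2 <- if (truncate) max(0, untruncated) else untruncated
  structure(list(method = method,
                 tau2 = tau2,
                 tau2_untruncated = untruncated,
                 truncated = truncate && untruncated < 0,
                 iterations = as.integer(iterations),
                 converged = converged),
            class = "tau2_estimate")
}

#' @export
print.tau2_estimate <- function(x, ...) {
  cat(sprintf("tau2 estimate [%s]: %.6g", x$method, x$tau2))
  if (x$truncated) cat(sprintf(" (untruncated %.6g)", x$tau2_untruncated))
  if (x$iterations > 0)
    cat(sprintf("  [%d iterations%s]", x$iterations,
                if (x$converged) "" else ", NOT converged"))
  cat("\n")
  invisible(x)
}

#' Generalised method-of-moments estimator of the between-study variance
#'
#' Equates the generalised Cochran statistic \eqn{Q_a} to its expectation
#' under the random-effects model and solves for \eqn{\tau^2}:
#' \deqn{\hat\tau^2 = \max\left(0, \frac{Q_a - (\sum a_i v_i - \sum a_i^2
#'   v_i / \sum a_i)}{\sum a_i - \sum a_i^2 / \sum a_i}\right).}
#' With `scheme = "fe"` this is the DerSimonian-Laird estimator; with
#' constant weights it is the Hedges-Olkin estimator.  Before truncation at
#' zero the estimator is unbiased when the within-study variances are known.
#'
#' @inheritParams generalized_q
#' @return A `tau2_estimate` object.
#' @export
tau2_gmm <- function(data, scheme = "fe") {
  stopifnot(inherits(data, "meta_data"))
  a <- resolve_weights(data, scheme)
  sa <- sum(a)
  denom <- sa - sum(a^2) / sa
  if (denom <= .Machine$double.eps * sa)
    stop("degenerate scheme: weights concentrate on a single study",
         call. = FALSE)
  qa <- generalized_q(data, a)
  num <- qa - (sum(a * data$v) - sum(a^2 * data$v) / sa)
  new_tau2_estimate("GMM", num / denom)
}

#' DerSimonian-Laird estimator
#'
#' \eqn{\hat\tau^2_{DL} = \max(0, (Q - (k-1)) / (S_1 - S_2/S_1))}, the
#' method-of-moments estimator based on Cochran's Q with fixed-effect
#' weights.
#'
#' @inheritParams pooled_effect
#' @return A `tau2_estimate` object.
#' @examples
#' tau2_dl(meta_fixture("F1"))  # 0.15
#' @export
tau2_dl <- function(data) {
  stopifnot(inherits(data, "meta_data"))
  s <- weight_sums(data)
  q <- cochran_q(data)
  est <- new_tau2_estimate("DL", (q - (nstudies(data) - 1)) /
                                   (s$S1 - s$S2 / s$S1))
  est
}

#' Positive DerSimonian-Laird estimator
#'
#' Returns the DL estimate when it is positive and an arbitrary positive
#' constant `c` otherwise, guaranteeing a strictly positive result.  The
#' conventional default is `c = 0.01` (on the squared effect scale).
#'
#' @inheritParams pooled_effect
#' @param c positive constant substituted when the DL estimate truncates to
#'   zero.
#' @return A `tau2_estimate` object with strictly positive `tau2`.
#' @export
tau2_dlp <- function(data, c = 0.01) {
  if (!is.numeric(c) || length(c) != 1 || c <= 0)
    stop("`c` must be a single positive number", call. = FALSE)
  dl <- tau2_dl(data)
  out <- if (dl$tau2 > 0) dl$tau2 else c
  est <- new_tau2_estimate("DLp", out, truncate = FALSE)
  est$tau2_untruncated <- dl$tau2_untruncated
  est
}

# Internal: the two-step estimators plug step-one random-effects weights
# a_i = 1/(v_i + tau2_step1) into the generalised method of moments.
two_step <- function(data, tau2_init, method) {
  a <- 1 / (data$v + tau2_init)
  est <- tau2_gmm(data, a)
  est$method <- method
  est
}

#' Two-step DerSimonian-Laird estimator
#'
#' Generalised method of moments with weights
#' \eqn{a_i = 1/(v_i + \hat\tau^2_{DL})}, i.e. random-effects weights formed
#' from a first-pass DL estimate.  Reduces to the Hedges-Olkin estimator
#' when all within-study variances are equal, and approximates the
#' Paule-Mandel estimator without iteration.
#'
#' @inheritParams pooled_effect
#' @return A `tau2_estimate` object.
#' @export
tau2_dl2 <- function(data) {
  two_step(data, tau2_dl(data)$tau2, "DL2")
}

#' Hedges-Olkin (variance-component) estimator
#'
#' Based on the unweighted sample variance of the study effects:
#' \eqn{\hat\tau^2_{HO} = \max(0, \sum(y_i - \bar y)^2/(k-1) - \sum v_i/k)}.
#' A special case of the generalised method of moments with constant
#' weights \eqn{a_i = 1/k}.
#'
#' @inheritParams pooled_effect
#' @return A `tau2_estimate` object.
#' @export
tau2_ho <- function(data) {
  stopifnot(inherits(data, "meta_data"))
  k <- nstudies(data)
  ybar <- mean(data$y)
  new_tau2_estimate("HO", sum((data$y - ybar)^2) / (k - 1) - mean(data$v))
}

#' Two-step Hedges-Olkin estimator
#'
#' Generalised method of moments with weights
#' \eqn{a_i = 1/(v_i + \hat\tau^2_{HO})}; the Hedges-Olkin analogue of
#' [tau2_dl2()].  Equals HO when all within-study variances are equal.
#'
#' @inheritParams pooled_effect
#' @return A `tau2_estimate` object.
#' @export
tau2_ho2 <- function(data) {
  two_step(data, tau2_ho(data)$tau2, "HO2")
}

#' Paule-Mandel (empirical Bayes) estimator
#'
#' Solves \eqn{Q_{gen}(\tau^2) = k - 1}, equating the profiled generalised Q
#' statistic to its expectation.  Because \eqn{Q_{gen}} is strictly
#' decreasing in \eqn{\tau^2}, the root is unique; when
#' \eqn{Q_{gen}(0) < k - 1} the estimate is set to zero.  The root is
#' located by bracket expansion (doubling from `max(v)`) followed by Brent's
#' method, which is derivative-free and globally convergent.
#'
#' @inheritParams pooled_effect
#' @param tol convergence tolerance on the root (in `tau2` units).
#' @param max_iter cap on the number of bracket doublings.
#' @return A `tau2_estimate` object; `iterations` counts root-finder
#'   function evaluations.
#' @export
tau2_pm <- function(data, tol = 1e-10, max_iter = 100) {
  stopifnot(inherits(data, "meta_data"))
  k <- nstudies(data)
  f <- function(t2) q_gen(data, t2) - (k - 1)
  f0 <- f(0)
  if (f0 <= 0)
    return(new_tau2_estimate("PM", 0, truncate = FALSE))
  hi <- max(data$v)
  it <- 0L
  while (f(hi) > 0) {
    hi <- hi * 2
    it <- it + 1L
    if (it > max_iter)
      stop("Paule-Mandel root not bracketed after ", max_iter,
           " doublings (last bracket [0, ", hi, "])", call. = FALSE)
  }
  r <- uniroot(f, c(0, hi), tol = tol)
  new_tau2_estimate("PM", r$root, truncate = FALSE,
                    iterations = it + r$iter, converged = TRUE)
}

#' Hartung-Makambi estimator
#'
#' A modification of DL that avoids truncation by multiplying the quadratic
#' form by \eqn{Q / (2(k-1) + Q)}:
#' \deqn{\hat\tau^2_{HM} = \frac{Q^2}{(2(k-1) + Q)(S_1 - S_2/S_1)}.}
#' Strictly positive whenever \eqn{Q > 0}; exactly zero on perfectly
#' homogeneous data (where \eqn{Q = 0}), a boundary the formula itself
#' forces.
#'
#' @inheritParams pooled_effect
#' @return A `tau2_estimate` object (never truncated).
#' @export
tau2_hm <- function(data) {
  stopifnot(inherits(data, "meta_data"))
  s <- weight_sums(data)
  q <- cochran_q(data)
  k <- nstudies(data)
  new_tau2_estimate("HM", q^2 / ((2 * (k - 1) + q) * (s$S1 - s$S2 / s$S1)),
                    truncate = FALSE)
}

#' Hunter-Schmidt estimator
#'
#' \eqn{\hat\tau^2_{HS} = \max(0, (Q - k)/S_1)}; a negatively biased
#' moment estimator included for completeness.
#'
#' @inheritParams pooled_effect
#' @return A `tau2_estimate` object.
#' @export
tau2_hs <- function(data) {
  stopifnot(inherits(data, "meta_data"))
  s <- weight_sums(data)
  new_tau2_estimate("HS", (cochran_q(data) - nstudies(data)) / s$S1)
}
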