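#' Chi-squared mixture coefficients of a generalised Q statistic
#'
#' Under the random-effects model the generalised Cochran statistic
#' \eqn{Q_a = y' A y} with \eqn{A = diag(a) - a a'/\sum a_i} is distributed
#' as \eqn{\sum_j \lambda_j \chi^2_1}, where the \eqn{\lambda_j} are the
#' non-zero eigenvalues of \eqn{\Sigma^{1/2} A \Sigma^{1/2}} and
#' \eqn{\Sigma = diag(v_i + \tau^2)}.  Exactly \eqn{k - 1} coefficients are
#' positive (the centering matrix annihilates the constant vector);
#' eigenvalues below \eqn{10^{-12}} of the largest are treated as that
#' structural zero and dropped.
#'
#' @inheritParams generalized_q
#' @param tau2 non-negative between-study variance of the generative model.
#' @return Numeric vector of positive coefficients, decreasing.
#' @export
mixture_coefficients <- function(data, tau2, scheme = "fe") {
  stopifnot(inherits(data, "meta_data"))
  if (tau2 < 0) stop("`tau2` must be non-negative", call. = FALSE)
  a <- resolve_weights(data, scheme)
  A <- diag(a) - tcrossprod(a) / sum(a)
  s <- sqrt(data$v + tau2)
  M <- t(A * s) * s  # Sigma^{1/2} A Sigma^{1/2} for diagonal Sigma
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lam <- sort(lam, decreasing = TRUE)
  keep <- lam > 1e-12 * max(lam)
  lam[keep]
}

#' CDF of a positive linear combination of chi-squared(1) variables
#'
#' Computes \eqn{P(\sum_j \lambda_j Z_j^2 \le x)} for independent standard
#' normal \eqn{Z_j} by numerical inversion of the characteristic function
#' (Imhof's integral), using adaptive quadrature:
#' \deqn{P(Q > x) = \tfrac12 + \frac{1}{\pi}\int_0^\infty
#'   \frac{\sin\theta(u)}{u\,\rho(u)}\,du,}
#' with \eqn{\theta(u) = \tfrac12\sum_j \arctan(\lambda_j u) - xu/2} and
#' \eqn{\rho(u) = \prod_j (1 + \lambda_j^2 u^2)^{1/4}}.
#'
#' @param lambdas positive mixture coefficients.
#' @param x non-negative evaluation point(s).
#' @param abs_tol absolute accuracy demanded of the quadrature; if the
#'   achieved error bound exceeds `100 * abs_tol` an error is raised.
#' @return Probabilities in `[0, 1]`, one per element of `x`.
#' @examples
#' mixture_cdf(c(1, 1, 1), 2.5)  # equals pchisq(2.5, df = 3)
#' @export
mixture_cdf <- function(lambdas, x, abs_tol = 1e-10) {
  if (any(lambdas <= 0)) stop("all coefficients must be positive",
                              call. = FALSE)
  if (any(x < 0)) stop("`x` must be non-negative", call. = FALSE)
  vapply(x, function(xx) imhof_cdf(lambdas, xx, abs_tol), numeric(1))
}

# 16-point Gauss-Legendre nodes/weights on [0, 1], fixed once.
.gl16 <- local({
  # Golub-Welsch from the Jacobi matrix of the Legendre recurrence
  n <- 16
  j <- seq_len(n - 1)
  b <- j / sqrt(4 * j^2 - 1)
  E <- eigen(diag(0, n) + rbind(cbind(0, diag(b)), 0)[1:n, 1:n] +
               cbind(rbind(0, diag(b)), 0)[1:n, 1:n], symmetric = TRUE)
  nodes <- (rev(E$values) + 1) / 2
  wts <- rev(2 * E$vectors[1, ]^2) / 2
  list(x = nodes, w = wts)
})

imhof_cdf <- function(lambdas, x, abs_tol) {
  if (x == 0) return(0)
  if (length(lambdas) == 1)  # a single term is exactly a scaled chi-square
    return(pchisq(x / lambdas, df = 1))
  # Chernoff bounds settle points far out in either tail directly
  tt <- 0.25 / max(lambdas)
  if (x > sum(lambdas) &&
      exp(-tt * x - 0.5 * sum(log1p(-2 * tt * lambdas))) < 1e-13)
    return(1)
  ts <- 2 / x
  if (x < sum(lambdas) &&
      exp(ts * x - 0.5 * sum(log1p(2 * ts * lambdas))) < 1e-13)
    return(0)
  theta <- function(u) 0.5 * colSums(atan(outer(lambdas, u))) - 0.5 * x * u
  integrand <- function(u) {
    rho <- exp(0.25 * colSums(log1p(outer(lambdas^2, u^2))))
    val <- sin(theta(u)) / (u * rho)
    val[u == 0] <- 0.5 * (sum(lambdas) - x)  # limit as u -> 0
    val
  }
  # The sine's phase is unimodal in u (rises, then falls linearly at rate
  # x/2), so beyond the first crossing of -pi the integrand is a strictly
  # alternating sequence of lobes delimited by theta = -n*pi.  The lobe
  # boundaries solve u = (sum(atan(lambda*u)) + 2*n*pi)/x, a contraction on
  # the falling branch.
  # enough lobes to reach the envelope's decay zone u ~ 4/min(lambda)
  n_lobes <- min(600L, max(28L, ceiling(x * 4 / min(lambdas) / (4 * pi))))
  nn <- seq_len(n_lobes)
  u_n <- (length(lambdas) * pi / 2 + 2 * nn * pi) / x
  for (it in 1:20)
    u_n <- (colSums(atan(outer(lambdas, u_n))) + 2 * nn * pi) / x
  # head: [0, u_1].  When x is small the first sine zero sits far beyond
  # the envelope's decay, so the far part is integrated in log(u), where
  # the phase is still bounded (it reaches only -pi by construction) and
  # the envelope decays exponentially.
  h1 <- min(u_n[1], 10 / min(lambdas))
  head <- integrate(integrand, 0, h1, rel.tol = 1e-12,
                    abs.tol = abs_tol, subdivisions = 5000L,
                    stop.on.error = FALSE)
  if (!is.finite(head$value))
    stop("characteristic-function inversion failed", call. = FALSE)
  head_value <- head$value
  head_error <- head$abs.error
  if (h1 < u_n[1]) {
    far <- integrate(function(w) integrand(exp(w)) * exp(w),
                     log(h1), log(u_n[1]), rel.tol = 1e-12,
                     abs.tol = abs_tol, subdivisions = 5000L,
                     stop.on.error = FALSE)
    if (!is.finite(far$value))
      stop("characteristic-function inversion failed", call. = FALSE)
    head_value <- head_value + far$value
    head_error <- head_error + far$abs.error
  }
  # lobes: fixed Gauss-Legendre per lobe, evaluated in one vectorised pass
  lo <- u_n[-n_lobes]
  widths <- diff(u_n)
  uu <- rep(lo, each = 16L) + as.vector(outer(.gl16$x, widths))
  vals <- integrand(uu)
  terms <- colSums(matrix(vals * .gl16$w, nrow = 16L)) * widths
  # alternating-series acceleration by repeated averaging of partial sums
  S <- cumsum(terms)
  for (it in 1:12) S <- (S[-1] + S[-length(S)]) / 2
  tail_sum <- S[length(S)]
  err <- head_error + abs(diff(S[length(S) - 1:0])) +
    .Machine$double.eps * 10
  if (err > max(100 * abs_tol, 1e-6))
    stop("quadrature accuracy ", format(err),
         " below requested tolerance", call. = FALSE)
  upper_tail <- 0.5 + (head_value + tail_sum) / pi
  min(1, max(0, 1 - upper_tail))
}

#' Gamma moment-matching for the distribution of Cochran's Q
#'
#' Under the random-effects model with known within-study variances,
#' \deqn{E(Q) = (S_1 - S_2/S_1)\tau^2 + k - 1,}
#' \deqn{Var(Q) = 4(S_1 - S_2/S_1)\tau^2 + 2(S_2 - 2S_3/S_1 +
#'   S_2^2/S_1^2)\tau^4 + 2(k-1),}
#' where \eqn{S_r = \sum (1/v_i)^r}.  Matching a gamma distribution gives
#' shape \eqn{r = E(Q)^2/Var(Q)} and scale \eqn{\lambda = Var(Q)/E(Q)}.
#'
#' @inheritParams pooled_effect
#' @return A list with elements `r` (shape), `lam` (scale), `mean`, `var`.
#' @export
gamma_moments <- function(data, tau2) {
  stopifnot(inherits(data, "meta_data"))
  if (tau2 < 0) stop("`tau2` must be non-negative", call. = FALSE)
  s <- weight_sums(data)
  k <- nstudies(data)
  c1 <- s$S1 - s$S2 / s$S1
  EQ <- c1 * tau2 + (k - 1)
  VQ <- 4 * c1 * tau2 +
    2 * (s$S2 - 2 * s$S3 / s$S1 + s$S2^2 / s$S1^2) * tau2^2 +
    2 * (k - 1)
  list(r = EQ^2 / VQ, lam = VQ / EQ, mean = EQ, var = VQ)
}
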