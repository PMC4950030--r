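#' Define a simulation scenario under the random-effects model
#'
#' Configures the generative model \eqn{\theta_i \sim N(\mu, \tau^2)},
#' \eqn{y_i \sim N(\theta_i, v_i)}.  Within-study variances are either
#' supplied (`v`) or drawn once, uniformly on `v_range`, and then held
#' fixed across replicates (`fixed_v = TRUE`, mimicking the known-variance
#' assumption); `fixed_v = FALSE` redraws them each replicate.  The
#' `binomial_logOR` outcome model instead simulates two binomial arms per
#' study and computes the empirical log odds ratio with Woolf variance,
#' adding a 0.5 continuity correction to all cells of a study when any cell
#' is zero, so within-study variances are estimated rather than known.
#'
#' @param k studies per replicate.
#' @param mu true mean effect.
#' @param tau2 true between-study variance (>= 0).
#' @param n_reps number of replicates.
#' @param seed integer master seed.
#' @param v optional fixed vector of within-study variances (length `k`).
#' @param v_range range for the uniform draw of within-study variances.
#' @param fixed_v draw `v` once (TRUE) or per replicate (FALSE).
#' @param outcome `"normal"` or `"binomial_logOR"`.
#' @param n_arm per-arm sample size (binomial model).
#' @param control_risk control-arm event probability (binomial model).
#' @param n_subjects optional per-study total sample sizes to attach
#'   (enables the Rukhin Bayes estimators on simulated data).
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(k = 10, mu = 0, tau2 = 0.1, n_reps = 1000,
                         seed = 1, v = NULL, v_range = c(0.05, 0.3),
                         fixed_v = TRUE,
                         outcome = c("normal", "binomial_logOR"),
                         n_arm = 50, control_risk = 0.2,
                         n_subjects = NULL) {
  outcome <- match.arg(outcome)
  if (tau2 < 0) stop("`tau2` must be non-negative", call. = FALSE)
  if (n_reps < 1) stop("`n_reps` must be at least 1", call. = FALSE)
  if (is.null(v) && fixed_v && outcome == "normal") {
    v <- with_local_seed(seed, runif(k, v_range[1], v_range[2]))
  }
  if (!is.null(v) && (length(v) != k || any(v <= 0)))
    stop("`v` must give a positive variance for each of the k studies",
         call. = FALSE)
  structure(list(k = k, mu = mu, tau2 = tau2, n_reps = n_reps, seed = seed,
                 v = v, v_range = v_range, fixed_v = fixed_v,
                 outcome = outcome, n_arm = n_arm,
                 control_risk = control_risk, n_subjects = n_subjects),
            class = "sim_scenario")
}

# Internal: derive a per-replicate substream seed from (seed, rep_index);
# a fixed-odd-multiplier hash keeps streams distinct and below 2^31.
rep_seed <- function(seed, rep_index) {
  (as.double(seed) * 48271 + as.double(rep_index) * 16807) %% 2147483647
}

#' Simulate one meta-analysis replicate
#'
#' Draws one dataset from the scenario's generative model.  Replicates are
#' indexed: the same `(seed, rep_index)` pair always reproduces the same
#' dataset, independently of evaluation order.
#'
#' @param scn a [sim_scenario()] object.
#' @param rep_index replicate number (1-based).
#' @return A [meta_data] object.
#' @export
simulate_meta <- function(scn, rep_index = 1) {
  stopifnot(inherits(scn, "sim_scenario"))
  with_local_seed(rep_seed(scn$seed, rep_index), {
    if (scn$outcome == "normal") {
      v <- if (is.null(scn$v)) runif(scn$k, scn$v_range[1], scn$v_range[2])
           else scn$v
      theta <- rnorm(scn$k, scn$mu, sqrt(scn$tau2))
      y <- rnorm(scn$k, theta, sqrt(v))
      meta_data(y = y, v = v, n = scn$n_subjects)
    } else {
      simulate_binary(scn)
    }
  })
}

# Internal: binomial two-arm generator; assumes an RNG state is in place.
simulate_binary <- function(scn) {
  k <- scn$k
  y <- v <- numeric(k)
  n_tot <- integer(k)
  for (i in seq_len(k)) {
    repeat {
      theta <- rnorm(1, scn$mu, sqrt(scn$tau2))
      pc <- scn$control_risk
      pt <- plogis(qlogis(pc) + theta)
      et <- rbinom(1, scn$n_arm, pt)
      ec <- rbinom(1, scn$n_arm, pc)
      if ((et + ec) == 0 || (et + ec) == 2 * scn$n_arm) next  # double zero
      cc <- if (et == 0 || ec == 0 || et == scn$n_arm || ec == scn$n_arm)
        0.5 else 0
      a <- et + cc; b <- scn$n_arm - et + cc
      c_ <- ec + cc; d <- scn$n_arm - ec + cc
      y[i] <- log(a * d / (b * c_))
      v[i] <- 1 / a + 1 / b + 1 / c_ + 1 / d
      n_tot[i] <- 2L * scn$n_arm
      break
    }
  }
  meta_data(y = y, v = v, n = n_tot)
}

#' Monte-Carlo study of point-estimator performance
#'
#' Runs the scenario's replicates, applies each requested estimator, and
#' summarises bias (of the truncated and untruncated values), mean squared
#' error, the proportion of zero estimates and the mean estimate, with
#' Monte-Carlo standard errors.  Replicates on which an estimator errors
#' are excluded and counted.
#'
#' @param scn a [sim_scenario()] object.
#' @param methods character vector of estimator tags (see
#'   [tau2_estimate()]).
#' @return A data frame of class `sim_summary`, one row per method.
#' @export
run_estimator_study <- function(scn, methods = c("DL", "PM", "REML")) {
  stopifnot(inherits(scn, "sim_scenario"))
  est <- array(NA_real_, c(scn$n_reps, length(methods), 2),
               dimnames = list(NULL, methods, c("tau2", "untruncated")))
  for (r in seq_len(scn$n_reps)) {
    d <- simulate_meta(scn, r)
    for (m in seq_along(methods)) {
      e <- try(tau2_estimate(d, methods[m]), silent = TRUE)
      if (!inherits(e, "try-error"))
        est[r, m, ] <- c(e$tau2, e$tau2_untruncated)
    }
  }
  out <- lapply(seq_along(methods), function(m) {
    t2 <- est[, m, 1]
    ut <- est[, m, 2]
    ok <- !is.na(t2)
    n <- sum(ok)
    data.frame(
      method = methods[m], n_ok = n, n_failed = scn$n_reps - n,
      mean_est = mean(t2[ok]),
      bias = mean(t2[ok]) - scn$tau2,
      bias_untruncated = mean(ut[ok]) - scn$tau2,
      mse = mean((t2[ok] - scn$tau2)^2),
      prop_zero = mean(t2[ok] == 0),
      mc_se_bias = sd(t2[ok]) / sqrt(n),
      mc_se_bias_untruncated = sd(ut[ok]) / sqrt(n),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("sim_summary", "data.frame")
  attr(out, "scenario") <- scn
  out
}

#' Monte-Carlo study of interval coverage
#'
#' Applies each requested (interval, estimator) pairing to the scenario's
#' replicates and reports empirical coverage of the true `tau2`, mean
#' width, and the proportion of degenerate (null-set) intervals, with
#' binomial standard errors.  Pairings flagged incompatible by
#' [compatibility()] are rejected unless `force = TRUE`.
#'
#' @inheritParams run_estimator_study
#' @param intervals character vector of interval tags, or a list of
#'   `c(interval_tag, estimator_tag)` pairs.
#' @param level nominal confidence level.
#' @param force allow incompatible pairings (with a warning).
#' @return A data frame of class `sim_summary`, one row per pairing, with
#'   columns including `coverage`, `miss_low` and `miss_high` (the two
#'   one-sided non-coverage rates), `mean_width` and `prop_degenerate`.
#' @export
run_interval_study <- function(scn, intervals = "QP", level = 0.95,
                               force = FALSE) {
  stopifnot(inherits(scn, "sim_scenario"))
  if (!is.list(intervals))
    intervals <- lapply(intervals, function(i)
      c(i, default_point_method(i)))
  for (p in intervals) {
    comp <- compatibility(p[2], p[1])
    if (comp == "incompatible") {
      if (!force) stop("incompatible pairing: ", p[2], " with ", p[1],
                       " (use force = TRUE to override)", call. = FALSE)
      warning("pairing ", p[2], " with ", p[1], " is not considered ",
              "compatible", call. = FALSE)
    }
  }
  tags <- vapply(intervals, function(p) paste(p[1], p[2], sep = "+"),
                 character(1))
  res <- array(NA_real_, c(scn$n_reps, length(intervals), 4),
               dimnames = list(NULL, tags,
                               c("lower", "upper", "degenerate", "ok")))
  for (r in seq_len(scn$n_reps)) {
    d <- simulate_meta(scn, r)
    for (m in seq_along(intervals)) {
      ci <- try(suppressMessages(
        tau2_interval(d, intervals[[m]][1], level)), silent = TRUE)
      if (!inherits(ci, "try-error"))
        res[r, m, ] <- c(ci$lower, ci$upper, as.numeric(ci$degenerate), 1)
    }
  }
  out <- lapply(seq_along(intervals), function(m) {
    ok <- !is.na(res[, m, 4])
    lo <- res[ok, m, 1]; hi <- res[ok, m, 2]
    n <- sum(ok)
    cover <- mean(lo <= scn$tau2 & scn$tau2 <= hi)
    data.frame(
      interval = intervals[[m]][1], estimator = intervals[[m]][2],
      n_ok = n, n_failed = scn$n_reps - n,
      coverage = cover,
      miss_low = mean(scn$tau2 < lo),
      miss_high = mean(scn$tau2 > hi),
      mean_width = mean(hi - lo),
      prop_degenerate = mean(res[ok, m, 3]),
      binom_se = sqrt(cover * (1 - cover) / n),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("sim_summary", "data.frame")
  attr(out, "scenario") <- scn
  out
}

# Internal: the estimator conventionally reported alongside each interval.
default_point_method <- function(interval) {
  switch(interval,
         PL = "ML", Wt_ML = "ML", Wt_REML = "REML",
         BT = "DL", BJ_DL = "DL", BJ_HM = "HM", Jackson = "DL",
         QP = "PM", SJ = "SJ", BootPar = "DL", BootNonpar = "DL",
         Credible = "FB",
         stop("unknown interval tag: ", interval, call. = FALSE))
}
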