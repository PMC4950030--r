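---
title: "Estimating the between-study variance and its uncertainty"
author: "hetvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the between-study variance and its uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetvar)
```

## The model

A random-effects meta-analysis observes one effect estimate per study,
$y_i$, $i = 1, \dots, k$, with within-study sampling variance $v_i$
conventionally treated as known:

$$y_i = \theta_i + \varepsilon_i, \qquad
  \theta_i = \mu + \delta_i, \qquad
  \varepsilon_i \sim N(0, v_i), \qquad
  \delta_i \sim N(0, \tau^2).$$

The between-study variance $\tau^2$ measures how much the *true* study
effects vary around the mean effect $\mu$ beyond sampling error.  Its
estimate drives the random-effects weights $w_i = 1/(v_i + \hat\tau^2)$ and
hence the pooled estimate $\hat\mu_{RE}$ and its uncertainty, yet $\tau^2$
is hard to estimate when $k$ is small — which is the typical situation in
practice.  `hetvar` implements the full tool chest: sixteen point
estimators and seven families of confidence/credible intervals for
$\tau^2$, together with a simulation harness that measures their bias,
mean squared error and coverage under the model above.

Everything operates on the $(y_i, v_i)$ abstraction.  Computing effect
sizes from arm-level data (2×2 tables, means and SDs) is deliberately out
of scope; any effect scale whose estimates are approximately normal with
known variance works unchanged.

## Point estimators

The method-of-moments family equates a quadratic form
$Q_a = \sum a_i (y_i - \hat\mu_a)^2$ with its expectation.  The choice of
weights $a_i$ spans the family: fixed-effect weights give
DerSimonian–Laird (`tau2_dl`), constant weights give Hedges–Olkin
(`tau2_ho`), random-effects weights built from a first-pass estimate give
the two-step estimators (`tau2_dl2`, `tau2_ho2`), and solving the implicit
equation $Q_{gen}(\tau^2) = k - 1$ with simultaneously profiled weights
gives Paule–Mandel (`tau2_pm`).  `tau2_gmm` exposes the family for any
positive weight vector.  Because $Q_{gen}$ is strictly decreasing, the
Paule–Mandel root is found by bracket doubling from $\max v_i$ plus
Brent's method — derivative-free and globally convergent.

Moment estimators are unbiased *before* truncation at zero; the published
discussions of their bias are largely about what the truncation
$\hat\tau^2 = \max(0, \cdot)$ does afterwards.  Every truncating estimator
here therefore records `tau2_untruncated`, and the simulation harness
summarises bias on both scales.  Hartung–Makambi (`tau2_hm`) and
Hunter–Schmidt (`tau2_hs`) complete the closed-form set.  `tau2_hm` is
positive whenever $Q > 0$; on exactly homogeneous data ($Q = 0$) its
formula vanishes and the package returns 0 — a boundary the "always
positive" description glosses over, adopted here as a documented
convention.

The likelihood family (`tau2_ml`, `tau2_reml`, `tau2_areml`) iterates the
fixed-point equations obtained from the (restricted) normal log-likelihood,
truncating at zero in each step, starting from the DL estimate, and
stopping when $|\tau^2_{t+1} - \tau^2_t| \le tol\,(1 + \tau^2_t)$ with
$tol = 10^{-10}$ (a relative-plus-absolute rule that behaves sensibly near
zero).  If an iteration fails to settle within 100 steps the estimator
falls back to bounded scalar maximisation of the corresponding profile
objective and flags `converged = FALSE`.  One genuine ambiguity: the
published REML display embeds the *ML*-weighted pooled mean inside the
update, while the self-consistent iteration recomputes the mean with
current REML weights.  Both are available (`mu_weights = "self"`/`"ml"`);
the default is self-consistent because it is the variant that agrees with
direct maximisation of the restricted log-likelihood, which the test suite
verifies against an independent dense-grid maximiser.

The auxiliary estimators are Sidik–Jonkman (`tau2_sj`; the `original`
variant seeds the weighted least-squares step with
$\tau_0^2 = \sum (y_i - \bar y)^2 / k$, the `improved` variant with the
Hedges–Olkin estimate, substituting $0.01$ when that is zero), the Rukhin
Bayes family (`tau2_rb`, `tau2_rbp`; closed-form shrinkage estimators that
need per-study sample sizes $n_i$), the Bayes modal estimator (`tau2_bm`),
and the bootstrap-aggregated `tau2_dlb` (the mean of DL over study-level
resamples; any base estimator can be plugged in).  Iterating the SJ update
to convergence reproduces the Paule–Mandel root exactly — the update can
be rewritten as $\tau^2 \mapsto \tau^2 Q_{gen}(\tau^2)/(k-1)$ — and
`tau2_sj_iterated` exists precisely to make that identity testable.

Two typesetting ambiguities in the sources for the Rukhin family had to be
resolved.  The grouping adopted for the general Bayes estimator is

$$\hat\tau^2_{RB} = \max\!\left(0,\;
  \frac{\sum (y_i - \bar y)^2}{k + 1} +
  \frac{2k (N - k)\,\tau^2_{prior} - (k - 1) \sum v_i}{(N + k)(k + 1)}
  \right), \qquad N = \sum n_i,$$

chosen because it is the parse that satisfies every structural property
claimed of the family: the prior term vanishes at $\tau^2_{prior} = 0$;
RB0 truncates to zero on homogeneous data; and the RBp prior mean
$(k-1)\sum v_i/(2k)$ makes the estimator strictly positive whenever
$N > k + 1$ (guaranteed by $n_i \ge 2$).  Tests pin the structural
properties and an independent re-evaluation of the same algebra rather
than pretending an external numeric reference exists.

`tau2_bm` maximises the profile log-likelihood of $\tau$ penalised by a
$G(2, 10^{-4})$ prior, whose $\log \tau$ term forces a strictly positive
mode that always exceeds the ML estimate.  The quadratic-expansion closed
form $\hat\tau_{BM} = [\hat\tau_{ML} + (\hat\tau_{ML}^2 +
4\,Var(\hat\tau_{ML}))^{1/2}]/2$ is provided as `tau2_bm_approx` for
cross-checking only: it needs the asymptotic variance of $\hat\tau$ (the
standard-deviation scale), which the package bridges from the
Fisher-information variance of $\hat\tau^2$ by the delta method,
$Var(\hat\tau) \approx Var(\hat\tau^2)/(4\hat\tau^2)$ — singular at the
boundary, another reason the direct maximisation is primary.

The fully Bayesian estimator (`tau2_fb`) integrates the hierarchical model
analytically over the study effects and (under the flat mean prior) over
$\mu$, leaving a one-dimensional marginal posterior in $\tau$ that is
integrated by deterministic quadrature — no Monte Carlo, hence exact
reproducibility and no convergence diagnostics.  The default prior is
half-normal on $\tau$ with variance $10^4$, effectively flat on any
realistic effect scale; a uniform prior on $\tau$ is available.  For few
studies the marginal posterior of $\tau$ has a polynomially heavy upper
tail (only the prior eventually cuts it off), so the 2048 quadrature nodes
are placed uniformly in the rational transform $s = \tau/(\tau + c)$,
which covers $[0, \infty)$ while keeping roughly half the nodes in the
posterior bulk; the scale $c$ is matched to
$(\overline v + \widehat{var}(y))^{1/2}$ and capped by the prior scale.  A
uniform-in-$\tau$ grid wide enough to satisfy the $10^{-6}$ tail-mass
bound would leave essentially no resolution in the bulk.  The point
summary is the posterior *median* of $\tau^2$ (the posterior of a variance
is strongly right-skewed, and the median is invariant under the
$\tau \mapsto \tau^2$ transform); `ci_credible` returns equal-tailed
posterior quantile intervals.  The quadrature is validated in the tests
against a long-run random-walk Metropolis sampler and against direct 2-D
numerical integration.

## Interval methods

Seven families, all parameterised by `level` (default 0.95):

* **Q-profile** (`ci_qp`): inverts the exact pivot
  $Q_{gen}(\tau^2) \sim \chi^2_{k-1}$.  Exact under the model with known
  $v_i$; pairs naturally with Paule–Mandel, in which case the interval
  always contains the point estimate.
* **Generalised-Q / chi-squared-mixture intervals** (`ci_bt`, `ci_bj`,
  `ci_jackson`): a quadratic form $Q_a$ is distributed as a positive
  linear combination $\sum_j \lambda_j \chi^2_1$ with $\lambda_j$ the
  non-zero eigenvalues of $\Sigma^{1/2} A \Sigma^{1/2}$.
  Biggerstaff–Tweedie approximates Cochran's $Q$ by a moment-matched gamma
  distribution; Biggerstaff–Jackson inverts the mixture distribution
  exactly; Jackson generalises to arbitrary weights, with reciprocal
  within-study standard errors ($a_i = 1/\sqrt{v_i}$) as the recommended
  default, exact under the model.  The BJ route through the
  Hartung–Makambi transformation is algebraically identical to the DL
  route (the observed HM statistic maps back to the observed $Q$); both
  are exposed and their equality is tested rather than assumed.
* **Profile likelihood** (`ci_pl`): the $\tau^2$ whose profile
  log-likelihood stays within $\chi^2_{1,level}/2$ of the ML maximum.  The
  exact quantile is used rather than the rounded 3.84.  At $\tau^2 = 0$
  the likelihood-ratio statistic is really a mixture of $\chi^2_1$ and a
  point mass, which makes the interval conservative for small
  heterogeneity; the standard cutoff is kept deliberately.
* **Wald-type** (`ci_wald`): $\hat\tau^2 \pm z\sqrt{Var(\hat\tau^2)}$ with
  the Fisher-information variance (ML or REML flavour), lower bound
  truncated at zero.  Requires large $k$ to be trustworthy.
* **Sidik–Jonkman** (`ci_sj`): $(k-1)\hat\tau^2_{SJ}$ scaled by
  $\chi^2_{k-1}$ quantiles.  Structurally never covers $\tau^2 = 0$.
* **Bootstrap** (`ci_bootstrap`): percentile intervals, parametric
  (redraw $y_i^* \sim N(\hat\mu_{RE}, \hat\tau^2 + v_i)$) or
  non-parametric (resample $(y_i, v_i)$ pairs), seeded and reproducible.
* **Credible** (`ci_credible`): see above.

Null sets: when even $\tau^2 = 0$ is rejected from above, the QP, BT, BJ
and Jackson constructions have no solution; the package reports `[0, 0]`
with `degenerate = TRUE` and a message that the data appear highly
homogeneous.  Root searches in $\tau^2$ expand a bracket by doubling from
$\max v_i$ up to $10^4 \max v_i$; hitting the cap raises an error rather
than silently truncating.  Every interval construction is self-verifying:
the tests substitute the returned bounds back into the defining equations
and check the residuals.

The `compatibility()` matrix classifies each (estimator, interval) pairing
as `natural`, `in_principle` or `incompatible`; `meta_report()` refuses
incompatible pairings unless forced, warns on merely-in-principle ones,
and warns whenever a returned interval fails to contain its paired point
estimate (possible for QP unless Paule–Mandel is the partner).

## The chi-squared mixture engine

`mixture_cdf` computes $P(\sum_j \lambda_j \chi^2_{1,j} \le x)$ by
numerical inversion of the characteristic function (an Imhof-type
integral).  The integrand's sine phase is unimodal, so beyond its first
$-\pi$ crossing the integral is an alternating series of lobes delimited
by consecutive phase zeros; the implementation integrates the head
adaptively (switching to log-$u$ for the far part when the evaluation
point is deep in the left tail), evaluates the lobes with fixed
Gauss–Legendre rules in one vectorised pass, and sums them with
repeated-averaging series acceleration.  Chernoff bounds short-circuit
points far out in either tail, and a single coefficient is returned as the
exact scaled chi-square.  Agreement with `pchisq` in the equal-coefficient
case is at the $10^{-14}$ level, and a $10^7$-draw Monte-Carlo oracle
bounds the error on random coefficient sets; the achieved quadrature error
is monitored and an error is raised if it exceeds the requested tolerance.
Mixture densities are not provided — the interval constructions only ever
need the cdf.

## The simulation harness

`sim_scenario` fixes the generative conditions: $k$ studies,
$\theta_i \sim N(\mu, \tau^2)$, $y_i \sim N(\theta_i, v_i)$, with the
$v_i$ either supplied, or drawn once from $U[0.05, 0.3]$ and held fixed
across replicates to mirror the known-variance assumption (per-replicate
redraws are available).  That default range spans precise to moderately
imprecise studies on the log hazard-ratio / log odds-ratio scale typical
of clinical meta-analyses.  A binomial two-arm generator
(`outcome = "binomial_logOR"`) produces empirical log odds ratios with
Woolf variances — adding 0.5 to all cells of a study when any cell is zero
and regenerating double-zero studies — to exercise the estimated-variance
regime the normal model idealises away.  Replicates are indexed: each
dataset is a deterministic function of `(seed, rep_index)` via a derived
substream seed, so results are bit-reproducible regardless of evaluation
order.  (A counter-based generator keyed additionally by study index was
considered; base R provides none, and the per-replicate substream already
delivers the reproducibility contract the tests pin down.)

`run_estimator_study` reports mean estimate, bias (truncated and
untruncated), MSE, the proportion of zero estimates and Monte-Carlo
standard errors; `run_interval_study` reports empirical coverage, the two
one-sided miss rates, mean width and the proportion of degenerate
intervals with binomial standard errors.

What passing simulations do and do not show: the harness draws from the
same normal, known-variance model the estimators assume, so it validates
internal correctness (unbiasedness of untruncated moment estimators, QP
and Jackson exactness) — not robustness to estimated variances,
non-normal effects, correlation between $y_i$ and $v_i$, or publication
selection, none of which the generator emulates except via the binomial
option.

## Problem sizes used in the checks

The shipped validation uses 5000 replicates of $k = 10$ at $\tau^2 = 0.1$
for the coverage and tail-calibration studies (binomial standard error
$\approx 0.003$ at 95% coverage), 10,000 replicates for the
pre-truncation unbiasedness checks at $\tau^2 \in \{0, 0.1, 0.5\}$, 200
random datasets for the equal-variance identity sweep, 100 for each
fixed-point/oracle equivalence sweep, and $10^7$ Monte-Carlo draws per
coefficient set for the mixture-cdf oracle.  These sizes make the
statistical assertions decisive (3-standard-error bands) while keeping the
full suite to a few minutes on one core.

## Known limitations

* Arm-level data ingestion and effect-size computation are out of scope.
* The Wald and profile-likelihood intervals rely on asymptotics in $k$ and
  are included for completeness, not endorsement; on the basis of the
  comparative literature the Paule–Mandel estimator paired with the
  Q-profile interval is the sensible default, which is what
  `meta_report()` pairs when asked for intervals.
* The rare-event refinements (continuity-corrected Paule–Mandel variants,
  Mantel–Haenszel-type pooling) and informative empirical priors for
  $\tau^2$ are not implemented.
* Confidence intervals for the pooled mean $\mu$ are not provided; the
  package is about $\tau^2$.

## A worked example

```{r example}
d <- meta_data(y = c(0.0, 0.5, 1.0), v = c(0.05, 0.1, 0.2),
               n = c(20, 40, 60))
meta_report(d, methods = c("DL", "PM", "REML", "SJ"), interval = "QP",
            force = TRUE)
```
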