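#' Estimate the between-study variance by method tag
#'
#' A single front door dispatching on the estimator tag; see the individual
#' `tau2_*` functions for the definitions.
#'
#' @inheritParams pooled_effect
#' @param method one of `DL, DLp, DL2, HO, HO2, PM, HM, HS, ML, REML,
#'   AREML, SJ, RB0, RBp, FB, BM, DLb`.
#' @param ... passed to the method-specific function (e.g. `c` for DLp,
#'   `B`/`seed` for DLb, `variant` for SJ, `prior` for FB).
#' @return A `tau2_estimate` object.
#' @examples
#' tau2_estimate(meta_fixture("F1"), "PM")
#' @export
tau2_estimate <- function(data, method = "DL", ...) {
  fn <- switch(method,
               DL = tau2_dl, DLp = tau2_dlp, DL2 = tau2_dl2,
               HO = tau2_ho, HO2 = tau2_ho2, PM = tau2_pm,
               HM = tau2_hm, HS = tau2_hs,
               ML = tau2_ml, REML = tau2_reml, AREML = tau2_areml,
               SJ = tau2_sj, RB0 = tau2_rb, RBp = tau2_rbp,
               FB = tau2_fb, BM = tau2_bm, DLb = tau2_dlb,
               stop("unknown method tag: ", method, "; valid tags: ",
                    paste(.estimator_tags, collapse = ", "), call. = FALSE))
  est <- fn(data, ...)
  if (method %in% c("RB0", "RBp")) est$method <- method
  est
}

#' Compute a confidence interval by method tag
#'
#' Dispatcher over the interval constructors; see the individual `ci_*`
#' functions.
#'
#' @inheritParams ci_pl
#' @param method one of `PL, Wt_ML, Wt_REML, BT, BJ_DL, BJ_HM, Jackson,
#'   QP, SJ, BootPar, BootNonpar, Credible`.
#' @param ... passed to the method-specific constructor.
#' @return A `tau2_interval` object.
#' @export
tau2_interval <- function(data, method = "QP", level = 0.95, ...) {
  switch(method,
         PL = ci_pl(data, level, ...),
         Wt_ML = ci_wald(data, level, kind = "ML", ...),
         Wt_REML = ci_wald(data, level, kind = "REML", ...),
         BT = ci_bt(data, level, ...),
         BJ_DL = ci_bj(data, level, statistic = "DL", ...),
         BJ_HM = ci_bj(data, level, statistic = "HM", ...),
         Jackson = ci_jackson(data, level, ...),
         QP = ci_qp(data, level, ...),
         SJ = ci_sj(data, level, ...),
         BootPar = ci_bootstrap(data, level, mode = "parametric", ...),
         BootNonpar = ci_bootstrap(data, level, mode = "nonparametric", ...),
         Credible = ci_credible(data, level, ...),
         stop("unknown interval tag: ", method, "; valid tags: ",
              paste(.interval_tags, collapse = ", "), call. = FALSE))
}
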