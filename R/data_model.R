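#' Construct and validate a meta-analysis dataset
#'
#' A `meta_data` object holds per-study summary statistics for a
#' meta-analysis: an effect estimate `y` (on any effect scale, e.g. log
#' hazard ratio, log odds ratio, mean difference), its within-study variance
#' `v`, and optionally the study's total sample size `n` (required only by
#' the Rukhin Bayes estimators).  Within-study precision may alternatively be
#' supplied as a standard error via `se`; it is squared at ingestion and
#' never downstream, so there is a single point at which the conversion can
#' happen.
#'
#' @param y numeric vector of effect estimates, one per study.
#' @param v numeric vector of within-study variances (mutually exclusive
#'   with `se`).
#' @param se numeric vector of within-study standard errors; converted to
#'   variances as `v = se^2`.
#' @param n optional integer vector of per-study total sample sizes
#'   (each at least 2).
#' @param labels optional character vector of unique study labels; defaults
#'   to `"study_1"`, `"study_2"`, ...
#'
#' @return An object of class `meta_data`: a data frame with columns
#'   `label`, `y`, `v` and (when given) `n`, and an attribute `k`, the
#'   number of studies.
#'
#' @examples
#' d <- meta_data(y = c(0.0, 0.5, 1.0), v = c(0.05, 0.1, 0.2))
#' nstudies(d)
#' @export
meta_data <- function(y, v = NULL, se = NULL, n = NULL, labels = NULL) {
  if (!is.null(v) && !is.null(se))
    stop("supply either `v` or `se`, not both", call. = FALSE)
  if (is.null(v)) {
    if (is.null(se)) stop("one of `v` or `se` is required", call. = FALSE)
    if (!is.numeric(se)) stop("`se` must be numeric", call. = FALSE)
    v <- se^2
  }
  if (!is.numeric(y) || !is.numeric(v))
    stop("`y` and `v` must be numeric", call. = FALSE)
  if (length(y) != length(v))
    stop("`y` and `v` must have equal length", call. = FALSE)
  k <- length(y)
  if (is.null(labels)) labels <- paste0("study_", seq_len(k))
  labels <- as.character(labels)
  if (length(labels) != k)
    stop("`labels` must have one entry per study", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate study labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  if (k < 2)
    stop("insufficient studies: at least 2 are required, got ", k,
         call. = FALSE)
  bad <- !is.finite(y)
  if (any(bad))
    stop("non-finite effect estimate in study ",
         paste(labels[bad], collapse = ", "), call. = FALSE)
  bad <- !is.finite(v) | v <= 0
  if (any(bad))
    stop("non-positive variance in study ",
         paste(labels[bad], collapse = ", "), call. = FALSE)
  out <- data.frame(label = labels, y = as.numeric(y), v = as.numeric(v),
                    stringsAsFactors = FALSE)
  if (!is.null(n)) {
    if (length(n) != k)
      stop("`n` must have one entry per study", call. = FALSE)
    if (any(!is.finite(n) | n < 2 | n != round(n)))
      stop("sample sizes `n` must be integers >= 2", call. = FALSE)
    out$n <- as.integer(n)
  }
  structure(out, k = k, class = c("meta_data", "data.frame"))
}

#' Validate raw study records into a `meta_data` object
#'
#' Accepts a data frame (columns `label`/`y`/`v` or `se`, optional `n`) or a
#' list of per-study records `(label, y, v[, n])` and runs the full set of
#' validity checks.
#'
#' @param raw a data frame or a list of study records.
#' @return A validated [meta_data] object.
#' @export
validate_dataset <- function(raw) {
  if (inherits(raw, "meta_data")) {
    return(meta_data(y = raw$y, v = raw$v, n = raw$n, labels = raw$label))
  }
  if (is.data.frame(raw)) {
    v <- if ("v" %in% names(raw)) raw$v else NULL
    se <- if (is.null(v) && "se" %in% names(raw)) raw$se else NULL
    return(meta_data(y = raw$y, v = v, se = se,
                     n = if ("n" %in% names(raw)) raw$n else NULL,
                     labels = if ("label" %in% names(raw)) raw$label else NULL))
  }
  if (is.list(raw)) {
    if (length(raw) == 0) stop("empty input", call. = FALSE)
    lab <- vapply(raw, function(r) as.character(r[[1]]), character(1))
    y <- vapply(raw, function(r) as.numeric(r[[2]]), numeric(1))
    v <- vapply(raw, function(r) as.numeric(r[[3]]), numeric(1))
    n <- if (all(lengths(raw) >= 4))
      vapply(raw, function(r) as.numeric(r[[4]]), numeric(1)) else NULL
    return(meta_data(y = y, v = v, n = n, labels = lab))
  }
  stop("cannot interpret input as a meta-analysis dataset", call. = FALSE)
}

#' Number of studies in a dataset
#' @param data a [meta_data] object.
#' @return Integer study count `k`.
#' @export
nstudies <- function(data) {
  stopifnot(inherits(data, "meta_data"))
  attr(data, "k")
}

#' @export
print.meta_data <- function(x, ...) {
  cat("Meta-analysis dataset: k =", nstudies(x), "studies\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Canonical small test datasets
#'
#' Three deterministic three-study datasets used throughout the package's
#' examples and tests: `F0` is homogeneous (identical effects, equal
#' variances), `F1` is heterogeneous with equal variances, and `F2` is
#' heterogeneous with unequal variances and sample sizes attached.
#'
#' @param name one of `"F0"`, `"F1"`, `"F2"`.
#' @return A [meta_data] object.
#' @examples
#' meta_fixture("F1")
#' @export
meta_fixture <- function(name = c("F0", "F1", "F2")) {
  name <- match.arg(name)
  switch(name,
    F0 = meta_data(y = c(0.5, 0.5, 0.5), v = c(0.1, 0.1, 0.1),
                   labels = c("A", "B", "C")),
    F1 = meta_data(y = c(0.0, 0.5, 1.0), v = c(0.1, 0.1, 0.1),
                   labels = c("A", "B", "C")),
    F2 = meta_data(y = c(0.0, 0.5, 1.0), v = c(0.05, 0.1, 0.2),
                   n = c(20L, 40L, 60L), labels = c("A", "B", "C"))
  )
}

# Internal: require per-study sample sizes (Rukhin Bayes family).
require_n <- function(data) {
  if (is.null(data$n))
    stop("sample sizes required: this estimator needs per-study `n`",
         call. = FALSE)
  data$n
}

# Internal: run `expr` under a temporary RNG seed, restoring the caller's
# RNG state afterwards so estimator calls never perturb a user's stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
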