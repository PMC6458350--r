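# Two-sample comparisons used for the upper- vs lower-incisor contrast:
# mean/sd/CV summaries, pooled t, variance-ratio F, and a Fligner-Killeen
# scale test with an optional per-group mean scaling that converts it
# into a test of CV homogeneity.

#' Group summary: n, mean, sd, CV
#'
#' Sample standard deviation uses the n - 1 denominator; the coefficient
#' of variation is 100 * sd / mean (percent) and requires a nonzero mean.
#'
#' @param data A data frame.
#' @param value Column of values to summarize (tidy-eval).
#' @param by Optional grouping column (tidy-eval); omit for a single
#'   overall summary.
#' @return A tibble with one row per group and columns `n`, `mean`, `sd`,
#'   `cv`.
#' @examples
#' group_summary(table1_fixture(), pct_circle, by = is_rodent)
#' @export
group_summary <- function(data, value, by = NULL) {
  value <- rlang::enquo(value)
  by <- rlang::enquo(by)
  if (!rlang::quo_is_null(by)) data <- dplyr::group_by(data, !!by)
  out <- dplyr::summarise(
    data,
    n = dplyr::n(),
    mean = mean(!!value),
    sd = stats::sd(!!value),
    .groups = "drop"
  )
  if (any(out$n < 2)) {
    stop("group summaries need at least 2 values per group", call. = FALSE)
  }
  if (any(out$mean == 0)) {
    stop("coefficient of variation is undefined for a zero mean",
         call. = FALSE)
  }
  dplyr::mutate(out, cv = 100 * .data$sd / .data$mean)
}

#' Two-sample t-test
#'
#' Classical pooled-variance Student t by default (df = n1 + n2 - 2,
#' two-tailed), with Welch's unequal-variance form available.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (Student, default) or not (Welch).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("both samples need at least 2 values", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) != mean(y)) {
      stop("zero variance in both samples with unequal means: ",
           "t is unbounded", call. = FALSE)
    }
    return(tibble::tibble(statistic = 0, df = length(x) + length(y) - 2,
                          p_value = 1,
                          method = if (var_equal) "student" else "welch"))
  }
  fit <- stats::t.test(x, y, var.equal = var_equal)
  tibble::tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    method = if (var_equal) "student" else "welch"
  )
}

#' Variance-ratio F-test
#'
#' F is the larger sample variance over the smaller (so F >= 1), with the
#' matching degree-of-freedom pair and a two-tailed p-value. When only
#' summary statistics are available for one group (published sd without
#' raw data), pass its sd and n via `sd_y`/`n_y` with `y = NULL`; p is
#' `NA` if `n_y` is unknown.
#'
#' @param x Numeric vector (length >= 2).
#' @param y Numeric vector, or `NULL` when using `sd_y`.
#' @param sd_y,n_y Summary-statistic alternative to `y`.
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p_value`.
#' @export
variance_ratio <- function(x, y = NULL, sd_y = NULL, n_y = NULL) {
  if (length(x) < 2) stop("x needs at least 2 values", call. = FALSE)
  v1 <- stats::var(x)
  n1 <- length(x)
  if (!is.null(y)) {
    if (length(y) < 2) stop("y needs at least 2 values", call. = FALSE)
    v2 <- stats::var(y)
    n2 <- length(y)
  } else {
    if (is.null(sd_y)) stop("supply `y` or `sd_y`", call. = FALSE)
    v2 <- sd_y^2
    n2 <- if (is.null(n_y)) NA_integer_ else n_y
  }
  if (v1 == 0 || v2 == 0) stop("zero variance: F undefined", call. = FALSE)
  if (v1 >= v2) {
    f <- v1 / v2; df1 <- n1 - 1; df2 <- n2 - 1
  } else {
    f <- v2 / v1; df1 <- n2 - 1; df2 <- n1 - 1
  }
  p <- if (is.na(df1) || is.na(df2)) NA_real_ else {
    min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  tibble::tibble(statistic = f, df1 = df1, df2 = df2, p_value = p)
}

#' Fligner-Killeen test of scale homogeneity
#'
#' Median-centred normal-scores rank test of equal scale across k groups.
#' For each observation the absolute deviation from its group median is
#' ranked over the pooled sample (midranks for ties) and mapped to a
#' normal score a_i = qnorm(1/2 + r_i / (2(N + 1))); the statistic is
#' sum over groups of n_j (Abar_j - abar)^2 / V^2, referred to a
#' chi-squared distribution with k - 1 degrees of freedom.
#'
#' With `scaling = "cv"` every group is first divided by its own mean, so
#' that scale differences are measured relative to location and the test
#' addresses homogeneity of coefficients of variation; `"log"` takes
#' log10 first (requires positive data).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @param scaling `"none"` (plain scale test), `"cv"` or `"log"`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `scaling`.
#' @export
fligner_killeen <- function(values, groups,
                            scaling = c("none", "cv", "log")) {
  scaling <- match.arg(scaling)
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  ns <- tabulate(groups)
  if (any(ns < 2)) stop("every group needs at least 2 values", call. = FALSE)
  values <- switch(scaling,
    none = values,
    cv = {
      mu <- tapply(values, groups, mean)
      if (any(mu == 0)) stop("zero group mean: CV scaling undefined",
                             call. = FALSE)
      values / mu[groups]
    },
    log = {
      if (any(values <= 0)) stop("log scaling requires positive values",
                                 call. = FALSE)
      log10(values)
    }
  )
  med <- tapply(values, groups, stats::median)
  dev <- abs(values - med[groups])
  n <- length(dev)
  a <- stats::qnorm(0.5 + rank(dev) / (2 * (n + 1)))
  abar <- mean(a)
  v2 <- sum((a - abar)^2) / (n - 1)
  group_means <- tapply(a, groups, mean)
  stat <- sum(tabulate(groups) * (group_means - abar)^2) / v2
  tibble::tibble(
    statistic = stat,
    df = k - 1,
    p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
    scaling = scaling
  )
}

#' Published upper-incisor reference statistics
#'
#' Summary statistics for the percentage of a circle encompassed by rodent
#' upper incisors, from an earlier analysis whose per-species raw data are
#' not reprinted here. Usable only for summary-level comparisons (e.g. a
#' variance ratio against the lower-incisor sample); sample size unknown.
#'
#' @return A one-row tibble: `mean`, `sd`, `cv` (percent of a circle).
#' @export
upper_incisor_reference <- function() {
  tibble::tibble(mean = 41.61, sd = 5.91, cv = 14.21)
}

#' Compare lower-incisor percentages against the upper-incisor reference
#'
#' Summarizes the supplied lower-incisor fractions of a circle and forms
#' the variance ratio against the published upper-incisor standard
#' deviation. The published comparison's t and Fligner-Killeen statistics
#' require the upper-incisor raw data and are not recomputable from
#' summary statistics alone.
#'
#' @param pct Numeric vector of lower-incisor percent-of-circle values.
#' @return A list with tibbles `lower` (group summary), `upper`
#'   (reference constants) and `variance_ratio`.
#' @export
incisor_comparison <- function(pct) {
  lower <- group_summary(tibble::tibble(pct = pct), pct)
  list(
    lower = lower,
    upper = upper_incisor_reference(),
    variance_ratio = variance_ratio(pct, sd_y = upper_incisor_reference()$sd)
  )
}
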