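#' Odds ratio from a 2x2 of counts
#'
#' Maximum-likelihood odds ratio of an exposed group against the referent:
#' \eqn{(a_i/b_i) / (a_0/b_0)}.  Counts may be real-valued (effective
#' counts).
#'
#' @param a_i,b_i cases and non-cases in the exposed group.
#' @param a_0,b_0 cases and non-cases in the referent group.
#' @return the odds ratio.
#' @export
or_from_counts <- function(a_i, b_i, a_0, b_0) {
  if (any(c(a_i, b_i, a_0, b_0) <= 0))
    stop("odds ratio undefined with a zero (or negative) cell", call. = FALSE)
  (a_i / b_i) / (a_0 / b_0)
}

#' Woolf standard error of the log odds ratio
#'
#' \eqn{\sqrt{1/a_i + 1/b_i + 1/a_0 + 1/b_0}}.
#'
#' @inheritParams or_from_counts
#' @return standard error of \eqn{\log OR}.
#' @export
se_log_or <- function(a_i, b_i, a_0, b_0) {
  if (any(c(a_i, b_i, a_0, b_0) <= 0))
    stop("SE of log OR is infinite with a zero cell", call. = FALSE)
  sqrt(1 / a_i + 1 / b_i + 1 / a_0 + 1 / b_0)
}

#' Lognormal summary statistics from a reported OR and CI
#'
#' Reported ORs are medians with skewed confidence intervals, consistent
#' with a lognormal sampling distribution.  The log-scale mean is
#' \eqn{\log OR} and the log-scale SD is recovered from the CI width:
#' \eqn{s' = \log(OR_U/OR_L) / (2 z)}, with \eqn{z} the standard-normal
#' quantile at \eqn{(1 + \mathrm{level})/2} (1.96 for a 95% CI, 1.645 for
#' a 90% CI).
#'
#' @param or_point,or_low,or_high reported OR and its CI bounds.
#' @param ci_level confidence level of the interval (default 0.95).
#' @return list with `mean_log`, `sd_log`.
#' @export
lognormal_from_ci <- function(or_point, or_low, or_high, ci_level = 0.95) {
  if (any(c(or_point, or_low, or_high) <= 0))
    stop("OR and CI bounds must be positive", call. = FALSE)
  if (or_low > or_point || or_point > or_high)
    stop("need or_low <= or_point <= or_high", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1)
    stop("ci_level must be in (0, 1)", call. = FALSE)
  z <- stats::qnorm((1 + ci_level) / 2)
  list(mean_log = log(or_point),
       sd_log = log(or_high / or_low) / (2 * z))
}

#' Model-ready arrays for the continuous (lognormal OR) track
#'
#' Assembles the four inputs a continuous benchmark-dose fit needs: the
#' adjusted midpoint dose, the subject count, and the log-scale mean and SD
#' of the OR in every group.  The referent group enters with mean 0 and SD
#' 0 (its OR is identically 1 and carries no interval).
#'
#' @param ds a [cc_dataset()]; midpoints must already be populated (see
#'   [adjust_dataset()]).
#' @return list of class `continuous_input` with vectors `dose`, `n`,
#'   `mean_log`, `sd_log` aligned by group, and scalars `d_ref` (referent
#'   midpoint) and `study_id`.
#' @export
continuous_input <- function(ds) {
  g <- ds$groups
  if (any(is.na(g$midpoint)))
    stop("midpoints missing; run adjust_dataset() first", call. = FALSE)
  G <- nrow(g)
  mean_log <- numeric(G)
  sd_log <- numeric(G)
  for (i in seq(2, G)) {
    if (is.na(g$or_low[i]) || is.na(g$or_high[i]))
      stop("group ", i, " lacks a confidence interval", call. = FALSE)
    ln <- lognormal_from_ci(g$or[i], g$or_low[i], g$or_high[i], ds$ci_level)
    mean_log[i] <- ln$mean_log
    sd_log[i] <- ln$sd_log
  }
  structure(list(dose = g$midpoint, n = g$n, mean_log = mean_log,
                 sd_log = sd_log, d_ref = g$midpoint[1],
                 study_id = ds$study_id),
            class = "continuous_input")
}

#' Model-ready arrays for the dichotomous (effective counts) track
#'
#' @param ds a [cc_dataset()] with midpoints and effective counts
#'   populated (see [adjust_dataset()] and [effective_dataset()]).
#' @return list of class `dichotomous_input` with vectors `dose`, `n`
#'   (effective subjects), `y` (effective cases), and scalars `d_ref` and
#'   `study_id`.
#' @export
dichotomous_input <- function(ds) {
  g <- ds$groups
  if (any(is.na(g$midpoint)))
    stop("midpoints missing; run adjust_dataset() first", call. = FALSE)
  if (any(is.na(g$eff_cases) | is.na(g$eff_noncases)))
    stop("effective counts missing; run effective_dataset() first",
         call. = FALSE)
  n_eff <- ifelse(is.na(g$n_eff), g$eff_cases + g$eff_noncases, g$n_eff)
  structure(list(dose = g$midpoint, n = n_eff, y = g$eff_cases,
                 d_ref = g$midpoint[1], study_id = ds$study_id),
            class = "dichotomous_input")
}
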