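#' Simulate a case-control summary table from a known dose-response curve
#'
#' Draws the case count of each exposure group from a binomial with
#' response probability given by a dichotomous dose-response model, then
#' reports the table the way a published case-control study would: crude
#' ORs against the referent group with Woolf 95% confidence intervals.
#' The resulting object has the same schema as a packaged fixture (the
#' simulated point doses are stored as reported medians, water intake at
#' the 2 L/day baseline, effective counts equal to the raw counts since
#' the simulated ORs are unadjusted).
#'
#' Groups that draw a zero cell (no cases or no non-cases, or either in
#' the referent) are redrawn up to `max_retries` times; after that a 0.5
#' continuity correction is applied to the affected 2x2 and recorded in
#' the `continuity_corrected` attribute.
#'
#' @param doses point exposures in ug/L, referent first; all positive.
#' @param n_per_group subjects per group (recycled if scalar).
#' @param model dichotomous model name (default `"quantal_linear"`).
#' @param theta model parameters (see [eval_model()]).
#' @param seed integer seed for reproducibility.
#' @param study_id identifier stored in the dataset.
#' @param max_retries redraw budget per zero-cell group.
#' @return a [cc_dataset()].
#' @export
simulate_case_control <- function(doses, n_per_group,
                                  model = c("quantal_linear",
                                            "dichotomous_hill"),
                                  theta, seed = NULL, study_id = "sim",
                                  max_retries = 10L) {
  model <- match.arg(model)
  G <- length(doses)
  if (G < 2) stop("need at least 2 dose groups", call. = FALSE)
  if (any(doses <= 0)) stop("simulated doses must be positive", call. = FALSE)
  n <- rep_len(n_per_group, G)
  if (!is.null(seed)) set.seed(seed)
  f <- eval_model(model, theta, doses)
  draw_group <- function(i) {
    for (r in 0:max_retries) {
      a <- stats::rbinom(1, n[i], f[i])
      if (a > 0 && a < n[i]) return(c(a, n[i] - a, 0))
    }
    c(a, n[i] - a, 1)  # keep last draw, flag for continuity correction
  }
  cc <- t(vapply(seq_len(G), draw_group, numeric(3)))
  corrected <- cc[, 3] == 1
  z <- stats::qnorm(0.975)
  or <- or_low <- or_high <- rep(NA_real_, G)
  or[1] <- 1
  for (i in seq(2, G)) {
    # 0.5 added to all four cells of the affected 2x2 (Woolf correction)
    cor_i <- 0.5 * (corrected[i] || corrected[1])
    ai <- cc[i, 1] + cor_i; bi <- cc[i, 2] + cor_i
    a0c <- cc[1, 1] + cor_i; b0c <- cc[1, 2] + cor_i
    or[i] <- or_from_counts(ai, bi, a0c, b0c)
    se <- se_log_or(ai, bi, a0c, b0c)
    or_low[i] <- or[i] * exp(-z * se)
    or_high[i] <- or[i] * exp(z * se)
  }
  groups <- data.frame(
    group_label = sprintf("%g", doses),
    dose_low = NA_real_, dose_high = NA_real_, dose_median = doses,
    midpoint = doses, midpoint_printed = NA_real_,
    or = or, or_low = or_low, or_high = or_high,
    cases = cc[, 1], noncases = cc[, 2], n = n,
    eff_cases = cc[, 1], eff_noncases = cc[, 2], n_eff = n,
    stringsAsFactors = FALSE)
  ds <- cc_dataset(study_id = study_id, endpoint = "other",
                   location = "synthetic", water_intake_rate = 2,
                   groups = groups)
  attr(ds, "truth") <- list(model = model, theta = theta)
  attr(ds, "continuity_corrected") <- which(corrected)
  ds
}
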