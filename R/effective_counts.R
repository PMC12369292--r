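#' Propagate referent effective counts through an adjusted OR
#'
#' Given referent effective counts \eqn{(A_0^e, B_0^e)}, the effective
#' counts of a treatment group are fixed by two conditions: the subject
#' count is preserved (\eqn{A_i^e + B_i^e = N_i}) and the crude OR of the
#' effective counts equals the adjusted OR.  Solving the pair gives
#' \eqn{A_i^e = N_i\,q/(1+q)} with \eqn{q = OR_i \cdot A_0^e/B_0^e}.
#'
#' @param a0e,b0e referent effective cases and non-cases (> 0).
#' @param or_i adjusted odds ratio of the treatment group (> 0).
#' @param n_i subject count of the treatment group.
#' @return list with real-valued `cases` and `noncases`.
#' @export
propagate_group <- function(a0e, b0e, or_i, n_i) {
  if (a0e <= 0 || b0e <= 0) stop("referent counts must be > 0", call. = FALSE)
  if (or_i <= 0) stop("or_i must be > 0", call. = FALSE)
  if (n_i <= 0) stop("n_i must be > 0", call. = FALSE)
  q <- or_i * a0e / b0e
  a <- n_i * q / (1 + q)
  list(cases = a, noncases = n_i - a)
}

#' Wang-style grid search for referent effective counts
#'
#' Estimates the effective case/non-case split of the referent group from
#' dataset-level summaries, following the sum-of-squares search of the
#' OR-to-RR conversion algorithm for studies with partial information.
#' All treatment groups are collapsed into one pseudo-group of
#' \eqn{N - N_0} subjects carrying the mean adjusted OR and mean CI
#' bounds.  For each candidate referent split \eqn{(a_0, N_0 - a_0)} the
#' pseudo-group's effective counts follow by [propagate_group()], a Woolf
#' 95% CI is reconstructed around the mean OR, and the objective is the
#' squared log-discrepancy between reconstructed and reported mean bounds
#' (`objective = "wang_log"`, the default) or the squared raw discrepancy
#' (`"wang_raw"`).  A custom objective `function(or_low_hat, or_high_hat,
#' or_low, or_high)` may be supplied.
#'
#' The objective is typically bimodal in \eqn{a_0}: a low-incidence and a
#' mirrored high-incidence branch reproduce similar interval widths.  The
#' search therefore returns every local minimum on the grid as a candidate
#' and selects the one with the smallest \eqn{a_0} (the low-incidence
#' branch; ties broken toward smaller counts for determinism).  All
#' candidates and their objective values are kept in the result so
#' disagreement with published counts can be inspected rather than
#' silently accepted.
#'
#' @param totals list from [totals_summary()].
#' @param referent_raw optional numeric `c(cases, noncases)` raw referent
#'   counts, used only as a fallback when the objective is flat
#'   (non-informative data, e.g. a single group at OR 1).
#' @param step grid step for candidate effective case counts (default 1;
#'   0.1 gives a real-valued search).
#' @param objective `"wang_log"`, `"wang_raw"`, or a function.
#' @param ci_level level of the reported intervals (default 0.95).
#' @return object of class `wang_result`: list with `a0e`, `b0e`,
#'   `objective_value`, a `candidates` data frame, and `flat` (logical,
#'   `TRUE` when the objective carried no information and the raw referent
#'   split was returned).
#' @export
wang_referent <- function(totals, referent_raw = NULL, step = 1,
                          objective = c("wang_log", "wang_raw"),
                          ci_level = 0.95) {
  obj_fun <- if (is.function(objective)) {
    objective
  } else {
    switch(match.arg(objective),
      wang_log = function(lo_hat, hi_hat, lo, hi)
        log(lo_hat / lo)^2 + log(hi_hat / hi)^2,
      wang_raw = function(lo_hat, hi_hat, lo, hi)
        (lo_hat - lo)^2 + (hi_hat - hi)^2)
  }
  n0 <- totals$n_referent
  nt <- totals$n_total - n0
  if (nt <= 0) stop("no treatment-group subjects", call. = FALSE)
  a0 <- seq(step, n0 - step, by = step)
  if (!length(a0)) stop("empty feasible grid", call. = FALSE)
  b0 <- n0 - a0
  q <- totals$mean_or * a0 / b0
  at <- nt * q / (1 + q)
  bt <- nt - at
  z <- stats::qnorm((1 + ci_level) / 2)
  se <- sqrt(1 / at + 1 / bt + 1 / a0 + 1 / b0)
  lo_hat <- totals$mean_or * exp(-z * se)
  hi_hat <- totals$mean_or * exp(z * se)
  ss <- obj_fun(lo_hat, hi_hat, totals$mean_or_low, totals$mean_or_high)
  if (!any(is.finite(ss)))
    stop("objective non-finite over the whole grid", call. = FALSE)
  # flat objective: no information to locate the referent split
  if (diff(range(ss[is.finite(ss)])) < 1e-12) {
    if (is.null(referent_raw))
      stop("flat objective and no raw referent fallback supplied",
           call. = FALSE)
    res <- list(a0e = referent_raw[1], b0e = referent_raw[2],
                objective_value = ss[1],
                candidates = data.frame(a0e = referent_raw[1],
                                        objective = ss[1]),
                flat = TRUE)
    return(structure(res, class = "wang_result"))
  }
  k <- length(ss)
  is_lmin <- ss < c(Inf, ss[-k]) & ss < c(ss[-1], Inf)
  cand <- data.frame(a0e = a0[is_lmin], objective = ss[is_lmin])
  cand <- cand[order(cand$a0e), , drop = FALSE]
  pick <- 1L  # smallest a0e: the low-incidence branch
  structure(list(a0e = cand$a0e[pick], b0e = n0 - cand$a0e[pick],
                 objective_value = cand$objective[pick],
                 candidates = cand, flat = FALSE),
            class = "wang_result")
}

#' @export
print.wang_result <- function(x, ...) {
  cat(sprintf("Wang referent search: a0e = %g, b0e = %g (objective %.4g%s)\n",
              x$a0e, x$b0e, x$objective_value,
              if (x$flat) ", flat objective - raw referent returned" else ""))
  if (nrow(x$candidates) > 1) {
    cat("  all local minima:\n")
    print(x$candidates, row.names = FALSE)
  }
  invisible(x)
}

#' Populate effective counts for a whole dataset
#'
#' Runs the Wang referent search on the dataset summaries, then propagates
#' the referent split through every non-referent group's adjusted OR.
#' Subject counts are preserved (`n_eff = n`) except where the dataset
#' already records a printed deviation in `n_eff`, which is kept verbatim.
#' With `rounding = "nearest_integer"` counts are rounded to the closest
#' integer and the non-case count repaired so pairs still sum to the
#' group's subjects; the default keeps real-valued counts for the
#' Gamma-extended likelihood.
#'
#' @param ds a [cc_dataset()].
#' @param rounding `"gamma_real"` (keep reals) or `"nearest_integer"`.
#' @param referent optional numeric `c(a0e, b0e)` to use instead of the
#'   Wang search (e.g. counts printed in a source table).
#' @param ... passed on to [wang_referent()].
#' @return the dataset with `eff_cases`, `eff_noncases`, `n_eff` populated;
#'   the `wang_result` (if computed) is attached as attribute `"wang"`.
#' @export
effective_dataset <- function(ds, rounding = c("gamma_real",
                                               "nearest_integer"),
                              referent = NULL, ...) {
  rounding <- match.arg(rounding)
  g <- ds$groups
  wres <- NULL
  if (is.null(referent)) {
    wres <- wang_referent(totals_summary(ds),
                          referent_raw = c(g$cases[1], g$noncases[1]),
                          ci_level = ds$ci_level, ...)
    referent <- c(wres$a0e, wres$b0e)
  }
  G <- nrow(g)
  ec <- numeric(G); en <- numeric(G); ne <- numeric(G)
  ec[1] <- referent[1]; en[1] <- referent[2]; ne[1] <- sum(referent)
  for (i in seq(2, G)) {
    ni <- if (!is.na(g$n_eff[i])) g$n_eff[i] else g$n[i]
    p <- propagate_group(referent[1], referent[2], g$or[i], ni)
    ec[i] <- p$cases; en[i] <- p$noncases; ne[i] <- ni
  }
  if (rounding == "nearest_integer") {
    ec <- round(ec)
    en <- ne - ec   # repair so pairs sum exactly
  }
  ds$groups$eff_cases <- ec
  ds$groups$eff_noncases <- en
  ds$groups$n_eff <- ne
  if (!is.null(wres)) attr(ds, "wang") <- wres
  ds
}
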