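#' Sampler configuration
#'
#' @param chains number of MCMC chains (>= 2).
#' @param iterations iterations per chain, including warmup.
#' @param warmup adaptation iterations discarded from each chain.
#' @param seed integer RNG seed; chain seeds are derived from it.
#' @param rhat_threshold split-Rhat above which a convergence warning is
#'   issued.
#' @param min_ess effective-sample-size floor for the warning.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4, iterations = 10000,
                           warmup = floor(iterations / 2), seed = NULL,
                           rhat_threshold = 1.05, min_ess = 400) {
  if (chains < 2) stop("chains must be >= 2", call. = FALSE)
  if (warmup >= iterations) stop("iterations must exceed warmup", call. = FALSE)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = seed,
                 rhat_threshold = rhat_threshold, min_ess = min_ess),
            class = "sampler_config")
}

#' Default weakly-informative priors
#'
#' Priors are stated on an internally rescaled dose axis (doses divided by
#' the maximum observed dose), so the same defaults serve exposure ranges
#' spanning 0.04 to 1080 ug/L:
#' \itemize{
#'   \item backgrounds `g` and the dichotomous-Hill asymptote `v`:
#'     uniform(0, 1) through a logit transform;
#'   \item quantal-linear slope (per scaled dose unit): half-normal(3);
#'   \item dichotomous-Hill log-dose slope `b`: half-normal(2), location
#'     `a`: normal(0, 10);
#'   \item continuous intercept `a`: normal(0, 10); linear slope (per
#'     scaled dose unit): normal(0, 3), sign-free so that flat data leave
#'     the slope sign-balanced;
#'   \item continuous Hill amplitude `v`: normal(0, 5), half-max `k` (on
#'     the scaled axis): lognormal(log 0.3, 1.5), power `n`: uniform(1, 18);
#'   \item residual log-scale SD `gamma`: half-Cauchy(1).
#' }
#'
#' @param model model name (see [eval_model()]).
#' @return a prior set understood by [fit_bmd()]: a list with the
#'   unconstrained-to-constrained `transform`, the log prior density plus
#'   transform Jacobian `lpj`, an `init` sampler and a text `description`.
#' @export
default_priors <- function(model = c("quantal_linear", "dichotomous_hill",
                                     "linear", "hill")) {
  model <- match.arg(model)
  track <- model_track(model)
  switch(model,
    quantal_linear = list(
      model = model, k = 2L, par_names = c("g", "beta"),
      transform = function(z) c(g = stats::plogis(z[1]), beta = exp(z[2])),
      lpj = function(z, th)
        stats::dlogis(z[1], log = TRUE) +
        stats::dnorm(th[2], 0, 3, log = TRUE) + log(2) + z[2],
      init = function() c(stats::qlogis(stats::runif(1, 0.02, 0.4)),
                          log(stats::runif(1, 0.1, 3))),
      description = c(g = "uniform(0,1)",
                      beta = "half-normal(3) per scaled dose")),
    dichotomous_hill = list(
      model = model, k = 4L, par_names = c("g", "v", "a", "b"),
      transform = function(z) c(g = stats::plogis(z[1]),
                                v = stats::plogis(z[2]),
                                a = z[3], b = exp(z[4])),
      lpj = function(z, th)
        stats::dlogis(z[1], log = TRUE) + stats::dlogis(z[2], log = TRUE) +
        stats::dnorm(z[3], 0, 10, log = TRUE) +
        stats::dnorm(th[4], 0, 2, log = TRUE) + log(2) + z[4],
      init = function() c(stats::qlogis(stats::runif(1, 0.02, 0.4)),
                          stats::qlogis(stats::runif(1, 0.2, 0.95)),
                          stats::rnorm(1, 0, 2),
                          log(stats::runif(1, 0.3, 3))),
      description = c(g = "uniform(0,1)", v = "uniform(0,1)",
                      a = "normal(0,10)", b = "half-normal(2)")),
    linear = list(
      model = model, k = 3L, par_names = c("a", "b", "gamma"),
      transform = function(z) c(a = z[1], b = z[2], gamma = exp(z[3])),
      lpj = function(z, th)
        stats::dnorm(z[1], 0, 10, log = TRUE) +
        stats::dnorm(z[2], 0, 3, log = TRUE) +
        stats::dcauchy(th[3], 0, 1, log = TRUE) + log(2) + z[3],
      init = function() c(stats::rnorm(1, 0, 0.3), stats::rnorm(1, 0, 0.5),
                          log(stats::runif(1, 0.1, 1))),
      description = c(a = "normal(0,10)",
                      b = "normal(0,3) per scaled dose",
                      gamma = "half-Cauchy(1)")),
    hill = list(
      model = model, k = 5L, par_names = c("a", "v", "k", "n", "gamma"),
      transform = function(z) c(a = z[1], v = z[2], k = exp(z[3]),
                                n = 1 + 17 * stats::plogis(z[4]),
                                gamma = exp(z[5])),
      lpj = function(z, th)
        stats::dnorm(z[1], 0, 10, log = TRUE) +
        stats::dnorm(z[2], 0, 5, log = TRUE) +
        stats::dnorm(z[3], log(0.3), 1.5, log = TRUE) +
        stats::dlogis(z[4], log = TRUE) +
        stats::dcauchy(th[5], 0, 1, log = TRUE) + log(2) + z[5],
      init = function() c(stats::rnorm(1, 0, 0.3), stats::rnorm(1, 0, 1),
                          stats::rnorm(1, log(0.3), 0.7),
                          stats::qlogis(stats::runif(1, 0.05, 0.5)),
                          log(stats::runif(1, 0.1, 1))),
      description = c(a = "normal(0,10)", v = "normal(0,5)",
                      k = "lognormal(log 0.3, 1.5) on scaled dose",
                      n = "uniform(1,18)", gamma = "half-Cauchy(1)")))
}

# convert a parameter vector fitted on the d/dmax axis back to ug/L units
unscale_theta <- function(model, theta, dmax) {
  switch(model,
    quantal_linear = c(theta["g"], beta = unname(theta["beta"]) / dmax),
    dichotomous_hill = c(theta["g"], theta["v"],
                         a = unname(theta["a"]) - unname(theta["b"]) * log(dmax),
                         theta["b"]),
    linear = c(theta["a"], b = unname(theta["b"]) / dmax,
               if ("gamma" %in% names(theta)) theta["gamma"]),
    hill = c(theta["a"], theta["v"], k = unname(theta["k"]) * dmax,
             theta["n"],
             if ("gamma" %in% names(theta)) theta["gamma"]))
}

#' Bayesian fit of a dose-response model
#'
#' Samples the posterior of a dose-response model under the track-matching
#' likelihood: the Gamma-extended binomial for `dichotomous_input` data or
#' the summary-statistics normal (with common log-scale SD `gamma`) for
#' `continuous_input` data.  Sampling runs on an internally rescaled dose
#' axis for numerical stability; returned draws are in original ug/L
#' units.  Convergence trouble (split-Rhat or effective sample size beyond
#' the configured bounds) raises a warning, not an error.
#'
#' @param data a [dichotomous_input()] or [continuous_input()].
#' @param model model name matching the data track (see [eval_model()]).
#' @param priors prior set; defaults to [default_priors()].
#' @param config a [sampler_config()].
#' @return object of class `bmd_fit`: draws matrix (one row per retained
#'   draw, named parameter columns, `gamma` included for continuous
#'   models), diagnostics, and the inputs needed for BMD summarisation.
#' @export
fit_bmd <- function(data, model, priors = NULL, config = sampler_config()) {
  track <- model_track(model)
  if (!inherits(data, c("dichotomous_input", "continuous_input")))
    stop("data must be a dichotomous_input or continuous_input", call. = FALSE)
  if ((track == "dichotomous") != inherits(data, "dichotomous_input"))
    stop(model, " needs ", track, " data", call. = FALSE)
  if (is.null(priors)) priors <- default_priors(model)
  dmax <- max(data$dose)
  if (dmax <= 0) stop("need at least one positive dose", call. = FALSE)
  sdata <- data
  sdata$dose <- data$dose / dmax
  npar <- model_npar(model)
  # constraint violations (e.g. a saturated logit at extreme proposals)
  # are treated as zero posterior mass, not errors
  log_post <- if (track == "dichotomous") {
    function(z) {
      th <- priors$transform(z)
      ll <- tryCatch(loglik_dichotomous(model, th[seq_len(npar)], sdata),
                     error = function(e) -Inf)
      if (!is.finite(ll)) return(-Inf)
      ll + priors$lpj(z, th)
    }
  } else {
    function(z) {
      th <- priors$transform(z)
      ll <- tryCatch(
        loglik_continuous(model, th[seq_len(npar)], th[npar + 1L], sdata),
        error = function(e) -Inf)
      if (!is.finite(ll)) return(-Inf)
      ll + priors$lpj(z, th)
    }
  }
  chains <- vector("list", config$chains)
  accept <- numeric(config$chains)
  base_seed <- config$seed %||% sample.int(1e6, 1)
  for (c_i in seq_len(config$chains)) {
    set.seed((base_seed + 7919L * c_i) %% 2147483629L)
    z0 <- NULL
    for (try_i in 1:200) {
      cand <- priors$init()
      if (is.finite(log_post(cand))) { z0 <- cand; break }
    }
    if (is.null(z0))
      stop("could not find a finite-posterior initial point", call. = FALSE)
    res <- am_chain(log_post, z0, config$iterations, config$warmup)
    chains[[c_i]] <- res$draws
    accept[c_i] <- res$accept
  }
  # constrained, unscaled draws
  kept <- config$iterations - config$warmup
  all_names <- priors$par_names
  draws <- matrix(NA_real_, kept * config$chains, length(all_names),
                  dimnames = list(NULL, all_names))
  rhat <- ess <- stats::setNames(numeric(length(all_names)), all_names)
  con_by_par <- lapply(seq_along(all_names), function(j)
    matrix(NA_real_, kept, config$chains))
  for (c_i in seq_len(config$chains)) {
    zc <- chains[[c_i]]
    thc <- t(apply(zc, 1, function(z)
      unscale_theta(model, priors$transform(z), dmax)))
    draws[seq((c_i - 1) * kept + 1, c_i * kept), ] <- thc
    for (j in seq_along(all_names)) con_by_par[[j]][, c_i] <- thc[, j]
  }
  for (j in seq_along(all_names)) {
    rhat[j] <- split_rhat(con_by_par[[j]])
    ess[j] <- ess_basic(con_by_par[[j]])
  }
  diag <- list(rhat = rhat, ess = ess, accept = accept,
               converged = all(rhat < config$rhat_threshold, na.rm = TRUE) &&
                 all(ess > config$min_ess, na.rm = TRUE))
  if (!diag$converged)
    warning(sprintf(
      "fit of %s (%s): max split-Rhat %.3f, min ESS %.0f; inspect before use",
      model, data$study_id %||% "?", max(rhat, na.rm = TRUE),
      min(ess, na.rm = TRUE)), call. = FALSE)
  structure(list(model = model, track = track, draws = draws,
                 diagnostics = diag, d_ref = data$d_ref,
                 max_dose = max(data$dose), data = data,
                 priors = priors$description, config = config,
                 seed = base_seed),
            class = "bmd_fit")
}

#' @export
print.bmd_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s fit (%s track), %d retained draws\n",
              x$model, x$track, nrow(x$draws)))
  s <- apply(x$draws, 2, function(v)
    c(median = stats::median(v), q05 = unname(stats::quantile(v, 0.05)),
      q95 = unname(stats::quantile(v, 0.95))))
  print(t(s), digits = 4)
  cat(sprintf("max split-Rhat %.3f, min ESS %.0f, mean acceptance %.2f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE),
              mean(x$diagnostics$accept)))
  invisible(x)
}

#' Posterior benchmark-dose summary
#'
#' Applies [bmd_from_theta()] to every retained posterior draw at a stated
#' benchmark response and summarises the draw-wise BMD distribution into a
#' median (BMD) and lower/upper credible bounds (BMDL, BMDU; one-sided
#' bounds at `level`, i.e. the `1 - level` and `level` posterior
#' quantiles).  Draws whose curve never reaches the benchmark response
#' within the search bracket are excluded and counted; more than 50%
#' unattainable flags the estimate unreliable.
#'
#' @param fit a [fit_bmd()] result.
#' @param bmr benchmark response on the fit's own track scale.
#' @param level one-sided credible level for BMDL/BMDU (default 0.95, the
#'   regulatory convention: 5th and 95th posterior percentiles).
#' @return object of class `bmd_estimate` with `bmd`, `bmdl`, `bmdu`,
#'   `bmr`, `level`, `n_draws`, `n_unattainable`, `unreliable`.
#' @export
summarize_bmd <- function(fit, bmr, level = 0.95) {
  draws <- fit$draws
  npar <- model_npar(fit$model)
  bmds <- vapply(seq_len(nrow(draws)), function(i)
    bmd_from_theta(fit$model, draws[i, seq_len(npar)], bmr,
                   fit$d_ref, fit$max_dose), numeric(1))
  ok <- is.finite(bmds)
  n_bad <- sum(!ok)
  unreliable <- n_bad > 0.5 * length(bmds)
  if (unreliable)
    warning(sprintf("BMR %.4g unattainable for %d of %d draws; estimate unreliable",
                    bmr, n_bad, length(bmds)), call. = FALSE)
  if (!any(ok)) {
    est <- c(bmd = NA_real_, bmdl = NA_real_, bmdu = NA_real_)
  } else {
    q <- stats::quantile(bmds[ok], c(1 - level, 0.5, level), names = FALSE)
    est <- c(bmd = q[2], bmdl = q[1], bmdu = q[3])
  }
  structure(list(bmd = est[["bmd"]], bmdl = est[["bmdl"]],
                 bmdu = est[["bmdu"]], bmr = bmr, level = level,
                 n_draws = length(bmds), n_unattainable = n_bad,
                 unreliable = unreliable, model = fit$model,
                 track = fit$track),
            class = "bmd_estimate")
}

#' @export
print.bmd_estimate <- function(x, ...) {
  cat(sprintf("BMD %.4g ug/L [BMDL %.4g, BMDU %.4g] at BMR %.4g (%s %s)%s\n",
              x$bmd, x$bmdl, x$bmdu, x$bmr, x$model, x$track,
              if (x$unreliable) " [UNRELIABLE]" else ""))
  if (x$n_unattainable > 0)
    cat(sprintf("  %d of %d draws excluded (BMR unattainable)\n",
                x$n_unattainable, x$n_draws))
  invisible(x)
}
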