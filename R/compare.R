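#' Cross-track agreement statistics
#'
#' Quantifies the agreement between dichotomous-track and continuous-track
#' benchmark-dose estimates.  Pearson's r is pooled over all pairs (raw
#' scale, with a log-scale companion reported alongside); Spearman's rho
#' and Kendall's tau-b are computed per dataset and aggregated through
#' Fisher's Z transformation (atanh mean, back-transformed, with the SD
#' propagated the same way).  Coefficients of exactly 1 are clamped at
#' `1 - 1e-6` before the atanh.
#'
#' @param pairs data frame with numeric columns `dich` and `cont` (one row
#'   per estimate pair) and optionally a `dataset` column for the
#'   per-dataset rank aggregation.
#' @return object of class `cc_agreement`.
#' @export
agreement <- function(pairs) {
  if (nrow(pairs) < 3) stop("need at least 3 estimate pairs", call. = FALSE)
  x <- pairs$dich; y <- pairs$cont
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("estimate pairs must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  pearson <- stats::cor(x, y)
  pearson_log <- if (all(x > 0 & y > 0)) stats::cor(log(x), log(y)) else NA_real_
  per_ds <- function(method) {
    # without a dataset column the whole set is one comparison group
    if (is.null(pairs$dataset)) pairs$dataset <- "all"
    ids <- unique(pairs$dataset)
    r <- vapply(ids, function(id) {
      sub <- pairs[pairs$dataset == id, ]
      if (nrow(sub) < 3 || stats::sd(sub$dich) == 0 || stats::sd(sub$cont) == 0)
        return(NA_real_)
      stats::cor(sub$dich, sub$cont, method = method)
    }, numeric(1))
    stats::setNames(r, ids)
  }
  fisher_mean <- function(r) {
    r <- r[is.finite(r)]
    if (!length(r)) return(c(mean = NA_real_, sd = NA_real_))
    z <- atanh(pmin(pmax(r, -1 + 1e-6), 1 - 1e-6))
    c(mean = tanh(mean(z)), sd = tanh(stats::sd(z)))
  }
  sp <- per_ds("spearman")
  kd <- per_ds("kendall")
  structure(list(pearson = pearson, pearson_log = pearson_log,
                 spearman = fisher_mean(sp), spearman_by_dataset = sp,
                 kendall = fisher_mean(kd), kendall_by_dataset = kd,
                 n_pairs = nrow(pairs)),
            class = "cc_agreement")
}

#' @export
print.cc_agreement <- function(x, ...) {
  cat(sprintf("Cross-track agreement over %d estimate pairs\n", x$n_pairs))
  cat(sprintf("  Pearson r      = %.3f (log scale %.3f)\n",
              x$pearson, x$pearson_log))
  if (!is.null(x$spearman_by_dataset)) {
    cat(sprintf("  Spearman rho   = %.3f +/- %.3f (Fisher-Z over %d datasets)\n",
                x$spearman["mean"], x$spearman["sd"],
                sum(is.finite(x$spearman_by_dataset))))
    cat(sprintf("  Kendall tau-b  = %.3f +/- %.3f\n",
                x$kendall["mean"], x$kendall["sd"]))
  }
  invisible(x)
}

#' Run the full two-track comparison pipeline
#'
#' For every dataset: populate midpoints, build both model-ready inputs,
#' fit the simple model pair (quantal-linear vs linear) and the complex
#' pair (dichotomous Hill vs Hill) by MCMC, convert each dichotomous BMR
#' into its dataset-specific continuous equivalent via [convert_bmr()],
#' and summarise BMD/BMDL/BMDU from both tracks.  Fixture datasets carry
#' printed effective counts and midpoints, which are used as-is
#' (`use_printed = TRUE`); datasets without effective counts get them from
#' the Wang search.
#'
#' @param datasets list of [cc_dataset()] objects; defaults to the ten
#'   packaged arsenic fixtures (5 bladder + 5 lung).
#' @param bmr_levels dichotomous extra-risk BMR levels (default 0.1%,
#'   0.5%, 1%).
#' @param config a [sampler_config()]; its `seed` drives every fit.
#' @param use_printed use printed midpoints where stored (see
#'   [adjust_dataset()]).
#' @param pairs which model pairs to run: subset of `c("simple",
#'   "complex")`.
#' @return list with `estimates` (data frame: dataset, pair, bmr_d, bmr_c,
#'   quantity, dich, cont), `agreement` (one [agreement()] report per
#'   pair), and `failures` (character vector of skipped dataset/pair
#'   combinations).
#' @export
run_paper_pipeline <- function(datasets = NULL,
                               bmr_levels = c(0.001, 0.005, 0.01),
                               config = sampler_config(),
                               use_printed = TRUE,
                               pairs = c("simple", "complex")) {
  if (is.null(datasets)) {
    bl <- load_fixture("bladder"); lu <- load_fixture("lung")
    names(bl) <- paste0("bladder_", names(bl))
    names(lu) <- paste0("lung_", names(lu))
    datasets <- c(bl, lu)
  }
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, function(d) d$study_id, character(1))
  pair_models <- list(simple = c(dich = "quantal_linear", cont = "linear"),
                      complex = c(dich = "dichotomous_hill", cont = "hill"))
  pairs <- match.arg(pairs, several.ok = TRUE)
  base_seed <- config$seed %||% sample.int(1e6, 1)
  rows <- list()
  failures <- character(0)
  for (d_i in seq_along(datasets)) {
    ds <- adjust_dataset(datasets[[d_i]], use_printed = use_printed)
    ds_id <- names(datasets)[d_i]
    if (any(is.na(ds$groups$eff_cases)))
      ds <- effective_dataset(ds, rounding = "nearest_integer")
    din <- dichotomous_input(ds)
    cin <- continuous_input(ds)
    f_ref <- din$y[1] / din$n[1]
    for (p in pairs) {
      mods <- pair_models[[p]]
      fit_pair <- tryCatch({
        cfg_d <- config
        cfg_d$seed <- (base_seed + 1009L * d_i +
                         101L * match(p, names(pair_models))) %% 2147483629L
        cfg_c <- cfg_d; cfg_c$seed <- cfg_d$seed + 31L
        list(dich = fit_bmd(din, mods[["dich"]], config = cfg_d),
             cont = fit_bmd(cin, mods[["cont"]], config = cfg_c))
      }, error = function(e) e)
      if (inherits(fit_pair, "error")) {
        failures <- c(failures, sprintf("%s/%s: %s", ds_id, p,
                                        conditionMessage(fit_pair)))
        next
      }
      for (bmr_d in bmr_levels) {
        bmr_c <- convert_bmr(bmr_d, f_ref)
        est_d <- summarize_bmd(fit_pair$dich, bmr_d)
        est_c <- summarize_bmd(fit_pair$cont, bmr_c)
        for (qty in c("bmd", "bmdl", "bmdu")) {
          rows[[length(rows) + 1L]] <- data.frame(
            dataset = ds_id, pair = p, bmr_d = bmr_d, bmr_c = bmr_c,
            quantity = qty, dich = est_d[[qty]], cont = est_c[[qty]],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  estimates <- do.call(rbind, rows)
  agr <- list()
  for (p in pairs) {
    sub <- estimates[estimates$pair == p & is.finite(estimates$dich) &
                       is.finite(estimates$cont), ]
    agr[[p]] <- if (nrow(sub) >= 3) agreement(sub) else NULL
  }
  list(estimates = estimates, agreement = agr, failures = failures)
}
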