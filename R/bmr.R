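#' Equivalent continuous benchmark response
#'
#' Converts a dichotomous extra-risk benchmark response into the
#' continuous-track relative change in OR that defines the same incidence
#' rate at the benchmark dose.  With \eqn{f_{ref}} the referent-group
#' incidence (effective cases over subjects) and the referent OR fixed at
#' 1:
#' \deqn{BMR_C = \frac{BMR_D (1 - f_{ref}) + f_{ref}}{f_{ref}} - 1}
#' The conversion is done from the input data, before any model fitting.
#'
#' @param bmr_d dichotomous extra-risk BMR, in (0, 1).
#' @param f_ref referent-group incidence rate, in (0, 1).
#' @return the equivalent continuous BMR (relative change in OR).
#' @export
convert_bmr <- function(bmr_d, f_ref) {
  if (any(bmr_d <= 0 | bmr_d >= 1)) stop("bmr_d must be in (0,1)", call. = FALSE)
  if (any(f_ref <= 0 | f_ref >= 1)) stop("f_ref must be in (0,1)", call. = FALSE)
  (bmr_d * (1 - f_ref) + f_ref) / f_ref - 1
}

#' Benchmark dose implied by a parameter vector
#'
#' Inverts a fitted dose-response curve at a stated benchmark response,
#' measured from the referent dose \eqn{d_{ref}} (the adjusted midpoint of
#' the lowest exposure group, not zero, since background exposure always
#' exists in epidemiological studies).
#'
#' Dichotomous track (extra risk): solves
#' \eqn{f(BMD) = f(d_{ref}) + BMR_D (1 - f(d_{ref}))}.
#' Continuous track (relative change in OR, model on the log-OR scale):
#' solves \eqn{f(BMD) - f(d_{ref}) = \log(1 + BMR_C)}.
#'
#' Both are solved by bracketed root finding on
#' \eqn{[d_{ref}, 50 \cdot d_{max}]}, expanding the bracket once (to
#' \eqn{500 \cdot d_{max}}) before declaring the BMR unattainable.
#' Closed forms exist for the two simple models
#' (\eqn{BMD = d_{ref} - \log(1 - BMR_D)/\beta} for quantal-linear,
#' \eqn{BMD = d_{ref} + \log(1 + BMR_C)/b} for linear) and are used as
#' independent oracles in the test suite.
#'
#' @param model model name (see [eval_model()]).
#' @param theta model parameters.
#' @param bmr benchmark response on the track's own scale (extra risk for
#'   dichotomous models, relative OR change for continuous models).
#' @param d_ref referent dose, ug/L.
#' @param max_dose largest observed dose, used to set the search bracket
#'   (defaults to `d_ref` when not given).
#' @return the BMD in ug/L, or `NA_real_` when the BMR is unattainable
#'   within the expanded bracket.
#' @export
bmd_from_theta <- function(model, theta, bmr, d_ref, max_dose = d_ref) {
  if (bmr <= 0) stop("bmr must be > 0", call. = FALSE)
  if (d_ref < 0) stop("d_ref must be >= 0", call. = FALSE)
  track <- model_track(model)
  f_ref <- eval_model(model, theta, d_ref)
  target <- if (track == "dichotomous") {
    if (f_ref >= 1) return(NA_real_)
    f_ref + bmr * (1 - f_ref)
  } else {
    f_ref + log1p(bmr)
  }
  h <- function(d) eval_model(model, theta, d) - target
  upper <- 50 * max(max_dose, d_ref, 1e-12)
  for (attempt in 1:2) {
    if (h(upper) >= 0) {
      lo <- max(d_ref, 1e-300)
      if (h(lo) >= 0) return(lo)  # degenerate: response already past target
      r <- stats::uniroot(h, c(lo, upper),
                          tol = 1e-15 * max(1, upper), maxiter = 500L)
      return(r$root)
    }
    upper <- upper * 10
  }
  NA_real_
}
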