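#' Binomial coefficient extended to real arguments
#'
#' \eqn{\log C(n, y)} via the Gamma function, continuous in both
#' arguments; coincides with `lchoose` at integers.
#' @noRd
lchoose_real <- function(n, y) {
  lgamma(n + 1) - lgamma(y + 1) - lgamma(n - y + 1)
}

#' Gamma-extended binomial log-likelihood (dichotomous track)
#'
#' Sum over groups of \eqn{\log C(n_i, y_i) + y_i \log f(d_i|\theta) +
#' (n_i - y_i)\log(1 - f(d_i|\theta))}, with the binomial coefficient
#' extended to the real-valued effective counts through the Gamma
#' function.  `-Inf` is returned when the model pins the response at 0 or
#' 1 against a non-zero opposing count.
#'
#' @param model `"quantal_linear"` or `"dichotomous_hill"`.
#' @param theta model parameters (see [eval_model()]).
#' @param data a `dichotomous_input` (or any list with `dose`, `n`, `y`).
#' @return the log-likelihood (scalar, possibly `-Inf`).
#' @export
loglik_dichotomous <- function(model, theta, data) {
  if (model_track(model) != "dichotomous")
    stop(model, " is not a dichotomous model", call. = FALSE)
  y <- data$y; n <- data$n
  if (any(y < 0 | y > n)) stop("need 0 <= y <= n", call. = FALSE)
  f <- eval_model(model, theta, data$dose)
  t1 <- ifelse(y > 0, y * log(f), 0)
  t2 <- ifelse(n - y > 0, (n - y) * log1p(-f), 0)
  sum(lchoose_real(n, y) + t1 + t2)
}

#' Summary-statistics normal log-likelihood (continuous track)
#'
#' Normal likelihood of per-group sample means and SDs of the log OR about
#' a continuous dose-response model, with a common within-group log-scale
#' SD \eqn{\gamma}:
#' \deqn{\sum_i \left[-\frac{n_i}{2}\log(2\pi\gamma^2)
#'   - \frac{(n_i-1) s_i'^2 + n_i(\bar y_i' - f(d_i|\theta))^2}
#'          {2\gamma^2}\right]}
#' The referent group has \eqn{s_0' = 0} and contributes only its mean
#' term.
#'
#' @param model `"linear"` or `"hill"`.
#' @param theta model parameters (see [eval_model()]).
#' @param gamma within-group SD on the log scale, > 0.
#' @param data a `continuous_input` (or any list with `dose`, `n`,
#'   `mean_log`, `sd_log`).
#' @return the log-likelihood (scalar).
#' @export
loglik_continuous <- function(model, theta, gamma, data) {
  if (model_track(model) != "continuous")
    stop(model, " is not a continuous model", call. = FALSE)
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  mu <- eval_model(model, theta, data$dose)
  n <- data$n
  sum(-(n / 2) * log(2 * pi * gamma^2) -
        ((n - 1) * data$sd_log^2 + n * (data$mean_log - mu)^2) /
        (2 * gamma^2))
}
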