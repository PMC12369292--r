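#' Dose-response models
#'
#' Four models, two per track.  Dichotomous models return a response
#' probability in (0, 1); continuous models return a mean log-OR.
#'
#' \describe{
#'   \item{quantal_linear}{\eqn{f(d) = g + (1-g)(1 - e^{-\beta d})};
#'     `theta = c(g, beta)`, \eqn{g \in (0,1)}, \eqn{\beta \ge 0}.}
#'   \item{dichotomous_hill}{\eqn{f(d) = g + (v - v g) / (1 + e^{-a - b
#'     \log d})}; `theta = c(g, v, a, b)`, \eqn{g \in (0,1)},
#'     \eqn{v \in (0,1]}, \eqn{b > 0}; the \eqn{d = 0} limit is \eqn{g}.}
#'   \item{linear}{\eqn{f(d) = a + b d} on the log-OR scale;
#'     `theta = c(a, b)`.}
#'   \item{hill}{\eqn{f(d) = a + v d^n / (k^n + d^n)} on the log-OR scale;
#'     `theta = c(a, v, k, n)`, \eqn{k > 0}, \eqn{n \ge 1}.}
#' }
#'
#' @param model model name.
#' @param theta numeric parameter vector in the order listed above.
#' @param d dose vector (ug/L), non-negative.
#' @return response vector: probability (dichotomous) or mean log-OR
#'   (continuous).
#' @export
eval_model <- function(model = c("quantal_linear", "dichotomous_hill",
                                 "linear", "hill"), theta, d) {
  model <- match.arg(model)
  if (any(d < 0)) stop("doses must be non-negative", call. = FALSE)
  check_theta(model, theta)
  switch(model,
    quantal_linear = {
      g <- theta[1]; beta <- theta[2]
      g + (1 - g) * (1 - exp(-beta * d))
    },
    dichotomous_hill = {
      g <- theta[1]; v <- theta[2]; a <- theta[3]; b <- theta[4]
      out <- ifelse(d > 0,
                    g + (v - v * g) * stats::plogis(a + b * log(pmax(d, 1e-300))),
                    g)
      out
    },
    linear = theta[1] + theta[2] * d,
    hill = {
      a <- theta[1]; v <- theta[2]; k <- theta[3]; n <- theta[4]
      a + v * d^n / (k^n + d^n)
    })
}

model_track <- function(model) {
  if (model %in% c("quantal_linear", "dichotomous_hill")) "dichotomous"
  else "continuous"
}

model_npar <- function(model) {
  switch(model, quantal_linear = 2L, dichotomous_hill = 4L,
         linear = 2L, hill = 4L)
}

model_par_names <- function(model) {
  switch(model,
         quantal_linear = c("g", "beta"),
         dichotomous_hill = c("g", "v", "a", "b"),
         linear = c("a", "b"),
         hill = c("a", "v", "k", "n"))
}

check_theta <- function(model, theta) {
  if (length(theta) != model_npar(model))
    stop(model, " needs ", model_npar(model), " parameters", call. = FALSE)
  ok <- switch(model,
    quantal_linear = theta[1] > 0 && theta[1] < 1 && theta[2] >= 0,
    dichotomous_hill = theta[1] > 0 && theta[1] < 1 &&
      theta[2] > 0 && theta[2] <= 1 && theta[4] > 0,
    linear = TRUE,
    hill = theta[3] > 0 && theta[4] >= 1)
  if (!ok) stop("theta outside the ", model, " parameter constraints",
                call. = FALSE)
  invisible(TRUE)
}
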