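# Adaptive random-walk Metropolis machinery and convergence diagnostics.
# The sampler is deliberately generic: any log-posterior over an
# unconstrained parameter vector.  Proposal covariance and global scale are
# adapted during warmup (Robbins-Monro toward 23.4% acceptance with an
# empirical-covariance proposal), then frozen.

am_chain <- function(log_post, z0, iterations, warmup) {
  k <- length(z0)
  z <- z0
  lp <- log_post(z)
  if (!is.finite(lp)) stop("non-finite log posterior at the initial point",
                           call. = FALSE)
  mu <- z
  Sigma <- diag(k)
  lambda <- 2.38^2 / k
  L <- chol(lambda * (Sigma + 1e-6 * diag(k)))
  keep <- matrix(NA_real_, iterations - warmup, k)
  n_acc <- 0L
  for (t in seq_len(iterations)) {
    prop <- z + drop(rnorm(k) %*% L)
    lp_prop <- log_post(prop)
    alpha <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp)) else 0
    if (stats::runif(1) < alpha) {
      z <- prop; lp <- lp_prop
      if (t > warmup) n_acc <- n_acc + 1L
    }
    if (t <= warmup) {
      gam <- min(0.9, 5 * t^-0.7)
      dz <- z - mu
      mu <- mu + gam * dz
      Sigma <- Sigma + gam * (tcrossprod(dz) - Sigma)
      lambda <- lambda * exp(gam * (alpha - 0.234))
      if (t %% 25L == 0L || t == warmup)
        L <- chol(lambda * (Sigma + 1e-8 * diag(k)))
    } else {
      keep[t - warmup, ] <- z
    }
  }
  list(draws = keep, accept = n_acc / (iterations - warmup))
}

# Split-Rhat of one parameter; x is an (iterations x chains) matrix.
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[seq(n - half + 1, n), , drop = FALSE])
  m <- ncol(xs); nn <- nrow(xs)
  means <- colMeans(xs)
  vars <- apply(xs, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Effective sample size via Geyer's initial positive sequence, averaged
# over chains; x is an (iterations x chains) matrix.
ess_basic <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4) return(NA_real_)
  rho_sum <- 0
  for (j in seq_len(m)) {
    v <- x[, j]
    if (stats::var(v) == 0) next
    ac <- stats::acf(v, lag.max = min(n - 2, 500), plot = FALSE,
                     demean = TRUE)$acf[-1]
    s <- 0
    i <- 1
    while (i < length(ac)) {
      pair <- ac[i] + ac[i + 1]
      if (pair < 0) break
      s <- s + pair
      i <- i + 2
    }
    rho_sum <- rho_sum + s
  }
  rho <- rho_sum / m
  m * n / (1 + 2 * rho)
}
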