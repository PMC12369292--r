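test_that("model curves evaluate their closed forms", {
  # flat quantal-linear
  expect_equal(eval_model("quantal_linear", c(0.1, 0), c(0, 5, 1e4)),
               rep(0.1, 3))
  # frozen: 0.1 + 0.9 * (1 - exp(-1))
  expect_equal(eval_model("quantal_linear", c(0.1, 0.001), 1000),
               0.66891, tolerance = 1e-5)
  # Hill half-max identity at d = k
  expect_equal(eval_model("hill", c(0.2, 1.4, 50, 3), 50), 0.2 + 1.4 / 2)
  # linear
  expect_equal(eval_model("linear", c(-0.5, 0.01), c(0, 100)), c(-0.5, 0.5))
  # dichotomous Hill: d -> 0 limit is the background
  th <- c(0.1, 0.5, -3, 1)
  expect_equal(eval_model("dichotomous_hill", th, 0), 0.1)
  expect_lt(abs(eval_model("dichotomous_hill", th, 1e-12) - 0.1), 1e-9)
  # and its large-dose limit is g + v(1 - g)
  expect_equal(eval_model("dichotomous_hill", th, 1e12),
               0.1 + 0.5 * 0.9, tolerance = 1e-6)
  expect_error(eval_model("quantal_linear", c(1.5, 1), 1), "constraints")
  expect_error(eval_model("hill", c(0, 1, -2, 3), 1), "constraints")
})

test_that("dichotomous models are nondecreasing in dose", {
  d <- sort(runif(200, 0, 2000))
  expect_true(!is.unsorted(eval_model("quantal_linear", c(0.05, 0.003), d)))
  expect_true(!is.unsorted(eval_model("dichotomous_hill",
                                      c(0.05, 0.8, -4, 1.5), d)))
  probs <- eval_model("dichotomous_hill", c(0.05, 0.8, -4, 1.5), d)
  expect_true(all(probs > 0 & probs < 1))
})

test_that("the Gamma-extended binomial matches the binomial pmf at integers", {
  set.seed(41)
  for (i in 1:25) {
    G <- sample(2:5, 1)
    n <- sample(5:200, G, replace = TRUE)
    y <- vapply(n, function(ni) sample(0:ni, 1), numeric(1))
    d <- sort(runif(G, 1, 100))
    th <- c(runif(1, 0.01, 0.3), runif(1, 0.001, 0.05))
    data <- list(dose = d, n = n, y = y)
    ll <- loglik_dichotomous("quantal_linear", th, data)
    oracle <- sum(dbinom(y, n, eval_model("quantal_linear", th, d),
                         log = TRUE))
    expect_equal(ll, oracle, tolerance = 1e-10)
  }
})

test_that("the Gamma extension is continuous in real-valued counts", {
  data_at <- function(y) list(dose = 10, n = 3.2, y = y)
  th <- c(0.2, 0.01)
  v <- vapply(seq(1.0, 2.0, by = 0.05), function(y)
    loglik_dichotomous("quantal_linear", th, data_at(y)), numeric(1))
  expect_true(all(is.finite(v)))
  # no jumps: successive differences are small and smoothly varying
  expect_lt(max(abs(diff(v))), 0.2)
  # interpolates between the integer neighbours
  ll1 <- loglik_dichotomous("quantal_linear", th, data_at(1))
  ll2 <- loglik_dichotomous("quantal_linear", th, data_at(2))
  llmid <- loglik_dichotomous("quantal_linear", th, data_at(1.5))
  expect_gt(llmid, min(ll1, ll2) - 0.5)
  expect_lt(llmid, max(ll1, ll2) + 0.5)
})

test_that("one-group closed forms and degenerate responses behave", {
  # n = 2, y = 1, f = 0.5: log C(2,1) + log(1/4) = -log 2
  th_flat <- c(0.5, 0)
  expect_equal(loglik_dichotomous("quantal_linear", th_flat,
                                  list(dose = 1, n = 2, y = 1)),
               -log(2))
  # all-zero responders at vanishing background: likelihood tends to 0
  data0 <- list(dose = c(1, 2), n = c(5, 7), y = c(0, 0))
  ll <- loglik_dichotomous("quantal_linear", c(1e-12, 0), data0)
  expect_equal(ll, 0, tolerance = 1e-9)
  # response pinned against an opposing count is -Inf
  expect_identical(
    loglik_dichotomous("quantal_linear", c(1 - 1e-12, 1e5),
                       list(dose = 1e5, n = 10, y = 2)), -Inf)
})

test_that("continuous likelihood matches a per-subject normal-density oracle", {
  # a summary-statistics likelihood must equal the joint density of n_i
  # subject-level normals with the same sample mean and (n-1)-denominator SD
  set.seed(42)
  for (i in 1:10) {
    G <- sample(2:4, 1)
    n <- sample(3:12, G, replace = TRUE)
    d <- sort(runif(G, 0, 100))
    gamma <- runif(1, 0.1, 0.8)
    th <- c(rnorm(1, 0, 0.5), runif(1, 0, 0.02))
    xs <- lapply(n, function(ni) rnorm(ni))
    ybar <- vapply(xs, mean, numeric(1))
    s <- vapply(xs, sd, numeric(1))
    data <- list(dose = d, n = n, mean_log = ybar, sd_log = s)
    ll <- loglik_continuous("linear", th, gamma, data)
    mu <- eval_model("linear", th, d)
    oracle <- sum(vapply(seq_len(G), function(j)
      sum(dnorm(xs[[j]], mu[j], gamma, log = TRUE)), numeric(1)))
    expect_equal(ll, oracle, tolerance = 1e-9)
  }
})

test_that("continuous likelihood is translation invariant and referent-degenerate", {
  data <- list(dose = c(0, 10), n = c(10, 10), mean_log = c(0, 0.5),
               sd_log = c(0, 0.2))
  ll1 <- loglik_continuous("linear", c(0, 0.05), 0.3, data)
  data2 <- data; data2$mean_log <- data$mean_log + 2
  ll2 <- loglik_continuous("linear", c(2, 0.05), 0.3, data2)
  expect_equal(ll1, ll2)

  # single residual-free observation: -(1/2) log(2 pi gamma^2)
  g1 <- list(dose = 5, n = 1, mean_log = 0.25, sd_log = 0)
  expect_equal(loglik_continuous("linear", c(0, 0.05), 0.3, g1),
               -0.5 * log(2 * pi * 0.3^2))
  expect_error(loglik_continuous("linear", c(0, 1), -1, data), "gamma")
})

test_that("likelihoods peak at the generating parameters on noise-free toys", {
  # dichotomous: expected counts at a known curve; grid maximum at truth
  d <- c(1, 50, 150, 400)
  th0 <- c(0.1, 0.004)
  f <- eval_model("quantal_linear", th0, d)
  data <- list(dose = d, n = rep(100, 4), y = 100 * f)  # real-valued counts
  grid_g <- seq(0.02, 0.3, by = 0.02)
  grid_b <- seq(0.001, 0.01, by = 0.0005)
  ll <- outer(grid_g, grid_b, Vectorize(function(g, b)
    loglik_dichotomous("quantal_linear", c(g, b), data)))
  best <- arrayInd(which.max(ll), dim(ll))
  expect_equal(grid_g[best[1]], 0.1)
  expect_equal(grid_b[best[2]], 0.004)

  # continuous: means exactly on the line, grid maximum at the true slope
  datac <- list(dose = d, n = rep(50, 4), mean_log = 0.3 + 0.002 * d,
                sd_log = rep(0.1, 4))
  grid_b2 <- seq(0.0005, 0.005, by = 0.00025)
  llc <- vapply(grid_b2, function(b)
    loglik_continuous("linear", c(0.3, b), 0.1, datac), numeric(1))
  expect_equal(grid_b2[which.max(llc)], 0.002)
})
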