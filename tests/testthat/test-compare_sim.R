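test_that("agreement reproduces hand-counted rank statistics", {
  ident <- data.frame(dich = 1:6, cont = 1:6)
  a <- agreement(ident)
  expect_equal(a$pearson, 1)
  expect_equal(unname(a$spearman["mean"]), 1, tolerance = 1e-5)
  expect_equal(unname(a$kendall["mean"]), 1, tolerance = 1e-5)

  rev <- data.frame(dich = 1:5, cont = 5:1)
  ar <- agreement(rev)
  expect_equal(unname(ar$spearman["mean"]), -1, tolerance = 1e-5)
  expect_equal(unname(ar$kendall["mean"]), -1, tolerance = 1e-5)

  # frozen by exhaustive pair counting: one discordant pair out of six,
  # tau-b = (5 - 1)/6; Spearman rho on the ranks = 0.8
  toy <- data.frame(dich = c(1, 2, 3, 4), cont = c(2, 1, 3, 4))
  at <- agreement(toy)
  expect_equal(unname(at$kendall["mean"]), 2 / 3, tolerance = 1e-6)
  expect_equal(unname(at$spearman["mean"]), 0.8, tolerance = 1e-6)

  expect_error(agreement(data.frame(dich = c(1, 1, 1), cont = 1:3)),
               "constant")
  expect_error(agreement(data.frame(dich = 1:2, cont = 1:2)), "3")
})

test_that("tau-b uses the tie-corrected denominator", {
  # with ties: x = (1,2,2,3), y = (1,2,3,3)
  # concordant pairs 4, discordant 0, ties broken out by hand:
  # tau-b = 4 / sqrt((6-1)(6-1)) = 0.8
  pairs <- data.frame(dich = c(1, 2, 2, 3), cont = c(1, 2, 3, 3))
  a <- agreement(pairs)
  expect_equal(unname(a$kendall["mean"]), 0.8, tolerance = 1e-6)
})

test_that("tau-b and rho agree in sign and hit 1 on co-monotone pairs", {
  set.seed(81)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    a <- agreement(data.frame(dich = x, cont = y))
    s <- unname(a$spearman["mean"]); k <- unname(a$kendall["mean"])
    expect_true(sign(round(s, 6)) == sign(round(k, 6)) ||
                  abs(s) < 1e-6 || abs(k) < 1e-6)
    mono <- sort(x)
    am <- agreement(data.frame(dich = mono, cont = exp(mono)))
    expect_equal(unname(am$spearman["mean"]), 1, tolerance = 1e-5)
    expect_equal(unname(am$kendall["mean"]), 1, tolerance = 1e-5)
  }
})

test_that("simulated case-control tables are deterministic and schema-complete", {
  ds1 <- simulate_case_control(c(5, 50, 200), 300, "quantal_linear",
                               c(0.05, 0.002), seed = 82)
  ds2 <- simulate_case_control(c(5, 50, 200), 300, "quantal_linear",
                               c(0.05, 0.002), seed = 82)
  expect_identical(ds1$groups, ds2$groups)
  expect_s3_class(ds1, "cc_dataset")
  expect_equal(ds1$groups$or[1], 1)
  expect_true(all(ds1$groups$cases + ds1$groups$noncases == ds1$groups$n))
  # ORs in the table reproduce the count-based estimator
  g <- ds1$groups
  expect_equal(g$or[2],
               or_from_counts(g$cases[2], g$noncases[2], g$cases[1],
                              g$noncases[1]))
})

test_that("a zero-slope generator yields null ORs on average", {
  set.seed(83)
  logors <- replicate(200, {
    ds <- simulate_case_control(c(5, 50), 200, "quantal_linear", c(0.2, 0))
    log(ds$groups$or[2])
  })
  se <- sd(logors) / sqrt(length(logors))
  expect_lt(abs(mean(logors)), 3 * se)
})

test_that("empirical ORs approach the model odds ratio for large groups", {
  th <- c(0.05, 0.002)
  doses <- c(10, 100, 300)
  ds <- simulate_case_control(doses, 2e5, "quantal_linear", th, seed = 84)
  f <- eval_model("quantal_linear", th, doses)
  target <- (f / (1 - f)) / (f[1] / (1 - f[1]))
  expect_equal(ds$groups$or, target, tolerance = 0.05)
})

test_that("zero-cell groups get the continuity correction after retries", {
  # referent response ~5e-7: zero referent cases almost surely
  ds <- simulate_case_control(c(0.001, 10), c(30, 30), "quantal_linear",
                              c(1e-9, 0.5), seed = 85, max_retries = 2)
  expect_true(length(attr(ds, "continuity_corrected")) >= 1)
  expect_true(is.finite(ds$groups$or[2]))
  expect_true(is.finite(ds$groups$or_high[2]))
})

test_that("both tracks recover correlated BMDs across simulated studies", {
  # reduced-scale end-to-end recovery: 10 studies simulated from
  # quantal-linear truths, both tracks fit with a short sampler
  # true BMDs span roughly 11-30 ug/L: slopes log-uniform over a 16-fold
  # range, the spread real arsenic studies show across populations
  set.seed(86)
  rows <- NULL
  for (s in 1:10) {
    beta <- exp(runif(1, log(5e-4), log(8e-3)))
    ds <- simulate_case_control(c(10, 80, 250, 600), 600, "quantal_linear",
                                c(runif(1, 0.03, 0.1), beta), seed = 860 + s)
    ds <- adjust_dataset(ds)
    cfg <- sampler_config(chains = 2, iterations = 1500, seed = 860 + s)
    fd <- suppressWarnings(fit_bmd(dichotomous_input(ds), "quantal_linear",
                                   config = cfg))
    fc <- suppressWarnings(fit_bmd(continuous_input(ds), "linear",
                                   config = cfg))
    f_ref <- ds$groups$eff_cases[1] / ds$groups$n_eff[1]
    ed <- summarize_bmd(fd, 0.01)
    ec <- summarize_bmd(fc, convert_bmr(0.01, f_ref))
    rows <- rbind(rows, data.frame(dich = ed$bmd, cont = ec$bmd))
  }
  rho <- cor(rows$dich, rows$cont, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("pipeline bookkeeping: one dataset and one BMR give six pairs per quantity set", {
  ds <- simulate_case_control(c(10, 80, 250, 600), 400, "quantal_linear",
                              c(0.05, 0.002), seed = 87)
  res <- suppressWarnings(run_paper_pipeline(
    list(sim = ds), bmr_levels = 0.01,
    config = sampler_config(chains = 2, iterations = 1200, seed = 87)))
  expect_equal(nrow(res$estimates), 6)  # 3 quantities x 2 model pairs
  expect_setequal(unique(res$estimates$quantity), c("bmd", "bmdl", "bmdu"))
  expect_setequal(unique(res$estimates$pair), c("simple", "complex"))
})
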