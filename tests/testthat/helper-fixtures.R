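# Shared fixtures for the test suite.  Everything is built in code.

# a small, fully closed-interval dataset with self-consistent crude ORs
toy_dataset <- function() {
  a <- c(20, 30); b <- c(80, 70); n <- a + b
  or <- c(1, (a[2] / b[2]) / (a[1] / b[1]))
  se <- sqrt(1 / a[2] + 1 / b[2] + 1 / a[1] + 1 / b[1])
  z <- qnorm(0.975)
  cc_dataset(
    study_id = "toy", endpoint = "other", location = "nowhere",
    water_intake_rate = 2,
    groups = data.frame(
      group_label = c("0-10", "10-30"),
      dose_low = c(0, 10), dose_high = c(10, 30), dose_median = NA_real_,
      or = or, or_low = c(NA, or[2] * exp(-z * se)),
      or_high = c(NA, or[2] * exp(z * se)),
      cases = a, noncases = b, n = n))
}

# printed referent effective counts of the ten arsenic fixtures
printed_referents <- function() {
  list(bladder = c(Ferreccio2000 = 19, Kurttio = 13, Pu = 18,
                   Steinmaus = 14, Wu = 27),
       lung = c(Ferreccio1998 = 5, Ferreccio2000 = 32, Mostafa = 109,
                Smith = 8, Steinmaus = 21))
}

fast_config <- function(seed, chains = 2, iterations = 2500) {
  sampler_config(chains = chains, iterations = iterations, seed = seed)
}
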