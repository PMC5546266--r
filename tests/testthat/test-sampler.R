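test_that("MCMC output is bit-identical under a fixed seed", {
  tr <- fig1_tree()
  cal <- propagate_calibrations(tr, fig1_calibrations(), "st2")
  a <- sample_time_prior(tr, cal, "conditional",
    iterations = 1000, burnin = 200, thin = 5, chains = 1, seed = 42
  )
  b <- sample_time_prior(tr, cal, "conditional",
    iterations = 1000, burnin = 200, thin = 5, chains = 1, seed = 42
  )
  expect_identical(a$draws, b$draws)
  c2 <- sample_time_prior(tr, cal, "conditional",
    iterations = 1000, burnin = 200, thin = 5, chains = 1, seed = 43
  )
  expect_false(identical(a$draws, c2$draws))
})

test_that("every stored sample respects the tree partial order", {
  sim <- simulate_timetree(7, seed = 3)
  cal <- simulate_calibrations(sim, frac_calibrated = 0.6, seed = 3)
  ps <- sample_time_prior(sim$tree, cal, "conditional",
    iterations = 1500, burnin = 300, thin = 3, chains = 1, seed = 5
  )
  ok <- apply(ps$draws, 1, function(a) {
    timeprior:::ages_feasible(sim$tree, a)
  })
  expect_true(all(ok))
})

test_that("a single calibrated root is reproduced without truncation distortion", {
  tr <- read_timetree("((A,B),C);")
  rows <- tibble::tibble(taxon_a = "A", taxon_b = "C", min_age = NA, max_age = 100)
  cal <- calibration_set(tr, rows, hard = TRUE)
  ps <- sample_time_prior(tr, cal, "conditional",
    iterations = 30000, burnin = 2000, thin = 3, chains = 1, seed = 9
  )
  root <- ps$draws[, "4"]
  expect_close(mean(root), 50, 3 * 100 / sqrt(12) / sqrt(5000))
  ks <- suppressWarnings(stats::ks.test(root, function(q) pmin(1, q / 100)))
  expect_gt(ks$p.value, 0.01)
})

test_that("summaries have the stated structural properties", {
  sim <- simulate_timetree(6, seed = 8)
  cal <- simulate_calibrations(sim, frac_calibrated = 0.7, seed = 8)
  ps <- sample_time_prior(sim$tree, cal, "conditional",
    iterations = 3000, burnin = 600, thin = 3, chains = 2, seed = 10
  )
  s <- summarize_prior(ps)
  expect_equal(s$node, sim$tree$interior)
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  # HPD is never wider than the equal-tail interval
  expect_true(all(s$hpd_upper - s$hpd_lower <= s$upper - s$lower + 1e-12))
  # tidy/glance round out the interface
  long <- tidy(ps)
  expect_setequal(unique(long$node), sim$tree$interior)
  expect_equal(nrow(long), nrow(ps$draws) * ncol(ps$draws))
  g <- glance(ps)
  expect_equal(g$n_chains, 2)
  expect_equal(g$construction, "conditional")
})

test_that("interval summaries match known i.i.d. references", {
  set.seed(21)
  x <- matrix(runif(2e4, 10, 100), ncol = 1, dimnames = list(NULL, "4"))
  ps <- structure(
    list(
      draws = x, chain = rep(1L, nrow(x)),
      ess = c("4" = nrow(x)),
      settings = list(sampler = "manual")
    ),
    class = "prior_samples"
  )
  s <- summarize_prior(ps)
  expect_close(s$lower, 12.25, 0.6)
  expect_close(s$upper, 97.75, 0.6)
  # constant samples collapse every interval to the point
  y <- matrix(rep(7, 100), ncol = 1, dimnames = list(NULL, "4"))
  ps2 <- structure(
    list(draws = y, chain = rep(1L, 100), ess = c("4" = 100),
         settings = list(sampler = "manual")),
    class = "prior_samples"
  )
  s2 <- summarize_prior(ps2)
  expect_equal(c(s2$lower, s2$upper, s2$hpd_lower, s2$hpd_upper), rep(7, 4))
})

test_that("effective sample size estimator is calibrated on known chains", {
  set.seed(33)
  x <- rnorm(5000)
  expect_gt(timeprior:::ess_geyer(x), 3000) # i.i.d. -> near n
  rho <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = rho), 5000))
  tau <- (1 + rho) / (1 - rho) # autocorrelation time 19
  ess_ar <- timeprior:::ess_geyer(ar)
  expect_lt(ess_ar, 1000)
  expect_gt(ess_ar, 5000 / tau / 3)
})

test_that("reflection keeps proposals inside the feasible interval", {
  set.seed(2)
  for (i in 1:200) {
    lo <- runif(1, 0, 50)
    hi <- lo + runif(1, 0.1, 50)
    x <- runif(1, lo - 100, hi + 100)
    y <- timeprior:::reflect_interval(x, lo, hi)
    expect_true(y >= lo && y <= hi)
  }
  y <- timeprior:::reflect_interval(5, 10, Inf)
  expect_equal(y, 15)
})

test_that("rejection sampler acceptance equals the truncation normalizer", {
  tr <- fig1_tree()
  cal <- fig1_calibrations()
  rj <- rejection_sample_prior(tr, cal, "conditional", n = 20000, seed = 17)
  # stage-one acceptance IS the st1 conditional normalizing constant
  expect_close(rj$accept_rate, 0.80001, 0.01)
  # with only the root calibrated, multiplicative acceptance is the
  # probability that three i.i.d. uniforms are ordered: 1/3!
  rows <- tibble::tibble(taxon_a = "A", taxon_b = "E", min_age = NA, max_age = 100)
  root_only <- calibration_set(tr, rows, hard = TRUE)
  rj2 <- rejection_sample_prior(tr, root_only, "multiplicative",
    n = 5000, seed = 18
  )
  expect_close(rj2$accept_rate, 1 / 6, 0.02)
})

test_that("contradictory bounds fail fast with a clear error", {
  tr <- read_timetree("((A,B),(C,D));")
  rows <- tibble::tibble(
    taxon_a = c("A", "A"), taxon_b = c("D", "B"),
    min_age = c(NA, 50), max_age = c(40, NA)
  )
  cal <- calibration_set(tr, rows, hard = TRUE)
  expect_error(
    sample_time_prior(tr, cal, "conditional", iterations = 100, seed = 1),
    "feasible"
  )
})
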