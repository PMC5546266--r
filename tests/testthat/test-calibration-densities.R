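test_that("every density family has unit mass and exact tail masses", {
  grid <- list(
    cal_uniform(20, 80, 0.01, 0.05),
    cal_uniform(10, 100, 0.05, 0.1),
    cal_uniform(20, 80, hard = TRUE),
    cal_uniform(0, 100, pL = 0, pU = 0.05), # maximum-only bound
    cal_offset_exp(10, 0.1),
    cal_offset_exp(33.7),
    cal_cauchy_min(20, 0.1, 0.1, 0.01),
    cal_cauchy_min(45, 0.2, 0.5, 1e-4)
  )
  for (d in grid) {
    mass <- stats::integrate(function(t) cal_pdf(d, t), 0, Inf,
      rel.tol = 1e-9, subdivisions = 500L
    )$value
    expect_equal(mass, 1, tolerance = 1e-6)
    tL <- timeprior:::cal_min_bound(d)
    tU <- timeprior:::cal_max_bound(d)
    if (!is.na(tL)) {
      pL <- if (is.null(d$pL)) 0 else d$pL
      expect_close(cal_cdf(d, tL), pL, 1e-8)
    }
    if (!is.na(tU)) {
      expect_close(1 - cal_cdf(d, tU), d$pU, 1e-8)
    }
  }
})

test_that("hard bounds assign exactly zero density outside the bounds", {
  d <- cal_uniform(20, 80, hard = TRUE)
  expect_identical(cal_pdf(d, c(0, 10, 19.99, 80.01, 200)), rep(0, 5))
  expect_equal(cal_pdf(d, c(25, 50, 79)), rep(1 / 60, 3))
  oe <- cal_offset_exp(10, 0.1)
  expect_identical(cal_pdf(oe, c(0, 9.99)), c(0, 0))
})

test_that("closed-form cdfs agree with quadrature of the pdf", {
  ds <- list(
    cal_uniform(20, 80, 0.01, 0.05),
    cal_offset_exp(10, 0.1),
    cal_cauchy_min(20, 0.1, 0.1, 0.01)
  )
  for (d in ds) {
    for (t in c(5, 19, 21, 50, 79, 85, 200)) {
      num <- stats::integrate(function(u) cal_pdf(d, u), 0, t,
        rel.tol = 1e-12, subdivisions = 500L
      )$value
      expect_close(cal_cdf(d, t), num, 1e-8)
    }
  }
})

test_that("quantile function inverts the cdf across all branches", {
  ds <- list(
    cal_uniform(20, 80, 0.01, 0.05),
    cal_offset_exp(10, 0.1),
    cal_cauchy_min(20, 0.1, 0.1, 0.01)
  )
  q <- c(0.001, 0.005, 0.01, 0.2, 0.5, 0.9, 0.95, 0.99, 0.999)
  for (d in ds) {
    expect_equal(cal_cdf(d, cal_quantile(d, q)), q, tolerance = 1e-9)
  }
})

test_that("sampling is seed-reproducible and matches the cdf", {
  d <- cal_offset_exp(10, 0.1)
  set.seed(99)
  x1 <- cal_sample(d, 1000)
  set.seed(99)
  x2 <- cal_sample(d, 1000)
  expect_identical(x1, x2)

  set.seed(7)
  x <- cal_sample(d, 1e5)
  # exponential moments: mean 20, MC error 3 * 10 / sqrt(n)
  expect_close(mean(x), 20, 3 * 10 / sqrt(1e5))

  set.seed(8)
  u <- cal_sample(cal_uniform(0, 100, hard = TRUE), 1e5)
  expect_close(mean(u), 50, 3 * (100 / sqrt(12)) / sqrt(1e5))

  set.seed(9)
  for (d in list(
    cal_uniform(20, 80, 0.01, 0.05),
    cal_cauchy_min(20, 0.1, 0.1, 0.01)
  )) {
    x <- cal_sample(d, 2e4)
    ks <- suppressWarnings(stats::ks.test(x, function(q) cal_cdf(d, q)))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("truncated Cauchy mode sits at (1+p)tL and mass concentrates as p, c shrink", {
  d <- cal_cauchy_min(20, p = 0.1, c = 0.1, pL = 0.01)
  mode <- stats::optimize(function(t) -cal_pdf(d, t), c(10, 60))$minimum
  expect_close(mode, 22, 1e-4)
  # P(t < 1.5 tL) monotone decreasing in p and in c
  p_near <- function(p, c) cal_cdf(cal_cauchy_min(20, p, c, 0.01), 30)
  ps <- vapply(c(0.1, 0.2, 0.5, 1), p_near, 0, c = 0.1)
  expect_true(all(diff(ps) < 0))
  cs <- vapply(c(0.05, 0.1, 0.2, 0.5, 1), function(cc) p_near(0.1, cc), 0)
  expect_true(all(diff(cs) < 0))
})

test_that("offset-exponential mean conventions hold", {
  expect_equal(cal_mean(cal_offset_exp(10, theta = 1 / 10)), 20)
  expect_equal(cal_mean(cal_offset_exp(10)), 11) # default theta = 10/tL
  expect_equal(cal_mean(cal_cauchy_min(20)), Inf)
})

test_that("calibration strings parse with field defaults and round-trip", {
  d <- parse_calibration("B(23.5,34)")
  expect_s3_class(d, "cal_uniform")
  expect_equal(c(d$tL, d$tU, d$pL, d$pU), c(23.5, 34, 0.01, 0.05))
  expect_equal(format(d), "B(23.5,34,0.01,0.05)")

  d <- parse_calibration("L(45)")
  expect_s3_class(d, "cal_cauchy_min")
  expect_equal(c(d$tL, d$p, d$c, d$pL), c(45, 0.1, 0.1, 0.01))

  d <- parse_calibration("U(100)", hard = TRUE)
  expect_equal(c(d$tL, d$tU, d$pU), c(0, 100, 0))

  d <- parse_calibration("OE(10,0.1)")
  expect_equal(cal_mean(d), 20)

  expect_error(parse_calibration("X(1,2)"), "cannot parse")
  expect_error(parse_calibration("B(10)"), "2-4 arguments")
})

test_that("invalid parameters are rejected at construction", {
  expect_error(cal_uniform(80, 20), "tU")
  expect_error(cal_uniform(10, 100, pL = 0.5, pU = 0.6), "tail")
  expect_error(cal_offset_exp(10, theta = -1), "theta")
  expect_error(cal_cauchy_min(0), "tL")
  expect_error(cal_pdf(cal_offset_exp(10), -1), "ages")
})
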