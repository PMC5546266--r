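test_that("conditional normalizers take their simple exact values", {
  # st2: ordered pair of uniforms -> 1/2; st3: four ordered uniforms -> 1/4!
  expect_equal(analytic_normalizer("st2", "conditional")$value, 1 / 2,
    tolerance = 1e-9
  )
  expect_equal(analytic_normalizer("st3", "conditional")$value, 1 / 24,
    tolerance = 1e-9
  )
  r <- analytic_normalizer("st1", "conditional")
  expect_lt(r$abs_error, 1e-8)
})

test_that("marginal pdfs are proper densities with the stated support", {
  cfg <- five_species_config()
  grid <- seq(10, 100, length.out = 301)
  for (st in c("st1", "st2", "st3")) {
    for (co in c("conditional", "multiplicative")) {
      for (nd in c("t1", "t4")) {
        pdf <- analytic_marginal_pdf(st, co, nd, grid, cfg)
        expect_true(all(pdf >= 0))
        mass <- stats::integrate(
          function(t) analytic_marginal_pdf(st, co, nd, t, cfg),
          10, 100,
          rel.tol = 1e-8, subdivisions = 400L
        )$value
        expect_equal(mass, 1, tolerance = 1e-6)
        expect_equal(analytic_marginal_pdf(st, co, nd, c(5, 105), cfg), c(0, 0))
      }
    }
  }
})

test_that("quadrature marginals reproduce the printed closed forms", {
  cfg <- five_species_config()
  k1 <- analytic_normalizer("st1", "conditional", cfg)$value
  t <- c(15, 30, 55, 80, 95)
  # st1 conditional: f(t4) ~ theta e^{-theta(t4-tL)} (tU - t4) / (k1 tU)
  expect_equal(
    analytic_marginal_pdf("st1", "conditional", "t4", t, cfg),
    0.1 * exp(-0.1 * (t - 10)) * (100 - t) / (k1 * 100),
    tolerance = 1e-7
  )
  # st1 conditional: f(t1) ~ (1 - e^{-theta(t1-tL)}) / (k1 tU)
  expect_equal(
    analytic_marginal_pdf("st1", "conditional", "t1", t, cfg),
    (1 - exp(-0.1 * (t - 10))) / (k1 * 100),
    tolerance = 1e-7
  )
  # st2 conditional: linear order-statistic densities of a pair
  expect_equal(
    analytic_marginal_pdf("st2", "conditional", "t1", t, cfg),
    2 * (t - 10) / 90^2,
    tolerance = 1e-7
  )
  expect_equal(
    analytic_marginal_pdf("st2", "conditional", "t4", t, cfg),
    2 * (100 - t) / 90^2,
    tolerance = 1e-7
  )
  # st3 conditional: extreme order statistics of four uniforms
  expect_equal(
    analytic_marginal_pdf("st3", "conditional", "t1", t, cfg),
    st3_order_statistic_pdf(4, t, cfg),
    tolerance = 1e-7
  )
  expect_equal(
    analytic_marginal_pdf("st3", "conditional", "t4", t, cfg),
    st3_order_statistic_pdf(1, t, cfg),
    tolerance = 1e-7
  )
  # st2 multiplicative root marginal: (t1-tL)^3 / (k3 t1^3 (tU-tL)^2)
  k3 <- analytic_normalizer("st2", "multiplicative", cfg)$value
  expect_equal(
    analytic_marginal_pdf("st2", "multiplicative", "t1", t, cfg),
    (t - 10)^3 / (k3 * t^3 * 90^2),
    tolerance = 1e-7
  )
  # st3 multiplicative root marginal: 4! (t1-tL)^3 / (k4 t1^3 (tU-tL)^4)
  k4 <- analytic_normalizer("st3", "multiplicative", cfg)$value
  expect_equal(
    analytic_marginal_pdf("st3", "multiplicative", "t1", t, cfg),
    24 * (t - 10)^3 / (k4 * t^3 * 90^4),
    tolerance = 1e-7
  )
})

test_that("specific marginal values and means match derivation", {
  cfg <- five_species_config()
  # st3 conditional f(t1) at the right endpoint: 4/(tU - tL)
  expect_equal(
    analytic_marginal_pdf("st3", "conditional", "t1", 100 - 1e-9, cfg),
    4 / 90,
    tolerance = 1e-6
  )
  # st1 conditional f(t1) at 100
  k1 <- analytic_normalizer("st1", "conditional", cfg)$value
  expect_equal(
    analytic_marginal_pdf("st1", "conditional", "t1", 100 - 1e-9, cfg),
    (1 - exp(-9)) / (k1 * 100),
    tolerance = 1e-6
  )
  expect_close(analytic_marginal_mean("st2", "conditional", "t1", cfg), 70, 1e-4)
  expect_close(analytic_marginal_mean("st2", "conditional", "t4", cfg), 40, 1e-4)
  expect_close(analytic_marginal_mean("st3", "conditional", "t1", cfg), 82, 1e-4)
  expect_close(analytic_marginal_mean("st3", "conditional", "t4", cfg), 28, 1e-4)
})

test_that("order-statistic pdfs integrate to one with means tL + k(tU-tL)/5", {
  cfg <- five_species_config()
  for (k in 1:4) {
    mass <- stats::integrate(function(t) st3_order_statistic_pdf(k, t, cfg),
      10, 100,
      rel.tol = 1e-9
    )$value
    expect_equal(mass, 1, tolerance = 1e-7)
    mean_k <- stats::integrate(function(t) t * st3_order_statistic_pdf(k, t, cfg),
      10, 100,
      rel.tol = 1e-9
    )$value
    expect_equal(mean_k, 10 + k * 90 / 5, tolerance = 1e-6)
  }
})

test_that("tabulated cdfs are monotone and invert the pdf", {
  cfg <- five_species_config()
  cdf <- analytic_marginal_cdf("st1", "multiplicative", "t4", cfg)
  q <- cdf(seq(0, 110, by = 5))
  expect_true(all(diff(q) >= 0))
  expect_equal(cdf(10), 0)
  expect_equal(cdf(100), 1)
  mid_mass <- stats::integrate(
    function(t) analytic_marginal_pdf("st1", "multiplicative", "t4", t, cfg),
    10, 40,
    rel.tol = 1e-8
  )$value
  expect_equal(cdf(40), mid_mass, tolerance = 1e-4)
})

test_that("marginal grid tabulates all combinations for plotting", {
  g <- analytic_marginal_grid(n = 32)
  expect_equal(nrow(g), 3 * 2 * 2 * 32)
  expect_true(all(g$prior >= 0))
  expect_true(all(is.finite(g$calibration)))
})
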