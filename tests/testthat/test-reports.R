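test_that("without truncation pressure the effective prior equals the calibration", {
  tr <- read_timetree("((A,B),C);")
  rows <- tibble::tibble(taxon_a = "A", taxon_b = "C", min_age = NA, max_age = 100)
  cal <- calibration_set(tr, rows) # soft U(0,100), pU = 0.05
  ps <- sample_time_prior(tr, cal, "conditional",
    iterations = 30000, burnin = 2000, thin = 1, chains = 1, seed = 4
  )
  rep <- compare_prior_to_calibration(ps)
  expect_equal(nrow(rep), 1)
  expect_lt(rep$ks, 0.02)
  expect_gt(rep$overlap, 0.9)
  expect_lt(abs(rep$mean_shift), 1.5)
  # the bound-violation probability reduces to the soft tail mass
  expect_close(rep$p_violation, 0.05, 0.01)
})

test_that("five-species st3 truncation shifts the cherry by about -27", {
  tr <- fig1_tree()
  st3 <- propagate_calibrations(tr, fig1_calibrations(), "st3")
  ps <- sample_time_prior(tr, st3, "conditional",
    iterations = 20000, burnin = 3000, thin = 4, chains = 2, seed = 12
  )
  rep <- compare_prior_to_calibration(ps)
  # calibration mean 55 vs order-statistic mean 28
  shift <- rep$mean_shift[rep$node == 9]
  expect_close(shift, -27, 1)
  # hard bounds: no violations possible
  expect_equal(rep$p_violation, rep(0, 4))
  expect_true(all(rep$ks >= 0 & rep$ks <= 1))
  expect_true(all(rep$overlap >= 0 & rep$overlap <= 1))
})

test_that("nodes without samples are skipped with a notice", {
  tr <- fig1_tree()
  cal <- fig1_calibrations()
  ps <- sample_time_prior(tr, cal, "conditional",
    iterations = 500, burnin = 100, thin = 5, chains = 1, seed = 2
  )
  ps$draws <- ps$draws[, c("6", "7", "8"), drop = FALSE] # drop the cherry
  expect_message(rep <- compare_prior_to_calibration(ps), "skipping")
  expect_equal(rep$node, 6)
})

test_that("the pipeline produces per-combination summaries, reports and CSVs", {
  out_dir <- withr::local_tempdir()
  pt <- primate_tree()
  pc <- primate_calibrations()
  res <- run_prior_comparison(pt, pc,
    strategies = c("st1", "st2"), constructions = "conditional",
    iterations = 1200, burnin = 400, thin = 4, chains = 1, seed = 3,
    out_dir = out_dir
  )
  expect_setequal(
    unique(res$summary$strategy), c("st1", "st2")
  )
  # nine calibration-node rows per strategy in the truncation report
  expect_equal(nrow(res$truncation), 18)
  expect_equal(nrow(res$summary), 18) # all interior nodes are calibrated
  files <- list.files(out_dir)
  expect_setequal(files, c(
    "summary_st1_conditional.csv", "truncation_st1_conditional.csv",
    "summary_st2_conditional.csv", "truncation_st2_conditional.csv"
  ))
  # identical config + seed => byte-identical outputs
  out2 <- withr::local_tempdir()
  run_prior_comparison(pt, pc,
    strategies = c("st1", "st2"), constructions = "conditional",
    iterations = 1200, burnin = 400, thin = 4, chains = 1, seed = 3,
    out_dir = out2
  )
  for (f in files) {
    expect_identical(
      readBin(file.path(out_dir, f), "raw", 1e6),
      readBin(file.path(out2, f), "raw", 1e6)
    )
  }
})

test_that("autoplot returns a faceted comparison plot", {
  tr <- fig1_tree()
  st3 <- propagate_calibrations(tr, fig1_calibrations(), "st3")
  ps <- sample_time_prior(tr, st3, "conditional",
    iterations = 1000, burnin = 200, thin = 5, chains = 1, seed = 1
  )
  p <- ggplot2::autoplot(ps)
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
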