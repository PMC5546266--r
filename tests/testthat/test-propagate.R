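test_that("st1 leaves the calibration set unchanged", {
  tr <- fig1_tree()
  cal <- fig1_calibrations()
  expect_identical(
    propagate_calibrations(tr, cal, "st1")$label,
    cal$label[order(cal$node)]
  )
})

test_that("the five-species example propagates as described", {
  tr <- fig1_tree()
  cal <- fig1_calibrations() # min 10 on the cherry, max 100 on the root
  st2 <- propagate_calibrations(tr, cal, "st2")
  b2 <- calibration_bounds(st2)
  # both calibration nodes end up with joint bounds U(10, 100)
  expect_setequal(b2$node, c(6, 9))
  expect_equal(b2$min_age, c(10, 10))
  expect_equal(b2$max_age, c(100, 100))
  st3 <- propagate_calibrations(tr, cal, "st3")
  b3 <- calibration_bounds(st3)
  expect_equal(b3$node, 6:9)
  expect_equal(b3$min_age, rep(10, 4))
  expect_equal(b3$max_age, rep(100, 4))
  # hard input bounds stay hard through propagation
  expect_true(all(purrr::map_lgl(st3$density, "hard")))
})

test_that("st2 inherits the largest descendant minimum and smallest ancestral maximum", {
  pt <- primate_tree()
  pc <- primate_calibrations()
  st2 <- propagate_calibrations(pt, pc, "st2")
  b <- calibration_bounds(st2)
  # node 12 (min 55.6, no max) inherits the root maximum 130
  expect_equal(b$min_age[b$node == 12], 55.6)
  expect_equal(b$max_age[b$node == 12], 130)
  # node 17 inherits the closer Hominidae maximum 33.7, not the root's 130
  expect_equal(b$max_age[b$node == 17], 33.7)
  # joint-bound nodes keep their original (soft) densities
  expect_equal(st2$label[st2$node == 15], pc$label[pc$node == 15])
})

test_that("on the fully calibrated primate tree st2 and st3 coincide", {
  pt <- primate_tree()
  pc <- primate_calibrations()
  a <- propagate_calibrations(pt, pc, "st2")
  b <- propagate_calibrations(pt, pc, "st3")
  expect_equal(a$node, b$node)
  expect_equal(a$label, b$label)
})

test_that("st3 calibrates every interior node, with minimum 0 where no fossil sits below", {
  sim <- simulate_timetree(12, seed = 4)
  cal <- simulate_calibrations(sim, frac_calibrated = 0.4, seed = 4)
  st3 <- propagate_calibrations(sim$tree, cal, "st3")
  expect_setequal(st3$node, sim$tree$interior)
  b <- calibration_bounds(st3)
  expect_true(all(!is.na(b$max_age)))
  sc <- seedplant_calibrations()
  spt <- seedplant_tree()
  b3 <- calibration_bounds(propagate_calibrations(spt, sc, "st3"))
  expect_equal(nrow(b3), 47)
})

test_that("propagation is idempotent", {
  for (fix in list(
    list(tree = primate_tree(), cal = primate_calibrations()),
    list(tree = seedplant_tree(), cal = seedplant_calibrations())
  )) {
    for (stg in c("st2", "st3")) {
      once <- propagate_calibrations(fix$tree, fix$cal, stg)
      twice <- propagate_calibrations(fix$tree, once, stg)
      expect_equal(calibration_bounds(once), calibration_bounds(twice))
    }
  }
})

test_that("propagation failure modes are caught", {
  tr <- read_timetree("((A,B),(C,D));")
  # no maximum anywhere: st2 cannot propagate
  rows <- tibble::tibble(taxon_a = "A", taxon_b = "B", min_age = 10, max_age = NA)
  cal <- calibration_set(tr, rows)
  expect_error(propagate_calibrations(tr, cal, "st2"), "maximum bound on the root")
  # descendant minimum above the root maximum: infeasible
  rows2 <- tibble::tibble(
    taxon_a = c("A", "A"), taxon_b = c("D", "B"),
    min_age = c(NA, 50), max_age = c(40, NA)
  )
  cal2 <- calibration_set(tr, rows2)
  expect_error(propagate_calibrations(tr, cal2, "st2"), "infeasible")
})
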