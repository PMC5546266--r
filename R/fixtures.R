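#' Built-in fixtures: five-species ladder, primates, seed plants
#'
#' Three data sets ship with the package as plain-text files under
#' `inst/extdata`:
#'
#' * `fig1_tree()` -- the five-species ladder used throughout the analytic
#'   example.  Interior nodes are numbered 6 (root) to 9 (the youngest,
#'   `(A,B)` cherry); in the analytic example the root is "node 1" and the
#'   cherry "node 4".
#' * `primate_tree()` / `primate_table()` -- a 10-taxon primate tree
#'   (nine primates plus the treeshrew *Tupaia* as outgroup) and its nine
#'   fossil calibrations: five joint min/max bounds and four minimum-only
#'   bounds.  Every interior node is calibrated.
#' * `seedplant_tree()` / `seedplant_table()` -- a 48-taxon seed-plant tree
#'   with 15 fossil calibrations (seven joint, eight minimum-only).  The
#'   calibrated clades (angiosperms, eudicots, monocots, Proteales,
#'   conifers, Gnetales, ...) are defined by taxon pairs; the remaining
#'   resolution of this **synthetic** topology follows standard seed-plant
#'   relationships and is not itself data.
#'
#' Calibrated nodes are always resolved as the most recent common ancestor
#' of the defining taxon pair, never by node number.
#'
#' @param min_type,hard Passed to [calibration_set()]: how minimum-only
#'   bounds are encoded and whether bounds are hard.
#' @param theta Offset-exponential rate used when `min_type = "offset_exp"`.
#' @name fixtures
NULL

tp_extdata <- function(file) {
  path <- system.file("extdata", file, package = "timeprior")
  if (path == "") stop("missing package data file: ", file, call. = FALSE)
  path
}

#' @rdname fixtures
#' @export
fig1_tree <- function() read_timetree(tp_extdata("fig1_ladder.nwk"))

#' Calibrations of the five-species analytic example
#'
#' The ladder's youngest interior node ("node 4", id 9) carries a minimum
#' bound at `tL = 10` and the root ("node 1", id 6) a maximum bound at
#' `tU = 100`.  Defaults follow the analytic treatment: hard bounds and an
#' offset-exponential minimum with rate `theta = 1/tL`, so the minimum-bound
#' mean is `2 tL = 20`.
#'
#' @inheritParams fixtures
#' @param tL,tU Minimum and maximum bounds of the example.
#' @return A calibration set tibble with two rows.
#' @export
fig1_calibrations <- function(min_type = c("offset_exp", "cauchy"),
                              tL = 10, tU = 100, theta = 1 / tL,
                              hard = TRUE, p = 0.1, c = 0.1) {
  min_type <- match.arg(min_type)
  tree <- fig1_tree()
  rows <- tibble::tibble(
    clade = c("root", "node4"),
    taxon_a = c("A", "A"),
    taxon_b = c("E", "B"),
    min_age = c(NA, tL),
    max_age = c(tU, NA)
  )
  calibration_set(tree, rows,
    min_type = min_type, hard = hard,
    theta = theta, p = p, c = c
  )
}

#' @rdname fixtures
#' @export
primate_tree <- function() read_timetree(tp_extdata("primates.nwk"))

#' @rdname fixtures
#' @export
primate_table <- function() read_calibration_table(tp_extdata("primates_calib.tsv"))

#' @rdname fixtures
#' @export
primate_calibrations <- function(min_type = c("cauchy", "offset_exp"),
                                 hard = FALSE,
                                 theta = function(tL) 10 / tL) {
  calibration_set(primate_tree(), primate_table(),
    min_type = match.arg(min_type), hard = hard, theta = theta
  )
}

#' @rdname fixtures
#' @export
seedplant_tree <- function() read_timetree(tp_extdata("seedplants.nwk"))

#' @rdname fixtures
#' @export
seedplant_table <- function() read_calibration_table(tp_extdata("seedplants_calib.tsv"))

#' @rdname fixtures
#' @export
seedplant_calibrations <- function(min_type = c("cauchy", "offset_exp"),
                                   hard = FALSE,
                                   theta = function(tL) 10 / tL) {
  calibration_set(seedplant_tree(), seedplant_table(),
    min_type = match.arg(min_type), hard = hard, theta = theta
  )
}
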