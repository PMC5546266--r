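#' Simulate random calibrated time trees
#'
#' `simulate_timetree()` generates a random rooted binary ultrametric-age
#' tree by recursive splitting: each interior node receives an age equal to
#' a random fraction of its parent's age (tips at age 0), so the
#' ancestor-older-than-descendant partial order holds by construction.
#' `ladder = TRUE` produces the caterpillar (ladder) topology of the
#' five-species example.  Only the partial-order structure and age nesting
#' matter for testing the prior machinery, so no attempt is made to mimic a
#' particular macroevolutionary process.
#'
#' `simulate_calibrations()` places calibration densities on a configurable
#' fraction of interior nodes such that every bound straddles the true age
#' (`tL < age` for minima, `tL < age < tU` for joint bounds), which
#' guarantees a feasible age assignment exists.  The root always receives a
#' maximum bound.
#'
#' @param tips Number of tips (>= 3).
#' @param root_age True age of the root.
#' @param ladder Use the ladder topology instead of random splits?
#' @param seed Optional integer seed.
#' @return `simulate_timetree()`: a list with `tree` (a [timetree]
#'   object) and `ages` (true interior-node ages, named by node id).
#' @export
#' @examples
#' sim <- simulate_timetree(8, seed = 42)
#' cal <- simulate_calibrations(sim, seed = 42)
simulate_timetree <- function(tips, root_age = 100, ladder = FALSE, seed = NULL) {
  stopifnot(tips >= 3, root_age > 0)
  if (!is.null(seed)) set.seed(seed)
  labels <- if (tips <= 26) LETTERS[seq_len(tips)] else paste0("t", seq_len(tips))
  # newick with branch lengths encoding the node ages
  nwk_bl <- paste0(build2(labels, root_age, ladder), ";")
  phy <- ape::read.tree(text = nwk_bl)
  tree <- as_timetree(phy)
  depth <- ape::node.depth.edgelength(phy)
  ages <- max(depth) - depth[tree$interior]
  ages <- stats::setNames(round(ages, 10), tree$interior)
  list(tree = tree, ages = ages)
}

# recursive newick builder: each subtree string carries the branch length
# from its parent; ages decrease by a random factor per level
build2 <- function(labs, age, ladder, parent_age = NULL) {
  bl <- function(node_age) {
    if (is.null(parent_age)) "" else sprintf(":%.10g", parent_age - node_age)
  }
  if (length(labs) == 1L) {
    return(sprintf("%s%s", labs, bl(0)))
  }
  if (ladder) {
    left <- labs[-length(labs)]
    right <- labs[length(labs)]
    a_left <- if (length(left) == 1L) 0 else age * (length(labs) - 2) / (length(labs) - 1)
  } else {
    k <- sample(length(labs) - 1L, 1L)
    left <- labs[seq_len(k)]
    right <- labs[-seq_len(k)]
    a_left <- if (length(left) == 1L) 0 else age * stats::runif(1, 0.55, 0.9)
  }
  a_right <- if (length(right) == 1L) 0 else age * stats::runif(1, 0.55, 0.9)
  sprintf(
    "(%s,%s)%s",
    build2(left, a_left, ladder, age),
    build2(right, a_right, ladder, age),
    bl(age)
  )
}

#' @rdname simulate_timetree
#' @param sim A list as returned by `simulate_timetree()`.
#' @param frac_calibrated Fraction of interior nodes carrying a calibration
#'   (the root is always calibrated).
#' @param frac_joint Fraction of calibrations that are joint bounds rather
#'   than minimum-only.
#' @param min_type Encoding of minimum-only bounds (see [calibration_set()]).
#' @param hard Use hard bounds?
#' @return `simulate_calibrations()`: a calibration set tibble whose bounds
#'   straddle the true ages.
#' @export
simulate_calibrations <- function(sim, frac_calibrated = 0.5, frac_joint = 0.5,
                                  min_type = c("cauchy", "offset_exp"),
                                  hard = FALSE, seed = NULL) {
  stopifnot(frac_calibrated >= 0, frac_calibrated <= 1,
            frac_joint >= 0, frac_joint <= 1)
  min_type <- match.arg(min_type)
  if (!is.null(seed)) set.seed(seed)
  tree <- sim$tree
  ages <- sim$ages
  nodes <- tree$interior
  others <- setdiff(nodes, tree$root)
  n_extra <- max(0L, round(frac_calibrated * length(nodes)) - 1L)
  chosen <- c(tree$root, sample(others, min(n_extra, length(others))))
  pL <- if (hard) 0 else 0.01
  pU <- if (hard) 0 else 0.05

  density <- purrr::map(chosen, function(v) {
    tru <- ages[[as.character(v)]]
    joint <- stats::runif(1) < frac_joint
    tL <- tru * stats::runif(1, 0.55, 0.95)
    tU <- tru * stats::runif(1, 1.1, 1.8)
    if (v == tree$root) {
      # the root always receives a maximum
      if (joint) cal_uniform(tL, tU, pL, pU) else cal_uniform(0, tU, 0, pU)
    } else if (joint) {
      cal_uniform(tL, tU, pL, pU)
    } else {
      switch(min_type,
        cauchy = cal_cauchy_min(tL, pL = pL),
        offset_exp = cal_offset_exp(tL)
      )
    }
  })
  out <- tibble::tibble(
    node = as.integer(chosen),
    clade = NA_character_, taxon_a = NA_character_, taxon_b = NA_character_,
    density = density,
    label = purrr::map_chr(density, format)
  )
  dplyr::arrange(out, .data$node)
}
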