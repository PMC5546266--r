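#' Unnormalized log density of the time prior
#'
#' Two constructions combine user-specified calibration densities with the
#' branching-process (birth-death-sampling, BDS) model to form the joint
#' prior of all interior-node ages:
#'
#' * the **conditional construction** (MCMCTree):
#'   `f(t) = f_cal(t_C) * f_BDS(t_notC | t_C)` -- the truncated product of
#'   calibration densities times the BDS conditional density of the
#'   uncalibrated ages.  Under the uniform kernel the conditional factor is
#'   the reciprocal of the [order_polytope_volume()] with the calibration
#'   ages fixed.  The truncation normalizer is constant in the ages and is
#'   omitted (MCMC needs only unnormalized densities).
#' * the **multiplicative construction** (BEAST2/MrBayes):
#'   `f(t) ∝ f_cal(t_C) * f_BDS(t_nonroot | t_root)` -- the calibration
#'   densities multiplied with the *full* BDS density of all non-root ages,
#'   so the calibration-node ages appear twice.  This construction does not
#'   follow the rules of probability calculus; it is implemented as the
#'   heuristic it is.
#'
#' Only the uniform BDS kernel (`lambda = mu`, `rho -> 0`) is implemented:
#' conditioned on the root age `t1`, the `s - 2` non-root interior ages are
#' order statistics of i.i.d. `U(0, t1)` draws, with joint density
#' `(s-2)! / t1^(s-2)` on the feasible region.
#'
#' All evaluators return `-Inf` for age vectors violating the tree partial
#' order.
#'
#' @param tree A `timetree` with `s` tips.
#' @param ages Ages of the interior nodes: either a plain numeric vector in
#'   internal layout (entry `i` is the age of node `s + i`; root first) or a
#'   named vector keyed by node id.
#' @param calibs A (typically [propagated][propagate_calibrations])
#'   calibration set.
#' @return A single log-density value.
#' @name time_prior
NULL

#' @rdname time_prior
#' @export
bds_uniform_logdensity <- function(tree, ages) {
  tree <- as_timetree(tree)
  a <- ages_as_vector(tree, ages)
  if (!ages_feasible(tree, a)) return(-Inf)
  s <- tree$s
  lfactorial(s - 2) - (s - 2) * log(a[1])
}

#' @rdname time_prior
#' @export
conditional_logdensity <- function(tree, calibs, ages) {
  tree <- as_timetree(tree)
  a <- ages_as_vector(tree, ages)
  if (!(tree$root %in% calibs$node)) {
    stop("the conditional construction requires a calibrated root",
      call. = FALSE
    )
  }
  if (!ages_feasible(tree, a)) return(-Inf)
  cal_ages <- a[calibs$node - tree$s]
  lp <- sum(purrr::map2_dbl(calibs$density, cal_ages, function(d, t) {
    log(cal_pdf(d, t))
  }))
  if (!is.finite(lp)) return(-Inf)
  vol <- order_polytope_volume(
    tree,
    stats::setNames(cal_ages, calibs$node)
  )
  if (vol <= 0) return(-Inf)
  lp - log(vol)
}

#' @rdname time_prior
#' @export
multiplicative_logdensity <- function(tree, calibs, ages) {
  tree <- as_timetree(tree)
  a <- ages_as_vector(tree, ages)
  if (!ages_feasible(tree, a)) return(-Inf)
  cal_ages <- a[calibs$node - tree$s]
  lp <- sum(purrr::map2_dbl(calibs$density, cal_ages, function(d, t) {
    log(cal_pdf(d, t))
  }))
  if (!is.finite(lp)) return(-Inf)
  lp + lfactorial(tree$s - 2) - (tree$s - 2) * log(a[1])
}

#' Joint time-prior evaluator
#'
#' Returns a function of an age vector evaluating the unnormalized log
#' density of the chosen construction.
#'
#' @inheritParams time_prior
#' @param construction `"conditional"` or `"multiplicative"`.
#' @return A function `function(ages) -> log density`.
#' @export
#' @examples
#' tr <- fig1_tree()
#' cal <- propagate_calibrations(tr, fig1_calibrations(), "st2")
#' lp <- joint_log_prior(tr, cal, "conditional")
#' lp(c(90, 70, 50, 30))
joint_log_prior <- function(tree, calibs,
                            construction = c("conditional", "multiplicative")) {
  tree <- as_timetree(tree)
  construction <- match.arg(construction)
  force(calibs)
  if (construction == "conditional") {
    function(ages) conditional_logdensity(tree, calibs, ages)
  } else {
    function(ages) multiplicative_logdensity(tree, calibs, ages)
  }
}
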