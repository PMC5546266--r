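#' Propagate calibration bounds under strategies st1, st2, st3
#'
#' The three calibration strategies are different ways of turning a set of
#' user-specified fossil bounds into the node densities handed to the dating
#' machinery:
#'
#' * **st1** uses the calibrations exactly as given (identity).
#' * **st2** propagates bounds onto all *calibration* nodes so that each
#'   carries joint minimum and maximum bounds represented by a uniform
#'   density: a node lacking a minimum inherits the minimum of its oldest
#'   calibrated descendant (the largest descendant minimum), and a node
#'   lacking a maximum inherits the maximum of its youngest ancestor
#'   (the smallest ancestral maximum).
#' * **st3** does the same but onto *every* interior node; an interior node
#'   with no calibrated descendants inherits minimum 0 (no fossil evidence
#'   below it).
#'
#' Propagation is a single pass over the *original* bounds: inherited bounds
#' do not cascade.  Under st2/st3 the root must carry a maximum bound,
#' otherwise no maximum could propagate.  Minimum-only densities
#' (truncated Cauchy, offset-exponential) are converted to uniform joint
#' bounds, discarding their decay-shape parameters.
#'
#' @param tree A `timetree`.
#' @param calibs A calibration set tibble (see [calibration_set()]).
#' @param strategy `"st1"`, `"st2"` or `"st3"`.
#' @param pL,pU Soft tail probabilities for newly created uniform densities.
#' @param hard Hardness of newly created uniforms.  The default `NULL`
#'   inherits: new bounds are hard iff every original uniform density in
#'   `calibs` is hard.
#' @return A calibration set tibble.  Nodes added by st3 have `NA` clade
#'   and taxon columns.
#' @export
#' @examples
#' tr <- fig1_tree()
#' propagate_calibrations(tr, fig1_calibrations(), "st2")
propagate_calibrations <- function(tree, calibs,
                                   strategy = c("st1", "st2", "st3"),
                                   pL = 0.01, pU = 0.05, hard = NULL) {
  tree <- as_timetree(tree)
  strategy <- match.arg(strategy)
  if (strategy == "st1") {
    return(dplyr::arrange(calibs, .data$node))
  }
  if (is.null(hard)) {
    unis <- purrr::keep(calibs$density, ~ inherits(.x, "cal_uniform"))
    hard <- length(unis) > 0 && all(purrr::map_lgl(unis, "hard"))
  }
  if (hard) {
    pL <- 0
    pU <- 0
  }

  root_d <- calib_density(calibs, tree$root)
  if (is.null(root_d) || !has_max_bound(root_d)) {
    stop("strategies st2/st3 require a maximum bound on the root",
      call. = FALSE
    )
  }

  orig_min <- stats::setNames(
    purrr::map_dbl(calibs$density, cal_min_bound), calibs$node
  )
  orig_max <- stats::setNames(
    purrr::map_dbl(calibs$density, cal_max_bound), calibs$node
  )

  targets <- if (strategy == "st2") calibs$node else tree$interior

  rewrite <- function(node) {
    i <- match(node, calibs$node)
    d <- if (is.na(i)) NULL else calibs$density[[i]]
    tmin <- if (is.null(d)) NA_real_ else cal_min_bound(d)
    tmax <- if (is.null(d)) NA_real_ else cal_max_bound(d)
    if (!is.null(d) && !is.na(tmin) && !is.na(tmax)) {
      return(d) # already joint: keep as given
    }
    if (is.na(tmin)) {
      desc <- intersect(node_descendants(tree, node), calibs$node)
      mins <- orig_min[as.character(desc)]
      mins <- mins[!is.na(mins)]
      tmin <- if (length(mins) > 0) max(mins) else 0
    }
    if (is.na(tmax)) {
      anc <- intersect(node_ancestors(tree, node), calibs$node)
      maxs <- orig_max[as.character(anc)]
      maxs <- maxs[!is.na(maxs)]
      if (length(maxs) == 0) {
        stop("no ancestral maximum available for node ", node, call. = FALSE)
      }
      tmax <- min(maxs)
    }
    if (!(tmin < tmax)) {
      stop(
        "propagation produced infeasible bounds at node ", node,
        " (tL = ", tmin, " >= tU = ", tmax, ")",
        call. = FALSE
      )
    }
    cal_uniform(tmin, tmax, pL = if (tmin > 0) pL else 0, pU = pU, hard = hard)
  }

  density <- purrr::map(targets, rewrite)
  idx <- match(targets, calibs$node)
  out <- tibble::tibble(
    node = as.integer(targets),
    clade = ifelse(is.na(idx), NA_character_, calibs$clade[idx]),
    taxon_a = ifelse(is.na(idx), NA_character_, calibs$taxon_a[idx]),
    taxon_b = ifelse(is.na(idx), NA_character_, calibs$taxon_b[idx]),
    density = density,
    label = purrr::map_chr(density, format)
  )
  out <- dplyr::arrange(out, .data$node)
  check_bound_nesting(tree, out)
  out
}

# error if any calibrated descendant's minimum exceeds an ancestor's maximum
check_bound_nesting <- function(tree, calibs) {
  mins <- purrr::map_dbl(calibs$density, cal_min_bound)
  maxs <- purrr::map_dbl(calibs$density, cal_max_bound)
  for (i in seq_along(calibs$node)) {
    if (is.na(maxs[i])) next
    desc <- intersect(node_descendants(tree, calibs$node[i]), calibs$node)
    dm <- mins[match(desc, calibs$node)]
    dm <- dm[!is.na(dm)]
    if (length(dm) > 0 && max(dm) > maxs[i]) {
      stop(
        "infeasible calibrations: a descendant minimum (", max(dm),
        ") exceeds the maximum (", maxs[i], ") at node ", calibs$node[i],
        call. = FALSE
      )
    }
  }
  invisible(calibs)
}
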