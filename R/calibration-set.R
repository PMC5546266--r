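#' Build a calibration set from a fossil-calibration table
#'
#' A calibration set maps interior nodes of a [timetree][read_timetree] to
#' [calibration densities][calibration_densities].  It is represented as a
#' tibble with one row per calibrated node and columns
#' `node` (interior node id), `clade`, `taxon_a`, `taxon_b`,
#' `density` (list of `cal_density`) and `label` (compact string form).
#'
#' Each input row names a clade by a pair of taxa whose most recent common
#' ancestor is the calibrated node, plus `min_age` / `max_age` columns (`NA`
#' for an absent bound).  Rows with both bounds become soft/hard uniform
#' densities; minimum-only rows become truncated-Cauchy or
#' offset-exponential densities according to `min_type`; maximum-only rows
#' become `U(0, max_age)` densities.  A `calibration` column holding a
#' [parse_calibration()] string overrides the bound columns for that row.
#'
#' @param tree A `timetree`.
#' @param rows A data frame of calibration rows (see Details).
#' @param min_type How to encode minimum-only bounds: `"cauchy"`
#'   (truncated Cauchy, the MCMCTree convention) or `"offset_exp"`
#'   (offset-exponential, the BEAST2/MrBayes convention).
#' @param hard Use hard bounds (all tail probabilities zero)?
#' @param pL,pU Soft tail probabilities for uniform densities.
#' @param p,c Truncated-Cauchy spread parameters.
#' @param theta Offset-exponential rate; either a single rate or a function
#'   of the minimum age.  The default `function(tL) 10 / tL` gives mean
#'   `1.1 * tL`.
#' @return A tibble (see Details), ordered by node id.
#' @export
#' @examples
#' tr <- primate_tree()
#' calibration_set(tr, primate_table())
calibration_set <- function(tree, rows,
                            min_type = c("cauchy", "offset_exp"),
                            hard = FALSE,
                            pL = 0.01, pU = 0.05,
                            p = 0.1, c = 0.1,
                            theta = function(tL) 10 / tL) {
  tree <- as_timetree(tree)
  min_type <- match.arg(min_type)
  rows <- tibble::as_tibble(rows)
  stopifnot(all(c("taxon_a", "taxon_b", "min_age", "max_age") %in% names(rows)))
  if (!"clade" %in% names(rows)) rows$clade <- NA_character_
  if (!"calibration" %in% names(rows)) rows$calibration <- NA_character_
  if (is.numeric(theta)) {
    th <- theta
    theta <- function(tL) th
  }

  build_row <- function(taxon_a, taxon_b, min_age, max_age, calibration, ...) {
    if (!is.na(calibration) && nzchar(calibration)) {
      return(parse_calibration(calibration, hard = hard))
    }
    has_min <- !is.na(min_age) && min_age > 0
    has_max <- !is.na(max_age)
    if (has_min && has_max) {
      cal_uniform(min_age, max_age, pL = pL, pU = pU, hard = hard)
    } else if (has_min) {
      switch(min_type,
        cauchy     = cal_cauchy_min(min_age, p = p, c = c,
                                    pL = if (hard) 0 else pL),
        offset_exp = cal_offset_exp(min_age, theta = theta(min_age))
      )
    } else if (has_max) {
      cal_uniform(0, max_age, pL = 0, pU = if (hard) 0 else pU)
    } else {
      stop("calibration row with neither bound", call. = FALSE)
    }
  }

  node <- purrr::map2_int(rows$taxon_a, rows$taxon_b, function(a, b) {
    as.integer(mrca_node(tree, c(a, b)))
  })
  if (any(node <= tree$s)) {
    bad <- which(node <= tree$s)
    stop("calibration row ", bad[1], " resolves to a tip, not a clade",
      call. = FALSE
    )
  }
  if (anyDuplicated(node)) {
    dup <- node[duplicated(node)][1]
    stop("multiple calibration rows resolve to node ", dup, call. = FALSE)
  }
  density <- purrr::pmap(rows, build_row)
  out <- tibble::tibble(
    node = node,
    clade = rows$clade,
    taxon_a = rows$taxon_a,
    taxon_b = rows$taxon_b,
    density = density,
    label = purrr::map_chr(density, format)
  )
  dplyr::arrange(out, .data$node)
}

#' Read a calibration table from a TSV file
#'
#' Expects tab-separated columns `clade`, `taxon_a`, `taxon_b`, `min_age`,
#' `max_age` (empty cells for absent bounds) and optionally `calibration`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of raw calibration rows (pass to [calibration_set()]).
#' @export
read_calibration_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  tibble::as_tibble(df)
}

# density for a node id, or NULL
calib_density <- function(calibs, node) {
  i <- match(node, calibs$node)
  if (is.na(i)) NULL else calibs$density[[i]]
}

# tidy dump of a calibration set for audit (bounds as numeric columns)
#' Summarise a calibration set as plain bounds
#'
#' @param calibs A calibration set tibble.
#' @return A tibble with `node`, `label`, `min_age`, `max_age` columns
#'   (`NA` where a bound is absent).
#' @export
calibration_bounds <- function(calibs) {
  tibble::tibble(
    node = calibs$node,
    label = calibs$label,
    min_age = purrr::map_dbl(calibs$density, cal_min_bound),
    max_age = purrr::map_dbl(calibs$density, cal_max_bound)
  )
}
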