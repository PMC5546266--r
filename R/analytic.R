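#' Analytic results for the five-species example
#'
#' For the five-species ladder with a minimum bound `tL` on the youngest
#' interior node ("node 4") and a maximum bound `tU` on the root
#' ("node 1"), every strategy x construction combination has a tractable
#' time prior.  After integrating out the two middle ages (`t2`, `t3`), all
#' six joint densities reduce to a bivariate function of `(t1, t4)` on
#' `tL < t4 < t1 < tU`:
#'
#' * st1 conditional: `(1/tU) * theta * exp(-theta (t4 - tL))`
#' * st2 conditional: `1 / (tU - tL)^2`
#' * st3 conditional: `(t1 - t4)^2 / (2 (tU - tL)^4)` -- all four ages are
#'   i.i.d. uniforms constrained to be ordered, so `t1` and `t4` are the
#'   extreme order statistics
#' * multiplicative variants: the corresponding calibration product times
#'   the uniform-kernel factor `3!/t1^3`, times the middle-age volume
#'   `(t1 - t4)^2 / 2`
#'
#' `analytic_normalizer()` integrates the reduced joint by adaptive nested
#' quadrature; for the multiplicative construction this reproduces the
#' constants `k2 = 0.0174371` (st1), `k3 = 0.00530524` (st2) and
#' `k4 = 0.000015719` (st3), and for st1 conditional the truncation
#' normalizer `k1 = 0.80001`.  `analytic_marginal_pdf()` and
#' `analytic_marginal_cdf()` give the effective marginal prior of `t1` or
#' `t4`, computed by quadrature of the reduced joint (the printed closed
#' forms are recovered as cross-checks in the test suite).
#'
#' @param tL,tU Minimum and maximum bound of the example (default 10, 100).
#' @param theta Rate of the st1 offset-exponential minimum (default `1/tL`,
#'   so its mean is `2 tL`).
#' @return `five_species_config()` returns a config list; see the
#'   individual functions for their values.
#' @name analytic_oracle
NULL

#' @rdname analytic_oracle
#' @export
five_species_config <- function(tL = 10, tU = 100, theta = 1 / tL) {
  stopifnot(tL >= 0, tU > tL, theta > 0)
  list(tL = tL, tU = tU, theta = theta)
}

# reduced joint over (t1, t4), *unnormalized*; vectorized in both arguments
reduced_joint <- function(strategy, construction, config) {
  tL <- config$tL
  tU <- config$tU
  th <- config$theta
  cal2 <- switch(strategy,
    st1 = function(t1, t4) (1 / tU) * th * exp(-th * (t4 - tL)),
    st2 = function(t1, t4) rep(1 / (tU - tL)^2, length(t1)),
    st3 = function(t1, t4) rep(1 / (tU - tL)^4, length(t1)) # raw product; the
    # two middle uniforms are integrated out as the (t1-t4)^2/2 volume below
  )
  # middle-age factor from integrating out t2, t3:
  #  conditional: the uniform-kernel conditional 2/(t1-t4)^2 cancels the
  #    (t1-t4)^2/2 volume for st1/st2; under st3 the kernel plays no role and
  #    only the middle-age volume remains.
  #  multiplicative: the kernel factor 3!/t1^3 multiplies in, and the printed
  #    st3 normalizer is defined over the density *including* the 4!
  #    order-statistics factor.
  if (construction == "conditional") {
    if (strategy == "st3") {
      function(t1, t4) cal2(t1, t4) * (t1 - t4)^2 / 2
    } else {
      cal2
    }
  } else {
    ord <- if (strategy == "st3") 24 else 1
    function(t1, t4) ord * cal2(t1, t4) * (t1 - t4)^2 / 2 * 6 / t1^3
  }
}

#' @rdname analytic_oracle
#' @param strategy `"st1"`, `"st2"` or `"st3"`.
#' @param construction `"conditional"` or `"multiplicative"`.
#' @param config A [five_species_config()] list.
#' @param rel_tol Requested relative quadrature accuracy.
#' @return `analytic_normalizer()`: list with `value` (the integral of the
#'   unnormalized reduced joint over `tL < t4 < t1 < tU`) and `abs_error`
#'   (quadrature error estimate).
#' @export
#' @examples
#' analytic_normalizer("st1", "conditional")$value # ~0.80001
analytic_normalizer <- function(strategy = c("st1", "st2", "st3"),
                                construction = c("conditional", "multiplicative"),
                                config = five_species_config(),
                                rel_tol = 1e-10) {
  strategy <- match.arg(strategy)
  construction <- match.arg(construction)
  j2 <- reduced_joint(strategy, construction, config)
  inner <- function(t1) {
    vapply(t1, function(u) {
      stats::integrate(function(t4) j2(rep(u, length(t4)), t4),
        lower = config$tL, upper = u,
        rel.tol = rel_tol, subdivisions = 400L
      )$value
    }, 0)
  }
  res <- stats::integrate(inner,
    lower = config$tL, upper = config$tU,
    rel.tol = rel_tol, subdivisions = 400L
  )
  if (res$message != "OK") {
    stop("quadrature did not converge: ", res$message, call. = FALSE)
  }
  list(value = res$value, abs_error = res$abs.error)
}

#' @rdname analytic_oracle
#' @param node `"t1"` (root age) or `"t4"` (youngest interior age).
#' @param t Vector of ages at which to evaluate.
#' @return `analytic_marginal_pdf()`: the effective-prior marginal density
#'   of the chosen node at `t` (vectorized; 0 outside `(tL, tU)`).
#' @export
analytic_marginal_pdf <- function(strategy, construction, node = c("t1", "t4"),
                                  t, config = five_species_config()) {
  node <- match.arg(node)
  j2 <- reduced_joint(strategy, construction, config)
  k <- analytic_normalizer(strategy, construction, config)$value
  tL <- config$tL
  tU <- config$tU
  out <- numeric(length(t))
  inside <- t > tL & t < tU
  f1 <- function(u) {
    stats::integrate(function(t4) j2(rep(u, length(t4)), t4),
      lower = tL, upper = u, rel.tol = 1e-10, subdivisions = 400L
    )$value
  }
  f4 <- function(u) {
    stats::integrate(function(t1) j2(t1, rep(u, length(t1))),
      lower = u, upper = tU, rel.tol = 1e-10, subdivisions = 400L
    )$value
  }
  out[inside] <- vapply(t[inside], if (node == "t1") f1 else f4, 0) / k
  out
}

#' @rdname analytic_oracle
#' @param n_grid Grid size used to tabulate the cdf.
#' @return `analytic_marginal_cdf()`: a vectorized cdf function built by
#'   cumulative quadrature on a fine grid (monotone spline interpolation).
#' @export
analytic_marginal_cdf <- function(strategy, construction, node = c("t1", "t4"),
                                  config = five_species_config(),
                                  n_grid = 2048L) {
  node <- match.arg(node)
  grid <- seq(config$tL, config$tU, length.out = n_grid)
  pdf <- analytic_marginal_pdf(strategy, construction, node, grid, config)
  dx <- diff(grid)
  cum <- c(0, cumsum((pdf[-1] + pdf[-n_grid]) / 2 * dx))
  cum <- cum / cum[n_grid] # renormalize away residual quadrature error
  sf <- stats::splinefun(grid, cum, method = "hyman")
  function(q) {
    pmin(1, pmax(0, ifelse(q <= config$tL, 0, ifelse(q >= config$tU, 1, sf(q)))))
  }
}

#' @rdname analytic_oracle
#' @return `analytic_marginal_mean()`: the mean of the effective marginal
#'   prior, by quadrature.
#' @export
analytic_marginal_mean <- function(strategy, construction, node = c("t1", "t4"),
                                   config = five_species_config()) {
  node <- match.arg(node)
  stats::integrate(
    function(t) t * analytic_marginal_pdf(strategy, construction, node, t, config),
    lower = config$tL, upper = config$tU,
    rel.tol = 1e-8, subdivisions = 400L
  )$value
}

#' Order-statistic marginals of the all-nodes-uniform prior
#'
#' Under strategy st3 with the conditional construction the four interior
#' ages are i.i.d. `U(tL, tU)` constrained to be ordered, so the k-th
#' youngest age is the k-th order statistic of four uniforms, a scaled
#' Beta(k, 5 - k) density with mean `tL + k (tU - tL) / 5`.
#'
#' @param k Rank (1 = youngest, `n` = oldest/root).
#' @param t Vector of ages.
#' @param config A [five_species_config()].
#' @param n Number of interior nodes (default 4).
#' @return Density values at `t`.
#' @export
st3_order_statistic_pdf <- function(k, t, config = five_species_config(), n = 4L) {
  stopifnot(k >= 1, k <= n)
  x <- (t - config$tL) / (config$tU - config$tL)
  out <- numeric(length(t))
  inside <- x > 0 & x < 1
  out[inside] <- stats::dbeta(x[inside], k, n - k + 1) / (config$tU - config$tL)
  out
}

#' Tabulate calibration and effective-prior curves for the ladder example
#'
#' Evaluates, for each requested strategy and construction, the
#' user-specified calibration density and the effective marginal prior of
#' the two calibrated nodes on a regular age grid -- the data behind the
#' classic six-panel comparison figure for this example.
#'
#' @param strategies,constructions Character vectors.
#' @param config A [five_species_config()].
#' @param n Number of grid points.
#' @return A tibble with columns `strategy`, `construction`, `node`, `t`,
#'   `calibration` (user-specified density; `NA` for nodes whose st1
#'   density is the one propagated) and `prior` (effective marginal).
#' @export
analytic_marginal_grid <- function(strategies = c("st1", "st2", "st3"),
                                   constructions = c("conditional", "multiplicative"),
                                   config = five_species_config(),
                                   n = 256L) {
  grid <- seq(config$tL + 1e-9, config$tU - 1e-9, length.out = n)
  combos <- tidyr::expand_grid(
    strategy = strategies, construction = constructions, node = c("t1", "t4")
  )
  purrr::pmap_dfr(combos, function(strategy, construction, node) {
    cal <- if (strategy == "st1") {
      if (node == "t1") {
        rep(1 / config$tU, n)
      } else {
        config$theta * exp(-config$theta * (grid - config$tL))
      }
    } else {
      rep(1 / (config$tU - config$tL), n)
    }
    prior <- analytic_marginal_pdf(strategy, construction, node, grid, config)
    tibble::tibble(
      strategy = strategy, construction = construction, node = node,
      t = grid, calibration = cal, prior = prior
    )
  })
}
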