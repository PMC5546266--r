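#' Calibration densities for fossil-calibrated node ages
#'
#' Bayesian clock-dating programs encode fossil evidence about a node age as
#' one of three families of calibration density:
#'
#' * **joint bounds** `cal_uniform(tL, tU)` -- a uniform density on
#'   `(tL, tU)`, optionally with *soft* tails that place a small probability
#'   `pL` below the minimum and `pU` above the maximum.  A maximum-only bound
#'   is the special case `tL = 0, pL = 0`.
#' * **offset-exponential minimum** `cal_offset_exp(tL, theta)` -- the age is
#'   `tL + y` with `y ~ Exp(theta)`, so the mean is `tL + 1/theta`.
#' * **truncated-Cauchy minimum** `cal_cauchy_min(tL, p, c, pL)` -- a
#'   heavy-tailed minimum bound whose mode sits at `(1 + p) * tL` and whose
#'   scale is `c * tL`, with soft left-tail probability `pL`.
#'
#' Soft tails are implemented as a power density `f(t) = f(tL) (t/tL)^(a-1)`
#' on `(0, tL)` with `a` chosen so the tail is continuous at `tL` and carries
#' mass exactly `pL`, and (for uniforms) an exponential right tail matched for
#' continuity at `tU` with mass exactly `pU`.  Hard bounds set `pL = pU = 0`
#' and assign zero density outside the bounds.
#'
#' Ages are in unspecified "time units" (typically Ma); densities are per
#' time unit.
#'
#' @param tL Minimum age (>= 0; > 0 when a soft left tail is requested).
#' @param tU Maximum age (> `tL`).
#' @param pL Probability that the true age violates the minimum bound.
#' @param pU Probability that the true age violates the maximum bound.
#' @param hard If `TRUE`, force `pL = pU = 0` (hard bounds).
#' @param theta Rate of the exponential part (1/time units).
#' @param p Mode-offset factor of the truncated Cauchy (dimensionless).
#' @param c Scale factor of the truncated Cauchy (dimensionless).
#'
#' @return An object of class `cal_density` (subclass `cal_uniform`,
#'   `cal_offset_exp` or `cal_cauchy_min`).
#' @name calibration_densities
#' @examples
#' b <- cal_uniform(20, 80, pL = 0.01, pU = 0.05)
#' cal_cdf(b, 20)       # 0.01: mass below the soft minimum
#' 1 - cal_cdf(b, 80)   # 0.05: mass above the soft maximum
#' cal_mean(cal_offset_exp(10, theta = 0.1))  # 20
NULL

new_cal_density <- function(subclass, ...) {
  structure(list(...), class = c(subclass, "cal_density"))
}

#' @rdname calibration_densities
#' @export
cal_uniform <- function(tL, tU, pL = 0.01, pU = 0.05, hard = FALSE) {
  if (hard) {
    pL <- 0
    pU <- 0
  }
  stopifnot(is.numeric(tL), is.numeric(tU), length(tL) == 1L, length(tU) == 1L)
  if (!(tL >= 0)) stop("`tL` must be >= 0", call. = FALSE)
  if (!(tU > tL)) stop("`tU` must be > `tL`", call. = FALSE)
  if (pL < 0 || pL >= 1 || pU < 0 || pU >= 1 || pL + pU >= 1) {
    stop("tail probabilities must lie in [0, 1) with pL + pU < 1", call. = FALSE)
  }
  if (pL > 0 && tL <= 0) stop("a soft left tail requires `tL` > 0", call. = FALSE)
  h <- (1 - pL - pU) / (tU - tL)                 # body height
  d <- new_cal_density("cal_uniform",
    tL = tL, tU = tU, pL = pL, pU = pU, hard = (pL == 0 && pU == 0), h = h
  )
  d$alphaL <- if (pL > 0) h * tL / pL else NA_real_   # left power-tail shape
  d$betaU  <- if (pU > 0) h / pU else NA_real_        # right exp-tail rate
  d
}

#' @rdname calibration_densities
#' @export
cal_offset_exp <- function(tL, theta = 10 / tL) {
  stopifnot(is.numeric(tL), is.numeric(theta), length(tL) == 1L, length(theta) == 1L)
  if (!(tL >= 0)) stop("`tL` must be >= 0", call. = FALSE)
  if (!(theta > 0)) stop("`theta` must be > 0", call. = FALSE)
  new_cal_density("cal_offset_exp", tL = tL, theta = theta)
}

#' @rdname calibration_densities
#' @export
cal_cauchy_min <- function(tL, p = 0.1, c = 0.1, pL = 0.01) {
  stopifnot(is.numeric(tL), length(tL) == 1L)
  if (!(tL > 0)) stop("`tL` must be > 0 for a Cauchy minimum bound", call. = FALSE)
  if (!(p > 0) || !(c > 0)) stop("`p` and `c` must be > 0", call. = FALSE)
  if (pL < 0 || pL >= 1) stop("`pL` must lie in [0, 1)", call. = FALSE)
  A <- (1 + p) * tL        # mode
  s <- c * tL              # scale
  mass <- 1 - stats::pcauchy(tL, A, s)     # Cauchy mass on (tL, Inf)
  d <- new_cal_density("cal_cauchy_min",
    tL = tL, p = p, c = c, pL = pL, A = A, scale = s, body_mass = mass
  )
  d$f_tL <- (1 - pL) * stats::dcauchy(tL, A, s) / mass  # body density at tL
  d$alphaL <- if (pL > 0) d$f_tL * tL / pL else NA_real_
  d
}

#' Evaluate, integrate, invert and sample calibration densities
#'
#' `cal_pdf()` and `cal_cdf()` evaluate the probability density and
#' distribution function of a calibration density at ages `t`;
#' `cal_quantile()` inverts the cdf; `cal_sample()` draws `n` ages by
#' inversion (reproducible under [set.seed()]).  `cal_mean()`,
#' `cal_median()` and `cal_max_density()` return the mean (`Inf` for the
#' truncated Cauchy), median, and the supremum of the density (used as a
#' rejection envelope).
#'
#' @param d A `cal_density` object.
#' @param t Vector of ages (>= 0).
#' @param q Vector of probabilities in `[0, 1]`.
#' @param n Number of draws.
#' @return Numeric vector.
#' @export
cal_pdf <- function(d, t) {
  if (any(t < 0)) stop("ages must be >= 0", call. = FALSE)
  UseMethod("cal_pdf")
}

#' @rdname cal_pdf
#' @export
cal_cdf <- function(d, t) {
  if (any(t < 0)) stop("ages must be >= 0", call. = FALSE)
  UseMethod("cal_cdf")
}

#' @rdname cal_pdf
#' @export
cal_quantile <- function(d, q) {
  if (any(q < 0 | q > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  UseMethod("cal_quantile")
}

#' @rdname cal_pdf
#' @export
cal_sample <- function(d, n) {
  stopifnot(n >= 1)
  cal_quantile(d, stats::runif(n))
}

#' @rdname cal_pdf
#' @export
cal_mean <- function(d) UseMethod("cal_mean")

#' @rdname cal_pdf
#' @export
cal_median <- function(d) cal_quantile(d, 0.5)

#' @rdname cal_pdf
#' @export
cal_max_density <- function(d) UseMethod("cal_max_density")

## ---- soft/hard uniform ----------------------------------------------------

#' @export
cal_pdf.cal_uniform <- function(d, t) {
  out <- numeric(length(t))
  body <- t >= d$tL & t <= d$tU
  out[body] <- d$h
  if (d$pL > 0) {
    lo <- t < d$tL
    out[lo] <- d$h * (t[lo] / d$tL)^(d$alphaL - 1)
  }
  if (d$pU > 0) {
    hi <- t > d$tU
    out[hi] <- d$h * exp(-d$betaU * (t[hi] - d$tU))
  }
  out
}

#' @export
cal_cdf.cal_uniform <- function(d, t) {
  out <- numeric(length(t))
  lo <- t < d$tL
  body <- t >= d$tL & t <= d$tU
  hi <- t > d$tU
  out[lo] <- if (d$pL > 0) d$pL * (t[lo] / d$tL)^d$alphaL else 0
  out[body] <- d$pL + d$h * (t[body] - d$tL)
  out[hi] <- 1 - if (d$pU > 0) d$pU * exp(-d$betaU * (t[hi] - d$tU)) else 0
  out
}

#' @export
cal_quantile.cal_uniform <- function(d, q) {
  out <- numeric(length(q))
  lo <- q < d$pL
  hi <- q > 1 - d$pU
  body <- !lo & !hi
  if (any(lo)) out[lo] <- d$tL * (q[lo] / d$pL)^(1 / d$alphaL)
  out[body] <- d$tL + (q[body] - d$pL) / d$h
  if (any(hi)) out[hi] <- d$tU - log((1 - q[hi]) / d$pU) / d$betaU
  out
}

#' @export
cal_mean.cal_uniform <- function(d) {
  m <- d$h * (d$tU^2 - d$tL^2) / 2
  if (d$pL > 0) m <- m + d$pL * d$tL * d$alphaL / (d$alphaL + 1)
  if (d$pU > 0) m <- m + d$pU * (d$tU + 1 / d$betaU)
  m
}

#' @export
cal_max_density.cal_uniform <- function(d) d$h

## ---- offset exponential ----------------------------------------------------

#' @export
cal_pdf.cal_offset_exp <- function(d, t) {
  ifelse(t >= d$tL, d$theta * exp(-d$theta * (t - d$tL)), 0)
}

#' @export
cal_cdf.cal_offset_exp <- function(d, t) {
  ifelse(t >= d$tL, 1 - exp(-d$theta * (t - d$tL)), 0)
}

#' @export
cal_quantile.cal_offset_exp <- function(d, q) {
  d$tL + stats::qexp(q, rate = d$theta)
}

#' @export
cal_mean.cal_offset_exp <- function(d) d$tL + 1 / d$theta

#' @export
cal_max_density.cal_offset_exp <- function(d) d$theta

## ---- truncated Cauchy minimum ----------------------------------------------

#' @export
cal_pdf.cal_cauchy_min <- function(d, t) {
  out <- numeric(length(t))
  body <- t >= d$tL
  out[body] <- (1 - d$pL) * stats::dcauchy(t[body], d$A, d$scale) / d$body_mass
  if (d$pL > 0) {
    lo <- t < d$tL
    out[lo] <- d$f_tL * (t[lo] / d$tL)^(d$alphaL - 1)
  }
  out
}

#' @export
cal_cdf.cal_cauchy_min <- function(d, t) {
  out <- numeric(length(t))
  body <- t >= d$tL
  G_tL <- stats::pcauchy(d$tL, d$A, d$scale)
  out[body] <- d$pL +
    (1 - d$pL) * (stats::pcauchy(t[body], d$A, d$scale) - G_tL) / d$body_mass
  if (d$pL > 0) {
    lo <- t < d$tL
    out[lo] <- d$pL * (t[lo] / d$tL)^d$alphaL
  }
  out
}

#' @export
cal_quantile.cal_cauchy_min <- function(d, q) {
  out <- numeric(length(q))
  lo <- q < d$pL
  if (any(lo)) out[lo] <- d$tL * (q[lo] / d$pL)^(1 / d$alphaL)
  body <- !lo
  G_tL <- stats::pcauchy(d$tL, d$A, d$scale)
  frac <- (q[body] - d$pL) / (1 - d$pL)
  out[body] <- stats::qcauchy(G_tL + frac * d$body_mass, d$A, d$scale)
  out
}

#' @export
cal_mean.cal_cauchy_min <- function(d) Inf

#' @export
cal_max_density.cal_cauchy_min <- function(d) {
  (1 - d$pL) * stats::dcauchy(d$A, d$A, d$scale) / d$body_mass
}

## ---- printing and string form ----------------------------------------------

#' @export
format.cal_density <- function(x, ...) {
  switch(class(x)[1],
    cal_uniform = if (x$tL == 0) {
      sprintf("U(%g,%g)", x$tU, x$pU)
    } else {
      sprintf("B(%g,%g,%g,%g)", x$tL, x$tU, x$pL, x$pU)
    },
    cal_offset_exp = sprintf("OE(%g,%g)", x$tL, x$theta),
    cal_cauchy_min = sprintf("L(%g,%g,%g,%g)", x$tL, x$p, x$c, x$pL)
  )
}

#' @export
print.cal_density <- function(x, ...) {
  cat("<calibration density> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Parse a calibration string
#'
#' Accepts the compact syntax used in tree labels and calibration tables:
#' `L(tL,p,c,pL)` truncated-Cauchy minimum bound, `U(tU,pU)` maximum bound,
#' `B(tL,tU,pL,pU)` joint bounds, `OE(tL,theta)` offset-exponential minimum.
#' Omitted tail probabilities default to `pL = 0.01`, `pU = 0.05`
#' (or 0 when `hard = TRUE`); omitted Cauchy parameters default to
#' `p = 0.1`, `c = 0.1`.
#'
#' @param x A calibration string.
#' @param hard If `TRUE`, zero all tail probabilities.
#' @return A `cal_density` object.
#' @export
#' @examples
#' parse_calibration("B(23.5,34)")
#' parse_calibration("L(45)")
parse_calibration <- function(x, hard = FALSE) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^\\s*(L|U|B|OE)\\(([^)]*)\\)\\s*$", x))[[1]]
  if (length(m) == 0L) {
    stop("cannot parse calibration string: ", sQuote(x), call. = FALSE)
  }
  kind <- m[2]
  args <- as.numeric(strsplit(m[3], ",")[[1]])
  if (anyNA(args)) stop("non-numeric argument in ", sQuote(x), call. = FALSE)
  nargs <- length(args)
  switch(kind,
    L = {
      if (nargs < 1 || nargs > 4) stop("L() takes 1-4 arguments", call. = FALSE)
      cal_cauchy_min(args[1],
        p  = if (nargs >= 2) args[2] else 0.1,
        c  = if (nargs >= 3) args[3] else 0.1,
        pL = if (hard) 0 else if (nargs >= 4) args[4] else 0.01
      )
    },
    U = {
      if (nargs < 1 || nargs > 2) stop("U() takes 1-2 arguments", call. = FALSE)
      cal_uniform(0, args[1],
        pL = 0,
        pU = if (hard) 0 else if (nargs >= 2) args[2] else 0.05
      )
    },
    B = {
      if (nargs < 2 || nargs > 4) stop("B() takes 2-4 arguments", call. = FALSE)
      cal_uniform(args[1], args[2],
        pL = if (hard) 0 else if (nargs >= 3) args[3] else 0.01,
        pU = if (hard) 0 else if (nargs >= 4) args[4] else 0.05
      )
    },
    OE = {
      if (nargs < 1 || nargs > 2) stop("OE() takes 1-2 arguments", call. = FALSE)
      cal_offset_exp(args[1], theta = if (nargs >= 2) args[2] else 10 / args[1])
    }
  )
}

# TRUE if the density encodes a usable minimum bound (tL > 0 or min-only type)
has_min_bound <- function(d) {
  if (inherits(d, "cal_uniform")) d$tL > 0 else TRUE
}

# TRUE if the density encodes a maximum bound
has_max_bound <- function(d) inherits(d, "cal_uniform")

# the minimum bound carried by a density (NA if none)
cal_min_bound <- function(d) {
  if (inherits(d, "cal_uniform")) {
    if (d$tL > 0) d$tL else NA_real_
  } else {
    d$tL
  }
}

# the maximum bound carried by a density (NA if none)
cal_max_bound <- function(d) {
  if (inherits(d, "cal_uniform")) d$tU else NA_real_
}
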