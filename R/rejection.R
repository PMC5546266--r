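#' Exact rejection sampling of the time prior
#'
#' An independent reference sampler for small trees, used to cross-validate
#' the MCMC sampler.  For the **conditional** construction it draws the
#' calibration-node ages from their user-specified densities and accepts
#' iff they respect the tree partial order (the acceptance rate *is* the
#' truncation normalizer), then fills in the uncalibrated ages uniformly on
#' the order-polytope section by per-component rejection.  For the
#' **multiplicative** construction it draws the root age from its
#' calibration density, all other interior ages i.i.d. `U(0, t_root)` (the
#' uniform birth-death-sampling kernel), and accepts feasible draws with
#' probability proportional to the product of the non-root calibration
#' densities (envelope rejection with the density suprema as envelopes).
#' Both schemes sample the target exactly.
#'
#' @inheritParams sample_time_prior
#' @param n Number of samples required.
#' @param min_acceptance Guard: error out if the estimated acceptance rate
#'   falls below this (suggesting MCMC instead).
#' @return A `prior_samples` object (single chain); the achieved
#'   stage-one acceptance rate is stored in `accept_rate`.
#' @export
#' @examples
#' tr <- fig1_tree()
#' cal <- fig1_calibrations()
#' ps <- rejection_sample_prior(tr, cal, "conditional", n = 1000, seed = 1)
#' ps$accept_rate # ~0.80, the truncation normalizer of this example
rejection_sample_prior <- function(tree, calibs,
                                   construction = c("conditional", "multiplicative"),
                                   n = 10000L, seed = NULL,
                                   min_acceptance = 1e-4) {
  tree <- as_timetree(tree)
  construction <- match.arg(construction)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  s <- tree$s
  n_int <- tree$n_interior
  if (!(tree$root %in% calibs$node)) {
    stop("rejection sampling requires a calibrated root", call. = FALSE)
  }
  draws <- matrix(NA_real_, n, n_int, dimnames = list(NULL, tree$interior))
  got <- 0L
  tried <- 0L
  kept <- 0L
  batch <- max(1000L, 2L * n)

  if (construction == "conditional") {
    # nearest calibrated ancestor of each calibrated node
    anc_pair <- purrr::map_int(calibs$node, function(v) {
      anc <- node_ancestors(tree, v)
      hit <- anc[anc %in% calibs$node]
      if (length(hit) > 0) hit[1] else NA_integer_
    })
    st <- polytope_structure(tree, calibs$node)
    while (got < n) {
      cal_draws <- vapply(calibs$density, function(d) cal_sample(d, batch), numeric(batch))
      ok <- rep(TRUE, batch)
      for (i in seq_along(calibs$node)) {
        if (!is.na(anc_pair[i])) {
          ok <- ok & cal_draws[, match(anc_pair[i], calibs$node)] > cal_draws[, i]
        }
      }
      tried <- tried + batch
      kept <- kept + sum(ok)
      guard_acceptance(kept, tried, min_acceptance)
      idx <- which(ok)
      for (r in idx) {
        if (got >= n) break
        age_of <- numeric(s + n_int)
        age_of[calibs$node] <- cal_draws[r, ]
        feasible <- TRUE
        for (cp in st$components) {
          vals <- fill_component(tree, cp, age_of)
          if (is.null(vals)) {
            feasible <- FALSE
            break
          }
          age_of[cp$order] <- vals
        }
        if (!feasible) next
        got <- got + 1L
        draws[got, ] <- age_of[tree$interior]
      }
    }
  } else {
    ri <- match(tree$root, calibs$node)
    root_d <- calibs$density[[ri]]
    others <- calibs$node[-ri]
    od <- calibs$density[-ri]
    lmax <- sum(vapply(od, function(d) log(cal_max_density(d)), 0))
    while (got < n) {
      t1 <- cal_sample(root_d, batch)
      u <- matrix(stats::runif(batch * (n_int - 1L)), batch) * t1
      cand <- cbind(t1, u)
      colnames(cand) <- tree$interior
      ok <- apply(cand, 1, function(a) ages_feasible(tree, a))
      if (length(others) > 0) {
        lw <- rep(0, batch)
        for (i in seq_along(others)) {
          lw <- lw + log(cal_pdf(od[[i]], cand[, as.character(others[i])]))
        }
        ok <- ok & (log(stats::runif(batch)) < lw - lmax)
      }
      tried <- tried + batch
      kept <- kept + sum(ok)
      guard_acceptance(kept, tried, min_acceptance)
      idx <- which(ok)
      take <- idx[seq_len(min(length(idx), n - got))]
      if (length(take) > 0) {
        draws[(got + 1L):(got + length(take)), ] <- cand[take, , drop = FALSE]
        got <- got + length(take)
      }
    }
  }

  structure(
    list(
      draws = draws, chain = rep(1L, n), tree = tree, calibs = calibs,
      construction = construction,
      ess = stats::setNames(rep(n, n_int), tree$interior),
      accept = NULL, accept_rate = kept / tried,
      settings = list(n = n, seed = seed, sampler = "rejection")
    ),
    class = "prior_samples"
  )
}

# Draw the free ages of one component exactly uniformly on its polytope
# section, sequentially from the top: each node's age given its parent's
# age has density proportional to the product of its free children's
# volume polynomials F_c (nondecreasing), sampled by rejection against a
# uniform envelope with the density's value at the upper endpoint.
# Returns ages ordered as cp$order, or NULL when the section is empty.
fill_component <- function(tree, cp, age_of, max_tries = 100000L) {
  A <- age_of[cp$top]
  dp <- component_dp(cp, age_of)
  m <- length(cp$order)
  x <- numeric(m)
  p_of <- function(fc, t) {
    j <- findInterval(t, dp$lows)
    out <- 1
    for (q in fc) out <- out * poly_eval(dp$Fs[[q]][[j]], t)
    out
  }
  for (k in rev(seq_len(m))) {
    a_p <- if (cp$parent_pos[k] == 0L) A else x[cp$parent_pos[k]]
    L <- dp$Lv[k]
    if (a_p <= L) return(NULL)
    fc <- cp$free_kids[[k]]
    if (length(fc) == 0L) {
      x[k] <- stats::runif(1, L, a_p)
      next
    }
    # the density is zero below the children's support start; the uniform
    # proposal needs only cover the support (it stays a valid envelope
    # because the target is the *renormalized* conditional on (L, a_p))
    L <- max(L, max(dp$S[fc]))
    if (a_p <= L) return(NULL)
    M <- p_of(fc, a_p)
    if (M <= 0) return(NULL)
    ok <- FALSE
    for (i in seq_len(max_tries)) {
      t <- stats::runif(1, L, a_p)
      if (stats::runif(1) * M < p_of(fc, t)) {
        x[k] <- t
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("component sampling failed to accept; section nearly degenerate",
        call. = FALSE
      )
    }
  }
  x
}

guard_acceptance <- function(kept, tried, min_acceptance) {
  if (tried >= 20000L && kept / tried < min_acceptance) {
    stop(
      "estimated acceptance rate ", signif(kept / tried, 2),
      " below ", min_acceptance, "; use sample_time_prior() instead",
      call. = FALSE
    )
  }
  invisible(TRUE)
}
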