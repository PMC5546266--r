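#' Prior-only MCMC over node ages
#'
#' Samples the effective time prior -- the joint prior of all interior-node
#' ages -- by Markov chain Monte Carlo *without any sequence data*, exactly
#' as dating programs are run to inspect their prior.  The sampler is a
#' Metropolis-within-Gibbs scheme:
#'
#' * calibrated nodes get sliding-window proposals reflected at the dynamic
#'   feasible interval (max of children ages, parent age); soft bounds mean
#'   proposals are *not* reflected at the calibration bounds themselves;
#' * uncalibrated nodes are drawn exactly from their conditional, which
#'   under the uniform birth-death-sampling kernel is uniform on the same
#'   interval (for the multiplicative construction an uncalibrated root is
#'   drawn from its power-law conditional);
#' * one whole-tree multiplicative scaling move per sweep improves mixing
#'   of deep nodes.
#'
#' Proposal windows are auto-tuned during burn-in towards 20--40%
#' acceptance and frozen afterwards, preserving detailed balance.  Two
#' independent chains are run by default and their means compared as a
#' convergence check.
#'
#' @param tree A `timetree`.
#' @param calibs A calibration set (typically after
#'   [propagate_calibrations()]).  The conditional construction requires a
#'   calibrated root.
#' @param construction `"conditional"` or `"multiplicative"`.
#' @param iterations Number of post-burn-in sweeps per chain.
#' @param burnin Number of burn-in sweeps per chain (tuning happens here).
#' @param thin Store every `thin`-th sweep.
#' @param chains Number of independent chains.
#' @param seed Integer seed; the sampler is fully reproducible given it.
#' @param init Optional named initial age vector (defaults to a feasible
#'   recursive-midpoint construction inside the propagated bounds).
#' @return A `prior_samples` object: list with `draws` (matrix, one column
#'   per interior node, column names = node ids), `chain` (chain index per
#'   row), `accept` (per-node acceptance rates), `ess` (per-node effective
#'   sample sizes), plus the tree, calibration set and settings.
#' @seealso [summarize_prior()], [rejection_sample_prior()]
#' @export
#' @examples
#' tr <- fig1_tree()
#' cal <- propagate_calibrations(tr, fig1_calibrations(), "st2")
#' ps <- sample_time_prior(tr, cal, "conditional",
#'   iterations = 2000, burnin = 500, thin = 5, seed = 1
#' )
#' summarize_prior(ps)
sample_time_prior <- function(tree, calibs,
                              construction = c("conditional", "multiplicative"),
                              iterations = 20000L, burnin = round(iterations / 4),
                              thin = 10L, chains = 2L, seed = NULL,
                              init = NULL) {
  tree <- as_timetree(tree)
  construction <- match.arg(construction)
  stopifnot(iterations >= 1, burnin >= 0, thin >= 1, chains >= 1)
  s <- tree$s
  n_int <- tree$n_interior
  conditional <- construction == "conditional"
  if (conditional && !(tree$root %in% calibs$node)) {
    stop("the conditional construction requires a calibrated root",
      call. = FALSE
    )
  }
  if (!conditional && !(tree$root %in% calibs$node) && s < 4) {
    stop("multiplicative construction with an uncalibrated root needs >= 4 tips",
      call. = FALSE
    )
  }

  # --- static structure, internal index j = node id - s -----------------
  kids_int <- vector("list", n_int) # interior children (internal idx)
  for (j in seq_len(n_int)) {
    ch <- tree$children[[j + s]]
    kids_int[[j]] <- ch[ch > s] - s
  }
  parent_int <- ifelse(tree$parent[tree$interior] == 0L, 0L,
    tree$parent[tree$interior] - s
  )
  cal_idx <- calibs$node - s
  is_cal <- rep(FALSE, n_int)
  is_cal[cal_idx] <- TRUE
  logpdf <- vector("list", n_int)
  qfun <- vector("list", n_int)
  cfun <- vector("list", n_int)
  for (i in seq_along(cal_idx)) {
    logpdf[[cal_idx[i]]] <- make_cal_logpdf(calibs$density[[i]])
    qfun[[cal_idx[i]]] <- make_cal_quantile(calibs$density[[i]])
    cfun[[cal_idx[i]]] <- make_cal_cdf(calibs$density[[i]])
  }
  root_j <- 1L
  pow <- s - 2 # exponent of the uniform-kernel factor 1/t1^(s-2)
  # interior descendants (internal idx, self included) for subtree scaling
  desc_int <- lapply(seq_len(n_int), function(j) {
    c(j, node_descendants(tree, j + s) - s)
  })
  n_sub_moves <- max(1L, n_int %/% 6L)

  # component structure for the conditional volume factor
  comps <- list()
  dep_comps <- vector("list", n_int)
  n_free_total <- 0L
  if (conditional) {
    st <- polytope_structure(tree, calibs$node)
    comps <- st$components
    n_free_total <- sum(vapply(comps, function(cp) length(cp$members), 0L))
    for (ci in seq_along(comps)) {
      for (d in comps[[ci]]$deps) {
        dep_comps[[d - s]] <- c(dep_comps[[d - s]], ci)
      }
    }
  }
  # components whose volume depends on an age inside each subtree
  comps_touch <- lapply(seq_len(n_int), function(j) {
    if (length(comps) == 0L) return(integer(0))
    which(vapply(comps, function(cp) {
      any((cp$deps - s) %in% desc_int[[j]])
    }, TRUE))
  })

  n_stored <- (iterations %/% thin) * chains
  draws <- matrix(NA_real_, n_stored, n_int,
    dimnames = list(NULL, tree$interior)
  )
  chain_id <- integer(n_stored)
  acc_all <- matrix(0, chains, n_int)

  if (!is.null(seed)) set.seed(seed)
  row <- 0L
  for (chain in seq_len(chains)) {
    if (!is.null(seed)) set.seed(seed + 7919L * (chain - 1L))
    ages <- if (is.null(init)) {
      init_ages(tree, calibs)
    } else {
      ages_as_vector(tree, init)
    }
    age_of <- numeric(s + n_int)
    age_of[tree$interior] <- ages
    # per-component log volumes
    lvol <- if (conditional && length(comps) > 0) {
      vapply(comps, function(cp) log(component_volume(tree, cp, age_of)), 0)
    } else {
      numeric(0)
    }
    if (any(!is.finite(lvol))) {
      stop("no feasible initialization found (contradictory bounds?)",
        call. = FALSE
      )
    }
    # proposal windows
    w <- vapply(seq_len(n_int), function(j) {
      if (!is_cal[j]) return(NA_real_)
      d <- calibs$density[[match(j + s, calibs$node)]]
      tU <- cal_max_bound(d)
      tL <- cal_min_bound(d)
      if (!is.na(tU) && !is.na(tL)) (tU - tL) / 3 else if (!is.na(tU)) tU / 3 else tL / 2
    }, 0)
    w_init <- w
    w_scale <- 0.2
    w_sub <- 0.3
    acc <- numeric(n_int)
    try_cnt <- numeric(n_int)
    acc_s <- 0
    try_s <- 0
    acc_sub <- 0
    try_sub <- 0

    total <- burnin + iterations
    for (it in seq_len(total)) {
      tuning <- it <= burnin
      for (j in seq_len(n_int)) {
        kk <- kids_int[[j]]
        lower <- if (length(kk) > 0) max(ages[kk]) else 0
        upper <- if (parent_int[j] > 0L) ages[parent_int[j]] else Inf
        if (!is_cal[j]) {
          # exact Gibbs draw from the flat (or root power-law) conditional
          ages[j] <- if (j == root_j && !conditional) {
            # density on (lower, Inf) proportional to t^-(s-2)
            lower * (1 - stats::runif(1))^(-1 / (pow - 1))
          } else if (j == root_j && conditional) {
            stop("internal: free root under conditional construction")
          } else {
            stats::runif(1, lower, upper)
          }
          age_of[j + s] <- ages[j]
          next
        }
        t0 <- ages[j]
        if (conditional && length(dep_comps[[j]]) == 0L) {
          # the full conditional is the calibration density truncated to the
          # feasible interval: draw it exactly by quantile inversion
          Flo <- cfun[[j]](lower)
          Fhi <- if (is.finite(upper)) cfun[[j]](upper) else 1
          if (Fhi > Flo) {
            t1 <- qfun[[j]](stats::runif(1, Flo, Fhi))
            if (t1 > lower && (t1 < upper)) {
              ages[j] <- t1
              age_of[j + s] <- t1
            }
          }
          next
        }
        # two sub-updates per sweep: a reflected sliding-window move and an
        # independence draw from the calibration density (whose log-pdf
        # cancels against the proposal density in the Hastings ratio)
        for (window_move in c(TRUE, FALSE)) {
          t0 <- ages[j]
          if (window_move) {
            t1 <- reflect_interval(t0 + stats::runif(1, -w[j], w[j]), lower, upper)
            if (!is.finite(t1)) next
            delta <- logpdf[[j]](t1) - logpdf[[j]](t0)
          } else {
            t1 <- qfun[[j]](stats::runif(1))
            if (!is.finite(t1) || t1 <= lower || t1 >= upper) next
            delta <- 0
          }
          if (j == root_j && !conditional) {
            delta <- delta - pow * (log(t1) - log(t0))
          }
          new_lv <- NULL
          if (conditional && length(dep_comps[[j]]) > 0 && is.finite(delta)) {
            cis <- dep_comps[[j]]
            age_of[j + s] <- t1
            new_lv <- vapply(cis, function(ci) {
              log(component_volume(tree, comps[[ci]], age_of))
            }, 0)
            age_of[j + s] <- t0
            delta <- delta - sum(new_lv) + sum(lvol[cis])
          }
          if (window_move) try_cnt[j] <- try_cnt[j] + 1
          if (is.finite(delta) && log(stats::runif(1)) < delta) {
            ages[j] <- t1
            age_of[j + s] <- t1
            if (!is.null(new_lv)) lvol[dep_comps[[j]]] <- new_lv
            if (window_move) acc[j] <- acc[j] + 1
          }
        }
      }
      # whole-tree scaling move
      cc <- exp(w_scale * (stats::runif(1) - 0.5))
      delta <- n_int * log(cc) # Jacobian
      for (j in which(is_cal)) {
        delta <- delta + logpdf[[j]](cc * ages[j]) - logpdf[[j]](ages[j])
      }
      delta <- delta - if (conditional) n_free_total * log(cc) else pow * log(cc)
      try_s <- try_s + 1
      if (is.finite(delta) && log(stats::runif(1)) < delta) {
        ages <- cc * ages
        age_of[tree$interior] <- ages
        if (length(lvol) > 0) {
          lvol <- lvol + vapply(comps, function(cp) length(cp$members), 0L) * log(cc)
        }
        acc_s <- acc_s + 1
      }
      # subtree scaling moves: scale random interior clades coherently
      if (n_int > 2L) {
        for (rep_sub in seq_len(n_sub_moves)) {
          v <- sample.int(n_int - 1L, 1L) + 1L # any non-root interior node
          mem <- desc_int[[v]]
          cc <- exp(w_sub * (stats::runif(1) - 0.5))
          new_v <- cc * ages[v]
          if (new_v >= ages[parent_int[v]]) next
          new_ages <- ages
          new_ages[mem] <- cc * ages[mem]
          delta <- length(mem) * log(cc)
          cal_mem <- mem[is_cal[mem]]
          for (j in cal_mem) {
            delta <- delta + logpdf[[j]](new_ages[j]) - logpdf[[j]](ages[j])
          }
          cis <- comps_touch[[v]]
          new_lv <- NULL
          if (conditional && length(cis) > 0 && is.finite(delta)) {
            new_age_of <- age_of
            new_age_of[mem + s] <- new_ages[mem]
            new_lv <- vapply(cis, function(ci) {
              log(component_volume(tree, comps[[ci]], new_age_of))
            }, 0)
            delta <- delta - sum(new_lv) + sum(lvol[cis])
          }
          try_sub <- try_sub + 1
          if (is.finite(delta) && log(stats::runif(1)) < delta) {
            ages <- new_ages
            age_of[mem + s] <- new_ages[mem]
            if (!is.null(new_lv)) lvol[cis] <- new_lv
            acc_sub <- acc_sub + 1
          }
        }
      }
      # window tuning during burn-in
      if (tuning && it %% 50L == 0L) {
        for (j in which(is_cal)) {
          if (try_cnt[j] > 0) {
            # clamp to avoid runaway windows when acceptance saturates
            w[j] <- min(
              20 * w_init[j],
              max(0.01 * w_init[j], w[j] * exp(acc[j] / try_cnt[j] - 0.3))
            )
          }
        }
        if (try_s > 0) w_scale <- max(1e-3, w_scale * exp(acc_s / try_s - 0.3))
        if (try_sub > 0) w_sub <- max(1e-3, w_sub * exp(acc_sub / try_sub - 0.3))
        acc[] <- 0
        try_cnt[] <- 0
        acc_s <- 0
        try_s <- 0
        acc_sub <- 0
        try_sub <- 0
      }
      if (!tuning && (it - burnin) %% thin == 0L) {
        row <- row + 1L
        draws[row, ] <- ages
        chain_id[row] <- chain
      }
    }
    acc_all[chain, ] <- ifelse(try_cnt > 0, acc / try_cnt, NA_real_)
  }

  ess <- vapply(seq_len(n_int), function(j) {
    sum(vapply(seq_len(chains), function(chn) {
      ess_geyer(draws[chain_id == chn, j])
    }, 0))
  }, 0)
  names(ess) <- tree$interior

  out <- structure(
    list(
      draws = draws, chain = chain_id, tree = tree, calibs = calibs,
      construction = construction, ess = ess,
      accept = colMeans(acc_all),
      settings = list(
        iterations = iterations, burnin = burnin, thin = thin,
        chains = chains, seed = seed, sampler = "mcmc"
      )
    ),
    class = "prior_samples"
  )
  if (chains >= 2) check_chain_agreement(out)
  if (any(ess < 100)) {
    warning("low effective sample size (min ", round(min(ess)),
      "); consider more iterations",
      call. = FALSE
    )
  }
  out
}

# specialized log-pdf closures (avoid S3 dispatch in the MCMC inner loop)
make_cal_logpdf <- function(d) {
  if (inherits(d, "cal_uniform")) {
    tL <- d$tL; tU <- d$tU; h <- d$h; pL <- d$pL; pU <- d$pU
    aL <- d$alphaL; bU <- d$betaU; lh <- log(h)
    function(t) {
      if (t >= tL && t <= tU) return(lh)
      if (t < tL) {
        if (pL > 0) lh + (aL - 1) * (log(t) - log(tL)) else -Inf
      } else {
        if (pU > 0) lh - bU * (t - tU) else -Inf
      }
    }
  } else if (inherits(d, "cal_offset_exp")) {
    tL <- d$tL; th <- d$theta; lth <- log(th)
    function(t) if (t >= tL) lth - th * (t - tL) else -Inf
  } else {
    tL <- d$tL; A <- d$A; sc <- d$scale; pL <- d$pL
    lbody <- log(1 - pL) - log(d$body_mass)
    lf_tL <- log(d$f_tL); aL <- d$alphaL
    function(t) {
      if (t >= tL) {
        lbody + stats::dcauchy(t, A, sc, log = TRUE)
      } else if (pL > 0) {
        lf_tL + (aL - 1) * (log(t) - log(tL))
      } else {
        -Inf
      }
    }
  }
}

# scalar cdf closures matching make_cal_logpdf (dispatch-free inner loop)
make_cal_cdf <- function(d) {
  if (inherits(d, "cal_uniform")) {
    tL <- d$tL; tU <- d$tU; h <- d$h; pL <- d$pL; pU <- d$pU
    aL <- d$alphaL; bU <- d$betaU
    function(t) {
      if (t < tL) {
        if (pL > 0) pL * (t / tL)^aL else 0
      } else if (t <= tU) {
        pL + h * (t - tL)
      } else {
        1 - if (pU > 0) pU * exp(-bU * (t - tU)) else 0
      }
    }
  } else if (inherits(d, "cal_offset_exp")) {
    tL <- d$tL; th <- d$theta
    function(t) if (t >= tL) 1 - exp(-th * (t - tL)) else 0
  } else {
    tL <- d$tL; A <- d$A; sc <- d$scale; pL <- d$pL
    G_tL <- stats::pcauchy(tL, A, sc); bm <- d$body_mass; aL <- d$alphaL
    function(t) {
      if (t >= tL) {
        pL + (1 - pL) * (stats::pcauchy(t, A, sc) - G_tL) / bm
      } else if (pL > 0) {
        pL * (t / tL)^aL
      } else {
        0
      }
    }
  }
}

# scalar quantile closures
make_cal_quantile <- function(d) {
  if (inherits(d, "cal_uniform")) {
    tL <- d$tL; tU <- d$tU; h <- d$h; pL <- d$pL; pU <- d$pU
    aL <- d$alphaL; bU <- d$betaU
    function(q) {
      if (q < pL) {
        tL * (q / pL)^(1 / aL)
      } else if (q <= 1 - pU) {
        tL + (q - pL) / h
      } else {
        tU - log((1 - q) / pU) / bU
      }
    }
  } else if (inherits(d, "cal_offset_exp")) {
    tL <- d$tL; th <- d$theta
    function(q) tL - log1p(-q) / th
  } else {
    tL <- d$tL; A <- d$A; sc <- d$scale; pL <- d$pL
    G_tL <- stats::pcauchy(tL, A, sc); bm <- d$body_mass; aL <- d$alphaL
    function(q) {
      if (q < pL) {
        tL * (q / pL)^(1 / aL)
      } else {
        stats::qcauchy(G_tL + (q - pL) / (1 - pL) * bm, A, sc)
      }
    }
  }
}

# fold a proposal back into (lower, upper); upper may be Inf
reflect_interval <- function(x, lower, upper) {
  if (is.infinite(upper)) {
    return(lower + abs(x - lower))
  }
  width <- upper - lower
  y <- (x - lower) %% (2 * width)
  if (y < 0) y <- y + 2 * width
  lower + if (y <= width) y else 2 * width - y
}

# feasible starting ages: recursive midpointing inside the available bounds
init_ages <- function(tree, calibs) {
  s <- tree$s
  n_int <- tree$n_interior
  lb <- numeric(n_int) # hard floor from descendant minima
  cal_min <- rep(NA_real_, n_int)
  cal_max <- rep(NA_real_, n_int)
  for (i in seq_along(calibs$node)) {
    j <- calibs$node[i] - s
    cal_min[j] <- cal_min_bound(calibs$density[[i]])
    cal_max[j] <- cal_max_bound(calibs$density[[i]])
  }
  po <- postorder_interior(tree)
  for (j in po) {
    kk <- tree$children[[j + s]]
    kk <- kk[kk > s] - s
    lb[j] <- max(0, cal_min[j], lb[kk], na.rm = TRUE)
  }
  root_j <- 1L
  H <- cal_max[root_j]
  if (is.na(H)) H <- 2 * max(lb) + 1
  if (any(lb >= H)) {
    stop("no feasible initialization: a descendant minimum (", max(lb),
      ") reaches the root maximum (", H, ")",
      call. = FALSE
    )
  }
  ages <- numeric(n_int)
  for (j in po) {
    kk <- tree$children[[j + s]]
    kk <- kk[kk > s] - s
    base <- max(lb[j], if (length(kk) > 0) max(ages[kk]) else 0)
    ages[j] <- base + 0.1 * (H - base)
  }
  ages
}

# interior internal indices, children before parents
postorder_interior <- function(tree) {
  pre <- integer(0)
  stack <- tree$root
  while (length(stack) > 0) {
    v <- stack[[1]]
    stack <- stack[-1]
    pre <- c(pre, v)
    ch <- tree$children[[v]]
    stack <- c(ch[ch > tree$s], stack)
  }
  rev(pre) - tree$s
}

# compare per-node means between chains in units of pooled MC error
check_chain_agreement <- function(ps, factor = 3) {
  ch <- unique(ps$chain)
  if (length(ch) < 2) return(invisible(TRUE))
  m <- vapply(ch, function(c0) colMeans(ps$draws[ps$chain == c0, , drop = FALSE]), numeric(ncol(ps$draws)))
  se <- vapply(seq_len(ncol(ps$draws)), function(j) {
    stats::sd(ps$draws[, j]) / sqrt(max(ps$ess[j], 1))
  }, 0)
  spread <- apply(m, 1, function(x) max(x) - min(x))
  bad <- spread > factor * 2 * se
  if (any(bad)) {
    warning(
      "chains disagree at node(s) ",
      paste(colnames(ps$draws)[bad], collapse = ", "),
      " beyond ", factor, " pooled MC standard errors",
      call. = FALSE
    )
  }
  invisible(!any(bad))
}
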