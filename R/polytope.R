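# Piecewise-polynomial machinery for exact order-polytope volumes.
#
# Under the uniform birth-death-sampling kernel the non-calibration node
# ages, conditioned on the calibration-node ages, are uniform on the
# "section" of the tree's order polytope obtained by fixing the calibration
# ages.  The conditional density is therefore 1 / volume of that section,
# and the volume factorises over the connected components of free
# (uncalibrated) nodes.  Each component's volume is computed exactly by a
# postorder recursion F_v(a) = int_{L_v}^{a} prod_children F_c(t) dt where
# L_v is the largest fixed age directly below v; the F_v are piecewise
# polynomials with breakpoints at the fixed ages.

poly_mul <- function(a, b) {
  res <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] != 0) {
      idx <- i:(i + length(b) - 1L)
      res[idx] <- res[idx] + a[i] * b
    }
  }
  res
}

poly_eval <- function(p, x) {
  out <- rep(p[length(p)], length(x))
  if (length(p) > 1L) {
    for (i in (length(p) - 1L):1L) out <- out * x + p[i]
  }
  out
}

poly_antider <- function(p) c(0, p / seq_along(p))

## ---- component structure ---------------------------------------------------

# Decompose the free (non-fixed) interior nodes into connected components.
# Returns a list of components, each a list with:
#   members      free interior node ids (component)
#   top          the fixed parent node bounding the component above
#   fixed_below  fixed interior nodes that are children of members
#   deps         all fixed nodes whose ages enter this component's volume
polytope_structure <- function(tree, fixed_nodes) {
  tree <- as_timetree(tree)
  fixed_nodes <- as.integer(fixed_nodes)
  if (!(tree$root %in% fixed_nodes)) {
    stop("the root age must be fixed to compute the section volume",
      call. = FALSE
    )
  }
  is_fixed <- rep(FALSE, tree$s + tree$n_interior)
  is_fixed[fixed_nodes] <- TRUE
  free <- setdiff(tree$interior, fixed_nodes)
  comps <- list()
  for (r in free) {
    if (!is_fixed[tree$parent[r]]) next # not a component root
    members <- integer(0)
    fixed_below <- integer(0)
    stack <- r
    while (length(stack) > 0) {
      v <- stack[[1]]
      stack <- stack[-1]
      members <- c(members, v)
      for (ch in tree$children[[v]]) {
        if (ch <= tree$s) next
        if (is_fixed[ch]) fixed_below <- c(fixed_below, ch) else stack <- c(stack, ch)
      }
    }
    cp <- list(
      root = r, members = members, top = tree$parent[r],
      fixed_below = fixed_below,
      deps = c(tree$parent[r], fixed_below)
    )
    cp$chain_bottom <- chain_bottom_node(tree, cp)
    cp <- precompute_component(tree, cp)
    comps[[length(comps) + 1L]] <- cp
  }
  list(tree = tree, fixed = fixed_nodes, components = comps)
}

# If the component is a chain whose only fixed interior children hang off
# its bottom member, the free ages are a shifted simplex with volume
# (A - L)^m / m!.  Returns the bottom member id, or NA.
chain_bottom_node <- function(tree, cp) {
  bottom <- NA_integer_
  for (v in cp$members) {
    ch <- tree$children[[v]]
    ch <- ch[ch > tree$s]
    in_comp <- ch[ch %in% cp$members]
    fixed_ch <- setdiff(ch, in_comp)
    if (length(in_comp) > 1L) return(NA_integer_)
    if (length(in_comp) == 0L) {
      if (!is.na(bottom)) return(NA_integer_) # two chain ends
      bottom <- v
    } else if (length(fixed_ch) > 0L) {
      return(NA_integer_) # fixed child off a non-bottom member
    }
  }
  bottom
}

# volume of one component given ages (full named lookup vector over nodes)
component_volume <- function(tree, comp, age_of) {
  A <- age_of[comp$top]
  m <- length(comp$members)
  if (length(comp$fixed_below) == 0L) {
    # fast path: pure subtree below one fixed ancestor, lower bounds all 0
    sizes <- subtree_sizes(tree, comp)
    if (A <= 0) return(0)
    return(A^m / prod(sizes))
  }
  if (!is.na(comp$chain_bottom)) {
    L <- max(age_of[comp$fixed_below])
    if (A <= L) return(0)
    return((A - L)^m / factorial(m))
  }
  dp <- component_dp(comp, age_of)
  j <- findInterval(A, dp$lows, left.open = FALSE) # A > 0 so j >= 1
  v <- poly_eval(dp$Fs[[m]][[j]], A)
  max(v, 0)
}

# postorder DP on a common breakpoint grid (the fixed ages): for each member
# (in comp$order), the piecewise-polynomial F_v(a) = volume of the free
# subtree below v given its parent age a
component_dp <- function(comp, age_of) {
  m <- length(comp$order)
  Lv <- numeric(m)
  for (k in seq_len(m)) {
    fx <- comp$fixed_kids[[k]]
    Lv[k] <- if (length(fx) > 0) max(age_of[fx], 0) else 0
  }
  br <- sort.int(unique(Lv[Lv > 0]), method = "quick")
  lows <- c(0, br)
  np <- length(lows) # pieces: (lows[j], lows[j+1]), last unbounded
  zero <- 0
  Fs <- vector("list", m)
  for (k in seq_len(m)) {
    L <- Lv[k]
    fc <- comp$free_kids[[k]]
    out <- vector("list", np)
    if (length(fc) == 0L) {
      base <- c(-L, 1)
      for (j in seq_len(np)) out[[j]] <- if (lows[j] >= L) base else zero
    } else {
      running <- 0
      for (j in seq_len(np)) {
        if (lows[j] < L) {
          out[[j]] <- zero
          next
        }
        p <- Fs[[fc[1]]][[j]]
        if (length(fc) > 1L) {
          for (q in fc[-1]) {
            pq <- Fs[[q]][[j]]
            p <- if (length(p) == 1L && p == 0) 0 else if (length(pq) == 1L && pq == 0) 0 else poly_mul(p, pq)
          }
        }
        if (length(p) == 1L && p[1] == 0) {
          out[[j]] <- running # integrand zero: constant carries over
        } else {
          Aj <- poly_antider(p)
          Aj[1] <- Aj[1] + running - poly_eval(Aj, lows[j])
          out[[j]] <- Aj
          if (j < np) running <- poly_eval(Aj, lows[j + 1])
        }
      }
    }
    Fs[[k]] <- out
  }
  # support start of each F_v: F_v > 0 exactly above max(L_v, children's)
  S <- numeric(m)
  for (k in seq_len(m)) {
    fc <- comp$free_kids[[k]]
    S[k] <- max(Lv[k], if (length(fc) > 0) max(S[fc]) else 0)
  }
  list(Fs = Fs, Lv = Lv, lows = lows, S = S)
}

# postorder member layout: for each member (children before parents), the
# positions of its free children and the ids of its fixed interior children
precompute_component <- function(tree, cp) {
  ord <- integer(0)
  walk <- function(v) {
    for (ch in tree$children[[v]]) {
      if (ch > tree$s && ch %in% cp$members) walk(ch)
    }
    ord <<- c(ord, v)
  }
  walk(cp$root)
  cp$order <- ord # postorder, root last
  cp$free_kids <- lapply(ord, function(v) {
    ch <- tree$children[[v]]
    match(ch[ch > tree$s & ch %in% cp$members], ord)
  })
  cp$fixed_kids <- lapply(ord, function(v) {
    ch <- tree$children[[v]]
    ch[ch > tree$s & !(ch %in% cp$members)]
  })
  cp$parent_pos <- vapply(ord, function(v) {
    p <- tree$parent[v]
    if (p %in% ord) match(p, ord) else 0L
  }, 0L)
  cp
}

# number of component members in the component-subtree rooted at each member
subtree_sizes <- function(tree, comp) {
  in_comp <- comp$members
  sz <- stats::setNames(integer(length(in_comp)), in_comp)
  # postorder via recursion (components are small)
  count <- function(v) {
    n <- 1L
    for (ch in tree$children[[v]]) {
      if (ch > tree$s && ch %in% in_comp) n <- n + count(ch)
    }
    sz[[as.character(v)]] <<- n
    n
  }
  count(comp$root)
  as.integer(sz)
}

#' Volume of the order-polytope section with some node ages fixed
#'
#' Computes the exact volume (in time-units to the power of the number of
#' free nodes) of the set of age assignments to the uncalibrated interior
#' nodes that respect the tree's ancestor-older-than-descendant partial
#' order, given fixed ages at the calibration nodes.  The root age must be
#' among the fixed ages.  Under the uniform birth-death-sampling kernel the
#' conditional density of the free ages given the fixed ones is the
#' reciprocal of this volume.
#'
#' @param tree A `timetree`.
#' @param fixed_ages Named numeric vector of fixed ages; names are interior
#'   node ids and must include the root.
#' @return A single nonnegative number; 0 when the fixed ages are
#'   infeasible, 1 when there are no free nodes.
#' @export
#' @examples
#' tr <- fig1_tree()
#' # ladder with root (node 6) and cherry (node 9) fixed: (t1 - t4)^2 / 2
#' order_polytope_volume(tr, c("6" = 100, "9" = 10)) # 4050
order_polytope_volume <- function(tree, fixed_ages) {
  tree <- as_timetree(tree)
  if (is.null(names(fixed_ages))) {
    stop("`fixed_ages` must be named by interior node id", call. = FALSE)
  }
  nodes <- as.integer(names(fixed_ages))
  st <- polytope_structure(tree, nodes)
  age_of <- rep(NA_real_, tree$s + tree$n_interior)
  age_of[nodes] <- as.numeric(fixed_ages)
  if (!fixed_ages_consistent(tree, nodes, age_of)) return(0)
  if (length(st$components) == 0L) return(1)
  prod(vapply(st$components, function(cp) {
    component_volume(tree, cp, age_of)
  }, 0))
}

# every fixed node must be younger than its nearest fixed ancestor and > 0
fixed_ages_consistent <- function(tree, fixed_nodes, age_of) {
  if (any(age_of[fixed_nodes] <= 0)) return(FALSE)
  for (v in fixed_nodes) {
    p <- tree$parent[v]
    while (p != 0L && is.na(age_of[p])) p <- tree$parent[p]
    if (p != 0L && age_of[p] <= age_of[v]) return(FALSE)
  }
  TRUE
}
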