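# Independent oracles used across the suite.

# brute-force MRCA by intersecting root-ward ancestor chains
brute_mrca <- function(tree, taxa) {
  tips <- match(taxa, tree$tip_label)
  chain <- function(v) {
    out <- v
    p <- tree$parent[v]
    while (p != 0L) {
      out <- c(out, p)
      p <- tree$parent[p]
    }
    out
  }
  Reduce(intersect, lapply(tips, chain))[1]
}

# Monte-Carlo estimate of the order-polytope section volume: free ages
# drawn i.i.d. U(0, root age), hit fraction scaled by the box volume
mc_volume <- function(tree, fixed_ages, n = 2e5) {
  nodes <- as.integer(names(fixed_ages))
  free <- setdiff(tree$interior, nodes)
  k <- length(free)
  t1 <- fixed_ages[[as.character(tree$root)]]
  ages <- matrix(NA_real_, n, tree$n_interior)
  colnames(ages) <- tree$interior
  for (nd in nodes) ages[, as.character(nd)] <- fixed_ages[[as.character(nd)]]
  for (nd in free) ages[, as.character(nd)] <- stats::runif(n, 0, t1)
  ok <- rep(TRUE, n)
  for (v in tree$interior) {
    for (ch in tree$children[[v]]) {
      if (ch > tree$s) {
        ok <- ok & ages[, as.character(v)] > ages[, as.character(ch)]
      }
    }
  }
  hit <- ok
  list(
    estimate = mean(hit) * t1^k,
    se = stats::sd(hit) * t1^k / sqrt(n)
  )
}

# feasible random age vector for a tree given (propagated or not) calibs
random_feasible_ages <- function(tree, calibs) {
  timeprior:::init_ages(tree, calibs)
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) < tol,
    label = sprintf("|%.8g - %.8g| < %g", object, expected, tol)
  )
}
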