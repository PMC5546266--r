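#' Rooted time trees
#'
#' A `timetree` is a rooted (multifurcating allowed) tree whose `s` tips sit
#' at age 0 and whose `s - 1` (binary case) interior nodes carry ages that
#' increase root-ward.  Topology is stored as an [ape::phylo] object; node
#' numbering follows the `ape` convention (tips `1..s`, interior nodes
#' `s+1 .. s+Nnode` with the root at `s + 1`).  Ages are *not* part of the
#' tree object: they live in age vectors and sample sets, indexed by interior
#' node id.
#'
#' @param x A `phylo` object, a Newick string, or a file path.
#' @return A `timetree` object: list with elements `phy` (the `phylo`),
#'   `s` (tip count), `n_interior`, `root`, `interior` (interior node ids),
#'   `parent` (parent id per node, 0 for the root), `children` (list of
#'   child ids per node), and `tip_label`.
#' @export
#' @examples
#' tr <- read_timetree("((A,B),C);")
#' n_tips(tr)
read_timetree <- function(x) {
  if (inherits(x, "phylo")) {
    phy <- x
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    looks_like_newick <- grepl("[();]", x)
    if (!looks_like_newick && !file.exists(x)) {
      stop("no such tree file: ", x, call. = FALSE)
    }
    phy <- if (file.exists(x)) {
      ape::read.tree(x)
    } else {
      ape::read.tree(text = x)
    }
    if (is.null(phy)) stop("failed to parse Newick input", call. = FALSE)
  }
  as_timetree(phy)
}

#' @rdname read_timetree
#' @export
as_timetree <- function(x) {
  if (inherits(x, "timetree")) return(x)
  stopifnot(inherits(x, "phylo"))
  phy <- x
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf names in tree", call. = FALSE)
  }
  if (!ape::is.rooted(phy)) stop("tree must be rooted", call. = FALSE)
  s <- length(phy$tip.label)
  if (s < 2) stop("tree must have at least 2 tips", call. = FALSE)
  n_node <- phy$Nnode
  n_all <- s + n_node
  parent <- integer(n_all)
  children <- vector("list", n_all)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]
    b <- phy$edge[i, 2]
    parent[b] <- a
    children[[a]] <- c(children[[a]], b)
  }
  root <- s + 1L
  structure(
    list(
      phy = phy, s = s, n_interior = n_node, root = root,
      interior = seq.int(s + 1L, s + n_node),
      parent = parent, children = children,
      tip_label = phy$tip.label
    ),
    class = "timetree"
  )
}

#' @export
print.timetree <- function(x, ...) {
  cat(sprintf(
    "<timetree> %d tips, %d interior nodes (root = node %d)\n",
    x$s, x$n_interior, x$root
  ))
  invisible(x)
}

#' @rdname read_timetree
#' @export
n_tips <- function(x) as_timetree(x)$s

#' Write a timetree as Newick
#'
#' @param tree A `timetree` (or `phylo`).
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @export
write_timetree <- function(tree, file = NULL) {
  phy <- as_timetree(tree)$phy
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(file)
  }
}

#' Most recent common ancestor of a set of taxa
#'
#' Returns the lowest node ancestral to all named taxa.  A single taxon
#' returns the tip itself.
#'
#' @param tree A `timetree`.
#' @param taxa Character vector of leaf names.
#' @return An integer node id.
#' @export
#' @examples
#' tr <- read_timetree("((A,B),C);")
#' mrca_node(tr, c("A", "B"))
mrca_node <- function(tree, taxa) {
  tree <- as_timetree(tree)
  stopifnot(length(taxa) >= 1)
  miss <- setdiff(taxa, tree$tip_label)
  if (length(miss) > 0) {
    stop("unknown taxa: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tips <- match(unique(taxa), tree$tip_label)
  if (length(tips) == 1L) return(tips)
  ape::getMRCA(tree$phy, tips)
}

# all interior-node ancestors of a node, bottom-up (excluding the node)
node_ancestors <- function(tree, node) {
  out <- integer(0)
  p <- tree$parent[node]
  while (p != 0L) {
    out <- c(out, p)
    p <- tree$parent[p]
  }
  out
}

# interior-node descendants of an interior node (excluding the node)
node_descendants <- function(tree, node) {
  out <- integer(0)
  stack <- tree$children[[node]]
  while (length(stack) > 0) {
    v <- stack[[1]]
    stack <- stack[-1]
    if (v > tree$s) {
      out <- c(out, v)
      stack <- c(stack, tree$children[[v]])
    }
  }
  out
}

# check that an age vector (named by interior node id) respects the tree:
# every interior node older than its interior children, all ages > 0
ages_feasible <- function(tree, ages) {
  a <- ages_as_vector(tree, ages)
  if (any(!is.finite(a)) || any(a <= 0)) return(FALSE)
  for (v in tree$interior) {
    av <- a[v - tree$s]
    for (ch in tree$children[[v]]) {
      if (ch > tree$s && a[ch - tree$s] >= av) return(FALSE)
    }
  }
  TRUE
}

# coerce ages given as a named vector (names = node ids) or a plain vector
# over interior nodes (root first) to the plain internal layout
ages_as_vector <- function(tree, ages) {
  if (!is.null(names(ages))) {
    a <- rep(NA_real_, tree$n_interior)
    idx <- as.integer(names(ages)) - tree$s
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > tree$n_interior)) {
      stop("age names must be interior node ids", call. = FALSE)
    }
    a[idx] <- as.numeric(ages)
    a
  } else {
    if (length(ages) != tree$n_interior) {
      stop("ages must have one entry per interior node", call. = FALSE)
    }
    as.numeric(ages)
  }
}
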