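#' Read a rooted phylogeny from a Newick string
#'
#' Strict reader for the analyses in this package: the tree must be rooted,
#' every edge must carry a branch length, branch lengths must be non-negative
#' and tip labels must be unique. Trees failing any of these checks are
#' rejected rather than repaired.
#'
#' @param text A Newick string (single tree).
#' @return An object of class `phylo` (see \pkg{ape}).
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("could not parse Newick string")
  validate_tree(tree)
  tree
}

#' Write a phylogeny as a Newick string
#'
#' @param tree A `phylo` tree.
#' @return A Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 15)
}

# Shared validation for trees entering any analysis operation.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length))
    stop("all edges must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  invisible(tree)
}

#' Shared evolutionary time between species
#'
#' Builds the matrix of shared root-to-MRCA path lengths `t_ij` between every
#' pair of tips, the basic ingredient of all phylogenetic variance-covariance
#' structures: `t_ij` is the summed branch length from the root down to the
#' most recent common ancestor of tips i and j, and the diagonal `t_ii` is the
#' root-to-tip distance.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A symmetric matrix with rows/columns in `tree$tip.label` order.
#' @export
#' @examples
#' shared_time_matrix(read_newick("((A:1,B:1):1,C:2);"))
shared_time_matrix <- function(tree) {
  validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Restrict a tree to a subset of species
#'
#' Drops all tips outside `keep`, collapsing the resulting degree-two internal
#' nodes by summing branch lengths, so that path lengths among retained tips
#' (and hence their shared-time matrix) are unchanged.
#'
#' @param tree A `phylo` tree.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo` tree.
#' @export
prune_to <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop(sprintf("species not in tree: %s", paste(unknown, collapse = ", ")))
  if (length(keep) < 2L) stop("must keep at least 2 species")
  ape::keep.tip(tree, keep)
}

#' Simulate an ultrametric pure-birth tree
#'
#' Yule (pure-birth) tree with the requested number of tips, rescaled so the
#' root-to-tip height is exactly 1. Heights are normalized so optimizer bounds
#' for time-scaled parameters (such as the Ornstein-Uhlenbeck pull) are
#' independent of tree scale.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional integer seed for reproducibility.
#' @return An ultrametric `phylo` tree of height 1 with tips `t1..tn`.
#' @export
simulate_pure_birth <- function(n_tips, seed = NULL) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 2L) stop("n_tips must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depths <- ape::node.depth.edgelength(tree)
  h <- max(depths[seq_len(n_tips)])
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Raise all branch lengths to a power (Pagel's kappa transform)
#'
#' Replaces every branch length b by b^kappa. `kappa = 1` leaves the tree
#' unchanged; `kappa = 0` equalizes all branch lengths at 1 (0^0 is defined as
#' 1), so that divergence is proportional to the number of nodes separating
#' species rather than to time.
#'
#' @param tree A `phylo` tree.
#' @param kappa Power, >= 0.
#' @return The transformed `phylo` tree.
#' @export
kappa_branch_transform <- function(tree, kappa) {
  validate_tree(tree)
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be >= 0")
  b <- tree$edge.length
  out <- b^kappa
  if (kappa == 0) out[b == 0] <- 1
  tree$edge.length <- out
  tree
}

#' Height of a tree
#'
#' Maximum root-to-tip distance.
#' @param tree A `phylo` tree.
#' @return Numeric scalar.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

# Root-to-node depths for all nodes (tips then internals, ape numbering).
node_depths <- function(tree) ape::node.depth.edgelength(tree)

is_ultrametric <- function(tree, tol = 1e-8) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= tol * max(d, 1)
}
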