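#' Rescale a phylogeny by Pagel's lambda
#'
#' Multiplies internal branch lengths by `lambda` and extends terminal
#' branches so every tip keeps its original depth. On an ultrametric tree this
#' reproduces exactly the lambda-model covariance: off-diagonal shared times
#' are multiplied by `lambda` while root-to-tip times are unchanged. Used to
#' inject the fitted phylogenetic signal into a tree before a Brownian-motion
#' ancestral reconstruction.
#'
#' @param tree An ultrametric `phylo` tree.
#' @param lambda Signal strength in `[0, 1]`.
#' @return The rescaled `phylo` tree.
#' @export
lambda_rescale <- function(tree, lambda) {
  validate_tree(tree)
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  if (!is_ultrametric(tree))
    stop("lambda_rescale requires an ultrametric tree")
  ntip <- ape::Ntip(tree)
  depths <- node_depths(tree)
  H <- max(depths[seq_len(ntip)])
  child <- tree$edge[, 2L]
  parent <- tree$edge[, 1L]
  terminal <- child <= ntip
  out <- tree
  out$edge.length[!terminal] <- lambda * tree$edge.length[!terminal]
  # tips stay at depth H: terminal branch runs from the rescaled parent depth
  out$edge.length[terminal] <- H - lambda * depths[parent[terminal]]
  out
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Joint maximum-likelihood estimates of all internal-node states under
#' Brownian motion, with 95% confidence intervals. The diffusion rate is fixed
#' at its tip-based ML estimate (from [fit_model()] with the `bm` kind), and
#' node estimates solve the weighted tree Laplacian system (each node state is
#' the ML compromise of its neighbours, weighted by inverse branch length).
#' Per-node variances are the conditional variances of the node states given
#' the tip data with the rate plugged in, i.e. the diagonal of the inverse
#' internal-node block of the Laplacian precision; the confidence interval is
#' `estimate +/- 1.96 * sqrt(variance)`.
#'
#' The root estimate equals the generalized-least-squares root state of the
#' Brownian fit exactly.
#'
#' @param tree A `phylo` tree (>= 2 tips).
#' @param traits Named numeric tip values (or data frame, see [fit_model()]).
#' @return Object of class `anc_states`: data frame with one row per internal
#'   node (`node` in ape numbering, `depth`, `estimate`, `var`, `ci_lo`,
#'   `ci_hi`), plus attributes `sigma2`, `z0` and `degenerate`.
#' @export
anc_ml_bm <- function(tree, traits) {
  validate_tree(tree)
  ntip <- ape::Ntip(tree)
  x <- align_to_tips(tree, traits, what = "trait")
  nnode <- tree$Nnode
  nodes <- ntip + seq_len(nnode)
  depths <- node_depths(tree)

  fit <- fit_model(tree, x, "bm")
  s2 <- fit$params$sigma2
  z0 <- fit$params$z0

  if (fit$degenerate || s2 <= 0) {
    est <- rep(x[[1L]], nnode)
    out <- data.frame(node = nodes, depth = depths[nodes], estimate = est,
                      var = 0, ci_lo = est, ci_hi = est)
    class(out) <- c("anc_states", "data.frame")
    attr(out, "sigma2") <- 0
    attr(out, "z0") <- z0
    attr(out, "degenerate") <- TRUE
    return(out)
  }

  # weighted graph Laplacian over all nodes, weights 1/branch length
  ntot <- ntip + nnode
  w <- 1 / pmax(tree$edge.length, 1e-12)
  L <- matrix(0, ntot, ntot)
  p <- tree$edge[, 1L]
  ch <- tree$edge[, 2L]
  for (e in seq_along(w)) {
    L[p[e], p[e]] <- L[p[e], p[e]] + w[e]
    L[ch[e], ch[e]] <- L[ch[e], ch[e]] + w[e]
    L[p[e], ch[e]] <- L[p[e], ch[e]] - w[e]
    L[ch[e], p[e]] <- L[ch[e], p[e]] - w[e]
  }
  Laa <- L[nodes, nodes, drop = FALSE]
  Lax <- L[nodes, seq_len(ntip), drop = FALSE]
  Laa_inv <- solve(Laa)
  est <- drop(Laa_inv %*% (-Lax %*% x))
  v <- s2 * diag(Laa_inv)
  half <- 1.96 * sqrt(v)
  out <- data.frame(node = nodes, depth = depths[nodes], estimate = est,
                    var = v, ci_lo = est - half, ci_hi = est + half)
  class(out) <- c("anc_states", "data.frame")
  attr(out, "sigma2") <- s2
  attr(out, "z0") <- z0
  attr(out, "degenerate") <- FALSE
  out
}

#' Signal-rescaled ancestral state reconstruction
#'
#' The full reconstruction pipeline for a prevalence-type trait: fit Pagel's
#' lambda to the tip data, rescale the tree by the fitted (or a supplied)
#' lambda, then reconstruct ancestral states under Brownian motion on the
#' rescaled tree with 95% confidence intervals.
#'
#' @param tree An ultrametric `phylo` tree.
#' @param traits Named numeric tip values (or data frame).
#' @param lambda `"auto"` (default) to use the ML estimate from the lambda
#'   model, or a fixed value in `[0, 1]`.
#' @return An `anc_states` data frame (see [anc_ml_bm()]) with an extra
#'   `lambda` attribute.
#' @export
asr_lambda_bm <- function(tree, traits, lambda = "auto") {
  if (identical(lambda, "auto")) {
    fit <- fit_model(tree, traits, "lambda")
    lambda <- fit$params$lambda
  }
  scaled <- lambda_rescale(tree, lambda)
  out <- anc_ml_bm(scaled, traits)
  attr(out, "lambda") <- lambda
  out
}
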