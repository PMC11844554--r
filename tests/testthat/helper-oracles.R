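# Independent oracles used across the test files. These deliberately avoid
# the package's own matrix routines: shared times come from explicit
# root-to-tip path enumeration, and the Brownian likelihood from the
# recursive pruning (contrasts) algorithm.

# Shared-time matrix by exhaustive path enumeration: for each pair of tips,
# sum the branch lengths of the edges common to both root-to-tip paths.
oracle_shared_time <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  # path of edge indices from root to each tip
  paths <- lapply(seq_len(ntip), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2L] == node)
      path <- c(e, path)
      node <- tree$edge[e, 1L]
    }
    path
  })
  M <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(i)) {
    shared <- intersect(paths[[i]], paths[[j]])
    M[i, j] <- M[j, i] <- sum(tree$edge.length[shared])
  }
  M
}

# Brownian-motion log-likelihood of tip data by the recursive pruning
# algorithm (Felsenstein), for given root state z0 and rate sigma2.
oracle_bm_loglik <- function(tree, x, z0, sigma2) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2L])
  ll <- 0
  visit <- function(node) {
    if (node <= ntip) return(c(xhat = unname(x[tree$tip.label[node]]), v = 0))
    kids <- children[[as.character(node)]]
    parts <- lapply(kids, function(k) {
      p <- visit(k)
      c(p["xhat"], v = unname(p["v"]) + sigma2 * elen[[as.character(k)]])
    })
    est <- parts[[1L]]
    for (i in seq_along(parts)[-1L]) {
      p <- parts[[i]]
      ll <<- ll + stats::dnorm(est[["xhat"]] - p[["xhat"]], 0,
                               sqrt(est[["v"]] + p[["v"]]), log = TRUE)
      w <- c(1 / est[["v"]], 1 / p[["v"]])
      est <- c(xhat = sum(w * c(est[["xhat"]], p[["xhat"]])) / sum(w),
               v = 1 / sum(w))
    }
    est
  }
  top <- visit(root)
  ll + stats::dnorm(top[["xhat"]] - z0, 0, sqrt(top[["v"]]), log = TRUE)
}

# A deterministic random tree with branch-length variety (not ultrametric).
random_test_tree <- function(n, seed) {
  tr <- with_seed2(seed, ape::rtree(n))
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

# Seed helper local to the tests (keeps the global stream untouched).
with_seed2 <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}
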