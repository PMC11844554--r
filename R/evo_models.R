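#' Specify a model of continuous trait evolution
#'
#' Constructs a model specification combining a kind, the diffusion rate
#' `sigma2` (trait-units^2 per unit time), the root state `z0` and the single
#' shape parameter relevant to that kind. The nine kinds and their
#' variance-covariance forms over shared times `t_ij` are:
#'
#' * `bm`: random-walk evolution, `sigma2 * t_ij`.
#' * `ou`: stabilizing selection with pull `alpha`;
#'   `sigma2/(2*alpha) * (1 - exp(-2*alpha*t_ij))` (`ou_form = "rooted"`), or
#'   the same multiplied by `exp(-alpha*d_ij)` with `d_ij` the patristic
#'   distance (`ou_form = "hansen"`, the stationary form).
#' * `eb`: early burst, rates decaying at `a <= 0`;
#'   `sigma2 * (exp(a*t_ij) - 1)/a`, reducing to `bm` as `a -> 0`.
#' * `lambda`: Pagel's lambda in `[0,1]` multiplying off-diagonal entries;
#'   0 = independent evolution, 1 = Brownian motion.
#' * `delta`: Pagel's delta > 0, `sigma2 * t_ij^delta`; delta < 1 decelerating,
#'   > 1 accelerating rates towards the present.
#' * `kappa`: Pagel's kappa in `[0,1]`: Brownian motion on the tree whose
#'   branch lengths are raised to the power kappa (speciational change at
#'   kappa = 0).
#' * `rate_trend`: instantaneous rate `sigma2 * (1 + slope*t)` changing
#'   linearly in time; the covariance is its time integral
#'   `sigma2 * (t_ij + slope*t_ij^2/2)`, which vanishes at `t_ij = 0` and
#'   reduces to `bm` at `slope = 0`.
#' * `mean_trend`: Brownian covariance plus a directional drift in the mean,
#'   `z0 + drift * t_ii` per tip (identifiable only on non-ultrametric trees).
#' * `white`: phylogeny-free, `sigma2` on the diagonal and 0 elsewhere.
#'
#' @param kind One of `"bm"`, `"ou"`, `"eb"`, `"lambda"`, `"delta"`,
#'   `"kappa"`, `"rate_trend"`, `"mean_trend"`, `"white"`.
#' @param sigma2 Diffusion rate, > 0.
#' @param z0 Root state.
#' @param alpha OU pull strength (> 0, per unit time).
#' @param a Early-burst rate-change parameter (<= 0, per unit time).
#' @param lambda,delta,kappa Pagel transform parameters.
#' @param slope Rate-trend coefficient (per unit time).
#' @param drift Mean-trend coefficient (trait units per unit time).
#' @param ou_form `"rooted"` (non-stationary form) or `"hansen"` (stationary).
#' @return An object of class `evol_model`.
#' @export
#' @examples
#' evol_model("ou", sigma2 = 1, alpha = 2)
evol_model <- function(kind = c("bm", "ou", "eb", "lambda", "delta", "kappa",
                                "rate_trend", "mean_trend", "white"),
                       sigma2 = 1, z0 = 0,
                       alpha = NULL, a = NULL, lambda = NULL, delta = NULL,
                       kappa = NULL, slope = NULL, drift = NULL,
                       ou_form = c("rooted", "hansen")) {
  kind <- match.arg(kind)
  ou_form <- match.arg(ou_form)
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
  if (!is.finite(z0)) stop("z0 must be finite")
  shape_name <- switch(kind,
    ou = "alpha", eb = "a", lambda = "lambda", delta = "delta",
    kappa = "kappa", rate_trend = "slope", mean_trend = "drift",
    bm = , white = NA_character_)
  given <- list(alpha = alpha, a = a, lambda = lambda, delta = delta,
                kappa = kappa, slope = slope, drift = drift)
  set <- names(given)[!vapply(given, is.null, logical(1))]
  irrelevant <- setdiff(set, shape_name)
  if (length(irrelevant))
    stop(sprintf("parameter(s) %s are not part of the '%s' model",
                 paste(irrelevant, collapse = ", "), kind))
  shape <- if (is.na(shape_name)) NULL else given[[shape_name]]
  if (!is.na(shape_name)) {
    if (is.null(shape)) {
      # neutral defaults: the value at which each kind collapses to bm
      shape <- switch(kind, ou = 1e-8, eb = 0, lambda = 1, delta = 1,
                      kappa = 1, rate_trend = 0, mean_trend = 0)
    }
    ok <- switch(kind,
      ou = shape > 0,
      eb = shape <= 0,
      lambda = shape >= 0 && shape <= 1,
      delta = shape > 0,
      kappa = shape >= 0 && shape <= 1,
      rate_trend = TRUE,  # tree-dependent bound checked in model_vcv
      mean_trend = TRUE)
    if (!is.finite(shape) || !ok)
      stop(sprintf("invalid %s = %g for model '%s'", shape_name, shape, kind))
  }
  structure(
    list(kind = kind, sigma2 = sigma2, z0 = z0,
         shape = shape, shape_name = shape_name, ou_form = ou_form),
    class = "evol_model"
  )
}

#' @export
print.evol_model <- function(x, ...) {
  cat(sprintf("Evolutionary model: %s  (sigma2 = %.4g, z0 = %.4g%s)\n",
              x$kind, x$sigma2, x$z0,
              if (!is.na(x$shape_name))
                sprintf(", %s = %.4g", x$shape_name, x$shape) else ""))
  invisible(x)
}

#' Number of fitted parameters of a model kind
#'
#' Two (`sigma2`, `z0`) for Brownian motion and white noise; three (plus one
#' shape parameter) for all other kinds.
#'
#' @param kind Model kind string or an `evol_model`.
#' @return Integer parameter count.
#' @export
model_k <- function(kind) {
  if (inherits(kind, "evol_model")) kind <- kind$kind
  if (kind %in% c("bm", "white")) 2L else 3L
}

#' Model variance-covariance matrix over tips
#'
#' Builds the expected trait covariance among species implied by a model
#' specification and a tree, by transforming the shared-time matrix.
#'
#' @param spec An `evol_model`.
#' @param tree A `phylo` tree.
#' @param C Optional precomputed [shared_time_matrix()] of `tree` (a cache for
#'   repeated calls during fitting); kappa ignores it.
#' @return Covariance matrix in tip order.
#' @export
model_vcv <- function(spec, tree, C = NULL) {
  stopifnot(inherits(spec, "evol_model"))
  if (is.null(C)) C <- shared_time_matrix(tree)
  if (spec$kind %in% c("ou", "eb", "delta") && !is_ultrametric(tree))
    warning(sprintf("'%s' model on a non-ultrametric tree", spec$kind))
  if (spec$kind == "mean_trend" && is_ultrametric(tree))
    stop("mean_trend is unidentifiable on an ultrametric tree: ",
         "all tips share the same elapsed time, so drift and z0 are confounded")
  spec$sigma2 * structure_matrix(spec$kind, spec$shape, tree, C, spec$ou_form)
}

# Unit-rate structure matrix R(theta): the single source of the covariance
# formulas, shared by model_vcv and the fitting engine.
structure_matrix <- function(kind, theta, tree, C, ou_form = "rooted") {
  switch(kind,
    bm = ,
    mean_trend = C,          # drift sits in the mean, covariance is Brownian
    white = {
      V <- diag(1, nrow(C))
      dimnames(V) <- dimnames(C)
      V
    },
    ou = {
      core <- -expm1(-2 * theta * C) / (2 * theta)
      if (ou_form == "hansen") {
        d <- outer(diag(C), diag(C), "+") - 2 * C
        core <- core * exp(-theta * d)
      }
      core
    },
    eb = if (theta == 0) C else expm1(theta * C) / theta,
    lambda = {
      V <- theta * C
      diag(V) <- diag(C)
      V
    },
    delta = C^theta,
    kappa = shared_time_matrix(kappa_branch_transform(tree, theta)),
    rate_trend = {
      if (1 + theta * max(diag(C)) / 2 <= 0)
        stop("rate_trend slope makes variance non-positive over the tree depth")
      C + theta * C^2 / 2
    })
}

#' Model mean vector over tips
#'
#' Constant at the root state `z0` for every kind except the mean trend, where
#' each tip expects `z0 + drift * t_ii` with `t_ii` its root-to-tip time.
#'
#' @inheritParams model_vcv
#' @return Named numeric vector in tip order.
#' @export
model_mean <- function(spec, tree, C = NULL) {
  stopifnot(inherits(spec, "evol_model"))
  tips <- tree$tip.label
  if (spec$kind == "mean_trend") {
    if (is_ultrametric(tree))
      stop("mean_trend is unidentifiable on an ultrametric tree: ",
           "all tips share the same elapsed time, so drift and z0 are confounded")
    depths <- if (is.null(C)) node_depths(tree)[seq_along(tips)] else diag(C)
    stats::setNames(spec$z0 + spec$shape * depths, tips)
  } else {
    stats::setNames(rep(spec$z0, length(tips)), tips)
  }
}

#' Simulate trait values under an evolutionary model
#'
#' One (or several) multivariate normal draw(s) with mean [model_mean()] and
#' covariance [model_vcv()].
#'
#' @inheritParams model_vcv
#' @param seed Optional integer seed.
#' @param nsim Number of independent replicate draws.
#' @return For `nsim = 1` a named vector in tip order; otherwise an
#'   `nsim x n_tips` matrix.
#' @export
simulate_traits <- function(spec, tree, seed = NULL, nsim = 1L, C = NULL) {
  V <- model_vcv(spec, tree, C = C)
  mu <- model_mean(spec, tree, C = C)
  n <- length(mu)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    # PSD but singular covariance (e.g. zero-length branches): eigen square root
    e <- eigen(V, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values)))
      stop("model covariance is not positive semidefinite")
    ch <- t(e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors)))
  }
  z <- with_seed(seed, matrix(stats::rnorm(nsim * n), nsim, n))
  x <- sweep(z %*% ch, 2L, mu, "+")
  colnames(x) <- names(mu)
  if (nsim == 1L) x[1L, ] else x
}
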