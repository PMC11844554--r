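#' Arcsine square root transform of a prevalence
#'
#' Variance-stabilizing transform `asin(sqrt(p))` applied to prevalence data
#' before model fitting and regression; monotone from `[0, 1]` onto
#' `[0, pi/2]` (radians).
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @return Transformed value(s) in radians.
#' @export
#' @examples
#' arcsine_sqrt(c(0, 0.5, 1))
arcsine_sqrt <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("prevalence must lie in [0, 1]")
  asin(sqrt(p))
}

#' Inverse arcsine square root transform
#'
#' @param y Value(s) in `[0, pi/2]` (radians).
#' @return Proportion(s) `sin(y)^2`.
#' @export
inv_arcsine_sqrt <- function(y) sin(y)^2

#' Akaike information criterion
#'
#' `2k - 2*loglik`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of fitted parameters (>= 1).
#' @return AIC value.
#' @export
aic <- function(loglik, k) {
  if (k < 1) stop("k must be >= 1")
  2 * k - 2 * loglik
}

#' Multivariate normal log-likelihood
#'
#' `-0.5 * ((x-mu)' V^{-1} (x-mu) + log det V + n log 2 pi)`, evaluated via
#' the Cholesky factor of `V`.
#'
#' @param x Observed vector.
#' @param mean Mean vector.
#' @param V Covariance matrix (symmetric positive definite).
#' @return Log-likelihood scalar.
#' @export
mvn_loglik <- function(x, mean, V) {
  n <- length(x)
  stopifnot(length(mean) == n, all(dim(V) == n))
  ch <- chol_safe(V)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * (sum(z^2) + 2 * sum(log(diag(ch))) + n * log(2 * pi))
}

# GLS profile of the mean coefficients for fixed V (given as Cholesky factor).
# Returns beta, the residual quadratic form r' V^{-1} r and log|V|.
gls_profile <- function(ch, x, X) {
  Xt <- backsolve(ch, X, transpose = TRUE)
  xt <- backsolve(ch, x, transpose = TRUE)
  if (ncol(X) == 1L) {
    xx <- sum(Xt * Xt)
    beta <- sum(Xt * xt) / xx
    r <- xt - Xt * beta
    XtViX <- matrix(xx, 1L, 1L)
  } else {
    beta <- qr.coef(qr(Xt), xt)
    r <- xt - Xt %*% beta
    XtViX <- crossprod(Xt)
  }
  list(beta = drop(beta), qf = sum(r^2), logdet = 2 * sum(log(diag(ch))),
       XtViX = XtViX)
}

# Profile log-likelihood when all measurement SEs are zero: sigma2 has the
# closed-form ML solution qf/n given the unit-rate structure R.
profile_loglik_se0 <- function(x, X, R) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  g <- gls_profile(ch, x, X)
  n <- length(x)
  s2 <- g$qf / n
  if (s2 <= 0) return(list(loglik = Inf, sigma2 = 0, beta = g$beta, degenerate = TRUE))
  ll <- -0.5 * (n * log(2 * pi * s2) + g$logdet + n)
  list(loglik = ll, sigma2 = s2, beta = g$beta, degenerate = FALSE)
}

# Log-likelihood with measurement error: V = sigma2 * R + diag(se2), mean
# coefficients profiled by GLS.
loglik_sey <- function(log_s2, x, X, R, se2) {
  V <- exp(log_s2) * R
  diag(V) <- diag(V) + se2
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  g <- gls_profile(ch, x, X)
  n <- length(x)
  ll <- -0.5 * (g$qf + g$logdet + n * log(2 * pi))
  list(loglik = ll, beta = g$beta, XtViX = g$XtViX, qf = g$qf)
}

# Shape-parameter bounds per model kind; T is the tree height.
shape_bounds <- function(kind, T) {
  switch(kind,
    ou = c(1e-8, 50 / T),
    eb = c(-10 / T, 0),
    lambda = c(0, 1),
    delta = c(1e-5, 3),
    kappa = c(0, 1),
    rate_trend = c(-1.99 / T, 10 / T),
    NULL)
}

# Optimizer parametrization of the shape parameter: positive parameters are
# searched on the log scale (OU pull, delta), the rate-trend slope on a
# shifted log scale away from its singular lower bound. Returns the
# transform, its inverse, the bounds and the start values in search space.
shape_search <- function(kind, T, restarts = 1L) {
  lin <- function(x) x
  s <- switch(kind,
    ou = list(tf = exp, inv = log, lo = log(1e-8), hi = log(50 / T),
              starts = log(c(1, 8, 0.05) / T)),
    eb = list(tf = lin, inv = lin, lo = -10 / T, hi = 0,
              starts = c(-1, -4, -0.1) / T),
    lambda = list(tf = lin, inv = lin, lo = 0, hi = 1,
                  starts = c(0.7, 0.2, 0.95)),
    delta = list(tf = exp, inv = log, lo = log(1e-5), hi = log(3),
                 starts = log(c(1, 0.3, 2.5))),
    kappa = list(tf = lin, inv = lin, lo = 0, hi = 1,
                 starts = c(0.7, 0.2, 0.95)),
    rate_trend = list(tf = function(u) exp(u) - 2 / T,
                      inv = function(th) log(th + 2 / T),
                      lo = log(0.01 / T), hi = log(12 / T),
                      starts = log(c(2, 0.5, 8) / T)))
  s$starts <- s$starts[seq_len(min(max(restarts, 1L), 3L))]
  s
}

#' Fit an evolutionary model to tip data by maximum likelihood
#'
#' Maximizes the multivariate normal likelihood of tip values under the chosen
#' model kind. The root state (and, for the mean trend, the drift) is profiled
#' analytically by generalized least squares at every candidate covariance;
#' with no measurement error the rate `sigma2` also has a closed-form profile,
#' leaving at most a single bounded shape parameter to optimize numerically.
#' Per-species standard errors, when given, are added as `se^2` on the
#' covariance diagonal before likelihood evaluation, and `sigma2` is then
#' optimized jointly with the shape parameter.
#'
#' @param tree A `phylo` tree.
#' @param data Named numeric vector of trait values, or a data frame with
#'   columns `species` and `value` (and optionally `se`).
#' @param kind Model kind (see [evol_model()]).
#' @param se Optional per-species standard errors of the species means (named
#'   vector or taken from the `se` column of `data`); `NULL` or all zero means
#'   values are treated as exact.
#' @param ou_form Ornstein-Uhlenbeck covariance form, see [evol_model()].
#' @param restarts Number of optimizer starts (1-3) over the shape-parameter
#'   search space (only used when measurement error is present).
#' @param control List: `maxit` (default 40) iteration cap for the bounded
#'   quasi-Newton search.
#' @param C Optional precomputed shared-time matrix.
#' @return An object of class `evo_fit`: list with `kind`, `params`
#'   (`sigma2`, `z0`, shape, and `drift` for the mean trend), `loglik`, `k`,
#'   `aic`, `converged`, `degenerate`, `n`.
#' @export
fit_model <- function(tree, data, kind, se = NULL,
                      ou_form = c("rooted", "hansen"),
                      restarts = 3L, control = list(), C = NULL) {
  ou_form <- match.arg(ou_form)
  kinds <- c("bm", "ou", "eb", "lambda", "delta", "kappa",
             "rate_trend", "mean_trend", "white")
  kind <- match.arg(kind, kinds)
  validate_tree(tree)
  if (is.data.frame(data) && is.null(se) && "se" %in% names(data))
    se <- align_to_tips(tree, data, column = "se", what = "standard error")
  x <- align_to_tips(tree, data, column = "value", what = "trait")
  n <- length(x)
  if (n < 3L && model_k(kind) == 3L)
    stop("3-parameter models need at least 3 species")
  if (is.null(se)) se <- rep(0, n)
  if (length(se) == n && !is.null(names(se))) se <- se[tree$tip.label]
  if (any(!is.finite(se)) || any(se < 0)) stop("se must be >= 0")
  se2 <- se^2
  have_se <- any(se2 > 0)
  if (is.null(C)) C <- shared_time_matrix(tree)
  Tht <- max(diag(C))
  maxit <- control$maxit %||% 40L

  # design matrix for the mean: intercept, plus elapsed time for mean_trend
  if (kind == "mean_trend") {
    if (is_ultrametric(tree))
      stop("mean_trend is unidentifiable on an ultrametric tree")
    X <- cbind(z0 = rep(1, n), drift = diag(C))
  } else {
    X <- cbind(z0 = rep(1, n))
  }

  if (stats::var(x) == 0 && !have_se) {
    res <- list(kind = kind, params = list(sigma2 = 0, z0 = x[[1L]]),
                loglik = Inf, k = model_k(kind), aic = -Inf,
                converged = TRUE, degenerate = TRUE, n = n)
    class(res) <- "evo_fit"
    return(res)
  }

  bounds <- shape_bounds(kind, Tht)
  shape_name <- switch(kind, ou = "alpha", eb = "a", lambda = "lambda",
                       delta = "delta", kappa = "kappa", rate_trend = "slope",
                       NA_character_)
  # sigma2 search window on the log scale, anchored at a moment estimate
  s2_anchor <- max((stats::var(x) - mean(se2)) / max(Tht, 1e-12),
                   1e-4 * stats::var(x) / max(Tht, 1e-12), 1e-12)
  ls2_lo <- log(s2_anchor) - 18
  ls2_hi <- log(s2_anchor) + 12

  best <- NULL
  conv <- TRUE

  if (is.na(shape_name) || kind == "mean_trend") {
    # no numeric shape parameter: bm, white, mean_trend
    R <- structure_matrix(kind, NULL, tree, C, ou_form)
    if (!have_se) {
      p <- profile_loglik_se0(x, X, R)
      if (is.null(p)) stop("singular model covariance")
      best <- list(loglik = p$loglik, sigma2 = p$sigma2, beta = p$beta,
                   theta = NULL, degenerate = isTRUE(p$degenerate))
    } else if (kind == "white") {
      f <- function(ls2) {
        v <- exp(ls2) + se2
        w <- 1 / v
        z0 <- sum(w * x) / sum(w)
        -(-0.5 * sum((x - z0)^2 / v + log(v) + log(2 * pi)))
      }
      opt <- stats::optimize(f, c(ls2_lo, ls2_hi), tol = 1e-7)
      v <- exp(opt$minimum) + se2
      z0 <- sum(x / v) / sum(1 / v)
      best <- list(loglik = -opt$objective, sigma2 = exp(opt$minimum),
                   beta = c(z0 = z0), theta = NULL, degenerate = FALSE)
    } else {
      f <- function(ls2) -loglik_sey(ls2, x, X, R, se2)$loglik
      opt <- stats::optimize(f, c(ls2_lo, ls2_hi), tol = 1e-7)
      fit <- loglik_sey(opt$minimum, x, X, R, se2)
      best <- list(loglik = fit$loglik, sigma2 = exp(opt$minimum),
                   beta = fit$beta, theta = NULL, degenerate = FALSE)
    }
  } else if (!have_se) {
    # profile likelihood in the single shape parameter; closed-form sigma2
    f <- function(th) {
      R <- structure_matrix(kind, th, tree, C, ou_form)
      p <- profile_loglik_se0(x, X, R)
      if (is.null(p)) return(1e10)
      -p$loglik
    }
    cand <- seq(bounds[1L], bounds[2L], length.out = 7L)[2:6]
    vals <- vapply(cand, f, numeric(1))
    opt1 <- stats::optimize(f, bounds, tol = 1e-6 * diff(bounds))
    i <- which.min(vals)
    sub <- c(if (i == 1L) bounds[1L] else cand[i - 1L],
             if (i == 5L) bounds[2L] else cand[i + 1L])
    opt2 <- stats::optimize(f, sub, tol = 1e-6 * diff(bounds))
    # boundary values matter for lambda/kappa (0 and 1 can be optimal)
    extra <- c(bounds, cand, opt1$minimum, opt2$minimum)
    vx <- c(f(bounds[1L]), f(bounds[2L]), vals, opt1$objective, opt2$objective)
    th <- extra[which.min(vx)]
    R <- structure_matrix(kind, th, tree, C, ou_form)
    p <- profile_loglik_se0(x, X, R)
    best <- list(loglik = p$loglik, sigma2 = p$sigma2, beta = p$beta,
                 theta = th, degenerate = isTRUE(p$degenerate))
  } else {
    # joint bounded search over (log sigma2, transformed shape), mean profiled
    srch <- shape_search(kind, Tht, restarts)
    negll <- function(par) {
      R <- structure_matrix(kind, srch$tf(par[2L]), tree, C, ou_form)
      ll <- loglik_sey(par[1L], x, X, R, se2)$loglik
      if (!is.finite(ll)) 1e10 else -ll
    }
    best_val <- Inf; best_par <- NULL; conv <- FALSE
    for (u0 in srch$starts) {
      o <- tryCatch(
        stats::nlminb(c(log(s2_anchor), u0), negll,
                      lower = c(ls2_lo, srch$lo), upper = c(ls2_hi, srch$hi),
                      control = list(rel.tol = 1e-7, iter.max = maxit,
                                     eval.max = 3L * maxit)),
        error = function(e) NULL)
      if (!is.null(o) && o$objective < best_val) {
        best_val <- o$objective; best_par <- o$par
        conv <- conv || o$convergence == 0L
      }
    }
    if (is.null(best_par)) stop("model fit failed to converge after restarts")
    theta <- srch$tf(best_par[2L])
    R <- structure_matrix(kind, theta, tree, C, ou_form)
    fit <- loglik_sey(best_par[1L], x, X, R, se2)
    best <- list(loglik = fit$loglik, sigma2 = exp(best_par[1L]),
                 beta = fit$beta, theta = theta, degenerate = FALSE)
  }

  params <- list(sigma2 = unname(best$sigma2), z0 = unname(best$beta[1L]))
  if (kind == "mean_trend") params$drift <- unname(best$beta[2L])
  if (!is.na(shape_name) && kind != "mean_trend")
    params[[shape_name]] <- unname(best$theta)
  k <- model_k(kind)
  res <- list(kind = kind, params = params, loglik = best$loglik, k = k,
              aic = aic(best$loglik, k), converged = conv,
              degenerate = isTRUE(best$degenerate), n = n, ou_form = ou_form)
  class(res) <- "evo_fit"
  res
}

#' Fit several model kinds to the same data
#'
#' @inheritParams fit_model
#' @param kinds Character vector of model kinds.
#' @return Named list of `evo_fit` objects (failed fits are dropped with a
#'   warning).
#' @export
fit_all_models <- function(tree, data, kinds = c("bm", "ou", "eb", "lambda",
                                                 "delta", "kappa",
                                                 "rate_trend", "white"),
                           se = NULL, ...) {
  fits <- lapply(kinds, function(k) {
    tryCatch(fit_model(tree, data, k, se = se, ...),
             error = function(e) {
               warning(sprintf("fit of '%s' failed: %s", k, conditionMessage(e)))
               NULL
             })
  })
  names(fits) <- kinds
  Filter(Negate(is.null), fits)
}

#' @export
print.evo_fit <- function(x, ...) {
  cat(sprintf("ML fit of '%s' model (n = %d)\n", x$kind, x$n))
  cat("  params:", paste(sprintf("%s = %.5g", names(x$params),
                                 unlist(x$params)), collapse = ", "), "\n")
  cat(sprintf("  loglik = %.4f, k = %d, AIC = %.4f%s\n", x$loglik, x$k, x$aic,
              if (x$degenerate) "  [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Turn an `evo_fit` into an `evol_model` specification
#'
#' @param fit An `evo_fit`.
#' @return The corresponding [evol_model()] with fitted parameters.
#' @export
as_evol_model <- function(fit) {
  stopifnot(inherits(fit, "evo_fit"))
  p <- fit$params
  args <- list(kind = fit$kind,
               sigma2 = max(p$sigma2, 1e-12), z0 = p$z0,
               ou_form = fit$ou_form %||% "rooted")
  shape_name <- setdiff(names(p), c("sigma2", "z0"))
  if (length(shape_name)) args[[shape_name]] <- p[[shape_name]]
  do.call(evol_model, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
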