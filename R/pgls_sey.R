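#' Sampling standard error of a prevalence on the arcsine scale
#'
#' Delta-method standard error of `asin(sqrt(phat))` for a binomial proportion
#' estimated from `n` records: `1/(2*sqrt(n))`, independent of the proportion
#' itself (the variance-stabilizing property of the transform).
#'
#' @param p Proportion(s) in `[0, 1]` (validated; the result does not depend
#'   on `p`).
#' @param n Record count(s), >= 1.
#' @return Standard error(s) on the arcsine scale (radians).
#' @export
#' @examples
#' prevalence_se(0.3, 25)  # 0.1
prevalence_se <- function(p, n) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("prevalence must lie in [0, 1]")
  if (any(!is.finite(n)) || any(n < 1)) stop("record count must be >= 1")
  rep_len(1 / (2 * sqrt(n)), max(length(p), length(n)))
}

# Align and validate the regression data; returns list(x, y, se_y) in tip order.
regression_data <- function(tree, data) {
  stopifnot(is.data.frame(data))
  need <- c("species", "x", "y")
  if (!all(need %in% names(data)))
    stop("regression data needs columns species, x, y (and optionally se_y)")
  x <- align_to_tips(tree, data, column = "x", what = "predictor")
  y <- align_to_tips(tree, data, column = "y", what = "response")
  se_y <- if ("se_y" %in% names(data))
    align_to_tips(tree, data, column = "se_y", what = "se_y")
  else stats::setNames(rep(0, length(y)), names(y))
  if (any(se_y < 0)) stop("se_y must be >= 0")
  if (length(y) < 3L) stop("need at least 3 species")
  list(x = x, y = y, se_y = se_y)
}

#' Phylogenetic regression with measurement error on the response
#'
#' Generalized least squares regression of `y` on `x` whose residual
#' covariance is `sigma2 * R + diag(se_y^2)`, with `R` the unit-rate
#' variance-covariance structure of a chosen evolutionary model and `se_y` the
#' per-species sampling error of the response (for a prevalence estimated from
#' `n` records, `1/(2*sqrt(n))` on the arcsine scale, see [prevalence_se()]).
#' `sigma2` is estimated by maximum likelihood (bounded scalar search with the
#' coefficients profiled analytically); slope and intercept tests are
#' two-sided Student-t on `n - 2` degrees of freedom.
#'
#' @param tree A `phylo` tree.
#' @param data Data frame with columns `species`, `x`, `y` and optionally
#'   `se_y` (default 0).
#' @param spec An [evol_model()] giving the residual covariance structure with
#'   its shape parameter fixed; its `sigma2` is ignored (re-estimated).
#'   Default Brownian motion.
#' @return Object of class `pgls_fit`: `coefficients` (estimate, SE, t, p),
#'   `sigma2`, `kind`, `shape`, `df`, `loglik`, `n`, `degenerate`.
#' @export
pgls_sey <- function(tree, data, spec = evol_model("bm")) {
  validate_tree(tree)
  stopifnot(inherits(spec, "evol_model"))
  d <- regression_data(tree, data)
  n <- length(d$y)
  X <- cbind(`(Intercept)` = rep(1, n), x = d$x)
  if (qr(X)$rank < 2L) stop("constant predictor: design matrix is rank deficient")
  unit <- spec
  unit$sigma2 <- 1
  R <- suppressWarnings(model_vcv(unit, tree))
  se2 <- d$se_y^2

  # ML for sigma2 on the log scale; coefficients profiled at each value
  sy <- stats::var(d$y)
  anchor <- max(sy / max(diag(R)), 1e-12)
  f <- function(ls2) {
    ll <- loglik_sey(ls2, d$y, X, R, se2)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  lo <- log(anchor) - 30
  hi <- log(anchor) + 12
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-7)
  s2 <- exp(opt$minimum)
  degenerate <- opt$minimum < lo + 1e-6  # sigma2 driven to the boundary
  if (degenerate && all(se2 == 0)) {
    # perfect linear fit: residual variance collapses to zero
    s2 <- 0
  }
  V <- s2 * R
  diag(V) <- diag(V) + se2
  if (all(se2 == 0) && s2 == 0) {
    # degenerate: report OLS coefficients with zero residual variance
    beta <- qr.coef(qr(X), d$y)
    co <- cbind(Estimate = beta, `Std. Error` = 0, `t value` = Inf,
                `Pr(>|t|)` = 0)
    res <- list(coefficients = co, sigma2 = 0, kind = spec$kind,
                shape = spec$shape, df = n - 2L, loglik = Inf, n = n,
                degenerate = TRUE)
    class(res) <- "pgls_fit"
    return(res)
  }
  ch <- chol_safe(V)
  g <- gls_profile(ch, d$y, X)
  covb <- solve(g$XtViX)
  se_b <- sqrt(diag(covb))
  tval <- g$beta / se_b
  df <- n - 2L
  pval <- 2 * stats::pt(-abs(tval), df = df)
  ll <- -0.5 * (g$qf + g$logdet + n * log(2 * pi))
  co <- cbind(Estimate = g$beta, `Std. Error` = se_b, `t value` = tval,
              `Pr(>|t|)` = pval)
  rownames(co) <- colnames(X)
  res <- list(coefficients = co, sigma2 = s2, kind = spec$kind,
              shape = spec$shape, df = df, loglik = ll, n = n,
              degenerate = degenerate)
  class(res) <- "pgls_fit"
  res
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic GLS with measurement error (model '%s'%s)\n",
              x$kind,
              if (!is.null(x$shape) && !is.na(x$shape %||% NA))
                sprintf(", shape = %.4g", x$shape) else ""))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("sigma2 = %.5g, df = %d, n = %d%s\n", x$sigma2, x$df, x$n,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Phylogenetic regression under the best-fitting evolutionary model
#'
#' Two-step regression: (1) every candidate model kind is fit by maximum
#' likelihood to the *response* (with its measurement error), and the kind
#' with the lowest AIC is selected; (2) [pgls_sey()] is run with the selected
#' kind and its fitted shape parameter held fixed, so the covariance structure
#' used for trend estimation is the one the response data itself supports.
#'
#' @inheritParams pgls_sey
#' @param candidates Model kinds to consider for the response (default:
#'   Brownian motion, Ornstein-Uhlenbeck, Pagel's lambda, delta and kappa,
#'   white noise and the rate trend).
#' @param decisive_threshold If non-`NULL`, the lowest-AIC kind is only kept
#'   when it wins by at least this many AIC points; otherwise Brownian motion
#'   is used. Default `NULL`: plain lowest-AIC selection.
#' @param restarts,control Passed to [fit_model()].
#' @return A `pgls_fit` with additional fields `selected_kind`, `fits_aic`
#'   (named AIC vector of the candidate fits).
#' @export
pgls_sey_optim <- function(tree, data,
                           candidates = c("bm", "ou", "lambda", "delta",
                                          "kappa", "white", "rate_trend"),
                           decisive_threshold = NULL,
                           restarts = 1L, control = list()) {
  validate_tree(tree)
  d <- regression_data(tree, data)
  C <- shared_time_matrix(tree)
  fits <- suppressWarnings(
    fit_all_models(tree, d$y, kinds = candidates, se = d$se_y,
                   restarts = restarts, control = control, C = C))
  if (!length(fits)) {
    warning("all candidate fits failed; falling back to Brownian motion")
    spec <- evol_model("bm")
    sel <- "bm"
    aics <- NULL
  } else if (length(fits) == 1L) {
    sel <- names(fits)
    spec <- as_evol_model(fits[[1L]])
    aics <- stats::setNames(fits[[1L]]$aic, sel)
  } else {
    bm <- best_model(fits, threshold = decisive_threshold %||% 10)
    sel <- if (!is.null(decisive_threshold) && !bm$decisive) "bm" else bm$kind
    aics <- bm$aic
    spec <- if (sel %in% names(fits)) as_evol_model(fits[[sel]]) else evol_model("bm")
  }
  out <- pgls_sey(tree, data, spec = spec)
  out$selected_kind <- sel
  out$fits_aic <- aics
  out
}
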