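#' Pick the best-fitting evolutionary model by AIC
#'
#' Compares a set of fits of different model kinds to the same data. The model
#' with the lowest AIC wins; the win is *decisive* only when the runner-up AIC
#' is at least `threshold` points higher (default 10). A gap below the
#' threshold is weak evidence, and the comparison is reported as not decisive.
#' Exact ties (below 1e-9) report all tied kinds and are never decisive.
#'
#' @param fits Named list of `evo_fit` objects (at least 2), all fitted to the
#'   same data.
#' @param threshold AIC-gap required for a decisive win (default 10; the
#'   boundary counts as decisive).
#' @return List with `kind`, `decisive`, `delta_aic` (gap to the runner-up),
#'   `aic` (named vector of all AICs), and `tied_with` (character vector,
#'   usually empty).
#' @export
best_model <- function(fits, threshold = 10) {
  if (length(fits) < 2L) stop("need at least 2 model fits to compare")
  ok <- vapply(fits, function(f) inherits(f, "evo_fit"), logical(1))
  if (!all(ok)) stop("fits must be 'evo_fit' objects")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L) stop("fits compare different data sizes")
  ord <- order(aics)
  best_aic <- aics[[ord[1L]]]
  delta <- aics[[ord[2L]]] - best_aic
  tied <- names(aics)[abs(aics - best_aic) < 1e-9]
  tied_with <- setdiff(tied, names(aics)[ord[1L]])
  list(kind = names(aics)[ord[1L]],
       decisive = (delta >= threshold) && length(tied_with) == 0L,
       delta_aic = delta,
       aic = aics,
       tied_with = tied_with)
}

#' Hierarchical clade-level model assignment
#'
#' Implements the parent-inheritance rule for clade-level model choice: every
#' candidate model is refit on each clade's pruned subtree, and a clade keeps
#' its own best-fit kind only when that fit is decisive (AIC at least
#' `threshold` points below the runner-up). Otherwise the clade inherits the
#' model assigned to its parent grouping, keeping model assumptions consistent
#' unless a group demonstrates a significant deviation in fit. Clades smaller
#' than `min_size` species are not refit and inherit directly.
#'
#' @param tree A `phylo` tree.
#' @param data Trait values (named vector or data frame, see [fit_model()]).
#' @param clades Data frame with columns `species` and `clade` partitioning
#'   the tips, or a named character vector of clade labels.
#' @param parent_kind Model kind of the parent grouping. `NULL` (default)
#'   first fits all candidates to the full tree and uses the overall best-fit
#'   kind as the parent.
#' @param candidates Model kinds to consider. Defaults to all kinds except the
#'   mean trend when the tree is ultrametric.
#' @param threshold Decisiveness threshold in AIC points (default 10).
#' @param min_size Minimum clade size for a clade-level refit (default 10).
#' @param se Optional per-species standard errors.
#' @param ... Passed to [fit_model()].
#' @return Data frame with one row per clade: `clade`, `n_species`, `kind`,
#'   `decisive`, `delta_aic`, `inherited`.
#' @export
hierarchical_assignment <- function(tree, data, clades, parent_kind = NULL,
                                    candidates = NULL, threshold = 10,
                                    min_size = 10L, se = NULL, ...) {
  validate_tree(tree)
  if (is.data.frame(clades)) {
    if (!all(c("species", "clade") %in% names(clades)))
      stop("clades data frame needs 'species' and 'clade' columns")
    cl <- stats::setNames(as.character(clades$clade),
                          trimws(as.character(clades$species)))
  } else cl <- clades
  missing <- setdiff(tree$tip.label, names(cl))
  if (length(missing))
    stop("clade map does not cover all tips: ", paste(utils::head(missing, 5), collapse = ", "))
  cl <- cl[tree$tip.label]
  if (is.null(candidates)) {
    candidates <- c("bm", "ou", "eb", "lambda", "delta", "kappa",
                    "rate_trend", "white")
    if (!is_ultrametric(tree)) candidates <- c(candidates, "mean_trend")
  }
  x <- align_to_tips(tree, data, what = "trait")
  if (is.data.frame(data) && is.null(se) && "se" %in% names(data))
    se <- align_to_tips(tree, data, column = "se", what = "standard error")

  if (is.null(parent_kind)) {
    overall <- fit_all_models(tree, x, kinds = candidates, se = se, ...)
    parent_kind <- best_model(overall, threshold = threshold)$kind
  }

  groups <- split(names(cl), cl)
  rows <- lapply(names(groups), function(g) {
    sp <- groups[[g]]
    if (length(sp) < min_size) {
      message(sprintf("clade '%s' has %d species (< %d): inheriting '%s'",
                      g, length(sp), min_size, parent_kind))
      return(data.frame(clade = g, n_species = length(sp), kind = parent_kind,
                        decisive = FALSE, delta_aic = NA_real_,
                        inherited = TRUE))
    }
    sub <- prune_to(tree, sp)
    fits <- fit_all_models(sub, x[sp], kinds = candidates,
                           se = if (is.null(se)) NULL else se[sp], ...)
    bm <- best_model(fits, threshold = threshold)
    data.frame(clade = g, n_species = length(sp),
               kind = if (bm$decisive) bm$kind else parent_kind,
               decisive = bm$decisive, delta_aic = bm$delta_aic,
               inherited = !bm$decisive)
  })
  out <- do.call(rbind, rows)
  attr(out, "parent_kind") <- parent_kind
  out
}
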