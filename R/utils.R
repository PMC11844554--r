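#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's RNG
#' state so that seeded helpers do not perturb an enclosing simulation stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Draw a block of sub-seeds (< 2^31) from one stream, used to split a master
# seed across cells/trials reproducibly.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

#' Align a per-species vector to the tip order of a tree
#'
#' Values are matched by species label, never by position.
#'
#' @param tree A `phylo` tree.
#' @param values Named numeric vector, or a data frame with a `species` column
#'   plus the column named in `column`.
#' @param column Column to extract when `values` is a data frame.
#' @param what Label used in error messages.
#' @return Numeric vector ordered as `tree$tip.label`, with names.
#' @keywords internal
align_to_tips <- function(tree, values, column = "value", what = "trait") {
  if (is.data.frame(values)) {
    if (!"species" %in% names(values))
      stop("data frame must have a 'species' column")
    if (!column %in% names(values))
      stop(sprintf("data frame must have a '%s' column", column))
    v <- values[[column]]
    names(v) <- trimws(as.character(values$species))
    values <- v
  }
  if (is.null(names(values)))
    stop(sprintf("%s values must be named by species", what))
  names(values) <- trimws(names(values))
  missing <- setdiff(tree$tip.label, names(values))
  if (length(missing))
    stop(sprintf("no %s value for species: %s", what,
                 paste(utils::head(missing, 5L), collapse = ", ")))
  out <- values[tree$tip.label]
  if (any(!is.finite(out)))
    stop(sprintf("non-finite %s values", what))
  out
}

# Stable log-determinant and quadratic forms from a Cholesky factor.
chol_safe <- function(V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) stop("covariance matrix is not positive definite")
  ch
}
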