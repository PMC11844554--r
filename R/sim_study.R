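#' Configuration of the method-comparison simulation grid
#'
#' Defines the Monte-Carlo grid used to compare false-positive and
#' false-negative rates of the binomial GEE, the Brownian-motion
#' measurement-error PGLS and the model-selection-aware PGLS. Each grid cell
#' is a combination of species count, minimum record threshold and generating
#' model (three trait-evolution models for trend cells plus a null with
#' independent variables); every cell is replicated `reps` times.
#'
#' @param n_species Species counts (default `c(50, 150, 350)`).
#' @param min_records Minimum records per species (default `c(1, 5, 10, 20)`).
#' @param gen_models Generating models for trend cells plus `"null"`
#'   (default `c("bm", "ou", "lambda", "null")`).
#' @param reps Replicates per cell (default 100).
#' @param slope_range Uniform range the trend slope is drawn from
#'   (default `c(-2, 2)`).
#' @param tau Standard deviation of the independent noise added to the linear
#'   relationship before squashing (default 0.05, on the unit-rate trait
#'   scale).
#' @param nb_mean,nb_size Negative-binomial mean and dispersion of the
#'   per-species record counts (defaults 15 and 0.8: a heavy right tail
#'   resembling zoological record databases).
#' @param ou_alpha Pull strength used when the generating model is `"ou"`
#'   (default 2 on height-1 trees).
#' @param lambda_gen Signal used when the generating model is `"lambda"`
#'   (default 0.5, an intermediate signal).
#' @param seed Master seed splitting into per-trial seeds.
#' @param binomial_draw If `TRUE`, occurrence counts are binomial draws from
#'   the latent prevalence; default `FALSE` rounds `prevalence * records`
#'   deterministically, so occurrences derive from the same data the
#'   regression methods see.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_species = c(50L, 150L, 350L),
                       min_records = c(1L, 5L, 10L, 20L),
                       gen_models = c("bm", "ou", "lambda", "null"),
                       reps = 100L,
                       slope_range = c(-2, 2),
                       tau = 0.05,
                       nb_mean = 15, nb_size = 0.8,
                       ou_alpha = 2, lambda_gen = 0.5,
                       seed = 1L,
                       binomial_draw = FALSE) {
  stopifnot(all(n_species >= 4), all(min_records >= 1), reps >= 1,
            tau > 0, nb_mean > 0, nb_size > 0,
            length(slope_range) == 2L, slope_range[1] < slope_range[2])
  gen_models <- match.arg(gen_models, c("bm", "ou", "lambda", "null"),
                          several.ok = TRUE)
  structure(list(n_species = as.integer(n_species),
                 min_records = as.integer(min_records),
                 gen_models = gen_models, reps = as.integer(reps),
                 slope_range = slope_range, tau = tau,
                 nb_mean = nb_mean, nb_size = nb_size,
                 ou_alpha = ou_alpha, lambda_gen = lambda_gen,
                 seed = as.integer(seed),
                 binomial_draw = isTRUE(binomial_draw)),
            class = "sim_config")
}

#' Simulate per-species record counts
#'
#' Independent negative-binomial draws (mean `m`, dispersion `r`),
#' rejection-resampled until every species has at least `min_records` records
#' - the truncated distribution that mimics zoological databases where each
#' included species clears a minimum-evidence bar.
#'
#' @param n_species Number of species.
#' @param min_records Minimum records per species.
#' @param m,r Negative-binomial mean and dispersion (size).
#' @param seed Optional integer seed.
#' @return Integer vector of length `n_species`, all `>= min_records`.
#' @export
sample_records <- function(n_species, min_records, m = 15, r = 0.8,
                           seed = NULL) {
  stopifnot(n_species >= 1, min_records >= 1, m > 0, r > 0)
  p_acc <- 1 - stats::pnbinom(min_records - 1, size = r, mu = m)
  if (p_acc < 1e-6)
    stop("record threshold is essentially unreachable under these parameters")
  with_seed(seed, {
    out <- stats::rnbinom(n_species, size = r, mu = m)
    bad <- which(out < min_records)
    while (length(bad)) {
      out[bad] <- stats::rnbinom(length(bad), size = r, mu = m)
      bad <- bad[out[bad] < min_records]
    }
    out
  })
}

# Rank-preserving affine map of a raw trait onto the valid arcsine-scale
# interval, kept away from the 0/1 prevalence boundaries.
squash_to_arcsine <- function(y_raw, lo = 0.02, hi = pi / 2 - 0.02) {
  rng <- range(y_raw)
  if (diff(rng) == 0) return(rep((lo + hi) / 2, length(y_raw)))
  lo + (y_raw - rng[1L]) / diff(rng) * (hi - lo)
}

#' Simulate one trial of the method-comparison study
#'
#' Draws a pure-birth tree, per-species record counts, a predictor and a
#' prevalence-type response, and (optionally) runs the three regression
#' methods on the same dataset. In trend cells the predictor evolves under the
#' generating model (unit rate) and the response follows
#' `slope * x + noise` with `slope ~ U(slope_range)`; the raw response is
#' squashed onto the arcsine scale, converted to a prevalence, and realized as
#' `round(prevalence * records)` occurrences. In the null cell predictor and
#' response are independent standard normals pushed through the same pipeline.
#' The regression methods observe the arcsine-transformed occurrence
#' proportion with its sampling error `1/(2*sqrt(records))`.
#'
#' @param config A [sim_config()].
#' @param n_species,min_records,gen_model The cell coordinates.
#' @param seed Trial seed (drives tree, records, traits and noise).
#' @param run_methods If `TRUE` (default) also compute the regression
#'   methods' slope p-values.
#' @param methods Which methods to run: any of `"gee"`, `"pgls_bm"`,
#'   `"pgls_optim"`.
#' @return List with the dataset (`tree`, `x`, `prevalence`, `records`,
#'   `occurrences`, `y_obs`, `se_y`, `slope`) and, when requested, `p_values`
#'   (named: `gee`, `pgls_bm`, `pgls_optim`), `selected_kind`, `failures`.
#' @export
simulate_trial <- function(config, n_species, min_records, gen_model,
                           seed = NULL, run_methods = TRUE,
                           methods = c("gee", "pgls_bm", "pgls_optim")) {
  stopifnot(inherits(config, "sim_config"))
  gen_model <- match.arg(gen_model, c("bm", "ou", "lambda", "null"))
  dat <- with_seed(seed, {
    tree <- simulate_pure_birth(n_species)
    records <- sample_records(n_species, min_records,
                              m = config$nb_mean, r = config$nb_size)
    if (gen_model == "null") {
      x <- stats::setNames(stats::rnorm(n_species), tree$tip.label)
      y_raw <- stats::rnorm(n_species)
      slope <- NA_real_
    } else {
      spec <- switch(gen_model,
        bm = evol_model("bm"),
        ou = evol_model("ou", alpha = config$ou_alpha),
        lambda = evol_model("lambda", lambda = config$lambda_gen))
      x <- simulate_traits(spec, tree)
      slope <- stats::runif(1L, config$slope_range[1L], config$slope_range[2L])
      y_raw <- slope * x + stats::rnorm(n_species, sd = config$tau)
    }
    y_true <- squash_to_arcsine(y_raw)
    prevalence <- inv_arcsine_sqrt(y_true)
    occurrences <- if (config$binomial_draw)
      stats::rbinom(n_species, records, prevalence)
    else as.integer(round(prevalence * records))
    list(tree = tree, x = x, records = records, slope = slope,
         gen_model = gen_model, prevalence = prevalence,
         occurrences = occurrences,
         y_obs = arcsine_sqrt(occurrences / records),
         se_y = prevalence_se(prevalence, records))
  })
  if (run_methods) dat <- c(dat, run_trial_methods(dat, methods = methods))
  dat
}

# Run the three regression methods on one simulated dataset; p-values of the
# slope term, with per-method failures recorded rather than fatal.
run_trial_methods <- function(dat, methods = c("gee", "pgls_bm",
                                               "pgls_optim")) {
  tips <- dat$tree$tip.label
  reg <- data.frame(species = tips, x = dat$x, y = dat$y_obs, se_y = dat$se_y)
  cnt <- data.frame(species = tips, occurrences = dat$occurrences,
                    trials = dat$records, x = dat$x)
  p <- stats::setNames(rep(NA_real_, length(methods)), methods)
  failures <- character(0)
  sel <- NA_character_
  if ("gee" %in% methods) {
    f <- tryCatch(suppressWarnings(gee_binomial(dat$tree, cnt)),
                  error = function(e) e)
    if (inherits(f, "gee_fit")) p["gee"] <- f$coefficients["x", "Pr(>|t|)"]
    else failures <- c(failures, paste0("gee: ", conditionMessage(f)))
  }
  if ("pgls_bm" %in% methods) {
    f <- tryCatch(pgls_sey(dat$tree, reg), error = function(e) e)
    if (inherits(f, "pgls_fit"))
      p["pgls_bm"] <- f$coefficients["x", "Pr(>|t|)"]
    else failures <- c(failures, paste0("pgls_bm: ", conditionMessage(f)))
  }
  if ("pgls_optim" %in% methods) {
    f <- tryCatch(pgls_sey_optim(dat$tree, reg), error = function(e) e)
    if (inherits(f, "pgls_fit")) {
      p["pgls_optim"] <- f$coefficients["x", "Pr(>|t|)"]
      sel <- f$selected_kind
    } else failures <- c(failures, paste0("pgls_optim: ", conditionMessage(f)))
  }
  list(p_values = p, selected_kind = sel, failures = failures)
}

#' Run the full simulation grid
#'
#' Executes every (n_species, min_records, generating model) cell of the
#' configuration with `reps` trials each, scoring a false positive when a
#' null-cell p-value falls below 0.05 and a false negative when a trend-cell
#' p-value exceeds 0.05. Per-trial seeds are split deterministically from the
#' master seed, so the whole grid is reproducible bitwise.
#'
#' @param config A [sim_config()].
#' @param alpha Significance threshold (default 0.05).
#' @param methods Which methods to run (default all three).
#' @param verbose Print per-cell progress messages.
#' @return Data frame of class `error_rate_table`: one row per (cell, method)
#'   with `error_type` (`fp`/`fn`), `error_rate`, `n_ok`, `n_fail`, `mc_se`.
#' @export
run_grid <- function(config, alpha = 0.05,
                     methods = c("gee", "pgls_bm", "pgls_optim"),
                     verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  cells <- expand.grid(n_species = config$n_species,
                       min_records = config$min_records,
                       gen_model = config$gen_models,
                       stringsAsFactors = FALSE)
  n_cells <- nrow(cells)
  seeds <- matrix(derive_seeds(config$seed, n_cells * config$reps),
                  nrow = n_cells)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cell <- cells[i, ]
    is_null <- cell$gen_model == "null"
    pmat <- matrix(NA_real_, config$reps, length(methods),
                   dimnames = list(NULL, methods))
    nfail <- 0L
    for (r in seq_len(config$reps)) {
      tr <- simulate_trial(config, cell$n_species, cell$min_records,
                           cell$gen_model, seed = seeds[i, r],
                           methods = methods)
      pmat[r, ] <- tr$p_values
      nfail <- nfail + length(tr$failures)
    }
    err <- if (is_null) pmat < alpha else pmat > alpha
    n_ok <- colSums(!is.na(err))
    rate <- colMeans(err, na.rm = TRUE)
    rows[[i]] <- data.frame(
      n_species = cell$n_species, min_records = cell$min_records,
      gen_model = cell$gen_model, method = methods,
      error_type = if (is_null) "fp" else "fn",
      error_rate = rate, n_ok = n_ok,
      n_fail = config$reps - n_ok,
      mc_se = sqrt(rate * (1 - rate) / pmax(n_ok, 1L)),
      row.names = NULL)
    if (verbose)
      message(sprintf("[%d/%d] n=%d min=%d %s: %s", i, n_cells,
                      cell$n_species, cell$min_records, cell$gen_model,
                      paste(sprintf("%s=%.3f", methods, rate), collapse = " ")))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("error_rate_table", "data.frame")
  attr(out, "config") <- config
  attr(out, "alpha") <- alpha
  out
}

#' Grand mean error rate per method
#'
#' Unweighted mean of the per-cell error rates (false positives on null cells
#' pooled with false negatives on trend cells) for each method across all
#' cells of the grid.
#'
#' @param rates An `error_rate_table` from [run_grid()].
#' @return Named numeric vector of grand mean error rates (proportions).
#' @export
summarize_average_error <- function(rates) {
  stopifnot(is.data.frame(rates))
  need <- c("method", "error_rate", "n_species", "min_records", "gen_model")
  if (!all(need %in% names(rates))) stop("not an error-rate table")
  if (anyNA(rates$error_rate)) stop("missing cells in the error-rate table")
  key <- interaction(rates$n_species, rates$min_records, rates$gen_model,
                     drop = TRUE)
  per_method <- tapply(as.character(key), rates$method,
                       function(k) sort(unique(k)))
  all_cells <- sort(unique(as.character(key)))
  if (!all(vapply(per_method, identical, logical(1), all_cells)))
    stop("incomplete grid: some methods are missing cells")
  m <- tapply(rates$error_rate, rates$method, mean)
  m[unique(rates$method)]
}
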