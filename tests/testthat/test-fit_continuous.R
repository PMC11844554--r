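test_that("arcsine square root transform and AIC behave as defined", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2)
  expect_equal(arcsine_sqrt(0.5), pi / 4)
  expect_equal(inv_arcsine_sqrt(arcsine_sqrt(0.3)), 0.3)
  expect_error(arcsine_sqrt(1.1), "\\[0, 1\\]")
  expect_error(arcsine_sqrt(-0.1), "\\[0, 1\\]")
  expect_equal(aic(0, 2), 4)
  expect_equal(aic(-10, 3), 26)
  expect_error(aic(0, 0), "k")
})

test_that("multivariate normal log-likelihood matches closed forms", {
  expect_equal(mvn_loglik(0, 0, matrix(1)), -0.5 * log(2 * pi))
  expect_equal(mvn_loglik(c(1, 3), c(2, 2), diag(2)), -log(2 * pi) - 1)
  expect_error(mvn_loglik(c(1, 2), c(0, 0), matrix(c(1, 1, 1, 1), 2)),
               "positive definite")
})

test_that("Brownian likelihood agrees with the pruning-algorithm oracle", {
  for (seed in 1:4) {
    tr <- random_test_tree(10, seed = seed)
    x <- simulate_traits(evol_model("bm", z0 = 1), tr, seed = seed + 50)
    V <- model_vcv(evol_model("bm", sigma2 = 0.7), tr)
    mu <- model_mean(evol_model("bm", sigma2 = 0.7, z0 = 0.3), tr)
    expect_equal(mvn_loglik(x, mu, V),
                 oracle_bm_loglik(tr, x, z0 = 0.3, sigma2 = 0.7),
                 tolerance = 1e-8)
  }
})

test_that("white and Brownian fits recover closed-form ML solutions", {
  tr2 <- read_newick("(A:1,B:1);")
  x <- c(A = 1, B = 3)
  f <- fit_model(tr2, x, "white")
  expect_equal(f$params$z0, 2)
  expect_equal(f$params$sigma2, 1)  # ML with n in the denominator
  expect_equal(f$loglik, -log(2 * pi) - 1, tolerance = 1e-9)
  expect_equal(f$aic, aic(f$loglik, 2), tolerance = 1e-9)

  fb <- fit_model(tr2, c(A = 0, B = 2), "bm")
  expect_equal(fb$params$z0, 1)
  expect_equal(fb$params$sigma2, 1)  # two independent unit-time increments
})

test_that("all-equal trait values are flagged degenerate", {
  tr <- simulate_pure_birth(8, seed = 2)
  f <- fit_model(tr, stats::setNames(rep(0.3, 8), tr$tip.label), "bm")
  expect_true(f$degenerate)
  expect_equal(f$params$sigma2, 0)
})

test_that("fitted likelihood beats random admissible parameters", {
  tr <- simulate_pure_birth(40, seed = 6)
  x <- simulate_traits(evol_model("lambda", lambda = 0.6), tr, seed = 7)
  C <- shared_time_matrix(tr)
  draws <- list(
    bm = function() list(),
    ou = function() list(alpha = runif(1, 0.01, 40)),
    eb = function() list(a = -runif(1, 0.01, 8)),
    lambda = function() list(lambda = runif(1)),
    delta = function() list(delta = runif(1, 0.05, 3)),
    kappa = function() list(kappa = runif(1)),
    rate_trend = function() list(slope = runif(1, -1.8, 8)),
    white = function() list()
  )
  with_seed2(99, {
    for (kind in names(draws)) {
      fit <- fit_model(tr, x, kind, C = C)
      for (i in 1:20) {
        pars <- draws[[kind]]()
        spec <- do.call(evol_model,
                        c(list(kind = kind,
                               sigma2 = runif(1, 0.05, 5),
                               z0 = rnorm(1)), pars))
        ll <- tryCatch(
          mvn_loglik(x, model_mean(spec, tr), model_vcv(spec, tr, C = C)),
          error = function(e) -Inf)  # numerically singular draw
        expect_gte(fit$loglik, ll - 1e-6)
      }
    }
  })
})

test_that("fits are invariant to tip reordering and zero SEs", {
  tr <- simulate_pure_birth(20, seed = 12)
  x <- simulate_traits(evol_model("bm"), tr, seed = 13)
  f1 <- fit_model(tr, x, "lambda")
  f2 <- fit_model(tr, x[rev(names(x))], "lambda")
  expect_equal(f1$aic, f2$aic)
  expect_equal(f1$params, f2$params)

  f3 <- fit_model(tr, x, "lambda", se = stats::setNames(rep(0, 20), names(x)))
  expect_equal(f3$loglik, f1$loglik, tolerance = 1e-10)
  expect_equal(f3$params$lambda, f1$params$lambda, tolerance = 1e-6)
})

test_that("lambda fitted to Brownian data approaches 1 on large trees", {
  tr <- simulate_pure_birth(300, seed = 21)
  x <- simulate_traits(evol_model("bm"), tr, seed = 22)
  fl <- fit_model(tr, x, "lambda")
  fb <- fit_model(tr, x, "bm")
  expect_gt(fl$params$lambda, 0.9)
  # at the lambda = 1 boundary the AIC gap is 2 plus half a chi-square
  expect_lte(fb$aic - fl$aic, 3)
})

test_that("measurement error enters the likelihood as an SE^2 diagonal", {
  tr <- simulate_pure_birth(15, seed = 31)
  x <- simulate_traits(evol_model("bm"), tr, seed = 32)
  se <- stats::setNames(rep(0.3, 15), names(x))
  f <- fit_model(tr, x, "bm", se = se)
  V <- f$params$sigma2 * shared_time_matrix(tr) + diag(0.3^2, 15)
  mu <- stats::setNames(rep(f$params$z0, 15), names(x))
  expect_equal(f$loglik, mvn_loglik(x, mu, V), tolerance = 1e-6)
  # the optimum cannot beat a fine profile over sigma2
  grid <- exp(seq(log(1e-4), log(20), length.out = 200))
  lls <- vapply(grid, function(s2) {
    V <- s2 * shared_time_matrix(tr) + diag(0.3^2, 15)
    ch <- chol(V)
    one <- rep(1, 15)
    z0 <- sum(backsolve(ch, one, transpose = TRUE) *
                backsolve(ch, x, transpose = TRUE)) /
      sum(backsolve(ch, one, transpose = TRUE)^2)
    mvn_loglik(x, rep(z0, 15), V)
  }, numeric(1))
  expect_gte(f$loglik, max(lls) - 1e-4)
})

test_that("mean trend fits drift on non-ultrametric trees", {
  tr <- random_test_tree(30, seed = 41)
  depths <- ape::node.depth.edgelength(tr)[1:30]
  x <- simulate_traits(evol_model("bm"), tr, seed = 42) + 2 * depths
  names(x) <- tr$tip.label
  f <- fit_model(tr, x, "mean_trend")
  expect_equal(f$params$drift, 2, tolerance = 0.6)
  expect_equal(f$k, 3L)
  expect_error(fit_model(simulate_pure_birth(10, seed = 1),
                         stats::setNames(rnorm(10), paste0("t", 1:10)),
                         "mean_trend"),
               "unidentifiable")
})
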