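test_that("prevalence standard error is the delta-method closed form", {
  expect_equal(prevalence_se(0.5, 25), 0.1)
  expect_equal(prevalence_se(0.9, 100), 0.05)
  expect_equal(prevalence_se(0, 1), 0.5)
  expect_error(prevalence_se(1.5, 10), "\\[0, 1\\]")
  expect_error(prevalence_se(0.5, 0), ">= 1")
})

test_that("white covariance with zero SE reduces to ordinary least squares", {
  star <- read_newick("(A:1,B:1,C:1);")
  d <- data.frame(species = c("A", "B", "C"), x = c(0, 1, 2), y = c(1, 2, 4))
  f <- pgls_sey(star, d, spec = evol_model("white"))
  expect_equal(unname(f$coefficients["x", "Estimate"]), 1.5, tolerance = 1e-8)
  expect_equal(unname(f$coefficients["(Intercept)", "Estimate"]), 5 / 6,
               tolerance = 1e-8)

  # any data: white structure with se_y = 0 is exactly OLS
  tr <- simulate_pure_birth(20, seed = 70)
  d2 <- data.frame(species = tr$tip.label,
                   x = with_seed2(71, rnorm(20)),
                   y = with_seed2(72, rnorm(20)))
  f2 <- pgls_sey(tr, d2, spec = evol_model("white"))
  ols <- summary(lm(y ~ x, data = d2))$coefficients
  expect_equal(unname(f2$coefficients[, "Estimate"]),
               unname(ols[, "Estimate"]), tolerance = 1e-6)
  # the residual variance is ML (n denominator), so SEs differ from the
  # least-squares ones by exactly sqrt((n-2)/n)
  expect_equal(unname(f2$coefficients[, "Std. Error"]),
               unname(ols[, "Std. Error"]) * sqrt(18 / 20), tolerance = 1e-6)
})

test_that("a perfect linear relation is flagged degenerate with exact slope", {
  tr <- simulate_pure_birth(10, seed = 75)
  x <- with_seed2(76, rnorm(10))
  d <- data.frame(species = tr$tip.label, x = x, y = 2 * x)
  f <- pgls_sey(tr, d)
  expect_true(f$degenerate)
  expect_equal(unname(f$coefficients["x", "Estimate"]), 2, tolerance = 1e-6)
})

test_that("Brownian PGLS with zero SE equals textbook GLS", {
  for (seed in c(80, 81)) {
    tr <- simulate_pure_birth(15, seed = seed)
    x <- simulate_traits(evol_model("bm"), tr, seed = seed + 1)
    y <- 0.5 * x + simulate_traits(evol_model("bm", sigma2 = 0.5), tr,
                                   seed = seed + 2)
    d <- data.frame(species = tr$tip.label, x = x, y = y)
    f <- pgls_sey(tr, d)
    # brute-force GLS with V = C (coefficients are scale free in sigma2)
    C <- shared_time_matrix(tr)
    X <- cbind(1, x)
    Ci <- solve(C)
    beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
    expect_equal(unname(f$coefficients[, "Estimate"]), unname(drop(beta)),
                 tolerance = 1e-8)
    # and the reported SEs match the GLS covariance at the fitted sigma2
    covb <- solve(t(X) %*% solve(f$sigma2 * C) %*% X)
    expect_equal(unname(f$coefficients[, "Std. Error"]),
                 unname(sqrt(diag(covb))), tolerance = 1e-6)
  }
})

test_that("slope is equivariant to predictor scaling and y-shifts", {
  tr <- simulate_pure_birth(25, seed = 90)
  x <- simulate_traits(evol_model("bm"), tr, seed = 91)
  y <- 0.7 * x + simulate_traits(evol_model("bm", sigma2 = 0.2), tr, seed = 92)
  se <- stats::setNames(rep(0.1, 25), tr$tip.label)
  d <- data.frame(species = tr$tip.label, x = x, y = y, se_y = se)
  f <- pgls_sey(tr, d)

  d_scaled <- transform(d, x = 4 * x)
  f_scaled <- pgls_sey(tr, d_scaled)
  expect_equal(unname(f_scaled$coefficients["x", "Estimate"]),
               unname(f$coefficients["x", "Estimate"]) / 4, tolerance = 1e-8)
  expect_equal(unname(f_scaled$coefficients["x", "Pr(>|t|)"]),
               unname(f$coefficients["x", "Pr(>|t|)"]), tolerance = 1e-6)

  d_shift <- transform(d, y = y + 5)
  f_shift <- pgls_sey(tr, d_shift)
  expect_equal(unname(f_shift$coefficients["x", "Estimate"]),
               unname(f$coefficients["x", "Estimate"]), tolerance = 1e-7)
  expect_equal(unname(f_shift$coefficients["(Intercept)", "Estimate"]),
               unname(f$coefficients["(Intercept)", "Estimate"]) + 5,
               tolerance = 1e-6)
})

test_that("degenerate inputs raise informative errors", {
  tr <- simulate_pure_birth(10, seed = 95)
  d <- data.frame(species = tr$tip.label, x = 1, y = rnorm(10))
  expect_error(pgls_sey(tr, d), "constant predictor")
})

test_that("model-selected PGLS is consistent with its components", {
  tr <- simulate_pure_birth(40, seed = 100)
  x <- simulate_traits(evol_model("bm"), tr, seed = 101)
  y <- 0.4 * x + simulate_traits(evol_model("bm", sigma2 = 0.3), tr, seed = 102)
  se <- stats::setNames(rep(0.05, 40), tr$tip.label)
  d <- data.frame(species = tr$tip.label, x = x, y = y, se_y = se)

  # a single-candidate run is exactly pgls_sey under that model
  fb <- pgls_sey_optim(tr, d, candidates = "bm")
  f0 <- pgls_sey(tr, d)
  expect_equal(fb$selected_kind, "bm")
  expect_equal(fb$coefficients, f0$coefficients, tolerance = 1e-9)

  # whenever Brownian motion wins the AIC comparison, the slope matches the
  # Brownian PGLS slope to numerical precision
  fo <- pgls_sey_optim(tr, d)
  if (fo$selected_kind == "bm")
    expect_equal(unname(fo$coefficients["x", "Estimate"]),
                 unname(f0$coefficients["x", "Estimate"]), tolerance = 1e-6)
  expect_true(fo$selected_kind %in% names(fo$fits_aic))
  expect_equal(unname(which.min(fo$fits_aic)),
               unname(match(fo$selected_kind, names(fo$fits_aic))))
})

test_that("phylogeny-free responses give near-OLS slopes after selection", {
  # y independent of the tree: the selected structure should not distort the
  # slope away from OLS by more than sampling error
  ok <- 0L
  for (s in 1:10) {
    tr <- simulate_pure_birth(100, seed = 200 + s)
    x <- simulate_traits(evol_model("bm"), tr, seed = 300 + s)
    y <- stats::setNames(0.3 * x + with_seed2(400 + s, rnorm(100, sd = 0.5)),
                         tr$tip.label)
    d <- data.frame(species = tr$tip.label, x = x, y = y,
                    se_y = stats::setNames(rep(0.05, 100), tr$tip.label))
    f <- pgls_sey_optim(tr, d)
    ols <- summary(lm(y ~ x))$coefficients
    if (abs(f$coefficients["x", "Estimate"] - ols["x", "Estimate"]) <=
        2 * ols["x", "Std. Error"]) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})
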