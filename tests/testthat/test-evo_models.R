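tree3 <- read_newick("((A:1,B:1):1,C:2);")

test_that("model specifications validate their parameters", {
  expect_s3_class(evol_model("ou", alpha = 2), "evol_model")
  expect_error(evol_model("bm", sigma2 = -1), "sigma2")
  expect_error(evol_model("ou", alpha = -1), "alpha")
  expect_error(evol_model("lambda", lambda = 1.2), "lambda")
  expect_error(evol_model("eb", a = 0.5), "a")
  expect_error(evol_model("bm", lambda = 0.5), "not part")
  expect_equal(model_k("bm"), 2L)
  expect_equal(model_k("white"), 2L)
  expect_equal(model_k(evol_model("ou", alpha = 1)), 3L)
})

test_that("table VCV forms match their closed expressions", {
  C <- shared_time_matrix(tree3)

  # lambda = 1 is Brownian motion; lambda = 0 kills the off-diagonals
  expect_equal(model_vcv(evol_model("lambda", lambda = 1), tree3),
               model_vcv(evol_model("bm"), tree3))
  V0 <- model_vcv(evol_model("lambda", lambda = 0, sigma2 = 2), tree3)
  expect_equal(unname(V0), diag(c(4, 4, 4)))

  # white noise is a scaled identity
  expect_equal(unname(model_vcv(evol_model("white", sigma2 = 3), tree3)),
               3 * diag(3))

  # OU as printed: sigma2/(2 alpha) (1 - exp(-2 alpha t_ij))
  a <- 1.3
  expect_equal(model_vcv(evol_model("ou", alpha = a), tree3),
               (1 / (2 * a)) * (1 - exp(-2 * a * C)))

  # delta is an entrywise power, kappa a branch-power Brownian motion
  expect_equal(model_vcv(evol_model("delta", delta = 2), tree3), C^2)
  expect_equal(model_vcv(evol_model("kappa", kappa = 0.5), tree3),
               shared_time_matrix(kappa_branch_transform(tree3, 0.5)))

  # rate trend integrates the linear instantaneous rate
  s <- 0.4
  expect_equal(model_vcv(evol_model("rate_trend", slope = s), tree3),
               C + s * C^2 / 2)
  expect_error(model_vcv(evol_model("rate_trend", slope = -1.5), tree3),
               "non-positive")
})

test_that("early burst approaches Brownian motion as a -> 0", {
  Vbm <- model_vcv(evol_model("bm"), tree3)
  Veb <- model_vcv(evol_model("eb", a = -1e-6), tree3)
  expect_true(max(abs(Veb - Vbm)) < 1e-5)
})

test_that("every kind collapses to Brownian motion at its neutral parameter", {
  tr <- simulate_pure_birth(25, seed = 3)
  Vbm <- model_vcv(evol_model("bm"), tr)
  neutral <- list(evol_model("lambda", lambda = 1),
                  evol_model("delta", delta = 1),
                  evol_model("kappa", kappa = 1),
                  evol_model("eb", a = -1e-10),
                  evol_model("rate_trend", slope = 0))
  for (spec in neutral)
    expect_lt(max(abs(model_vcv(spec, tr) - Vbm)), 1e-8)
})

test_that("generated VCVs are symmetric and PSD", {
  tr <- simulate_pure_birth(20, seed = 5)
  specs <- list(evol_model("bm"), evol_model("ou", alpha = 3),
                evol_model("ou", alpha = 3, ou_form = "hansen"),
                evol_model("eb", a = -2), evol_model("lambda", lambda = 0.4),
                evol_model("delta", delta = 0.5),
                evol_model("kappa", kappa = 0.3),
                evol_model("rate_trend", slope = 1), evol_model("white"))
  for (spec in specs) {
    V <- model_vcv(spec, tr)
    expect_equal(V, t(V))
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) >= -1e-9 * max(ev))
  }
})

test_that("model means are constant except under the mean trend", {
  expect_equal(unname(model_mean(evol_model("bm", z0 = 5), tree3)),
               rep(5, 3))
  nu <- read_newick("((A:1,B:1):1,C:1);")  # tips at depths 2, 2, 1
  m <- model_mean(evol_model("mean_trend", z0 = 0, drift = 2), nu)
  expect_equal(unname(m), c(4, 4, 2))
  expect_equal(model_mean(evol_model("mean_trend", drift = 0), nu),
               model_mean(evol_model("bm"), nu))
  # drift is confounded with z0 when all tips are equidistant from the root
  expect_error(model_mean(evol_model("mean_trend", drift = 1), tree3),
               "unidentifiable")
  expect_error(model_vcv(evol_model("mean_trend", drift = 1), tree3),
               "unidentifiable")
})

test_that("simulated traits reproduce the model covariance", {
  # white noise: unit variance, uncorrelated tips
  tr <- simulate_pure_birth(6, seed = 8)
  X <- simulate_traits(evol_model("white"), tr, seed = 1, nsim = 5000)
  expect_lt(abs(mean(apply(X, 2, var)) - 1), 0.05)
  expect_lt(abs(cor(X[, 1], X[, 4])), 0.05)

  # Brownian cherry with 90% shared history: correlation about 0.9
  cherry <- read_newick("((A:0.1,B:0.1):0.9,C:1);")
  Y <- simulate_traits(evol_model("bm"), cherry, seed = 2, nsim = 5000)
  expect_lt(abs(cor(Y[, "A"], Y[, "B"]) - 0.9), 0.03)

  # sigma2 -> 0 pins every tip at the root state
  z <- simulate_traits(evol_model("bm", sigma2 = 1e-12, z0 = 3), tr, seed = 3)
  expect_true(all(abs(z - 3) < 1e-4))

  # empirical covariance matches model_vcv within Monte-Carlo error
  spec <- evol_model("lambda", lambda = 0.5, sigma2 = 2)
  Z <- simulate_traits(spec, tr, seed = 4, nsim = 6000)
  V <- model_vcv(spec, tr)
  emp <- cov(Z)
  mc_se <- sqrt((V^2 + outer(diag(V), diag(V))) / 6000)
  expect_true(all(abs(emp - V) < 3.5 * mc_se))

  # determinism
  expect_identical(simulate_traits(spec, tr, seed = 9),
                   simulate_traits(spec, tr, seed = 9))
})
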