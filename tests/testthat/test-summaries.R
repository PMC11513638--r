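test_that("posterior mode finds the peak of constant, normal and skewed samples", {
  expect_equal(posterior_mode(rep(2, 200)), 2)
  set.seed(1)
  expect_lt(abs(posterior_mode(rnorm(1e5))), 0.05)
  set.seed(2)
  expect_lt(abs(posterior_mode(rexp(1e5))), 0.1)
  expect_error(posterior_mode(rnorm(50)), class = "colonyQG_insufficient_samples")
})

test_that("HPD intervals are shortest and correctly calibrated", {
  set.seed(3)
  u <- runif(1e6)
  h <- hpd_interval(u)
  expect_equal(h[["hi"]] - h[["lo"]], 0.95, tolerance = 0.01)
  z <- rnorm(1e6)
  hz <- hpd_interval(z)
  expect_equal(hz[["lo"]], -1.96, tolerance = 0.02)
  expect_equal(hz[["hi"]], 1.96, tolerance = 0.02)
  cc <- hpd_interval(rep(1.5, 150))
  expect_equal(unname(cc[2] - cc[1]), 0)
  expect_error(hpd_interval(z, prob = 1.2), class = "colonyQG_invalid_argument")
  # agreement with coda on a skewed posterior-like sample
  skip_if_not_installed("coda")
  set.seed(4)
  g <- rgamma(5e4, 2, 4)
  hg <- hpd_interval(g)
  hcoda <- coda::HPDinterval(coda::mcmc(g))
  expect_equal(unname(hg), unname(as.vector(hcoda)), tolerance = 0.01)
})

test_that("ESS matches the AR(1) closed form and flags degenerate chains", {
  set.seed(5)
  iid <- rnorm(1000)
  e <- ess_and_autocorr(iid)
  expect_gt(e$ess, 800); expect_lt(e$ess, 1200)
  ar <- as.vector(arima.sim(list(ar = 0.5), 1e5))
  ea <- ess_and_autocorr(ar)
  expect_equal(ea$ess / 1e5, 1 / 3, tolerance = 0.1)
  expect_equal(ea$lag1_autocorr, 0.5, tolerance = 0.05)
  expect_error(ess_and_autocorr(rep(1, 100)),
               class = "colonyQG_undefined_autocorrelation")
  expect_error(ess_and_autocorr(rnorm(5)), class = "colonyQG_insufficient_samples")
  # same order of magnitude as coda's spectral estimator
  skip_if_not_installed("coda")
  expect_equal(ea$ess, unname(coda::effectiveSize(coda::mcmc(ar))),
               tolerance = 0.15)
})

test_that("posterior contrasts summarize elementwise differences", {
  set.seed(6)
  a <- rnorm(1e5, 1, 1)
  b <- rnorm(1e5, 0, 1)
  ct <- posterior_contrast(a, b)
  expect_equal(mean(ct$difference), 1, tolerance = 0.02)
  expect_equal(ct$median, 1, tolerance = 0.02)
  same <- posterior_contrast(a, a)
  expect_true(all(same$difference == 0))
  expect_error(posterior_contrast(a, b[-1]), class = "colonyQG_alignment_error")
})

test_that("variance decomposition arithmetic on point-mass chains", {
  chains <- structure(list(
    samples = data.frame(V_A = rep(1, 200), V_PE = 1, V_year = 1,
                         V_island = 1, V_resid = 1),
    meta = list(trait_mean = 2)), class = "posterior_chains")
  vd <- variance_decomposition(chains)
  expect_equal(vd$chains$h2[1], 0.2)
  expect_equal(vd$chains$R[1], 0.4)
  expect_equal(vd$summary["R", "median"], 0.4)
  # proportions sum to one and R >= h2 sample-wise
  tot <- vd$chains$h2 + vd$chains$prop_pe + vd$chains$prop_year +
    vd$chains$prop_island + vd$chains$prop_resid
  expect_equal(tot, rep(1, 200))
  expect_true(all(vd$chains$R >= vd$chains$h2))
  # CV_A formula: V_A = 0.04, mean 2 -> 10%
  chains2 <- structure(list(
    samples = data.frame(V_A = rep(0.04, 200), V_PE = 0.01, V_year = 0.01,
                         V_island = 0.01, V_resid = 0.01),
    meta = list(trait_mean = 2)), class = "posterior_chains")
  expect_equal(variance_decomposition(chains2)$chains$CV_A[1], 10)
  # slope-model chains are rejected
  rr <- structure(list(samples = data.frame(V_A_int = rep(1, 200))),
                  class = "posterior_chains")
  expect_error(variance_decomposition(rr), class = "colonyQG_wrong_model")
})

test_that("DIC is the deviance at a point-mass posterior and penalizes complexity", {
  y <- rpois(50, 5)
  eta <- log(pmax(y, 0.5))
  dev0 <- -2 * sum(dpois(y, exp(eta), log = TRUE))
  chains <- structure(list(deviance = rep(dev0, 100), eta_mean = eta, y = y,
                           family = "poisson"), class = "posterior_chains")
  d <- dic(chains)
  expect_equal(d$pD, 0, tolerance = 1e-10)
  expect_equal(d$dic, dev0, tolerance = 1e-10)
  expect_error(dic(structure(list(deviance = numeric(0)),
                             class = "posterior_chains")),
               class = "colonyQG_invalid_argument")
})

test_that("pD approximates the parameter count in a fixed-effects Gaussian toy", {
  # y = X beta + e with known-variance-ish residual: pD ~ number of
  # coefficients when the prior is diffuse
  set.seed(7)
  n <- 400
  d <- data.frame(female_id = sprintf("f%03d", 1:n),
                  x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$count <- 1 + 0.5 * d$x1 - 0.3 * d$x2 + 0.2 * d$x3 + rnorm(n, 0, 0.7)
  sp <- model_spec(response = "count", fixed = ~ x1 + x2 + x3,
                   random = character(0))
  fit <- fit_glmm_animal(d, spec = sp, family = "gaussian",
                         config = quick_cfg(1, n_iter = 3000, burn_in = 500,
                                            thin = 2))
  pd <- dic(fit)$pD
  # 4 location parameters (intercept + 3 slopes) plus residual-variance
  # uncertainty
  expect_gt(pd, 3.2)
  expect_lt(pd, 7.5)
})
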