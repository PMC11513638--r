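test_that("model_spec validates random terms and configs validate sizes", {
  expect_error(model_spec(random = c("individual_slopes", "genetic_slopes")),
               class = "colonyQG_invalid_argument")
  expect_error(model_spec(random = "nonsense"),
               class = "colonyQG_invalid_argument")
  expect_error(mcmc_config(n_iter = 100, burn_in = 200),
               class = "colonyQG_invalid_argument")
  expect_error(mcmc_config(n_iter = 120, burn_in = 100, thin = 50),
               class = "colonyQG_invalid_argument")
})

test_that("fit_glmm_animal validates inputs with informative errors", {
  ds <- simulate_qg_dataset(n_females = 30, obs_per_female = 3,
                            truth = true_params(), seed = 1)
  d <- ds$nests
  expect_error(fit_glmm_animal(d[setdiff(names(d), "count")],
                               pedigree = ds$pedigree),
               class = "colonyQG_schema_error")
  d2 <- d; d2$count <- d2$count + 0.5
  expect_error(fit_glmm_animal(d2, pedigree = ds$pedigree),
               class = "colonyQG_invalid_argument")
  expect_error(fit_glmm_animal(d, pedigree = NULL),
               class = "colonyQG_invalid_argument")
  d3 <- d; d3$female_id[1] <- "not_in_pedigree"
  expect_error(fit_glmm_animal(d3, pedigree = ds$pedigree),
               class = "colonyQG_inconsistent_pedigree")
  dropped <- d[setdiff(names(d), "year_std")]
  expect_error(fit_glmm_animal(dropped, pedigree = ds$pedigree),
               regexp = "year_std")
})

test_that("the chain is a deterministic function of the seed", {
  ds <- simulate_qg_dataset(n_females = 60, obs_per_female = 3,
                            truth = true_params(), seed = 2)
  f1 <- fit_glmm_animal(ds$nests, pedigree = ds$pedigree,
                        config = quick_cfg(7))
  f2 <- fit_glmm_animal(ds$nests, pedigree = ds$pedigree,
                        config = quick_cfg(7))
  expect_identical(f1$samples, f2$samples)
  f3 <- fit_glmm_animal(ds$nests, pedigree = ds$pedigree,
                        config = quick_cfg(8))
  expect_false(identical(f1$samples$V_A, f3$samples$V_A))
})

test_that("Gaussian special case matches the REML oracle within 15%", {
  skip_if_not_installed("lme4")
  set.seed(5)
  nf <- 50; nobs <- 4
  d <- data.frame(female_id = rep(sprintf("f%02d", 1:nf), each = nobs),
                  year = rep_len(1:20, nf * nobs))
  u <- rnorm(nf, 0, sqrt(0.3)); yr <- rnorm(20, 0, sqrt(0.15))
  d$x <- rnorm(nrow(d))
  d$count <- 2 + 0.5 * d$x + u[as.integer(factor(d$female_id))] +
    yr[d$year] + rnorm(nrow(d), 0, sqrt(0.2))
  sp <- model_spec(response = "count", fixed = ~ x,
                   random = c("permanent_env", "year"))
  fit <- fit_glmm_animal(d, spec = sp, family = "gaussian",
                         config = quick_cfg(1, n_iter = 5000, burn_in = 1000,
                                            thin = 4))
  post <- summary(fit)
  lf <- lme4::lmer(count ~ x + (1 | female_id) + (1 | year), d)
  vc <- as.data.frame(lme4::VarCorr(lf))
  reml <- setNames(vc$vcov, c("V_PE", "V_year", "V_resid"))
  for (nm in names(reml)) {
    est <- post$median[post$parameter == nm]
    expect_lt(abs(est - reml[[nm]]) / reml[[nm]], 0.15)
  }
  expect_equal(post$median[post$parameter == "x"],
               unname(lme4::fixef(lf)["x"]), tolerance = 0.05)
})

test_that("posterior predictive from posterior means conserves the count mean", {
  tr <- true_params(V_A = 0.2, V_PE = 0.1, V_year = 0.05, V_island = 0.02,
                    V_resid = 0.3, beta0 = 1.6)
  ds <- simulate_qg_dataset(n_females = 120, obs_per_female = 3, truth = tr,
                            seed = 4)
  fit <- fit_glmm_animal(ds$nests, pedigree = ds$pedigree,
                         config = quick_cfg(3, n_iter = 2500, burn_in = 800))
  set.seed(99)
  sim_mean <- mean(rpois(length(fit$eta_mean) * 20, exp(fit$eta_mean)))
  expect_equal(sim_mean, mean(ds$nests$count), tolerance = 0.1)
})

test_that("record order does not change posterior summaries beyond MC error", {
  tr <- true_params(V_A = 0.2, V_PE = 0.1, V_year = 0.05, V_island = 0.02,
                    V_resid = 0.3, beta0 = 1.6)
  ds <- simulate_qg_dataset(n_females = 100, obs_per_female = 3, truth = tr,
                            seed = 9)
  perm <- sample(nrow(ds$nests))
  f1 <- fit_glmm_animal(ds$nests, pedigree = ds$pedigree,
                        config = quick_cfg(5, n_iter = 3000, burn_in = 1000))
  f2 <- fit_glmm_animal(ds$nests[perm, ], pedigree = ds$pedigree,
                        config = quick_cfg(5, n_iter = 3000, burn_in = 1000))
  s1 <- summary(f1); s2 <- summary(f2)
  expect_equal(s1$median[s1$parameter == "delta_age"],
               s2$median[s2$parameter == "delta_age"], tolerance = 0.05)
  expect_equal(s1$median[s1$parameter == "V_resid"],
               s2$median[s2$parameter == "V_resid"], tolerance = 0.12)
})

test_that("reaction-norm chains respect per-sample identities", {
  tr <- true_params(slopes = TRUE, V_year = 0.05, V_island = 0.02,
                    V_resid = 0.3, beta0 = 1.6)
  ds <- simulate_qg_dataset(n_females = 80, obs_per_female = 4, truth = tr,
                            seed = 12)
  fit <- fit_random_regression(ds$nests, level = "individual",
                               config = quick_cfg(2, n_iter = 2000,
                                                  burn_in = 700))
  s <- fit$samples
  # correlation bounded, covariance consistent, per sample
  expect_true(all(abs(s$r_I) <= 1))
  expect_equal(s$COV_I / sqrt(s$V_I_int * s$V_I_slope), s$r_I, tolerance = 1e-12)
  # five residual classes, all positive
  expect_true(all(grepl("^V_resid_c[1-5]$",
                        grep("V_resid", colnames(s), value = TRUE))))
  expect_true(all(as.matrix(s[grep("V_resid", colnames(s))]) > 0))
  # variance-at-age function: V(0) = V_int exactly; V(g) >= 0 on the range
  rn <- reaction_norm_estimates(fit, gradient_values = c(-2, 0, 2))
  v0 <- rn$I$variance_at_age
  expect_equal(v0$mode[v0$gradient == 0],
               unname(rn$I$summary["V_int", "mode"]), tolerance = 1e-10)
  for (g in c(-2, 2)) {
    expect_true(all(s$V_I_int + 2 * g * s$COV_I + g^2 * s$V_I_slope >= 0))
  }
})

test_that("variance decomposition of a fitted intercept model is coherent", {
  tr <- true_params(V_A = 0.2, V_PE = 0.1, V_year = 0.05, V_island = 0.02,
                    V_resid = 0.3, beta0 = 1.6)
  ds <- simulate_qg_dataset(n_females = 100, obs_per_female = 3, truth = tr,
                            seed = 20)
  fit <- fit_glmm_animal(ds$nests, pedigree = ds$pedigree,
                         config = quick_cfg(6, n_iter = 2500, burn_in = 800))
  vd <- variance_decomposition(fit)
  tot <- vd$chains$h2 + vd$chains$prop_pe + vd$chains$prop_year +
    vd$chains$prop_island + vd$chains$prop_resid
  expect_equal(tot, rep(1, nrow(vd$chains)), tolerance = 1e-12)
  expect_true(all(vd$chains$R >= vd$chains$h2))
  expect_true(all(vd$chains$h2 >= 0 & vd$chains$h2 <= 1))
})

test_that("prior scale has limited influence at moderate data size", {
  tr <- true_params(V_A = 0.2, V_PE = 0.1, V_year = 0.05, V_island = 0.02,
                    V_resid = 0.3, beta0 = 1.6)
  ds <- simulate_qg_dataset(n_females = 450, obs_per_female = 5, truth = tr,
                            seed = 14)
  base <- quick_cfg(4, n_iter = 2600, burn_in = 1000, thin = 2)
  wide <- quick_cfg(4, n_iter = 2600, burn_in = 1000, thin = 2)
  wide$prior$px_scale <- 2   # doubled parameter-expansion prior scale
  f1 <- fit_glmm_animal(ds$nests, pedigree = ds$pedigree, config = base)
  f2 <- fit_glmm_animal(ds$nests, pedigree = ds$pedigree, config = wide)
  for (v in c("V_A", "V_PE", "V_resid")) {
    m1 <- median(f1$samples[[v]]); m2 <- median(f2$samples[[v]])
    expect_lt(abs(m1 - m2) / max(m1, 0.02), 0.2)
  }
})
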