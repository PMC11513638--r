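test_that("simulate_pedigree respects its preconditions and shape", {
  tiny <- simulate_pedigree(2, 1, 1, seed = 1)
  expect_equal(nrow(tiny), 3)
  expect_equal(sum(!is.na(tiny$sire) & !is.na(tiny$dam)), 1)
  expect_error(simulate_pedigree(10, 0), class = "colonyQG_invalid_argument")
  expect_error(simulate_pedigree(7, 2), class = "colonyQG_invalid_argument")
  # depth equals the number of generations (longest-path oracle via stats)
  ped <- simulate_pedigree(20, 5, 2, seed = 7)
  expect_equal(pedigree_stats(ped)$max_depth, 5)
  # determinism
  expect_identical(simulate_pedigree(12, 3, 2, seed = 5),
                   simulate_pedigree(12, 3, 2, seed = 5))
})

test_that("breeding values have the stated covariance structure", {
  # zero matrix -> all zero
  ped <- simulate_pedigree(10, 2, 2, seed = 3)
  bv0 <- simulate_breeding_values(ped, matrix(0, 2, 2), seed = 1)
  expect_true(all(bv0 == 0))
  # founders only: sample covariance approaches G2
  founders <- pedigree(sprintf("f%05d", 1:10000), rep(NA, 10000), rep(NA, 10000))
  bv <- simulate_breeding_values(founders, diag(2), seed = 2)
  expect_equal(cov(bv), diag(2), tolerance = 0.05, ignore_attr = TRUE)
  # trio: child's expected value is the parental midpoint (Monte Carlo over
  # redraws of the Mendelian deviate)
  trio <- pedigree(c("S", "D", "O"), c(NA, NA, "S"), c(NA, NA, "D"))
  mids <- vapply(1:10000, function(s) {
    b <- simulate_breeding_values(trio, matrix(1), seed = s)
    b["O", 1] - mean(b[c("S", "D"), 1])
  }, numeric(1))
  expect_lt(abs(mean(mids)), 0.03)       # mendelian deviation has mean 0
  expect_equal(var(mids), 0.5, tolerance = 0.05)  # and variance G2/2
})

test_that("stacked breeding values have covariance A kron G2 (MC oracle)", {
  ped <- random_test_pedigree(12, seed = 8)
  A <- build_a_matrix(ped)
  G2 <- matrix(c(1, 0.3, 0.3, 0.5), 2)
  reps <- 4000
  draws <- vapply(seq_len(reps), function(s)
    as.vector(simulate_breeding_values(ped, G2, seed = s)),
    numeric(2 * nrow(ped)))
  emp <- cov(t(draws))
  theo <- G2 %x% A  # column stacking: (intercepts, slopes) blocks
  theo <- rbind(cbind(G2[1, 1] * A, G2[1, 2] * A),
                cbind(G2[2, 1] * A, G2[2, 2] * A))
  expect_lt(max(abs(emp - theo)), 0.12)
  # relative error on the well-identified diagonal
  expect_lt(max(abs(diag(emp) - diag(theo)) / diag(theo)), 0.15)
})

test_that("season simulation respects island geometry and phenology", {
  expect_equal(nrow(simulate_colony_season(2000, 0)), 0)
  s <- simulate_colony_season(2001, 5000, seed = 4)
  expect_true(all(s$x >= 0 & s$x <= 10.7))
  expect_true(all(s$y >= 0 & s$y <= 4.6))
  expect_true(all(s$island %in% 1:6))
  expect_true(all(s$age >= 2 & s$age <= 27))
  # negative phenology slope gives clearly negative age/laying-date correlation
  r <- cor(s$age, s$laying_date)
  expect_lt(r, -0.1)
  expect_error(simulate_colony_season(2001, 10, island_dims = c(-1, 4.6)),
               class = "colonyQG_invalid_argument")
})

test_that("trait counts follow Poisson-lognormal moments", {
  nf <- 100000
  nests <- data.frame(female_id = sprintf("f%06d", 1:nf),
                      year = 1L, island = 1L,
                      age = 5L, mean_age = 5, delta_age = 0)
  effects <- list(bv = matrix(0, nf, 1, dimnames = list(nests$female_id, NULL)),
                  pe = matrix(0, nf, 1, dimnames = list(nests$female_id, NULL)),
                  year = c("1" = 0), island = c("1" = 0))
  # pure Poisson(5): all variances zero, beta0 = log 5
  tr0 <- true_params(beta0 = log(5), beta_age_between = 0, beta_age_within = 0,
                     beta_year = 0, beta_colony_density = 0,
                     beta_island_density = 0,
                     V_A = 0, V_PE = 0, V_year = 0, V_island = 0, V_resid = 0)
  out0 <- simulate_trait_counts(nests, tr0, effects, seed = 1)
  expect_gt(mean(out0$count), 4.9)
  expect_lt(mean(out0$count), 5.1)
  expect_gt(var(out0$count) / mean(out0$count), 0.95)
  expect_lt(var(out0$count) / mean(out0$count), 1.05)
  # V_resid = 0.5, beta0 = 0: closed-form Poisson-lognormal moments
  tr1 <- true_params(beta0 = 0, beta_age_between = 0, beta_age_within = 0,
                     beta_year = 0, beta_colony_density = 0,
                     beta_island_density = 0,
                     V_A = 0, V_PE = 0, V_year = 0, V_island = 0, V_resid = 0.5)
  out1 <- simulate_trait_counts(nests, tr1, effects, seed = 2)
  m <- exp(0.25)
  v <- m + m^2 * (exp(0.5) - 1)
  expect_equal(mean(out1$count), m, tolerance = 0.03)
  expect_equal(var(out1$count), v, tolerance = 0.03)
  # determinism and missing-covariate schema error
  out1b <- simulate_trait_counts(nests, tr1, effects, seed = 2)
  expect_identical(out1$count, out1b$count)
  tr2 <- true_params()
  expect_error(simulate_trait_counts(nests[, c("female_id", "year", "island")],
                                     tr2, effects),
               class = "colonyQG_schema_error")
  expect_error(simulate_trait_counts(nests, tr2, effects),
               regexp = "island_density_std")
})

test_that("generator round-trip: stored latent components reassemble eta", {
  ds <- simulate_qg_dataset(n_females = 40, obs_per_female = 3, truth = true_params(),
                            seed = 6)
  lat <- ds$latent_values
  expect_equal(lat$fixed + lat$a + lat$pe + lat$year + lat$island + lat$e,
               ds$nests$eta, tolerance = 1e-12)
  # every phenotyped female is in the pedigree; counts are integers >= 0
  expect_true(all(ds$nests$female_id %in% ds$pedigree$id))
  expect_true(all(ds$nests$count >= 0 & ds$nests$count == round(ds$nests$count)))
})

test_that("full colony study emulates the target study conditions", {
  ds <- simulate_colony_study(n_years = 29, seed = 10)
  nst <- ds$nests
  expect_equal(length(unique(nst$year)), 29)
  # one record per female per year
  expect_false(any(duplicated(nst[c("female_id", "year")])))
  sizes <- table(nst$year)
  expect_lt(abs(min(sizes) - 90) / 90, 0.5)
  expect_gt(max(sizes), 500)
  expect_true(all(nst$age >= 2 & nst$age <= 27))
  # age / laying-date annual-mean correlation is negative (study-like)
  r <- annual_mean_correlation(nst)$r
  expect_lt(r, 0)
  # file round trip
  dir <- tempfile()
  write_colony_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("nests.csv", "pedigree.csv",
                                               "truth.json")))))
  ped2 <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_equal(nrow(ped2), nrow(ds$pedigree))
})
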