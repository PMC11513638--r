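# Synthetic colony generation with known ground truth.
#
# The generator emulates the study system the package targets: a closed
# seabird colony breeding on six identical rectangular islands (10.7 x 4.6 m)
# monitored over ~29 annual seasons, colony size 90-740 pairs, female ages
# 2-27 with a survival-shaped distribution, an age-dependent advance in
# laying date, and a pedigree of limited depth. Trait counts are drawn from
# the overdispersed-Poisson (Poisson-lognormal) animal model that the
# inference machinery fits, so every variance component and slope has a known
# generative value.

ISLAND_LEN <- 10.7
ISLAND_WID <- 4.6
N_ISLANDS <- 6L

run_seeded <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generative parameter set for synthetic colony datasets
#'
#' Bundles every fixed effect and variance component of the latent-scale
#' (log-link) model under which synthetic counts are drawn. Defaults are
#' chosen so that the implied variance proportions are of the magnitude seen
#' in long-term colony studies of neighbour density (heritability ~0.36,
#' permanent environment ~0.28, year ~0.09, island ~0.01).
#'
#' @param beta0 latent intercept (log counts).
#' @param beta_age_between,beta_age_within latent slopes per year of a
#'   female's mean age and of her deviation from that mean.
#' @param beta_age_interaction coefficient on mean_age x delta_age
#'   (default 0: linear within-individual ageing).
#' @param beta_year,beta_colony_density,beta_island_density,beta_laying_date,beta_wall
#'   latent slopes per standardized unit of the respective covariate.
#' @param V_A,V_PE,V_year,V_island,V_resid latent-scale variances (>= 0) for
#'   additive genetic, permanent environment, year, island and residual
#'   (overdispersion) components.
#' @param slopes if `TRUE`, individual/genetic effects are reaction norms
#'   (intercept + slope over standardized age) drawn from `G2`/`P2`; if
#'   `FALSE` (default) they are intercepts with variances `V_A`/`V_PE`.
#' @param G2,P2 2x2 intercept/slope covariance matrices (genetic, permanent
#'   environment), used when `slopes = TRUE`.
#' @param seed integer master seed; all randomness derives from it.
#' @return A list of class `"true_params"`.
#' @export
true_params <- function(beta0 = 1.795,
                        beta_age_between = -0.024,
                        beta_age_within = -0.059,
                        beta_age_interaction = 0,
                        beta_year = 0.015,
                        beta_colony_density = 0.037,
                        beta_island_density = 0.3,
                        beta_laying_date = 0,
                        beta_wall = 0,
                        V_A = 0.20, V_PE = 0.155, V_year = 0.05,
                        V_island = 0.005, V_resid = 0.14,
                        slopes = FALSE,
                        G2 = matrix(c(0.2, 0.06, 0.06, 0.05), 2),
                        P2 = matrix(c(0.155, 0, 0, 0), 2),
                        seed = 1L) {
  vs <- c(V_A = V_A, V_PE = V_PE, V_year = V_year,
          V_island = V_island, V_resid = V_resid)
  if (any(vs < 0)) cqg_stop("variances must be >= 0", "colonyQG_invalid_argument")
  for (M in list(G2, P2)) {
    if (!isTRUE(all.equal(M, t(M))) || min(eigen(M, only.values = TRUE)$values) < -1e-8)
      cqg_stop("G2 and P2 must be symmetric positive semidefinite",
               "colonyQG_invalid_argument")
  }
  structure(list(beta0 = beta0,
                 beta_age_between = beta_age_between,
                 beta_age_within = beta_age_within,
                 beta_age_interaction = beta_age_interaction,
                 beta_year = beta_year,
                 beta_colony_density = beta_colony_density,
                 beta_island_density = beta_island_density,
                 beta_laying_date = beta_laying_date,
                 beta_wall = beta_wall,
                 V_A = V_A, V_PE = V_PE, V_year = V_year,
                 V_island = V_island, V_resid = V_resid,
                 slopes = slopes, G2 = G2, P2 = P2,
                 seed = as.integer(seed)),
            class = "true_params")
}

#' Simulate a discrete-generation monogamous pedigree
#'
#' Founders form generation 0; within each later generation, individuals of
#' the previous generation are randomly paired (monogamously, half as sires,
#' half as dams) and each pair produces `offspring_per_pair` offspring.
#'
#' @param n_founders even integer >= 2.
#' @param n_generations integer >= 1.
#' @param offspring_per_pair integer >= 1.
#' @param seed integer seed.
#' @return A [pedigree()] object with attributes `sex` (named "M"/"F"
#'   vector) and `generation` (named integer vector, founders = 0).
#' @export
simulate_pedigree <- function(n_founders, n_generations, offspring_per_pair = 2L,
                              seed = 1L) {
  if (!is_count(n_founders) || n_founders < 2 || n_founders %% 2 != 0)
    cqg_stop("n_founders must be an even integer >= 2", "colonyQG_invalid_argument")
  if (!is_count(n_generations) || n_generations < 1)
    cqg_stop("n_generations must be a positive integer", "colonyQG_invalid_argument")
  if (!is_count(offspring_per_pair) || offspring_per_pair < 1)
    cqg_stop("offspring_per_pair must be a positive integer", "colonyQG_invalid_argument")
  run_seeded(derive_seed(seed, "pedigree"), {
    id <- sprintf("G0_%03d", seq_len(n_founders))
    sire <- dam <- rep(NA_character_, n_founders)
    gen <- rep(0L, n_founders)
    sex <- rep(c("M", "F"), length.out = n_founders)
    prev <- id; prev_sex <- sex
    for (g in seq_len(n_generations)) {
      males <- sample(prev[prev_sex == "M"])
      females <- sample(prev[prev_sex == "F"])
      np <- min(length(males), length(females))
      if (np == 0L) break
      ns <- rep(males[seq_len(np)], each = offspring_per_pair)
      nd <- rep(females[seq_len(np)], each = offspring_per_pair)
      nid <- sprintf("G%d_%03d", g, seq_along(ns))
      nsex <- rep(c("F", "M"), length.out = length(ns))
      id <- c(id, nid); sire <- c(sire, ns); dam <- c(dam, nd)
      gen <- c(gen, rep(g, length(nid)))
      sex <- c(sex, nsex)
      prev <- nid; prev_sex <- nsex
    }
    ped <- pedigree(id, sire, dam)
    ord <- match(ped$id, id)
    attr(ped, "sex") <- setNames(sex[ord], ped$id)
    attr(ped, "generation") <- setNames(gen[ord], ped$id)
    ped
  })
}

# factor a k x k PSD matrix, tolerating exact semidefiniteness
psd_factor <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    cqg_stop("covariance matrix must be positive semidefinite",
             "colonyQG_invalid_argument")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(M))
}

#' Simulate breeding values down a pedigree
#'
#' Founders receive independent zero-mean (multivariate) normal values with
#' covariance `G2`; each non-founder receives the mean of its parents' values
#' plus a Mendelian-sampling deviation with covariance
#' `G2 * (1/2) * (1 - (F_s + F_d)/2)` (adjusted when a parent is unknown).
#' Over the whole pedigree the stacked values have covariance `A %x% G2`.
#'
#' @param ped a [pedigree()] object.
#' @param G2 k x k PSD covariance matrix (k = 1 for a single intercept value,
#'   k = 2 for intercept/slope reaction norms).
#' @param seed integer seed.
#' @return numeric matrix (individuals x k), rownames = pedigree ids.
#' @export
simulate_breeding_values <- function(ped, G2, seed = 1L) {
  stopifnot(inherits(ped, "colony_pedigree"))
  G2 <- as.matrix(G2)
  k <- nrow(G2)
  Ck <- psd_factor(G2)
  pf <- pedigree_factor(ped)
  Fi <- pf$F
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  run_seeded(derive_seed(seed, "bv"), {
    bv <- matrix(0, n, k, dimnames = list(ped$id, NULL))
    Z <- matrix(rnorm(n * k), n, k)
    for (i in seq_len(n)) {
      s <- ped$sire[i]; d <- ped$dam[i]
      if (!is.na(s) && !(s %in% ped$id))
        cqg_stop(paste0("unlisted parent: ", s), "colonyQG_inconsistent_pedigree")
      if (!is.na(d) && !(d %in% ped$id))
        cqg_stop(paste0("unlisted parent: ", d), "colonyQG_inconsistent_pedigree")
      if (is.na(s) && is.na(d)) {
        bv[i, ] <- Ck %*% Z[i, ]
      } else if (is.na(s) || is.na(d)) {
        p <- idx[[if (is.na(s)) d else s]]
        v <- 0.75 - 0.25 * Fi[p]
        bv[i, ] <- 0.5 * bv[p, ] + sqrt(v) * (Ck %*% Z[i, ])
      } else {
        si <- idx[[s]]; di <- idx[[d]]
        v <- 0.5 * (1 - (Fi[si] + Fi[di]) / 2)
        bv[i, ] <- 0.5 * (bv[si, ] + bv[di, ]) + sqrt(v) * (Ck %*% Z[i, ])
      }
    }
    bv
  })
}

#' Sample female ages from a survival-shaped distribution
#'
#' Geometric-like distribution truncated to ages 2-27, with annual adult
#' survival `survival` (default 0.87), mimicking the age structure of a
#' long-lived colonial seabird (mean near 8 years).
#'
#' @param n number of draws.
#' @param survival annual survival probability.
#' @param ages support of the distribution.
#' @return integer vector of ages.
#' @export
sample_colony_ages <- function(n, survival = 0.87, ages = 2:27) {
  w <- survival^(seq_along(ages) - 1)
  sample(ages, n, replace = TRUE, prob = w)
}

#' Simulate the nest map of one breeding season
#'
#' Places `pairs` nests uniformly on the six rectangular islands and assigns
#' each female an age and a laying date. Laying date decreases with age:
#' `laying_date = season_start + slope_age * (age - ref_age) + noise`, so a
#' negative `slope_age` makes older females breed earlier (the default slope
#' and noise give a within-season age/laying-date correlation near -0.5).
#' Centring at a fixed reference age (not the season mean) lets cohort shifts
#' in age structure propagate into annual mean laying dates, as in a real
#' colony.
#'
#' @param year season label (integer).
#' @param pairs number of breeding pairs (nests) this season, >= 0.
#' @param age_distribution function `n -> ages`; default [sample_colony_ages()].
#' @param island_dims length-2 numeric, island rectangle in metres.
#' @param phenology list with `season_start` (day-of-year), `slope_age`
#'   (days/year of age), `sd_noise` (days) and `ref_age` (years).
#' @param female_ids optional ids; autogenerated when `NULL`.
#' @param seed integer seed.
#' @return data.frame of nest records with columns `female_id`, `year`,
#'   `island`, `x`, `y`, `laying_date`, `age`.
#' @export
simulate_colony_season <- function(year, pairs,
                                   age_distribution = sample_colony_ages,
                                   island_dims = c(ISLAND_LEN, ISLAND_WID),
                                   phenology = list(season_start = 135,
                                                    slope_age = -1.1,
                                                    sd_noise = 8.5,
                                                    ref_age = 8),
                                   female_ids = NULL,
                                   seed = 1L) {
  if (pairs < 0 || !is_count(pairs))
    cqg_stop("pairs must be a non-negative integer", "colonyQG_invalid_argument")
  if (any(island_dims <= 0))
    cqg_stop("island dimensions must be positive", "colonyQG_invalid_argument")
  if (pairs == 0L) {
    return(data.frame(female_id = character(0), year = integer(0),
                      island = integer(0), x = numeric(0), y = numeric(0),
                      laying_date = integer(0), age = integer(0)))
  }
  run_seeded(derive_seed(seed, "season", year), {
    ages <- age_distribution(pairs)
    ld <- phenology$season_start +
      phenology$slope_age * (ages - (phenology$ref_age %||% 8)) +
      rnorm(pairs, 0, phenology$sd_noise)
    data.frame(
      female_id = female_ids %||% sprintf("Y%d_%04d", year, seq_len(pairs)),
      year = as.integer(year),
      island = sample.int(N_ISLANDS, pairs, replace = TRUE),
      x = runif(pairs, 0, island_dims[1]),
      y = runif(pairs, 0, island_dims[2]),
      laying_date = as.integer(pmin(366, pmax(1, round(ld)))),
      age = as.integer(ages)
    )
  })
}

# required covariate columns for count simulation, mapped to their truth betas
count_covariates <- function(truth) {
  b <- c(mean_age = truth$beta_age_between,
         delta_age = truth$beta_age_within,
         year_std = truth$beta_year,
         colony_density_std = truth$beta_colony_density,
         island_density_std = truth$beta_island_density,
         laying_date_std = truth$beta_laying_date,
         wall_std = truth$beta_wall)
  b[b != 0 | names(b) %in% c("mean_age", "delta_age")]
}

#' Simulate trait counts under the Poisson-lognormal animal model
#'
#' Builds the latent linear predictor `eta = beta0 + sum(beta_k x_k) + a(+
#' g * a_slope) + pe(+ g * pe_slope) + year + island + e` with
#' `e ~ N(0, V_resid)`, and draws `count ~ Poisson(exp(eta))`. The random
#' effects must already have been drawn (see [simulate_qg_dataset()] for the
#' one-call generator); this function is the deterministic-given-draws core,
#' which also returns all latent components for white-box testing.
#'
#' @param nests data.frame with one row per breeding record; must contain the
#'   covariate columns implied by non-zero betas in `truth` (e.g. `mean_age`,
#'   `delta_age`, `year_std`, ...), a `female_id`, `year` and `island` column,
#'   and `age_std` when `truth$slopes` is `TRUE`.
#' @param truth a [true_params()] object.
#' @param effects list with `bv` (individuals x 1 or 2 matrix of breeding
#'   values, rownames = ids), `pe` (same shape for permanent-environment
#'   deviations), `year` (named vector) and `island` (named vector).
#' @param seed integer seed for residuals and Poisson noise.
#' @return `nests` with added columns `count`, `eta`, `e`, plus attribute
#'   `latent` (data.frame of every latent component per record).
#' @export
simulate_trait_counts <- function(nests, truth, effects, seed = 1L) {
  betas <- count_covariates(truth)
  missing_cols <- setdiff(names(betas), names(nests))
  if (length(missing_cols))
    cqg_stop(paste0("missing covariate column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "colonyQG_schema_error")
  if (truth$slopes && !("age_std" %in% names(nests)))
    cqg_stop("missing covariate column(s): age_std", "colonyQG_schema_error")
  run_seeded(derive_seed(seed, "counts"), {
    n <- nrow(nests)
    fix <- truth$beta0 +
      as.matrix(nests[names(betas)]) %*% betas +
      truth$beta_age_interaction * nests$mean_age * nests$delta_age
    fix <- as.vector(fix)
    g <- if (truth$slopes) nests$age_std else rep(0, n)
    bv <- effects$bv[nests$female_id, , drop = FALSE]
    pe <- effects$pe[nests$female_id, , drop = FALSE]
    a_term <- bv[, 1] + if (ncol(bv) > 1) g * bv[, 2] else 0
    pe_term <- pe[, 1] + if (ncol(pe) > 1) g * pe[, 2] else 0
    yr_term <- effects$year[as.character(nests$year)]
    is_term <- effects$island[as.character(nests$island)]
    e <- rnorm(n, 0, sqrt(truth$V_resid))
    eta <- fix + a_term + pe_term + yr_term + is_term + e
    out <- nests
    out$eta <- eta
    out$e <- e
    out$count <- rpois(n, exp(eta))
    attr(out, "latent") <- data.frame(fixed = fix, a = as.vector(a_term),
                                      pe = as.vector(pe_term),
                                      year = as.vector(yr_term),
                                      island = as.vector(is_term), e = e)
    out
  })
}

draw_group_effects <- function(levels, v, seed_key, seed) {
  run_seeded(derive_seed(seed, seed_key),
             setNames(rnorm(length(levels), 0, sqrt(v)), levels))
}

#' Simulate a complete pedigreed dataset for parameter-recovery studies
#'
#' One call produces a pedigree, repeated measures on phenotyped females with
#' realistic covariates, and counts drawn from the animal model with known
#' `truth`. Females are the female members of the last two pedigree
#' generations; each is observed in consecutive seasons starting at a random
#' age, giving a longitudinal design with between- and within-individual age
#' variation.
#'
#' @param n_females target number of phenotyped females.
#' @param obs_per_female mean number of annual records per female (actual
#'   numbers vary 1..2*mean-1).
#' @param n_generations pedigree depth (default 3).
#' @param n_years number of seasons covariates span.
#' @param truth a [true_params()] object.
#' @param seed master seed.
#' @return list of class `"colony_dataset"`: `pedigree`, `nests` (with
#'   `count`), `truth`, `effects`, `latent_values`.
#' @export
simulate_qg_dataset <- function(n_females = 500, obs_per_female = 4,
                                n_generations = 3, n_years = 20,
                                truth = true_params(), seed = truth$seed) {
  # founders sized so the last two generations hold ~2*n_females individuals
  n_found <- 2 * ceiling(n_females / 2)
  ped <- simulate_pedigree(n_found, n_generations, 2L, seed = derive_seed(seed, "ped"))
  sex <- attr(ped, "sex"); gen <- attr(ped, "generation")
  females <- ped$id[sex[ped$id] == "F" & gen[ped$id] >= n_generations - 1]
  if (length(females) > n_females) females <- females[seq_len(n_females)]
  k <- if (truth$slopes) 2L else 1L
  G <- if (truth$slopes) truth$G2 else matrix(truth$V_A, 1, 1)
  P <- if (truth$slopes) truth$P2 else matrix(truth$V_PE, 1, 1)
  bv <- simulate_breeding_values(ped, G, seed = derive_seed(seed, "bv"))
  pe <- run_seeded(derive_seed(seed, "pe"), {
    m <- matrix(rnorm(length(females) * k), length(females), k) %*% t(psd_factor(P))
    rownames(m) <- females
    m
  })
  effects <- list(bv = bv, pe = pe,
                  year = draw_group_effects(seq_len(n_years), truth$V_year, "yr", seed),
                  island = draw_group_effects(seq_len(N_ISLANDS), truth$V_island, "is", seed))
  nests <- run_seeded(derive_seed(seed, "design"), {
    nf <- length(females)
    n_obs <- pmax(1L, 1L + rpois(nf, obs_per_female - 1))
    start_age <- sample_colony_ages(nf, ages = 2:20)
    start_year <- sample.int(n_years, nf, replace = TRUE)
    home_island <- sample.int(N_ISLANDS, nf, replace = TRUE)
    colony_density_by_year <- round(seq(90, 740, length.out = n_years) +
                                      rnorm(n_years, 0, 30))
    rows <- lapply(seq_len(nf), function(i) {
      ni <- n_obs[i]
      yrs <- start_year[i] + seq_len(ni) - 1L
      keep <- yrs <= n_years
      if (!any(keep)) keep[1] <- TRUE
      yrs <- pmin(yrs[keep], n_years)
      ages <- start_age[i] + seq_along(yrs) - 1L
      data.frame(female_id = females[i], year = yrs,
                 island = home_island[i],
                 x = runif(length(yrs), 0, ISLAND_LEN),
                 y = runif(length(yrs), 0, ISLAND_WID),
                 age = ages,
                 colony_density = colony_density_by_year[yrs],
                 island_density = pmax(0, round(colony_density_by_year[yrs] / 6 +
                                                  rnorm(length(yrs), 0, 8))),
                 laying_date = as.integer(round(135 - 1.1 * (ages - 8) +
                                                  rnorm(length(yrs), 0, 8.5))))
    })
    do.call(rbind, rows)
  })
  nests <- add_age_partition(nests)
  nests$age_std <- standardize(nests$age)$x
  nests$year_std <- standardize(nests$year)$x
  nests$colony_density_std <- standardize(nests$colony_density)$x
  nests$island_density_std <- standardize(nests$island_density)$x
  nests$laying_date_std <- standardize(nests$laying_date)$x
  nests$wall_std <- standardize(distance_to_nearest_wall(nests$x, nests$y))$x
  nests <- simulate_trait_counts(nests, truth, effects,
                                 seed = derive_seed(seed, "counts"))
  structure(list(pedigree = ped, nests = nests, truth = truth,
                 effects = effects, latent_values = attr(nests, "latent")),
            class = "colony_dataset")
}

#' Simulate the full multi-season colony study
#'
#' Builds an overlapping-generation colony over `n_years` seasons: colony
#' size ramps between `pairs_range` limits, females survive between seasons
#' with probability `survival`, recruits enter at age 2 and (when the colony
#' is old enough) descend from pairs breeding two seasons earlier, giving a
#' pedigree of gradually increasing depth. Nest maps follow the single-season
#' generator; counts are drawn from the animal model with `truth`.
#'
#' @param truth a [true_params()] object.
#' @param n_years number of seasons (default 29).
#' @param pairs_range range of breeding pairs over the period.
#' @param survival annual female survival.
#' @param local_recruitment probability a recruit has known (local) parents.
#' @param phenology_year_sd sd (days) of a year-level shock to the season
#'   start (weather), which dilutes the annual-mean age/laying-date
#'   correlation towards the realistic -0.5 range; 0 disables it.
#' @param seed master seed.
#' @return list of class `"colony_dataset"` as in [simulate_qg_dataset()].
#' @export
simulate_colony_study <- function(truth = true_params(), n_years = 29,
                                  pairs_range = c(90, 740), survival = 0.87,
                                  local_recruitment = 0.8,
                                  phenology_year_sd = 3, seed = truth$seed) {
  run_seeded(derive_seed(seed, "study"), {
    target <- round(seq(pairs_range[1], pairs_range[2], length.out = n_years))
    # state: per-individual sex, age, alive, home island
    id <- character(0); sire <- character(0); dam <- character(0)
    sex <- character(0); age <- integer(0); alive <- logical(0)
    home <- integer(0)
    pairs_by_year <- vector("list", n_years)
    nests_all <- vector("list", n_years)
    next_id <- 1L
    new_birds <- function(n, yr, s, d) {
      ids <- sprintf("B%05d", next_id + seq_len(n) - 1L)
      next_id <<- next_id + n
      id <<- c(id, ids); sire <<- c(sire, s); dam <<- c(dam, d)
      sex <<- c(sex, sample(rep(c("M", "F"), length.out = n)))
      age <<- c(age, rep(2L, n)); alive <<- c(alive, rep(TRUE, n))
      home <<- c(home, sample.int(N_ISLANDS, n, replace = TRUE))
      ids
    }
    for (t in seq_len(n_years)) {
      n_alive_f <- sum(alive & sex == "F")
      need <- max(0L, target[t] - n_alive_f)
      if (need > 0) {
        src <- pairs_by_year[[max(1L, t - 2L)]]
        local <- !is.null(src) && t > 2
        ns <- nd <- rep(NA_character_, 2L * need)
        if (local) {
          pick <- sample(nrow(src), 2L * need, replace = TRUE)
          use <- runif(2L * need) < local_recruitment
          ns[use] <- src$sire[pick][use]
          nd[use] <- src$dam[pick][use]
        }
        new_birds(2L * need, t, ns, nd)
      }
      fem <- which(alive & sex == "F")
      mal <- which(alive & sex == "M")
      np <- min(length(fem), length(mal), target[t])
      fem <- sample(fem, np); mal <- sample(mal, np)
      pairs_by_year[[t]] <- data.frame(sire = id[mal], dam = id[fem])
      start_t <- 135 + rnorm(1, 0, phenology_year_sd)
      season <- simulate_colony_season(
        year = t, pairs = np,
        age_distribution = function(n) age[fem],
        phenology = list(season_start = start_t, slope_age = -1.1,
                         sd_noise = 8.5, ref_age = 8),
        female_ids = id[fem],
        seed = derive_seed(seed, "season", t))
      # island fidelity: nest on the home island with high probability
      stay <- runif(np) < 0.94
      season$island <- ifelse(stay, home[fem], season$island)
      nests_all[[t]] <- season
      # survival + ageing
      die <- runif(length(alive)) > survival
      alive[die] <- FALSE
      age[alive] <- age[alive] + 1L
      alive[age > 27L] <- FALSE
    }
    nests <- do.call(rbind, nests_all)
    ped <- pedigree(id, sire, dam)
    nests <- nests[order(nests$year, nests$female_id), ]
    rownames(nests) <- NULL
    # covariates + model-based counts
    nests$colony_density <- stats::ave(nests$year, nests$year, FUN = length)
    yf <- factor(nests$year)
    nests$island_density <- unsplit(lapply(split(nests, yf),
                                           island_density_at_breeding), yf)
    nests <- add_age_partition(nests)
    nests$age_std <- standardize(nests$age)$x
    nests$year_std <- standardize(nests$year)$x
    nests$colony_density_std <- standardize(nests$colony_density)$x
    nests$island_density_std <- standardize(nests$island_density)$x
    nests$laying_date_std <- standardize(nests$laying_date)$x
    nests$wall_std <- standardize(distance_to_nearest_wall(nests$x, nests$y))$x
    k <- if (truth$slopes) 2L else 1L
    G <- if (truth$slopes) truth$G2 else matrix(truth$V_A, 1, 1)
    P <- if (truth$slopes) truth$P2 else matrix(truth$V_PE, 1, 1)
    bv <- simulate_breeding_values(ped, G, seed = derive_seed(seed, "bv"))
    fems <- unique(nests$female_id)
    pe <- run_seeded(derive_seed(seed, "pe"), {
      m <- matrix(rnorm(length(fems) * k), length(fems), k) %*% t(psd_factor(P))
      rownames(m) <- fems
      m
    })
    effects <- list(bv = bv, pe = pe,
                    year = draw_group_effects(seq_len(n_years), truth$V_year, "yr", seed),
                    island = draw_group_effects(seq_len(N_ISLANDS), truth$V_island, "is", seed))
    nests <- simulate_trait_counts(nests, truth, effects,
                                   seed = derive_seed(seed, "counts"))
    structure(list(pedigree = ped, nests = nests, truth = truth,
                   effects = effects, latent_values = attr(nests, "latent")),
              class = "colony_dataset")
  })
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `nests.csv` (one breeding record per row, including the simulated
#' `count`), `pedigree.csv` (id, sire, dam; empty = unknown) and
#' `truth.json` (the generative parameters) into `dir`.
#'
#' @param dataset a `"colony_dataset"` from [simulate_qg_dataset()] or
#'   [simulate_colony_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_colony_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keep <- intersect(c("female_id", "year", "island", "x", "y", "laying_date",
                      "age", "count"), names(dataset$nests))
  write.csv(dataset$nests[keep], file.path(dir, "nests.csv"), row.names = FALSE)
  write_pedigree(dataset$pedigree, file.path(dir, "pedigree.csv"))
  tr <- dataset$truth
  tr$G2 <- as.vector(tr$G2); tr$P2 <- as.vector(tr$P2)
  jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.colony_dataset <- function(x, ...) {
  cat(sprintf("<colony_dataset> %d records, %d females, pedigree of %d\n",
              nrow(x$nests), length(unique(x$nests$female_id)),
              nrow(x$pedigree)))
  invisible(x)
}
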