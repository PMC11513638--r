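# Bayesian MCMC engine for overdispersed-Poisson (Poisson-lognormal) animal
# models.
#
# Model: count_i ~ Poisson(exp(eta_i)),
#        eta = X beta + Z_a a + Z_pe pe + Z_yr yr + Z_is is + e,
#        a ~ N(0, V_A * A), other random intercepts iid normal,
#        e ~ N(0, V_resid) is the latent overdispersion residual.
# Random-regression variants replace the intercept terms by (intercept,
# slope) pairs over a standardized age gradient, with 2x2 covariance
# matrices at the individual or at the genetic + permanent-environment
# level, and five heterogeneous residual variances by age class.
#
# Sampling scheme (MH-within-Gibbs):
#   1. joint Gaussian Gibbs draw of (beta, all random effects) given eta,
#      via the sparse mixed-model normal equations (genetic effects are
#      reparameterized through the pedigree factor L with A = L L', so every
#      random-effect vector has an iid prior);
#   2. single-site random-walk Metropolis update of each latent eta_i
#      (adaptive proposal scales during burn-in only, frozen afterwards);
#   3. conjugate inverse-gamma / inverse-Wishart draws for variances;
#   4. one parameter-expansion move per variance component (scaled working
#      variable xi with a normal prior), giving half-t-type marginal priors
#      on standard deviations and good mixing for variances near zero.

#' Declarative model specification for the animal-model sampler
#'
#' @param response name of the count column.
#' @param fixed one-sided formula of fixed-effect terms (may include
#'   interactions such as `mean_age:delta_age`).
#' @param random character vector of random terms, from: `"genetic"`
#'   (pedigree-linked intercepts), `"permanent_env"`, `"year"`, `"island"`,
#'   `"genetic_slopes"`, `"pe_slopes"`, `"individual_slopes"` (the three
#'   `*_slopes` terms are (intercept, slope) reaction norms over `gradient`).
#'   `"individual_slopes"` may not be combined with `"genetic_slopes"` or
#'   `"pe_slopes"`.
#' @param residual `"homogeneous"` for a single overdispersion variance or
#'   `"by_age_class"` for `n_residual_classes` age-quantile-specific
#'   variances (assumed uncorrelated).
#' @param n_residual_classes number of residual age classes (default 5).
#' @param gradient name of the standardized age column used by slope terms.
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(response = "count",
                       fixed = ~ mean_age + delta_age + mean_age:delta_age +
                         year_std + colony_density_std + island_density_std,
                       random = c("genetic", "permanent_env", "year", "island"),
                       residual = c("homogeneous", "by_age_class"),
                       n_residual_classes = 5,
                       gradient = "age_std") {
  residual <- match.arg(residual)
  allowed <- c("genetic", "permanent_env", "year", "island",
               "genetic_slopes", "pe_slopes", "individual_slopes")
  bad <- setdiff(random, allowed)
  if (length(bad))
    cqg_stop(paste0("unknown random term(s): ", paste(bad, collapse = ", ")),
             "colonyQG_invalid_argument")
  if ("individual_slopes" %in% random &&
      any(c("genetic_slopes", "pe_slopes") %in% random))
    cqg_stop("individual_slopes may not be combined with genetic_slopes/pe_slopes",
             "colonyQG_invalid_argument")
  structure(list(response = response, fixed = fixed, random = random,
                 residual = residual, n_residual_classes = n_residual_classes,
                 gradient = gradient),
            class = "model_spec")
}

#' MCMC configuration
#'
#' @param n_iter total iterations (default 50000).
#' @param burn_in discarded initial iterations (default 8000).
#' @param thin thinning interval (default 35), so the default stores 1200
#'   samples. The defaults are sized so that variance-component chains reach
#'   an effective sample size near 1000 with absolute lag-1 autocorrelation
#'   below 0.1 on a mid-sized colony dataset (hundreds of females, a few
#'   thousand records); shorter chains are adequate for exploratory fits.
#' @param seed integer seed; one seed determines the entire chain.
#' @param mh_sweeps Metropolis sweeps over the latent predictor per Gibbs
#'   iteration.
#' @param marg_moves marginalized variance-component Metropolis moves per
#'   iteration (adaptive correlated proposals on the log scale with all
#'   location effects integrated out; improves mixing of weakly separated
#'   components such as additive-genetic vs permanent-environment variance).
#' @param prior list of prior hyperparameters: `fixed_var` (diffuse normal
#'   variance for fixed effects), `px_nu` and `px_scale` (degrees of freedom
#'   and scale of the half-t-type parameter-expanded prior on each random sd),
#'   `resid_nu`, `resid_V` (inverse-gamma prior for residual variances, as
#'   degree-of-belief and scale), `wishart_df`, `wishart_scale` (inverse-
#'   Wishart working prior for 2x2 covariance matrices).
#' @return list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_iter = 50000, burn_in = 8000, thin = 35, seed = 1L,
                        mh_sweeps = 2, marg_moves = 2,
                        prior = list()) {
  if (burn_in >= n_iter) cqg_stop("burn_in must be < n_iter", "colonyQG_invalid_argument")
  if ((n_iter - burn_in) / thin < 2)
    cqg_stop("(n_iter - burn_in)/thin must allow stored samples",
             "colonyQG_invalid_argument")
  defaults <- list(fixed_var = 1e8, px_nu = 1, px_scale = 1,
                   resid_nu = 0.002, resid_V = 1,
                   wishart_df = 3, wishart_scale = diag(2))
  prior <- utils::modifyList(defaults, prior)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 mh_sweeps = as.integer(mh_sweeps),
                 marg_moves = as.integer(marg_moves), prior = prior),
            class = "mcmc_config")
}

sparse_indicator <- function(f) {
  f <- factor(f)
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                       dims = c(length(f), nlevels(f)),
                       dimnames = list(NULL, levels(f)))
}

# Assemble the random-effect design blocks for a spec.
build_blocks <- function(data, spec, ped_factor) {
  need_ped <- any(c("genetic", "genetic_slopes") %in% spec$random)
  if (need_ped && is.null(ped_factor))
    cqg_stop("genetic terms require a pedigree", "colonyQG_invalid_argument")
  Mg <- NULL
  if (need_ped) {
    L <- ped_factor$L
    miss <- setdiff(unique(data$female_id), rownames(L))
    if (length(miss))
      cqg_stop(paste0(length(miss), " phenotyped female(s) missing from pedigree"),
               "colonyQG_inconsistent_pedigree")
    Mg <- L[match(data$female_id, rownames(L)), , drop = FALSE]
  }
  g <- if (any(grepl("slopes", spec$random))) {
    gr <- data[[spec$gradient]]
    if (is.null(gr)) cqg_stop(paste0("gradient column missing: ", spec$gradient),
                              "colonyQG_schema_error")
    if (abs(mean(gr)) > 0.2 || abs(sd(gr) - 1) > 0.3)
      cqg_warn("gradient does not look mean-centred and variance-standardized",
               "colonyQG_unstandardized_gradient")
    gr
  } else NULL
  Zi <- sparse_indicator(data$female_id)
  blocks <- list()
  for (term in spec$random) {
    b <- switch(term,
      genetic = list(M = Mg, type = "scalar", vname = "V_A"),
      permanent_env = list(M = Zi, type = "scalar", vname = "V_PE"),
      year = list(M = sparse_indicator(data$year), type = "scalar", vname = "V_year"),
      island = list(M = sparse_indicator(data$island), type = "scalar", vname = "V_island"),
      genetic_slopes = list(M = cbind(Mg, g * Mg), type = "pair", vname = "A"),
      pe_slopes = list(M = cbind(Zi, g * Zi), type = "pair", vname = "PE"),
      individual_slopes = list(M = cbind(Zi, g * Zi), type = "pair", vname = "I"))
    b$term <- term
    b$q <- ncol(b$M)
    blocks[[term]] <- b
  }
  blocks
}

rinvgamma1 <- function(shape, rate) 1 / rgamma(1, shape = shape, rate = rate)

rinvwishart <- function(df, S) {
  W <- stats::rWishart(1, df, solve(S))[, , 1]
  solve((W + t(W)) / 2)
}

# Core MH-within-Gibbs sampler. `family = "gaussian"` fixes eta at the
# observed response (identity link), turning the model into a linear mixed
# model: used for oracle tests against REML.
run_animal_mcmc <- function(y, X, blocks, res_class, cfg, family = "poisson") {
  n <- length(y)
  pX <- ncol(X)
  prior <- cfg$prior
  Ws <- c(list(Matrix::Matrix(X, sparse = TRUE)), lapply(blocks, `[[`, "M"))
  W <- do.call(cbind, Ws)
  p <- ncol(W)
  cols <- vector("list", length(blocks)); names(cols) <- names(blocks)
  off <- pX
  for (k in seq_along(blocks)) {
    cols[[k]] <- off + seq_len(blocks[[k]]$q)
    off <- off + blocks[[k]]$q
  }
  nclass <- max(res_class)
  rows_c <- split(seq_len(n), res_class)
  WtW_c <- lapply(rows_c, function(r) {
    M <- methods::as(Matrix::crossprod(W[r, , drop = FALSE]), "symmetricMatrix")
    if (M@uplo != "U") M <- Matrix::t(M)
    M
  })

  # fixed sparsity pattern for the prior-precision matrix Q (stored upper:
  # row index <= column index)
  Qi <- seq_len(pX); Qj <- seq_len(pX)
  for (k in seq_along(blocks)) {
    ck <- cols[[k]]
    if (blocks[[k]]$type == "scalar") {
      Qi <- c(Qi, ck); Qj <- c(Qj, ck)
    } else {
      q2 <- blocks[[k]]$q / 2
      int_c <- ck[seq_len(q2)]; slo_c <- ck[q2 + seq_len(q2)]
      Qi <- c(Qi, int_c, slo_c, int_c)
      Qj <- c(Qj, int_c, slo_c, slo_c)
    }
  }
  make_Qx <- function(state) {
    x <- rep(1 / prior$fixed_var, pX)
    for (k in seq_along(blocks)) {
      b <- blocks[[k]]
      if (b$type == "scalar") {
        x <- c(x, rep(1 / state$V[[k]], b$q))
      } else {
        Ginv <- solve(state$G[[k]])
        q2 <- b$q / 2
        x <- c(x, rep(Ginv[1, 1], q2), rep(Ginv[2, 2], q2), rep(Ginv[1, 2], q2))
      }
    }
    x
  }

  # Assemble C = sum_c WtW_c / Vres_c + Q once symbolically, then update
  # only the numeric slot each iteration (entry positions precomputed).
  dsc_keys <- function(M) {
    i <- M@i + 1L
    j <- rep.int(seq_len(ncol(M)), diff(M@p))
    (as.double(j) - 1) * p + i
  }
  Qmat <- Matrix::sparseMatrix(i = Qi, j = Qj, x = rep(1, length(Qi)),
                               dims = c(p, p), symmetric = TRUE)
  Ct <- Reduce(`+`, WtW_c) + Qmat
  Ct <- methods::as(Ct, "symmetricMatrix")
  keyC <- dsc_keys(Ct)
  map_w <- lapply(WtW_c, function(M) match(dsc_keys(M), keyC))
  keyQ <- (as.double(pmax(Qi, Qj)) - 1) * p + pmin(Qi, Qj)
  stopifnot(Ct@uplo == "U")
  mapQ <- match(keyQ, keyC)
  WtW_x <- lapply(WtW_c, function(M) M@x)
  nnzC <- length(keyC)
  assemble_C <- function(Vres, state) {
    x <- numeric(nnzC)
    for (cl in seq_len(nclass)) {
      ix <- map_w[[cl]]
      x[ix] <- x[ix] + WtW_x[[cl]] / Vres[cl]
    }
    qx <- make_Qx(state)
    # accumulate (duplicate Q positions are distinct entries here only if
    # patterns repeat; they do not, so direct addition is safe)
    x[mapQ] <- x[mapQ] + qx
    Ct@x <- x
    Ct
  }

  # initial state
  state <- list(
    V = lapply(blocks, function(b) if (b$type == "scalar") 0.2 else NULL),
    G = lapply(blocks, function(b) if (b$type == "pair") diag(c(0.2, 0.05)) else NULL),
    xi = lapply(blocks, function(b) if (b$type == "scalar") 1 else c(1, 1)),
    sw2 = lapply(blocks, function(b) if (b$type == "scalar") 0.2 else NULL),
    Omega = lapply(blocks, function(b) if (b$type == "pair") diag(c(0.2, 0.05)) else NULL)
  )
  Vres <- rep(0.3, nclass)
  eta <- if (family == "poisson") log(y + 0.5) else as.numeric(y)
  theta <- rep(0, p)
  mh_scale <- rep(0.6, n)
  acc_sum <- 0; acc_n <- 0
  marg_acc <- 0; marg_n <- 0

  ch <- Matrix::Cholesky(assemble_C(Vres, state), LDL = FALSE, perm = TRUE, super = TRUE)

  # Marginalized Metropolis move on the confounded variance components
  # (genetic vs permanent-environment, and reaction-norm covariance scales):
  # proposes jointly on the log scale with all location effects (beta and
  # every random-effect vector) integrated out analytically, which breaks
  # the strong effect/variance coupling that slows plain Gibbs mixing.
  marg_scalar <- which(vapply(blocks, function(b) b$type == "scalar", TRUE))
  marg_pair <- which(vapply(blocks, function(b) b$type == "pair", TRUE))
  marg_d <- length(marg_scalar) + 2 * length(marg_pair)
  s_marg <- 0.5
  # adaptive (Haario-type) proposal: covariance of the log-variance vector
  # is learned during burn-in so proposals follow the posterior ridge
  get_phi <- function(state) {
    c(unlist(lapply(marg_scalar, function(k) log(state$sw2[[k]]))),
      unlist(lapply(marg_pair, function(k) log(diag(state$Omega[[k]])))))
  }
  phi_mean <- numeric(marg_d)
  phi_M2 <- diag(0, marg_d)
  phi_n <- 0
  Lprop <- diag(0.4, marg_d)
  # log of: marginal likelihood p(eta | V) (up to V-free constants) + prior
  # on the moved components + the log-scale proposal Jacobian terms
  marg_lp <- function(ch, u1, state) {
    ld <- as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    lp <- -ld + 0.5 * sum(u1^2)
    for (k in marg_scalar) {
      lp <- lp - 0.5 * blocks[[k]]$q * log(state$V[[k]])
      sw2 <- state$sw2[[k]]
      lp <- lp + (1 - prior$px_nu / 2) * log(sw2) - prior$px_nu / (2 * sw2)
    }
    for (k in marg_pair) {
      q2 <- blocks[[k]]$q / 2
      Om <- state$Omega[[k]]
      lp <- lp - 0.5 * q2 * log(det(state$G[[k]]))
      lp <- lp + (1.5 - (prior$wishart_df + 3) / 2) * log(det(Om)) -
        0.5 * sum(diag(prior$wishart_scale %*% solve(Om)))
    }
    lp
  }

  n_store <- floor((cfg$n_iter - cfg$burn_in) / cfg$thin)
  store_names <- c(colnames(X), unlist(lapply(blocks, function(b) {
    if (b$type == "scalar") b$vname
    else paste0(c("V_", "V_", "COV_", "r_"), b$vname,
                c("_int", "_slope", "", ""))
  })), if (nclass == 1) "V_resid" else paste0("V_resid_c", seq_len(nclass)))
  samples <- matrix(NA_real_, n_store, length(store_names),
                    dimnames = list(NULL, store_names))
  deviance <- numeric(n_store)
  eta_sum <- numeric(n)
  m_sum <- numeric(n)
  s_idx <- 0L

  for (iter in seq_len(cfg$n_iter)) {
    ## 1. joint Gaussian update of (beta, random effects) | eta, variances
    C <- assemble_C(Vres, state)
    ch <- tryCatch(Matrix::.updateCHMfactor(ch, C, mult = 0),
                   error = function(e) Matrix::Cholesky(C, LDL = FALSE, perm = TRUE, super = TRUE))
    inv_vres <- (1 / Vres)[res_class]
    rhs <- as.vector(Matrix::crossprod(W, eta * inv_vres))
    u1 <- as.vector(Matrix::solve(ch, Matrix::solve(ch, rhs, system = "P"),
                                  system = "L"))

    ## 1b. marginalized variance moves (effects integrated out)
    if (marg_d > 0) {
      lp1 <- marg_lp(ch, u1, state)
      for (mv in seq_len(cfg$marg_moves)) {
        prop <- state
        u <- s_marg * as.vector(Lprop %*% rnorm(marg_d))
        ui <- 1L
        for (k in marg_scalar) {
          prop$sw2[[k]] <- state$sw2[[k]] * exp(u[ui]); ui <- ui + 1L
          prop$V[[k]] <- prop$xi[[k]]^2 * prop$sw2[[k]]
        }
        for (k in marg_pair) {
          D <- diag(exp(u[c(ui, ui + 1L)] / 2)); ui <- ui + 2L
          Om2 <- D %*% state$Omega[[k]] %*% D
          prop$Omega[[k]] <- Om2
          Xi <- diag(prop$xi[[k]])
          prop$G[[k]] <- Xi %*% Om2 %*% Xi
        }
        C2 <- assemble_C(Vres, prop)
        ch2 <- tryCatch(Matrix::.updateCHMfactor(ch, C2, mult = 0),
                        error = function(e) NULL)
        if (is.null(ch2)) next
        u12 <- as.vector(Matrix::solve(ch2, Matrix::solve(ch2, rhs, system = "P"),
                                       system = "L"))
        lp2 <- marg_lp(ch2, u12, prop)
        if (is.finite(lp2) && log(runif(1)) < lp2 - lp1) {
          state <- prop; ch <- ch2; u1 <- u12; lp1 <- lp2
          if (iter > cfg$burn_in) marg_acc <- marg_acc + 1
        }
        if (iter > cfg$burn_in) marg_n <- marg_n + 1
        if (iter <= cfg$burn_in) {
          s_marg <- min(3, max(0.02,
            s_marg * exp(0.08 * (min(1, exp(lp2 - lp1)) - 0.3))))
        }
      }
      if (iter <= cfg$burn_in && iter > 200) {
        # Welford update of the log-variance covariance; refresh the
        # proposal factor periodically so proposals follow the ridge
        phi <- get_phi(state)
        phi_n <- phi_n + 1
        d1 <- phi - phi_mean
        phi_mean <- phi_mean + d1 / phi_n
        phi_M2 <- phi_M2 + tcrossprod(d1, phi - phi_mean)
        if (phi_n >= 300 && phi_n %% 200 == 0) {
          S <- phi_M2 / (phi_n - 1) + diag(1e-6, marg_d)
          Lp_try <- tryCatch(t(chol(2.38^2 / marg_d * S)), error = function(e) NULL)
          if (!is.null(Lp_try)) {
            Lprop <- Lp_try
            s_marg <- 1
          }
        }
      }
    }

    # theta ~ N(C^-1 rhs, C^-1): theta = P'(L')^-1 (L^-1 P rhs + z)
    z <- rnorm(p)
    theta <- as.vector(Matrix::solve(ch, Matrix::solve(ch, u1 + z, system = "Lt"),
                                     system = "Pt"))
    m <- as.vector(W %*% theta)

    ## 2. Metropolis update of the latent predictor (Poisson only)
    if (family == "poisson") {
      vres_i <- Vres[res_class]
      for (s in seq_len(cfg$mh_sweeps)) {
        prop <- eta + rnorm(n, 0, mh_scale)
        logr <- y * (prop - eta) - (exp(prop) - exp(eta)) -
          ((prop - m)^2 - (eta - m)^2) / (2 * vres_i)
        acc <- log(runif(n)) < logr
        eta[acc] <- prop[acc]
        if (iter <= cfg$burn_in) {
          gain <- 1 / sqrt(iter)
          mh_scale <- pmin(10, pmax(0.01,
            mh_scale * exp(gain * (pmin(1, exp(logr)) - 0.44))))
        } else {
          acc_sum <- acc_sum + sum(acc); acc_n <- acc_n + n
        }
      }
    }

    ## 3. residual variances, conjugate
    e <- eta - m
    for (cl in seq_len(nclass)) {
      ec <- e[rows_c[[cl]]]
      Vres[cl] <- rinvgamma1((prior$resid_nu + length(ec)) / 2,
                             (prior$resid_nu * prior$resid_V + sum(ec^2)) / 2)
    }

    ## 4. parameter-expansion variance updates per block
    vres_i <- Vres[res_class]
    for (k in seq_along(blocks)) {
      b <- blocks[[k]]
      ck <- cols[[k]]
      if (b$type == "scalar") {
        xi <- state$xi[[k]]
        if (abs(xi) < 1e-10) xi <- sign(xi + 1e-16) * 1e-10
        w <- theta[ck] / xi
        sw2 <- rinvgamma1((prior$px_nu + b$q) / 2,
                          (prior$px_nu + sum(w^2)) / 2)
        x <- as.vector(b$M %*% w)
        r <- e + xi * x
        prec <- sum(x^2 / vres_i) + 1 / prior$px_scale^2
        mn <- sum(x * r / vres_i) / prec
        xi_new <- rnorm(1, mn, sqrt(1 / prec))
        theta[ck] <- xi_new * w
        m <- m + (xi_new - xi) * x
        e <- eta - m
        state$xi[[k]] <- xi_new
        state$sw2[[k]] <- sw2
        state$V[[k]] <- xi_new^2 * sw2
      } else {
        q2 <- b$q / 2
        xi <- state$xi[[k]]
        xi[abs(xi) < 1e-10] <- 1e-10
        U <- cbind(theta[ck[seq_len(q2)]], theta[ck[q2 + seq_len(q2)]])
        W2 <- sweep(U, 2, xi, "/")
        Omega <- rinvwishart(prior$wishart_df + q2,
                             prior$wishart_scale + crossprod(W2))
        x1 <- as.vector(b$M[, seq_len(q2), drop = FALSE] %*% W2[, 1])
        x2 <- as.vector(b$M[, q2 + seq_len(q2), drop = FALSE] %*% W2[, 2])
        r <- e + xi[1] * x1 + xi[2] * x2
        D <- cbind(x1, x2)
        P2m <- crossprod(D / sqrt(vres_i)) + diag(1 / prior$px_scale^2, 2)
        bvec <- as.vector(crossprod(D, r / vres_i))
        Pc <- chol(P2m)
        mn <- backsolve(Pc, backsolve(Pc, bvec, transpose = TRUE))
        xi_new <- as.vector(mn + backsolve(Pc, rnorm(2)))
        theta[ck] <- c(xi_new[1] * W2[, 1], xi_new[2] * W2[, 2])
        m <- m + (xi_new[1] - xi[1]) * x1 + (xi_new[2] - xi[2]) * x2
        e <- eta - m
        state$xi[[k]] <- xi_new
        state$Omega[[k]] <- Omega
        state$G[[k]] <- diag(xi_new) %*% Omega %*% diag(xi_new)
      }
    }

    ## 5. record
    if (iter > cfg$burn_in && (iter - cfg$burn_in) %% cfg$thin == 0) {
      s_idx <- s_idx + 1L
      if (s_idx <= n_store) {
        vals <- theta[seq_len(pX)]
        for (k in seq_along(blocks)) {
          b <- blocks[[k]]
          if (b$type == "scalar") {
            vals <- c(vals, state$V[[k]])
          } else {
            G <- state$G[[k]]
            vals <- c(vals, G[1, 1], G[2, 2], G[1, 2],
                      G[1, 2] / sqrt(G[1, 1] * G[2, 2]))
          }
        }
        vals <- c(vals, Vres)
        samples[s_idx, ] <- vals
        deviance[s_idx] <- if (family == "poisson") {
          -2 * sum(dpois(y, exp(eta), log = TRUE))
        } else {
          -2 * sum(stats::dnorm(y, m, sqrt(Vres[res_class]), log = TRUE))
        }
        eta_sum <- eta_sum + eta
        m_sum <- m_sum + m
      }
    }
  }
  if (any(!is.finite(deviance)))
    cqg_stop("sampler diverged: non-finite deviance in stored samples",
             "colonyQG_sampler_failure")
  list(samples = as.data.frame(samples), deviance = deviance,
       eta_mean = eta_sum / s_idx, m_mean = m_sum / s_idx,
       accept_rate = if (acc_n) acc_sum / acc_n else NA_real_,
       marg_accept_rate = if (marg_n) marg_acc / marg_n else NA_real_,
       marg_step = s_marg)
}

#' Fit a Bayesian Poisson-lognormal animal model
#'
#' Fits the overdispersed-Poisson generalized linear mixed model described in
#' [model_spec()] by MCMC, with additive genetic effects structured by the
#' pedigree-derived relationship matrix.
#'
#' @param trait_table data.frame with the response, fixed-effect covariates,
#'   `female_id`, `year`, `island` and (for residual age classes or slope
#'   terms) `age` / the gradient column.
#' @param pedigree a [pedigree()] object covering all phenotyped females, or
#'   `NULL` for models without genetic terms.
#' @param spec a [model_spec()].
#' @param config an [mcmc_config()].
#' @param family `"poisson"` (default) for the count model; `"gaussian"`
#'   treats the response as the directly observed latent predictor (identity
#'   link), the linear-mixed-model special case used in validation.
#' @param ped_factor optional precomputed [pedigree_factor()] (skips
#'   refactoring when fitting several models to one pedigree).
#' @return An object of class `"posterior_chains"`: stored samples (fixed
#'   effects, variance components, derived covariances/correlations,
#'   residual variances), the deviance trace, and metadata.
#' @export
fit_glmm_animal <- function(trait_table, pedigree = NULL, spec = model_spec(),
                            config = mcmc_config(), family = c("poisson", "gaussian"),
                            ped_factor = NULL) {
  family <- match.arg(family)
  if (!spec$response %in% names(trait_table))
    cqg_stop(paste0("response column missing: ", spec$response),
             "colonyQG_schema_error")
  y <- trait_table[[spec$response]]
  if (family == "poisson" && (any(y < 0) || any(y != round(y))))
    cqg_stop("response must be non-negative integer counts",
             "colonyQG_invalid_argument")
  mf_vars <- all.vars(spec$fixed)
  miss <- setdiff(mf_vars, names(trait_table))
  if (length(miss))
    cqg_stop(paste0("fixed-effect column(s) missing: ", paste(miss, collapse = ", ")),
             "colonyQG_schema_error")
  X <- model.matrix(spec$fixed, trait_table)
  if (is.null(ped_factor) && !is.null(pedigree)) ped_factor <- pedigree_factor(pedigree)
  blocks <- build_blocks(trait_table, spec, ped_factor)
  res_class <- if (spec$residual == "by_age_class") {
    assign_age_classes(trait_table$age, spec$n_residual_classes)
  } else rep(1L, nrow(trait_table))
  fit <- run_seeded(config$seed, run_animal_mcmc(y, X, blocks, res_class,
                                                 config, family))
  structure(list(samples = fit$samples, deviance = fit$deviance,
                 eta_mean = fit$eta_mean, m_mean = fit$m_mean,
                 y = y, spec = spec, config = config, family = family,
                 res_class = res_class,
                 meta = list(trait_mean = mean(y), n_obs = length(y),
                             n_females = length(unique(trait_table$female_id)),
                             accept_rate = fit$accept_rate,
                             marg_accept_rate = fit$marg_accept_rate,
                             marg_step = fit$marg_step)),
            class = "posterior_chains")
}

#' Fit a random-regression (reaction-norm) animal model
#'
#' Random intercepts and slopes over a standardized age gradient, either at
#' the individual level (an unstructured 2x2 individual covariance matrix)
#' or split into additive genetic plus permanent-environment levels
#' (genotype-by-age and permanent-environment-by-age interactions), with
#' year and island intercepts and five age-class residual variances.
#'
#' @param trait_table as in [fit_glmm_animal()]; the gradient column must be
#'   mean-centred and variance-standardized.
#' @param pedigree required for `level = "genetic+pe"`.
#' @param level `"individual"` or `"genetic+pe"`.
#' @param gradient name of the standardized age column.
#' @param fixed fixed-effect formula (actual standardized age, not the
#'   partitioned components, plus the other covariates).
#' @param config an [mcmc_config()].
#' @param n_residual_classes number of residual age classes (default 5).
#' @param ped_factor optional precomputed [pedigree_factor()].
#' @return A `"posterior_chains"` object; intercept/slope variances,
#'   covariances and correlations appear as `V_<lev>_int`, `V_<lev>_slope`,
#'   `COV_<lev>`, `r_<lev>` with `<lev>` one of `I`, `A`, `PE`.
#' @export
fit_random_regression <- function(trait_table, pedigree = NULL,
                                  level = c("individual", "genetic+pe"),
                                  gradient = "age_std",
                                  fixed = ~ age_std + year_std +
                                    colony_density_std + island_density_std,
                                  config = mcmc_config(),
                                  n_residual_classes = 5,
                                  ped_factor = NULL) {
  level <- match.arg(level)
  random <- if (level == "individual") {
    c("individual_slopes", "year", "island")
  } else {
    c("genetic_slopes", "pe_slopes", "year", "island")
  }
  spec <- model_spec(response = "count", fixed = fixed, random = random,
                     residual = "by_age_class",
                     n_residual_classes = n_residual_classes,
                     gradient = gradient)
  fit_glmm_animal(trait_table, pedigree = pedigree, spec = spec,
                  config = config, ped_factor = ped_factor)
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat(sprintf("<posterior_chains> %d stored samples, %d observations (%s family)\n",
              nrow(x$samples), x$meta$n_obs, x$family))
  cat("monitored:", paste(colnames(x$samples), collapse = ", "), "\n")
  invisible(x)
}
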