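# Posterior summaries: KDE modes, HPD intervals, effective sample sizes,
# DIC, variance decompositions and posterior contrasts.

check_samples <- function(samples, min_n) {
  samples <- as.numeric(samples)
  if (anyNA(samples)) cqg_stop("samples contain NA", "colonyQG_invalid_argument")
  if (length(samples) < min_n)
    cqg_stop(paste0("need at least ", min_n, " samples"),
             "colonyQG_insufficient_samples")
  samples
}

#' Posterior mode via kernel density estimation
#'
#' The mode of a Gaussian-kernel density estimate, the point-estimate
#' convention for skewed variance posteriors. A narrow bandwidth (0.2 times
#' the "nrd0" reference, in the spirit of the small `adjust` values
#' customary for variance-component posteriors) keeps the bias low for
#' strongly skewed densities; the peak location is then refined by a
#' parabolic fit over the top 15% of the density curve, which averages out
#' the grid- and sampling-noise of the raw argmax.
#'
#' @param samples numeric vector of at least 100 posterior draws.
#' @return the refined abscissa of the KDE maximum.
#' @export
posterior_mode <- function(samples) {
  samples <- check_samples(samples, 100)
  if (var(samples) == 0) return(samples[1])
  d <- density(samples, adjust = 0.2, n = 2048)
  w <- which(d$y >= 0.85 * max(d$y))
  peak <- d$x[which.max(d$y)]
  if (length(w) < 4) return(peak)
  co <- coef(lm(y ~ x + I(x^2), data.frame(x = d$x[w], y = d$y[w])))
  if (anyNA(co) || co[3] >= 0) return(peak)
  v <- unname(-co[2] / (2 * co[3]))
  if (v < min(d$x[w]) || v > max(d$x[w])) peak else v
}

#' Highest posterior density interval
#'
#' The shortest interval containing a fraction `prob` of the samples,
#' computed from the order statistics.
#'
#' @param samples numeric vector of at least 100 posterior draws.
#' @param prob coverage probability in (0, 1); default 0.95.
#' @return numeric `c(lo, hi)`.
#' @export
hpd_interval <- function(samples, prob = 0.95) {
  if (!is.numeric(prob) || length(prob) != 1 || prob <= 0 || prob >= 1)
    cqg_stop("prob must be in (0, 1)", "colonyQG_invalid_argument")
  samples <- check_samples(samples, 100)
  xs <- sort(samples)
  n <- length(xs)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(lo = xs[1], hi = xs[n]))
  widths <- xs[(k + 1):n] - xs[1:(n - k)]
  i <- which.min(widths)
  c(lo = xs[i], hi = xs[i + k])
}

#' Effective sample size and lag-1 autocorrelation of a chain
#'
#' ESS by the initial positive sequence estimator: the integrated
#' autocorrelation time is `2 * sum(Gamma_m) - 1` with
#' `Gamma_m = rho(2m) + rho(2m+1)`, summed until the first non-positive
#' pair; `ess = n / tau`.
#'
#' @param samples numeric chain of at least 10 values.
#' @return list with `ess` and `lag1_autocorr`.
#' @export
ess_and_autocorr <- function(samples) {
  samples <- check_samples(samples, 10)
  if (var(samples) == 0)
    cqg_stop("zero-variance chain: autocorrelation undefined",
             "colonyQG_undefined_autocorrelation")
  n <- length(samples)
  lag_max <- min(n - 1, 1000)
  rho <- as.vector(acf(samples, lag.max = lag_max, plot = FALSE,
                       demean = TRUE)$acf)
  gam_sum <- 0
  m <- 0
  repeat {
    i1 <- 2 * m + 1; i2 <- 2 * m + 2   # rho(2m), rho(2m+1) (1-based)
    if (i1 > length(rho)) break
    g <- rho[i1] + if (i2 <= length(rho)) rho[i2] else 0
    if (g <= 0) break
    gam_sum <- gam_sum + g
    m <- m + 1
  }
  tau <- max(2 * gam_sum - 1, 1e-8)
  list(ess = min(n / tau, n * 1.5), lag1_autocorr = rho[2])
}

#' Deviance information criterion
#'
#' `DIC = mean(D) + pD` with `pD = mean(D) - D(posterior mean of the latent
#' predictor)` — the conditional-deviance convention, in which the deviance
#' is evaluated at the posterior mean of `eta` (Poisson) or of the fitted
#' values and residual variance (Gaussian). Lower is better. DIC for
#' hierarchical models is representation-dependent; this convention focuses
#' on the observation-level fit.
#'
#' @param chains a `"posterior_chains"` object.
#' @return list with `dic`, `mean_deviance`, `pD`.
#' @export
dic <- function(chains) {
  if (is.null(chains$deviance) || !length(chains$deviance))
    cqg_stop("no deviance trace stored", "colonyQG_invalid_argument")
  dbar <- mean(chains$deviance)
  dhat <- if (chains$family == "poisson") {
    -2 * sum(dpois(chains$y, exp(chains$eta_mean), log = TRUE))
  } else {
    vres_cols <- grep("^V_resid", colnames(chains$samples))
    vhat <- colMeans(chains$samples[, vres_cols, drop = FALSE])
    vr <- if (length(vhat) == 1) rep(vhat, length(chains$y)) else vhat[chains$res_class]
    -2 * sum(stats::dnorm(chains$y, chains$m_mean, sqrt(vr), log = TRUE))
  }
  pd <- dbar - dhat
  list(dic = dbar + pd, mean_deviance = dbar, pD = pd)
}

#' Latent-scale variance decomposition of an intercept animal model
#'
#' Per posterior sample, the phenotypic variance `V_P` is the sum of all
#' estimated random-component variances (additive genetic, permanent
#' environment, year, island and the overdispersion residual; fixed-effect
#' variance excluded, i.e. conditional on the fixed effects). Heritability
#' `h2 = V_A / V_P`, repeatability `R = (V_A + V_PE) / V_P`, and analogous
#' proportions for year, island and residual are formed sample-wise and then
#' summarized (posterior mode, median, 95% HPD). Evolvability
#' `CV_A = 100 * sqrt(V_A) / mean(trait)` uses the data-scale trait mean.
#'
#' @param chains a `"posterior_chains"` object from an intercept model.
#' @param trait_mean data-scale trait mean for `CV_A`; defaults to the mean
#'   of the fitted response.
#' @return list of class `"variance_decomposition"` with per-sample chains
#'   (`chains`) and a summary table (`summary`: mode, median, lower, upper
#'   per quantity).
#' @export
variance_decomposition <- function(chains, trait_mean = chains$meta$trait_mean) {
  s <- chains$samples
  need <- c("V_A", "V_PE", "V_year", "V_island", "V_resid")
  if (!all(need %in% colnames(s)))
    cqg_stop("variance decomposition needs an intercept animal model with genetic, permanent_env, year and island terms",
             "colonyQG_wrong_model")
  vp <- s$V_A + s$V_PE + s$V_year + s$V_island + s$V_resid
  per_sample <- data.frame(
    V_P = vp,
    h2 = s$V_A / vp,
    R = (s$V_A + s$V_PE) / vp,
    prop_pe = s$V_PE / vp,
    prop_year = s$V_year / vp,
    prop_island = s$V_island / vp,
    prop_resid = s$V_resid / vp,
    CV_A = 100 * sqrt(s$V_A) / trait_mean
  )
  summ <- t(vapply(per_sample, function(x) {
    h <- hpd_interval(x)
    c(mode = posterior_mode(x), median = median(x), lower = h[[1]], upper = h[[2]])
  }, numeric(4)))
  structure(list(chains = per_sample, summary = as.data.frame(summ),
                 trait_mean = trait_mean),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Latent-scale variance decomposition (mode [95% HPD]):\n")
  s <- x$summary
  for (nm in rownames(s)) {
    cat(sprintf("  %-12s %8.4f  [%8.4f, %8.4f]\n", nm, s[nm, "mode"],
                s[nm, "lower"], s[nm, "upper"]))
  }
  invisible(x)
}

#' Reaction-norm (random-regression) estimates
#'
#' Extracts, for each fitted level (individual `I`, genetic `A`,
#' permanent-environment `PE`), the posterior of intercept variance, slope
#' variance, intercept-slope covariance and correlation, and the implied
#' variance-at-age function `V(g) = V_int + 2 g COV + g^2 V_slope`.
#'
#' @param chains a `"posterior_chains"` object from [fit_random_regression()].
#' @param gradient_values gradient points at which to summarize `V(g)`.
#' @return list of class `"reaction_norm_estimates"` with one element per
#'   level: `summary` (mode, median, HPD per quantity) and `variance_at_age`
#'   (matrix of posterior modes and HPD bounds over `gradient_values`).
#' @export
reaction_norm_estimates <- function(chains, gradient_values = seq(-2, 2, 0.5)) {
  s <- chains$samples
  levels_present <- intersect(c("I", "A", "PE"),
                              sub("^V_(I|A|PE)_int$", "\\1",
                                  grep("^V_(I|A|PE)_int$", colnames(s), value = TRUE)))
  if (!length(levels_present))
    cqg_stop("no random-regression terms in these chains", "colonyQG_wrong_model")
  out <- lapply(levels_present, function(lev) {
    vi <- s[[paste0("V_", lev, "_int")]]
    vs <- s[[paste0("V_", lev, "_slope")]]
    cv <- s[[paste0("COV_", lev)]]
    rr <- s[[paste0("r_", lev)]]
    qs <- list(V_int = vi, V_slope = vs, COV = cv, r = rr)
    summ <- t(vapply(qs, function(x) {
      h <- hpd_interval(x)
      c(mode = posterior_mode(x), median = median(x), lower = h[[1]], upper = h[[2]])
    }, numeric(4)))
    vag <- t(vapply(gradient_values, function(g) {
      vg <- vi + 2 * g * cv + g^2 * vs
      h <- hpd_interval(vg)
      c(gradient = g, mode = posterior_mode(vg), lower = h[[1]], upper = h[[2]])
    }, numeric(4)))
    list(summary = as.data.frame(summ), variance_at_age = as.data.frame(vag))
  })
  names(out) <- levels_present
  structure(out, class = "reaction_norm_estimates")
}

#' Posterior contrast between two aligned chains
#'
#' Elementwise difference `a - b` of two equal-length chains from one
#' posterior (e.g. the mean-age and delta-age effects, whose difference
#' tests for selective disappearance), summarized by mode, median and HPD.
#'
#' @param chain_a,chain_b numeric chains of equal length.
#' @return list with `mode`, `median`, `lower`, `upper`, `prob_positive`
#'   and the `difference` chain.
#' @export
posterior_contrast <- function(chain_a, chain_b) {
  if (length(chain_a) != length(chain_b))
    cqg_stop("chains must be of equal length", "colonyQG_alignment_error")
  d <- as.numeric(chain_a) - as.numeric(chain_b)
  h <- hpd_interval(d)
  list(mode = posterior_mode(d), median = median(d),
       lower = h[[1]], upper = h[[2]],
       prob_positive = mean(d > 0), difference = d)
}

#' Summarize every monitored parameter of a fit
#'
#' @param object a `"posterior_chains"` object.
#' @param ... unused.
#' @return data.frame with posterior mode, median, 95% HPD bounds, ESS and
#'   lag-1 autocorrelation per monitored parameter.
#' @export
summary.posterior_chains <- function(object, ...) {
  s <- object$samples
  rows <- lapply(colnames(s), function(nm) {
    x <- s[[nm]]
    h <- hpd_interval(x)
    ea <- tryCatch(ess_and_autocorr(x),
                   error = function(e) list(ess = NA_real_, lag1_autocorr = NA_real_))
    data.frame(parameter = nm, mode = posterior_mode(x), median = median(x),
               lower = h[[1]], upper = h[[2]], ess = ea$ess,
               lag1 = ea$lag1_autocorr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write posterior chains to CSV plus JSON metadata
#'
#' @param chains a `"posterior_chains"` object.
#' @param path CSV output path (one column per monitored parameter plus the
#'   deviance); metadata is written to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_chains <- function(chains, path) {
  out <- chains$samples
  out$deviance <- chains$deviance
  write.csv(out, path, row.names = FALSE)
  meta <- list(family = chains$family,
               n_obs = chains$meta$n_obs, n_females = chains$meta$n_females,
               trait_mean = chains$meta$trait_mean,
               random = chains$spec$random,
               fixed = deparse(chains$spec$fixed),
               residual = chains$spec$residual,
               config = chains$config[c("n_iter", "burn_in", "thin", "seed")])
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
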