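# Independent oracles used across the suite. These deliberately use naive
# algorithms (memoized recursion, exhaustive double loops) so that they share
# no code with the implementation they check.

# 2 x kinship coefficient by memoized recursion over the pedigree.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  memo <- new.env(hash = TRUE)
  phi <- function(a, b) {
    if (a < b) { t <- a; a <- b; b <- t }
    key <- paste(a, b)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (a == b) {
      f <- if (!is.na(si[a]) && !is.na(di[a])) phi(si[a], di[a]) else 0
      0.5 * (1 + f)
    } else {
      # a is later in the (topologically sorted) pedigree than b
      ps <- if (!is.na(si[a])) phi(si[a], b) else 0
      pd <- if (!is.na(di[a])) phi(di[a], b) else 0
      0.5 * (ps + pd)
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (a in seq_len(n)) for (b in seq_len(a)) {
    A[a, b] <- A[b, a] <- 2 * phi(a, b)
  }
  A
}

# Random pedigree with arbitrary missing parents and cross-generation matings.
random_test_pedigree <- function(n, seed) {
  set.seed(seed)
  id <- sprintf("i%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && runif(1) < 0.7) {
      pool <- seq_len(i - 1)
      p <- sample(pool, min(2, length(pool)))
      sire[i] <- id[p[1]]
      if (length(p) > 1 && runif(1) < 0.85) dam[i] <- id[p[2]]
    }
  }
  pedigree(id, sire, dam)
}

# Exhaustive O(n^2) neighbour-count oracle: plain double loop.
neighbour_count_oracle <- function(records, radius_m, window_days) {
  n <- nrow(records)
  counts <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (records$island[j] != records$island[i]) next
      d <- sqrt((records$x[i] - records$x[j])^2 + (records$y[i] - records$y[j])^2)
      if (d > radius_m) next
      lag <- records$laying_date[i] - records$laying_date[j]
      if (lag >= 0 && lag <= window_days) counts[i] <- counts[i] + 1L
    }
  }
  counts
}

random_test_season <- function(n, seed, year = 2000) {
  set.seed(seed)
  data.frame(female_id = sprintf("f%03d", seq_len(n)),
             year = year,
             island = sample.int(6, n, replace = TRUE),
             x = runif(n, 0, 10.7),
             y = runif(n, 0, 4.6),
             laying_date = sample(120:180, n, replace = TRUE),
             age = sample(2:20, n, replace = TRUE))
}

# Short MCMC configuration for unit tests (not for inference quality).
quick_cfg <- function(seed, n_iter = 1500, burn_in = 500, thin = 2) {
  mcmc_config(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed)
}
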