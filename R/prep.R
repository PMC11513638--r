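# Model covariate preparation: within-subject centring of age,
# standardization, residual age classes.

#' Partition age into between- and within-individual components
#'
#' Within-subject centring: each female's ages are split into her mean age
#' over all her records (`mean_age`, the between-individual component) and
#' the annual deviation from that mean (`delta_age`, the within-individual
#' component). `age = mean_age + delta_age` holds exactly row-wise, and
#' `delta_age` sums to zero within each female. A female with a single record
#' has `delta_age = 0`.
#'
#' @param trait_table data.frame with `female_id` and `age` columns; ages
#'   must all be known (filter first with [apply_study_filters()]).
#' @return data.frame with columns `female_id`, `age`, `mean_age`,
#'   `delta_age`.
#' @seealso [add_age_partition()] to append the columns in place.
#' @export
partition_age <- function(trait_table) {
  if (anyNA(trait_table$age))
    cqg_stop("unknown ages present; apply_study_filters() first",
             "colonyQG_must_filter_first")
  mean_age <- stats::ave(as.numeric(trait_table$age), trait_table$female_id)
  data.frame(female_id = trait_table$female_id,
             age = trait_table$age,
             mean_age = mean_age,
             delta_age = trait_table$age - mean_age)
}

#' @rdname partition_age
#' @export
add_age_partition <- function(trait_table) {
  p <- partition_age(trait_table)
  trait_table$mean_age <- p$mean_age
  trait_table$delta_age <- p$delta_age
  trait_table
}

#' Mean-centre and variance-standardize a covariate
#'
#' Centres at the mean and divides by the population standard deviation
#' (denominator `n`, not `n - 1`) times `divisor_sd_multiples`; with the
#' default the result has mean 0 and population sd 1. Setting
#' `divisor_sd_multiples = 2` gives the Gelman convention in which slopes are
#' per two standard deviations. The centre and scale are recorded for exact
#' back-transformation.
#'
#' @param x numeric vector with positive variance.
#' @param divisor_sd_multiples how many standard deviations one standardized
#'   unit represents (default 1).
#' @return list with `x` (standardized values), `center`, `scale`.
#' @export
standardize <- function(x, divisor_sd_multiples = 1) {
  x <- as.numeric(x)
  s <- sqrt(mean((x - mean(x))^2))
  if (!is.finite(s) || s == 0)
    cqg_stop("column has zero variance; cannot standardize",
             "colonyQG_degenerate_column")
  center <- mean(x)
  scale <- s * divisor_sd_multiples
  list(x = (x - center) / scale, center = center, scale = scale)
}

#' Invert [standardize()]
#'
#' @param z standardized values.
#' @param std the list returned by [standardize()].
#' @return the original-scale values.
#' @export
unstandardize <- function(z, std) z * std$scale + std$center

#' Assign quantile-based age classes
#'
#' Bins actual ages into `n_classes` quantile classes (used for
#' heterogeneous residual variances in random-regression models). Ties go to
#' the lower bin; every returned class is non-empty. If fewer distinct ages
#' than classes exist, the number of classes is reduced with a warning.
#'
#' @param ages numeric vector.
#' @param n_classes number of classes (default 5).
#' @return integer vector of class labels in `1:n_classes`.
#' @export
assign_age_classes <- function(ages, n_classes = 5) {
  if (!is_count(n_classes) || n_classes < 1)
    cqg_stop("n_classes must be a positive integer", "colonyQG_invalid_argument")
  if (n_classes == 1) return(rep(1L, length(ages)))
  # exact type-1 quantile breaks (order statistics at ceiling(k*n/c)),
  # avoiding floating-point drift in probability grids
  xs <- sort(ages)
  n <- length(xs)
  pos <- ceiling(seq_len(n_classes - 1) * n / n_classes)
  breaks <- unique(c(xs[1], xs[pos], xs[n]))
  if (length(breaks) - 1 < n_classes)
    cqg_warn(sprintf("only %d distinct quantile bins available (asked for %d)",
                     length(breaks) - 1, n_classes), "colonyQG_reduced_classes")
  # ties to the lower bin: right-open intervals, last bin closed
  lab <- findInterval(ages, breaks, rightmost.closed = TRUE, left.open = TRUE)
  lab[ages <= breaks[1]] <- 1L
  as.integer(lab)
}
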