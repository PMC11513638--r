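# Construction of the social trait (active-neighbour count) and spatial /
# phenological covariates from mapped nest records.

check_one_year <- function(records) {
  if (length(unique(records$year)) > 1)
    cqg_stop("records span multiple years; compute per season (see build_trait_table)",
             "colonyQG_grouping_error")
}

#' Count actively breeding neighbours around each nest
#'
#' For a focal nest, a neighbour is any other nest on the same island within
#' `radius_m` metres (Euclidean, ties at the radius included) whose clutch
#' was initiated within `window_days` days *before* (or on the same day as)
#' the focal laying date. The window is one-sided: a nest started after the
#' focal date never counts, so two same-day nests count each other but an
#' earlier layer does not count a later one.
#'
#' @param records data.frame of nest records from one season (columns
#'   `island`, `x`, `y`, `laying_date`).
#' @param radius_m neighbourhood radius in metres (> 0); default 2.
#' @param window_days activity window in days; default 28 (four weeks, the
#'   laying-to-hatching span during which a pair attends its nest).
#' @return integer vector of neighbour counts, aligned with `records`.
#' @export
count_active_neighbours <- function(records, radius_m = 2, window_days = 28) {
  if (!is.numeric(radius_m) || radius_m <= 0)
    cqg_stop("radius_m must be > 0", "colonyQG_invalid_argument")
  check_one_year(records)
  n <- nrow(records)
  counts <- integer(n)
  for (isl in unique(records$island)) {
    ii <- which(records$island == isl)
    if (length(ii) < 2) next
    dx <- outer(records$x[ii], records$x[ii], "-")
    dy <- outer(records$y[ii], records$y[ii], "-")
    close_enough <- sqrt(dx^2 + dy^2) <= radius_m
    dl <- outer(records$laying_date[ii], records$laying_date[ii], "-")
    active <- dl >= 0 & dl <= window_days   # focal (row) minus other (col)
    m <- close_enough & active
    diag(m) <- FALSE
    counts[ii] <- as.integer(rowSums(m))
  }
  counts
}

#' Island density at the time of breeding
#'
#' Number of nests (excluding the focal one) initiated on the focal island in
#' the `window_days` days up to and including the focal laying date.
#' Equivalent to [count_active_neighbours()] with an infinite radius.
#'
#' @inheritParams count_active_neighbours
#' @return integer vector aligned with `records`.
#' @export
island_density_at_breeding <- function(records, window_days = 28) {
  check_one_year(records)
  n <- nrow(records)
  counts <- integer(n)
  for (isl in unique(records$island)) {
    ii <- which(records$island == isl)
    if (length(ii) < 2) next
    dl <- outer(records$laying_date[ii], records$laying_date[ii], "-")
    m <- dl >= 0 & dl <= window_days
    diag(m) <- FALSE
    counts[ii] <- as.integer(rowSums(m))
  }
  counts
}

#' Distance from a nest to the nearest island wall
#'
#' Islands are 10.7 x 4.6 m rectangles; the distance to the nearest of the
#' four walls is `min(x, 10.7 - x, y, 4.6 - y)`.
#'
#' @param x,y coordinates in metres along the long and short island sides.
#' @param island_dims island rectangle (metres).
#' @return numeric vector of distances in metres, in `[0, 2.3]` for the
#'   default island.
#' @export
distance_to_nearest_wall <- function(x, y, island_dims = c(ISLAND_LEN, ISLAND_WID)) {
  if (any(x < 0 | x > island_dims[1] | y < 0 | y > island_dims[2], na.rm = TRUE))
    cqg_stop("coordinates outside the island rectangle", "colonyQG_invalid_coordinate")
  pmin(x, island_dims[1] - x, y, island_dims[2] - y)
}

#' Apply the study's record filters
#'
#' `mode = "known_age"` drops every record of females whose age is unknown in
#' any record (age must be known to partition it). `mode = "presumed_dead"`
#' additionally keeps only females that can be presumed dead because they
#' were not observed in either of the two most recent seasons.
#'
#' @param records data.frame with `female_id` and `age` columns.
#' @param mode `"known_age"` or `"presumed_dead"`.
#' @param last_observation_year the final monitored season (required for
#'   `"presumed_dead"`); females whose latest record is in that season or the
#'   one before are removed.
#' @return the filtered data.frame.
#' @export
apply_study_filters <- function(records, mode = c("known_age", "presumed_dead"),
                                last_observation_year = NULL) {
  mode <- match.arg(mode)
  if (!"age" %in% names(records))
    cqg_stop("records must contain an age column", "colonyQG_schema_error")
  unknown <- unique(records$female_id[is.na(records$age)])
  out <- records[!(records$female_id %in% unknown), , drop = FALSE]
  if (mode == "presumed_dead") {
    if (is.null(last_observation_year))
      cqg_stop("presumed_dead filtering requires last_observation_year",
               "colonyQG_config_error")
    last_seen <- tapply(out$year, out$female_id, max)
    maybe_alive <- names(last_seen)[last_seen >= last_observation_year - 1]
    out <- out[!(out$female_id %in% maybe_alive), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Build the analysis-ready trait table from nest records
#'
#' Groups multi-season records by year and computes, per record: the
#' active-neighbour count (the social trait), island density at breeding,
#' distance to the nearest wall, and colony density (number of nests that
#' season).
#'
#' @param records data.frame of nest records (any number of seasons).
#' @param radius_m,window_days passed to [count_active_neighbours()].
#' @return `records` with added columns `neighbour_count`, `island_density`,
#'   `wall_distance`, `colony_density`.
#' @export
build_trait_table <- function(records, radius_m = 2, window_days = 28) {
  f <- factor(records$year)
  parts <- split(records, f)
  records$neighbour_count <- unsplit(lapply(parts, count_active_neighbours,
                                            radius_m = radius_m,
                                            window_days = window_days), f)
  records$island_density <- unsplit(lapply(parts, island_density_at_breeding,
                                           window_days = window_days), f)
  records$wall_distance <- distance_to_nearest_wall(records$x, records$y)
  records$colony_density <- stats::ave(records$year, records$year, FUN = length)
  records
}
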