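test_that("neighbour counting applies the one-sided window and radius ties", {
  two <- data.frame(female_id = c("a", "b"), year = 1, island = 1,
                    x = c(0, 1.5), y = c(0, 0), laying_date = c(100, 110))
  expect_equal(count_active_neighbours(two), c(0L, 1L))  # later layer counts 1
  far <- transform(two, x = c(0, 2.5), laying_date = c(100, 100))
  expect_equal(count_active_neighbours(far), c(0L, 0L))
  # same-day nests count mutually; ties at exactly the radius count
  tie <- transform(two, x = c(0, 2.0), laying_date = c(100, 100))
  expect_equal(count_active_neighbours(tie), c(1L, 1L))
  expect_error(count_active_neighbours(two, radius_m = 0),
               class = "colonyQG_invalid_argument")
  expect_error(count_active_neighbours(transform(two, year = c(1, 2))),
               class = "colonyQG_grouping_error")
})

test_that("neighbour counts match the exhaustive pairwise oracle", {
  for (seed in 1:4) {
    season <- random_test_season(120, seed = seed)
    for (r in c(1, 2, 3, 4)) {
      for (w in c(14, 28, 56)) {
        expect_identical(count_active_neighbours(season, r, w),
                         neighbour_count_oracle(season, r, w))
      }
    }
  }
})

test_that("neighbour counts are monotone in radius and window", {
  season <- random_test_season(200, seed = 11)
  c1 <- count_active_neighbours(season, 1, 28)
  c2 <- count_active_neighbours(season, 2, 28)
  c4 <- count_active_neighbours(season, 4, 28)
  expect_true(all(c2 >= c1) && all(c4 >= c2))
  w14 <- count_active_neighbours(season, 2, 14)
  w56 <- count_active_neighbours(season, 2, 56)
  expect_true(all(c2 >= w14) && all(w56 >= c2))
  # translation invariance within an island
  shifted <- season
  shifted$x <- shifted$x * 0.5 + 1      # compress+shift keeps all in bounds
  expect_identical(count_active_neighbours(shifted, 2, 28),
                   neighbour_count_oracle(shifted, 2, 28))
  shifted2 <- shifted
  shifted2$x <- shifted2$x + 2
  expect_identical(count_active_neighbours(shifted2, 2, 28),
                   count_active_neighbours(shifted, 2, 28))
})

test_that("island density equals neighbour count at infinite radius", {
  one <- data.frame(female_id = "a", year = 1, island = 3, x = 1, y = 1,
                    laying_date = 140)
  expect_equal(island_density_at_breeding(one), 0L)
  three <- data.frame(female_id = c("a", "b", "c"), year = 1, island = 1,
                      x = c(1, 2, 3), y = c(1, 1, 1),
                      laying_date = c(100, 110, 150))
  expect_equal(island_density_at_breeding(three)[2], 1L)
  season <- random_test_season(150, seed = 2)
  expect_identical(island_density_at_breeding(season),
                   count_active_neighbours(season, radius_m = 1e9))
  # all dates equal at infinite radius: n_island - 1 each
  same <- transform(season, laying_date = 140)
  n_isl <- table(same$island)
  expect_identical(island_density_at_breeding(same),
                   as.integer(n_isl[as.character(same$island)] - 1L))
})

test_that("wall distance is the minimum over the four walls", {
  expect_equal(distance_to_nearest_wall(5.35, 2.3), 2.3)
  expect_equal(distance_to_nearest_wall(0, 0), 0)
  expect_equal(distance_to_nearest_wall(1.0, 2.0), 1.0)
  expect_true(all(distance_to_nearest_wall(runif(100, 0, 10.7),
                                           runif(100, 0, 4.6)) <= 2.3))
  expect_error(distance_to_nearest_wall(11, 1),
               class = "colonyQG_invalid_coordinate")
})

test_that("study filters drop unknown-age and possibly-alive females", {
  rec <- data.frame(female_id = rep(c("a", "b", "c"), each = 3),
                    year = rep(2019:2021, 3),
                    age = c(3:5, NA, NA, NA, 6:8))
  known <- apply_study_filters(rec, "known_age")
  expect_setequal(unique(known$female_id), c("a", "c"))
  expect_equal(nrow(known), 6)
  # presumed dead: last two seasons (2020, 2021) disqualify
  rec2 <- data.frame(female_id = rep(c("a", "b"), each = 2),
                     year = c(2015, 2016, 2015, 2021),
                     age = c(2, 3, 2, 8))
  pd <- apply_study_filters(rec2, "presumed_dead", last_observation_year = 2021)
  expect_setequal(unique(pd$female_id), "a")
  expect_error(apply_study_filters(rec2, "presumed_dead"),
               class = "colonyQG_config_error")
  # set-difference oracle on a larger synthetic table
  set.seed(30)
  big <- data.frame(female_id = rep(sprintf("f%02d", 1:50), each = 2),
                    year = rep(c(2000, 2001), 50),
                    age = rep(sample(2:20, 50, TRUE), each = 2))
  flag <- sprintf("f%02d", sample(1:50, 5))
  big$age[big$female_id %in% flag] <- NA
  filt <- apply_study_filters(big, "known_age")
  expect_equal(nrow(filt), nrow(big) - sum(big$female_id %in% flag))
})

test_that("build_trait_table assembles all covariates over multiple seasons", {
  set.seed(7)
  recs <- do.call(rbind, lapply(1:3, function(y) random_test_season(80, y, year = y)))
  tab <- build_trait_table(recs)
  expect_true(all(c("neighbour_count", "island_density", "wall_distance",
                    "colony_density") %in% names(tab)))
  expect_true(all(tab$colony_density == 80))
  expect_true(all(tab$neighbour_count <= tab$island_density))
  # per-year equality with single-season computation
  y2 <- recs[recs$year == 2, ]
  expect_identical(tab$neighbour_count[tab$year == 2],
                   count_active_neighbours(y2))
})
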