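two_track_gps <- function() {
  tibble::tibble(t = rep(1:30, each = 2),
                 individual_id = rep(c("a", "b"), 30),
                 x_m = rep(1:30, each = 2) + c(0, 10),
                 y_m = 0)
}

test_that("the centroid is the unweighted mean of available fixes", {
  gps <- tibble::tibble(t = c(1, 1), individual_id = c("a", "b"),
                        x_m = c(0, 10), y_m = c(0, 0))
  cen <- compute_centroid(gps)
  expect_equal(cen$x_m, 5)
  expect_equal(cen$y_m, 0)
  expect_equal(cen$n_contributing, 2L)
})

test_that("centroid speed and heading are translation-equivariant", {
  gps <- two_track_gps()
  cen <- compute_centroid(gps, speed_window = 4)
  gps2 <- dplyr::mutate(gps, x_m = x_m + 100, y_m = y_m - 50)
  cen2 <- compute_centroid(gps2, speed_window = 4)
  expect_equal(cen2$x_m, cen$x_m + 100)
  expect_equal(cen2$speed_ms, cen$speed_ms)
  expect_equal(cen2$heading_x, cen$heading_x)
})

test_that("coverage below threshold leaves the centroid undefined", {
  gps <- two_track_gps()[-3, ]  # drop one fix at t = 2
  cen <- compute_centroid(gps, coverage_threshold = 2)
  expect_true(is.na(cen$x_m[cen$t == 2]))
  expect_false(anyNA(cen$x_m[cen$t != 2]))
})

test_that("a constant speed series produces a single segment", {
  cen <- tibble::tibble(t = 1:500, speed_ms = 0.5, n_contributing = 10)
  bouts <- detect_bouts(cen)
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$state, "non-stationary")
})

test_that("a step change is located within 10 s of the oracle breakpoint", {
  set.seed(4)
  x <- c(rnorm(600, 0.05, 0.02), rnorm(600, 0.5, 0.02))
  cen <- tibble::tibble(t = seq_along(x), speed_ms = x,
                        n_contributing = 20)
  bouts <- detect_bouts(cen)
  expect_equal(nrow(bouts), 2)
  expect_lt(abs(bouts$t_end[1] - 600), 10)
  # independent oracle: exhaustive single-breakpoint least squares
  expect_lt(abs(bouts$t_end[1] - best_single_breakpoint(x)), 10)
})

test_that("segmentation recovers the scheduled travel bouts of a day", {
  # no solo windows: with few individuals a lone walker drags the centroid
  # of a small group above the stationary threshold (1/n of walking speed)
  day <- small_day(8, seed = 5,
                   motion = motion_params(solo_per_individual = 0))
  cen <- compute_centroid(day$gps)
  bouts <- detect_bouts(cen)
  big <- bouts[bouts$state == "non-stationary" & bouts$duration_s >= 120, ]
  expect_equal(nrow(big), 2)  # two scheduled travel segments
  seg <- day$schedule$segments
  off <- cumsum(c(0, seg$duration)) + 6 * 3600
  sched_start <- off[which(seg$state == "travel")]
  sched_end <- off[which(seg$state == "travel") + 1]
  expect_true(all(abs(big$t_start - sched_start) <= 30))
  expect_true(all(abs(big$t_end - sched_end) <= 30))
})

test_that("the bout filter applies closed duration and coverage bounds", {
  bouts <- tibble::tibble(
    bout_id = 1:5,
    t_start = 0, t_end = 1,
    duration_s = c(90, 300, 120, 500, 200),
    state = c("non-stationary", "non-stationary", "non-stationary",
              "stationary", "non-stationary"),
    mean_speed_ms = 1,
    coverage = c(20, 15, 16, 20, 25))
  kept <- filter_bouts(bouts)
  # 90 s excluded (too short); 15 individuals excluded (coverage);
  # stationary excluded; exactly 120 s / 16 individuals retained
  expect_equal(kept$bout_id, c(3L, 5L))
})

test_that("front-back coordinates align with the heading", {
  # two individuals travelling east; a is 5 m ahead of b
  gps <- two_track_gps()
  cen <- compute_centroid(gps, speed_window = 4)
  fr <- front_back_positions(gps, cen)
  a <- fr[fr$individual_id == "b" & fr$t == 15, ]
  expect_equal(a$d_m, 5)
  expect_equal(a$rank, 2L)
  expect_equal(a$p, 1)
  expect_equal(a$spread_m, 10)
})

test_that("positions, ranks and spread are rotation-invariant", {
  gps <- tibble::tibble(t = rep(1:20, each = 3),
                        individual_id = rep(c("a", "b", "c"), 20),
                        x_m = rep(1:20, each = 3) + c(-5, 0, 5),
                        y_m = rep(c(2, 0, -2), 20))
  fr <- front_back_positions(gps, compute_centroid(gps, speed_window = 4))
  th <- 1.1
  gps2 <- dplyr::mutate(gps,
    xr = x_m * cos(th) - y_m * sin(th),
    yr = x_m * sin(th) + y_m * cos(th), x_m = xr, y_m = yr)[, 1:4]
  fr2 <- front_back_positions(gps2, compute_centroid(gps2, speed_window = 4))
  expect_equal(fr2$d_m, fr$d_m, tolerance = 1e-10)
  expect_equal(fr2$rank, fr$rank)
  expect_equal(fr2$p, fr$p)
  expect_equal(fr2$spread_m, fr$spread_m, tolerance = 1e-10)
})

test_that("three equally spaced individuals rescale to -1, 0, +1", {
  gps <- tibble::tibble(t = rep(1:20, each = 3),
                        individual_id = rep(c("a", "b", "c"), 20),
                        x_m = rep(1:20, each = 3) + c(-5, 0, 5), y_m = 0)
  fr <- front_back_positions(gps, compute_centroid(gps, speed_window = 4))
  at10 <- fr[fr$t == 10, ]
  expect_equal(sort(at10$p), c(-1, 0, 1))
  expect_equal(at10$spread_m, rep(10, 3))
})

test_that("group spread summarises extent and is zero when coincident", {
  fr <- tibble::tibble(t = c(1, 1, 2, 2), individual_id = c("a", "b") |>
                         rep(2),
                       d_m = c(-10, 10, 0, 0), lr_m = 0)
  sp <- group_spread(fr)
  expect_equal(sp$spread_m, c(20, 0))
})

test_that("rank persistence is finite and shortens with speed noise", {
  mk <- function(noise_sd, seed) {
    b <- simulate_bout_1d(small_troop(8, 3), "II",
                          sim_params(g = 0.05, noise_sd = noise_sd,
                                     duration = 400), seed = seed)
    fr <- b$positions %>%
      dplyr::group_by(t) %>%
      dplyr::arrange(x_m, individual_id, .by_group = TRUE) %>%
      dplyr::mutate(rank = dplyr::row_number()) %>%
      dplyr::ungroup()
    mean(rank_duration(fr)$mean_rank_duration_s)
  }
  calm <- mk(0.05, 1)
  noisy <- mk(0.5, 1)
  expect_true(is.finite(calm) && is.finite(noisy))
  expect_gt(calm, noisy)
})
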