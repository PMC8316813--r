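test_that("discretised distance is exact on a straight line", {
  trk <- tibble::tibble(t = 0:100, x_m = 0:100, y_m = 0)
  expect_equal(daily_travel_distance(trk, step = 5), 100)
  kept <- discretize_track(trk, step = 5)
  expect_equal(kept$x_m, seq(0, 100, by = 5))
})

test_that("degenerate tracks give zero distance", {
  expect_equal(daily_travel_distance(tibble::tibble(t = 1, x_m = 0,
                                                    y_m = 0)), 0)
  expect_equal(daily_travel_distance(tibble::tibble(t = numeric(),
                                                    x_m = numeric(),
                                                    y_m = numeric())), 0)
})

test_that("discretisation suppresses stationary GPS jitter", {
  jit <- withr::with_seed(1, tibble::tibble(t = 0:3599, x_m = rnorm(3600),
                                            y_m = rnorm(3600)))
  raw <- sum(sqrt(diff(jit$x_m)^2 + diff(jit$y_m)^2))
  expect_lt(daily_travel_distance(jit, step = 5), 0.05 * raw)
})

test_that("discretised distance is monotone non-increasing in step size", {
  trk <- withr::with_seed(2, tibble::tibble(
    t = 0:999, x_m = cumsum(rnorm(1000, 0.5)), y_m = cumsum(rnorm(1000))))
  d <- vapply(c(1, 2, 5, 10, 20), function(s)
    daily_travel_distance(trk, step = s), numeric(1))
  expect_true(all(diff(d) <= 1e-9))
})

test_that("maximum displacement measures the farthest point from the start", {
  out <- c(seq(0, 3000, by = 10), seq(3000, 0, by = -10))
  trk <- tibble::tibble(t = seq_along(out), x_m = out, y_m = 0)
  expect_equal(daily_max_displacement(trk), 3000)
  expect_equal(daily_max_displacement(trk, sleep_site = c(-1000, 0)), 4000)
})

test_that("travel distance dominates displacement on every individual-day", {
  day <- small_day(6, seed = 13)
  ds <- daily_summary(day$gps)
  expect_true(all(ds$travel_distance_m >= ds$max_displacement_m))
  expect_true(all(ds$max_displacement_m >= 0))
})

test_that("characteristic stride frequency comes from solo windows", {
  day <- small_day(5, seed = 11)
  tr <- day$troop
  activity <- activity_from_labels(day$labels)
  strides <- purrr::map_dfr(1:5, function(i) {
    lab <- day$labels[day$labels$individual_id == tr$individual_id[i], ]
    acc <- despike_accel(synth_accel(lab, tr[i, ], seed = 40 + i))
    dplyr::mutate(estimate_stride_frequency(acc),
                  individual_id = tr$individual_id[i])
  })
  fchar <- characteristic_stride_frequency(strides, activity)
  cmp <- dplyr::left_join(fchar, tr, by = "individual_id")
  expect_true(all(cmp$n_windows >= 1))
  expect_true(all(abs(cmp$f_char_hz - cmp$f_char_true_hz) <= 0.1))
})

test_that("individuals who never move alone are flagged undefined", {
  strides <- tibble::tibble(individual_id = "a", t_start = c(0, 10),
                            stride_hz = c(2, 2.1))
  act <- tibble::tibble(t = rep(0:19, 2),
                        individual_id = rep(c("a", "b"), each = 20),
                        state = "moving")  # b always moves: never solo
  out <- characteristic_stride_frequency(strides, act)
  expect_true(is.na(out$f_char_hz[out$individual_id == "a"]))
})

test_that("a troop of one qualifies all its moving windows", {
  strides <- tibble::tibble(individual_id = "a", t_start = c(0, 10),
                            stride_hz = c(2, 2.2))
  act <- tibble::tibble(t = 0:19, individual_id = "a", state = "moving")
  out <- characteristic_stride_frequency(strides, act)
  expect_equal(out$f_char_hz, 2.1)
  expect_equal(out$n_windows, 2L)
})

test_that("stride deviation is a linear percent scale", {
  st <- tibble::tibble(individual_id = "a", stride_hz = c(2, 2.2, NA))
  fc <- tibble::tibble(individual_id = "a", f_char_hz = 2)
  dev <- stride_deviation(st, fc)
  expect_equal(dev$stride_dev_pct, c(0, 10, NA))
  expect_equal(stride_deviation(st, 2)$stride_dev_pct, c(0, 10, NA))
})

test_that("move:pause ratios handle balance and boundaries", {
  bal <- move_pause_ratio(rep(c(TRUE, FALSE), each = 30))
  expect_equal(bal$ratio, 1)
  allm <- move_pause_ratio(rep(TRUE, 60))
  expect_equal(allm$ratio, Inf)
  expect_equal(allm$prop_shrunk, (1 * 59 + 0.5) / 60)
  expect_true(is.na(move_pause_ratio(logical())$ratio))
  expect_equal(shrink_proportion(0, 10), 0.05)
})

test_that("nearest-neighbour size differences are antisymmetric and gated", {
  fr <- tibble::tibble(t = 1, individual_id = c("a", "b", "c"),
                       d_m = c(0, 3, 50), lr_m = 0)
  troop <- tibble::tibble(individual_id = c("a", "b", "c"),
                          leg_length_cm = c(35, 45, 40))
  nn <- nn_size_difference(fr, troop)
  expect_equal(nn$nn_leg_diff_cm[nn$individual_id == "a"], 10)
  expect_equal(nn$nn_leg_diff_cm[nn$individual_id == "b"], -10)
  expect_true(is.na(nn$nn_leg_diff_cm[nn$individual_id == "c"]))  # 47 m away
  # neighbour at exactly the radius does not qualify ("under 5 m")
  fr2 <- tibble::tibble(t = 1, individual_id = c("a", "b"),
                        d_m = c(0, 5), lr_m = 0)
  nn2 <- nn_size_difference(fr2, troop)
  expect_true(all(is.na(nn2$nn_leg_diff_cm)))
})

test_that("separation profiles recover pause-rule breakpoints", {
  tr <- make_troop(troop_config(seed = 42))
  recs <- function(mp, seed) {
    p <- sim_params(g = 0, T_spread = 0, noise_sd = 0.3, duration = 700,
                    move_pause = mp, init_spread_sd = 10)
    purrr::map_dfr(1:6, function(b)
      bout_separation_records(simulate_bout_1d(tr, "I", p, seed = seed + b)))
  }
  pr <- separation_profile(recs(move_pause_rule(), 100),
                           range = c(-100, 60))
  bp <- pr$breakpoints
  expect_setequal(bp$side, c("front", "back"))
  expect_lte(abs(bp$breakpoint_m[bp$side == "front"] - 20), 10)
  expect_lte(abs(bp$breakpoint_m[bp$side == "back"] - (-40)), 10)
  # mirrored rule gives mirrored breakpoints
  pr2 <- separation_profile(
    recs(move_pause_rule(front_bp = 40, back_bp = -20), 200),
    range = c(-100, 60))
  bp2 <- pr2$breakpoints
  expect_lte(abs(bp2$breakpoint_m[bp2$side == "front"] - 40), 10)
  expect_lte(abs(bp2$breakpoint_m[bp2$side == "back"] - (-20)), 10)
  # position-independent pausing: a flat profile, no breakpoints
  pr3 <- separation_profile(
    recs(move_pause_rule(b_leg = 0, s_front = 0, s_back = 0), 300),
    range = c(-100, 60))
  expect_equal(nrow(pr3$breakpoints), 0)
  expect_s3_class(plot_separation_profile(pr), "ggplot")
})

test_that("window records combine position, activity and gait measures", {
  day <- small_day(8, seed = 4, durations = c(400, 500, 200, 400, 100),
                   motion = motion_params(solo_per_individual = 0))
  cen <- compute_centroid(day$gps)
  bouts <- filter_bouts(detect_bouts(cen), min_coverage = 8)
  frames <- front_back_positions(day$gps, cen, bouts)
  rec <- aggregate_windows(frames, activity_from_labels(day$labels),
                           troop = day$troop)
  expect_true(all(c("p", "spread_m", "prop_shrunk", "move_pause",
                    "leg_length_cm") %in% names(rec)))
  expect_true(all(rec$prop_shrunk > 0 & rec$prop_shrunk < 1, na.rm = TRUE))
  expect_true(all(rec$n_sec <= 10))
  # ratio and proportion agree
  ok <- is.finite(rec$move_pause)
  expect_equal(rec$move_pause[ok],
               rec$prop_moving[ok] / (1 - rec$prop_moving[ok]))
})
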