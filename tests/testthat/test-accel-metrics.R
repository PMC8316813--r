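test_that("Hampel replaces a lone outlier in a constant series and no more", {
  x <- rep(5, 200)
  x[77] <- 5 + 50
  y <- hampel_filter(x)
  expect_equal(y[77], 5)
  expect_equal(y[-77], x[-77])
})

test_that("Hampel leaves a clean sine untouched", {
  t <- seq(0, 10, by = 1 / 12)
  x <- 9.81 + 2 * sin(2 * pi * 2 * t)
  expect_identical(hampel_filter(x), x)
})

test_that("Hampel is idempotent on day-like signals", {
  acc <- synth_accel(gait_track(2, secs = 120), one_individual(), seed = 1)
  art <- inject_artifacts(acc, spike_rate = 5, spike_magnitude = 10,
                          seed = 2)
  once <- hampel_filter(art$accel$heave)
  expect_identical(hampel_filter(once), once)
})

test_that("Hampel preserves missing samples and warns on short segments", {
  x <- c(rnorm(100), NA, rnorm(5))
  expect_warning(y <- hampel_filter(x), "shorter")
  expect_true(is.na(y[101]))
  expect_equal(y[102:106], x[102:106])  # short tail untouched
})

test_that("flat heave yields no stride estimate", {
  acc <- tibble::tibble(t = seq(0, 10 - 1 / 12, by = 1 / 12),
                        heave = 9.81)
  st <- estimate_stride_frequency(acc)
  expect_true(all(is.na(st$stride_hz)))
  expect_true(all(st$n_peaks == 0))
})

test_that("stride frequency is recovered to 0.1 Hz across the gait range", {
  errs <- vapply(seq_along(fs <- seq(1, 3, by = 0.5)), function(i) {
    acc <- despike_accel(synth_accel(gait_track(fs[i]), one_individual(),
                                     seed = i))
    st <- estimate_stride_frequency(acc)
    max(abs(st$stride_hz - fs[i]))
  }, numeric(1))
  expect_true(all(errs <= 0.1))
})

test_that("stride estimates are invariant to amplitude scaling", {
  a1 <- synth_accel(gait_track(2), one_individual(),
                    accel_params(footfall_amp = 3), seed = 5)
  a2 <- a1
  a2$heave <- 9.81 + 4 * (a1$heave - 9.81)  # scale the dynamic part
  s1 <- estimate_stride_frequency(a1)
  s2 <- estimate_stride_frequency(a2)
  expect_equal(s1$stride_hz, s2$stride_hz, tolerance = 0.02)
})

test_that("VeDBA of a constant vector is zero", {
  t <- seq(0, 30 - 1 / 12, by = 1 / 12)
  acc <- tibble::tibble(t = t, surge = 0, sway = 0, heave = 9.81)
  expect_lt(max(compute_vedba(acc)$vedba), 1e-9)
})

test_that("VeDBA of a sine matches the 2A/pi closed form", {
  # 1.92 Hz: the 25-sample static boxcar has an exact spectral zero there
  # and the 12 Hz grid sweeps the phase uniformly, so the discrete mean of
  # |A sin| converges to 2A/pi
  A <- 2
  t <- seq(0, 60 - 1 / 12, by = 1 / 12)
  acc <- tibble::tibble(t = t, surge = 0, sway = 0,
                        heave = 9.81 + A * sin(2 * pi * 1.92 * t))
  v <- compute_vedba(acc)
  expect_lt(abs(mean(v$vedba) - 2 * A / pi) / (2 * A / pi), 0.05)
})

test_that("VeDBA is invariant to a constant offset and monotone in amplitude", {
  acc <- synth_accel(gait_track(2), one_individual(), seed = 6)
  shifted <- acc
  shifted$surge <- shifted$surge + 3
  shifted$heave <- shifted$heave - 5
  expect_equal(compute_vedba(acc)$vedba, compute_vedba(shifted)$vedba,
               tolerance = 1e-9)
  louder <- synth_accel(gait_track(2), one_individual(),
                        accel_params(footfall_amp = 6), seed = 6)
  expect_true(all(compute_vedba(louder)$vedba >= compute_vedba(acc)$vedba))
})

test_that("threshold fallback classifies the obvious cases", {
  still <- synth_accel(tibble::tibble(t = 0:29, moving = FALSE,
                                      speed_true_ms = 0),
                       one_individual(), seed = 7)
  walk <- synth_accel(gait_track(2, secs = 30), one_individual(), seed = 8)
  cs <- classify_activity(accel_features(still))
  cw <- classify_activity(accel_features(walk))
  expect_true(all(cs$state == "stationary"))
  expect_true(all(cw$state == "moving"))
})

test_that("an untrained model argument of the wrong type errors", {
  feats <- accel_features(synth_accel(gait_track(2, secs = 10),
                                      one_individual(), seed = 9))
  expect_error(classify_activity(feats, model = lm(t ~ 1, feats)),
               "activity_model")
})

test_that("the SVM classifier beats 95% on a labelled synthetic day", {
  day <- small_day(4, seed = 21, durations = c(400, 500, 300, 400, 200))
  tr <- day$troop
  tabs <- purrr::map(1:4, function(i) {
    lab <- day$labels[day$labels$individual_id == tr$individual_id[i], ]
    acc <- despike_accel(synth_accel(lab, tr[i, ], seed = 30 + i))
    dplyr::left_join(accel_features(acc), lab[, c("t", "moving")], by = "t")
  })
  mod <- train_activity_classifier(dplyr::bind_rows(tabs[1:2]))
  test <- dplyr::bind_rows(tabs[3:4])
  pred <- classify_activity(test, mod)
  expect_gt(mean((pred$state == "moving") == test$moving, na.rm = TRUE),
            0.95)
})
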