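test_that("pearson_corr matches the textbook cases", {
  expect_equal(pearson_corr(NULL, x = 1:10, y = 2 * (1:10))$r, 1)
  expect_equal(pearson_corr(NULL, x = 1:10, y = -(1:10))$r, -1)
  df <- tibble::tibble(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
  expect_equal(pearson_corr(df, "a", "b")$r, cor(df$a, df$b))
  expect_error(pearson_corr(NULL, x = c(1, 1, 1), y = 1:3), "variance")
  expect_error(pearson_corr(NULL, x = 1:2, y = 1:2), "at least 3")
})

test_that("a noise-free linear response is recovered exactly", {
  df <- tidyr::expand_grid(individual_id = sprintf("i%d", 1:4), w = 1:20)
  df$x <- seq_len(nrow(df))
  df$y <- 1 + 0.25 * df$x
  df$t_start <- df$w
  f <- fit_lmm(df, y ~ x, ar1 = FALSE)
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "x"], 0.25, tolerance = 1e-8)
})

test_that("both engines recover a known slope with AR1 residuals", {
  df <- sim_lmm_records(3)
  td <- tidy(fit_lmm(df, y ~ x, bout = "bout_id", engine = "nlme"))
  row <- td[td$term == "x", ]
  expect_lt(abs(row$estimate - 0.5), 4 * row$std.error)
  expect_lt(row$std.error, 0.1)
  # glmmTMB engine: crossed intercepts + ar1 covariance (no redundant bout
  # level here, whose zero variance would sit on the boundary)
  td2 <- tidy(fit_lmm(df, y ~ x, time = "t_start", engine = "glmmTMB"))
  row2 <- td2[td2$term == "x", ]
  expect_lt(abs(row2$estimate - 0.5), 4 * row2$std.error)
  expect_lt(row2$std.error, 0.1)
})

test_that("coefficients rescale exactly under affine unit changes", {
  df <- sim_lmm_records(4)
  df$x_m <- df$x / 100  # cm -> m
  t1 <- tidy(fit_lmm(df, y ~ x, bout = "bout_id"))
  t2 <- tidy(fit_lmm(df, y ~ x_m, bout = "bout_id"))
  expect_equal(t2$estimate[t2$term == "x_m"],
               100 * t1$estimate[t1$term == "x"], tolerance = 1e-6)
})

test_that("nominal coverage holds for the AR1 mixed model", {
  hits <- vapply(1:30, function(s) {
    td <- tidy(fit_lmm(sim_lmm_records(s), y ~ x, bout = "bout_id"))
    row <- td[td$term == "x", ]
    abs(row$estimate - 0.5) <= 1.96 * row$std.error
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a constant-mean proportion yields a null intercept", {
  cst <- tibble::tibble(individual_id = rep(sprintf("i%d", 1:5), each = 50),
                        prop = withr::with_seed(7, rbeta(250, 25, 25)))
  td <- tidy(fit_beta_glmm(cst, prop ~ 1))
  expect_lt(abs(td$estimate[td$term == "(Intercept)"]), 0.1)
})

test_that("the beta GLMM recovers coefficient sign and magnitude", {
  gen <- function(seed, b_leg = -0.4, n_ind = 15, n_bout = 8, n_win = 10,
                  phi = 30) {
    withr::with_seed(seed, {
      df <- tidyr::expand_grid(individual_id = sprintf("i%02d", 1:n_ind),
                               bout_id = sprintf("b%02d", 1:n_bout),
                               w = 1:n_win)
      leg <- rnorm(n_ind)
      a_i <- rnorm(n_ind, 0, 0.3)
      b_b <- rnorm(n_bout, 0, 0.3)
      df$leg_z <- leg[as.integer(factor(df$individual_id))]
      mu <- plogis(1 + b_leg * df$leg_z +
                     a_i[as.integer(factor(df$individual_id))] +
                     b_b[as.integer(factor(df$bout_id))])
      df$prop <- pmin(pmax(rbeta(nrow(df), mu * phi, (1 - mu) * phi),
                           1e-4), 1 - 1e-4)
      df
    })
  }
  signs <- vapply(1:5, function(s) {
    td <- tidy(fit_beta_glmm(gen(s), prop ~ leg_z, bout = "bout_id"))
    td$estimate[td$term == "leg_z"] < 0 && td$p.value[td$term == "leg_z"] < 0.05
  }, logical(1))
  expect_true(all(signs))
  big <- gen(99, n_ind = 25, n_bout = 20)
  td <- tidy(fit_beta_glmm(big, prop ~ leg_z, bout = "bout_id"))
  expect_lt(abs(td$estimate[td$term == "leg_z"] - (-0.4)) / 0.4, 0.15)
})

test_that("boundary proportions are rejected with guidance", {
  df <- tibble::tibble(individual_id = rep("a", 10),
                       prop = c(rep(0.5, 9), 1))
  expect_error(fit_beta_glmm(df, prop ~ 1), "shrink_proportion")
})

test_that("smaller individuals' higher move proportions surface in the GLMM", {
  # end-to-end: day generator encodes less pausing for smaller individuals
  day <- small_day(12, seed = 8, durations = c(300, 700, 200, 700, 100),
                   motion = motion_params(solo_per_individual = 0))
  cen <- compute_centroid(day$gps)
  bouts <- filter_bouts(detect_bouts(cen), min_coverage = 12)
  frames <- front_back_positions(day$gps, cen, bouts)
  rec <- aggregate_windows(frames, activity_from_labels(day$labels),
                           troop = day$troop)
  # transient NA/NaN evaluations inside the TMB optimizer are expected
  td <- tidy(suppressWarnings(
    fit_beta_glmm(rec, prop_shrunk ~ leg_length_cm, bout = "bout_id")))
  row <- td[td$term == "leg_length_cm", ]
  expect_lt(row$estimate, 0)
  expect_lt(row$p.value, 0.05)
})
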