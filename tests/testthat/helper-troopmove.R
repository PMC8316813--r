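# Shared fixture builders. Everything is generated in code at test time.

small_troop <- function(n = 8, seed = 2) {
  make_troop(troop_config(n_individuals = n, seed = seed))
}

# A compact day: stationary (with solo windows) / travel east / stationary /
# travel north / stationary. Small enough to run in seconds.
small_day <- function(n = 8, seed = 5,
                      durations = c(900, 600, 700, 500, 400),
                      motion = motion_params()) {
  sched <- day_schedule(tibble::tibble(
    state = c("stationary", "travel", "stationary", "travel", "stationary"),
    duration = durations,
    heading_x = c(NA, 1, NA, 0, NA),
    heading_y = c(NA, 0, NA, 1, NA)))
  simulate_day(small_troop(n, seed), sched, motion, seed = seed)
}

# Constant-gait accel track for one individual walking at stride `f_hz`.
gait_track <- function(f_hz, secs = 60, leg_cm = 38, kappa = 1.3) {
  tibble::tibble(t = seq_len(secs) - 1L, moving = TRUE,
                 speed_true_ms = f_hz * kappa * leg_cm / 100)
}

one_individual <- function(leg_cm = 38) {
  tibble::tibble(individual_id = "a", leg_length_cm = leg_cm,
                 f_char_true_hz = 2, v_char_true_ms = 1.3 * 2 * leg_cm / 100)
}

activity_from_labels <- function(labels) {
  dplyr::transmute(labels, t = t, individual_id = individual_id,
                   state = ifelse(moving, "moving", "stationary"))
}

# Simulated window records with nested random intercepts and AR1 residuals;
# the structure matches the fit_lmm nlme engine so calibration tests have a
# correctly specified null.
sim_lmm_records <- function(seed, beta = 0.5, rho = 0.5, n_ind = 8,
                            n_bout = 4, n_win = 40) {
  withr::with_seed(seed, {
    df <- tidyr::expand_grid(individual_id = sprintf("i%02d", 1:n_ind),
                             bout_id = sprintf("b%02d", 1:n_bout),
                             w = 1:n_win)
    a_i <- rnorm(n_ind, 0, 0.5)
    b_ib <- rnorm(n_ind * n_bout, 0, 0.3)
    series <- as.integer(factor(paste(df$individual_id, df$bout_id)))
    df$x <- rnorm(nrow(df))
    eps <- unlist(purrr::map(seq_len(n_ind * n_bout), function(k)
      as.numeric(stats::arima.sim(list(ar = rho), n_win, sd = 1))))
    df$y <- 2 + beta * df$x + a_i[as.integer(factor(df$individual_id))] +
      b_ib[series] + eps
    df$t_start <- df$w * 10
    df
  })
}

# Exhaustive single-breakpoint least-squares oracle for mean-shift detection.
best_single_breakpoint <- function(x) {
  n <- length(x)
  rss <- vapply(2:(n - 1), function(k) {
    sum((x[1:k] - mean(x[1:k]))^2) + sum((x[(k + 1):n] - mean(x[(k + 1):n]))^2)
  }, numeric(1))
  which.min(rss) + 1L
}
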