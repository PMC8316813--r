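#' Build a day schedule from explicit segments
#'
#' A day alternates stationary periods and collective travel segments. Travel
#' segments carry a heading (unit vector) and the decision rule used by the
#' embedded 1D travel engine.
#'
#' @param segments Tibble/data frame with columns `state`
#'   (`"stationary"`/`"travel"`), `duration` (s), and for travel rows
#'   `heading_x`, `heading_y` (normalised internally) and optionally `rule`
#'   (default `"III"`).
#' @param day_start Clock hour at which the record starts (default 6).
#' @return Class `day_schedule`.
#' @export
day_schedule <- function(segments, day_start = 6) {
  segments <- as_tibble(segments)
  stopifnot_cols(segments, c("state", "duration"), "segments")
  if (!all(segments$state %in% c("stationary", "travel"))) {
    abort("segment `state` must be 'stationary' or 'travel'")
  }
  if (any(segments$duration <= 0)) abort("segment durations must be positive")
  if (sum(segments$duration) > 12 * 3600) {
    abort("total schedule duration exceeds the 12 h daylight window")
  }
  if (!"rule" %in% names(segments)) segments$rule <- "III"
  trav <- segments$state == "travel"
  if (any(trav)) {
    stopifnot_cols(segments, c("heading_x", "heading_y"), "segments")
    nrm <- sqrt(segments$heading_x^2 + segments$heading_y^2)
    if (any(trav & (is.na(nrm) | nrm == 0))) {
      abort("travel segments need a non-zero heading")
    }
    segments$heading_x <- segments$heading_x / nrm
    segments$heading_y <- segments$heading_y / nrm
  } else {
    if (!"heading_x" %in% names(segments)) segments$heading_x <- NA_real_
    if (!"heading_y" %in% names(segments)) segments$heading_y <- NA_real_
  }
  segments$duration <- as.integer(round(segments$duration))
  structure(list(segments = segments, day_start = day_start),
            class = "day_schedule")
}

#' Draw a random day schedule
#'
#' Travel-segment durations are lognormal, calibrated to collective travel
#' bouts averaging ~26 min with a broad spread, truncated to [2, 90] min;
#' stationary gaps fill the remaining daylight. Headings are uniform random
#' unit vectors.
#'
#' @param n_travel Number of travel segments.
#' @param total_duration Total scheduled duration, s (at most 12 h).
#' @param travel_mean,travel_sd Mean and SD of travel durations, s.
#' @param rule Decision rule for travel segments.
#' @param day_start Clock hour of the first sample.
#' @param seed Integer seed.
#' @return A [day_schedule()].
#' @export
make_day_schedule <- function(n_travel = 6, total_duration = 12 * 3600,
                              travel_mean = 1560, travel_sd = 1200,
                              rule = "III", day_start = 6, seed = 1L) {
  if (n_travel < 1) abort("`n_travel` must be >= 1")
  local_seed(seed, {
    s2 <- log(1 + (travel_sd / travel_mean)^2)
    dur <- stats::rlnorm(n_travel, log(travel_mean) - s2 / 2, sqrt(s2))
    dur <- pmin(pmax(dur, 120), 5400)
    total_travel <- sum(dur)
    if (total_travel > 0.8 * total_duration) {
      dur <- dur * 0.8 * total_duration / total_travel
    }
    n_stat <- n_travel + 1L
    w <- runif(n_stat, 0.5, 1.5)
    stat_dur <- (total_duration - sum(dur)) * w / sum(w)
    ang <- runif(n_travel, 0, 2 * pi)
  })
  seg <- vector("list", n_travel * 2L + 1L)
  for (i in seq_len(n_travel)) {
    seg[[2L * i - 1L]] <- tibble(state = "stationary",
                                 duration = stat_dur[i],
                                 heading_x = NA_real_, heading_y = NA_real_,
                                 rule = NA_character_)
    seg[[2L * i]] <- tibble(state = "travel", duration = dur[i],
                            heading_x = cos(ang[i]), heading_y = sin(ang[i]),
                            rule = rule)
  }
  seg[[n_travel * 2L + 1L]] <- tibble(state = "stationary",
                                      duration = stat_dur[n_stat],
                                      heading_x = NA_real_,
                                      heading_y = NA_real_,
                                      rule = NA_character_)
  day_schedule(bind_rows(seg), day_start = day_start)
}

#' Motion parameters for the synthetic day generator
#'
#' @param gps_noise_sd Isotropic Gaussian GPS error SD, m.
#' @param stationary_step_sd SD (m) of per-axis burst steps during
#'   stationary periods.
#' @param burst_prob Per-second probability an individual takes a burst step
#'   while the group is stationary.
#' @param motion_threshold True per-second displacement (m) above which a
#'   second is labelled moving.
#' @param solo_per_individual Scheduled solo-movement windows per individual
#'   per day (focal walks at its characteristic speed while all group-mates
#'   hold still), which make the characteristic stride frequency estimable.
#' @param solo_duration Length of each solo window, s.
#' @param g,T_spread,speed_noise_sd Travel-engine parameters (see
#'   [sim_params()]).
#' @param move_pause A [move_pause_rule()] applied during travel, or `NULL`.
#' @param init_spread_sd SD (m) of initial scatter of individuals.
#' @param kappa Stride-to-speed constant used for true stride frequencies.
#' @return List of class `motion_params`.
#' @export
motion_params <- function(gps_noise_sd = 1, stationary_step_sd = 0.3,
                          burst_prob = 0.05, motion_threshold = 0.1,
                          solo_per_individual = 1, solo_duration = 60,
                          g = 0.01, T_spread = 80, speed_noise_sd = 0.1,
                          move_pause = move_pause_rule(),
                          init_spread_sd = 10, kappa = 1.3) {
  structure(list(gps_noise_sd = gps_noise_sd,
                 stationary_step_sd = stationary_step_sd,
                 burst_prob = burst_prob,
                 motion_threshold = motion_threshold,
                 solo_per_individual = solo_per_individual,
                 solo_duration = solo_duration,
                 g = g, T_spread = T_spread,
                 speed_noise_sd = speed_noise_sd,
                 move_pause = move_pause,
                 init_spread_sd = init_spread_sd,
                 kappa = kappa),
            class = "motion_params")
}

#' Simulate a day of troop GPS tracks with ground truth
#'
#' Generates 1 Hz planar tracks for every individual. Stationary segments are
#' bounded random walks (occasional burst steps about a fixed anchor) with
#' scheduled solo-movement windows; travel segments embed the 1D
#' collective-movement engine ([simulate_bout_1d()]'s rules) along the
#' segment heading, so speed modulation, pausing and spread dynamics carry
#' over. GPS noise is added on top of the true positions.
#'
#' @param troop Troop tibble from [make_troop()].
#' @param schedule A [day_schedule()].
#' @param motion A [motion_params()].
#' @param seed Integer seed.
#' @return Class `troop_day`: list with
#'   `gps` (tibble `t`, `individual_id`, `x_m`, `y_m`; noisy),
#'   `labels` (tibble `t`, `individual_id`, `moving`, `speed_true_ms`,
#'   `stride_hz_true`, `solo`, `group_state`, `x_true_m`, `y_true_m`),
#'   `schedule`, `motion`, `solo_windows`.
#' @export
simulate_day <- function(troop, schedule, motion = motion_params(),
                         seed = 1L) {
  stopifnot(inherits(schedule, "day_schedule"),
            inherits(motion, "motion_params"))
  if (nrow(troop) < 1) abort("`troop` must contain at least one individual")
  n <- nrow(troop)
  seg <- schedule$segments
  total <- sum(seg$duration)
  t0 <- round(schedule$day_start * 3600)
  kappa <- attr(troop, "kappa") %||% motion$kappa

  local_seed(seed, {
    # initial scatter
    P <- cbind(rnorm(n, 0, motion$init_spread_sd),
               rnorm(n, 0, motion$init_spread_sd))
    # allocate solo windows inside stationary segments
    solo <- allocate_solo_windows(seg, n, motion$solo_per_individual,
                                  motion$solo_duration)
    # per-individual per-second true positions
    X <- matrix(NA_real_, total + 1L, n)
    Y <- matrix(NA_real_, total + 1L, n)
    X[1L, ] <- P[, 1L]
    Y[1L, ] <- P[, 2L]
    grp_state <- character(total)
    offset <- 0L
    for (si in seq_len(nrow(seg))) {
      dur <- seg$duration[si]
      rows <- offset + seq_len(dur)  # second indices within the day
      if (seg$state[si] == "stationary") {
        grp_state[rows] <- "stationary"
        anchors <- cbind(X[offset + 1L, ], Y[offset + 1L, ])
        res <- step_stationary(anchors, X[offset + 1L, ], Y[offset + 1L, ],
                               dur, motion, troop, solo, offset, kappa)
        X[rows + 1L, ] <- res$X
        Y[rows + 1L, ] <- res$Y
      } else {
        grp_state[rows] <- "non-stationary"
        h <- c(seg$heading_x[si], seg$heading_y[si])
        hp <- c(-h[2L], h[1L])
        px <- X[offset + 1L, ]
        py <- Y[offset + 1L, ]
        cx <- mean(px)
        cy <- mean(py)
        d0 <- (px - cx) * h[1L] + (py - cy) * h[2L]
        lat <- (px - cx) * hp[1L] + (py - cy) * hp[2L]
        p <- sim_params(g = motion$g, T_spread = motion$T_spread,
                        noise_sd = motion$speed_noise_sd, dt = 1,
                        duration = dur, move_pause = motion$move_pause,
                        init_spread_sd = 0)
        leg_z <- if (sd(troop$leg_length_cm) > 0)
          as.vector(scale(troop$leg_length_cm)) else rep(0, n)
        eng <- sim_engine(troop$v_char_true_ms, seg$rule[si], p,
                          n_steps = dur, R = 1L, leg_z = leg_z,
                          record = TRUE)
        along <- eng$positions  # (dur+1) x n, starts at 0-centred d0? no: N(0, init)
        # engine starts at 0; shift so the bout continues from current d0
        along <- sweep(along, 2L, d0, `+`)
        X[rows + 1L, ] <- cx + outer(rep(1, dur), lat) * hp[1L] +
          along[-1L, , drop = FALSE] * h[1L]
        Y[rows + 1L, ] <- cy + outer(rep(1, dur), lat) * hp[2L] +
          along[-1L, , drop = FALSE] * h[2L]
      }
      offset <- offset + dur
    }
    gps_noise_x <- matrix(rnorm((total + 1L) * n, 0, motion$gps_noise_sd),
                          total + 1L, n)
    gps_noise_y <- matrix(rnorm((total + 1L) * n, 0, motion$gps_noise_sd),
                          total + 1L, n)
  })

  # per-second true displacement (assigned to the second it ends)
  disp <- sqrt(diff(X)^2 + diff(Y)^2)
  moving <- disp > motion$motion_threshold
  speed <- disp
  stride <- ifelse(moving, speed / (kappa * rep(troop$leg_length_cm,
                                                each = total) / 100),
                   NA_real_)
  tgrid <- t0 + seq_len(total)
  in_solo <- matrix(FALSE, total, n)
  if (nrow(solo) > 0) {
    for (k in seq_len(nrow(solo))) {
      in_solo[solo$start[k]:solo$end[k], solo$individual[k]] <- TRUE
    }
  }
  ids <- troop$individual_id
  labels <- tibble(
    t = rep(tgrid, times = n),
    individual_id = rep(ids, each = total),
    moving = as.vector(moving),
    speed_true_ms = as.vector(speed),
    stride_hz_true = as.vector(stride),
    solo = as.vector(in_solo),
    group_state = rep(grp_state, times = n),
    x_true_m = as.vector(X[-1L, , drop = FALSE]),
    y_true_m = as.vector(Y[-1L, , drop = FALSE]))
  gps <- tibble(
    t = rep(tgrid, times = n),
    individual_id = rep(ids, each = total),
    x_m = as.vector(X[-1L, , drop = FALSE] + gps_noise_x[-1L, , drop = FALSE]),
    y_m = as.vector(Y[-1L, , drop = FALSE] + gps_noise_y[-1L, , drop = FALSE]))
  solo_windows <- if (nrow(solo) > 0) {
    tibble(individual_id = ids[solo$individual],
           t_start = t0 + solo$start, t_end = t0 + solo$end)
  } else {
    tibble(individual_id = character(), t_start = numeric(),
           t_end = numeric())
  }
  structure(list(gps = gps, labels = labels, schedule = schedule,
                 motion = motion, troop = troop,
                 solo_windows = solo_windows, seed = seed),
            class = "troop_day")
}

# Non-overlapping solo windows, placed in stationary segments round-robin.
allocate_solo_windows <- function(seg, n, per_individual, solo_duration) {
  if (per_individual < 1) {
    return(tibble(individual = integer(), start = integer(),
                  end = integer()))
  }
  seg_off <- cumsum(c(0L, seg$duration))
  stat <- which(seg$state == "stationary" & seg$duration > solo_duration + 20)
  if (length(stat) == 0) {
    warn("no stationary segment long enough for solo windows")
    return(tibble(individual = integer(), start = integer(),
                  end = integer()))
  }
  # capacity per stationary segment (with 10 s guard between windows)
  slot <- solo_duration + 10L
  slots <- purrr::map(stat, function(si) {
    k <- (seg$duration[si] - 10L) %/% slot
    if (k <= 0) return(integer())
    seg_off[si] + 10L + (seq_len(k) - 1L) * slot
  })
  # interleave slots across stationary segments so solo walks spread over
  # the day instead of packing into the first quiet period
  kmax <- max(lengths(slots))
  starts <- unlist(purrr::map(seq_len(kmax), function(j) {
    unlist(purrr::map(slots, function(s) if (length(s) >= j) s[j] else NULL))
  }))
  need <- n * per_individual
  if (length(starts) < need) {
    warn(sprintf(
      "only %d solo slots available for %d requested; some individuals get fewer",
      length(starts), need))
  }
  use <- head(rep(starts, length.out = max(need, 0L)), need)
  use <- use[seq_len(min(need, length(starts)))]
  ind <- rep(seq_len(n), times = per_individual)[seq_along(use)]
  tibble(individual = ind,
         start = as.integer(use),
         end = as.integer(use) + as.integer(solo_duration) - 1L)
}

# Stationary-period dynamics for one segment. Returns dur x n matrices.
# RNG is consumed from the caller's stream.
step_stationary <- function(anchors, x0, y0, dur, motion, troop, solo,
                            seg_offset, kappa) {
  n <- length(x0)
  Xs <- matrix(NA_real_, dur, n)
  Ys <- matrix(NA_real_, dur, n)
  rows <- seg_offset + seq_len(dur)
  solo_mask <- matrix(FALSE, dur, n)
  solo_dir <- matrix(NA_real_, dur, n)  # walk heading angle while solo
  if (nrow(solo) > 0) {
    for (k in seq_len(nrow(solo))) {
      hit <- solo$start[k] <= rows[dur] && solo$end[k] >= rows[1L]
      if (!hit) next
      idx <- pmax(solo$start[k], rows[1L]):pmin(solo$end[k], rows[dur]) -
        seg_offset
      solo_mask[idx, solo$individual[k]] <- TRUE
      half <- idx[seq_len(ceiling(length(idx) / 2))]
      ang <- runif(1, 0, 2 * pi)
      solo_dir[idx, solo$individual[k]] <- ang
      solo_dir[setdiff(idx, half), solo$individual[k]] <- ang + pi
    }
  }
  any_solo <- rowSums(solo_mask) > 0
  burst <- matrix(runif(dur * n) < motion$burst_prob, dur, n)
  burst[any_solo, ] <- FALSE  # group-mates hold still during solo windows
  stepx <- matrix(rnorm(dur * n, 0, motion$stationary_step_sd), dur, n) * burst
  stepy <- matrix(rnorm(dur * n, 0, motion$stationary_step_sd), dur, n) * burst
  v <- troop$v_char_true_ms
  x <- x0
  y <- y0
  for (s in seq_len(dur)) {
    dx <- stepx[s, ]
    dy <- stepy[s, ]
    sol <- solo_mask[s, ]
    if (any(sol)) {
      dx[sol] <- v[sol] * cos(solo_dir[s, sol])
      dy[sol] <- v[sol] * sin(solo_dir[s, sol])
    }
    # soft tether to the anchor keeps the walk bounded
    pull <- 0.02
    dx <- dx - pull * (x - anchors[, 1L]) * !sol
    dy <- dy - pull * (y - anchors[, 2L]) * !sol
    x <- x + dx
    y <- y + dy
    Xs[s, ] <- x
    Ys[s, ] <- y
  }
  list(X = Xs, Y = Ys)
}

#' @export
print.troop_day <- function(x, ...) {
  cat(sprintf(
    "<troop_day> %d individuals, %d s (%d travel segment(s)), seed %d\n",
    dplyr::n_distinct(x$gps$individual_id),
    dplyr::n_distinct(x$gps$t),
    sum(x$schedule$segments$state == "travel"), x$seed))
  invisible(x)
}
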