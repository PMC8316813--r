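#' Group centroid track with displacement speed and heading
#'
#' Per-second unweighted mean of the available individual positions. The
#' displacement speed at time `t` is the centroid displacement across a
#' centred `speed_window` (default 10 s) divided by the window, and the
#' heading is that displacement normalised; the heading is undefined below
#' `heading_threshold` where it would be noise-dominated.
#'
#' @param gps Tibble `t`, `individual_id`, `x_m`, `y_m`.
#' @param coverage_threshold Minimum individuals with a fix for the centroid
#'   to be defined that second.
#' @param speed_window Displacement window, s.
#' @param heading_threshold Speed (m/s) below which the heading is `NA`.
#' @return Tibble: `t`, `x_m`, `y_m`, `n_contributing`, `speed_ms`,
#'   `heading_x`, `heading_y`, on the full second grid of the input.
#' @export
compute_centroid <- function(gps, coverage_threshold = 1,
                             speed_window = 10, heading_threshold = 0.1) {
  stopifnot_cols(gps, c("t", "individual_id", "x_m", "y_m"), "gps")
  if (nrow(gps) == 0) abort("`gps` is empty")
  cen <- gps %>%
    filter(!is.na(.data$x_m), !is.na(.data$y_m)) %>%
    group_by(.data$t) %>%
    summarise(x_m = mean(.data$x_m), y_m = mean(.data$y_m),
              n_contributing = dplyr::n(), .groups = "drop")
  grid <- tibble(t = seq(min(cen$t), max(cen$t)))
  cen <- left_join(grid, cen, by = "t") %>%
    mutate(n_contributing = tidyr::replace_na(.data$n_contributing, 0L))
  low <- cen$n_contributing < coverage_threshold
  cen$x_m[low] <- NA_real_
  cen$y_m[low] <- NA_real_
  w <- as.integer(speed_window)
  h <- w %/% 2L
  n <- nrow(cen)
  lead_i <- pmin(seq_len(n) + h, n)
  lag_i <- pmax(seq_len(n) - (w - h), 1L)
  denom <- cen$t[lead_i] - cen$t[lag_i]
  dx <- cen$x_m[lead_i] - cen$x_m[lag_i]
  dy <- cen$y_m[lead_i] - cen$y_m[lag_i]
  sp <- sqrt(dx^2 + dy^2) / denom
  sp[denom <= 0] <- NA_real_
  hx <- ifelse(sp > heading_threshold, dx / (sp * denom), NA_real_)
  hy <- ifelse(sp > heading_threshold, dy / (sp * denom), NA_real_)
  cen %>% mutate(speed_ms = sp, heading_x = hx, heading_y = hy)
}

# PELT segmentation of a numeric series under an L2 (mean-shift) cost with a
# linear penalty per changepoint. Returns 0-based changepoint positions
# (indices after which a new segment starts).
pelt_mean <- function(x, penalty) {
  n <- length(x)
  if (n == 0L) return(integer())
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  seg_cost <- function(s, t) {
    # cost of x[(s+1):t] around its mean; s, t are 0-based boundaries
    len <- t - s
    cs2[t + 1L] - cs2[s + 1L] - (cs[t + 1L] - cs[s + 1L])^2 / len
  }
  F <- c(-penalty, rep(Inf, n))
  cp <- integer(n + 1L)
  cand <- 0L
  for (t in seq_len(n)) {
    vals <- F[cand + 1L] + seg_cost(cand, t) + penalty
    best <- which.min(vals)
    F[t + 1L] <- vals[best]
    cp[t + 1L] <- cand[best]
    keep <- F[cand + 1L] + seg_cost(cand, t) <= F[t + 1L]
    cand <- c(cand[keep], t)
  }
  out <- integer()
  tt <- n
  while (tt > 0L) {
    tau <- cp[tt + 1L]
    if (tau > 0L) out <- c(tau, out)
    tt <- tau
  }
  out
}

#' Segment the day into group activity bouts
#'
#' Penalised change-point segmentation (PELT, L2 cost on the mean) of the
#' centroid displacement speed. Each segment is labelled stationary when its
#' mean speed is below `speed_threshold`, non-stationary otherwise; adjacent
#' segments with the same label are merged. The default penalty is
#' BIC-style, `2 * sigma^2 * log(n)`, with `sigma` estimated robustly from
#' first differences.
#'
#' @param centroid Tibble from [compute_centroid()] (needs `t`, `speed_ms`;
#'   `n_contributing` used for bout coverage when present). Missing speeds
#'   are linearly interpolated for segmentation.
#' @param penalty Changepoint penalty, or `NULL` for the BIC-style default.
#' @param speed_threshold Stationary/non-stationary label threshold, m/s.
#' @return Tibble of bouts partitioning the series: `bout_id`, `t_start`,
#'   `t_end`, `duration_s`, `state`, `mean_speed_ms`, `coverage`.
#' @export
detect_bouts <- function(centroid, penalty = NULL, speed_threshold = 0.1) {
  stopifnot_cols(centroid, c("t", "speed_ms"), "centroid")
  if (nrow(centroid) == 0) {
    return(tibble(bout_id = integer(), t_start = numeric(),
                  t_end = numeric(), duration_s = numeric(),
                  state = character(), mean_speed_ms = numeric(),
                  coverage = numeric()))
  }
  x <- centroid$speed_ms
  if (all(is.na(x))) abort("centroid speed is entirely missing")
  if (anyNA(x)) {
    x <- stats::approx(seq_along(x)[!is.na(x)], x[!is.na(x)],
                       xout = seq_along(x), rule = 2)$y
  }
  n <- length(x)
  if (is.null(penalty)) {
    sigma <- mad(diff(x)) / sqrt(2)
    if (!is.finite(sigma) || sigma == 0) sigma <- max(sd(x), 1e-6)
    penalty <- 2 * sigma^2 * log(n)
  }
  cps <- pelt_mean(x, penalty)
  bounds <- c(0L, cps, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  seg <- tibble(
    t_start = centroid$t[starts], t_end = centroid$t[ends],
    mean_speed_ms = purrr::map2_dbl(starts, ends,
                                    function(a, b) mean(x[a:b]))) %>%
    mutate(state = ifelse(.data$mean_speed_ms < speed_threshold,
                          "stationary", "non-stationary"))
  # merge adjacent same-label segments
  seg$grp <- cumsum(c(TRUE, seg$state[-1L] != seg$state[-nrow(seg)]))
  bouts <- seg %>%
    group_by(.data$grp) %>%
    summarise(t_start = min(.data$t_start), t_end = max(.data$t_end),
              state = .data$state[1L], .groups = "drop") %>%
    select(-"grp") %>%
    arrange(.data$t_start) %>%
    mutate(bout_id = row_number(),
           duration_s = .data$t_end - .data$t_start + 1)
  cov <- if ("n_contributing" %in% names(centroid)) {
    purrr::map2_dbl(bouts$t_start, bouts$t_end, function(a, b) {
      median(centroid$n_contributing[centroid$t >= a & centroid$t <= b])
    })
  } else NA_real_
  spd <- purrr::map2_dbl(bouts$t_start, bouts$t_end, function(a, b) {
    mean(x[centroid$t >= a & centroid$t <= b])
  })
  bouts %>%
    mutate(coverage = cov, mean_speed_ms = spd) %>%
    select("bout_id", "t_start", "t_end", "duration_s", "state",
           "mean_speed_ms", "coverage")
}

#' Retain collective travel bouts meeting duration and coverage rules
#'
#' Keeps non-stationary bouts of at least `min_duration` seconds with data
#' for at least `min_coverage` individuals (closed bounds: a 120-s bout with
#' exactly 16 individuals is retained).
#'
#' @param bouts Tibble from [detect_bouts()].
#' @param min_duration Minimum bout duration, s (default 120).
#' @param min_coverage Minimum per-bout individual coverage (default 16).
#' @return Filtered bout tibble.
#' @export
filter_bouts <- function(bouts, min_duration = 120, min_coverage = 16) {
  stopifnot_cols(bouts, c("state", "duration_s"), "bouts")
  if (min_coverage > 0 && !"coverage" %in% names(bouts)) {
    abort("`bouts` has no coverage column; use min_coverage = 0 or supply it")
  }
  keep <- bouts$state == "non-stationary" & bouts$duration_s >= min_duration
  if (min_coverage > 0) {
    keep <- keep & !is.na(bouts$coverage) & bouts$coverage >= min_coverage
  }
  bouts[keep, , drop = FALSE]
}

#' Front-back positions, ranks and group spread
#'
#' Re-expresses each individual's position relative to the group centroid in
#' a frame rotated to the centroid heading: `d_m` is the signed front-back
#' coordinate (positive = ahead), `lr_m` the left-right coordinate.
#' Positional ranks order `d_m` (rank 1 = backmost; ties broken by
#' individual id) and the rescaled position is
#' `p = 2 * (rank - 1) / (N - 1) - 1`, so +1 is the front and -1 the back
#' regardless of spread. Group spread is the front-back extent
#' `max(d) - min(d)`; the mean distance to the centroid is kept as a
#' secondary statistic. Seconds without a defined heading are skipped.
#'
#' @param gps Tibble `t`, `individual_id`, `x_m`, `y_m`.
#' @param centroid Tibble from [compute_centroid()].
#' @param bouts Optional bout tibble; when given, frames are restricted to
#'   the bouts and tagged with `bout_id`.
#' @return Frame tibble: `t` (+ `bout_id`), `individual_id`, `d_m`, `lr_m`,
#'   `rank`, `p`, `n_present`, `spread_m`, `mean_dist_m`,
#'   `group_speed_ms`.
#' @export
front_back_positions <- function(gps, centroid, bouts = NULL) {
  stopifnot_cols(gps, c("t", "individual_id", "x_m", "y_m"), "gps")
  stopifnot_cols(centroid,
                 c("t", "x_m", "y_m", "heading_x", "heading_y", "speed_ms"),
                 "centroid")
  cen <- centroid %>%
    filter(!is.na(.data$heading_x)) %>%
    select("t", cx = "x_m", cy = "y_m", hx = "heading_x",
           hy = "heading_y", group_speed_ms = "speed_ms")
  frames <- gps %>%
    filter(!is.na(.data$x_m)) %>%
    inner_join(cen, by = "t") %>%
    mutate(relx = .data$x_m - .data$cx, rely = .data$y_m - .data$cy,
           d_m = .data$relx * .data$hx + .data$rely * .data$hy,
           lr_m = -.data$relx * .data$hy + .data$rely * .data$hx,
           dist = sqrt(.data$relx^2 + .data$rely^2)) %>%
    group_by(.data$t) %>%
    arrange(.data$d_m, .data$individual_id, .by_group = TRUE) %>%
    mutate(rank = row_number(), n_present = dplyr::n(),
           p = ifelse(.data$n_present > 1,
                      2 * (.data$rank - 1) / (.data$n_present - 1) - 1, 0),
           spread_m = max(.data$d_m) - min(.data$d_m),
           mean_dist_m = mean(.data$dist)) %>%
    ungroup() %>%
    select("t", "individual_id", "d_m", "lr_m", "rank", "p", "n_present",
           "spread_m", "mean_dist_m", "group_speed_ms")
  if (!is.null(bouts)) {
    key <- bouts %>% select("bout_id", "t_start", "t_end")
    frames <- frames %>%
      inner_join(key, by = dplyr::join_by(between(t, t_start, t_end))) %>%
      select(-"t_start", -"t_end") %>%
      dplyr::relocate("bout_id")
  }
  frames
}

#' Group spread per second
#'
#' Front-back extent (`max(d) - min(d)`) and mean distance to the centroid,
#' summarised from a frame table. A single present individual gives zero
#' spread.
#'
#' @param frames Tibble from [front_back_positions()].
#' @return Tibble: (`bout_id`,) `t`, `spread_m`, `mean_dist_m`,
#'   `n_present`.
#' @export
group_spread <- function(frames) {
  stopifnot_cols(frames, c("t", "d_m"), "frames")
  keys <- intersect(c("bout_id", "t"), names(frames))
  frames %>%
    group_by(across(all_of(keys))) %>%
    summarise(spread_m = max(.data$d_m) - min(.data$d_m),
              mean_dist_m = mean(sqrt(.data$d_m^2 + .data$lr_m^2)),
              n_present = dplyr::n(), .groups = "drop")
}

#' Persistence of front-back positional ranks
#'
#' Mean duration (s) of runs of constant positional rank per individual:
#' how long group members hold the same front-back rank before being
#' overtaken or overtaking. Shorter durations indicate more churn in the
#' travel order.
#'
#' @param frames Tibble from [front_back_positions()].
#' @return Tibble: (`bout_id`,) `individual_id`, `mean_rank_duration_s`,
#'   `n_runs`.
#' @export
rank_duration <- function(frames) {
  stopifnot_cols(frames, c("t", "individual_id", "rank"), "frames")
  keys <- intersect(c("bout_id", "individual_id"), names(frames))
  frames %>%
    group_by(across(all_of(keys))) %>%
    arrange(.data$t, .by_group = TRUE) %>%
    summarise(mean_rank_duration_s = {
      r <- rle(.data$rank)
      step <- if (length(.data$t) > 1) .data$t[2] - .data$t[1] else 1
      mean(r$lengths) * step
    }, n_runs = length(rle(.data$rank)$lengths), .groups = "drop")
}

#' Front-back separation from the rest of the group
#'
#' Adds `sep_m`: the focal front-back coordinate minus the front-back
#' coordinate of the centroid of all other present individuals,
#' `sep = d * N / (N - 1)`.
#'
#' @param frames Tibble from [front_back_positions()].
#' @return `frames` with a `sep_m` column.
#' @export
add_separation <- function(frames) {
  stopifnot_cols(frames, c("d_m", "n_present"), "frames")
  frames %>%
    mutate(sep_m = ifelse(.data$n_present > 1,
                          .data$d_m * .data$n_present /
                            (.data$n_present - 1), NA_real_))
}
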