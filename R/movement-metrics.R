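#' Discretize a track to a fixed spatial resolution
#'
#' Greedy sequential thinning: the first point is kept, and each subsequent
#' point is kept only when it lies at least `step` metres from the last kept
#' point. Suppresses GPS jitter when summing path length.
#'
#' @param track Tibble `t`, `x_m`, `y_m`, time-ordered, one individual.
#' @param step Resolution, m (default 5).
#' @return The kept-point tibble.
#' @export
discretize_track <- function(track, step = 5) {
  stopifnot_cols(track, c("x_m", "y_m"), "track")
  track <- track[!is.na(track$x_m) & !is.na(track$y_m), , drop = FALSE]
  n <- nrow(track)
  if (n == 0) return(track)
  keep <- logical(n)
  keep[1L] <- TRUE
  lx <- track$x_m[1L]
  ly <- track$y_m[1L]
  x <- track$x_m
  y <- track$y_m
  for (i in seq_len(n)[-1L]) {
    if (sqrt((x[i] - lx)^2 + (y[i] - ly)^2) >= step) {
      keep[i] <- TRUE
      lx <- x[i]
      ly <- y[i]
    }
  }
  track[keep, , drop = FALSE]
}

#' Daily travel distance at fixed spatial resolution
#'
#' Sum of consecutive distances between the points retained by
#' [discretize_track()]. An empty or single-point track gives 0.
#'
#' @inheritParams discretize_track
#' @return Distance in metres.
#' @export
daily_travel_distance <- function(track, step = 5) {
  kept <- discretize_track(track, step)
  if (nrow(kept) < 2) return(0)
  sum(sqrt(diff(kept$x_m)^2 + diff(kept$y_m)^2))
}

#' Daily maximum displacement from the sleeping site
#'
#' Straight-line distance between the morning sleeping site (by default the
#' first fix of the track) and the most distant position visited.
#'
#' @param track Tibble `t`, `x_m`, `y_m`, one individual.
#' @param sleep_site Optional numeric `c(x, y)`; defaults to the first fix.
#' @return Distance in metres (`NA` for an empty track).
#' @export
daily_max_displacement <- function(track, sleep_site = NULL) {
  stopifnot_cols(track, c("x_m", "y_m"), "track")
  track <- track[!is.na(track$x_m), , drop = FALSE]
  if (nrow(track) == 0) return(NA_real_)
  if (is.null(sleep_site)) {
    track <- arrange(track, .data$t)
    sleep_site <- c(track$x_m[1L], track$y_m[1L])
  }
  max(sqrt((track$x_m - sleep_site[1L])^2 +
             (track$y_m - sleep_site[2L])^2))
}

#' Per-individual daily movement summary
#'
#' @param gps Tibble `t`, `individual_id`, `x_m`, `y_m`.
#' @param step Discretisation resolution, m.
#' @param activity Optional per-second activity tibble (`t`,
#'   `individual_id`, `state`) contributing `minutes_moving`.
#' @return Tibble: `individual_id`, `travel_distance_m`,
#'   `max_displacement_m` (+ `minutes_moving`).
#' @export
daily_summary <- function(gps, step = 5, activity = NULL) {
  stopifnot_cols(gps, c("t", "individual_id", "x_m", "y_m"), "gps")
  out <- gps %>%
    group_by(.data$individual_id) %>%
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$t)
      tibble(travel_distance_m = daily_travel_distance(df, step),
             max_displacement_m = daily_max_displacement(df))
    }) %>%
    ungroup()
  if (!is.null(activity)) {
    mm <- activity %>%
      group_by(.data$individual_id) %>%
      summarise(minutes_moving = sum(.data$state == "moving",
                                     na.rm = TRUE) / 60, .groups = "drop")
    out <- left_join(out, mm, by = "individual_id")
  }
  out
}

#' Characteristic stride frequency during independent movement
#'
#' An individual's reference gait: the mean of its defined stride-frequency
#' estimates over windows in which it was moving while every other tracked
#' group-mate was stationary. Windows qualify when at least `solo_frac` of
#' their seconds satisfy that condition.
#'
#' @param strides Tibble `individual_id`, `t_start`, `stride_hz` (windowed
#'   estimates from [estimate_stride_frequency()]).
#' @param activity Tibble `t`, `individual_id`, `state`
#'   (`"moving"`/`"stationary"`) for all tracked individuals.
#' @param window Stride window length, s.
#' @param solo_frac Minimum fraction of solo seconds per qualifying window.
#' @return Tibble: `individual_id`, `f_char_hz` (`NA` when no window
#'   qualifies), `n_windows`.
#' @export
characteristic_stride_frequency <- function(strides, activity, window = 10,
                                            solo_frac = 0.8) {
  stopifnot_cols(strides, c("individual_id", "t_start", "stride_hz"),
                 "strides")
  stopifnot_cols(activity, c("t", "individual_id", "state"), "activity")
  per_sec <- activity %>%
    filter(!is.na(.data$state)) %>%
    group_by(.data$t) %>%
    mutate(n_moving = sum(.data$state == "moving")) %>%
    ungroup() %>%
    mutate(solo = .data$state == "moving" & .data$n_moving == 1L)
  ids <- unique(strides$individual_id)
  purrr::map_dfr(ids, function(id) {
    st <- strides[strides$individual_id == id, , drop = FALSE]
    sec <- per_sec[per_sec$individual_id == id, c("t", "solo")]
    if (nrow(sec) == 0) {
      return(tibble(individual_id = id, f_char_hz = NA_real_,
                    n_windows = 0L))
    }
    # cumulative solo count on a dense second grid -> O(1) window fractions
    t0 <- min(sec$t)
    t1 <- max(sec$t)
    grid <- rep(FALSE, t1 - t0 + 1L)
    grid[sec$t - t0 + 1L] <- sec$solo
    cg <- c(0L, cumsum(grid))
    lo <- pmax(pmin(round(st$t_start - t0 + 1), length(grid) + 1L), 1L)
    hi <- pmax(pmin(round(st$t_start + window - t0), length(grid)), 0L)
    frac <- ifelse(hi >= lo, (cg[hi + 1L] - cg[lo]) / window, 0)
    ok <- frac >= solo_frac & !is.na(st$stride_hz)
    tibble(individual_id = id,
           f_char_hz = if (any(ok)) mean(st$stride_hz[ok]) else NA_real_,
           n_windows = sum(ok))
  })
}

#' Stride-frequency deviation from the characteristic value
#'
#' Percent deviation `100 * (f - f_char) / f_char` per stride window;
#' undefined windows propagate `NA`.
#'
#' @param strides Tibble with `stride_hz` (and `individual_id` when
#'   `f_char` is a lookup tibble).
#' @param f_char Either a single reference frequency (Hz) or a tibble
#'   `individual_id`, `f_char_hz`.
#' @return `strides` with a `stride_dev_pct` column.
#' @export
stride_deviation <- function(strides, f_char) {
  stopifnot_cols(strides, "stride_hz", "strides")
  if (is.numeric(f_char)) {
    if (length(f_char) != 1 || is.na(f_char) || f_char <= 0) {
      abort("`f_char` must be a single positive frequency")
    }
    strides$f_char_hz <- f_char
  } else {
    stopifnot_cols(f_char, c("individual_id", "f_char_hz"), "f_char")
    strides <- left_join(strides, f_char, by = "individual_id")
  }
  strides %>%
    mutate(stride_dev_pct = 100 * (.data$stride_hz - .data$f_char_hz) /
             .data$f_char_hz)
}

#' Move:pause ratio of a window of activity states
#'
#' Ratio of seconds moving to seconds stationary. All-moving windows return
#' `Inf`; for beta-family modelling use the accompanying proportion with
#' boundary shrinkage (see [shrink_proportion()]).
#'
#' @param moving Logical vector (or `"moving"`/`"stationary"` character) of
#'   per-second states; `NA`s are dropped.
#' @return List: `ratio`, `prop_moving`, `prop_shrunk`, `n`.
#' @export
move_pause_ratio <- function(moving) {
  if (is.character(moving)) moving <- moving == "moving"
  moving <- moving[!is.na(moving)]
  n <- length(moving)
  if (n == 0) {
    return(list(ratio = NA_real_, prop_moving = NA_real_,
                prop_shrunk = NA_real_, n = 0L))
  }
  k <- sum(moving)
  p <- k / n
  list(ratio = if (k == n) Inf else k / (n - k),
       prop_moving = p,
       prop_shrunk = shrink_proportion(p, n),
       n = n)
}

#' Shrink proportions off the boundary for beta modelling
#'
#' `(p * (n - 1) + 0.5) / n`, mapping 0 and 1 slightly inside the open unit
#' interval.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @param n Number of observations behind each proportion.
#' @return Shrunken proportion(s) in `(0, 1)`.
#' @export
shrink_proportion <- function(p, n) {
  (p * (n - 1) + 0.5) / n
}

#' Nearest-neighbour leg-length difference
#'
#' For each focal individual and second, the leg length of the nearest
#' neighbour minus the focal's, defined only when the nearest-neighbour
#' distance is under `radius` (default 5 m).
#'
#' @param frames Tibble from [front_back_positions()] (uses `d_m`, `lr_m`).
#' @param troop Troop tibble with `individual_id`, `leg_length_cm`.
#' @param radius Qualification radius, m.
#' @return `frames` with `nn_dist_m`, `nn_individual_id`,
#'   `nn_leg_diff_cm` columns.
#' @export
nn_size_difference <- function(frames, troop, radius = 5) {
  stopifnot_cols(frames, c("t", "individual_id", "d_m", "lr_m"), "frames")
  stopifnot_cols(troop, c("individual_id", "leg_length_cm"), "troop")
  leg <- setNames(troop$leg_length_cm, troop$individual_id)
  keys <- intersect(c("bout_id", "t"), names(frames))
  frames %>%
    group_by(across(all_of(keys))) %>%
    dplyr::group_modify(function(df, key) {
      m <- nrow(df)
      if (m < 2) {
        df$nn_dist_m <- NA_real_
        df$nn_individual_id <- NA_character_
        df$nn_leg_diff_cm <- NA_real_
        return(df)
      }
      dm <- as.matrix(stats::dist(cbind(df$d_m, df$lr_m)))
      diag(dm) <- Inf
      j <- apply(dm, 1L, which.min)
      nnd <- dm[cbind(seq_len(m), j)]
      df$nn_dist_m <- nnd
      df$nn_individual_id <- df$individual_id[j]
      diff <- leg[df$nn_individual_id] - leg[df$individual_id]
      diff[nnd >= radius] <- NA_real_
      df$nn_leg_diff_cm <- unname(diff)
      df
    }) %>%
    ungroup()
}
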