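#' Aggregate per-second measures into 10-s window records
#'
#' Builds the analysis table used by the mixed models: one record per
#' individual per window within each travel bout, combining spatial position
#' (rescaled front-back position, spread, group speed), activity
#' (move:pause ratio and shrunken proportion moving), VeDBA, stride
#' deviation and nearest-neighbour size difference, whichever inputs are
#' supplied.
#'
#' @param frames Frame tibble from [front_back_positions()] with `bout_id`.
#' @param activity Per-second tibble `t`, `individual_id`, `state`.
#' @param vedba Optional per-second tibble `t`, `individual_id`, `vedba`.
#' @param strides Optional windowed tibble `individual_id`, `t_start`,
#'   `stride_hz`; matched to the record window containing the stride-window
#'   midpoint. Provide `f_char` to convert to deviations.
#' @param f_char Optional tibble `individual_id`, `f_char_hz`.
#' @param troop Optional troop tibble contributing `leg_length_cm`.
#' @param width Window length, s (default 10).
#' @return Tibble: `bout_id`, `individual_id`, `t_start`, `p`, `spread_m`,
#'   `group_speed_ms`, `sep_m`, `move_pause`, `prop_moving`,
#'   `prop_shrunk`, `n_sec` (+ `vedba`, `stride_dev_pct`,
#'   `nn_leg_diff_cm`, `leg_length_cm` when available).
#' @export
aggregate_windows <- function(frames, activity, vedba = NULL,
                              strides = NULL, f_char = NULL, troop = NULL,
                              width = 10) {
  stopifnot_cols(frames, c("bout_id", "t", "individual_id", "d_m", "p",
                           "spread_m", "group_speed_ms"), "frames")
  stopifnot_cols(activity, c("t", "individual_id", "state"), "activity")
  fr <- add_separation(frames) %>%
    left_join(activity %>% select("t", "individual_id", "state"),
              by = c("t", "individual_id")) %>%
    group_by(.data$bout_id) %>%
    mutate(t_start = min(.data$t) +
             width * ((.data$t - min(.data$t)) %/% width)) %>%
    ungroup()
  if (!is.null(vedba)) {
    fr <- left_join(fr, vedba %>% select("t", "individual_id", "vedba"),
                    by = c("t", "individual_id"))
  }
  has_nn <- "nn_leg_diff_cm" %in% names(fr)
  rec <- fr %>%
    group_by(.data$bout_id, .data$individual_id, .data$t_start) %>%
    summarise(
      p = mean(.data$p),
      spread_m = mean(.data$spread_m),
      group_speed_ms = mean(.data$group_speed_ms),
      sep_m = mean(.data$sep_m),
      n_sec = sum(!is.na(.data$state)),
      k_moving = sum(.data$state == "moving", na.rm = TRUE),
      vedba = if ("vedba" %in% names(fr)) mean(.data$vedba, na.rm = TRUE)
              else NA_real_,
      nn_leg_diff_cm = if (has_nn)
        mean(.data$nn_leg_diff_cm, na.rm = TRUE) else NA_real_,
      .groups = "drop") %>%
    mutate(
      prop_moving = ifelse(.data$n_sec > 0, .data$k_moving / .data$n_sec,
                           NA_real_),
      move_pause = ifelse(.data$k_moving == .data$n_sec, Inf,
                          .data$k_moving / (.data$n_sec - .data$k_moving)),
      prop_shrunk = shrink_proportion(.data$prop_moving, .data$n_sec)) %>%
    select(-"k_moving")
  if (!is.null(strides)) {
    st <- strides %>%
      mutate(t_mid = .data$t_start + width / 2) %>%
      select("individual_id", "t_mid", "stride_hz")
    if (!is.null(f_char)) st <- stride_deviation(st, f_char)
    rec <- rec %>%
      left_join(st %>% mutate(t_start = .data$t_mid - (.data$t_mid -
                  min(rec$t_start)) %% width) %>%
                  select(-"t_mid"),
                by = c("individual_id", "t_start"))
  }
  if (!is.null(troop)) {
    rec <- left_join(rec,
                     troop %>% select("individual_id", "leg_length_cm"),
                     by = "individual_id")
  }
  rec
}
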