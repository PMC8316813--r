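#' Write a synthetic day to CSV files
#'
#' Writes `gps.csv` (`individual_id`, `timestamp`, `x_m`, `y_m`),
#' `labels.csv` and `troop.csv` into `dir`.
#'
#' @param day A `troop_day` from [simulate_day()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_day_csv <- function(day, dir) {
  stopifnot(inherits(day, "troop_day"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(gps = file.path(dir, "gps.csv"),
             labels = file.path(dir, "labels.csv"),
             troop = file.path(dir, "troop.csv"))
  readr::write_csv(day$gps %>% rename(timestamp = "t"), paths["gps"])
  readr::write_csv(day$labels %>% rename(timestamp = "t"),
                   paths["labels"])
  readr::write_csv(day$troop, paths["troop"])
  invisible(paths)
}

#' Read a GPS track table
#'
#' @param path CSV with `individual_id`, `timestamp`, `x_m`, `y_m`.
#' @return Tibble with `t`, `individual_id`, `x_m`, `y_m`.
#' @export
read_gps_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) %>%
    rename(t = "timestamp") %>%
    select("t", "individual_id", "x_m", "y_m")
}

#' Write an acceleration series to CSV
#'
#' @param accel Tibble from [synth_accel()].
#' @param individual_id Identifier stored with the samples.
#' @param path Output CSV.
#' @return Invisibly, `path`.
#' @export
write_accel_csv <- function(accel, individual_id, path) {
  readr::write_csv(
    accel %>%
      mutate(individual_id = individual_id) %>%
      select("individual_id", timestamp = "t", ax = "surge", ay = "sway",
             az = "heave"),
    path)
  invisible(path)
}

#' Read an acceleration series from CSV
#'
#' @param path CSV written by [write_accel_csv()].
#' @return Tibble with `t`, `surge`, `sway`, `heave`, `individual_id`.
#' @export
read_accel_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) %>%
    select(t = "timestamp", surge = "ax", sway = "ay", heave = "az",
           "individual_id")
}

#' Map of a troop day
#'
#' Plots every individual's (noisy) GPS track, coloured by leg length when
#' the day carries its troop.
#'
#' @param day A `troop_day`.
#' @param thin Plot every `thin`-th second (default 10).
#' @return A ggplot object.
#' @export
plot_troop_day <- function(day, thin = 10) {
  stopifnot(inherits(day, "troop_day"))
  df <- day$gps %>%
    filter((.data$t - min(.data$t)) %% thin == 0) %>%
    left_join(day$troop %>% select("individual_id", "leg_length_cm"),
              by = "individual_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$x_m, .data$y_m,
                                   group = .data$individual_id,
                                   colour = .data$leg_length_cm)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "east (m)", y = "north (m)",
                  colour = "leg length (cm)") +
    ggplot2::theme_minimal()
}
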