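#' Parameters for synthetic tri-axial accelerometry
#'
#' @param sample_rate Samples per second (Hz).
#' @param gravity Static heave-axis offset, m/s^2.
#' @param footfall_amp Peak amplitude of the footfall waveform, m/s^2.
#' @param pulse_shape Sharpness exponent of the periodic footfall waveform
#'   `A * ((1 + cos(2 pi u)) / 2)^pulse_shape` (`u` = cycle phase, peak at
#'   the footfall). The default 1 -- a sinusoidal gait oscillation -- keeps
#'   the waveform broad enough at 12 Hz sampling that despiking never
#'   mistakes footfalls for collar-strike spikes, at any cadence.
#' @param noise_sd SD of the white sensor noise on each axis, m/s^2.
#' @param kappa Stride-to-speed constant: instantaneous stride frequency is
#'   `speed / (kappa * leg_length / 100)`.
#' @return List of class `accel_params`.
#' @export
accel_params <- function(sample_rate = 12, gravity = 9.81,
                         footfall_amp = 3, pulse_shape = 1,
                         noise_sd = 0.15, kappa = 1.3) {
  if (sample_rate < 2) abort("`sample_rate` must be at least 2 Hz")
  if (pulse_shape < 1) abort("`pulse_shape` must be >= 1")
  if (footfall_amp < 0) abort("`footfall_amp` must be >= 0")
  structure(list(sample_rate = as.integer(sample_rate), gravity = gravity,
                 footfall_amp = footfall_amp, pulse_shape = pulse_shape,
                 noise_sd = noise_sd, kappa = kappa),
            class = "accel_params")
}

#' Synthesize tri-axial accelerometry for one individual
#'
#' Produces `sample_rate` samples per GPS second. While the individual is
#' moving at speed `v`, the heave axis carries a smooth periodic footfall
#' waveform (a sharpened raised cosine peaking once per stride) at
#' instantaneous frequency `f(t) = v(t) / (kappa * leg_length / 100)`, on
#' top of the gravity offset; while stationary it is gravity plus sensor
#' noise. Surge and sway carry noise only. Gaps in the input track yield
#' gaps in the output (no interpolation).
#'
#' @param track Per-second tibble for a single individual with columns `t`
#'   and either (`moving`, `speed_true_ms`) -- as in the `labels` element of
#'   [simulate_day()] -- or (`x_m`, `y_m`) from which speed is derived.
#' @param individual One-row slice of a troop tibble (needs
#'   `leg_length_cm`).
#' @param params An [accel_params()].
#' @param seed Integer seed.
#' @return Tibble with `t` (fractional seconds), `surge`, `sway`, `heave`
#'   (m/s^2).
#' @export
synth_accel <- function(track, individual, params = accel_params(),
                        seed = 1L) {
  stopifnot_cols(track, "t", "track")
  if (nrow(individual) != 1) abort("`individual` must be a single row")
  track <- arrange(as_tibble(track), t)
  if (!all(c("moving", "speed_true_ms") %in% names(track))) {
    stopifnot_cols(track, c("x_m", "y_m"), "track")
    step <- c(NA, sqrt(diff(track$x_m)^2 + diff(track$y_m)^2) /
                pmax(diff(track$t), 1e-9))
    track$speed_true_ms <- step
    track$moving <- !is.na(step) & step > 0.1
  }
  rate <- params$sample_rate
  leg_m <- individual$leg_length_cm / 100
  n_sec <- nrow(track)
  f_sec <- ifelse(track$moving & !is.na(track$speed_true_ms),
                  track$speed_true_ms / (params$kappa * leg_m), 0)
  f_samp <- rep(f_sec, each = rate)
  n_samp <- n_sec * rate
  local_seed(seed, {
    phase0 <- runif(1)
    noise <- matrix(rnorm(3 * n_samp, 0, params$noise_sd), n_samp, 3)
  })
  phase <- phase0 + cumsum(f_samp / rate)
  u <- phase - floor(phase)
  gait <- numeric(n_samp)
  mv <- f_samp > 0
  gait[mv] <- params$footfall_amp *
    ((1 + cos(2 * pi * u[mv])) / 2)^params$pulse_shape
  tibble(
    t = rep(track$t, each = rate) + rep((seq_len(rate) - 1L) / rate, n_sec),
    surge = noise[, 1L],
    sway = noise[, 2L],
    heave = params$gravity + gait + noise[, 3L])
}

#' Inject collar artifacts into an acceleration series
#'
#' Adds isolated single-sample spikes (a Poisson process in time, magnitude a
#' multiple of the heave SD, random sign, applied to all three axes) and
#' contiguous dropout spans (samples set to `NA`, never zero-filled). The
#' injected indices are returned so despiking can be validated against the
#' ground truth.
#'
#' @param accel Tibble from [synth_accel()].
#' @param spike_rate Spikes per minute.
#' @param spike_magnitude Spike size in multiples of the heave SD.
#' @param dropout_rate Target fraction of samples lost to dropouts.
#' @param dropout_mean_s Mean dropout span length, s.
#' @param seed Integer seed.
#' @param sample_rate Samples per second of `accel`.
#' @return List with `accel` (modified tibble), `spike_idx`, `dropout_idx`
#'   (integer row indices).
#' @export
inject_artifacts <- function(accel, spike_rate = 0, spike_magnitude = 10,
                             dropout_rate = 0, dropout_mean_s = 5,
                             seed = 1L, sample_rate = 12) {
  if (spike_rate < 0 || dropout_rate < 0) abort("artifact rates must be >= 0")
  n <- nrow(accel)
  if (spike_rate == 0 && dropout_rate == 0) {
    return(list(accel = accel, spike_idx = integer(),
                dropout_idx = integer()))
  }
  out <- local_seed(seed, {
    spike_idx <- integer()
    dropout_idx <- integer()
    if (dropout_rate > 0) {
      target <- dropout_rate * n
      span_len <- dropout_mean_s * sample_rate
      lost <- 0
      guard <- 0L
      while (lost < target && guard < 10000L) {
        guard <- guard + 1L
        len <- max(1L, stats::rgeom(1, 1 / span_len))
        start <- sample.int(n - len + 1L, 1L)
        idx <- start:(start + len - 1L)
        new <- setdiff(idx, dropout_idx)
        dropout_idx <- c(dropout_idx, new)
        lost <- lost + length(new)
      }
      dropout_idx <- sort(dropout_idx)
    }
    if (spike_rate > 0) {
      minutes <- n / (sample_rate * 60)
      n_spikes <- rpois(1, spike_rate * minutes)
      avail <- setdiff(seq_len(n), dropout_idx)
      if (n_spikes > 0 && length(avail) > 0) {
        cand <- sort(sample(avail, min(n_spikes, length(avail))))
        # enforce isolation: drop spikes closer than 3 samples
        keep <- c(TRUE, diff(cand) > 3L)
        spike_idx <- cand[keep]
      }
    }
    list(spike_idx = spike_idx, dropout_idx = dropout_idx,
         signs = sample(c(-1, 1), length(spike_idx), replace = TRUE))
  })
  axes <- c("surge", "sway", "heave")
  if (length(out$spike_idx) > 0) {
    for (ax in axes) {
      s <- sd(accel[[ax]], na.rm = TRUE)
      accel[[ax]][out$spike_idx] <- accel[[ax]][out$spike_idx] +
        out$signs * spike_magnitude * s
    }
  }
  if (length(out$dropout_idx) > 0) {
    for (ax in axes) accel[[ax]][out$dropout_idx] <- NA_real_
  }
  list(accel = accel, spike_idx = out$spike_idx,
       dropout_idx = out$dropout_idx)
}
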