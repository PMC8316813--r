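#' Hampel despiking filter
#'
#' Classic rolling-median outlier replacement: a sample deviating from the
#' centred rolling median by more than `n_mad` robust standard deviations
#' (1.4826 times the rolling median absolute deviation) is replaced by that
#' median; everything else is untouched. Missing samples are left missing and
#' the series is filtered per contiguous non-missing segment. A segment
#' shorter than the window is returned unchanged with a warning.
#'
#' @param x Numeric vector (may contain `NA`).
#' @param half_window Half window in samples (window = `2 * half_window + 1`;
#'   default 36, i.e. a 6.1 s window at 12 Hz: wide enough that the rolling
#'   MAD of pure sensor noise is stable, keeping chance replacements of
#'   clean samples well under 1 percent).
#' @param n_mad Rejection threshold in robust SDs.
#' @return Numeric vector, same length as `x`.
#' @export
hampel_filter <- function(x, half_window = 36, n_mad = 3) {
  if (half_window < 1) abort("`half_window` must be >= 1")
  if (n_mad <= 0) abort("`n_mad` must be > 0")
  out <- x
  width <- 2L * as.integer(half_window) + 1L
  warned <- FALSE
  for (idx in true_runs(!is.na(x))) {
    seg <- x[idx]
    if (length(seg) < width) {
      if (!warned) {
        warn("segment shorter than the Hampel window; returned unchanged")
        warned <- TRUE
      }
      next
    }
    med <- roll_median(seg, half_window)
    dev <- abs(seg - med)
    sig <- 1.4826 * roll_median(dev, half_window)
    repl <- dev > n_mad * sig
    seg[repl] <- med[repl]
    out[idx] <- seg
  }
  out
}

#' Despike a tri-axial acceleration table
#'
#' Applies [hampel_filter()] to the surge, sway and heave columns.
#'
#' @param accel Tibble with `surge`, `sway`, `heave`.
#' @inheritParams hampel_filter
#' @return The tibble with filtered axis columns.
#' @export
despike_accel <- function(accel, half_window = 36, n_mad = 3) {
  stopifnot_cols(accel, c("surge", "sway", "heave"), "accel")
  for (ax in c("surge", "sway", "heave")) {
    accel[[ax]] <- hampel_filter(accel[[ax]], half_window, n_mad)
  }
  accel
}

# Footfall peak detection within one window of heave samples.
# Returns refined peak times (s). Peaks are strict local maxima above
# median + prominence_mult robust SDs, at least min_separation apart
# (greedy, highest first), with sub-sample timing by local quadratic fit.
# The low default multiplier admits crests of broad sinusoid-like gait
# waveforms even where the sample grid straddles the crest; downstream the
# inter-peak regularity gate rejects windows whose "peaks" are noise.
find_peaks_window <- function(x, t, prominence_mult = 0.4,
                              min_separation = 0.25) {
  n <- length(x)
  if (n < 3) return(numeric())
  med <- median(x)
  sig <- mad(x)
  thr <- med + prominence_mult * sig
  core <- 2:(n - 1L)
  is_pk <- x[core] > x[core - 1L] & x[core] >= x[core + 1L] & x[core] > thr
  cand <- core[is_pk]
  if (length(cand) == 0) return(numeric())
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- numeric(0)
  kept_t <- numeric(0)
  for (i in cand) {
    if (length(kept_t) == 0 || all(abs(t[i] - kept_t) >= min_separation)) {
      kept <- c(kept, i)
      kept_t <- c(kept_t, t[i])
    }
  }
  kept <- sort(kept)
  # local quadratic refinement of the peak time
  dt <- if (n >= 2) median(diff(t)) else 0
  ref <- vapply(kept, function(i) {
    y0 <- x[i - 1L]; y1 <- x[i]; y2 <- x[i + 1L]
    den <- y0 - 2 * y1 + y2
    delta <- if (den < 0) 0.5 * (y0 - y2) / den else 0
    delta <- max(min(delta, 0.5), -0.5)
    t[i] + delta * dt
  }, numeric(1))
  sort(ref)
}

#' Estimate stride frequency from heave-axis peaks
#'
#' Footfalls appear as peaks in the (despiked) heave signal. Within
#' consecutive windows, peaks are detected as local maxima exceeding the
#' window median by a prominence threshold, with a minimum separation, and
#' the stride frequency is `1 / median(inter-peak interval)`. Windows with
#' fewer than `min_peaks` peaks -- or whose inter-peak intervals are too
#' irregular to be a gait (coefficient of variation above `max_cv`, as for
#' chance maxima of sensor noise) -- give `NA`.
#'
#' @param accel Tibble with `t` and `heave` (despiked), single individual.
#' @param window Window length, s (default 10, matching the 10-s aggregation
#'   used downstream).
#' @param prominence_mult Prominence threshold in robust SDs of the window.
#' @param min_separation Minimum peak separation, s (0.25 s caps detectable
#'   strides at 4 Hz).
#' @param min_peaks Minimum peaks for a defined estimate.
#' @param max_cv Maximum coefficient of variation of inter-peak intervals
#'   for a defined estimate.
#' @return Tibble: `t_start`, `stride_hz`, `n_peaks` (one row per window).
#' @export
estimate_stride_frequency <- function(accel, window = 10,
                                      prominence_mult = 0.4,
                                      min_separation = 0.25,
                                      min_peaks = 3, max_cv = 0.35) {
  stopifnot_cols(accel, c("t", "heave"), "accel")
  ok <- !is.na(accel$heave)
  t <- accel$t[ok]
  x <- accel$heave[ok]
  if (length(t) == 0) {
    return(tibble(t_start = numeric(), stride_hz = numeric(),
                  n_peaks = integer()))
  }
  t0 <- floor(min(t) / window) * window
  win <- floor((t - t0) / window)
  idx_by_win <- split(seq_along(t), win)
  rows <- purrr::map(idx_by_win, function(ii) {
    pk <- find_peaks_window(x[ii], t[ii], prominence_mult, min_separation)
    np <- length(pk)
    f <- NA_real_
    if (np >= min_peaks) {
      iv <- diff(pk)
      if (sd(iv) / mean(iv) <= max_cv) f <- 1 / median(iv)
    }
    c(f, np)
  })
  m <- do.call(rbind, rows)
  tibble(t_start = t0 + as.numeric(names(idx_by_win)) * window,
         stride_hz = m[, 1L], n_peaks = as.integer(m[, 2L]))
}

#' Vectorial dynamic body acceleration
#'
#' Per sample, the static (gravitational) component of each axis is a
#' centred rolling mean over `static_window` seconds (truncated at segment
#' edges); the dynamic component is the residual, and the sample VeDBA is
#' the Euclidean norm of the three dynamic components. Per-second VeDBA is
#' the mean of the sample values within that second, so values are rate-like
#' and comparable across gap patterns.
#'
#' @param accel Tibble with `t`, `surge`, `sway`, `heave` for one
#'   individual.
#' @param static_window Static-component window, s (default 2).
#' @param sample_rate Samples per second.
#' @return Tibble: `t` (integer second), `vedba` (m/s^2), `n_samples`.
#' @export
compute_vedba <- function(accel, static_window = 2, sample_rate = 12) {
  stopifnot_cols(accel, c("t", "surge", "sway", "heave"), "accel")
  hw <- max(1L, as.integer(round(static_window * sample_rate / 2)))
  dyn2 <- rep(0, nrow(accel))
  for (ax in c("surge", "sway", "heave")) {
    d <- accel[[ax]] - roll_mean(accel[[ax]], hw)
    dyn2 <- dyn2 + d^2
  }
  v <- sqrt(dyn2)
  sec <- floor(accel$t)
  out <- tibble(sec = sec, v = v) %>%
    filter(!is.na(.data$v)) %>%
    group_by(.data$sec) %>%
    summarise(vedba = mean(.data$v), n_samples = dplyr::n(),
              .groups = "drop") %>%
    rename(t = "sec")
  out
}

#' Per-second activity features
#'
#' Builds the feature set used by the activity classifier: mean VeDBA,
#' footfall-peak count and dominant-frequency power of the mean-removed
#' heave within each second.
#'
#' @param accel Despiked tibble with `t`, `surge`, `sway`, `heave`.
#' @param sample_rate Samples per second.
#' @param static_window VeDBA static window, s.
#' @return Tibble: `t`, `vedba`, `n_peaks`, `dom_power`.
#' @export
accel_features <- function(accel, sample_rate = 12, static_window = 2) {
  ved <- compute_vedba(accel, static_window, sample_rate)
  ok <- !is.na(accel$heave)
  t <- accel$t[ok]
  x <- accel$heave[ok]
  sec <- floor(t)
  # peak count per second via the windowed peak finder (10-s context)
  pk_t <- numeric(0)
  if (length(t) > 0) {
    t0 <- floor(min(t) / 10) * 10
    win <- floor((t - t0) / 10)
    pk_t <- unlist(purrr::map(split(seq_along(t), win), function(ii) {
      find_peaks_window(x[ii], t[ii])
    }), use.names = FALSE)
  }
  pk_per_sec <- if (length(pk_t) > 0) {
    tibble(sec = floor(pk_t)) %>% count(.data$sec, name = "n_peaks")
  } else {
    tibble(sec = numeric(), n_peaks = integer())
  }
  # dominant spectral power per complete second
  dom <- tibble(sec = sec, x = x) %>%
    group_by(.data$sec) %>%
    summarise(dom_power = {
      xx <- .data$x
      if (length(xx) == sample_rate) {
        p <- Mod(fft(xx - mean(xx)))^2 / sample_rate
        max(p[2:(sample_rate %/% 2 + 1L)])
      } else NA_real_
    }, .groups = "drop")
  ved %>%
    left_join(pk_per_sec, by = c(t = "sec")) %>%
    left_join(dom, by = c(t = "sec")) %>%
    mutate(n_peaks = tidyr::replace_na(.data$n_peaks, 0L),
           dom_power = tidyr::replace_na(.data$dom_power, 0))
}

#' Train the moving/stationary classifier
#'
#' Linear support-vector machine on the three per-second features of
#' [accel_features()], trained against ground-truth labels (e.g. the
#' `labels` of a [simulate_day()]).
#'
#' @param features Tibble from [accel_features()] with a logical `moving`
#'   column appended.
#' @param cost SVM cost parameter.
#' @return An object of class `activity_model`.
#' @export
train_activity_classifier <- function(features, cost = 1) {
  stopifnot_cols(features, c("vedba", "n_peaks", "dom_power", "moving"),
                 "features")
  df <- features %>%
    filter(!is.na(.data$vedba), !is.na(.data$moving)) %>%
    mutate(moving = factor(.data$moving, levels = c(FALSE, TRUE),
                           labels = c("stationary", "moving")))
  if (dplyr::n_distinct(df$moving) < 2) {
    abort("training data must contain both states")
  }
  fit <- e1071::svm(moving ~ vedba + n_peaks + dom_power, data = df,
                    kernel = "linear", cost = cost, scale = TRUE)
  structure(list(fit = fit), class = "activity_model")
}

#' Classify per-second activity state
#'
#' With a trained `activity_model` the SVM decides; without one a documented
#' fallback is used: moving iff mean VeDBA exceeds `vedba_threshold`.
#'
#' @param features Tibble from [accel_features()].
#' @param model An `activity_model`, or `NULL` for the threshold fallback.
#' @param vedba_threshold Fallback threshold, m/s^2.
#' @return Tibble: `t`, `state` (`"moving"`/`"stationary"`), `score`.
#' @export
classify_activity <- function(features, model = NULL,
                              vedba_threshold = 0.5) {
  stopifnot_cols(features, c("t", "vedba"), "features")
  if (is.null(model)) {
    score <- features$vedba - vedba_threshold
    state <- ifelse(score > 0, "moving", "stationary")
  } else {
    if (!inherits(model, "activity_model")) {
      abort("`model` must be an activity_model (or NULL for the fallback)")
    }
    stopifnot_cols(features, c("n_peaks", "dom_power"), "features")
    pred <- predict(model$fit, features, decision.values = TRUE)
    state <- as.character(pred)
    dv <- attr(pred, "decision.values")
    score <- if (is.null(dv)) rep(NA_real_, length(state)) else
      as.numeric(dv[, 1L])
  }
  out <- tibble(t = features$t, state = state, score = score)
  out$state[is.na(features$vedba)] <- NA_character_
  out
}
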