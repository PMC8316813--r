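#' Speed-modulation parameters for the 1D cohesion simulator
#'
#' @param g Modulation gain (1/s): strength of the pull toward the group
#'   centroid under rules II and III. An agent `d` metres ahead of the
#'   centroid slows by `g * d` m/s.
#' @param T_spread Spread threshold (m) gating modulation under rule III.
#' @param noise_sd SD of the per-step additive speed noise, m/s.
#' @param dt Time step, s.
#' @param duration Bout duration, s.
#' @param move_pause Optional [move_pause_rule()]: position-dependent
#'   intermittent locomotion. `NULL` disables pausing.
#' @param init_spread_sd SD (m) of the Gaussian initial positions along the
#'   travel axis (0 starts all agents at a point).
#' @return List of class `sim_params`.
#' @export
sim_params <- function(g = 0.01, T_spread = 80, noise_sd = 0.1, dt = 1,
                       duration = 1560, move_pause = NULL,
                       init_spread_sd = 0) {
  if (g < 0) abort("`g` must be >= 0")
  if (T_spread < 0) abort("`T_spread` must be >= 0")
  if (dt <= 0) abort("`dt` must be > 0")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (duration < dt) abort("`duration` must cover at least one step")
  structure(list(g = g, T_spread = T_spread, noise_sd = noise_sd, dt = dt,
                 duration = duration, move_pause = move_pause,
                 init_spread_sd = init_spread_sd),
            class = "sim_params")
}

#' Position-dependent move/pause rule
#'
#' Intermittent locomotion: each step an agent moves with probability
#' `plogis(b0 + b_leg * z_leg + s_front * [sep > front_bp] +
#' s_back * [sep < back_bp])`, where `sep` is the agent's front-back
#' separation (m) from the centroid of the rest of the group and `z_leg` its
#' standardised leg length. Defaults encode the asymmetric response scales of
#' travelling baboons: agents react to being 20 m ahead (pausing to let the
#' group catch up) but tolerate 40 m of falling behind before hustling, and
#' smaller individuals pause less.
#'
#' @param b0 Baseline log-odds of moving in a given second.
#' @param b_leg Coefficient on standardised leg length (negative: smaller
#'   individuals move more).
#' @param front_bp Separation ahead (m) beyond which `s_front` applies.
#' @param back_bp Separation behind (m, negative) beyond which `s_back`
#'   applies.
#' @param s_front Log-odds shift when more than `front_bp` ahead (negative:
#'   pause and wait).
#' @param s_back Log-odds shift when more than `|back_bp|` behind (positive:
#'   pause less, catch up).
#' @return List of class `move_pause_rule`.
#' @export
move_pause_rule <- function(b0 = qlogis(0.9), b_leg = -0.35,
                            front_bp = 20, back_bp = -40,
                            s_front = -2.5, s_back = 1.5) {
  if (front_bp <= 0 || back_bp >= 0) {
    abort("`front_bp` must be positive and `back_bp` negative")
  }
  structure(list(b0 = b0, b_leg = b_leg, front_bp = front_bp,
                 back_bp = back_bp, s_front = s_front, s_back = s_back),
            class = "move_pause_rule")
}

scenario_n_params <- c(I = 0L, II = 1L, III = 2L)

check_scenario <- function(scenario) {
  scenario <- match.arg(as.character(scenario), c("I", "II", "III"))
  scenario
}

# Core vectorised engine: n agents x R replicate bouts advanced jointly.
# The RNG stream is consumed identically for every rule (noise and move/pause
# draws happen each step regardless of the rule), so rules II and III with
# g = 0 reproduce rule I trajectories exactly under a shared seed.
#
# Returns list(spread = steps x R matrix (NA after a bout's end),
#              x_final = n x R, moving = steps x n (R == 1 only),
#              positions = (steps+1) x n (R == 1 only),
#              speed = steps x n realized displacement/dt (R == 1 only)).
sim_engine <- function(v_char, scenario, params, n_steps, R = 1L,
                       durations = NULL, leg_z = NULL,
                       record = FALSE) {
  n <- length(v_char)
  scenario <- check_scenario(scenario)
  g <- params$g
  Ts <- params$T_spread
  dt <- params$dt
  mp <- params$move_pause
  if (is.null(durations)) durations <- rep(n_steps, R)
  stopifnot(length(durations) == R)
  if (is.null(leg_z)) leg_z <- rep(0, n)

  X <- matrix(rnorm(n * R, 0, params$init_spread_sd), n, R)
  V <- matrix(v_char, n, R)
  spread <- matrix(NA_real_, n_steps, R)
  active_steps <- matrix(rep(seq_len(n_steps), R), n_steps, R) <=
    matrix(durations, n_steps, R, byrow = TRUE)
  pos <- if (record && R == 1L) matrix(NA_real_, n_steps + 1L, n) else NULL
  mv <- if (record && R == 1L) matrix(NA, n_steps, n) else NULL
  if (record && R == 1L) pos[1L, ] <- X[, 1L]

  base_logit <- if (!is.null(mp)) mp$b0 + mp$b_leg * leg_z else NULL

  for (s in seq_len(n_steps)) {
    cent <- colMeans(X)
    d <- X - matrix(cent, n, R, byrow = TRUE)
    sp <- col_max(X) - col_min(X)
    vmod <- switch(scenario,
      I = V,
      II = V - g * d,
      III = V - g * d * matrix(as.numeric(sp > Ts), n, R, byrow = TRUE))
    eps <- matrix(rnorm(n * R, 0, params$noise_sd), n, R)
    dx <- pmax(vmod + eps, 0) * dt
    if (!is.null(mp)) {
      sep <- d * n / (n - 1)
      lgt <- base_logit + mp$s_front * (sep > mp$front_bp) +
        mp$s_back * (sep < mp$back_bp)
      move <- matrix(runif(n * R), n, R) < plogis(lgt)
      dx <- dx * move
    }
    act <- matrix(active_steps[s, ], n, R, byrow = TRUE)
    dx <- dx * act
    X <- X + dx
    spread[s, ] <- ifelse(active_steps[s, ], col_max(X) - col_min(X), NA_real_)
    if (record && R == 1L) {
      pos[s + 1L, ] <- X[, 1L]
      mv[s, ] <- dx[, 1L] > 0
    }
  }
  list(spread = spread, x_final = X,
       positions = pos, moving = mv,
       speed = if (record && R == 1L) diff(pos) / dt else NULL)
}

#' Simulate a single 1D collective travel bout
#'
#' Agents move along a line under one of three decision rules: (I) each at
#' its characteristic speed; (II) speed modulated by signed distance from the
#' group centroid, `v_i - g * d_i`; (III) rule I while the front-back spread
#' is at most `T_spread`, rule II once it exceeds it. Realised steps are
#' clipped at zero (agents pause rather than reverse) and optionally thinned
#' by a position-dependent move/pause rule.
#'
#' @param troop A troop tibble from [make_troop()] (columns
#'   `individual_id`, `v_char_true_ms`, `leg_length_cm`), or a numeric vector
#'   of characteristic speeds (m/s).
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return An object of class `sim_bout`: list with `positions` (long tibble
#'   `t`, `individual_id`, `x_m`, `moving`), `spread` (tibble `t`,
#'   `spread_m`), `final_ranks` (tibble; rank 1 = backmost), `scenario`,
#'   `params`.
#' @export
#' @examples
#' b <- simulate_bout_1d(c(1.2, 1.0), "II",
#'                       sim_params(g = 0.01, noise_sd = 0, duration = 300))
#' tail(b$spread)  # approaches (1.2 - 1.0) / 0.01 = 20 m
simulate_bout_1d <- function(troop, scenario, params = sim_params(),
                             seed = 1L) {
  info <- troop_speeds(troop)
  if (length(info$v) < 2) abort("need at least 2 individuals to simulate")
  n_steps <- floor(params$duration / params$dt)
  eng <- local_seed(seed,
    sim_engine(info$v, scenario, params, n_steps, R = 1L,
               leg_z = info$leg_z, record = TRUE))
  tgrid <- seq(0, by = params$dt, length.out = n_steps + 1L)
  positions <- tibble(
    t = rep(tgrid, times = length(info$v)),
    individual_id = rep(info$id, each = n_steps + 1L),
    x_m = as.vector(eng$positions),
    moving = as.vector(rbind(NA, eng$moving)))
  xf <- eng$x_final[, 1L]
  rk <- rank(xf, ties.method = "average")
  structure(list(
    positions = positions,
    spread = tibble(t = tgrid[-1L], spread_m = eng$spread[, 1L]),
    final_ranks = tibble(individual_id = info$id, x_m = xf, rank = rk,
                         leg_length_cm = info$leg,
                         v_char_ms = info$v),
    mean_speed = tibble(individual_id = info$id,
                        mean_speed_ms = colMeans(eng$speed)),
    scenario = check_scenario(scenario), params = params, seed = seed),
    class = "sim_bout")
}

#' Simulate replicate 1D travel bouts
#'
#' Vectorised multi-bout runner used for likelihood evaluation and emergent
#' segregation analyses. Bout durations are drawn (with replacement) from
#' `durations`, mirroring the use of an observed travel-bout duration
#' distribution.
#'
#' @inheritParams simulate_bout_1d
#' @param n_bouts Number of replicate bouts.
#' @param durations Numeric vector of candidate bout durations (s); defaults
#'   to `params$duration` for every bout.
#' @param sample_every Record the group spread every this many steps (s) for
#'   the pooled spread sample.
#' @param seed Integer seed.
#' @return Class `sim_bouts`: list with `spread_samples` (numeric vector of
#'   pooled spreads), `final` (tibble of per-bout final positions and ranks),
#'   `durations`, `scenario`, `params`.
#' @export
simulate_bouts <- function(troop, scenario, params = sim_params(),
                           n_bouts = 50, durations = NULL,
                           sample_every = 10, seed = 1L) {
  info <- troop_speeds(troop)
  n <- length(info$v)
  if (n < 2) abort("need at least 2 individuals to simulate")
  eng <- local_seed(seed, {
    dur <- if (is.null(durations)) rep(params$duration, n_bouts) else
      sample(durations, n_bouts, replace = TRUE)
    dur_steps <- pmax(floor(dur / params$dt), 1L)
    n_steps <- max(dur_steps)
    out <- sim_engine(info$v, scenario, params, n_steps, R = n_bouts,
                      durations = dur_steps, leg_z = info$leg_z)
    out$dur <- dur_steps
    out
  })
  keep <- seq(sample_every, nrow(eng$spread), by = sample_every)
  spread_samples <- as.vector(eng$spread[keep, , drop = FALSE])
  spread_samples <- spread_samples[!is.na(spread_samples)]
  rk <- apply(eng$x_final, 2, rank, ties.method = "average")
  final <- tibble(
    bout = rep(seq_len(n_bouts), each = n),
    individual_id = rep(info$id, n_bouts),
    x_m = as.vector(eng$x_final),
    rank = as.vector(rk),
    leg_length_cm = rep(info$leg, n_bouts),
    v_char_ms = rep(info$v, n_bouts))
  structure(list(spread_samples = spread_samples, final = final,
                 durations = eng$dur * params$dt,
                 scenario = check_scenario(scenario), params = params,
                 n_bouts = n_bouts, seed = seed),
            class = "sim_bouts")
}

# Normalise troop input: tibble from make_troop() or bare speed vector.
troop_speeds <- function(troop) {
  if (is.numeric(troop)) {
    v <- troop
    id <- sprintf("agent%02d", seq_along(v))
    leg <- rep(NA_real_, length(v))
    leg_z <- rep(0, length(v))
  } else {
    stopifnot_cols(troop, "v_char_true_ms", "troop")
    keep <- !is.na(troop$v_char_true_ms)
    if (!all(keep)) {
      warn(sprintf("%d individual(s) without a characteristic speed excluded",
                   sum(!keep)))
      troop <- troop[keep, , drop = FALSE]
    }
    v <- troop$v_char_true_ms
    id <- troop$individual_id %||% sprintf("agent%02d", seq_along(v))
    leg <- troop$leg_length_cm %||% rep(NA_real_, length(v))
    leg_z <- if (all(is.na(leg)) || sd(leg) == 0) rep(0, length(v)) else
      as.vector(scale(leg))
  }
  if (any(v < 0)) abort("characteristic speeds must be non-negative")
  list(v = v, id = id, leg = leg, leg_z = leg_z)
}

#' Per-second separation/activity records from a simulated bout
#'
#' Pairs every agent-second's move/pause outcome with the agent's front-back
#' separation from the rest of the group at the moment the decision was
#' taken (the start of the step), the alignment needed to recover
#' position-dependent pause rules with [separation_profile()].
#'
#' @param bout A `sim_bout` from [simulate_bout_1d()].
#' @return Tibble: `t`, `individual_id`, `sep_m`, `moving`.
#' @export
bout_separation_records <- function(bout) {
  stopifnot(inherits(bout, "sim_bout"))
  pos <- bout$positions
  sep <- pos %>%
    group_by(.data$t) %>%
    mutate(sep_m = (.data$x_m - mean(.data$x_m)) * dplyr::n() /
             pmax(dplyr::n() - 1L, 1L)) %>%
    ungroup() %>%
    select("t", "individual_id", "sep_m") %>%
    mutate(t = .data$t + bout$params$dt)  # decision applies to the next step
  pos %>%
    filter(!is.na(.data$moving)) %>%
    select("t", "individual_id", "moving") %>%
    inner_join(sep, by = c("t", "individual_id"))
}

#' Emergent size segregation in simulated bouts
#'
#' Splits agents into large/small classes at the median leg length, computes
#' the per-bout difference in mean front-back positional rank between the two
#' classes, and pools a regression of final rank on leg length across bouts.
#' Under rule I (no modulation) faster -- and therefore, through the gait
#' model, on average larger -- agents finish at the front; under strong
#' position-dependent modulation ranks decouple from size.
#'
#' @param bouts A `sim_bouts` object (from [simulate_bouts()]) whose troop
#'   carried leg lengths, or a `sim_bout`.
#' @return Class `segregation_fit`: list with `rank_diff` (per-bout mean rank
#'   large minus small), `slope` tibble (estimate, SE, t, p from the pooled
#'   `lm(rank ~ leg_length)`), and the underlying per-bout ranks.
#' @export
simulated_segregation <- function(bouts) {
  final <- if (inherits(bouts, "sim_bouts")) bouts$final
    else if (inherits(bouts, "sim_bout")) dplyr::mutate(bouts$final_ranks, bout = 1L)
    else abort("`bouts` must be a sim_bouts or sim_bout object")
  if (all(is.na(final$leg_length_cm))) {
    abort("leg lengths unavailable; simulate from a troop tibble")
  }
  med <- median(unique(final$leg_length_cm))
  classes <- dplyr::n_distinct(final$leg_length_cm > med)
  if (classes < 2) abort("single size class; segregation undefined")
  rank_diff <- final %>%
    mutate(size_class = ifelse(.data$leg_length_cm > med, "large", "small")) %>%
    group_by(.data$bout, .data$size_class) %>%
    summarise(mean_rank = mean(.data$rank), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "size_class", values_from = "mean_rank") %>%
    mutate(rank_diff = .data$large - .data$small)
  fit <- lm(rank ~ leg_length_cm, data = final)
  cf <- summary(fit)$coefficients["leg_length_cm", ]
  rd <- rank_diff$rank_diff
  tt <- if (length(rd) >= 2 && sd(rd) > 0) stats::t.test(rd) else NULL
  structure(list(
    rank_diff = rank_diff,
    rank_diff_test = tibble(
      mean_rank_diff = mean(rd),
      statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p.value = if (is.null(tt)) NA_real_ else tt$p.value,
      n_bouts = length(rd)),
    slope = tibble(term = "leg_length_cm", estimate = cf[1],
                   std.error = cf[2], statistic = cf[3], p.value = cf[4]),
    ranks = final),
    class = "segregation_fit")
}

#' @exportS3Method
tidy.segregation_fit <- function(x, ...) x$slope

#' @exportS3Method
glance.segregation_fit <- function(x, ...) {
  tibble(n_bouts = dplyr::n_distinct(x$ranks$bout),
         mean_rank_diff = x$rank_diff_test$mean_rank_diff,
         rank_diff_p = x$rank_diff_test$p.value,
         slope = x$slope$estimate, slope_p = x$slope$p.value)
}

#' @export
print.sim_bout <- function(x, ...) {
  cat(sprintf("<sim_bout> rule %s, %d agents, %d s, final spread %.1f m\n",
              x$scenario, nrow(x$final_ranks),
              max(x$spread$t), tail(x$spread$spread_m, 1)))
  invisible(x)
}

#' @export
print.sim_bouts <- function(x, ...) {
  cat(sprintf(
    "<sim_bouts> rule %s, %d bouts, median pooled spread %.1f m (n = %d)\n",
    x$scenario, x$n_bouts, median(x$spread_samples),
    length(x$spread_samples)))
  invisible(x)
}
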