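#' Move:pause response to separation from the group
#'
#' Bins per-second (separation, moving) records into a move:pause profile
#' along the signed front-back separation axis, then estimates -- on each
#' side of zero independently -- the separation at which the moving
#' probability steps to a different level (a two-piece segmented fit with a
#' single breakpoint, scored by binomial likelihood). A breakpoint is only
#' reported when the two-level model beats the flat model by BIC, so a
#' position-independent pause pattern yields a curve but no breakpoints.
#'
#' @param data Tibble of per-second records.
#' @param sep_col,moving_col Column names of the signed separation (m;
#'   positive = ahead of the rest of the group) and the logical (or
#'   `"moving"`/`"stationary"`) state.
#' @param bin Bin width, m.
#' @param range Separation range analysed, m.
#' @param min_count Bins with fewer records are dropped from the curve.
#' @return Class `separation_profile`: list with `curve` (tibble `sep_mid`,
#'   `prop_moving`, `n`), `breakpoints` (tibble `side`, `breakpoint_m`,
#'   `level_inner`, `level_outer`, `delta_bic`; only detected sides),
#'   `bin`, `range`.
#' @export
separation_profile <- function(data, sep_col = "sep_m",
                               moving_col = "moving", bin = 5,
                               range = c(-80, 80), min_count = 30) {
  stopifnot_cols(data, c(sep_col, moving_col), "data")
  sep <- data[[sep_col]]
  mv <- data[[moving_col]]
  if (is.character(mv)) mv <- mv == "moving"
  ok <- !is.na(sep) & !is.na(mv) & sep >= range[1] & sep <= range[2]
  sep <- sep[ok]
  mv <- mv[ok]
  if (length(sep) == 0) abort("no usable records in `range`")
  edges <- seq(range[1], range[2], by = bin)
  bidx <- findInterval(sep, edges, rightmost.closed = TRUE)
  agg <- tibble(bidx = bidx, mv = mv) %>%
    group_by(.data$bidx) %>%
    summarise(k = sum(.data$mv), n = dplyr::n(), .groups = "drop") %>%
    mutate(sep_lo = edges[.data$bidx], sep_mid = .data$sep_lo + bin / 2,
           prop_moving = .data$k / .data$n)
  curve <- agg %>% filter(.data$n >= min_count) %>%
    select("sep_mid", "prop_moving", "n")
  bks <- bind_rows(
    fit_step_side(agg, bin, side = "front"),
    fit_step_side(agg, bin, side = "back"))
  structure(list(curve = curve, breakpoints = bks, bin = bin,
                 range = range),
            class = "separation_profile")
}

# Single-breakpoint two-level binomial fit on one side of zero.
# side = "front": separations > 0, outer region is sep > c.
# side = "back": separations < 0, outer region is sep < c (c negative).
fit_step_side <- function(agg, bin, side) {
  sub <- if (side == "front") agg[agg$sep_lo >= 0, , drop = FALSE]
         else agg[agg$sep_lo < 0, , drop = FALSE]
  if (nrow(sub) < 3 || sum(sub$n) == 0) {
    return(tibble(side = character(), breakpoint_m = numeric(),
                  level_inner = numeric(), level_outer = numeric(),
                  delta_bic = numeric()))
  }
  ll_bin <- function(k, n) {
    p <- sum(k) / sum(n)
    p <- min(max(p, 1e-12), 1 - 1e-12)
    sum(k) * log(p) + (sum(n) - sum(k)) * log(1 - p)
  }
  N <- sum(sub$n)
  ll_flat <- ll_bin(sub$k, sub$n)
  bic_flat <- -2 * ll_flat + log(N)
  cands <- if (side == "front") sort(unique(sub$sep_lo))[-1]
           else sort(unique(sub$sep_lo + bin), decreasing = TRUE)[-1]
  if (length(cands) < 2) {
    return(tibble(side = character(), breakpoint_m = numeric(),
                  level_inner = numeric(), level_outer = numeric(),
                  delta_bic = numeric()))
  }
  res <- purrr::map_dfr(cands, function(cc) {
    outer <- if (side == "front") sub$sep_lo >= cc else sub$sep_lo + bin <= cc
    if (!any(outer) || all(outer)) {
      return(tibble(breakpoint_m = cc, ll = -Inf,
                    level_inner = NA_real_, level_outer = NA_real_))
    }
    tibble(breakpoint_m = cc,
           ll = ll_bin(sub$k[!outer], sub$n[!outer]) +
             ll_bin(sub$k[outer], sub$n[outer]),
           level_inner = sum(sub$k[!outer]) / sum(sub$n[!outer]),
           level_outer = sum(sub$k[outer]) / sum(sub$n[outer]))
  })
  best <- res[which.max(res$ll), ]
  bic_step <- -2 * best$ll + 3 * log(N)
  if (!is.finite(bic_step) || bic_step >= bic_flat) {
    return(tibble(side = character(), breakpoint_m = numeric(),
                  level_inner = numeric(), level_outer = numeric(),
                  delta_bic = numeric()))
  }
  tibble(side = side, breakpoint_m = best$breakpoint_m,
         level_inner = best$level_inner, level_outer = best$level_outer,
         delta_bic = bic_flat - bic_step)
}

#' @export
print.separation_profile <- function(x, ...) {
  cat(sprintf("<separation_profile> %d bins of %g m\n", nrow(x$curve),
              x$bin))
  if (nrow(x$breakpoints) > 0) print(x$breakpoints) else
    cat("no breakpoints detected (flat profile)\n")
  invisible(x)
}

#' @exportS3Method
tidy.separation_profile <- function(x, ...) x$breakpoints

#' Plot a separation profile
#'
#' Proportion of time moving against signed front-back separation, with any
#' detected breakpoints marked.
#'
#' @param x A [separation_profile()].
#' @return A ggplot object.
#' @export
plot_separation_profile <- function(x) {
  stopifnot(inherits(x, "separation_profile"))
  p <- ggplot2::ggplot(x$curve,
                       ggplot2::aes(.data$sep_mid, .data$prop_moving)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "front-back separation from rest of group (m)",
                  y = "proportion of time moving", size = "records") +
    ggplot2::theme_minimal()
  if (nrow(x$breakpoints) > 0) {
    p <- p + ggplot2::geom_vline(
      data = x$breakpoints,
      ggplot2::aes(xintercept = .data$breakpoint_m),
      linetype = "dashed", colour = "firebrick")
  }
  p
}
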