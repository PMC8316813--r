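# Internal numeric helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring RNG state afterwards.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Centred rolling mean with truncated windows at the edges; NA values are
# excluded from the window average (all-NA windows give NA).
roll_mean <- function(x, half_window) {
  n <- length(x)
  if (n == 0L) return(x)
  k <- as.integer(half_window)
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- cumsum(xs)
  cn <- cumsum(as.numeric(ok))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  prev_cs <- c(0, cs)[lo]   # cs[lo - 1], with 0 when lo == 1
  prev_cn <- c(0, cn)[lo]
  tot <- cs[hi] - prev_cs
  cnt <- cn[hi] - prev_cn
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

# Rolling median over a centred window of 2*half_window+1 samples.
# Interior via stats::runmed (O(n log k)); edges recomputed exactly with
# truncated windows so constant inputs are reproduced everywhere.
roll_median <- function(x, half_window) {
  n <- length(x)
  k <- 2L * as.integer(half_window) + 1L
  if (n == 0L) return(x)
  if (k >= n) return(rep(median(x), n))
  out <- as.numeric(runmed(x, k, endrule = "keep"))
  for (i in seq_len(half_window)) {
    out[i] <- median(x[1:(i + half_window)])
    out[n - i + 1L] <- median(x[(n - i + 1L - half_window):n])
  }
  out
}

# Split indices of a logical vector into contiguous runs where it is TRUE.
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(list())
  purrr::map2(starts[keep], ends[keep], seq.int)
}

# Column-wise max/min of a matrix without apply() overhead.
col_max <- function(m) do.call(pmax, lapply(seq_len(nrow(m)), function(i) m[i, ]))
col_min <- function(m) do.call(pmin, lapply(seq_len(nrow(m)), function(i) m[i, ]))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
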