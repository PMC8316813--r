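#' Pearson correlation with a two-sided test
#'
#' Thin tidy wrapper around [stats::cor.test()].
#'
#' @param data Data frame, or `NULL` when `x`/`y` are vectors.
#' @param x,y Column names (tidy-selected as strings) or numeric vectors.
#' @return One-row tibble: `r`, `p.value`, `n`, `conf.low`, `conf.high`.
#' @export
#' @examples
#' pearson_corr(NULL, x = 1:10, y = (1:10) * 2)
pearson_corr <- function(data, x, y) {
  if (!is.null(data)) {
    x <- data[[x]]
    y <- data[[y]]
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance; correlation undefined")
  ct <- cor.test(x, y)
  tibble(r = unname(ct$estimate), p.value = ct$p.value, n = length(x),
         conf.low = ct$conf.int[1], conf.high = ct$conf.int[2])
}

#' Linear mixed model with temporal autocorrelation
#'
#' Fits the window-record regressions: fixed effects of interest, random
#' intercepts for individual (and movement bout), and an AR1 component for
#' the residual series within each individual-by-bout run. Two engines are
#' offered: `"nlme"` (default) fits nested random intercepts
#' (`individual/bout`) with `corAR1` residuals -- a fast, documented
#' approximation of the crossed design -- while `"glmmTMB"` fits crossed
#' random intercepts with an `ar1()` covariance over the within-series
#' time index.
#'
#' @param data Window-record tibble.
#' @param fixed Fixed-effects formula, e.g. `stride_dev_pct ~ leg_length_cm *
#'   p + I(p^2) + spread_m`.
#' @param individual,bout Grouping column names (`bout = NULL` for a single
#'   grouping level).
#' @param time Column with the within-series time order (required when
#'   `ar1 = TRUE`).
#' @param ar1 Include the AR1 residual component?
#' @param engine `"nlme"` or `"glmmTMB"`.
#' @return Class `troop_lmm` wrapping the fit; use [tidy()]/[glance()].
#' @export
fit_lmm <- function(data, fixed, individual = "individual_id",
                    bout = NULL, time = "t_start", ar1 = TRUE,
                    engine = c("nlme", "glmmTMB")) {
  engine <- match.arg(engine)
  stopifnot_cols(data, c(all.vars(fixed), individual,
                         if (ar1) time, bout), "data")
  if (dplyr::n_distinct(data[[individual]]) < 2) {
    abort("need at least 2 individuals")
  }
  data <- as.data.frame(data)
  data$.ind <- factor(data[[individual]])
  if (!is.null(bout)) data$.bout <- factor(data[[bout]])
  converged <- TRUE
  fit <- NULL
  if (engine == "nlme") {
    grp <- if (is.null(bout)) ~ 1 | .ind else ~ 1 | .ind / .bout
    corr <- NULL
    if (ar1) {
      data$.tw <- as.numeric(data[[time]])
      # corAR1 needs unique integer positions inside each innermost group
      data <- data %>%
        group_by(across(all_of(c(".ind", if (!is.null(bout)) ".bout")))) %>%
        arrange(.data$.tw, .by_group = TRUE) %>%
        mutate(.pos = dplyr::row_number()) %>%
        ungroup() %>% as.data.frame()
      corr <- if (is.null(bout)) nlme::corAR1(form = ~ .pos | .ind) else
        nlme::corAR1(form = ~ .pos | .ind / .bout)
    }
    fit <- tryCatch(
      nlme::lme(fixed = fixed, random = grp, correlation = corr,
                data = data, method = "REML",
                control = nlme::lmeControl(opt = "optim",
                                           returnObject = TRUE)),
      error = function(e) {
        converged <<- FALSE
        e
      })
  } else {
    rhs <- paste(deparse(fixed[[3]]), collapse = " ")
    terms <- c(rhs, "(1 | .ind)", if (!is.null(bout)) "(1 | .bout)")
    if (ar1) {
      data$.series <- if (is.null(bout)) data$.ind else
        interaction(data$.ind, data$.bout, drop = TRUE)
      data <- data %>%
        group_by(.data$.series) %>%
        arrange(.data[[time]], .by_group = TRUE) %>%
        mutate(.pos = factor(dplyr::row_number())) %>%
        ungroup() %>% as.data.frame()
      terms <- c(terms, "ar1(.pos + 0 | .series)")
    }
    form <- stats::reformulate(terms, response = deparse(fixed[[2]]))
    fit <- tryCatch(
      glmmTMB::glmmTMB(form, data = data, family = stats::gaussian()),
      error = function(e) {
        converged <<- FALSE
        e
      })
    if (converged && !is.null(fit$fit$convergence)) {
      converged <- fit$fit$convergence == 0
    }
  }
  structure(list(fit = fit, engine = engine, converged = converged,
                 fixed = fixed, ar1 = ar1),
            class = "troop_lmm")
}

#' Beta GLMM for move:pause proportions
#'
#' Logit-link beta regression of the (boundary-shrunken) proportion of time
#' moving on predictors such as leg length and front-back position, with
#' crossed random intercepts for individual and bout (via glmmTMB).
#'
#' @param data Window-record tibble; the response must lie strictly in
#'   (0, 1) (apply [shrink_proportion()] first).
#' @param fixed Fixed-effects formula, e.g.
#'   `prop_shrunk ~ leg_length_cm + p`.
#' @param individual,bout Grouping column names (`bout = NULL` to omit).
#' @return Class `troop_lmm` (engine `"glmmTMB"`).
#' @export
fit_beta_glmm <- function(data, fixed, individual = "individual_id",
                          bout = NULL) {
  stopifnot_cols(data, c(all.vars(fixed), individual, bout), "data")
  resp <- data[[all.vars(fixed)[1]]]
  resp <- resp[!is.na(resp)]
  if (length(resp) == 0 || any(resp <= 0 | resp >= 1)) {
    abort("response must lie strictly in (0, 1); apply shrink_proportion()")
  }
  data <- as.data.frame(data)
  data$.ind <- factor(data[[individual]])
  terms <- c(paste(deparse(fixed[[3]]), collapse = " "), "(1 | .ind)")
  if (!is.null(bout)) {
    data$.bout <- factor(data[[bout]])
    terms <- c(terms, "(1 | .bout)")
  }
  form <- stats::reformulate(terms, response = deparse(fixed[[2]]))
  converged <- TRUE
  fit <- tryCatch(
    glmmTMB::glmmTMB(form, data = data,
                     family = glmmTMB::beta_family(link = "logit")),
    error = function(e) {
      converged <<- FALSE
      e
    })
  if (converged && !is.null(fit$fit$convergence)) {
    converged <- fit$fit$convergence == 0
  }
  structure(list(fit = fit, engine = "glmmTMB", converged = converged,
                 fixed = fixed, ar1 = FALSE),
            class = "troop_lmm")
}

#' @exportS3Method
tidy.troop_lmm <- function(x, ...) {
  if (!x$converged || inherits(x$fit, "error")) {
    return(tibble(term = character(), estimate = numeric(),
                  std.error = numeric(), statistic = numeric(),
                  p.value = numeric()))
  }
  if (x$engine == "nlme") {
    tt <- summary(x$fit)$tTable
    tibble(term = rownames(tt), estimate = unname(tt[, "Value"]),
           std.error = unname(tt[, "Std.Error"]),
           statistic = unname(tt[, "t-value"]),
           p.value = unname(tt[, "p-value"]))
  } else {
    cf <- summary(x$fit)$coefficients$cond
    tibble(term = rownames(cf), estimate = unname(cf[, 1]),
           std.error = unname(cf[, 2]), statistic = unname(cf[, 3]),
           p.value = unname(cf[, 4]))
  }
}

#' @exportS3Method
glance.troop_lmm <- function(x, ...) {
  if (!x$converged || inherits(x$fit, "error")) {
    return(tibble(logLik = NA_real_, AIC = NA_real_, converged = FALSE))
  }
  tibble(logLik = as.numeric(logLik(x$fit)), AIC = AIC(x$fit),
         converged = x$converged)
}

#' @export
print.troop_lmm <- function(x, ...) {
  cat(sprintf("<troop_lmm> engine %s, %s, converged: %s\n", x$engine,
              paste(deparse(x$fixed), collapse = " "), x$converged))
  if (x$converged) print(tidy(x))
  invisible(x)
}
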