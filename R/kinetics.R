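#' Fit the first-order thermal degradation model
#'
#' Fits `C(t) = C0 exp(-k t)` to one degradation time-series at a single
#' temperature. The default estimator is ordinary least squares of
#' `ln(C/C0)` on time with a free intercept (the intercept absorbs
#' measurement error in the time-0 reference); alternatives force the line
#' through the origin or fit the exponential directly by nonlinear least
#' squares. When a replicate column is given each replicate is fitted
#' separately and the rate constant is reported as mean +/- SD across
#' replicates, the convention used for replicated heating experiments;
#' `aggregate = "pooled"` instead fits all points jointly.
#'
#' Non-positive responses (possible under heavy degradation plus noise)
#' cannot enter the log-linear fit; they are dropped with a warning rather
#' than floored, because flooring biases the slope.
#'
#' @param formula Model formula `response ~ time`, with variables taken
#'   from `data` (e.g. `response ~ time_min`).
#' @param data Data frame holding the series.
#' @param replicate Optional name of the replicate-id column in `data`
#'   (character scalar), or a vector of replicate ids; `NULL` treats the
#'   series as one unreplicated run.
#' @param method Estimator: `"free_intercept"` (default),
#'   `"through_origin"`, or `"nonlinear"` (exponential NLS, initialised
#'   from the log-linear fit).
#' @param c0 Reference policy for normalising responses before the log
#'   transform: `"replicate"` (each replicate's own time-0 measurement,
#'   default) or `"mean"` (the mean time-0 response across replicates).
#'   When a series has no time-0 observation the raw responses are used
#'   and the free intercept absorbs the scale.
#' @param aggregate `"replicate"` (fit per replicate, then mean +/- SD) or
#'   `"pooled"` (single fit on all points).
#' @param temperature Optional temperature label (degC) carried into the
#'   result.
#' @param analyte Optional analyte label carried into the result.
#' @return An object of class `"first_order_fit"` with components `k`
#'   (rate constant, min^-1), `k_sd` (SD across replicates, `NA` when
#'   unreplicated or pooled), `k_se` (regression standard error), `r2`,
#'   `t_half`, `d_value`, `n_points`, `n_replicates`, `replicate_fits`,
#'   plus the labels. Supports `print()`, `summary()`, `coef()`,
#'   `predict()`, `residuals()` and `plot()`.
#' @seealso [half_life()], [decimal_reduction()], [arrhenius_fit()],
#'   [thermal_study()]
#' @examples
#' des <- degradation_design(noise_cv = 0)
#' sim <- simulate_degradation(des, k = c(0.0069, 0.0138, 0.0253, 0.0737,
#'                                        0.1865))
#' one <- sim[sim$temperature_C == 155, ]
#' fit <- first_order_fit(response ~ time_min, one, replicate = "replicate",
#'                        temperature = 155)
#' coef(fit)
#' @export
first_order_fit <- function(formula, data, replicate = NULL,
                            method = c("free_intercept", "through_origin",
                                       "nonlinear"),
                            c0 = c("replicate", "mean"),
                            aggregate = c("replicate", "pooled"),
                            temperature = NA_real_, analyte = NA_character_) {
  method <- match.arg(method)
  c0 <- match.arg(c0)
  aggregate <- match.arg(aggregate)
  if (!inherits(formula, "formula") || length(formula) != 3L)
    stop("'formula' must be of the form response ~ time", call. = FALSE)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  response <- mf[[1L]]
  time <- mf[[2L]]
  if (any(time < 0)) stop("times must be non-negative", call. = FALSE)

  kept <- match(rownames(mf), rownames(data))  # rows surviving na.omit
  rep_id <- if (is.null(replicate)) {
    rep(1L, length(response))
  } else if (is.character(replicate) && length(replicate) == 1L) {
    if (!replicate %in% names(data))
      stop("replicate column '", replicate, "' not found", call. = FALSE)
    data[[replicate]][kept]
  } else {
    if (length(replicate) != nrow(data))
      stop("'replicate' vector must match 'data' rows", call. = FALSE)
    replicate[kept]
  }

  bad <- !is.finite(response) | response <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive response(s) excluded from the ",
            "log-linear fit", call. = FALSE)
    response <- response[!bad]; time <- time[!bad]; rep_id <- rep_id[!bad]
  }
  if (length(unique(time)) < 3L)
    stop("at least 3 distinct time points with positive responses ",
         "are required", call. = FALSE)

  # per-replicate normalisation to the time-0 reference
  c0_mean <- if (any(time == 0)) mean(response[time == 0]) else NA_real_
  norm_ref <- function(r, t) {
    if (c0 == "mean" && is.finite(c0_mean)) return(c0_mean)
    i0 <- which(t == 0)
    if (length(i0)) mean(r[i0]) else if (is.finite(c0_mean)) c0_mean else 1
  }

  fit_one <- function(r, t) {
    ref <- norm_ref(r, t)
    y <- log(r / ref)
    if (method == "through_origin") {
      lm0 <- stats::lm(y ~ t - 1)
      slope <- unname(stats::coef(lm0)[["t"]])
      se <- unname(sqrt(diag(vcov_quiet(lm0)))[1L])
      # R2 against the mean-free null is not meaningful through the origin;
      # report squared correlation of fitted vs observed
      r2 <- if (stats::sd(y) > 0) stats::cor(stats::fitted(lm0), y)^2 else 1
      list(k = -slope, k_se = se, r2 = r2, intercept = 0, n = length(r))
    } else if (method == "nonlinear") {
      start_lm <- stats::lm(y ~ t)
      st <- list(c0 = ref * exp(unname(stats::coef(start_lm)[1L])),
                 k = max(1e-12, -unname(stats::coef(start_lm)[2L])))
      # scaleOffset makes the convergence test valid at zero residual
      nf <- stats::nls(r ~ c0 * exp(-k * t), start = st,
                       control = stats::nls.control(warnOnly = TRUE,
                                                    scaleOffset = 1))
      co <- stats::coef(nf)
      ss_res <- sum(stats::residuals(nf)^2)
      ss_tot <- sum((r - mean(r))^2)
      r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
      list(k = unname(co[["k"]]),
           k_se = unname(sqrt(diag(stats::vcov(nf)))[["k"]]),
           r2 = r2, intercept = log(unname(co[["c0"]]) / ref),
           n = length(r))
    } else {
      lmf <- stats::lm(y ~ t)
      co <- stats::coef(lmf)
      se <- sqrt(diag(vcov_quiet(lmf)))[["t"]]
      r2 <- r_squared(lmf)
      list(k = -unname(co[["t"]]), k_se = unname(se), r2 = r2,
           intercept = unname(co[["(Intercept)"]]), n = length(r))
    }
  }

  reps <- sort(unique(rep_id))
  if (aggregate == "replicate" && length(reps) > 1L) {
    fits <- lapply(reps, function(rr) {
      sel <- rep_id == rr
      if (length(unique(time[sel])) < 3L)
        stop("replicate '", rr, "' has fewer than 3 usable time points",
             call. = FALSE)
      fit_one(response[sel], time[sel])
    })
    names(fits) <- as.character(reps)
    ks <- vapply(fits, `[[`, numeric(1), "k")
    k <- mean(ks)
    k_sd <- stats::sd(ks)
    k_se <- k_sd / sqrt(length(ks))
    r2 <- mean(vapply(fits, `[[`, numeric(1), "r2"))
  } else {
    f <- fit_one(response, time)
    fits <- list(pooled = f)
    k <- f$k; k_sd <- NA_real_; k_se <- f$k_se; r2 <- f$r2
  }

  structure(
    list(k = k, k_sd = k_sd, k_se = k_se, r2 = r2,
         t_half = if (k > 0) log(2) / k else NA_real_,
         d_value = if (k > 0) log(10) / k else NA_real_,
         n_points = length(response),
         n_replicates = length(reps),
         replicate_fits = fits,
         method = method, aggregate = aggregate, c0_policy = c0,
         temperature = temperature, analyte = analyte,
         data = data.frame(time = time, response = response,
                           replicate = rep_id),
         call = match.call()),
    class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, digits = 4, ...) {
  lab <- if (!is.na(x$temperature)) paste0(" at ", x$temperature, " degC")
         else ""
  cat("First-order degradation fit", lab, "\n", sep = "")
  if (!is.na(x$analyte)) cat("  analyte: ", x$analyte, "\n", sep = "")
  cat("  k      = ", signif(x$k, digits), " min^-1",
      if (is.finite(x$k_sd)) paste0(" (SD ", signif(x$k_sd, digits),
                                    " across ", x$n_replicates,
                                    " replicates)"),
      "\n", sep = "")
  cat("  R^2    = ", signif(x$r2, digits), "\n", sep = "")
  cat("  t_1/2  = ", signif(x$t_half, digits), " min\n", sep = "")
  cat("  D      = ", signif(x$d_value, digits), " min\n", sep = "")
  invisible(x)
}

#' @export
coef.first_order_fit <- function(object, ...) {
  c(k = object$k, t_half = object$t_half, d_value = object$d_value)
}

#' @export
summary.first_order_fit <- function(object, ...) {
  out <- data.frame(
    analyte = object$analyte, temperature_C = object$temperature,
    k = object$k, k_sd = object$k_sd, k_se = object$k_se, r2 = object$r2,
    t_half_min = object$t_half, d_value_min = object$d_value,
    n_points = object$n_points, n_replicates = object$n_replicates,
    stringsAsFactors = FALSE)
  class(out) <- c("summary.first_order_fit", "data.frame")
  out
}

#' Predict retained response from a first-order fit
#'
#' @param object A [first_order_fit()].
#' @param times Times (min) at which to predict.
#' @param type `"retention"` for the retained fraction `exp(-k t)` or
#'   `"response"` for the fraction times the fitted reference.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.first_order_fit <- function(object, times,
                                    type = c("retention", "response"), ...) {
  type <- match.arg(type)
  frac <- predict_retention(object$k, times)
  if (type == "retention") frac
  else frac * mean(object$data$response[object$data$time == 0])
}

#' @export
residuals.first_order_fit <- function(object, ...) {
  d <- object$data
  ref <- mean(d$response[d$time == 0])
  log(d$response) - (log(ref) - object$k * d$time)
}

#' Diagnostic plot of a first-order degradation fit
#'
#' Plots `ln(C/C0)` against time with the fitted line, one symbol per
#' replicate.
#'
#' @param x A [first_order_fit()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.first_order_fit <- function(x, ...) {
  d <- x$data
  ref <- mean(d$response[d$time == 0])
  y <- log(d$response / ref)
  graphics::plot(d$time, y, xlab = "time (min)", ylab = "ln(C/C0)",
                 pch = as.integer(factor(d$replicate)),
                 main = if (!is.na(x$temperature))
                   paste0("First-order fit, ", x$temperature, " degC")
                 else "First-order fit", ...)
  graphics::abline(a = 0, b = -x$k, lty = 2)
  invisible(x)
}

#' Half-life of a first-order reaction
#'
#' `t_1/2 = ln(2) / k`, the time for the response to fall to half its
#' initial value.
#'
#' @param k First-order rate constant (min^-1).
#' @return Half-life (min); `NA` with a warning when `k <= 0` (a
#'   non-degrading series has no finite half-life).
#' @examples
#' half_life(0.1865) # ~3.72 min
#' @export
half_life <- function(k) {
  stopifnot(is.numeric(k))
  out <- ifelse(k > 0, log(2) / k, NA_real_)
  if (anyNA(out))
    warning("half-life undefined for k <= 0; returning NA", call. = FALSE)
  out
}

#' Decimal reduction time of a first-order reaction
#'
#' `D = ln(10) / k`, the time for a tenfold decrease in response — the
#' thermal-processing D-value.
#'
#' @param k First-order rate constant (min^-1).
#' @return D-value (min); `NA` with a warning when `k <= 0`.
#' @examples
#' decimal_reduction(0.1865) # ~12.35 min
#' @export
decimal_reduction <- function(k) {
  stopifnot(is.numeric(k))
  out <- ifelse(k > 0, log(10) / k, NA_real_)
  if (anyNA(out))
    warning("decimal reduction time undefined for k <= 0; returning NA",
            call. = FALSE)
  out
}

#' Fraction retained after heating
#'
#' Evaluates the first-order survival `exp(-k t)`.
#'
#' @param k First-order rate constant (min^-1, >= 0).
#' @param t Time (min, >= 0); vectorised.
#' @return Fraction retained in (0, 1].
#' @examples
#' predict_retention(0.1865, 60)
#' @export
predict_retention <- function(k, t) {
  if (any(!is.finite(k)) || any(k < 0))
    stop("'k' must be non-negative", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be non-negative", call. = FALSE)
  exp(-k * t)
}
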