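#' Percent enzyme inhibition from absorbances
#'
#' Control-relative inhibition, `100 (A_control - A_sample) / A_control`,
#' clipped to \[0, 100\] with a warning when a reading falls outside
#' (negative apparent inhibition or readings below blank).
#'
#' @param a_control Absorbance of the uninhibited control (> 0).
#' @param a_sample Absorbance in the presence of inhibitor; vectorised.
#' @return Percent inhibition in \[0, 100\].
#' @examples
#' inhibition_percent(0.8, 0.2) # 75
#' @export
inhibition_percent <- function(a_control, a_sample) {
  if (any(!is.finite(a_control)) || any(a_control <= 0))
    stop("'a_control' must be positive", call. = FALSE)
  raw <- 100 * (a_control - a_sample) / a_control
  if (any(raw < 0 | raw > 100))
    warning("inhibition outside [0, 100] clipped", call. = FALSE)
  pmin(100, pmax(0, raw))
}

#' Log-linear IC50 inference from a dose-response series
#'
#' Fits percent inhibition against log10 concentration by ordinary least
#' squares and interpolates the concentration giving 50% inhibition:
#' `IC50 = 10^((50 - intercept) / slope)`. With only a few tested
#' concentrations this linear-in-log interpolation is the identifiable
#' model (a four-parameter logistic would be under-determined at three
#' doses). The standard error comes from the delta method on the fitted
#' line; the `extrapolated` flag marks an IC50 outside the tested
#' concentration range.
#'
#' @param concentration Tested concentrations (ug/mL, > 0), or a data frame
#'   with columns `concentration_ug_mL` and `inhibition_pct` (the layout
#'   written by [simulate_dose_response()]).
#' @param inhibition Percent inhibition values (ignored when
#'   `concentration` is a data frame).
#' @param enzyme Optional label carried into the result.
#' @return Object of class `"ic50_fit"` with `ic50` (ug/mL), `se` (delta
#'   method), `slope` (% per log10 unit), `intercept`, `r2`,
#'   `extrapolated`, `n`, and the underlying `lm`. `coef()` returns
#'   `c(ic50, slope)`; `predict()` gives fitted inhibition at new
#'   concentrations.
#' @examples
#' ic50_loglinear(c(0.5, 5), c(30, 70)) # IC50 = sqrt(0.5 * 5)
#' @export
ic50_loglinear <- function(concentration, inhibition = NULL,
                           enzyme = NA_character_) {
  if (is.data.frame(concentration)) {
    df <- concentration
    if (!all(c("concentration_ug_mL", "inhibition_pct") %in% names(df)))
      stop("data frame needs columns 'concentration_ug_mL' and ",
           "'inhibition_pct'", call. = FALSE)
    if (is.na(enzyme) && "enzyme" %in% names(df))
      enzyme <- as.character(df$enzyme[1L])
    concentration <- df$concentration_ug_mL
    inhibition <- df$inhibition_pct
  }
  ok <- is.finite(concentration) & is.finite(inhibition)
  concentration <- concentration[ok]; inhibition <- inhibition[ok]
  if (any(concentration <= 0))
    stop("concentrations must be positive", call. = FALSE)
  if (length(unique(concentration)) < 2L)
    stop("at least two distinct concentrations are required", call. = FALSE)
  lx <- log10(concentration)
  fit <- stats::lm(inhibition ~ lx)
  b0 <- unname(stats::coef(fit)[["(Intercept)"]])
  b1 <- unname(stats::coef(fit)[["lx"]])
  if (b1 <= 0)
    stop("non-positive slope: inhibition does not increase with ",
         "concentration, IC50 undefined", call. = FALSE)
  g <- (50 - b0) / b1                      # log10 IC50
  ic50 <- 10^g
  V <- vcov_quiet(fit)
  grad <- c(-1 / b1, -(50 - b0) / b1^2)    # d g / d (b0, b1)
  se_g <- sqrt(drop(t(grad) %*% V %*% grad))
  structure(
    list(ic50 = ic50,
         se = log(10) * ic50 * se_g,
         slope = b1, intercept = b0,
         r2 = r_squared(fit),
         extrapolated = ic50 < min(concentration) |
                        ic50 > max(concentration),
         n = length(concentration), enzyme = enzyme, lm = fit,
         data = data.frame(concentration = concentration,
                           inhibition = inhibition)),
    class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, digits = 4, ...) {
  cat("Log-linear IC50 fit",
      if (!is.na(x$enzyme)) paste0(" (", x$enzyme, ")"), "\n", sep = "")
  cat("  IC50  = ", signif(x$ic50, digits), " +/- ", signif(x$se, digits),
      " ug/mL", if (x$extrapolated) "  [extrapolated]", "\n", sep = "")
  cat("  slope = ", signif(x$slope, digits), " % per log10 unit   R^2 = ",
      signif(x$r2, digits), "\n", sep = "")
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(ic50 = object$ic50, slope = object$slope)
}

#' @export
predict.ic50_fit <- function(object, concentration, ...) {
  if (any(concentration <= 0))
    stop("concentrations must be positive", call. = FALSE)
  object$intercept + object$slope * log10(concentration)
}

#' @export
plot.ic50_fit <- function(x, ...) {
  graphics::plot(log10(x$data$concentration), x$data$inhibition,
                 xlab = "log10 concentration (ug/mL)",
                 ylab = "inhibition (%)",
                 main = if (!is.na(x$enzyme))
                   paste0("Dose-response, ", x$enzyme) else "Dose-response",
                 ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  graphics::abline(h = 50, col = "grey")
  graphics::abline(v = log10(x$ic50), col = "grey")
  invisible(x)
}

#' Tukey HSD compact letters from group summary statistics
#'
#' One-way ANOVA and all-pairs Tukey honest-significant-difference
#' comparison reconstructed from per-group mean, SD and n (raw replicate
#' values are often not available from published tables). Groups that are
#' not significantly different at level `alpha` share a letter; letters are
#' assigned greedily starting from the smallest mean. The error mean square
#' is the pooled within-group variance `sum((n_i - 1) s_i^2) / (N - g)` and
#' the studentized-range statistic for a pair is
#' `|m_i - m_j| / sqrt(MSE/2 (1/n_i + 1/n_j))`.
#'
#' @param mean Group means, or a data frame with columns `mean`, `sd`, `n`
#'   and optionally `label`.
#' @param sd Group standard deviations.
#' @param n Group replicate counts (each >= 2; smaller groups are dropped
#'   with a warning).
#' @param labels Group labels.
#' @param alpha Significance level for the pairwise comparisons.
#' @return A data frame with columns `label`, `mean`, `sd`, `n`, `letter`,
#'   ordered by mean, with attributes `f_statistic`, `p_value`, `mse`,
#'   `df_error`, and `p_adj` (matrix of Tukey-adjusted pairwise p-values).
#' @examples
#' tukey_letters(mean = c(1.02, 4.49), sd = c(0.30, 0.44), n = c(3, 3),
#'               labels = c("extract", "acarbose"))
#' @export
tukey_letters <- function(mean, sd = NULL, n = NULL, labels = NULL,
                          alpha = 0.05) {
  if (is.data.frame(mean)) {
    df <- mean
    stopifnot(all(c("mean", "sd", "n") %in% names(df)))
    labels <- if ("label" %in% names(df)) df$label
              else paste0("group", seq_len(nrow(df)))
    sd <- df$sd; n <- df$n; mean <- df$mean
  }
  if (is.null(labels)) labels <- paste0("group", seq_along(mean))
  stopifnot(length(mean) == length(sd), length(mean) == length(n),
            length(mean) == length(labels))
  keep <- n >= 2
  if (!all(keep)) {
    warning("group(s) with n < 2 excluded: ",
            paste(labels[!keep], collapse = ", "), call. = FALSE)
    mean <- mean[keep]; sd <- sd[keep]; n <- n[keep]
    labels <- labels[keep]
  }
  g <- length(mean)
  if (g < 2L) stop("at least two groups with n >= 2 are required",
                   call. = FALSE)
  if (any(sd < 0)) stop("standard deviations must be non-negative",
                        call. = FALSE)

  ord <- order(mean)
  mean <- mean[ord]; sd <- sd[ord]; n <- n[ord]; labels <- labels[ord]

  N <- sum(n)
  gm <- sum(n * mean) / N
  ss_between <- sum(n * (mean - gm)^2)
  df_between <- g - 1
  df_error <- N - g
  mse <- sum((n - 1) * sd^2) / df_error
  f_stat <- (ss_between / df_between) / mse
  p_val <- stats::pf(f_stat, df_between, df_error, lower.tail = FALSE)

  p_adj <- matrix(1, g, g, dimnames = list(labels, labels))
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(mean[i] - mean[j]) / se
    p_adj[i, j] <- p_adj[j, i] <-
      stats::ptukey(q, nmeans = g, df = df_error, lower.tail = FALSE)
  }
  differs <- p_adj < alpha

  # greedy sweep from the smallest mean: each group seeds a set of all
  # later groups compatible with every member; duplicate sets collapse
  sets <- list()
  for (i in seq_len(g)) {
    s <- i
    for (j in seq_len(g)) {
      if (j == i || j %in% s) next
      if (!any(differs[j, s])) s <- c(s, j)
    }
    s <- sort(s)
    if (!any(vapply(sets, function(x) all(s %in% x), logical(1))))
      sets <- c(Filter(function(x) !all(x %in% s), sets), list(s))
  }
  sets <- sets[order(vapply(sets, min, integer(1)))]
  letter <- vapply(seq_len(g), function(i) {
    paste(letters[which(vapply(sets, function(s) i %in% s, logical(1)))],
          collapse = "")
  }, character(1))

  out <- data.frame(label = labels, mean = mean, sd = sd, n = n,
                    letter = letter, stringsAsFactors = FALSE)
  attr(out, "f_statistic") <- f_stat
  attr(out, "p_value") <- p_val
  attr(out, "mse") <- mse
  attr(out, "df_error") <- df_error
  attr(out, "p_adj") <- p_adj
  attr(out, "alpha") <- alpha
  class(out) <- c("tukey_letters", "data.frame")
  out
}

#' @export
print.tukey_letters <- function(x, digits = 4, ...) {
  cat("One-way ANOVA from summary statistics: F = ",
      signif(attr(x, "f_statistic"), digits), ", p = ",
      signif(attr(x, "p_value"), digits), "\n", sep = "")
  print(as.data.frame(x), row.names = FALSE, ...)
  cat("Groups sharing a letter are not significantly different (alpha = ",
      attr(x, "alpha"), ")\n", sep = "")
  invisible(x)
}
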