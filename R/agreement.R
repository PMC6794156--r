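# Paired method-agreement statistics for per-lesion FFR gradients: paired t,
# Pearson correlation, Bland-Altman limits of agreement, mean relative error
# and TOST equivalence.

#' Agreement between estimated and true FFR gradients
#'
#' Discrepancies are `truth - estimate`, so a positive bias means the method
#' underestimates the true gradient. Reported: mean and SD of the
#' discrepancy, mean relative error (percent of the true gradient), Pearson
#' correlation, Bland-Altman bias and 1.96-SD limits of agreement, the
#' two-tailed paired t-test p-value, and the TOST equivalence p-value at
#' `+/- tost_margin` (the larger of the two one-sided paired t p-values).
#'
#' @param pairs A data frame with columns `estimate` and `truth` (or the
#'   column names given in `estimate`/`truth`), one row per lesion.
#' @param estimate,truth Column names, default `"estimate"` and `"truth"`.
#' @param tost_margin Equivalence margin on the FFR-gradient scale
#'   (default 0.02).
#' @return An object of class `ffr_agreement`.
#' @export
#' @examples
#' assess_cohort(data.frame(estimate = c(0.06, 0.12), truth = c(0.10, 0.20)))
assess_cohort <- function(pairs, estimate = "estimate", truth = "truth",
                          tost_margin = 0.02) {
  est <- pairs[[estimate]]
  tru <- pairs[[truth]]
  if (is.null(est) || is.null(tru)) {
    stop("`pairs` must contain the estimate and truth columns", call. = FALSE)
  }
  ok <- stats::complete.cases(est, tru)
  est <- est[ok]; tru <- tru[ok]
  n <- length(est)
  if (n < 2) stop("at least 2 complete pairs are required", call. = FALSE)
  if (any(tru <= 0)) {
    stop("true gradients must be positive for relative error", call. = FALSE)
  }

  d <- tru - est
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  se <- sd_diff / sqrt(n)
  df <- n - 1

  if (sd_diff == 0) {
    paired_t_p <- if (mean_diff == 0) 1 else NA_real_
    tost_p <- if (abs(mean_diff) < tost_margin) 0 else NA_real_
    if (is.na(paired_t_p)) {
      message("zero variance with nonzero mean difference: t statistics undefined")
    }
  } else {
    paired_t_p <- stats::t.test(tru, est, paired = TRUE)$p.value
    p_lower <- stats::pt((mean_diff + tost_margin) / se, df, lower.tail = FALSE)
    p_upper <- stats::pt((mean_diff - tost_margin) / se, df)
    tost_p <- max(p_lower, p_upper)
  }

  pearson_r <- stats::cor(est, tru)

  structure(list(
    n = n,
    mean_diff = mean_diff,
    sd_diff = sd_diff,
    mean_relative_error_pct = mean(100 * abs(d) / tru),
    pearson_r = pearson_r,
    bland_altman = list(bias = mean_diff,
                        lo = mean_diff - 1.96 * sd_diff,
                        hi = mean_diff + 1.96 * sd_diff),
    paired_t_p = paired_t_p,
    tost_p = tost_p,
    tost_margin = tost_margin,
    data = tibble::tibble(estimate = est, truth = tru)
  ), class = "ffr_agreement")
}

#' @export
print.ffr_agreement <- function(x, ...) {
  cat(sprintf(
    paste0("<ffr_agreement> n = %d\n",
           "  discrepancy (truth - estimate): %.3f +/- %.3f\n",
           "  mean relative error: %.1f%%   Pearson r: %.3f\n",
           "  Bland-Altman: bias %.3f, LoA [%.3f, %.3f]\n",
           "  paired t p = %.3g   TOST p (margin %.3g) = %.3g\n"),
    x$n, x$mean_diff, x$sd_diff, x$mean_relative_error_pct, x$pearson_r,
    x$bland_altman$bias, x$bland_altman$lo, x$bland_altman$hi,
    x$paired_t_p, x$tost_margin, x$tost_p))
  invisible(x)
}

#' Tidy an agreement report
#'
#' @param x An `ffr_agreement`.
#' @param ... Unused.
#' @return A tibble with one row per statistic (`statistic`, `value`).
#' @export
tidy.ffr_agreement <- function(x, ...) {
  tibble::tibble(
    statistic = c("n", "mean_diff", "sd_diff", "mean_relative_error_pct",
                  "pearson_r", "ba_bias", "ba_lo", "ba_hi",
                  "paired_t_p", "tost_p"),
    value = c(x$n, x$mean_diff, x$sd_diff, x$mean_relative_error_pct,
              x$pearson_r, x$bland_altman$bias, x$bland_altman$lo,
              x$bland_altman$hi, x$paired_t_p, x$tost_p))
}

#' One-row summary of an agreement report
#'
#' @param x An `ffr_agreement`.
#' @param ... Unused.
#' @return A one-row tibble of all agreement statistics.
#' @export
glance.ffr_agreement <- function(x, ...) {
  tibble::tibble(n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 mean_relative_error_pct = x$mean_relative_error_pct,
                 pearson_r = x$pearson_r, ba_bias = x$bland_altman$bias,
                 ba_lo = x$bland_altman$lo, ba_hi = x$bland_altman$hi,
                 paired_t_p = x$paired_t_p, tost_p = x$tost_p,
                 tost_margin = x$tost_margin)
}

#' Bland-Altman plot of an agreement report
#'
#' @param object An `ffr_agreement`.
#' @param ... Unused.
#' @return A ggplot: pair means against differences, with bias and limits of
#'   agreement.
#' @export
autoplot.ffr_agreement <- function(object, ...) {
  d <- dplyr::mutate(object$data,
                     mean_pair = (.data$estimate + .data$truth) / 2,
                     diff_pair = .data$truth - .data$estimate)
  ba <- object$bland_altman
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_pair, y = .data$diff_pair)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(ba$lo, ba$hi), linetype = 2) +
    ggplot2::labs(x = "mean of pair (FFR gradient)",
                  y = "truth - estimate",
                  title = sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f]",
                                  ba$bias, ba$lo, ba$hi))
}
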