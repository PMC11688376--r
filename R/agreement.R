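#' Bland-Altman agreement between paired gestational-age estimates
#'
#' Quantifies agreement between a reference rater (e.g. the clinician) and a
#' test method (e.g. the automated pipeline) from paired estimates.
#' Differences are `test - reference` by default; the bias is their mean,
#' the 95% limits of agreement are `mean +/- 1.96 * SD` with the sample
#' (n - 1) standard deviation, and the mean absolute error summarizes the
#' magnitude of disagreement.
#'
#' @param data A data frame with one row per case.
#' @param reference,test Column names (strings) holding the reference and
#'   test estimates in weeks.
#' @param direction `"test - reference"` (default) or `"reference - test"`.
#' @return An object of class `"sac_agreement"`; see [tidy()] for the
#'   per-pair plot coordinates (pair mean vs difference) and [glance()] for
#'   the one-row summary (`mean_diff`, `loa_lower`, `loa_upper`, `mae`, `n`).
#' @export
#' @examples
#' df <- data.frame(doctor = c(7.1, 8.0, 6.5), auto = c(7.2, 7.9, 6.5))
#' glance(agreement(df, "doctor", "auto"))
agreement <- function(data, reference, test,
                      direction = c("test - reference", "reference - test")) {
  direction <- match.arg(direction)
  data <- as.data.frame(data)
  if (!all(c(reference, test) %in% names(data)))
    abort("reference/test columns not found in `data`")
  r <- as.numeric(data[[reference]]); t <- as.numeric(data[[test]])
  keep <- is.finite(r) & is.finite(t)
  r <- r[keep]; t <- t[keep]
  if (length(r) < 2L) abort("agreement needs at least 2 complete pairs")
  d <- if (direction == "test - reference") t - r else r - t
  m <- (r + t) / 2
  mean_diff <- mean(d)
  s <- stats::sd(d)
  structure(
    list(mean_diff = mean_diff,
         sd_diff = s,
         loa_lower = mean_diff - 1.96 * s,
         loa_upper = mean_diff + 1.96 * s,
         mae = mean(abs(d)),
         n = length(d),
         direction = direction,
         pairs = tibble::tibble(mean = m, diff = d)),
    class = "sac_agreement"
  )
}

#' @export
print.sac_agreement <- function(x, ...) {
  cat("Bland-Altman agreement (", x$direction, ", n = ", x$n, ")\n", sep = "")
  cat(sprintf("  bias %.4f weeks, 95%% LoA [%.4f, %.4f], MAE %.4f weeks\n",
              x$mean_diff, x$loa_lower, x$loa_upper, x$mae))
  invisible(x)
}

#' @export
tidy.sac_agreement <- function(x, ...) x$pairs

#' @export
glance.sac_agreement <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 mae = x$mae, n = x$n)
}

#' Bland-Altman plot
#'
#' @param object A [agreement()] result.
#' @param ... Unused.
#' @return A ggplot object: per-pair difference against per-pair mean, with
#'   the bias and 95% limits of agreement as horizontal lines.
#' @export
autoplot.sac_agreement <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff, color = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", color = "red") +
    ggplot2::labs(x = "Mean of paired estimates (weeks)",
                  y = paste0("Difference (", object$direction, ", weeks)"),
                  title = sprintf("Bias %.3f, LoA [%.3f, %.3f], MAE %.3f weeks",
                                  object$mean_diff, object$loa_lower,
                                  object$loa_upper, object$mae)) +
    ggplot2::theme_minimal()
}
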