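#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d probes, %d control vs %d case samples\n",
              x$method, x$n_probes, x$group_sizes[1], x$group_sizes[2]))
  cat(sprintf("  %d significant at alpha = %g (%s correction)\n",
              sum(x$results$significant), x$alpha, x$correction))
  if (!is.null(x$prior))
    cat(sprintf("  variance prior: df = %.4g, scale = %.4g\n",
                x$prior$df_prior, x$prior$var_prior))
  invisible(x)
}

#' Summarize a differential-expression fit
#'
#' @param object A `de_fit` object.
#' @param n Number of top probes (by p-value) to display.
#' @param ... Unused.
#' @return `object`, invisibly.
#' @export
summary.de_fit <- function(object, n = 10L, ...) {
  print(object)
  res <- object$results
  top <- res[order(res$p_value, -abs(res$statistic)), , drop = FALSE]
  cat("Top probes:\n")
  print(utils::head(top, n), row.names = FALSE, digits = 4)
  invisible(object)
}

#' Extract the per-probe statistics of a fit
#'
#' @param object A `de_fit` object.
#' @param ... Unused.
#' @return Named numeric vector of statistics in input probe order.
#' @export
coef.de_fit <- function(object, ...) {
  stats::setNames(object$results$statistic, object$results$probe_id)
}

#' @export
as.data.frame.de_fit <- function(x, ...) x$results

#' Diagnostic plot of a differential-expression fit
#'
#' Plots the per-probe statistic against the average of the two group
#' summaries (an MA-style view), marking significant probes.
#'
#' @param x A `de_fit` object.
#' @param ... Passed on to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.de_fit <- function(x, ...) {
  res <- x$results
  a <- (res$T + res$C) / 2
  ok <- is.finite(res$statistic)
  graphics::plot(a[ok], res$statistic[ok],
                 pch = 20, cex = 0.4,
                 col = ifelse(res$significant[ok], "red3", "grey40"),
                 xlab = "average group summary",
                 ylab = sprintf("%s statistic", x$method), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Write a fit's result table to a delimited file
#'
#' @param fit A `de_fit` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(fit, path) {
  stopifnot(inherits(fit, "de_fit"))
  utils::write.table(fit$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Dispatch a method name to its fitting function; shared by the
# benchmark, the reproducibility analysis and the command-line tool.
fit_method <- function(method, m, alpha = 0.05, p_adjust = "none",
                       bin_size = 1000, calibration = 0.455) {
  switch(method,
         sfc = sfc(m, bin_size = bin_size, calibration = calibration,
                   alpha = alpha, p_adjust = p_adjust),
         ttest = row_ttest(m, variant = "student", alpha = alpha,
                           p_adjust = p_adjust),
         welch = row_ttest(m, variant = "welch", alpha = alpha,
                           p_adjust = p_adjust),
         modt = moderated_t(m, alpha = alpha, p_adjust = p_adjust),
         stop("unknown method '", method,
              "' (expected sfc, ttest, welch or modt)"))
}
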