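#' Standardized fold change (SFC) differential expression
#'
#' Fits the standardized fold change statistic to a two-group expression
#' matrix. For probe i with case median `T_i` and control median `C_i`,
#'
#' \deqn{SFC_i = \frac{T_i - C_i}{\sqrt{\widehat{Var}_i}}, \qquad
#'   \widehat{Var}_i = \mathrm{median}\{(T_j - C_j)^2 : j \in W_i\} / 0.455,}
#'
#' where the window `W_i` contains the `b + 1` probes whose mean signal
#' (over all samples, both groups pooled) ranks nearest to probe i's.
#' Because the median of a chi-squared(1) variable is about 0.455,
#' dividing the median squared difference by 0.455 makes the denominator
#' a consistent estimator of `Var(T - C)` under locally homogeneous
#' Gaussian noise, and the statistic is referred to a standard normal for
#' two-sided p-values.
#'
#' @param x An [expression_matrix()], or a plain numeric matrix (then
#'   `group` is required).
#' @param group Optional group vector (`"case"`/`"control"`) when `x` is
#'   a plain matrix.
#' @param bin_size Number of rank-neighbouring probes pooled into the
#'   variance window (window size is `bin_size + 1`, the probe itself
#'   included). Clamped to the number of probes with a warning when
#'   larger. Default 1000.
#' @param calibration Positive divisor applied to the median squared
#'   difference; the default 0.455 is the median of chi-squared(1).
#' @param alpha Significance level for the `significant` call flag.
#' @param p_adjust Multiple-testing correction for the call flag:
#'   `"bonferroni"` (default) or `"none"`.
#'
#' @return An object of classes `"sfc_fit"` and `"de_fit"`; a list whose
#'   `results` element is a data frame in input probe order with columns
#'   `probe_id`, `T`, `C`, `diff`, `variance`, `statistic`, `p_value`,
#'   `p_adjusted`, `significant`. See [summary.de_fit()],
#'   [coef.de_fit()], [plot.de_fit()].
#'
#' @details Probes with an exactly zero window variance get statistic 0
#'   when their median difference is 0 and otherwise +/-Inf with p-value
#'   0; a warning counts such probes. The statistic is invariant to
#'   adding a constant to, or positively rescaling, the whole matrix.
#'
#' @seealso [row_ttest()], [moderated_t()] for the benchmark baselines
#'   sharing the same result schema.
#' @examples
#' sim <- simulate_expression(sim_config(n_probes = 500, theta = 0.5,
#'                                       pos_fraction = 0.1, k = 0.05),
#'                            seed = 1)
#' fit <- sfc(sim$matrix, bin_size = 100)
#' fit
#' @export
sfc <- function(x, group = NULL, bin_size = 1000, calibration = 0.455,
                alpha = 0.05, p_adjust = c("bonferroni", "none")) {
  m <- as_expr_mat(x, group)
  p_adjust <- match.arg(p_adjust)
  stopifnot(alpha > 0, alpha < 1, calibration > 0)
  med <- group_medians(m)
  d <- med$T - med$C
  ord <- rank_probes_by_mean(m)
  variance <- numeric(length(d))
  variance[ord] <- neighborhood_variance(d[ord], bin_size = bin_size,
                                         calibration = calibration)
  statistic <- ifelse(variance > 0, d / sqrt(variance),
                      ifelse(d == 0, 0, sign(d) * Inf))
  n_degenerate <- sum(variance == 0 & d != 0)
  if (n_degenerate > 0)
    warning(n_degenerate, " probe(s) had zero window variance with a ",
            "non-zero median difference; statistic set to +/-Inf, p-value 0")
  p <- sfc_pvalues(statistic)
  res <- build_results(rownames(m$values), med$T, med$C, d, variance,
                       statistic, p, p_adjust, alpha)
  new_de_fit(res, method = "sfc",
             params = list(bin_size = bin_size, calibration = calibration),
             alpha = alpha, correction = p_adjust, m = m,
             class = "sfc_fit")
}

#' Per-probe group medians
#'
#' Median of the case columns and of the control columns for every probe;
#' even sample counts use the midpoint of the two central values.
#'
#' @param x An [expression_matrix()] (or matrix with `group`).
#' @inheritParams sfc
#' @return A data frame with columns `probe_id`, `T` (case median) and
#'   `C` (control median).
#' @export
group_medians <- function(x, group = NULL) {
  m <- as_expr_mat(x, group)
  data.frame(probe_id = rownames(m$values),
             T = row_medians(m$values[, m$group == "case", drop = FALSE]),
             C = row_medians(m$values[, m$group == "control", drop = FALSE]),
             stringsAsFactors = FALSE)
}

# Row medians, vectorized for the small column counts typical of the
# designs handled here; midpoint convention for even counts.
row_medians <- function(v) {
  k <- ncol(v)
  if (k == 0L) stop("empty sample group")
  if (k == 1L) return(v[, 1L])
  if (k == 2L) return((v[, 1L] + v[, 2L]) / 2)
  if (k == 3L) {
    a <- v[, 1L]; b <- v[, 2L]; c <- v[, 3L]
    return(pmax(pmin(a, b), pmin(pmax(a, b), c)))
  }
  apply(v, 1L, stats::median)
}

#' Rank probes by their overall mean signal
#'
#' Returns the permutation of probe indices that sorts probes ascending
#' by the mean of their signal across all samples (cases and controls
#' pooled). Ties keep the input row order (stable sort), so results are
#' reproducible.
#'
#' @inheritParams group_medians
#' @return Integer permutation of `seq_len(nrow(x))`.
#' @export
rank_probes_by_mean <- function(x, group = NULL) {
  m <- as_expr_mat(x, group)
  order(rowMeans(m$values))  # order() is stable: ties keep input order
}

#' Rank-window robust variance of median differences
#'
#' For position i in a rank-ordered vector of per-probe median
#' differences, pools the squared differences of the `min(b + 1, n)`
#' probes in a window nominally centred at i (positions `i - floor(b/2)`
#' to `i + ceiling(b/2)`; an odd `b` puts the extra neighbour on the
#' high-rank side) and returns `median(squares) / calibration`. At the
#' ends of the list the window is shifted inward -- never truncated -- so
#' every probe's variance pools the same number of neighbours.
#'
#' @param diffs Numeric vector of median differences `T - C`, already in
#'   rank order (see [rank_probes_by_mean()]).
#' @inheritParams sfc
#' @return Numeric vector of variance estimates aligned with `diffs`.
#' @export
neighborhood_variance <- function(diffs, bin_size = 1000, calibration = 0.455) {
  n <- length(diffs)
  stopifnot(n >= 1L, calibration > 0)
  b <- as.integer(bin_size)
  if (b < 1L) stop("'bin_size' must be a positive integer")
  if (b > n) {
    warning("'bin_size' (", b, ") exceeds the number of probes (", n,
            "); clamped to ", n)
    b <- n
  }
  w <- min(b + 1L, n)
  half <- b %/% 2L
  sq <- diffs^2
  if (w == n) return(rep(stats::median(sq) / calibration, n))
  n_head <- half              # positions whose nominal window starts before 1
  n_tail <- w - 1L - half     # positions whose nominal window ends past n
  out <- numeric(n)
  if (w %% 2L == 1L) {
    # odd window (even b): interior medians via the running-median filter
    out <- as.vector(stats::runmed(sq, w, endrule = "keep"))
  } else {
    for (i in seq.int(n_head + 1L, n - n_tail)) {
      lo <- i - half
      out[i] <- stats::median(sq[lo:(lo + w - 1L)])
    }
  }
  if (n_head > 0L) out[seq_len(n_head)] <- stats::median(sq[seq_len(w)])
  if (n_tail > 0L) out[seq.int(n - n_tail + 1L, n)] <- stats::median(sq[seq.int(n - w + 1L, n)])
  out / calibration
}

# Two-sided p-values under the standard normal reference.
sfc_pvalues <- function(statistic) 2 * stats::pnorm(-abs(statistic))

# Shared result assembly for all three fitting functions.
build_results <- function(probe_id, T, C, d, variance, statistic, p,
                          p_adjust, alpha) {
  p_adjusted <- stats::p.adjust(p, method = p_adjust)
  data.frame(probe_id = probe_id, T = T, C = C, diff = d,
             variance = variance, statistic = statistic,
             p_value = p, p_adjusted = p_adjusted,
             significant = p_adjusted < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

new_de_fit <- function(results, method, params, alpha, correction, m,
                       class, extra = list()) {
  structure(c(list(results = results, method = method, params = params,
                   alpha = alpha, correction = correction,
                   n_probes = nrow(results),
                   group_sizes = tabulate(m$group, 2L)),
              extra),
            class = c(class, "de_fit"))
}
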