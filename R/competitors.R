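#' Per-probe two-sample t-test
#'
#' Student (pooled-variance) or Welch t-test applied row-wise to a
#' two-group expression matrix, returning the same result schema as
#' [sfc()] so that downstream evaluation is method-agnostic. The `T` and
#' `C` columns carry the group means for this method.
#'
#' @inheritParams sfc
#' @param variant `"student"` (pooled variance, `n1 + n2 - 2` df; the
#'   default) or `"welch"` (Satterthwaite df).
#' @return An object of classes `"ttest_fit"` and `"de_fit"`.
#' @details Probes with zero variance in both groups get statistic 0 and
#'   p-value 1 when the group means are equal, otherwise +/-Inf and
#'   p-value 0 (counted in a warning).
#' @export
row_ttest <- function(x, group = NULL, variant = c("student", "welch"),
                      alpha = 0.05, p_adjust = c("bonferroni", "none")) {
  m <- as_expr_mat(x, group)
  variant <- match.arg(variant)
  p_adjust <- match.arg(p_adjust)
  stopifnot(alpha > 0, alpha < 1)
  g <- two_group_moments(m)
  if (g$n1 < 2L || g$n2 < 2L)
    stop("the t-test needs at least 2 samples per group")
  d <- g$m1 - g$m2
  if (variant == "student") {
    df <- g$n1 + g$n2 - 2
    sp2 <- ((g$n1 - 1) * g$v1 + (g$n2 - 1) * g$v2) / df
    se2 <- sp2 * (1 / g$n1 + 1 / g$n2)
    variance <- sp2
  } else {
    a1 <- g$v1 / g$n1
    a2 <- g$v2 / g$n2
    se2 <- a1 + a2
    df <- se2^2 / (a1^2 / (g$n1 - 1) + a2^2 / (g$n2 - 1))
    df[se2 == 0] <- g$n1 + g$n2 - 2  # degenerate rows; statistic handled below
    variance <- se2
  }
  statistic <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, sign(d) * Inf))
  n_degenerate <- sum(se2 == 0 & d != 0)
  if (n_degenerate > 0)
    warning(n_degenerate, " probe(s) had zero variance in both groups with ",
            "unequal means; p-value set to 0")
  p <- 2 * stats::pt(-abs(statistic), df)
  p[se2 == 0 & d == 0] <- 1
  res <- build_results(rownames(m$values), g$m1, g$m2, d, variance,
                       statistic, p, p_adjust, alpha)
  new_de_fit(res, method = paste0("ttest_", variant),
             params = list(variant = variant), alpha = alpha,
             correction = p_adjust, m = m, class = "ttest_fit",
             extra = list(df = df))
}

#' Empirical-Bayes moderated t-statistic
#'
#' Per-probe t-statistic whose pooled sample variance is shrunk towards a
#' prior estimated from all probes. With per-probe pooled variance
#' `s_i^2` on `d` residual df and a scaled-inverse-chi-squared prior with
#' `d0` df and scale `s0^2`, the posterior variance is
#'
#' \deqn{\tilde s_i^2 = \frac{d_0 s_0^2 + d\, s_i^2}{d_0 + d},}
#'
#' the statistic is `diff / (s_i~ * sqrt(1/n1 + 1/n2))`, and two-sided
#' p-values come from a t distribution on `d0 + d` df. The prior
#' parameters are estimated by moment-matching the log sample variances
#' (digamma/trigamma equations; see [fit_variance_prior()]).
#'
#' @inheritParams sfc
#' @return An object of classes `"modt_fit"` and `"de_fit"`, with the
#'   estimated prior exposed as `$prior` (elements `df_prior`,
#'   `var_prior`).
#' @details When the trigamma moment equation has no positive solution
#'   (sample variances no more dispersed than chi-squared sampling noise
#'   explains), the prior df is infinite and every probe's variance is
#'   replaced by the common `s0^2`, so the statistics equal an ordinary t
#'   computed with that common variance (on infinite df, i.e. a normal
#'   reference).
#' @export
moderated_t <- function(x, group = NULL, alpha = 0.05,
                        p_adjust = c("bonferroni", "none")) {
  m <- as_expr_mat(x, group)
  p_adjust <- match.arg(p_adjust)
  stopifnot(alpha > 0, alpha < 1)
  g <- two_group_moments(m)
  if (g$n1 < 2L || g$n2 < 2L)
    stop("the moderated t needs at least 2 samples per group")
  if (nrow(m$values) < 2L)
    stop("the moderated t needs at least 2 probes to estimate the prior")
  df <- g$n1 + g$n2 - 2
  s2 <- ((g$n1 - 1) * g$v1 + (g$n2 - 1) * g$v2) / df
  prior <- fit_variance_prior(s2, df)
  d0 <- prior$df_prior
  s02 <- prior$var_prior
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + df * s2) / (d0 + df)
  d <- g$m1 - g$m2
  se2 <- s2_post * (1 / g$n1 + 1 / g$n2)
  statistic <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, sign(d) * Inf))
  p <- 2 * stats::pt(-abs(statistic), d0 + df)
  res <- build_results(rownames(m$values), g$m1, g$m2, d, s2_post,
                       statistic, p, p_adjust, alpha)
  new_de_fit(res, method = "modt", params = list(), alpha = alpha,
             correction = p_adjust, m = m, class = "modt_fit",
             extra = list(prior = prior))
}

#' Estimate the variance prior by moment-matching log variances
#'
#' Fits the scaled-F model `s_i^2 ~ s0^2 * F(df, df_prior)` to a vector
#' of sample variances, i.e. a scaled-inverse-chi-squared prior for the
#' true variances, by matching the mean and variance of `log(s_i^2)`
#' through the digamma/trigamma identities. The trigamma equation is
#' inverted by Newton iteration (tolerance 1e-8, at most 50 steps). When
#' the excess log-variance dispersion is non-positive the prior df is
#' infinite (complete shrinkage).
#'
#' @param s2 Per-probe sample variances (non-positive entries are
#'   excluded from the fit with a warning).
#' @param df Residual degrees of freedom of each sample variance
#'   (scalar).
#' @return A list with `df_prior` (`d0`, possibly `Inf`) and `var_prior`
#'   (`s0^2`).
#' @export
fit_variance_prior <- function(s2, df) {
  stopifnot(length(df) == 1L, df > 0)
  ok <- is.finite(s2) & s2 > 0
  if (!all(ok)) {
    warning(sum(!ok), " non-positive or non-finite variance(s) excluded ",
            "from the prior fit")
    s2 <- s2[ok]
  }
  if (length(s2) < 2L) stop("need at least 2 positive variances")
  z <- log(s2)
  if (diff(range(z)) < 1e-12)  # identical variances: shrink fully to their value
    return(list(df_prior = Inf, var_prior = s2[1L]))
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(df_prior = d0, var_prior = s02)
}

# Solve trigamma(x) = y by Newton iteration on the monotone decreasing
# trigamma function; asymptotic starts for extreme y.
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 50L) {
  stopifnot(length(y) == 1L, is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < tol) break
  }
  x
}

# Row-wise means and unbiased variances per group.
two_group_moments <- function(m) {
  case <- m$values[, m$group == "case", drop = FALSE]
  ctrl <- m$values[, m$group == "control", drop = FALSE]
  n1 <- ncol(case)
  n2 <- ncol(ctrl)
  m1 <- rowMeans(case)
  m2 <- rowMeans(ctrl)
  v1 <- if (n1 > 1L) rowSums((case - m1)^2) / (n1 - 1) else rep(NA_real_, nrow(case))
  v2 <- if (n2 > 1L) rowSums((ctrl - m2)^2) / (n2 - 1) else rep(NA_real_, nrow(ctrl))
  list(n1 = n1, n2 = n2, m1 = m1, m2 = m2, v1 = v1, v2 = v2)
}
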