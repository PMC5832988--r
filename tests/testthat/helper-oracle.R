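# Independent brute-force SFC implementation used as an oracle: explicit
# sorted medians, explicit stable sort of probe means, explicit window
# enumeration with the shift-at-ends rule. Deliberately naive; kept free
# of any code shared with the production path.
brute_sfc_statistic <- function(values, group, b, calibration = 0.455) {
  n <- nrow(values)
  med <- function(v) {
    v <- sort(v)
    k <- length(v)
    if (k %% 2 == 1) v[(k + 1) / 2] else (v[k / 2] + v[k / 2 + 1]) / 2
  }
  T <- numeric(n); C <- numeric(n); mu <- numeric(n)
  for (i in seq_len(n)) {
    T[i] <- med(values[i, group == "case"])
    C[i] <- med(values[i, group == "control"])
    mu[i] <- mean(values[i, ])
  }
  ord <- order(mu)                      # stable for ties
  d_ord <- (T - C)[ord]
  b_eff <- min(b, n)
  w <- min(b_eff + 1, n)
  half <- b_eff %/% 2
  var_ord <- numeric(n)
  for (i in seq_len(n)) {
    lo <- i - half
    hi <- lo + w - 1
    if (lo < 1) { lo <- 1; hi <- w }
    if (hi > n) { hi <- n; lo <- n - w + 1 }
    var_ord[i] <- med(d_ord[lo:hi]^2) / calibration
  }
  stat_ord <- ifelse(var_ord > 0, d_ord / sqrt(var_ord),
                     ifelse(d_ord == 0, 0, sign(d_ord) * Inf))
  stat <- numeric(n)
  stat[ord] <- stat_ord
  stat
}

# Tiny random two-group matrix for property tests.
random_expr <- function(n_probes, n_ctrl = 3, n_case = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(rnorm(n_probes * (n_ctrl + n_case), mean = 8, sd = 2),
              nrow = n_probes)
  rownames(v) <- sprintf("p%03d", seq_len(n_probes))
  colnames(v) <- c(paste0("c", seq_len(n_ctrl)), paste0("t", seq_len(n_case)))
  expression_matrix(v, rep(c("control", "case"), c(n_ctrl, n_case)))
}
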