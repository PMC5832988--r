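#' False-positive / false-negative rates of one set of calls
#'
#' Contingency summary of significance calls against a truth mask, in
#' percent:
#' * `FPR` = false positives / truly null probes,
#' * `FNR` = false negatives / truly differential probes (0 when no
#'   probe is truly differential),
#' * `total_calls` = called probes / all probes.
#'
#' @param calls The calls: a `de_fit` object (raw p-values compared to
#'   `alpha`), a numeric p-value vector, or a logical call vector.
#' @param truth Logical truth mask, `TRUE` for truly differential probes.
#' @param alpha Significance level applied to p-values (ignored for
#'   logical `calls`).
#' @return One-row data frame with columns `FPR`, `FNR`, `total_calls`
#'   (percent) and the counts `TP`, `FP`, `TN`, `FN`.
#' @examples
#' evaluate_calls(c(rep(0.01, 10), rep(0.5, 90)),
#'                truth = rep(c(TRUE, FALSE), c(10, 90)))
#' @export
evaluate_calls <- function(calls, truth, alpha = 0.05) {
  if (inherits(calls, "de_fit")) calls <- calls$results$p_value
  if (is.numeric(calls)) calls <- calls < alpha
  stopifnot(is.logical(calls), is.logical(truth))
  if (length(calls) != length(truth))
    stop("'calls' and 'truth' have different lengths (",
         length(calls), " vs ", length(truth), ")")
  tp <- sum(calls & truth)
  fp <- sum(calls & !truth)
  fn <- sum(!calls & truth)
  tn <- sum(!calls & !truth)
  data.frame(FPR = if (fp + tn > 0) 100 * fp / (fp + tn) else 0,
             FNR = if (tp + fn > 0) 100 * fn / (tp + fn) else 0,
             total_calls = 100 * (tp + fp) / length(truth),
             TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Replicated FPR/FNR simulation benchmark
#'
#' Runs the full benchmark grid: for every combination of `theta` and
#' `pos_fraction`, `n_reps` datasets are simulated (each replicate with
#' its own derived seed) and every requested method is fitted to the
#' same matrix; calls use raw p-values at each `alpha`. Rates are
#' averaged over replicates with Monte-Carlo standard errors.
#'
#' @param config A [sim_config()] providing probe/sample counts, `k`,
#'   the baseline distribution and the default replicate count. Its
#'   `theta`/`pos_fraction` are overridden by the grid arguments.
#' @param thetas,pos_fractions Numeric vectors defining the grid
#'   (use `thetas = 0, pos_fractions = 0` for a pure null cell).
#' @param alphas Significance level(s) applied to the raw p-values.
#' @param methods Character subset of `c("sfc", "ttest", "modt")`
#'   (`"welch"` is also accepted).
#' @param n_reps Replicates per grid cell; defaults to `config$n_reps`.
#' @param seed Master integer seed; replicate r of grid cell c uses seed
#'   `seed + 1000 * (c - 1) + r - 1`, so the study is reproducible and
#'   replicates are distinct.
#' @param bin_size,calibration Passed to [sfc()].
#'
#' @return A data frame of class `"sim_study"`, one row per
#'   method x theta x pos_fraction x alpha, with mean `FPR`, `FNR`,
#'   `total_calls` (percent), their standard errors and `n_reps`. The
#'   per-replicate table is attached as `attr(, "replicates")`.
#' @examples
#' study <- run_simulation_study(sim_config(n_probes = 300, n_reps = 2),
#'                               thetas = 0.5, pos_fractions = 0.1,
#'                               methods = "sfc", bin_size = 100, seed = 1)
#' study
#' @export
run_simulation_study <- function(config = sim_config(),
                                 thetas = c(0.1, 0.25, 0.5),
                                 pos_fractions = c(0.01, 0.05, 0.1),
                                 alphas = 0.05,
                                 methods = c("sfc", "ttest", "modt"),
                                 n_reps = config$n_reps, seed = 1,
                                 bin_size = 1000, calibration = 0.455) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  seed <- as.integer(seed)
  grid <- expand.grid(theta = thetas, pos_fraction = pos_fractions,
                      KEEP.OUT.ATTRS = FALSE)
  reps <- vector("list", nrow(grid) * n_reps * length(methods) * length(alphas))
  ri <- 0L
  for (cell in seq_len(nrow(grid))) {
    cfg <- config
    cfg$theta <- grid$theta[cell]
    cfg$pos_fraction <- grid$pos_fraction[cell]
    for (r in seq_len(n_reps)) {
      rep_seed <- seed + 1000L * (cell - 1L) + r - 1L
      sim <- simulate_expression(cfg, seed = rep_seed)
      for (method in methods) {
        fit <- fit_method(method, sim$matrix, p_adjust = "none",
                          bin_size = bin_size, calibration = calibration)
        for (alpha in alphas) {
          rates <- evaluate_calls(fit, sim$truth, alpha = alpha)
          ri <- ri + 1L
          reps[[ri]] <- cbind(data.frame(method = method,
                                         theta = cfg$theta,
                                         pos_fraction = cfg$pos_fraction,
                                         alpha = alpha, rep = r,
                                         seed = rep_seed), rates)
        }
      }
    }
  }
  reps <- do.call(rbind, reps)
  key <- interaction(reps$method, reps$theta, reps$pos_fraction, reps$alpha,
                     drop = TRUE)
  agg <- function(v, f) as.vector(tapply(v, key, f))
  se <- function(v) stats::sd(v) / sqrt(length(v))
  first <- !duplicated(key)
  out <- data.frame(method = reps$method[first],
                    theta = reps$theta[first],
                    pos_fraction = reps$pos_fraction[first],
                    alpha = reps$alpha[first])
  o <- order(match(out$method, methods), out$theta, out$pos_fraction, out$alpha)
  stat_cols <- data.frame(FPR = agg(reps$FPR, mean),
                          FNR = agg(reps$FNR, mean),
                          total_calls = agg(reps$total_calls, mean),
                          se_FPR = agg(reps$FPR, se),
                          se_FNR = agg(reps$FNR, se),
                          se_total_calls = agg(reps$total_calls, se),
                          n_reps = n_reps)
  # tapply orders by the interaction levels; realign to first-occurrence keys
  lev <- levels(key)
  stat_cols <- stat_cols[match(as.character(key[first]), lev), , drop = FALSE]
  out <- cbind(out, stat_cols)[o, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("sim_study", "data.frame"), replicates = reps)
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Simulation benchmark (", max(x$n_reps), " replicates per cell)\n",
      sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
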