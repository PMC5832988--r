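#' Configuration for the synthetic expression benchmark
#'
#' Describes the two-group generative model used throughout the
#' simulation benchmark. Each probe i has a true expression level `x_i`
#' drawn from the baseline distribution and shared between groups;
#' observed values are
#'
#' \deqn{y_{ij}^{ctrl} = x_i + \varepsilon_{ij} \cdot (k x_i) + 1, \qquad
#'       y_{ij}^{case} = (1+\theta_i) x_i +
#'         \varepsilon_{ij} \cdot (k (1+\theta_i) x_i) + 1,}
#'
#' with `eps ~ N(0, 1)` independent per probe and sample. For the
#' fraction `pos_fraction` of probes chosen uniformly at random,
#' `theta_i = theta` (truly differential); for the rest `theta_i = 0`.
#' The noise standard deviation is proportional to the (group-specific)
#' true signal, scaled by the multiplier `k`.
#'
#' @param n_probes Number of probes (default 10000).
#' @param n_case,n_control Samples per group (default 3 and 3, the
#'   typical small-replicate microarray design).
#' @param theta Fractional fold-change effect of truly differential
#'   probes (0 gives a pure null dataset).
#' @param k Noise-scale multiplier (default 1).
#' @param pos_fraction Fraction of probes truly differential (default 0);
#'   the number of true positives is `round(pos_fraction * n_probes)`.
#' @param baseline Baseline distribution of true expression: either a
#'   numeric vector `c(min, max)` for a uniform draw (default
#'   `c(1, 10)`) or a function of `n` returning `n` positive draws.
#' @param n_reps Default replicate count for [run_simulation_study()]
#'   (default 100).
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_probes = 10000, n_case = 3, n_control = 3,
                       theta = 0, k = 1, pos_fraction = 0,
                       baseline = c(1, 10), n_reps = 100) {
  stopifnot(n_probes >= 1, n_case >= 1, n_control >= 1,
            theta >= 0, k >= 0, pos_fraction >= 0, pos_fraction < 1,
            n_reps >= 1)
  if (is.numeric(baseline)) {
    stopifnot(length(baseline) == 2L, baseline[1] <= baseline[2])
  } else if (!is.function(baseline)) {
    stop("'baseline' must be c(min, max) or a function of n")
  }
  structure(list(n_probes = as.integer(n_probes),
                 n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 theta = theta, k = k, pos_fraction = pos_fraction,
                 baseline = baseline, n_reps = as.integer(n_reps)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d probes, %d control vs %d case, ",
                     "theta = %g, k = %g, pos_fraction = %g, n_reps = %d\n"),
              x$n_probes, x$n_control, x$n_case, x$theta, x$k,
              x$pos_fraction, x$n_reps))
  invisible(x)
}

#' Simulate a two-group expression dataset
#'
#' Draws one dataset from the generative model described in
#' [sim_config()] and returns it together with the truth mask of the
#' probes simulated as differential.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; identical `config` and `seed` give
#'   bit-identical data.
#' @return A list of class `"sim_data"` with elements `matrix` (an
#'   [expression_matrix()], control columns first), `truth` (logical
#'   vector, `TRUE` for truly differential probes) and `config`.
#' @examples
#' sim <- simulate_expression(sim_config(n_probes = 100, theta = 0.5,
#'                                       pos_fraction = 0.1), seed = 7)
#' sum(sim$truth)
#' @export
simulate_expression <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_probes
  x <- if (is.function(config$baseline)) config$baseline(n)
       else stats::runif(n, config$baseline[1], config$baseline[2])
  n_pos <- round(config$pos_fraction * n)
  truth <- rep(FALSE, n)
  if (n_pos > 0) truth[sample.int(n, n_pos)] <- TRUE
  theta_i <- ifelse(truth, config$theta, 0)
  draw <- function(mu) mu + stats::rnorm(n) * (config$k * mu) + 1
  ctrl <- matrix(vapply(seq_len(config$n_control), function(j) draw(x),
                        numeric(n)), nrow = n)
  case <- matrix(vapply(seq_len(config$n_case),
                        function(j) draw((1 + theta_i) * x), numeric(n)),
                 nrow = n)
  values <- cbind(ctrl, case)
  dimnames(values) <- list(sprintf("probe%05d", seq_len(n)),
                           c(sprintf("control_%d", seq_len(config$n_control)),
                             sprintf("case_%d", seq_len(config$n_case))))
  m <- expression_matrix(values,
                         rep(c("control", "case"),
                             c(config$n_control, config$n_case)))
  structure(list(matrix = m, truth = truth, config = config),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat("sim_data with", sum(x$truth), "truly differential probe(s)\n")
  print(x$matrix)
  invisible(x)
}
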