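#' sfcde: standardized fold change differential expression
#'
#' Two-group differential expression for probe-level expression matrices
#' built around the standardized fold change (SFC) statistic: the
#' difference of group medians standardized by a robust variance
#' estimated from the squared median differences of probes with similar
#' mean intensity (a rank window). The package also ships self-contained
#' re-implementations of the two classical baselines (per-probe t-test
#' and empirical-Bayes moderated t), a replicated FPR/FNR simulation
#' benchmark, leave-samples-out reproducibility analysis, and the
#' supporting preprocessing (natural-log transform, quantile
#' normalization) and probe-to-gene mapping.
#'
#' Main entry points: [sfc()], [row_ttest()], [moderated_t()] (fitting),
#' [simulate_expression()] and [run_simulation_study()] (benchmark),
#' [reproducibility_matrix()] and [intersect_phases()] (stability),
#' [probes_to_genes()] (gene level). A command-line wrapper lives at
#' `system.file("cli", "sfctools.R", package = "sfcde")`.
#'
#' @keywords internal
"_PACKAGE"
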