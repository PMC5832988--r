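# sfcde — standardized fold change for two-group differential expression

Small-replicate expression experiments (three arrays per condition is
common) make the per-probe t-test unstable: with 2–4 residual degrees of
freedom, a lucky small variance produces a huge statistic, and ranked
gene lists barely agree between repeated designs. `sfcde` implements the
**standardized fold change (SFC)** statistic, which replaces the
per-probe variance with a robust, *intensity-local* estimate pooled from
probes of similar mean signal.

For probe *i* with case median *T<sub>i</sub>* and control median
*C<sub>i</sub>*, probes are ranked by their mean signal over all samples
and

```
           T_i − C_i
SFC_i = ─────────────────,   Var_i = median{ (T_j − C_j)² : j ∈ W_i } / 0.455
          sqrt(Var_i)
```

where the window *W<sub>i</sub>* holds the `b + 1` rank-nearest probes
(default bin size `b = 1000`; windows are shifted, never truncated, at
the ends of the list). Because the median of a χ²₁ variable is ≈ 0.455,
the denominator is a consistent estimator of `Var(T − C)` wherever the
noise scale varies smoothly with intensity, and the statistic is
referred to a standard normal for two-sided p-values (Bonferroni
correction by default).

The package also provides, behind the same result interface:

* `row_ttest()` — per-probe Student/Welch t-test;
* `moderated_t()` — a from-scratch empirical-Bayes moderated t
  (variance shrinkage with digamma/trigamma moment-matched prior);
* `simulate_expression()` / `run_simulation_study()` — a replicated
  FPR/FNR benchmark on a configurable multiplicative-noise generative
  model;
* `reproducibility_matrix()` / `intersect_phases()` — leave-samples-out
  batch stability (top-k overlap or Jaccard) and multi-phase Venn
  reports;
* `read_expression_matrix()`, `log_transform()`, `quantile_normalize()`,
  `probes_to_genes()` — plumbing for real probe-level data.

## Worked example

Simulate a 2000-probe, 3 vs 3 experiment where 10% of probes are raised
by 50% against 5% multiplicative noise, and fit SFC:

```r
library(sfcde)
sim <- simulate_expression(sim_config(n_probes = 2000, theta = 0.5,
                                      pos_fraction = 0.1, k = 0.05), seed = 1)
fit <- sfc(sim$matrix)
summary(fit, n = 5)
#> sfc fit: 2000 probes, 3 control vs 3 case samples
#>   194 significant at alpha = 0.05 (bonferroni correction)
#> Top probes:
#>    probe_id     T      C  diff variance statistic   p_value p_adjusted
#>  probe00340 16.79 10.845 5.948   0.1795     14.04 8.780e-45  1.756e-41
#>  probe01742 16.00 10.373 5.628   0.1795     13.28 2.848e-40  5.695e-37
#>  ...
```

194 probes survive a Bonferroni-corrected 0.05 threshold. Scoring the
calls against the simulation truth, and measuring ranking stability over
the nine 2-of-3 × 2-of-3 sample batches:

```r
evaluate_calls(fit, sim$truth)
#>   FPR FNR total_calls  TP FP   TN FN
#> 1 3.5   0       13.15 200 63 1737  0

mean_overlap(reproducibility_matrix(sim$matrix, "sfc", k = 100))
#> [1] 0.829
```

At raw p < 0.05 SFC finds every one of the 200 truly raised probes
(FNR = 0%) with a false-positive rate of 3.5%, and 83% of its top-100
list is shared between any two batches (the t-test manages roughly a
third of that on the same data).

A command-line wrapper with `run`, `simulate`, `benchmark`, `overlap`
and `intersect` subcommands is installed at
`system.file("cli", "sfctools.R", package = "sfcde")`.

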