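test_that("group medians use the sorted-midpoint convention", {
  v <- matrix(c(4, 4, 4, 1, 2, 9), 1, 6,
              dimnames = list("p1", paste0("s", 1:6)))
  med <- group_medians(expression_matrix(v, rep(c("control", "case"), each = 3)))
  expect_equal(med$T, 2)
  expect_equal(med$C, 4)
  v2 <- matrix(c(2, 8, 1, 3), 1, 4, dimnames = list("p1", paste0("s", 1:4)))
  med2 <- group_medians(expression_matrix(v2, c("control", "control",
                                                "case", "case")))
  expect_equal(med2$T, 2)
  expect_equal(med2$C, 5)
  v3 <- matrix(c(1, 2, 7), 1, 3, dimnames = list("p1", paste0("s", 1:3)))
  med3 <- group_medians(expression_matrix(v3, c("control", "control", "case")))
  expect_equal(med3$T, 7)   # median of a single case sample
})

test_that("probes are ranked ascending by overall mean with stable ties", {
  v <- matrix(c(5, 5, 1, 1, 3, 3), 3, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  m <- expression_matrix(v, c("control", "case"))
  expect_equal(rank_probes_by_mean(m), c(2L, 3L, 1L))
  vt <- matrix(c(2, 2, 2, 2, 1, 1), 3, 2, byrow = TRUE,
               dimnames = list(c("pa", "pb", "pc"), c("s1", "s2")))
  expect_equal(rank_probes_by_mean(expression_matrix(vt, c("control", "case"))),
               c(3L, 1L, 2L))  # tied probes keep input order
  v1 <- matrix(c(1, 2), 1, 2, dimnames = list("p1", c("s1", "s2")))
  expect_equal(rank_probes_by_mean(expression_matrix(v1, c("control", "case"))),
               1L)
})

test_that("window variances follow the shifted-window median rule", {
  # constant differences: median of a constant set
  expect_equal(neighborhood_variance(rep(3, 20), bin_size = 6),
               rep(9 / 0.455, 20))
  # hand-evaluated shifted windows: n = 5, b = 2
  expect_equal(neighborhood_variance(1:5, bin_size = 2),
               c(4, 4, 9, 16, 16) / 0.455)
  # odd b: window of b + 1 probes with the extra neighbour on the high side
  expect_equal(neighborhood_variance(1:3, bin_size = 1),
               c(2.5, 6.5, 6.5) / 0.455)
  # bin size larger than the list is clamped with a warning
  expect_warning(v <- neighborhood_variance(1:4, bin_size = 10), "clamped")
  expect_equal(v, rep(median((1:4)^2) / 0.455, 4))
})

test_that("the 0.455 calibration makes the window median a consistent variance estimator", {
  set.seed(20)
  sigma <- 2
  d <- rnorm(1e5, sd = sigma)
  v <- neighborhood_variance(d, bin_size = 1000)
  expect_equal(mean(v), sigma^2, tolerance = 0.02)
})

test_that("the statistic is diff over the window standard deviation", {
  m <- random_expr(100, seed = 3)
  fit <- sfc(m, bin_size = 20)
  res <- fit$results
  ok <- res$variance > 0
  expect_equal(res$statistic[ok], res$diff[ok] / sqrt(res$variance[ok]))
  expect_true(all(res$variance >= 0))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$p_adjusted >= res$p_value))
  # all-equal differences: statistic = sqrt(0.455) everywhere
  v <- matrix(8, 10, 4, dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  v[, 3:4] <- v[, 3:4] + 2   # constant case-control difference of 2
  v <- v + rep(seq(0, 0.009, length.out = 10), 4)  # distinct means, same diff
  cfit <- sfc(expression_matrix(v, c("control", "control", "case", "case")),
              bin_size = 4)
  expect_equal(cfit$results$statistic, rep(sqrt(0.455), 10), tolerance = 1e-12)
})

test_that("zero-variance windows are handled explicitly", {
  v <- matrix(5, 5, 4, dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
  m <- expression_matrix(v, c("control", "control", "case", "case"))
  fit0 <- sfc(m, bin_size = 4)
  expect_equal(fit0$results$statistic, rep(0, 5))
  expect_equal(fit0$results$p_value, rep(1, 5))
  v2 <- v
  v2[5, 3:4] <- 10           # single probe with a non-zero difference
  m2 <- expression_matrix(v2, c("control", "control", "case", "case"))
  expect_warning(fit1 <- sfc(m2, bin_size = 4), "zero window variance")
  expect_equal(fit1$results$statistic[5], Inf)
  expect_equal(fit1$results$p_value[5], 0)
})

test_that("p-values come from a two-sided standard normal reference", {
  m <- random_expr(50, seed = 9)
  fit <- sfc(m, bin_size = 10)
  res <- fit$results
  expect_equal(res$p_value, 2 * pnorm(-abs(res$statistic)))
  expect_equal(2 * pnorm(-abs(1.959964)), 0.05, tolerance = 1e-5)
  expect_equal(2 * pnorm(-abs(-1.2)), 2 * pnorm(-abs(1.2)))
  # bonferroni adjustment multiplies by the probe count and caps at 1
  expect_equal(res$p_adjusted, pmin(1, nrow(res) * res$p_value))
  fit_none <- sfc(m, bin_size = 10, p_adjust = "none")
  expect_equal(fit_none$results$p_adjusted, fit_none$results$p_value)
})

test_that("production SFC agrees with the brute-force oracle", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    b <- sample(1:(n + 2), 1)
    m <- random_expr(n, seed = 100 + i)
    fit <- suppressWarnings(sfc(m, bin_size = b))
    oracle <- suppressWarnings(
      brute_sfc_statistic(m$values, as.character(m$group), b))
    expect_equal(fit$results$statistic, oracle, tolerance = 1e-12)
  }
})

test_that("SFC is invariant to shift, positive scaling and row permutation", {
  m <- random_expr(200, seed = 13)
  base <- sfc(m, bin_size = 50)$results$statistic
  shifted <- m; shifted$values <- shifted$values + 17.3
  expect_equal(sfc(shifted, bin_size = 50)$results$statistic, base,
               tolerance = 1e-9)
  scaled <- m; scaled$values <- scaled$values * 4.2
  expect_equal(sfc(scaled, bin_size = 50)$results$statistic, base,
               tolerance = 1e-9)
  perm <- sample(nrow(m$values))
  mp <- expression_matrix(m$values[perm, ], as.character(m$group))
  expect_equal(sfc(mp, bin_size = 50)$results$statistic, base[perm],
               tolerance = 1e-12)
})

test_that("probe significance maps to gene level by the minimum-p rule", {
  res <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    T = c(2, 2, 1, 5), C = c(1, 1.5, 2, 1),
                    diff = c(1, 0.5, -1, 4), variance = 1,
                    statistic = c(4, 1, -4.5, 6),
                    p_value = c(1e-4, 0.2, 5e-5, 1e-6),
                    p_adjusted = c(0.01, 0.2, 0.005, 1e-4),
                    significant = c(TRUE, FALSE, TRUE, TRUE),
                    stringsAsFactors = FALSE)
  fit <- structure(list(results = res, method = "sfc", alpha = 0.05),
                   class = c("sfc_fit", "de_fit"))
  ann <- data.frame(probe = c("p1", "p2", "p3"),
                    gene = c("G1", "G1", "G2"))
  out <- probes_to_genes(fit, ann)
  g1 <- out$genes[out$genes$gene == "G1", ]
  expect_true(g1$significant)
  expect_equal(g1$p, 0.01)
  expect_equal(g1$direction, "over")
  expect_equal(g1$best_probe, "p1")
  expect_equal(g1$n_probes, 2L)
  g2 <- out$genes[out$genes$gene == "G2", ]
  expect_equal(g2$direction, "under")
  expect_equal(out$unmapped, "p4")       # significant but unannotated
  expect_equal(out$genes$gene, c("G2", "G1"))  # sorted by gene p ascending
  # non-significant genes are reported but not flagged
  ann2 <- data.frame(probe = "p2", gene = "G9")
  out2 <- probes_to_genes(fit, ann2)
  expect_false(out2$genes$significant[out2$genes$gene == "G9"])
  # conflicting directions among significant probes keep the minimum p
  ann3 <- data.frame(probe = c("p1", "p3"), gene = "GX")
  expect_message(out3 <- probes_to_genes(fit, ann3), "conflict")
  expect_equal(out3$genes$direction[out3$genes$gene == "GX"], "under")
})
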