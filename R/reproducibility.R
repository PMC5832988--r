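#' Enumerate leave-samples-out batches
#'
#' All combinations of `per_group` case samples crossed with `per_group`
#' control samples, in deterministic order. With 3 cases and 3 controls
#' and `per_group = 2` this yields the 3 x 3 = 9 batches used for a
#' 9 x 9 reproducibility heatmap.
#'
#' @inheritParams group_medians
#' @param per_group Number of samples kept per group in each batch; must
#'   be smaller than both group sizes.
#' @return List of batches; each batch is a list with `label`, `case`
#'   and `control` (sample identifiers).
#' @export
enumerate_batches <- function(x, per_group, group = NULL) {
  m <- as_expr_mat(x, group)
  case_ids <- colnames(m$values)[m$group == "case"]
  ctrl_ids <- colnames(m$values)[m$group == "control"]
  if (per_group >= length(case_ids) || per_group >= length(ctrl_ids))
    stop("'per_group' must be smaller than both group sizes")
  if (per_group < 1L) stop("'per_group' must be at least 1")
  case_sets <- utils::combn(case_ids, per_group, simplify = FALSE)
  ctrl_sets <- utils::combn(ctrl_ids, per_group, simplify = FALSE)
  batches <- list()
  for (cs in case_sets) for (ts in ctrl_sets) {
    batches[[length(batches) + 1L]] <-
      list(label = paste0(paste(cs, collapse = "+"), "/",
                          paste(ts, collapse = "+")),
           case = cs, control = ts)
  }
  batches
}

#' Fraction of shared identifiers between two top-k lists
#'
#' @param list_a,list_b Character vectors of probe or gene identifiers,
#'   ranked most significant first.
#' @param k List length to compare. When either list is shorter than
#'   `k`, the shorter length is used instead, with a warning.
#' @return `|top_k(A) intersect top_k(B)| / k`, a fraction in `[0, 1]`.
#' @examples
#' topk_overlap(c("a", "b", "c"), c("b", "c", "d"), k = 3)
#' @export
topk_overlap <- function(list_a, list_b, k) {
  stopifnot(k >= 1)
  k_eff <- min(k, length(list_a), length(list_b))
  if (k_eff < k)
    warning("list(s) shorter than k = ", k, "; using k = ", k_eff)
  length(intersect(utils::head(list_a, k_eff),
                   utils::head(list_b, k_eff))) / k_eff
}

#' Ranked identifier list of a fit
#'
#' Probe identifiers sorted by significance: ascending p-value, ties by
#' decreasing absolute statistic, remaining ties by identifier, so the
#' ranking is fully deterministic.
#'
#' @param fit A `de_fit` object.
#' @return Character vector of probe identifiers, most significant first.
#' @export
ranked_ids <- function(fit) {
  stopifnot(inherits(fit, "de_fit"))
  res <- fit$results
  res$probe_id[order(res$p_value, -abs(res$statistic), res$probe_id)]
}

#' Pairwise reproducibility of a method across batches
#'
#' Runs one method independently on every leave-samples-out batch of the
#' matrix and measures how similar the resulting significance lists are
#' between every pair of batches. In `"topk"` mode the similarity is the
#' top-k overlap fraction `|top_k(A) intersect top_k(B)| / k`; in
#' `"threshold"` mode it is the Jaccard index `|A intersect B| /
#' |A union B|` of the sets called significant at `alpha` (raw
#' p-values), which is the natural measure when a significance cutoff
#' rather than a list length is of interest.
#'
#' @inheritParams group_medians
#' @param method One of `"sfc"`, `"ttest"`, `"welch"`, `"modt"`.
#' @param k Top-list length for `"topk"` mode (default 100).
#' @param per_group Samples kept per group in each batch (default one
#'   less than the smaller group).
#' @param mode `"topk"` (default) or `"threshold"`.
#' @param alpha Significance level for `"threshold"` mode.
#' @param bin_size,calibration Passed to [sfc()].
#' @return An object of class `"overlap_mat"`: the square symmetric
#'   matrix of overlap fractions (unit diagonal), with batch labels as
#'   dimnames and attributes `k`, `mode` and `method`.
#' @export
reproducibility_matrix <- function(x, method = "sfc", k = 100,
                                   per_group = NULL, group = NULL,
                                   mode = c("topk", "threshold"),
                                   alpha = 0.05, bin_size = 1000,
                                   calibration = 0.455) {
  m <- as_expr_mat(x, group)
  mode <- match.arg(mode)
  sizes <- tabulate(m$group, 2L)
  if (is.null(per_group)) per_group <- min(sizes) - 1L
  batches <- enumerate_batches(m, per_group)
  lists <- lapply(batches, function(b) {
    keep <- colnames(m$values) %in% c(b$case, b$control)
    sub <- expression_matrix(m$values[, keep, drop = FALSE],
                             as.character(m$group)[keep])
    fit <- fit_method(method, sub, alpha = alpha, p_adjust = "none",
                      bin_size = bin_size, calibration = calibration)
    if (mode == "topk") {
      ranked_ids(fit)
    } else {
      fit$results$probe_id[fit$results$p_value < alpha]
    }
  })
  nb <- length(batches)
  om <- diag(1, nb)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (j <= i) next
    om[i, j] <- om[j, i] <-
      if (mode == "topk") topk_overlap(lists[[i]], lists[[j]], k)
      else jaccard(lists[[i]], lists[[j]])
  }
  dimnames(om) <- list(vapply(batches, `[[`, "", "label"),
                       vapply(batches, `[[`, "", "label"))
  structure(om, k = if (mode == "topk") k else NA_integer_,
            mode = mode, method = method, class = c("overlap_mat", "matrix"))
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)  # two empty significant sets agree trivially
  length(intersect(a, b)) / u
}

#' Mean off-diagonal overlap of a reproducibility matrix
#'
#' @param om An `"overlap_mat"` from [reproducibility_matrix()].
#' @return Mean of the strictly off-diagonal entries.
#' @export
mean_overlap <- function(om) {
  stopifnot(inherits(om, "overlap_mat"))
  mean(om[upper.tri(om)])
}

#' @export
print.overlap_mat <- function(x, ...) {
  cat(sprintf("overlap_mat (%s, %s%s): %d batches, mean off-diagonal %.3f\n",
              attr(x, "method"), attr(x, "mode"),
              if (attr(x, "mode") == "topk")
                sprintf(", k = %d", attr(x, "k")) else "",
              nrow(x), mean_overlap(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' @export
plot.overlap_mat <- function(x, ...) {
  n <- nrow(x)
  graphics::image(seq_len(n), seq_len(n), t(unclass(x))[, n:1],
                  zlim = c(0, 1), axes = FALSE,
                  xlab = "", ylab = "",
                  main = sprintf("%s batch reproducibility",
                                 attr(x, "method")), ...)
  graphics::axis(1, seq_len(n), colnames(x), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(n), rev(rownames(x)), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Multi-phase intersection of significant gene sets
#'
#' Computes every Venn region over two or more named phases of
#' significant genes, plus the membership of the all-phase intersection
#' with each phase's direction annotation.
#'
#' @param phases Named list (length >= 2). Each element is either a
#'   character vector of gene identifiers, a data frame with columns
#'   `gene` and `direction`, or a [probes_to_genes()] result (its
#'   significant genes are used).
#' @return An object of class `"phase_intersection"`: a list with
#'   * `regions`: data frame of all non-empty-pattern Venn regions
#'     (membership pattern, count);
#'   * `core`: data frame of genes present in every phase, with one
#'     direction column per phase (when directions were supplied);
#'   * `per_phase`: counts of genes and over/under directions per phase.
#' @examples
#' intersect_phases(list(p1 = c("A", "B", "C"), p2 = c("B", "C", "D"),
#'                       p3 = c("C", "E")))
#' @export
intersect_phases <- function(phases) {
  if (length(phases) < 2L) stop("need at least 2 phases")
  if (is.null(names(phases)) || any(names(phases) == ""))
    names(phases) <- paste0("phase", seq_along(phases))
  norm <- lapply(phases, function(p) {
    if (inherits(p, "gene_results"))
      p <- p$genes[p$genes$significant, c("gene", "direction"), drop = FALSE]
    if (is.character(p))
      p <- data.frame(gene = p, direction = rep(NA_character_, length(p)),
                      stringsAsFactors = FALSE)
    stopifnot(is.data.frame(p), "gene" %in% names(p))
    if (!"direction" %in% names(p)) p$direction <- NA_character_
    p[!duplicated(p$gene), c("gene", "direction"), drop = FALSE]
  })
  all_genes <- unique(unlist(lapply(norm, `[[`, "gene")))
  member <- vapply(norm, function(p) all_genes %in% p$gene,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes),
                   dimnames = list(all_genes, names(norm)))
  pattern <- apply(member, 1L, function(z) paste(ifelse(z, "1", "0"),
                                                 collapse = ""))
  regions <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(regions) <- c("pattern", "count")
  core_genes <- all_genes[rowSums(member) == length(norm)]
  core <- data.frame(gene = core_genes, stringsAsFactors = FALSE)
  for (nm in names(norm))
    core[[paste0("direction_", nm)]] <-
      norm[[nm]]$direction[match(core_genes, norm[[nm]]$gene)]
  per_phase <- do.call(rbind, lapply(names(norm), function(nm) {
    p <- norm[[nm]]
    data.frame(phase = nm, n = nrow(p),
               over = sum(p$direction == "over", na.rm = TRUE),
               under = sum(p$direction == "under", na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  structure(list(regions = regions, core = core, per_phase = per_phase,
                 n_union = length(all_genes)),
            class = "phase_intersection")
}

#' @export
print.phase_intersection <- function(x, ...) {
  cat(sprintf("phase_intersection: %d phases, union %d genes, core %d\n",
              nrow(x$per_phase), x$n_union, nrow(x$core)))
  print(x$per_phase, row.names = FALSE)
  cat("Venn regions (membership pattern in phase order):\n")
  print(x$regions, row.names = FALSE)
  invisible(x)
}
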