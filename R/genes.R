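#' Convert probe-level significance to gene level
#'
#' Maps a fitted probe-level result to gene-level calls through a
#' probe-to-gene annotation table. A gene is significant when at least
#' one of its probes is; the gene p-value is the minimum adjusted probe
#' p-value, and the gene's direction (over/under expressed) is the sign
#' of the median difference of that minimum-p probe.
#'
#' @param fit A `de_fit` object (from [sfc()], [row_ttest()] or
#'   [moderated_t()]).
#' @param annotation Two-column data frame (probe identifier, gene
#'   symbol) or path to a headerless two-column TSV. Probes may repeat
#'   across genes; probes without an annotation row are allowed.
#' @param alpha Significance level; defaults to the one stored in `fit`.
#'
#' @return An object of class `"gene_results"`: a list with
#'   * `genes`: data frame sorted by gene p-value ascending, columns
#'     `gene`, `p`, `direction` (`"over"`/`"under"`), `n_probes`,
#'     `n_significant`, `best_probe`, `significant`;
#'   * `unmapped`: identifiers of significant probes with no annotation
#'     entry.
#'
#' Genes whose significant probes disagree in direction keep the
#' direction of the minimum-p probe; a message reports the conflicts.
#' @export
probes_to_genes <- function(fit, annotation, alpha = fit$alpha) {
  stopifnot(inherits(fit, "de_fit"))
  ann <- read_annotation(annotation)
  res <- fit$results
  sig_probes <- res$probe_id[res$p_adjusted < alpha]
  unmapped <- setdiff(sig_probes, ann$probe_id)
  ann <- ann[ann$probe_id %in% res$probe_id, , drop = FALSE]
  idx <- match(ann$probe_id, res$probe_id)
  tab <- data.frame(gene = ann$gene,
                    probe_id = ann$probe_id,
                    p = res$p_adjusted[idx],
                    diff = res$diff[idx],
                    sig = res$p_adjusted[idx] < alpha,
                    stringsAsFactors = FALSE)
  split_tab <- split(tab, tab$gene)
  genes <- do.call(rbind, lapply(split_tab, function(g) {
    best <- which.min(g$p)
    data.frame(gene = g$gene[1L],
               p = g$p[best],
               direction = if (g$diff[best] >= 0) "over" else "under",
               n_probes = nrow(g),
               n_significant = sum(g$sig),
               best_probe = g$probe_id[best],
               significant = any(g$sig),
               conflict = length(unique(sign(g$diff[g$sig]))) > 1L,
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$p, genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  n_conflict <- sum(genes$conflict & genes$significant)
  if (n_conflict > 0)
    message(n_conflict, " gene(s) had significant probes with conflicting ",
            "directions; the minimum-p direction was kept")
  genes$conflict <- NULL
  structure(list(genes = genes, unmapped = unmapped, alpha = alpha,
                 method = fit$method),
            class = "gene_results")
}

read_annotation <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- utils::read.table(annotation, sep = "\t", header = FALSE,
                                    colClasses = "character",
                                    stringsAsFactors = FALSE)
  }
  if (!is.data.frame(annotation) || ncol(annotation) < 2L)
    stop("'annotation' must be a two-column table (probe_id, gene)")
  data.frame(probe_id = as.character(annotation[[1L]]),
             gene = as.character(annotation[[2L]]),
             stringsAsFactors = FALSE)
}

#' @export
print.gene_results <- function(x, n = 10L, ...) {
  sig <- x$genes[x$genes$significant, , drop = FALSE]
  cat(sprintf("gene_results (%s): %d genes, %d significant at alpha = %g\n",
              x$method, nrow(x$genes), nrow(sig), x$alpha))
  if (length(x$unmapped))
    cat(sprintf("  %d significant probe(s) without annotation\n",
                length(x$unmapped)))
  if (nrow(sig)) {
    cat("Top significant genes:\n")
    print(utils::head(sig[, c("gene", "p", "direction", "n_probes",
                              "best_probe")], n), row.names = FALSE)
  }
  invisible(x)
}
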