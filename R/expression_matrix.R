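#' Probe-level expression matrix with a two-group design
#'
#' Bundles a probes x samples signal matrix with the case/control
#' assignment of each sample column. This is the input container for all
#' fitting functions in the package ([sfc()], [row_ttest()],
#' [moderated_t()]) and for the preprocessing steps ([log_transform()],
#' [quantile_normalize()]).
#'
#' @param values Numeric matrix, probes in rows and samples in columns.
#'   Row names are taken as probe identifiers and column names as sample
#'   identifiers unless given explicitly.
#' @param group Character or factor of length `ncol(values)` with values
#'   `"case"` or `"control"`, giving the group of each sample column.
#' @param probe_ids,sample_ids Optional identifier vectors overriding the
#'   dimnames of `values`.
#'
#' @return An object of class `"expr_mat"`: a list with elements
#'   `values` (the numeric matrix, dimnames set) and `group` (a factor
#'   with levels `control`, `case` aligned to the columns).
#'
#' @details Probe identifiers must be unique; each group must contain at
#'   least one sample. The two-sample fitting functions additionally
#'   require two samples per group ([sfc()] itself tolerates one, since
#'   a median is defined for a single value).
#'
#' @examples
#' m <- expression_matrix(matrix(rnorm(20), 5, 4,
#'                               dimnames = list(paste0("p", 1:5), paste0("s", 1:4))),
#'                        group = c("control", "control", "case", "case"))
#' m
#' @export
expression_matrix <- function(values, group,
                              probe_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(probe_ids)) probe_ids <- paste0("probe", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(values)))
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values))
    stop("number of probe_ids must equal the number of rows")
  if (length(sample_ids) != ncol(values))
    stop("number of sample_ids must equal the number of columns")
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup))
    stop("duplicate probe identifier(s): ", paste(unique(dup), collapse = ", "))
  if (length(group) != ncol(values))
    stop("'group' must have one entry per sample column")
  group <- as.character(group)
  bad <- setdiff(unique(group), c("case", "control"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected 'case' or 'control')")
  group <- factor(group, levels = c("control", "case"))
  if (any(tabulate(group, 2L) < 1L))
    stop("each of 'case' and 'control' needs at least one sample")
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(values = values, group = group), class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  n <- tabulate(x$group, 2L)
  cat(sprintf("expr_mat: %d probes x %d samples (%d control, %d case)\n",
              nrow(x$values), ncol(x$values), n[1], n[2]))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @export
as.matrix.expr_mat <- function(x, ...) x$values

# Coerce matrix + group to expr_mat; pass an expr_mat through unchanged.
as_expr_mat <- function(x, group = NULL) {
  if (inherits(x, "expr_mat")) return(x)
  if (is.null(group))
    stop("'group' is required when 'x' is a plain matrix")
  expression_matrix(as.matrix(x), group)
}

#' Read a delimited expression matrix with a two-group design
#'
#' Reads a delimited text table (first column probe identifiers, header
#' row sample identifiers) and restricts it to the samples named in the
#' design, preserving the row order of the file. Parsing is strict: any
#' cell that does not parse as a number is an error that names its
#' position.
#'
#' @param path Path to a TSV/CSV file. The separator is inferred from the
#'   file extension (`.csv` gives comma, anything else tab) unless `sep`
#'   is supplied.
#' @param design The sample-to-group assignment: either a named character
#'   vector (names are sample identifiers, values `"case"`/`"control"`),
#'   a two-column data frame (sample identifier, group), or the path to a
#'   two-column delimited file of the same shape with no header.
#' @param sep Field separator; overrides extension-based inference.
#'
#' @return An [expression_matrix()] restricted to the designed samples,
#'   columns in design order.
#' @export
read_expression_matrix <- function(path, design, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs a probe-id column plus sample columns")
  probe_ids <- raw[[1L]]
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup))
    stop("duplicate probe identifier(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  design <- normalize_design(design, sep = sep)
  missing <- setdiff(names(design), colnames(raw)[-1L])
  if (length(missing))
    stop("sample(s) named in the design but absent from the file header: ",
         paste(missing, collapse = ", "))
  cells <- as.matrix(raw[, names(design), drop = FALSE])
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(values) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at row %d (probe '%s'), column '%s'",
                 cells[bad[1L, , drop = FALSE]], bad[1L, 1L],
                 probe_ids[bad[1L, 1L]], names(design)[bad[1L, 2L]]))
  dimnames(values) <- list(probe_ids, names(design))
  expression_matrix(values, unname(design))
}

normalize_design <- function(design, sep = "\t") {
  if (is.character(design) && length(design) == 1L && file.exists(design)) {
    tab <- utils::read.table(design, sep = sep, header = FALSE,
                             colClasses = "character", stringsAsFactors = FALSE)
    design <- stats::setNames(tab[[2L]], tab[[1L]])
  } else if (is.data.frame(design)) {
    design <- stats::setNames(as.character(design[[2L]]), as.character(design[[1L]]))
  }
  if (is.null(names(design)) || any(names(design) == ""))
    stop("design must map sample identifiers to groups")
  design
}

#' Write an expression matrix to a delimited file
#'
#' Inverse of [read_expression_matrix()]: probes in rows, first column
#' `probe_id`, one column per sample, full double precision.
#'
#' @param m An [expression_matrix()].
#' @param path Output path; `.csv` selects comma separation, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "expr_mat"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(probe_id = rownames(m$values),
                   format(m$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
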