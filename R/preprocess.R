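#' Natural-log transform an expression matrix
#'
#' Replaces every signal by its natural logarithm. Raw microarray
#' intensities are strictly positive, so a non-positive value indicates a
#' data problem: by default it is an error reporting how many cells are
#' affected. An opt-in floor policy instead raises all values below a
#' small positive floor to that floor (with a warning) before logging.
#'
#' @param m An [expression_matrix()].
#' @param floor `NULL` (default, hard error on values <= 0) or a small
#'   positive number; values below it are replaced by it.
#' @return The transformed `expr_mat`; shape and metadata unchanged.
#' @export
log_transform <- function(m, floor = NULL) {
  stopifnot(inherits(m, "expr_mat"))
  v <- m$values
  n_bad <- sum(v <= 0)
  if (is.null(floor)) {
    if (n_bad > 0)
      stop(n_bad, " value(s) <= 0 cannot be log-transformed ",
           "(policy 'error'; pass a positive 'floor' to clamp instead)")
  } else {
    stopifnot(is.numeric(floor), length(floor) == 1L, floor > 0)
    n_floored <- sum(v < floor)
    if (n_floored > 0)
      warning(n_floored, " value(s) below the floor ", floor, " were clamped")
    v <- pmax(v, floor)
  }
  m$values <- log(v)
  m
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to share one empirical distribution: the
#' value of rank r in each column is replaced by the mean across columns
#' of the rank-r order statistics. Tied values within a column all
#' receive the mean of the reference values over their tied ranks, so the
#' result is deterministic and independent of input order.
#'
#' After normalization every column is a permutation of the common
#' reference vector (exactly so in the absence of ties), and the
#' operation is idempotent.
#'
#' @param m An [expression_matrix()] (or plain numeric matrix) with no
#'   missing values.
#' @return Object of the same type with normalized values.
#' @export
quantile_normalize <- function(m) {
  v <- if (inherits(m, "expr_mat")) m$values else as.matrix(m)
  if (anyNA(v)) stop("missing values are not allowed in quantile normalization")
  sorted <- apply(v, 2L, sort.int, method = "quick")
  ref <- rowMeans(sorted)
  out <- apply(v, 2L, function(x) {
    res <- numeric(length(x))
    res[order(x)] <- ref
    # ties: every member of a tie group gets the mean reference value
    # over the ranks the group occupies
    stats::ave(res, match(x, x), FUN = mean)
  })
  dimnames(out) <- dimnames(v)
  if (inherits(m, "expr_mat")) {
    m$values <- out
    m
  } else out
}
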