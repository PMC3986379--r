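#' Quantile normalization
#'
#' Forces every sample (column) onto the same empirical distribution: after
#' normalization the sorted values of each column equal the row-wise means of
#' the column-sorted matrix, while each column's rank order is preserved.
#' Ties within a column receive the mean of the target quantile values for
#' their tied ranks (the RMA-style convention), which makes the transform
#' deterministic and idempotent.
#'
#' @param X an [expression_matrix()] with >= 2 samples. A single-sample
#'   matrix is returned unchanged with a warning.
#' @return An [expression_matrix()] with `normalized = TRUE`.
#' @export
quantile_normalize <- function(X) {
  stopifnot(inherits(X, "expr_mat"))
  if (ncol(X$values) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged")
    return(X)
  }
  out <- limma::normalizeQuantiles(X$values, ties = TRUE)
  dimnames(out) <- dimnames(X$values)
  expression_matrix(pmax(out, if (X$scale == "linear") 0 else -Inf),
                    scale = X$scale, normalized = TRUE)
}

#' Log2 transform and its inverse
#'
#' `to_log2()` maps linear-scale values x to `log2(x + pseudocount)`;
#' `from_log2()` inverts it. With `pseudocount = NULL` (the default) a
#' pseudocount of 1 is used when the matrix contains zeros and 0 otherwise,
#' so strictly positive data round-trips exactly. The pseudocount actually
#' applied is stored on the result and used by `from_log2()` unless
#' overridden.
#'
#' @param X an [expression_matrix()] on the expected input scale (checked
#'   against the scale flag; a mismatch is an error, never a silent guess).
#' @param pseudocount value added before taking logs (and subtracted after
#'   exponentiating). `NULL` = automatic, see above.
#' @return An [expression_matrix()] on the other scale.
#' @export
to_log2 <- function(X, pseudocount = NULL) {
  stopifnot(inherits(X, "expr_mat"))
  if (X$scale != "linear") {
    stop("to_log2() expects a linear-scale matrix (scale flag is '",
         X$scale, "')", call. = FALSE)
  }
  if (is.null(pseudocount)) {
    pseudocount <- if (any(X$values == 0)) 1 else 0
  }
  if (any(X$values + pseudocount <= 0)) {
    stop("values + pseudocount must be strictly positive", call. = FALSE)
  }
  out <- expression_matrix(log2(X$values + pseudocount), scale = "log2",
                           normalized = X$normalized)
  out$pseudocount <- pseudocount
  out
}

#' @rdname to_log2
#' @export
from_log2 <- function(X, pseudocount = NULL) {
  stopifnot(inherits(X, "expr_mat"))
  if (X$scale != "log2") {
    stop("from_log2() expects a log2-scale matrix (scale flag is '",
         X$scale, "')", call. = FALSE)
  }
  if (is.null(pseudocount)) {
    pseudocount <- if (is.null(X$pseudocount)) 0 else X$pseudocount
  }
  vals <- 2^X$values - pseudocount
  # guard against roundoff pushing an exact zero a hair negative
  vals[vals < 0 & vals > -1e-9] <- 0
  expression_matrix(vals, scale = "linear", normalized = X$normalized)
}
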