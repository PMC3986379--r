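#' Expression matrix container
#'
#' A lightweight wrapper around a numeric features x samples matrix that
#' carries its measurement scale (`"linear"` or `"log2"`) and whether it has
#' been quantile normalized. Most functions in the package check these flags
#' rather than guessing: the mixing model is linear in linear-scale units,
#' while basis construction and reverse deconvolution default to
#' quantile-normalized log2 data.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param scale measurement scale of `values`.
#' @param normalized has the matrix been quantile normalized?
#' @return An `expr_mat` object.
#' @examples
#' X <- expression_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("g", 1:3), c("s1", "s2"))))
#' X
#' @export
expression_matrix <- function(values, scale = c("linear", "log2"),
                              normalized = FALSE) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and sample colnames", call. = FALSE)
  }
  check_unique_ids(rownames(values), "feature")
  check_unique_ids(colnames(values), "sample")
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale expression values must be >= 0", call. = FALSE)
  }
  structure(
    list(values = values, scale = scale, normalized = isTRUE(normalized)),
    class = "expr_mat"
  )
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf(
    "<expr_mat> %d features x %d samples [%s%s]\n",
    nrow(x$values), ncol(x$values), x$scale,
    if (x$normalized) ", quantile-normalized" else ""
  ))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x an `expr_mat`.
#' @param ... unused.
#' @method as_tibble expr_mat
#' @export
as_tibble.expr_mat <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "feature_id")
}

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) {
  if (inherits(x, "comp_mat")) rownames(x$weights) else colnames(x$values)
}

#' Cell-type composition matrix
#'
#' Samples x cell types matrix of proportions on the probability simplex:
#' every weight is non-negative (tolerance 1e-8) and each row sums to one
#' (tolerance 1e-6).
#'
#' @param weights numeric matrix, samples in rows (rownames = sample ids),
#'   cell types in columns (colnames = cell-type labels).
#' @return A `comp_mat` object.
#' @examples
#' W <- composition_matrix(matrix(c(0.6, 0.4, 0.3, 0.7), 2, 2, byrow = TRUE,
#'   dimnames = list(c("s1", "s2"), c("neutrophil", "lymphocyte"))))
#' @export
composition_matrix <- function(weights) {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights)) || is.null(colnames(weights))) {
    stop("`weights` must have sample rownames and cell-type colnames",
         call. = FALSE)
  }
  check_unique_ids(rownames(weights), "sample")
  check_unique_ids(colnames(weights), "cell type")
  storage.mode(weights) <- "double"
  ok <- stats::complete.cases(weights)
  if (any(weights[ok, ] < -1e-8)) {
    stop("composition weights must be >= 0 (tolerance 1e-8)", call. = FALSE)
  }
  rs <- rowSums(weights[ok, , drop = FALSE])
  if (any(abs(rs - 1) > 1e-6)) {
    stop("composition rows must sum to 1 (tolerance 1e-6)", call. = FALSE)
  }
  structure(list(weights = weights), class = "comp_mat")
}

#' @export
print.comp_mat <- function(x, ...) {
  cat(sprintf("<comp_mat> %d samples x %d cell types\n",
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

#' @rdname composition_matrix
#' @param x a `comp_mat`.
#' @param ... unused.
#' @return `as_tibble()` returns one row per (sample, cell type) with the
#'   proportion, in long form.
#' @method as_tibble comp_mat
#' @export
as_tibble.comp_mat <- function(x, ...) {
  tibble::as_tibble(x$weights, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id",
                        names_to = "cell_type", values_to = "proportion")
}

#' Basis (signature) matrix
#'
#' Marker features x cell types matrix of reference expression, used to infer
#' sample composition. Requires at least two cell types and no all-zero
#' column.
#'
#' @param values numeric matrix, marker features in rows, cell types in
#'   columns, both named.
#' @param scale measurement scale of the reference expression.
#' @return A `basis_mat` object.
#' @export
basis_matrix <- function(values, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and cell-type colnames",
         call. = FALSE)
  }
  check_unique_ids(rownames(values), "feature")
  check_unique_ids(colnames(values), "cell type")
  if (ncol(values) < 2) stop("a basis needs K >= 2 cell types", call. = FALSE)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("basis values must be finite", call. = FALSE)
  if (any(colSums(abs(values)) == 0)) {
    stop("basis must not contain an all-zero cell-type column", call. = FALSE)
  }
  structure(list(values = values, scale = scale), class = "basis_mat")
}

#' @export
print.basis_mat <- function(x, ...) {
  cat(sprintf("<basis_mat> %d marker features x %d cell types [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @rdname basis_matrix
#' @param x a `basis_mat`.
#' @param ... unused.
#' @method as_tibble basis_mat
#' @export
as_tibble.basis_mat <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "feature_id")
}

#' Total leukocyte differential
#'
#' Validates a tibble of measured aggregate blood fractions, one row per
#' sample with columns `sample_id`, `neutrophil`, `lymphocyte`, `monocyte`
#' and `eosinophil`. Each fraction must lie in [0, 1] and each row must sum
#' to at most 1 (tolerance 1e-6); the four compartments need not be
#' exhaustive (basophils and debris are unmeasured).
#'
#' @param x data frame with the columns above.
#' @return A validated tibble (class unchanged).
#' @export
differential <- function(x) {
  cols <- c("neutrophil", "lymphocyte", "monocyte", "eosinophil")
  x <- tibble::as_tibble(x)
  missing <- setdiff(c("sample_id", cols), names(x))
  if (length(missing) > 0) {
    stop("differential is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_unique_ids(x$sample_id, "sample")
  vals <- as.matrix(x[cols])
  if (any(vals < 0) || any(vals > 1)) {
    stop("differential fractions must lie in [0, 1]", call. = FALSE)
  }
  bad <- which(rowSums(vals) > 1 + 1e-6)
  if (length(bad) > 0) {
    stop("differential rows sum to > 1 for samples: ",
         paste(x$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  x
}

#' Two-group sample design
#'
#' @param sample_id character vector of sample ids, or a data frame with
#'   columns `sample_id` and `group`.
#' @param group group label per sample; exactly two distinct labels, each
#'   non-empty. The first level (alphabetical unless `group` is a factor) is
#'   treated as the case group in contrasts.
#' @return A tibble with columns `sample_id` and `group` (factor, 2 levels).
#' @export
group_design <- function(sample_id, group = NULL) {
  if (is.data.frame(sample_id)) {
    df <- sample_id
    if (!all(c("sample_id", "group") %in% names(df))) {
      stop("design data frame needs columns `sample_id` and `group`",
           call. = FALSE)
    }
    sample_id <- df$sample_id
    group <- df$group
  }
  check_unique_ids(sample_id, "sample")
  if (length(group) != length(sample_id)) {
    stop("`sample_id` and `group` lengths differ", call. = FALSE)
  }
  group <- as.factor(group)
  group <- droplevels(group)
  if (nlevels(group) != 2) {
    stop("design must have exactly two distinct group labels, got ",
         nlevels(group), call. = FALSE)
  }
  tibble::tibble(sample_id = as.character(sample_id), group = group)
}

check_unique_ids <- function(ids, what) {
  if (anyNA(ids)) stop(what, " ids must not be NA", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate ", what, " ids: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  invisible(ids)
}

#' The four lymphocyte sub-populations summed into the aggregate
#' "lymphocyte" compartment of a total leukocyte differential.
#' @keywords internal
#' @noRd
LYMPHOCYTE_SUBTYPES <- c("B", "CD4T", "CD8T", "NK")
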