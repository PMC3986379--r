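# Tab-separated interchange formats: UTF-8, '.' decimal separator, header
# row of sample/cell-type ids, first column of feature/sample ids.

read_tsv_matrix <- function(path, what) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("ragged or empty ", what, " file: ", path, call. = FALSE)
  ids <- as.character(df[[1]])
  check_unique_ids(ids, paste(what, "row"))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric values in ", what, " file, column '",
         names(df)[-1][bad], "'", call. = FALSE)
  }
  rownames(m) <- ids
  m
}

format_num <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "g")
}

write_tsv_matrix <- function(m, path, id_col, digits = 6) {
  df <- data.frame(rownames(m), format_num(m, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write expression matrices as TSV
#'
#' First column = feature ids, header row = sample ids; values written with
#' 6 significant digits by default, so a round trip is identical within
#' numeric formatting.
#'
#' @param path file path.
#' @param scale,normalized scale/normalization provenance flags to attach
#'   on read (the TSV itself is unannotated).
#' @return `read_expression_tsv()`: an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, scale = c("linear", "log2"),
                                normalized = FALSE) {
  scale <- match.arg(scale)
  expression_matrix(read_tsv_matrix(path, "expression"), scale = scale,
                    normalized = normalized)
}

#' @rdname read_expression_tsv
#' @param X an [expression_matrix()].
#' @param digits significant digits written.
#' @export
write_expression_tsv <- function(X, path, digits = 6) {
  stopifnot(inherits(X, "expr_mat"))
  write_tsv_matrix(X$values, path, "feature_id", digits)
}

#' Read and write composition matrices as TSV
#'
#' First column = sample ids, header row = cell-type labels.
#'
#' @param path file path.
#' @return `read_composition_tsv()`: a [composition_matrix()].
#' @export
read_composition_tsv <- function(path) {
  composition_matrix(read_tsv_matrix(path, "composition"))
}

#' @rdname read_composition_tsv
#' @param W a [composition_matrix()] (or a `deconv_result`).
#' @param digits significant digits written; the default 8 keeps re-read
#'   rows on the simplex within the validator's 1e-6 tolerance.
#' @export
write_composition_tsv <- function(W, path, digits = 8) {
  if (inherits(W, "deconv_result")) W <- W$composition
  wm <- if (inherits(W, "comp_mat")) W$weights else as.matrix(W)
  write_tsv_matrix(wm, path, "sample_id", digits)
}

#' Read and write basis matrices as TSV
#' @param path file path.
#' @param scale scale flag to attach on read.
#' @return `read_basis_tsv()`: a [basis_matrix()].
#' @export
read_basis_tsv <- function(path, scale = c("log2", "linear")) {
  basis_matrix(read_tsv_matrix(path, "basis"), scale = match.arg(scale))
}

#' @rdname read_basis_tsv
#' @param H a [basis_matrix()].
#' @param digits significant digits written.
#' @export
write_basis_tsv <- function(H, path, digits = 6) {
  stopifnot(inherits(H, "basis_mat"))
  write_tsv_matrix(H$values, path, "feature_id", digits)
}

#' Read a two-group design TSV
#'
#' Columns `sample_id` and `group`; exactly two distinct groups.
#' @param path file path.
#' @return A [group_design()] tibble.
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  group_design(df)
}

#' @rdname read_design_tsv
#' @param design a [group_design()].
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a total leukocyte differential TSV
#'
#' Columns `sample_id`, `neutrophil`, `lymphocyte`, `monocyte`,
#' `eosinophil`; fractions validated to [0, 1] with row sums at most 1.
#' @param path file path.
#' @return A validated [differential()] tibble.
#' @export
read_differential_tsv <- function(path) {
  differential(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_differential_tsv
#' @param diff a [differential()] tibble.
#' @param digits significant digits written.
#' @export
write_differential_tsv <- function(diff, path, digits = 6) {
  diff <- differential(diff)
  out <- diff
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_num, digits = digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tissue enrichment-score matrix TSV
#'
#' First column = feature ids, header row = tissue labels; all scores must
#' be finite.
#' @param path file path.
#' @return Numeric matrix (features x tissues) for [build_tissue_sets()]
#'   and [median_enrichment_profile()].
#' @export
read_enrichment_tsv <- function(path) {
  m <- read_tsv_matrix(path, "enrichment")
  if (!all(is.finite(m))) {
    stop("enrichment scores must be finite", call. = FALSE)
  }
  m
}

#' Read a platform id map TSV
#'
#' Two columns mapping discovery-platform ids to target-platform ids.
#' @param path file path.
#' @return Tibble with columns `source_id`, `target_id`.
#' @export
read_platform_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("platform map needs two columns", call. = FALSE)
  names(df)[1:2] <- c("source_id", "target_id")
  check_unique_ids(df$source_id, "source")
  tibble::as_tibble(df[1:2])
}

#' Write a run provenance file
#'
#' Records the package version, timestamp, seed, parameters and input file
#' checksums of a pipeline run as JSON next to its outputs, so every stage
#' can be re-run from its on-disk inputs alone.
#'
#' @param out_dir output directory (created if needed).
#' @param params named list of run parameters (must include any seed used).
#' @param inputs character vector of input file paths to checksum.
#' @return The provenance file path, invisibly.
#' @export
write_provenance <- function(out_dir, params, inputs = character()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checksums <- vapply(inputs, function(p) {
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  }, character(1))
  prov <- list(
    package = "wbdeconv",
    version = as.character(utils::packageVersion("wbdeconv")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    input_checksums = as.list(checksums)
  )
  path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
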