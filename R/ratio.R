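#' Build an up/down ratio signature from cell-type-specific calls
#'
#' Selects, for each named cell type, the `top_n` genes by absolute ranking
#' statistic among its FDR-passing calls in the required direction; the up
#' ids are the union over `up_cell_types` and the down ids the union over
#' `down_cell_types`. An optional platform map (discovery id -> target
#' platform id) translates ids; unmapped ids are dropped and counted. A gene
#' landing in both the up and the down union (possible across cell types) is
#' removed from both and reported.
#'
#' @param calls call table from [permutation_fdr()] (`$calls`), with
#'   columns `cell_type`, `gene`, `direction`.
#' @param ranks ranked-statistic tibble from [ranking_statistic()].
#' @param up_cell_types,down_cell_types cell types contributing up- and
#'   down-regulated genes (e.g. up in CD4+ T and NK cells, down in B cells).
#' @param top_n genes taken per cell type (default 20); fewer are used when
#'   fewer calls pass.
#' @param platform_map optional two-column data frame (`source_id`,
#'   `target_id`).
#' @return A `ratio_signature`: list with `up_ids`, `down_ids`,
#'   `n_unmapped`, `removed_overlap`.
#' @export
build_ratio_signature <- function(calls, ranks, up_cell_types,
                                  down_cell_types, top_n = 20,
                                  platform_map = NULL) {
  if (inherits(calls, "cs_fdr")) calls <- calls$calls
  calls <- tibble::as_tibble(calls)
  ranks <- tibble::as_tibble(ranks)
  pick <- function(cts, direction) {
    unlist(lapply(cts, function(ct) {
      sub <- calls[calls$cell_type == ct & calls$direction == direction, ]
      if (nrow(sub) == 0) return(character())
      r <- ranks[ranks$cell_type == ct & ranks$gene %in% sub$gene, ]
      r <- r[order(-abs(r$statistic), r$gene), ]
      utils::head(r$gene, top_n)
    }))
  }
  up <- unique(pick(up_cell_types, "up"))
  down <- unique(pick(down_cell_types, "down"))
  n_unmapped <- 0L
  if (!is.null(platform_map)) {
    platform_map <- tibble::as_tibble(platform_map)
    names(platform_map)[1:2] <- c("source_id", "target_id")
    map <- stats::setNames(platform_map$target_id, platform_map$source_id)
    n_unmapped <- sum(!up %in% names(map)) + sum(!down %in% names(map))
    if (n_unmapped > 0) {
      message(n_unmapped, " signature ids absent from the platform map were dropped")
    }
    up <- unname(map[up[up %in% names(map)]])
    down <- unname(map[down[down %in% names(map)]])
  }
  overlap <- intersect(up, down)
  if (length(overlap) > 0) {
    message(length(overlap),
            " genes appeared in both directions and were removed: ",
            paste(overlap, collapse = ", "))
    up <- setdiff(up, overlap)
    down <- setdiff(down, overlap)
  }
  if (length(up) == 0 || length(down) == 0) {
    stop("ratio signature needs non-empty up and down sets (got ",
         length(up), " up, ", length(down), " down)", call. = FALSE)
  }
  structure(
    list(up_ids = up, down_ids = down, n_unmapped = n_unmapped,
         removed_overlap = overlap),
    class = "ratio_signature"
  )
}

#' @export
print.ratio_signature <- function(x, ...) {
  cat(sprintf("<ratio_signature> %d up / %d down genes\n",
              length(x$up_ids), length(x$down_ids)))
  invisible(x)
}

#' Per-sample up/down ratio score
#'
#' Mean linear expression over the signature's up-regulated genes divided by
#' the mean over its down-regulated genes. Because numerator and denominator
#' are convolved by the same sample composition, the ratio is designed to
#' survive convolution in mixed-tissue data and is invariant to global
#' rescaling of the expression matrix. A `log_scale` mode averages log2
#' values and returns their difference instead.
#'
#' @param X [expression_matrix()] on the linear scale (log2 when
#'   `log_scale = TRUE`); must contain every signature gene.
#' @param signature a [build_ratio_signature()] result (or a list with
#'   `up_ids`/`down_ids`).
#' @param log_scale compute mean(log2 up) - mean(log2 down) instead.
#' @return Tibble with columns `sample_id`, `score`. A zero denominator
#'   yields `NaN` with a warning.
#' @export
ratio_score <- function(X, signature, log_scale = FALSE) {
  stopifnot(inherits(X, "expr_mat"))
  expected <- if (log_scale) "log2" else "linear"
  if (X$scale != expected) {
    stop("ratio_score(log_scale = ", log_scale, ") expects ", expected,
         "-scale expression", call. = FALSE)
  }
  ids <- c(signature$up_ids, signature$down_ids)
  missing <- setdiff(ids, feature_ids(X))
  if (length(missing) > 0) {
    stop("expression matrix lacks signature genes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  up <- colMeans(X$values[signature$up_ids, , drop = FALSE])
  dn <- colMeans(X$values[signature$down_ids, , drop = FALSE])
  score <- if (log_scale) up - dn else up / dn
  if (!log_scale && any(dn == 0)) {
    warning(sum(dn == 0), " samples have zero mean down-gene expression")
    score[dn == 0] <- NaN
  }
  tibble::tibble(sample_id = sample_ids(X), score = unname(score))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration p-value when both groups are small and there are no
#' ties; otherwise the normal approximation with midranks, tie correction
#' and continuity correction.
#'
#' @param values numeric vector, one value per design sample (in design
#'   order, or named by sample id).
#' @param design a [group_design()].
#' @param exact force the exact (`TRUE`) or approximate (`FALSE`) path;
#'   `NULL` (default) uses enumeration when the total sample size is at most
#'   20 and there are no ties.
#' @return The two-sided p-value.
#' @export
ranksum_test <- function(values, design, exact = NULL) {
  design <- group_design(design)
  if (!is.null(names(values))) {
    missing <- setdiff(design$sample_id, names(values))
    if (length(missing) > 0) {
      stop("values missing for samples: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    values <- values[design$sample_id]
  }
  if (length(values) != nrow(design)) {
    stop("need one value per design sample", call. = FALSE)
  }
  g <- design$group
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups need at least one sample", call. = FALSE)
  }
  if (all(values == values[1])) return(1)
  ties <- anyDuplicated(values) > 0
  if (is.null(exact)) exact <- !ties && length(values) <= 20
  if (exact && ties) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
}
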