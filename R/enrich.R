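#' Build tissue-specific gene sets from an enrichment-score matrix
#'
#' Thresholds an enrichment-score matrix (features x tissues, e.g. from a
#' tissue expression compendium) at a pooled percentile: the threshold is the
#' given percentile of all matrix entries taken together (strictly
#' exceeded), and each tissue's set is the features whose score in that
#' tissue exceeds it. A per-tissue thresholding mode is available behind
#' `per_tissue`. Percentiles use linear interpolation between order
#' statistics (quantile type 7), which matters for membership near the
#' threshold.
#'
#' @param E numeric matrix of enrichment scores with feature rownames and
#'   tissue colnames; all values finite.
#' @param percentile percentile threshold in (0, 100); default 99.
#' @param per_tissue compute the threshold within each tissue instead of
#'   pooled across all tissues.
#' @return Named list of character vectors (one set per tissue) — the
#'   gene-set collection format shared with [read_gmt()].
#' @export
build_tissue_sets <- function(E, percentile = 99, per_tissue = FALSE) {
  E <- as.matrix(E)
  if (length(E) == 0) stop("empty enrichment matrix", call. = FALSE)
  if (is.null(rownames(E)) || is.null(colnames(E))) {
    stop("`E` needs feature rownames and tissue colnames", call. = FALSE)
  }
  if (!all(is.finite(E))) stop("enrichment scores must be finite", call. = FALSE)
  sets <- lapply(seq_len(ncol(E)), function(s) {
    thr <- if (per_tissue) {
      stats::quantile(E[, s], percentile / 100, names = FALSE, type = 7)
    } else {
      stats::quantile(as.vector(E), percentile / 100, names = FALSE, type = 7)
    }
    rownames(E)[E[, s] > thr]
  })
  names(sets) <- colnames(E)
  sets
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least the actual overlap between a candidate
#' gene list and a gene set, when `|candidate|` draws are made without
#' replacement from a universe of size N containing `|geneset|` successes.
#' Ids outside the universe are dropped with a warning.
#'
#' @param candidate,geneset,universe character vectors of feature ids.
#' @return The raw upper-tail p-value.
#' @examples
#' # overlap 4 of 4 drawn from a 10-gene universe with a 5-gene set:
#' hypergeometric_overlap(paste0("g", 1:4), paste0("g", 1:5), paste0("g", 1:10))
#' # = choose(5,4)/choose(10,4) ~ 0.0238
#' @export
hypergeometric_overlap <- function(candidate, geneset, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  candidate <- unique(candidate)
  geneset <- unique(geneset)
  out_c <- setdiff(candidate, universe)
  out_g <- setdiff(geneset, universe)
  if (length(out_c) + length(out_g) > 0) {
    warning(length(out_c) + length(out_g),
            " ids outside the universe were dropped")
    candidate <- intersect(candidate, universe)
    geneset <- intersect(geneset, universe)
  }
  N <- length(universe)
  m <- length(geneset)
  k <- length(candidate)
  ov <- length(intersect(candidate, geneset))
  stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment, returned in the input order and capped
#' at 1.
#'
#' @param pvals numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Tissue enrichment of a candidate list across a gene-set collection
#'
#' Runs [hypergeometric_overlap()] of one candidate list against every set
#' of a collection and adjusts across the collection with
#' Benjamini-Hochberg (i.e. within the candidate list, across tissues).
#'
#' @param candidate character vector of feature ids.
#' @param sets named list of gene sets (e.g. from [build_tissue_sets()] or
#'   [read_gmt()]).
#' @param universe the feature universe for the test, e.g. the intersection
#'   of the analysis universe with the enrichment platform.
#' @return Tibble with one row per set: `set`, `overlap`, `set_size`,
#'   `candidate_size`, `universe_size`, `p_value`, `p_adjusted`.
#' @export
enrich_candidate <- function(candidate, sets, universe) {
  universe <- unique(universe)
  cand <- intersect(unique(candidate), universe)
  res <- purrr::imap_dfr(sets, function(members, nm) {
    members <- intersect(unique(members), universe)
    tibble::tibble(
      set = nm,
      overlap = length(intersect(cand, members)),
      set_size = length(members),
      candidate_size = length(cand),
      universe_size = length(universe),
      p_value = hypergeometric_overlap(cand, members, universe)
    )
  })
  res$p_adjusted <- bh_adjust(res$p_value)
  res
}

#' Median enrichment profile of a candidate list
#'
#' Per tissue, the median enrichment score over the candidate features
#' present in the matrix — the summary used to visualize where a
#' cell-type-specific list's expression is concentrated.
#'
#' @param candidate character vector of feature ids; must intersect the
#'   matrix rownames.
#' @param E enrichment-score matrix (features x tissues).
#' @return Tibble with columns `tissue`, `median_score`, `n_features`.
#' @export
median_enrichment_profile <- function(candidate, E) {
  E <- as.matrix(E)
  found <- intersect(unique(candidate), rownames(E))
  if (length(found) == 0) {
    stop("no candidate features present in the enrichment matrix",
         call. = FALSE)
  }
  sub <- E[found, , drop = FALSE]
  tibble::tibble(
    tissue = colnames(E),
    median_score = unname(apply(sub, 2, stats::median)),
    n_features = length(found)
  )
}

#' Read and write GMT gene-set files
#'
#' The standard gene-set exchange format: one set per line, fields separated
#' by tabs — set name, description, then member ids. `read_gmt()` rejects
#' duplicate set names and malformed lines with the offending line number;
#' empty member lists round-trip.
#'
#' @param path file path.
#' @return `read_gmt()`: a named list of character vectors with a
#'   `descriptions` attribute; `write_gmt()`: `path`, invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    # strsplit drops trailing empty fields; pad to tabs + 1
    n_tabs <- lengths(regmatches(lines[i], gregexpr("\t", lines[i], fixed = TRUE)))
    if (length(fields) < n_tabs + 1) {
      fields <- c(fields, rep("", n_tabs + 1 - length(fields)))
    }
    if (length(fields) < 2) {
      stop("malformed GMT line ", i, ": need at least name and description",
           call. = FALSE)
    }
    nm <- fields[1]
    if (nm %in% names(sets)) {
      stop("duplicate set name '", nm, "' at line ", i, call. = FALSE)
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    sets[[nm]] <- members
    desc[nm] <- fields[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled from the `descriptions` attribute, else empty strings).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyNA(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every set needs a name", call. = FALSE)
  }
  check_unique_ids(names(sets), "set")
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    d <- if (nm %in% names(descriptions)) descriptions[[nm]] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
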