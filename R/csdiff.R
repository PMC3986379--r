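#' Cell-type-specific expression fit (forward deconvolution)
#'
#' Within each group separately, regresses each gene's expression across
#' samples on the sample composition without an intercept: the fitted
#' coefficient for cell type k is interpreted as that group's average
#' expression of the gene in cell type k, with the usual least-squares
#' standard error \eqn{\sqrt{\hat\sigma^2_j [(W^T W)^{-1}]_{kk}}}.
#' Expression must be on the linear scale — the mixing model is linear and
#' fitting log-scale data would estimate a different quantity.
#'
#' @param X linear-scale [expression_matrix()].
#' @param W [composition_matrix()], restricted to the cell types retained by
#'   [detectability_filter()]; each group must have more samples than cell
#'   types.
#' @param design a [group_design()]; its first factor level is treated as
#'   the case group unless `case` says otherwise.
#' @param case optional group label to treat as group 1 in contrasts.
#' @param nonneg constrain fitted expression to be non-negative (quadratic
#'   programming per gene; standard errors are then the unconstrained OLS
#'   ones, an approximation). Off by default.
#' @return A `cs_fit` object: per group a K x p coefficient matrix `H_hat`
#'   and standard-error matrix `SE`, plus bookkeeping.
#' @export
cs_fit <- function(X, W, design, case = NULL, nonneg = FALSE) {
  stopifnot(inherits(X, "expr_mat"), inherits(W, "comp_mat"))
  if (X$scale != "linear") {
    stop("cs_fit() expects linear-scale expression (scale flag is '",
         X$scale, "'); see from_log2()", call. = FALSE)
  }
  design <- group_design(design)
  missing <- setdiff(design$sample_id,
                     intersect(sample_ids(X), rownames(W$weights)))
  if (length(missing) > 0) {
    stop("design samples absent from X or W: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(case)) {
    if (!case %in% levels(design$group)) {
      stop("`case` must be one of the design's group labels", call. = FALSE)
    }
    design$group <- stats::relevel(design$group, ref = case)
  }
  groups <- levels(design$group)
  K <- ncol(W$weights)
  sizes <- table(design$group)
  if (any(sizes <= K)) {
    stop("each group needs more samples than cell types (K = ", K, "); got ",
         paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", "),
         call. = FALSE)
  }
  fits <- lapply(groups, function(g) {
    ids <- design$sample_id[design$group == g]
    fit_group(t(X$values[, ids, drop = FALSE]),
              W$weights[ids, , drop = FALSE], nonneg)
  })
  names(fits) <- groups
  structure(
    list(
      groups = groups, case = groups[1],
      cell_types = colnames(W$weights), gene_ids = feature_ids(X),
      n = as.integer(sizes[groups]),
      H_hat = lapply(fits, `[[`, "coef"),
      SE = lapply(fits, `[[`, "se"),
      nonneg = nonneg
    ),
    class = "cs_fit"
  )
}

# One group's fit: Xg is samples x genes, Wg is samples x K.
# Returns K x genes coefficient and SE matrices.
fit_group <- function(Xg, Wg, nonneg = FALSE) {
  K <- ncol(Wg)
  WtW <- crossprod(Wg)
  q <- qr(WtW)
  if (q$rank < K) {
    dep <- colnames(Wg)[q$pivot[(q$rank + 1):K]]
    stop("composition columns are collinear within a group: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  WtW_inv <- chol2inv(chol(WtW))
  B <- WtW_inv %*% crossprod(Wg, Xg) # K x genes
  if (nonneg) {
    Amat <- diag(K)
    for (j in seq_len(ncol(Xg))) {
      if (any(B[, j] < 0)) {
        sol <- quadprog::solve.QP(WtW, crossprod(Wg, Xg[, j]), Amat,
                                  rep(0, K))
        B[, j] <- pmax(sol$solution, 0)
      }
    }
  }
  resid <- Xg - Wg %*% B
  df <- nrow(Wg) - K
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(outer(diag(WtW_inv), sigma2))
  dimnames(B) <- dimnames(se) <- list(colnames(Wg), colnames(Xg))
  list(coef = B, se = se)
}

#' @export
print.cs_fit <- function(x, ...) {
  cat(sprintf(
    "<cs_fit> %d cell types x %d genes; groups %s (n = %d, case) vs %s (n = %d)\n",
    length(x$cell_types), length(x$gene_ids),
    x$groups[1], x$n[1], x$groups[2], x$n[2]
  ))
  invisible(x)
}

#' @describeIn cs_fit Long-form tidy estimates: one row per (group,
#'   cell type, gene) with `estimate` and `std_error`.
#' @param x a `cs_fit`.
#' @param ... unused.
#' @method tidy cs_fit
#' @export
tidy.cs_fit <- function(x, ...) {
  purrr::map_dfr(x$groups, function(g) {
    tibble::as_tibble(x$H_hat[[g]], rownames = "cell_type") |>
      tidyr::pivot_longer(-"cell_type", names_to = "gene",
                          values_to = "estimate") |>
      dplyr::mutate(
        group = g,
        std_error = as.vector(t(x$SE[[g]])),
        .before = 1
      )
  })
}

#' @describeIn cs_fit One-row model summary.
#' @method glance cs_fit
#' @export
glance.cs_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_ids), n_cell_types = length(x$cell_types),
    case_group = x$groups[1], n_case = x$n[1],
    control_group = x$groups[2], n_control = x$n[2],
    nonneg = x$nonneg
  )
}

#' Cell-type-specific group contrast
#'
#' Difference of the group-wise cell-type expression estimates,
#' case minus control (the case group is the design's first factor level or
#' the `case` argument given to [cs_fit()]). Swapping the group labels flips
#' every sign.
#'
#' @param fit a [cs_fit()] result.
#' @return K x p numeric matrix `D` (cell types x genes).
#' @export
cs_contrast <- function(fit) {
  stopifnot(inherits(fit, "cs_fit"))
  fit$H_hat[[fit$groups[1]]] - fit$H_hat[[fit$groups[2]]]
}

#' Signal-to-noise ranking statistic per cell type
#'
#' For each cell type and gene, the group contrast divided by the estimated
#' standard error of the difference (independent groups:
#' \eqn{\sqrt{SE_1^2 + SE_2^2}}), analogous to the signal-to-noise ratio
#' used by ranked-list enrichment tools. Genes are ranked in descending
#' statistic order within each cell type, with ties broken by gene id so the
#' ordering is deterministic. A zero contrast with zero standard error
#' yields 0; a nonzero contrast with zero standard error yields +/-Inf (at
#' the ordering extremes) and is flagged with a warning.
#'
#' @param fit a [cs_fit()] result.
#' @return Tibble with columns `cell_type`, `gene`, `statistic`, `rank`,
#'   complete over the input gene universe for every cell type.
#' @export
ranking_statistic <- function(fit) {
  stopifnot(inherits(fit, "cs_fit"))
  D <- cs_contrast(fit)
  se_diff <- sqrt(fit$SE[[fit$groups[1]]]^2 + fit$SE[[fit$groups[2]]]^2)
  d <- D / se_diff
  d[D == 0 & se_diff == 0] <- 0
  if (any(is.infinite(d))) {
    warning(sum(is.infinite(d)),
            " statistics are infinite (zero standard error)")
  }
  tibble::as_tibble(d, rownames = "cell_type") |>
    tidyr::pivot_longer(-"cell_type", names_to = "gene",
                        values_to = "statistic") |>
    dplyr::arrange(.data$cell_type, dplyr::desc(.data$statistic),
                   .data$gene) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Export a ranked list in .rnk format
#'
#' Two-column tab-separated file (gene id, statistic), descending, no
#' header — the interchange format consumed by pre-ranked gene-set
#' enrichment tools. Values are written with 6 significant digits.
#'
#' @param ranked tibble from [ranking_statistic()] (or any tibble with
#'   `gene` and `statistic` columns; a `cell_type` column with several
#'   levels requires `cell_type` to pick one).
#' @param path output file path.
#' @param cell_type which cell type's list to export.
#' @return `path`, invisibly.
#' @export
export_rnk <- function(ranked, path, cell_type = NULL) {
  df <- tibble::as_tibble(ranked)
  if ("cell_type" %in% names(df)) {
    if (is.null(cell_type)) {
      if (length(unique(df$cell_type)) > 1) {
        stop("`ranked` holds several cell types; pick one via `cell_type`",
             call. = FALSE)
      }
    } else {
      df <- df[df$cell_type == cell_type, , drop = FALSE]
    }
  }
  df <- dplyr::arrange(df, dplyr::desc(.data$statistic), .data$gene)
  lines <- paste(df$gene,
                 formatC(df$statistic, digits = 6, format = "g"),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Permutation estimate of the false discovery rate for cell-type-specific
#' differential expression
#'
#' The observed contrast matrix `D` comes from [cs_fit()]/[cs_contrast()].
#' Group labels are then permuted over samples — each sample keeps its own
#' composition row, so the composition-expression pairing is preserved under
#' the null of no group-specific cell-type expression — and the contrast is
#' recomputed. For the one-tailed "up" hypothesis at cutoff c, the FDR
#' estimate for cell type k is the mean (over permutations) count of
#' \eqn{D^{perm}_{kj} \ge c} divided by the observed count, capped at 1; the
#' "down" direction uses \eqn{\le -c}. Cutoff grids are `n_cutoffs`
#' quantiles of the observed |D| per cell type; curves are monotonized
#' (running minimum along increasing cutoffs) so the FDR never increases as
#' the cutoff grows. Cutoffs with zero observed calls record FDR 0, flagged
#' in the curve table. When the number of distinct group-label assignments
#' is at most 10000 all of them are enumerated; otherwise `n_perm` random
#' permutations are drawn, deterministic given `seed`.
#'
#' Call lists per cell type and direction are formed at `fdr_target` by
#' taking the smallest cutoff whose monotonized FDR is at or below the
#' target and calling every gene beyond it.
#'
#' @inheritParams cs_fit
#' @param n_perm random permutations when enumeration is infeasible.
#' @param n_cutoffs cutoff grid size per cell type.
#' @param fdr_target FDR level for the call lists (default 0.30, the
#'   customary permissive discovery cutoff for this analysis).
#' @param perm_average summarize permutation counts by mean (default) or
#'   median.
#' @param seed integer seed.
#' @return A `cs_fdr` object: `curves` (tibble: direction, cell_type,
#'   cutoff, n_obs, perm_count, fdr_raw, fdr), `calls` (tibble: cell_type,
#'   gene, direction, contrast, fdr), the observed `fit`, and run metadata.
#' @export
permutation_fdr <- function(X, W, design, n_perm = 200, n_cutoffs = 100,
                            fdr_target = 0.30, case = NULL,
                            perm_average = c("mean", "median"),
                            nonneg = FALSE, seed = NULL) {
  perm_average <- match.arg(perm_average)
  design <- group_design(design)
  fit <- cs_fit(X, W, design, case = case, nonneg = nonneg)
  D_obs <- cs_contrast(fit)
  K <- nrow(D_obs)
  cell_types <- rownames(D_obs)
  n <- nrow(design)
  n_case <- sum(design$group == fit$groups[1])

  ## per cell type: ascending cutoff grid from quantiles of |D|
  grids <- lapply(seq_len(K), function(k) {
    sort(unique(stats::quantile(abs(D_obs[k, ]),
                                probs = seq(0, 1, length.out = n_cutoffs),
                                names = FALSE, type = 7)))
  })

  count_ge <- function(v, cuts) {
    s <- sort(v)
    length(v) - findInterval(cuts, s, left.open = TRUE)
  }
  obs_up <- lapply(seq_len(K), function(k) count_ge(D_obs[k, ], grids[[k]]))
  obs_dn <- lapply(seq_len(K), function(k) count_ge(-D_obs[k, ], grids[[k]]))

  ## permutation label assignments
  n_distinct <- choose(n, n_case)
  exhaustive <- is.finite(n_distinct) && n_distinct <= 10000
  perm_labels <- if (exhaustive) {
    combos <- utils::combn(n, n_case, simplify = FALSE)
    lapply(combos, function(idx) {
      g <- rep(fit$groups[2], n)
      g[idx] <- fit$groups[1]
      g
    })
  } else {
    with_seed(seed, {
      lapply(seq_len(n_perm), function(b) sample(as.character(design$group)))
    })
  }

  perm_up <- lapply(seq_len(K), function(k) {
    matrix(0, length(perm_labels), length(grids[[k]]))
  })
  perm_dn <- perm_up
  for (b in seq_along(perm_labels)) {
    des_b <- design
    des_b$group <- factor(perm_labels[[b]], levels = fit$groups)
    fit_b <- cs_fit(X, W, des_b, nonneg = nonneg)
    D_b <- cs_contrast(fit_b)
    for (k in seq_len(K)) {
      perm_up[[k]][b, ] <- count_ge(D_b[k, ], grids[[k]])
      perm_dn[[k]][b, ] <- count_ge(-D_b[k, ], grids[[k]])
    }
  }
  avg <- if (perm_average == "mean") colMeans else
    function(m) apply(m, 2, stats::median)

  build_curve <- function(k, direction) {
    cuts <- grids[[k]]
    n_obs <- if (direction == "up") obs_up[[k]] else obs_dn[[k]]
    pc <- avg(if (direction == "up") perm_up[[k]] else perm_dn[[k]])
    fdr_raw <- ifelse(n_obs == 0, 0, pmin(pc / pmax(n_obs, 1), 1))
    fdr <- cummin(fdr_raw)
    tibble::tibble(
      direction = direction, cell_type = cell_types[k], cutoff = cuts,
      n_obs = n_obs, perm_count = pc, fdr_raw = fdr_raw, fdr = fdr,
      zero_obs = n_obs == 0
    )
  }
  curves <- purrr::map_dfr(seq_len(K), function(k) {
    dplyr::bind_rows(build_curve(k, "up"), build_curve(k, "down"))
  })

  call_rows <- purrr::map_dfr(seq_len(K), function(k) {
    purrr::map_dfr(c("up", "down"), function(direction) {
      cv <- curves[curves$cell_type == cell_types[k] &
                     curves$direction == direction, ]
      ok <- cv$fdr <= fdr_target & cv$n_obs > 0
      if (!any(ok)) return(NULL)
      cut_sel <- min(cv$cutoff[ok])
      fdr_sel <- cv$fdr[ok][which.min(cv$cutoff[ok])]
      d <- D_obs[k, ]
      genes <- if (direction == "up") {
        names(d)[d >= cut_sel]
      } else {
        names(d)[d <= -cut_sel]
      }
      if (length(genes) == 0) return(NULL)
      tibble::tibble(
        cell_type = cell_types[k], gene = genes, direction = direction,
        contrast = unname(d[genes]), cutoff = cut_sel, fdr = fdr_sel
      )
    })
  })
  if (nrow(call_rows) == 0) {
    call_rows <- tibble::tibble(
      cell_type = character(), gene = character(), direction = character(),
      contrast = numeric(), cutoff = numeric(), fdr = numeric()
    )
  }

  structure(
    list(
      curves = curves, calls = call_rows, fit = fit,
      fdr_target = fdr_target,
      n_perm = length(perm_labels), exhaustive = exhaustive, seed = seed
    ),
    class = "cs_fdr"
  )
}

#' @export
print.cs_fdr <- function(x, ...) {
  cat(sprintf(
    "<cs_fdr> %d %s permutations; %d calls at FDR <= %.2f\n",
    x$n_perm, if (x$exhaustive) "exhaustive" else "random",
    nrow(x$calls), x$fdr_target
  ))
  if (nrow(x$calls) > 0) {
    print(dplyr::count(x$calls, .data$cell_type, .data$direction))
  }
  invisible(x)
}

#' @describeIn permutation_fdr Tidy FDR curves.
#' @param x a `cs_fdr`.
#' @param ... unused.
#' @method tidy cs_fdr
#' @export
tidy.cs_fdr <- function(x, ...) x$curves

#' @describeIn permutation_fdr One-row run summary.
#' @method glance cs_fdr
#' @export
glance.cs_fdr <- function(x, ...) {
  tibble::tibble(
    n_perm = x$n_perm, exhaustive = x$exhaustive,
    fdr_target = x$fdr_target, n_calls = nrow(x$calls),
    n_cell_types = length(x$fit$cell_types)
  )
}
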