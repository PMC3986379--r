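#' Reference panel of isolated cell-type expression profiles
#'
#' Replicate arrays of cell types purified from the mixed tissue (for blood:
#' sorted leukocyte sub-populations), used to build the basis matrix.
#'
#' @param values numeric matrix, features x replicate arrays, both named.
#' @param labels cell-type label per array column; K >= 2 distinct types,
#'   each with at least one replicate.
#' @param scale measurement scale; basis construction expects log2.
#' @return A `ref_panel` object.
#' @export
reference_panel <- function(values, labels, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and array colnames", call. = FALSE)
  }
  check_unique_ids(rownames(values), "feature")
  if (length(labels) != ncol(values)) {
    stop("one cell-type label per array column required", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("a reference panel needs K >= 2 cell types", call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(list(values = values, labels = labels, scale = scale),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<ref_panel> %d features, %d arrays, %d cell types [%s]\n",
              nrow(x$values), ncol(x$values), length(tab), x$scale))
  print(tab)
  invisible(x)
}

panel_type_means <- function(panel) {
  types <- unique(panel$labels)
  vapply(types, function(ct) {
    rowMeans(panel$values[, panel$labels == ct, drop = FALSE])
  }, numeric(nrow(panel$values)))
}

#' Fold-change prefilter of basis candidate features
#'
#' For every unordered pair of cell types, features are ranked by the
#' absolute difference of cell-type mean log2 expression (absolute log2 fold
#' change). A feature is eligible for the basis if it ranks in the top
#' `ceiling(top_fraction * p)` of at least one pairwise contrast and is not
#' on the exclusion list. Features tied with the boundary value of a
#' contrast are all included, which keeps the rule deterministic.
#'
#' @param panel a [reference_panel()] on log2 scale.
#' @param top_fraction fraction of features kept per contrast (default 0.05,
#'   i.e. "top 5% in at least one contrast").
#' @param exclude feature ids barred from eligibility (e.g. features absent
#'   from the study that will be deconvolved).
#' @param method rank contrasts by plain fold change (default) or by
#'   limma's moderated t statistic.
#' @return Character vector of eligible feature ids (in panel row order).
#' @export
contrast_prefilter <- function(panel, top_fraction = 0.05,
                               exclude = character(),
                               method = c("fold_change", "moderated_t")) {
  stopifnot(inherits(panel, "ref_panel"))
  method <- match.arg(method)
  if (panel$scale != "log2") {
    stop("contrast prefiltering expects a log2-scale panel", call. = FALSE)
  }
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("`top_fraction` must be in (0, 1]", call. = FALSE)
  }
  genes <- rownames(panel$values)
  p <- length(genes)
  m <- ceiling(top_fraction * p)
  types <- unique(panel$labels)
  pairs <- utils::combn(types, 2, simplify = FALSE)
  stat_for_pair <- function(pair) {
    if (method == "fold_change") {
      means <- panel_type_means(panel)
      abs(means[, pair[1]] - means[, pair[2]])
    } else {
      keep <- panel$labels %in% pair
      grp <- factor(panel$labels[keep], levels = pair)
      des <- stats::model.matrix(~grp)
      fit <- limma::eBayes(limma::lmFit(panel$values[, keep, drop = FALSE], des))
      abs(fit$t[, 2])
    }
  }
  eligible <- rep(FALSE, p)
  for (pair in pairs) {
    s <- stat_for_pair(pair)
    # boundary value of the top-m slice; ties at the boundary all included
    thr <- sort(s, decreasing = TRUE)[m]
    eligible <- eligible | (s >= thr)
  }
  setdiff(genes[eligible], exclude)
}

#' Multinomial elastic-net selection path over the eligible features
#'
#' Frames marker selection as multinomial classification of the panel arrays
#' into their cell types. For each elastic-net mixing parameter `alpha`, a
#' penalized multinomial model is fit over the eligible features
#' (cv.glmnet), the shrinkage parameter lambda is chosen as the largest
#' value whose cross-validated multinomial deviance is within one standard
#' error of the minimum (the 1-SE rule), and the selected feature set is the
#' union of features with a nonzero coefficient in any class at that lambda.
#' Cross-validation folds are stratified by cell type and shrunk to the
#' smallest per-type replicate count when `cv_folds` is infeasible.
#'
#' @param panel a [reference_panel()] (log2 scale).
#' @param eligible feature ids to fit over, typically from
#'   [contrast_prefilter()]; must contain at least K features.
#' @param alpha_grid elastic-net mixing parameters in [0, 1]; 1 = lasso.
#' @param cv_folds requested number of CV folds (default 10).
#' @param exclude feature ids that must never be selected (removed from the
#'   feature space before fitting).
#' @param seed integer seed; fits are deterministic given it.
#' @return Tibble with one row per alpha: `alpha`, `lambda`, `cv_deviance`
#'   (CV multinomial deviance at the chosen lambda), `n_features`, and a
#'   `features` list-column of selected feature ids.
#' @export
fit_selection_path <- function(panel, eligible,
                               alpha_grid = seq(0.1, 1, by = 0.1),
                               cv_folds = 10, exclude = character(),
                               seed = NULL) {
  stopifnot(inherits(panel, "ref_panel"))
  if (length(alpha_grid) == 0 || any(alpha_grid < 0 | alpha_grid > 1)) {
    stop("`alpha_grid` must be non-empty with values in [0, 1]", call. = FALSE)
  }
  eligible <- setdiff(eligible, exclude)
  y <- factor(panel$labels)
  K <- nlevels(y)
  if (length(eligible) < K) {
    stop("need at least K = ", K, " eligible features, got ",
         length(eligible), call. = FALSE)
  }
  x <- t(panel$values[eligible, , drop = FALSE])
  min_class <- min(table(y))
  nfolds <- max(3, min(cv_folds, min_class))
  purrr::map_dfr(seq_along(alpha_grid), function(a_i) {
    alpha <- alpha_grid[a_i]
    with_seed(child_seed(seed, a_i), {
      # stratified folds: cycle fold ids within each class in random order
      foldid <- integer(length(y))
      for (lev in levels(y)) {
        idx <- sample(which(y == lev))
        foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
      }
      cvfit <- glmnet::cv.glmnet(
        x, y, family = "multinomial", alpha = alpha,
        foldid = foldid, type.measure = "deviance"
      )
      i1se <- which(cvfit$lambda == cvfit$lambda.1se)
      cf <- stats::coef(cvfit, s = "lambda.1se")
      sel <- sort(unique(unlist(lapply(cf, function(b) {
        rownames(b)[which(as.matrix(b) != 0)]
      }))))
      sel <- setdiff(sel, "(Intercept)")
      tibble::tibble(
        alpha = alpha, lambda = cvfit$lambda.1se,
        cv_deviance = cvfit$cvm[i1se],
        n_features = length(sel), features = list(sel)
      )
    })
  })
}

#' Build a basis matrix from a reference panel
#'
#' The basis value for feature j in cell type k is the mean over that cell
#' type's replicate arrays, on the panel's scale (log2 by default); rows are
#' ordered by feature id.
#'
#' @param panel a [reference_panel()].
#' @param features non-empty set of feature ids (subset of the panel's).
#' @return A [basis_matrix()] on the panel's scale.
#' @export
build_basis <- function(panel, features) {
  stopifnot(inherits(panel, "ref_panel"))
  features <- unique(as.character(features))
  if (length(features) == 0) stop("empty feature set", call. = FALSE)
  missing <- setdiff(features, rownames(panel$values))
  if (length(missing) > 0) {
    stop("features absent from panel: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  means <- panel_type_means(panel)
  basis_matrix(means[sort(features), , drop = FALSE], scale = panel$scale)
}

#' Condition number of a basis matrix
#'
#' Ratio of the largest to the smallest singular value of the basis values;
#' a large value signals near-collinear cell-type profiles and unstable
#' composition estimates. Rank-deficient bases return `Inf`.
#'
#' @param H a [basis_matrix()].
#' @return A single number >= 1 (possibly `Inf`).
#' @export
condition_number <- function(H) {
  stopifnot(inherits(H, "basis_mat"))
  d <- svd(H$values, nu = 0, nv = 0)$d
  tol <- max(dim(H$values)) * .Machine$double.eps * d[1]
  if (d[length(d)] <= tol) return(Inf)
  d[1] / d[length(d)]
}

#' Evaluate basis candidates against measured leukocyte differentials
#'
#' For each candidate feature set, builds the basis, deconvolves the
#' training mixtures, aggregates the predicted B + CD4+ T + CD8+ T + NK
#' proportions into a lymphocyte fraction, and scores predictions against
#' the measured differential: RMSE and adjusted R-squared per measurable
#' compartment, plus the basis condition number.
#'
#' @param candidates tibble from [fit_selection_path()] (columns `alpha`,
#'   `features`, ...).
#' @param panel the [reference_panel()] the candidates were fit on.
#' @param train_X training mixtures ([expression_matrix()]), same scale as
#'   the panel; all differential samples must be present.
#' @param train_diff measured [differential()] for the training samples.
#' @param lymphocyte_types labels summed into the lymphocyte aggregate.
#' @return `candidates` with added columns `basis` (list), `condition_number`,
#'   `lymphocyte_rmse`, `neutrophil_rmse`, `monocyte_rmse`,
#'   `eosinophil_rmse` and `lymphocyte_r2`.
#' @export
evaluate_candidates <- function(candidates, panel, train_X, train_diff,
                                lymphocyte_types = LYMPHOCYTE_SUBTYPES) {
  stopifnot(inherits(train_X, "expr_mat"))
  train_diff <- differential(train_diff)
  missing <- setdiff(train_diff$sample_id, sample_ids(train_X))
  if (length(missing) > 0) {
    stop("training samples absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  score_one <- function(features) {
    H <- build_basis(panel, features)
    res <- deconvolve(train_X, H)
    W <- res$composition$weights[train_diff$sample_id, , drop = FALSE]
    lym <- rowSums(W[, lymphocyte_types, drop = FALSE])
    per_rmse <- function(col, pred) {
      if (col %in% names(train_diff)) rmse(pred, train_diff[[col]]) else NA_real_
    }
    tibble::tibble(
      basis = list(H),
      condition_number = condition_number(H),
      lymphocyte_rmse = rmse(lym, train_diff$lymphocyte),
      neutrophil_rmse = per_rmse("neutrophil", W[, "neutrophil"]),
      monocyte_rmse = per_rmse("monocyte", W[, "monocyte"]),
      eosinophil_rmse = per_rmse("eosinophil", W[, "eosinophil"]),
      lymphocyte_r2 = adjusted_r2(lym, train_diff$lymphocyte)
    )
  }
  metrics <- purrr::map_dfr(candidates$features, score_one)
  dplyr::bind_cols(candidates, metrics)
}

#' Select the optimal basis candidate
#'
#' Among candidates achieving the minimal lymphocyte RMSE (ties within
#' 1e-9), returns the one with the largest alpha — the sparsest, most
#' penalized model consistent with best lymphocyte prediction. The result is
#' invariant to the ordering of the candidate list.
#'
#' @param candidates evaluated candidate tibble (from
#'   [evaluate_candidates()]), with `lymphocyte_rmse` and `alpha` columns.
#' @return The selected candidate row (one-row tibble).
#' @export
select_basis <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("no candidates to select from", call. = FALSE)
  }
  if (!all(c("alpha", "lymphocyte_rmse") %in% names(candidates))) {
    stop("candidates must be evaluated first (see evaluate_candidates())",
         call. = FALSE)
  }
  best <- min(candidates$lymphocyte_rmse)
  tied <- candidates[candidates$lymphocyte_rmse <= best + 1e-9, , drop = FALSE]
  tied[which.max(tied$alpha), , drop = FALSE]
}
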