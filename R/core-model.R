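#' Forward mixing model: compose mixed expression from known parts
#'
#' Implements the linear mixing model for heterogeneous tissue: the observed
#' expression of gene j in sample i is the composition-weighted sum of the
#' cell-type-specific expression of that gene, plus zero-mean noise,
#' \deqn{x_{ij} = \sum_k w_{ik} h_{kj} + e_{ij}.}
#' Noise is additive Gaussian with standard deviation `noise_sd`, truncated
#' at zero so linear-scale expression stays non-negative. The simulation
#' module offers richer (multiplicative) noise; this forward model is kept
#' minimal and is exactly deterministic at `noise_sd = 0`.
#'
#' @param W a [composition_matrix()] (samples x cell types).
#' @param H a [basis_matrix()] on linear scale (features x cell types);
#'   cell types must match `W` in the same order.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   linear expression units; must be >= 0.
#' @param seed optional integer seed making the noise reproducible.
#' @return An [expression_matrix()] (features x samples, linear scale).
#' @examples
#' H <- basis_matrix(matrix(c(2, 8, 4, 1), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("A", "B"))), scale = "linear")
#' W <- composition_matrix(matrix(c(0.5, 0.5), 1, 2,
#'   dimnames = list("s1", c("A", "B"))))
#' mix(W, H)$values  # g1 = 3, g2 = 4.5
#' @export
mix <- function(W, H, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(W, "comp_mat"), inherits(H, "basis_mat"))
  if (H$scale != "linear") {
    stop("mix() requires a linear-scale basis; see from_log2()", call. = FALSE)
  }
  if (!identical(colnames(W$weights), colnames(H$values))) {
    stop("cell types of W and H differ or are ordered differently: W = [",
         paste(colnames(W$weights), collapse = ", "), "], H = [",
         paste(colnames(H$values), collapse = ", "), "]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  ## features x samples = (features x K) %*% (K x samples)
  X <- H$values %*% t(W$weights)
  if (noise_sd > 0) {
    E <- with_seed(seed, matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X)))
    X <- pmax(X + E, 0)
  }
  expression_matrix(X, scale = "linear")
}

#' Root mean squared error between predicted and measured proportions
#'
#' @param predicted,measured numeric vectors of equal length with values in
#'   [0, 1] (proportion units).
#' @return RMSE, in proportion units.
#' @examples
#' rmse(c(0.6, 0.4), c(0.5, 0.5))  # 0.1
#' @export
rmse <- function(predicted, measured) {
  if (length(predicted) != length(measured) || length(predicted) < 1) {
    stop("`predicted` and `measured` must have equal length >= 1",
         call. = FALSE)
  }
  if (any(predicted < 0 | predicted > 1) || any(measured < 0 | measured > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  sqrt(mean((predicted - measured)^2))
}

#' Adjusted coefficient of determination for composition predictions
#'
#' Ordinary least squares of `measured` on `predicted` (with intercept);
#' returns the adjusted R-squared \eqn{1 - (1 - R^2)(n - 1)/(n - 2)}.
#' Can be negative when the prediction carries no information.
#'
#' @param predicted,measured numeric vectors, length n >= 4.
#' @return Adjusted R-squared (<= 1).
#' @export
adjusted_r2 <- function(predicted, measured) {
  n <- length(predicted)
  if (length(measured) != n || n < 4) {
    stop("need equal-length vectors with n >= 4", call. = FALSE)
  }
  if (stats::var(predicted) == 0) {
    stop("`predicted` has zero variance; adjusted R^2 undefined", call. = FALSE)
  }
  fit <- stats::lm(measured ~ predicted)
  r2 <- summary(fit)$r.squared
  1 - (1 - r2) * (n - 1) / (n - 2)
}
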