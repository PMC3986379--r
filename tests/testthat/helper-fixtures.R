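# Small deterministic fixtures shared across test files.

toy_basis <- function(vals = NULL, scale = "linear") {
  if (is.null(vals)) {
    vals <- matrix(c(10, 1, 2, 1, 8, 3), nrow = 3, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  }
  basis_matrix(vals, scale = scale)
}

toy_composition <- function(w) {
  if (is.null(rownames(w))) rownames(w) <- paste0("s", seq_len(nrow(w)))
  composition_matrix(w)
}

random_composition <- function(n, types, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(stats::rexp(n * length(types)), n)
    w <- g / rowSums(g)
    dimnames(w) <- list(paste0("s", seq_len(n)), types)
    composition_matrix(w)
  })
}

random_expression <- function(p = 10, n = 4, seed = 1, scale = "linear") {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(p * n, 1, 100), p, n,
                dimnames = list(sprintf("g%02d", 1:p), paste0("s", 1:n)))
    expression_matrix(m, scale = scale)
  })
}

# Two-sided exact Wilcoxon rank-sum p-value by complete enumeration of all
# group-label assignments (midranks for ties): the independent oracle for
# ranksum_test().
enum_ranksum_p <- function(x, y) {
  values <- c(x, y)
  n1 <- length(x)
  r <- rank(values)
  obs <- sum(r[seq_len(n1)])
  all_w <- apply(utils::combn(length(values), n1), 2,
                 function(idx) sum(r[idx]))
  p_le <- mean(all_w <= obs)
  p_ge <- mean(all_w >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# Upper-tail hypergeometric p by exhaustive enumeration of every possible
# candidate draw from the universe (N <= 12): the oracle for
# hypergeometric_overlap().
enum_hypergeom_p <- function(universe, geneset, k, observed_overlap) {
  draws <- utils::combn(universe, k, simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, geneset)),
              integer(1)) >= observed_overlap)
}

# Benjamini-Hochberg step-up computed from first principles (independent of
# stats::p.adjust): q_(i) = min over j >= i of p_(j) * m / j, input order.
enum_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}
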