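make_cs_instance <- function(n_per_group = 8, K = 2, p = 6, seed = 1,
                             noise = 0.5) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    types <- LETTERS[seq_len(K)]
    w <- matrix(rexp(n * K), n)
    w <- w / rowSums(w)
    dimnames(w) <- list(paste0("s", seq_len(n)), types)
    H <- matrix(runif(K * p, 10, 100), K, p,
                dimnames = list(types, sprintf("g%02d", seq_len(p))))
    X <- t(w %*% H) + matrix(rnorm(p * n, 0, noise), p, n)
    X <- pmax(X, 0)
    dimnames(X) <- list(rownames(H %*% diag(p))[0] %||% sprintf("g%02d", 1:p),
                        rownames(w))
    dimnames(X) <- list(sprintf("g%02d", seq_len(p)), rownames(w))
    list(
      X = expression_matrix(X),
      W = composition_matrix(w),
      design = group_design(rownames(w),
                            rep(c("g1", "g2"), each = n_per_group)),
      H = H
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cs_fit reduces to group means when K = 1 with unit weights", {
  withr::with_seed(11, {
    n <- 12
    x <- matrix(rnorm(3 * n, mean = 50, sd = 4), 3, n,
                dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:n)))
  })
  X <- expression_matrix(pmax(x, 0))
  W <- composition_matrix(matrix(1, n, 1,
                                 dimnames = list(paste0("s", 1:n), "whole")))
  design <- group_design(paste0("s", 1:n), rep(c("g1", "g2"), each = 6))
  fit <- cs_fit(X, W, design)
  for (g in c("g1", "g2")) {
    ids <- design$sample_id[design$group == g]
    expect_equal(unname(fit$H_hat[[g]]["whole", ]),
                 unname(rowMeans(X$values[, ids])))
    expect_equal(unname(fit$SE[[g]]["whole", ]),
                 unname(apply(X$values[, ids], 1, sd) / sqrt(6)))
  }
  # contrast equals the plain difference of group means, exactly
  D <- cs_contrast(fit)
  mean_diff <- rowMeans(X$values[, design$group == "g1"]) -
    rowMeans(X$values[, design$group == "g2"])
  expect_equal(unname(D["whole", ]), unname(mean_diff), tolerance = 1e-12)
})

test_that("cs_fit recovers noiseless coefficients and matches normal equations", {
  inst <- make_cs_instance(seed = 12, noise = 0)
  fit <- cs_fit(inst$X, inst$W, inst$design)
  for (g in c("g1", "g2")) {
    expect_equal(unname(fit$H_hat[[g]]), unname(inst$H), tolerance = 1e-6)
    expect_lt(max(fit$SE[[g]]), 1e-6)
  }

  # normal-equations oracle over 50 random noisy instances
  for (s in 1:50) {
    inst <- make_cs_instance(n_per_group = 6, K = 3, p = 4, seed = 100 + s,
                             noise = 2)
    fit <- cs_fit(inst$X, inst$W, inst$design)
    for (g in c("g1", "g2")) {
      ids <- inst$design$sample_id[inst$design$group == g]
      Wg <- inst$W$weights[ids, ]
      Xg <- t(inst$X$values[, ids])
      beta <- solve(crossprod(Wg)) %*% t(Wg) %*% Xg
      expect_equal(unname(fit$H_hat[[g]]), unname(beta), tolerance = 1e-8)
      res <- Xg - Wg %*% beta
      sig2 <- colSums(res^2) / (length(ids) - ncol(Wg))
      se <- sqrt(outer(diag(solve(crossprod(Wg))), sig2))
      expect_equal(unname(fit$SE[[g]]), unname(se), tolerance = 1e-8)
    }
  }
})

test_that("cs_fit rejects collinear compositions and undersized groups", {
  inst <- make_cs_instance(seed = 13)
  w <- inst$W$weights
  w_bad <- cbind(w, C = w[, "B"]) / rowSums(cbind(w, w[, "B"]))
  colnames(w_bad) <- c("A", "B", "C")
  expect_error(cs_fit(inst$X, composition_matrix(w_bad), inst$design),
               "collinear")

  small <- group_design(rownames(w)[1:4], c("g1", "g1", "g2", "g2"))
  expect_error(cs_fit(inst$X, inst$W, small), "more samples than cell types")
})

test_that("cs_contrast is antisymmetric under group relabeling", {
  inst <- make_cs_instance(seed = 14)
  fit12 <- cs_fit(inst$X, inst$W, inst$design)
  fit21 <- cs_fit(inst$X, inst$W, inst$design, case = "g2")
  expect_equal(cs_contrast(fit12), -cs_contrast(fit21))

  # toy subtraction oracle
  D <- cs_contrast(fit12)
  expect_equal(D, fit12$H_hat[["g1"]] - fit12$H_hat[["g2"]])
})

test_that("ranking statistic standardizes the contrast per gene", {
  fit <- structure(list(
    groups = c("g1", "g2"), case = "g1", cell_types = "A",
    gene_ids = c("ga", "gb", "gc"), n = c(5L, 5L),
    H_hat = list(g1 = matrix(c(5, 4, 3), 1, dimnames = list("A", c("ga", "gb", "gc"))),
                 g2 = matrix(c(3, 4, 2), 1, dimnames = list("A", c("ga", "gb", "gc")))),
    SE = list(g1 = matrix(1, 1, 3, dimnames = list("A", c("ga", "gb", "gc"))),
              g2 = matrix(1, 1, 3, dimnames = list("A", c("ga", "gb", "gc")))),
    nonneg = FALSE
  ), class = "cs_fit")
  rs <- ranking_statistic(fit)
  expect_equal(rs$statistic[rs$gene == "ga"], 2 / sqrt(2))
  expect_equal(rs$statistic[rs$gene == "gb"], 0)
  # ordering: ga (1.41) > gc (0.71) > gb (0)
  expect_equal(rs$gene[order(rs$rank)], c("ga", "gc", "gb"))

  # zero SE with nonzero difference: infinite, flagged
  fit$SE$g1[1, 1] <- 0
  fit$SE$g2[1, 1] <- 0
  expect_warning(rs2 <- ranking_statistic(fit), "infinite")
  expect_true(is.infinite(rs2$statistic[rs2$gene == "ga"]))
})

test_that("rnk export round-trips with six significant digits", {
  rs <- tibble::tibble(cell_type = "A",
                       gene = c("g1", "g2", "g3"),
                       statistic = c(1.234567891, -0.5, 3.1e-7))
  path <- withr::local_tempfile(fileext = ".rnk")
  export_rnk(rs, path)
  lines <- readLines(path)
  expect_length(lines, 3)
  back <- read.delim(path, header = FALSE)
  expect_equal(back[[1]], c("g1", "g3", "g2")) # descending statistic
  expect_equal(back[[2]], signif(c(1.234567891, 3.1e-7, -0.5), 6),
               tolerance = 1e-6)
})

test_that("permutation FDR curves are valid, monotone and enumeration-aware", {
  sim <- simulate_panel(K = 2, p = 150, markers_per_type = 10, replicates = 2,
                        seed = 81)
  S <- 2^sim$truth$profiles_log2
  mx <- simulate_mixtures(S, n_per_group = 4, dirichlet_alpha = c(3, 3),
                          de_spec = data.frame(cell_type = colnames(S)[1],
                                               n_genes = 15, fold = 4,
                                               direction = "up"),
                          noise_cv = 0.05, seed = 82)
  res <- permutation_fdr(mx$expr, mx$truth$true_W, mx$design,
                         n_perm = 50, n_cutoffs = 40, seed = 83)
  expect_true(res$exhaustive) # choose(8, 4) = 70 <= 10000
  expect_equal(res$n_perm, choose(8, 4))
  cv <- res$curves
  expect_true(all(cv$fdr >= 0 & cv$fdr <= 1))
  by_curve <- split(cv, interaction(cv$cell_type, cv$direction))
  for (b in by_curve) {
    b <- b[order(b$cutoff), ]
    expect_true(all(diff(b$fdr) <= 1e-12)) # non-increasing in cutoff
    expect_true(all(diff(b$n_obs) <= 0)) # calls shrink as cutoff grows
  }
  expect_true(all(cv$fdr_raw[cv$zero_obs] == 0))
})

test_that("swapping group labels maps up-calls onto down-calls exactly", {
  sim <- simulate_panel(K = 2, p = 120, markers_per_type = 8, replicates = 2,
                        seed = 84)
  S <- 2^sim$truth$profiles_log2
  mx <- simulate_mixtures(S, n_per_group = 4, dirichlet_alpha = c(2, 4),
                          de_spec = data.frame(cell_type = colnames(S)[2],
                                               n_genes = 10, fold = 5,
                                               direction = "up"),
                          noise_cv = 0.05, seed = 85)
  res_a <- permutation_fdr(mx$expr, mx$truth$true_W, mx$design,
                           n_perm = 50, seed = 86)
  res_b <- permutation_fdr(mx$expr, mx$truth$true_W, mx$design,
                           n_perm = 50, case = "g2", seed = 86)
  up_a <- sort(res_a$calls$gene[res_a$calls$direction == "up"])
  down_b <- sort(res_b$calls$gene[res_b$calls$direction == "down"])
  expect_identical(up_a, down_b)
  down_a <- sort(res_a$calls$gene[res_a$calls$direction == "down"])
  up_b <- sort(res_b$calls$gene[res_b$calls$direction == "up"])
  expect_identical(down_a, up_b)
})

test_that("granular composition beats the collapsed compartment on spiked data", {
  sim <- simulate_panel(K = 7, p = 800, markers_per_type = 10, replicates = 3,
                        seed = 87)
  S <- 2^sim$truth$profiles_log2
  mx <- simulate_mixtures(S, n_per_group = 16,
                          dirichlet_alpha = blood_dirichlet_alpha(20),
                          de_spec = data.frame(cell_type = "CD4T",
                                               n_genes = 50, fold = 3,
                                               direction = "up"),
                          noise_cv = 0.02, seed = 88)
  sp <- mx$truth$spiked$gene
  res7 <- permutation_fdr(mx$expr, mx$truth$true_W, mx$design,
                          n_perm = 100, case = "g2", seed = 89)
  rec7 <- mean(sp %in% res7$calls$gene[res7$calls$cell_type == "CD4T" &
                                         res7$calls$direction == "up"])
  wt <- mx$truth$true_W$weights
  w4 <- cbind(neutrophil = wt[, "neutrophil"],
              lymphocyte = rowSums(wt[, c("B", "CD4T", "CD8T", "NK")]),
              monocyte = wt[, "monocyte"], eosinophil = wt[, "eosinophil"])
  res4 <- permutation_fdr(mx$expr, composition_matrix(w4), mx$design,
                          n_perm = 100, case = "g2", seed = 89)
  rec4 <- mean(sp %in% res4$calls$gene[res4$calls$cell_type == "lymphocyte" &
                                         res4$calls$direction == "up"])
  expect_gt(rec7, rec4)
})

test_that("tidy and glance methods summarize csdiff objects", {
  inst <- make_cs_instance(seed = 15)
  fit <- cs_fit(inst$X, inst$W, inst$design)
  td <- tidy(fit)
  expect_setequal(names(td),
                  c("group", "std_error", "cell_type", "gene", "estimate"))
  expect_equal(nrow(td), 2 * 2 * 6)
  # tidy estimates agree with the matrices they flatten
  one <- td[td$group == "g1" & td$cell_type == "A" & td$gene == "g03", ]
  expect_equal(one$estimate, fit$H_hat$g1["A", "g03"])
  expect_equal(one$std_error, fit$SE$g1["A", "g03"])
  gl <- glance(fit)
  expect_equal(gl$n_case, 8L)

  res <- permutation_fdr(inst$X, inst$W, inst$design, n_perm = 20, seed = 16)
  expect_s3_class(tidy(res), "tbl_df")
  expect_s3_class(autoplot(res), "ggplot")
  expect_equal(glance(res)$n_cell_types, 2L)
})
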