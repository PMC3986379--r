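make_two_type_panel <- function(contrasts) {
  # two cell types, one array each, log2 difference exactly `contrasts`
  p <- length(contrasts)
  genes <- sprintf("g%03d", seq_len(p))
  vals <- cbind(a1 = rep(5, p), b1 = 5 + contrasts)
  rownames(vals) <- genes
  reference_panel(vals, c("A", "B"), scale = "log2")
}

test_that("contrast prefilter keeps top-fraction features per contrast", {
  # one feature with |log2FC| 10, everything else flat
  panel <- make_two_type_panel(c(rep(0, 99), 10))
  expect_true("g100" %in% contrast_prefilter(panel, top_fraction = 0.01))

  # contrasts constructed as 1..100: top 5% = ranks 96..100
  panel2 <- make_two_type_panel(1:100)
  expect_setequal(contrast_prefilter(panel2, top_fraction = 0.05),
                  sprintf("g%03d", 96:100))

  # fully degenerate contrasts: boundary ties include everything
  panel3 <- make_two_type_panel(rep(0, 50))
  expect_setequal(contrast_prefilter(panel3, top_fraction = 0.1),
                  sprintf("g%03d", 1:50))

  # exclusions are honored and shrinking top_fraction never enlarges the set
  expect_false("g100" %in%
    contrast_prefilter(panel, top_fraction = 0.01, exclude = "g100"))
  panel4 <- make_two_type_panel(sample(1:200, 200))
  prev <- contrast_prefilter(panel4, top_fraction = 0.5)
  for (tf in c(0.2, 0.1, 0.02)) {
    cur <- contrast_prefilter(panel4, top_fraction = tf)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("selection path recovers planted markers and respects exclusions", {
  sim <- simulate_panel(K = 7, p = 400, markers_per_type = 2, replicates = 6,
                        seed = 61)
  eligible <- contrast_prefilter(sim$panel, top_fraction = 0.2)
  markers <- unlist(sim$truth$markers)
  expect_true(all(markers %in% eligible))

  path <- suppressWarnings(
    fit_selection_path(sim$panel, eligible, alpha_grid = c(0.5, 1), seed = 62)
  )
  expect_equal(nrow(path), 2)
  for (i in 1:2) {
    sel <- path$features[[i]]
    expect_gt(length(sel), 0)
    expect_true(all(sel %in% eligible))
  }
  # lasso recovers at least 90% of the sparse planted markers
  sel1 <- path$features[[which(path$alpha == 1)]]
  expect_gte(mean(markers %in% sel1), 0.9)

  # excluded features are never selected, at any alpha
  path_ex <- suppressWarnings(
    fit_selection_path(sim$panel, eligible, alpha_grid = c(0.5, 1),
                       exclude = markers[1:3], seed = 62)
  )
  for (i in 1:2) expect_false(any(markers[1:3] %in% path_ex$features[[i]]))
})

test_that("build_basis averages replicates per cell type", {
  vals <- cbind(a1 = c(2, 5), a2 = c(4, 7), b1 = c(1, 1))
  rownames(vals) <- c("g1", "g2")
  panel <- reference_panel(vals, c("A", "A", "B"), scale = "log2")
  H <- build_basis(panel, c("g2", "g1"))
  expect_equal(H$values["g1", "A"], 3) # mean of 2 and 4
  expect_equal(rownames(H$values), c("g1", "g2")) # id-ordered

  # single replicate per type: basis equals the profile restricted to features
  panel1 <- reference_panel(vals[, c("a1", "b1")], c("A", "B"), scale = "log2")
  H1 <- build_basis(panel1, "g1")
  expect_error(basis_check <- H1$values, NA)
  expect_equal(unname(H1$values["g1", ]), unname(vals["g1", c("a1", "b1")]))

  # per-type column-mean oracle on a simulated panel
  sim <- simulate_panel(K = 3, p = 50, markers_per_type = 4, replicates = 3,
                        seed = 63)
  feats <- rownames(sim$panel$values)[1:20]
  H2 <- build_basis(sim$panel, feats)
  for (ct in unique(sim$panel$labels)) {
    oracle <- rowMeans(sim$panel$values[sort(feats), sim$panel$labels == ct])
    expect_equal(H2$values[, ct], oracle)
  }

  expect_error(build_basis(panel, character()), "empty")
})

test_that("condition_number matches singular-value arithmetic", {
  ortho <- basis_matrix(matrix(c(1, 0, 0, 1), 2, 2,
                               dimnames = list(c("g1", "g2"), c("A", "B"))),
                        scale = "linear")
  expect_equal(condition_number(ortho), 1)

  dup <- basis_matrix(matrix(c(1, 2, 1, 2), 2, 2,
                             dimnames = list(c("g1", "g2"), c("A", "B"))),
                      scale = "linear")
  expect_identical(condition_number(dup), Inf)

  # 2x2 closed form: singular values of [[a,0],[0,b]] are |a|,|b|
  m <- matrix(c(6, 0, 0, 2), 2, 2, dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_equal(condition_number(basis_matrix(m, scale = "linear")), 3)
})

test_that("select_basis prefers the largest alpha among RMSE ties", {
  cands <- tibble::tibble(alpha = c(1, 0.6, 0.3),
                          lymphocyte_rmse = c(0.10, 0.05, 0.05))
  expect_equal(select_basis(cands)$alpha, 0.6)
  expect_equal(select_basis(cands[2, ])$alpha, 0.6)
  # invariant to candidate ordering
  expect_equal(select_basis(cands[c(3, 1, 2), ])$alpha, 0.6)
  expect_error(select_basis(cands[0, ]), "no candidates")
  expect_error(select_basis(tibble::tibble(alpha = 1)), "evaluated")
})

test_that("candidate evaluation scores predictions against differentials", {
  sim <- simulate_panel(K = 7, p = 600, markers_per_type = 8, replicates = 3,
                        seed = 64)
  S <- 2^sim$truth$profiles_log2
  mx <- simulate_mixtures(S, n_per_group = 8, noise_cv = 0, seed = 65)
  # measured differentials without error: predictions must match exactly
  diff_exact <- simulate_differentials(mx$truth$true_W, error_cv = 0, seed = 66)
  markers <- unlist(sim$truth$markers)
  panel_lin <- reference_panel(2^sim$panel$values, sim$panel$labels,
                               scale = "linear")
  cands <- tibble::tibble(alpha = 1, features = list(markers))
  # basis from noiseless profiles: use the truth directly for the exact case
  ev <- evaluate_candidates(cands, panel_lin, mx$expr, diff_exact)
  expect_true(all(c("lymphocyte_rmse", "condition_number") %in% names(ev)))
  # replicate noise in the panel keeps this from being exactly zero, but the
  # recovered composition must track the truth closely on noise-free mixtures
  expect_lt(ev$lymphocyte_rmse, 0.05)

  # RMSE recomputed independently from the saved composition
  H <- ev$basis[[1]]
  W_est <- deconvolve(mx$expr, H)$composition$weights[diff_exact$sample_id, ]
  lym <- rowSums(W_est[, c("B", "CD4T", "CD8T", "NK")])
  expect_equal(ev$lymphocyte_rmse,
               sqrt(mean((lym - diff_exact$lymphocyte)^2)))

  bad_diff <- diff_exact
  bad_diff$sample_id[1] <- "missing_sample"
  expect_error(evaluate_candidates(cands, panel_lin, mx$expr, bad_diff),
               "absent")
})
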