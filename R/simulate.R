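#' Default leukocyte cell-type labels used by the simulator
#'
#' Seven sub-populations of peripheral whole blood: neutrophils,
#' eosinophils, monocytes, CD4+ T cells, CD8+ T cells, NK cells and B cells.
#' @return Character vector of length 7.
#' @export
leukocyte_types <- function() {
  c("neutrophil", "eosinophil", "monocyte", "CD4T", "CD8T", "NK", "B")
}

#' Default Dirichlet concentration parameters for blood-like composition
#'
#' Mean proportions reflect a typical adult leukocyte differential
#' (neutrophils dominant at ~55%, lymphocyte sub-populations summing to
#' ~34%), scaled by a concentration controlling between-sample variability.
#'
#' @param concentration total Dirichlet concentration; larger = less
#'   sample-to-sample variability. The default 20 gives the wide
#'   lymphocyte-fraction spread (roughly 0.1-0.6) seen across clinical
#'   transplant cohorts; ~60 reproduces the tighter spread of healthy-donor
#'   differentials.
#' @return Named numeric vector of Dirichlet alphas over [leukocyte_types()].
#' @export
blood_dirichlet_alpha <- function(concentration = 20) {
  means <- c(neutrophil = 0.55, eosinophil = 0.03, monocyte = 0.08,
             CD4T = 0.15, CD8T = 0.09, NK = 0.05, B = 0.05)
  means * concentration
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

# Multiplicative lognormal noise factors with unit mean and the given
# coefficient of variation.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a reference panel of isolated cell-type profiles
#'
#' Emulates replicate expression arrays of leukocyte sub-populations
#' isolated from blood. Each gene gets a shared baseline log2 expression
#' drawn from Gaussian(6, 1.5); each cell type receives
#' `markers_per_type` disjoint marker genes elevated by `marker_log2fc`
#' log2 units in that type only; replicate arrays add Gaussian log2 noise of
#' sd `replicate_sd`.
#'
#' @param K number of cell types (default 7, labelled by
#'   [leukocyte_types()]).
#' @param p number of genes; must satisfy `K * markers_per_type <= p`.
#' @param markers_per_type planted marker genes per cell type.
#' @param replicates replicate arrays per cell type.
#' @param marker_log2fc marker elevation, log2 units (>= 2 recommended so
#'   markers are unambiguous).
#' @param replicate_sd replicate array noise, log2 units.
#' @param cell_types optional label vector of length `K`.
#' @param seed integer seed; the output is fully reproducible from it.
#' @return A list with `panel` (a [reference_panel()], log2 scale) and
#'   `truth`: `profiles_log2` (p x K true mean log2 expression),
#'   `markers` (named list of marker gene ids per cell type), and the
#'   generator parameters.
#' @export
simulate_panel <- function(K = 7, p = 1000, markers_per_type = 20,
                           replicates = 5, marker_log2fc = 4,
                           replicate_sd = 0.25, cell_types = NULL,
                           seed = NULL) {
  if (is.null(cell_types)) {
    cell_types <- if (K == 7) leukocyte_types() else paste0("cell", seq_len(K))
  }
  stopifnot(length(cell_types) == K)
  if (K * markers_per_type > p) {
    stop("cannot allocate ", K, " x ", markers_per_type,
         " disjoint markers among ", p, " genes", call. = FALSE)
  }
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(p))
    baseline <- stats::rnorm(p, mean = 6, sd = 1.5)
    profiles <- matrix(baseline, nrow = p, ncol = K,
                       dimnames = list(genes, cell_types))
    markers <- list()
    idx <- 1
    for (k in seq_len(K)) {
      mk <- genes[idx:(idx + markers_per_type - 1)]
      profiles[mk, k] <- profiles[mk, k] + marker_log2fc
      markers[[cell_types[k]]] <- mk
      idx <- idx + markers_per_type
    }
    arrays <- profiles[, rep(seq_len(K), each = replicates), drop = FALSE]
    if (replicate_sd > 0) {
      arrays <- arrays + stats::rnorm(length(arrays), 0, replicate_sd)
    }
    labels <- rep(cell_types, each = replicates)
    colnames(arrays) <- sprintf("%s_r%d", labels, rep(seq_len(replicates), K))
    panel <- reference_panel(arrays, labels, scale = "log2")
    list(
      panel = panel,
      truth = list(
        profiles_log2 = profiles, markers = markers,
        marker_log2fc = marker_log2fc, replicate_sd = replicate_sd,
        seed = seed
      )
    )
  })
}

#' Simulate whole-blood-like mixtures with known composition and spikes
#'
#' Draws per-sample cell-type proportions from group-specific Dirichlet
#' distributions, optionally modifies the second group's cell-type profiles
#' by multiplicative fold changes on the linear scale (cell-type-specific
#' differential expression, applied before mixing so that composition shifts
#' and expression spikes vary independently), mixes, and applies
#' multiplicative lognormal noise with coefficient of variation `noise_cv`.
#'
#' @param profiles p x K linear-scale matrix of true cell-type expression
#'   (rownames = gene ids, colnames = cell types), e.g.
#'   `2^truth$profiles_log2` from [simulate_panel()].
#' @param n_per_group samples per group (length-1 or length-2 integer).
#' @param dirichlet_alpha Dirichlet parameters: a single named vector
#'   (both groups share it) or a list of two vectors (`g1`, `g2`),
#'   each of length K in `colnames(profiles)` order.
#' @param de_spec optional data frame with columns `cell_type`, `n_genes`,
#'   `fold` (> 0) and `direction` (`"up"`/`"down"`): for each row,
#'   `n_genes` genes are picked (avoiding genes already spiked) and the
#'   *second* group's profile for that cell type is multiplied by `fold`
#'   (up) or divided (down). An optional `genes` list-column names the
#'   spiked genes explicitly (overriding `n_genes`); useful because a
#'   down-regulation's observable effect is bounded by the gene's own
#'   abundance, so detectable down-spikes must sit in expressed genes.
#' @param noise_cv coefficient of variation of the lognormal measurement
#'   noise; 0 gives exactly `X = W %*% t(S)`.
#' @param seed integer seed.
#' @return List with `expr` (linear [expression_matrix()], genes x samples),
#'   `design` (a [group_design()] with groups `g1`/`g2`), and `truth`:
#'   `true_W` ([composition_matrix()]), `spiked` (tibble of gene, cell_type,
#'   direction, fold), group-specific profile matrices, and parameters.
#' @export
simulate_mixtures <- function(profiles, n_per_group = 24,
                              dirichlet_alpha = blood_dirichlet_alpha(),
                              de_spec = NULL, noise_cv = 0, seed = NULL) {
  profiles <- as.matrix(profiles)
  if (any(profiles < 0)) {
    stop("`profiles` must be linear scale (non-negative)", call. = FALSE)
  }
  K <- ncol(profiles)
  cell_types <- colnames(profiles)
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  if (!is.list(dirichlet_alpha)) {
    dirichlet_alpha <- list(dirichlet_alpha, dirichlet_alpha)
  }
  if (any(lengths(dirichlet_alpha) != K)) {
    stop("each Dirichlet alpha vector must have length K = ", K, call. = FALSE)
  }
  with_seed(seed, {
    ## group-specific profiles: spikes modify group 2 before mixing
    S <- list(g1 = profiles, g2 = profiles)
    spiked <- tibble::tibble(gene = character(), cell_type = character(),
                             direction = character(), fold = numeric())
    if (!is.null(de_spec) && nrow(de_spec) > 0) {
      de_spec <- tibble::as_tibble(de_spec)
      if (any(de_spec$fold <= 0)) stop("`fold` must be > 0", call. = FALSE)
      taken <- character()
      for (r in seq_len(nrow(de_spec))) {
        ct <- de_spec$cell_type[r]
        if (!ct %in% cell_types) {
          stop("unknown cell type in de_spec: ", ct, call. = FALSE)
        }
        if ("genes" %in% names(de_spec) && !is.null(de_spec$genes[[r]])) {
          gs <- setdiff(unlist(de_spec$genes[[r]]), taken)
        } else {
          pool <- setdiff(rownames(profiles), taken)
          gs <- sample(pool, de_spec$n_genes[r])
        }
        taken <- c(taken, gs)
        f <- if (de_spec$direction[r] == "up") de_spec$fold[r] else 1 / de_spec$fold[r]
        S$g2[gs, ct] <- S$g2[gs, ct] * f
        spiked <- dplyr::bind_rows(spiked, tibble::tibble(
          gene = gs, cell_type = ct,
          direction = de_spec$direction[r], fold = de_spec$fold[r]
        ))
      }
    }
    n <- sum(n_per_group)
    grp <- rep(c("g1", "g2"), n_per_group)
    ids <- sprintf("s%03d", seq_len(n))
    W <- rbind(rdirichlet(n_per_group[1], dirichlet_alpha[[1]]),
               rdirichlet(n_per_group[2], dirichlet_alpha[[2]]))
    dimnames(W) <- list(ids, cell_types)
    X <- matrix(0, nrow(profiles), n, dimnames = list(rownames(profiles), ids))
    for (i in seq_len(n)) {
      X[, i] <- S[[grp[i]]] %*% W[i, ]
    }
    if (noise_cv > 0) {
      X <- X * matrix(lognormal_noise(length(X), noise_cv), nrow(X))
    }
    list(
      expr = expression_matrix(X, scale = "linear"),
      design = group_design(ids, grp),
      truth = list(
        true_W = composition_matrix(W), spiked = spiked,
        profiles_g1 = S$g1, profiles_g2 = S$g2,
        dirichlet_alpha = dirichlet_alpha, noise_cv = noise_cv, seed = seed
      )
    )
  })
}

#' Simulate noisy total leukocyte differentials from true composition
#'
#' Aggregates the true composition into the four compartments a clinical
#' differential reports (neutrophil, lymphocyte = B + CD4+ T + CD8+ T + NK,
#' monocyte, eosinophil), then perturbs each fraction with multiplicative
#' lognormal noise of coefficient of variation `error_cv`. The default 0.08
#' reflects reported lymphocyte measurement error of clinical differentials
#' (roughly 4-12%). Rows whose noisy fractions exceed 1 in total are
#' rescaled to sum to 1.
#'
#' @param true_W a [composition_matrix()] whose columns include the four
#'   lymphocyte sub-populations plus neutrophil/monocyte/eosinophil.
#' @param error_cv measurement-noise coefficient of variation.
#' @param seed integer seed.
#' @return A [differential()] tibble.
#' @export
simulate_differentials <- function(true_W, error_cv = 0.08, seed = NULL) {
  stopifnot(inherits(true_W, "comp_mat"))
  W <- true_W$weights
  need <- c("neutrophil", "monocyte", "eosinophil", LYMPHOCYTE_SUBTYPES)
  missing <- setdiff(need, colnames(W))
  if (length(missing) > 0) {
    stop("true_W lacks cell types: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  agg <- cbind(
    neutrophil = W[, "neutrophil"],
    lymphocyte = rowSums(W[, LYMPHOCYTE_SUBTYPES, drop = FALSE]),
    monocyte = W[, "monocyte"],
    eosinophil = W[, "eosinophil"]
  )
  noisy <- with_seed(seed, {
    agg * matrix(lognormal_noise(length(agg), error_cv), nrow(agg))
  })
  noisy <- pmin(noisy, 1)
  over <- rowSums(noisy) > 1
  noisy[over, ] <- noisy[over, , drop = FALSE] / rowSums(noisy[over, , drop = FALSE])
  differential(tibble::tibble(
    sample_id = rownames(W),
    neutrophil = noisy[, "neutrophil"],
    lymphocyte = noisy[, "lymphocyte"],
    monocyte = noisy[, "monocyte"],
    eosinophil = noisy[, "eosinophil"]
  ))
}
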