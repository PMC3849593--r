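#' Laplace (double-exponential) random variates
#'
#' @param n number of draws.
#' @param location,scale Laplace location and scale `b` (variance `2 b^2`).
#' @return Numeric vector.
#' @export
rlaplace <- function(n, location = 0, scale = 1) {
  u <- runif(n) - 0.5
  location - scale * sign(u) * log(1 - 2 * abs(u))
}

#' Design of the sparse-regression simulation study
#'
#' The simulation that anchors the method comparison: 90 predictors in three
#' platform groups of 30, iid standard-normal design entries, 30 coefficients
#' exactly zero (chosen uniformly at random) and 60 drawn from a
#' Laplace(0, 1/7), unit error variance, 100 training and 400 test samples.
#'
#' @param n_train,n_test training / test sample sizes.
#' @param J number of platform groups.
#' @param p_per_group predictors per group.
#' @param n_zero number of exactly-zero coefficients.
#' @param laplace_location,laplace_scale coefficient law for the nonzeros.
#' @param sigma2_true error variance.
#' @return List of class `simulation_design`.
#' @export
simulation_design <- function(n_train = 100, n_test = 400, J = 3,
                              p_per_group = 30, n_zero = 30,
                              laplace_location = 0, laplace_scale = 1 / 7,
                              sigma2_true = 1) {
  stopifnot(n_zero <= J * p_per_group, n_train > 0, n_test > 0,
            sigma2_true > 0)
  structure(list(n_train = n_train, n_test = n_test, J = J,
                 p_per_group = p_per_group, n_zero = n_zero,
                 laplace_location = laplace_location,
                 laplace_scale = laplace_scale, sigma2_true = sigma2_true),
            class = "simulation_design")
}

#' Generate one train/test dataset from the simulation design
#'
#' @param design a [simulation_design()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return List with `train` and `test` (each `list(X, y)`), `beta_true`,
#'   `groups` (platform index per column), `zero_idx` and `design`.
#' @export
generate_table1_data <- function(design = simulation_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- design$J * design$p_per_group
  zero_idx <- sample.int(p, design$n_zero)
  beta <- rlaplace(p, design$laplace_location, design$laplace_scale)
  beta[zero_idx] <- 0
  make_split <- function(n) {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("x", seq_len(p))
    y <- drop(X %*% beta) + rnorm(n, sd = sqrt(design$sigma2_true))
    list(X = X, y = y)
  }
  list(train = make_split(design$n_train),
       test = make_split(design$n_test),
       beta_true = beta,
       groups = rep(seq_len(design$J), each = design$p_per_group),
       zero_idx = sort(zero_idx),
       design = design)
}

#' Design of the GBM-like multi-platform generator
#'
#' Emulates the shape of a matched multi-platform glioblastoma cohort: 163
#' samples, 49 pathway genes, 1-21 methylation markers and 1-43 copy-number
#' markers per gene (one gene carries no methylation data at all), strictly
#' positive survival times, and sparse missingness (about 5% in methylation,
#' about 0.1% in copy number).
#'
#' Each gene's marker block is driven by a single latent factor with loading
#' 0.8 plus iid noise; the methylation-driven, copy-number-driven and other
#' expression components are the latent factors themselves (unit variance),
#' so planted clinical effects are approximately on the standardized
#' predictor scale. Log survival is centred at `log_time_center` (default
#' log(365): median survival about a year) with Gaussian noise of standard
#' deviation `survival_sd`.
#'
#' @param n_samples,n_genes cohort shape.
#' @param meth_range,cn_range inclusive ranges for markers per gene.
#' @param n_no_meth number of genes with no methylation markers.
#' @param n_effects number of truly prognostic (gene, platform) components.
#' @param effect_size absolute planted effect on log survival per component
#'   unit; signs alternate. The default 0.5 corresponds to a 65% change in
#'   survival time per standard deviation of the component.
#' @param survival_sd residual standard deviation of log survival.
#' @param log_time_center baseline log survival (days).
#' @param missing_meth,missing_cn missing-cell rates.
#' @param loading latent-factor loading within each marker block.
#' @return List of class `omics_design`.
#' @export
omics_design <- function(n_samples = 163, n_genes = 49,
                         meth_range = c(1, 21), cn_range = c(1, 43),
                         n_no_meth = 1, n_effects = 6, effect_size = 0.5,
                         survival_sd = 0.5, log_time_center = log(365),
                         missing_meth = 0.05, missing_cn = 0.001,
                         loading = 0.8) {
  stopifnot(n_samples > 1, n_genes >= 1, n_no_meth < n_genes,
            meth_range[1] >= 1, cn_range[1] >= 1,
            survival_sd >= 0, loading > 0, loading < 1,
            n_effects <= 3 * n_genes)
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 meth_range = meth_range, cn_range = cn_range,
                 n_no_meth = n_no_meth, n_effects = n_effects,
                 effect_size = effect_size, survival_sd = survival_sd,
                 log_time_center = log_time_center,
                 missing_meth = missing_meth, missing_cn = missing_cn,
                 loading = loading),
            class = "omics_design")
}

#' Generate a GBM-like multi-platform dataset with known truth
#'
#' Per gene, a latent methylation factor and a latent copy-number factor
#' drive correlated marker blocks; expression is the exact sum of the
#' methylation-driven, copy-number-driven and other components, so the
#' mechanistic decomposition identity holds by construction before any
#' missingness is injected. Log survival is a sparse linear combination of
#' the true components plus noise; the planted coefficients are returned for
#' recovery tests.
#'
#' @param design an [omics_design()].
#' @param seed integer seed.
#' @return List with `dataset` (a `platform_dataset`), `truth` (tibble:
#'   `gene_id`, `platform`, `beta`), `components` (list of n x genes matrices
#'   `M`, `CN`, `O`), `meth_counts`, `cn_counts`, `design`.
#' @export
generate_omics_data <- function(design = omics_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_samples
  G <- design$n_genes
  genes <- sprintf("gene%02d", seq_len(G))
  samples <- sprintf("S%03d", seq_len(n))

  meth_counts <- sample(design$meth_range[1]:design$meth_range[2], G,
                        replace = TRUE)
  if (design$n_no_meth > 0) {
    meth_counts[seq(G, by = -1, length.out = design$n_no_meth)] <- 0
  }
  cn_counts <- sample(design$cn_range[1]:design$cn_range[2], G,
                      replace = TRUE)

  lo <- design$loading
  noise_sd <- sqrt(1 - lo^2)
  M <- matrix(0, n, G); CN <- matrix(0, n, G); O <- matrix(0, n, G)
  colnames(M) <- colnames(CN) <- colnames(O) <- genes
  meth_cols <- list(); meth_ids <- character(0); meth_gene <- character(0)
  cn_cols <- list(); cn_ids <- character(0); cn_gene <- character(0)
  for (g in seq_len(G)) {
    if (meth_counts[g] > 0) {
      f <- rnorm(n)
      M[, g] <- f
      blk <- lo * matrix(f, n, meth_counts[g]) +
        noise_sd * matrix(rnorm(n * meth_counts[g]), n)
      meth_cols[[length(meth_cols) + 1L]] <- blk
      meth_ids <- c(meth_ids, sprintf("%s_meth%02d", genes[g],
                                      seq_len(meth_counts[g])))
      meth_gene <- c(meth_gene, rep(genes[g], meth_counts[g]))
    }
    f <- rnorm(n)
    CN[, g] <- f
    blk <- lo * matrix(f, n, cn_counts[g]) +
      noise_sd * matrix(rnorm(n * cn_counts[g]), n)
    cn_cols[[length(cn_cols) + 1L]] <- blk
    cn_ids <- c(cn_ids, sprintf("%s_cn%02d", genes[g], seq_len(cn_counts[g])))
    cn_gene <- c(cn_gene, rep(genes[g], cn_counts[g]))
    O[, g] <- rnorm(n)
  }
  mrna <- M + CN + O
  dimnames(mrna) <- list(samples, genes)
  meth <- do.call(cbind, meth_cols)
  dimnames(meth) <- list(samples, meth_ids)
  cn <- do.call(cbind, cn_cols)
  dimnames(cn) <- list(samples, cn_ids)

  # plant sparse prognostic effects on (gene, platform) components
  slots <- tibble::tibble(
    gene_id = rep(genes, 3),
    platform = rep(c("M", "CN", "O"), each = G),
    beta = 0
  )
  eligible <- !(slots$platform == "M" & rep(meth_counts == 0, 3))
  hit <- sample(which(eligible), design$n_effects)
  slots$beta[hit] <- design$effect_size *
    rep_len(c(1, -1), design$n_effects)

  comp_of <- list(M = M, CN = CN, O = O)
  lin <- rep(0, n)
  for (i in which(slots$beta != 0)) {
    lin <- lin + slots$beta[i] * comp_of[[slots$platform[i]]][, slots$gene_id[i]]
  }
  log_t <- design$log_time_center + lin + rnorm(n, sd = design$survival_sd)
  survival_days <- exp(log_t)
  names(survival_days) <- samples

  inject <- function(mat, rate) {
    if (rate <= 0) return(mat)
    mask <- matrix(rbinom(length(mat), 1, rate) == 1, nrow(mat))
    # keep at least two observed values per column
    for (j in which(colSums(!mask) < 2)) mask[, j] <- FALSE
    mat[mask] <- NA
    mat
  }
  meth <- inject(meth, design$missing_meth)
  cn <- inject(cn, design$missing_cn)

  dataset <- assemble_dataset(
    mrna, meth, marker_map(meth_ids, meth_gene),
    cn, marker_map(cn_ids, cn_gene), survival_days
  )
  list(dataset = dataset,
       truth = slots,
       components = comp_of,
       meth_counts = meth_counts,
       cn_counts = cn_counts,
       design = design)
}
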