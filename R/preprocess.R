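#' Impute missing marker values by correlated-donor regression
#'
#' Four-step imputation for a samples-by-markers matrix with a small fraction
#' of missing entries: (1) fill each missing cell with its marker's mean over
#' the observed samples, giving a working matrix `Temp`; (2) compute the
#' marker-by-marker Pearson correlation matrix from `Temp`; (3) for each
#' marker with missing values, regress its observed entries (ordinary least
#' squares with intercept) on the three markers with which it is most highly
#' positively correlated, taking predictor values from `Temp`; (4) substitute
#' the fitted values for the originally missing cells only. Observed cells
#' are never altered, and because donors always use `Temp`, the result does
#' not depend on the order in which markers are processed.
#'
#' When fewer than three other markers are positively correlated with a
#' target marker, the available ones (at least one) are used; with none, the
#' step-1 mean fill is kept. Both fallbacks warn. Correlation ties are broken
#' by column order.
#'
#' @param x numeric matrix (samples x markers), possibly with `NA` entries.
#' @return Complete numeric matrix of the same shape and dimnames.
#' @export
impute_missing <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!anyNA(x)) return(x)
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0)) {
    stop("column(s) with no observed values: ",
         paste(head(which(n_obs == 0), 5), collapse = ", "))
  }
  col_means <- colMeans(x, na.rm = TRUE)
  temp <- x
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) temp[miss, j] <- col_means[j]
  }
  cm <- suppressWarnings(cor(temp))  # constant columns give NA correlations
  out <- x
  targets <- which(colSums(is.na(x)) > 0)
  for (j in targets) {
    r <- cm[, j]
    r[j] <- NA
    donors <- which(!is.na(r) & r > 0)
    donors <- donors[order(-r[donors], donors)]  # ties by column order
    donors <- head(donors, 3)
    miss <- which(is.na(x[, j]))
    if (length(donors) == 0) {
      warning("marker ", j, ": no positively correlated donors; ",
              "keeping mean fill", call. = FALSE)
      out[miss, j] <- col_means[j]
      next
    }
    if (length(donors) < 3) {
      warning("marker ", j, ": only ", length(donors),
              " positively correlated donor(s) available", call. = FALSE)
    }
    obs <- which(!is.na(x[, j]))
    dm <- cbind(1, temp[, donors, drop = FALSE])
    fit <- lm.fit(dm[obs, , drop = FALSE], x[obs, j])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    out[miss, j] <- dm[miss, , drop = FALSE] %*% beta
  }
  out
}

#' Principal-component scores for one gene's marker block
#'
#' With a single marker the raw column is passed through unchanged (one
#' "score", no centering). With several markers the columns are mean-centered
#' (not rescaled, by default: markers within a platform share a scale) and a
#' PCA is taken; the smallest number of leading components whose cumulative
#' explained variance reaches `variance_threshold` is retained.
#'
#' @param block numeric matrix (samples x markers), no missing values.
#' @param variance_threshold fraction of total variance to retain (default
#'   0.90).
#' @param scale. logical; standardize columns before the PCA (correlation
#'   PCA). Default `FALSE` (covariance PCA).
#' @return List with `scores` (n x k), `loadings` (markers x k), `k`,
#'   `explained` (per-component variance fractions) and `center`.
#' @export
pc_scores <- function(block, variance_threshold = 0.90, scale. = FALSE) {
  stopifnot(is.matrix(block), !anyNA(block),
            variance_threshold > 0, variance_threshold <= 1)
  m <- ncol(block)
  if (m == 0) {
    return(list(scores = matrix(0, nrow(block), 0), loadings = NULL, k = 0L,
                explained = numeric(0), center = numeric(0)))
  }
  if (m == 1) {
    return(list(scores = block, loadings = matrix(1, 1, 1), k = 1L,
                explained = 1, center = 0))
  }
  vars <- apply(block, 2, var)
  if (all(vars < .Machine$double.eps)) {
    warning("zero-variance marker block; no components retained",
            call. = FALSE)
    return(list(scores = matrix(0, nrow(block), 0), loadings = NULL, k = 0L,
                explained = numeric(0), center = colMeans(block)))
  }
  pca <- stats::prcomp(block, center = TRUE, scale. = scale.)
  ev <- pca$sdev^2
  frac <- cumsum(ev) / sum(ev)
  k <- which(frac >= variance_threshold - 1e-12)[1]
  list(scores = pca$x[, seq_len(k), drop = FALSE],
       loadings = pca$rotation[, seq_len(k), drop = FALSE],
       k = as.integer(k),
       explained = ev / sum(ev),
       center = pca$center)
}

#' Mechanistic decomposition of one gene's expression
#'
#' Jointly regresses the gene's expression on its methylation and copy-number
#' PC scores (with intercept) and splits the fit into a methylation-driven
#' component `M`, a copy-number-driven component `CN`, and an "other"
#' component `O` that absorbs the intercept and the residuals, so that
#' `M + CN + O` reproduces the expression vector exactly (to numerical
#' tolerance). A gene with no methylation markers gets `M = 0` (and likewise
#' for copy number).
#'
#' @param mrna_i expression vector (length n).
#' @param meth_scores n x K matrix of methylation scores (0 columns allowed).
#' @param cn_scores n x R matrix of copy-number scores (0 columns allowed).
#' @param gene_id optional gene label carried through.
#' @return Object of class `gene_decomposition`: list with `gene_id`, `M`,
#'   `CN`, `O`, `K`, `R`, `coef_M`, `coef_CN`.
#' @export
decompose_gene <- function(mrna_i, meth_scores = NULL, cn_scores = NULL,
                           gene_id = NA_character_) {
  n <- length(mrna_i)
  if (is.null(meth_scores)) meth_scores <- matrix(0, n, 0)
  if (is.null(cn_scores)) cn_scores <- matrix(0, n, 0)
  stopifnot(nrow(meth_scores) == n, nrow(cn_scores) == n)

  # guard against a rank-deficient regression: drop lowest-variance scores
  while (ncol(meth_scores) + ncol(cn_scores) + 1 >= n &&
         ncol(meth_scores) + ncol(cn_scores) > 0) {
    vm <- if (ncol(meth_scores) > 0) var(meth_scores[, ncol(meth_scores)]) else Inf
    vc <- if (ncol(cn_scores) > 0) var(cn_scores[, ncol(cn_scores)]) else Inf
    warning("too many PC scores for n; dropping lowest-variance component",
            call. = FALSE)
    if (vm <= vc) {
      meth_scores <- meth_scores[, -ncol(meth_scores), drop = FALSE]
    } else {
      cn_scores <- cn_scores[, -ncol(cn_scores), drop = FALSE]
    }
  }
  K <- ncol(meth_scores)
  R <- ncol(cn_scores)
  X <- cbind(1, meth_scores, cn_scores)
  fit <- lm.fit(X, mrna_i)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  coef_M <- beta[seq_len(K) + 1]
  coef_CN <- beta[seq_len(R) + 1 + K]
  M <- if (K > 0) drop(meth_scores %*% coef_M) else rep(0, n)
  CN <- if (R > 0) drop(cn_scores %*% coef_CN) else rep(0, n)
  O <- mrna_i - M - CN  # intercept + residuals
  structure(list(gene_id = gene_id, M = M, CN = CN, O = O,
                 K = as.integer(K), R = as.integer(R),
                 coef_M = unname(coef_M), coef_CN = unname(coef_CN)),
            class = "gene_decomposition")
}

#' Decompose every gene of an aligned dataset
#'
#' Runs [impute_missing()] on the methylation and copy-number matrices (when
#' needed), extracts each gene's marker blocks via the marker maps, computes
#' PC scores retaining `variance_threshold` of the variance, and applies
#' [decompose_gene()] gene by gene.
#'
#' @param dataset a `platform_dataset` from [assemble_dataset()].
#' @param variance_threshold cumulative-variance cutoff for retained PCs.
#' @param scale. passed to [pc_scores()].
#' @return List of class `gene_decompositions`; one `gene_decomposition` per
#'   mRNA column, in mRNA column order, plus attributes `sample_ids` and
#'   `survival_days`.
#' @export
decompose_dataset <- function(dataset, variance_threshold = 0.90,
                              scale. = FALSE) {
  stopifnot(inherits(dataset, "platform_dataset"))
  meth <- impute_missing(dataset$meth)
  cn <- impute_missing(dataset$cn)
  genes <- colnames(dataset$mrna)
  decomps <- lapply(genes, function(g) {
    mk <- dataset$meth_map$marker_id[dataset$meth_map$gene_id == g]
    ck <- dataset$cn_map$marker_id[dataset$cn_map$gene_id == g]
    ms <- pc_scores(meth[, mk, drop = FALSE], variance_threshold, scale.)
    cs <- pc_scores(cn[, ck, drop = FALSE], variance_threshold, scale.)
    decompose_gene(dataset$mrna[, g], ms$scores, cs$scores, gene_id = g)
  })
  structure(decomps, class = "gene_decompositions",
            sample_ids = dataset$sample_ids,
            survival_days = dataset$survival_days)
}

#' @export
print.gene_decompositions <- function(x, ...) {
  cat("<gene_decompositions> ", length(x), " genes, ",
      length(attr(x, "sample_ids")), " samples\n", sep = "")
  invisible(x)
}

#' Summarize per-gene decompositions
#'
#' @param x a `gene_decompositions` list.
#' @param ... unused.
#' @return Tibble with one row per gene: `gene_id`, `K`, `R`, and the
#'   variance of each component.
#' @method tidy gene_decompositions
#' @export
tidy.gene_decompositions <- function(x, ...) {
  purrr::map_dfr(x, function(d) {
    tibble::tibble(gene_id = d$gene_id, K = d$K, R = d$R,
                   var_M = var(d$M), var_CN = var(d$CN), var_O = var(d$O))
  })
}

#' Build the clinical-model design from gene decompositions
#'
#' Stacks all methylation-driven components, then all copy-number-driven
#' components, then all "other" components into one predictor matrix (a gene
#' with no retained scores on a platform contributes no column there), labels
#' each column with its platform group (M = 1, CN = 2, O = 3), standardizes
#' every column to mean zero and unit standard deviation (n - 1 denominator),
#' and takes the response as log survival days. Zero-variance columns are
#' dropped with a warning. Standardization constants are stored so effects
#' can be reported per original component unit.
#'
#' @param decompositions a `gene_decompositions` list (or plain list of
#'   `gene_decomposition` objects).
#' @param survival_days strictly positive vector of survival times (days); if
#'   missing, taken from the attribute stored by [decompose_dataset()].
#' @return Object of class `clinical_design`: list with `X` (standardized
#'   n x p matrix), `y` (log survival), `groups` (integer 1/2/3 per column),
#'   `annotation` (tibble: column, gene_id, platform), `center`, `scale`.
#' @export
build_clinical_design <- function(decompositions, survival_days = NULL) {
  if (is.null(survival_days))
    survival_days <- attr(decompositions, "survival_days")
  stopifnot(!is.null(survival_days), all(survival_days > 0))
  n <- length(decompositions[[1]]$M)
  stopifnot(length(survival_days) == n)

  cols <- list(); genes <- character(0); platform <- character(0)
  for (comp in c("M", "CN", "O")) {
    for (d in decompositions) {
      keep <- switch(comp, M = d$K > 0, CN = d$R > 0, O = TRUE)
      if (!keep) next
      cols[[length(cols) + 1L]] <- d[[comp]]
      genes <- c(genes, d$gene_id)
      platform <- c(platform, comp)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- paste(platform, genes, sep = ":")
  ids <- attr(decompositions, "sample_ids")
  rownames(X) <- if (!is.null(ids)) ids else sprintf("s%d", seq_len(n))
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  ok <- scl > 1e-12
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " zero-variance column(s): ",
            paste(head(colnames(X)[!ok], 5), collapse = ", "), call. = FALSE)
  }
  X <- sweep(sweep(X[, ok, drop = FALSE], 2, ctr[ok], "-"), 2, scl[ok], "/")
  platform <- platform[ok]; genes <- genes[ok]
  groups <- match(platform, c("M", "CN", "O"))
  structure(list(
    X = X,
    y = log(as.numeric(survival_days)),
    groups = groups,
    annotation = tibble::tibble(column = colnames(X), gene_id = genes,
                                platform = platform),
    center = ctr[ok],
    scale = scl[ok]
  ), class = "clinical_design")
}

#' @export
print.clinical_design <- function(x, ...) {
  cat("<clinical_design> n = ", length(x$y), ", p = ", ncol(x$X),
      " (M: ", sum(x$groups == 1), ", CN: ", sum(x$groups == 2),
      ", O: ", sum(x$groups == 3), ")\n", sep = "")
  invisible(x)
}
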