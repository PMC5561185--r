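# Principal components of ancestry.
#
# The ancestry investigation is phrased as multidimensional scaling in some
# cohort pipelines; classical (Torgerson) MDS of standardized genotype
# distances and genotype PCA give the same component scores up to sign and
# scale, so PCA is implemented here and the equivalence is asserted in the
# test suite.

#' Fit principal components of ancestry
#'
#' Components of the column-standardized dosage matrix (per-SNP mean-centred
#' and unit-variance scaled; missing dosages mean-imputed per SNP before the
#' decomposition), ordered by decreasing explained variance. Zero-variance
#' SNPs are dropped with a warning. The sign convention makes each loading
#' vector's largest-magnitude entry positive so runs are reproducible across
#' linear-algebra backends. Component scores are standardized to mean 0, SD 1
#' over the fitting samples.
#'
#' @param gm a `genotype_matrix`, or a plain samples x variants dosage matrix.
#' @param n_components number of components to retain.
#' @param scaling per-SNP scale: observed SD (robust default for dosage data)
#'   or the binomial SD sqrt(2 p (1-p)).
#' @return object of class `ancestry_model`: standardized `pcs` (samples x
#'   components), `loadings` (variants x components), `explained_variance`
#'   (eigenvalues) and `explained_share`, plus the raw score SDs/means needed
#'   to reproduce the standardization.
#' @export
fit_pca <- function(gm, n_components = 20, scaling = c("observed", "binomial")) {
  scaling <- match.arg(scaling)
  X <- if (inherits(gm, "genotype_matrix")) gm$dosages else as.matrix(gm)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples to fit PCA", call. = FALSE)

  # per-SNP mean imputation of missing dosages
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  ctr <- colMeans(X)
  scl <- if (scaling == "observed") {
    sqrt(pmax(colSums(X^2) - n * ctr^2, 0) / (n - 1))
  } else {
    p <- ctr / 2
    sqrt(2 * p * (1 - p))
  }
  zero <- !is.finite(scl) | scl < 1e-12
  if (any(zero)) {
    warning(sum(zero), " zero-variance SNP(s) dropped before PCA")
    X <- X[, !zero, drop = FALSE]
    ctr <- ctr[!zero]
    scl <- scl[!zero]
  }
  if (ncol(X) < 1) stop("no variable SNPs left for PCA", call. = FALSE)
  # covariance of the standardized matrix from raw moments: avoids building
  # the n x m standardized copy (S = D^-1 (X'X - n ctr ctr') D^-1 / (n-1))
  S <- crossprod(X) - n * tcrossprod(ctr)
  S <- S / tcrossprod(scl) / (n - 1)
  m <- ncol(S)
  if (m > 400 && n_components <= m / 4) {
    # large panels: Lanczos top-k eigenpairs (deterministic start vector)
    eig <- RSpectra::eigs_sym(S, k = n_components,
                              opts = list(initvec = rep(1, m), tol = 1e-12,
                                          maxitr = 5000))
    tol <- max(eig$values[1], 0) * 1e-10
    if (length(eig$values) < n_components || any(eig$values <= tol)) {
      stop("n_components (", n_components, ") exceeds the rank of the ",
           "standardized genotype matrix", call. = FALSE)
    }
  } else {
    eig <- eigen(S, symmetric = TRUE)
    tol <- max(eig$values[1], 0) * 1e-10
    rank <- sum(eig$values > tol)
    if (n_components > rank) {
      stop("n_components (", n_components, ") exceeds the rank (", rank,
           ") of the standardized genotype matrix", call. = FALSE)
    }
  }
  V <- eig$vectors[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|loading| entry positive
  for (k in seq_len(n_components)) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  # scores of the standardized matrix via rescaled loadings:
  # Xs V = X (V / scl) - 1 ctr'(V / scl)
  Vs <- V / scl
  scores <- X %*% Vs - tcrossprod(rep(1, n), drop(crossprod(ctr, Vs)))
  sc_mean <- colMeans(scores)
  sc_sd <- sqrt(pmax(colSums(scores^2) - n * sc_mean^2, 0) / (n - 1))
  if (any(sc_sd < 1e-12)) stop("degenerate component with zero score variance", call. = FALSE)
  pcs <- sweep(sweep(scores, 2, sc_mean), 2, sc_sd, "/")
  pc_names <- paste0("PC", seq_len(n_components))
  dimnames(pcs) <- list(rownames(X), pc_names)
  dimnames(V) <- list(colnames(X), pc_names)

  structure(
    list(
      pcs = pcs, loadings = V,
      explained_variance = eig$values[seq_len(n_components)],
      # total variance of the standardized matrix = trace of S
      explained_share = eig$values[seq_len(n_components)] / sum(diag(S)),
      score_mean = sc_mean, score_sd = sc_sd,
      center = ctr, scale = scl, scaling = scaling,
      sample_ids = rownames(X), n_components = n_components,
      reference_stats = NULL
    ),
    class = "ancestry_model"
  )
}

#' @export
print.ancestry_model <- function(x, ...) {
  cat(sprintf("Ancestry model: %d samples, %d components (top shares: %s)\n",
              nrow(x$pcs), x$n_components,
              paste(sprintf("%.1f%%", 100 * utils::head(x$explained_share, 4)),
                    collapse = ", ")))
  invisible(x)
}

#' Classify ancestry outliers by the k-SD reference rule
#'
#' A sample is an outlier iff its score differs from the reference-group mean
#' by strictly more than `k_sd` reference-group SDs on any of the first
#' `n_check` components ("exceeding" is a strict inequality: a sample at
#' exactly `k_sd` SDs is reference-like).
#'
#' @param model an `ancestry_model`.
#' @param reference_ids sample ids of the designated reference subgroup
#'   (e.g. a European reference panel subset); at least 2.
#' @param k_sd SD threshold.
#' @param n_check number of leading components checked.
#' @return character vector (`"reference-like"` / `"outlier"`) named by
#'   sample, with the per-component reference means/SDs in attribute
#'   `reference_stats`.
#' @export
classify_outliers <- function(model, reference_ids, k_sd = 4, n_check = 4) {
  stopifnot(inherits(model, "ancestry_model"))
  idx <- match(reference_ids, model$sample_ids)
  if (length(idx) == 0 || anyNA(idx)) {
    stop("reference_ids must be a nonempty subset of the fitted samples", call. = FALSE)
  }
  if (length(idx) < 2) stop("reference group of size < 2: SD undefined", call. = FALSE)
  n_check <- min(n_check, model$n_components)
  ref <- model$pcs[idx, seq_len(n_check), drop = FALSE]
  ref_mean <- colMeans(ref)
  ref_sd <- apply(ref, 2, stats::sd)
  if (any(ref_sd < 1e-12)) stop("reference group has zero SD on a checked component", call. = FALSE)
  dev <- sweep(abs(sweep(model$pcs[, seq_len(n_check), drop = FALSE], 2, ref_mean)),
               2, ref_sd, "/")
  out <- ifelse(apply(dev, 1, max) > k_sd, "outlier", "reference-like")
  names(out) <- model$sample_ids
  attr(out, "reference_stats") <- data.frame(
    component = colnames(ref), mean = ref_mean, sd = ref_sd, row.names = NULL
  )
  out
}

#' Refit ancestry PCA on a sample subset
#'
#' A full refit on the subset (not a projection of the full-cohort loadings),
#' as appropriate for analyses restricted to a genetically homogeneous
#' subsample.
#'
#' @param gm a `genotype_matrix`.
#' @param sample_subset ids of the samples to refit on.
#' @param n_components,scaling as in [fit_pca()].
#' @return an `ancestry_model` fitted on the subset.
#' @export
refit_subsample <- function(gm, sample_subset, n_components = 20,
                            scaling = c("observed", "binomial")) {
  if (length(sample_subset) == 0) stop("sample_subset is empty", call. = FALSE)
  fit_pca(subset_samples(gm, sample_subset), n_components = n_components,
          scaling = match.arg(scaling))
}

#' Write PC scores as TSV
#'
#' @param model an `ancestry_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pcs <- function(model, path) {
  df <- data.frame(sample_id = model$sample_ids, model$pcs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
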