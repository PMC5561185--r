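# Polygenic hair-colour score: training, pruning, scoring.

vif_one <- function(X, j) {
  # VIF of column j of X given all other columns (plus intercept)
  others <- cbind(1, X[, -j, drop = FALSE])
  fit <- stats::lm.fit(others, X[, j])
  rss <- sum(fit$residuals^2)
  tss <- sum((X[, j] - mean(X[, j]))^2)
  if (tss < 1e-12) return(Inf)
  r2 <- 1 - rss / tss
  1 / max(1 - r2, 1e-12)
}

# VIFs of every column at once via the inverse correlation matrix
# (diag(solve(cor(X))) = 1/(1 - R2_j | others)); falls back to per-column
# regressions when the correlation matrix is numerically singular
vif_all <- function(X) {
  if (ncol(X) == 1L) {
    v <- 1
    names(v) <- colnames(X)
    return(v)
  }
  v <- tryCatch(diag(solve(stats::cor(X))), error = function(e) NULL)
  if (is.null(v) || any(!is.finite(v))) {
    v <- vapply(seq_len(ncol(X)), function(j) vif_one(X, j), numeric(1))
  }
  names(v) <- colnames(X)
  v
}

#' Prune multicollinear candidate SNPs by variance inflation factor
#'
#' Iteratively drops the candidate SNP with the highest VIF - computed as
#' 1/(1 - R^2) of that SNP regressed on all other predictors in the training
#' design (remaining candidates plus covariates) - until every candidate VIF
#' is at or below the threshold. Mirrors the conventional exclusion of one
#' member of a strong-LD pair before score training.
#'
#' @param design numeric matrix of training predictors; columns named; must
#'   contain every candidate SNP column. Covariate columns (e.g. PCs) are part
#'   of each VIF regression but are never dropped.
#' @param candidate_snps column names eligible for dropping.
#' @param vif_threshold maximum tolerated VIF (> 1).
#' @return list with `kept` (candidate names retained), `dropped`
#'   (data.frame `snp_id`, `vif` at time of dropping) and `vif` (final VIFs of
#'   kept candidates).
#' @export
prune_multicollinearity <- function(design, candidate_snps, vif_threshold = 10) {
  if (vif_threshold <= 1) stop("vif_threshold must be > 1", call. = FALSE)
  design <- as.matrix(design)
  if (!all(candidate_snps %in% colnames(design))) {
    stop("candidate_snps must all be columns of the design", call. = FALSE)
  }
  dropped <- data.frame(snp_id = character(0), vif = numeric(0),
                        stringsAsFactors = FALSE)
  repeat {
    cand <- intersect(colnames(design), candidate_snps)
    if (length(cand) == 0) break
    vifs <- vif_all(design)[cand]
    worst <- which.max(vifs)
    if (vifs[worst] <= vif_threshold) {
      return(list(kept = cand, dropped = dropped, vif = vifs))
    }
    dropped <- rbind(dropped, data.frame(snp_id = cand[worst], vif = vifs[worst],
                                         stringsAsFactors = FALSE))
    design <- design[, colnames(design) != cand[worst], drop = FALSE]
  }
  list(kept = character(0), dropped = dropped, vif = numeric(0))
}

#' Train polygenic hair-colour score weights
#'
#' One joint ordinary-least-squares fit of hair colour (7-category, treated
#' continuous) on all post-pruning candidate SNP dosages, plus the
#' standardized ancestry PCs when `ancestry` is supplied (so only SNPs with
#' explanatory power beyond ancestry are selected). Retained score entries
#' are exactly the SNPs with two-sided coefficient p < `alpha`; their weights
#' are the coefficients of that same joint fit (no refit) unless
#' `refit_selected = TRUE`, which refits on the selected subset for
#' sensitivity analysis.
#'
#' @param train_gm `genotype_matrix` of candidate pigmentation SNPs for the
#'   training samples only.
#' @param hair_color numeric vector (1-7, or a continuous pigmentation
#'   phenotype), aligned with `train_gm` samples.
#' @param ancestry optional `ancestry_model`; its standardized PCs (matched by
#'   sample id) enter the model as covariates.
#' @param alpha selection threshold on the two-sided coefficient p-value.
#' @param vif_threshold VIF pruning threshold (see
#'   [prune_multicollinearity()]).
#' @param refit_selected take weights from a refit on the selected SNPs.
#' @return object of class `score_model`.
#' @export
train_weights <- function(train_gm, hair_color, ancestry = NULL, alpha = 0.05,
                          vif_threshold = 10, refit_selected = FALSE) {
  stopifnot(inherits(train_gm, "genotype_matrix"))
  ids <- train_gm$sample_ids
  if (length(hair_color) != length(ids)) {
    stop("hair_color must align with the training samples", call. = FALSE)
  }
  snp_ids <- train_gm$snps$snp_id
  X <- train_gm$dosages
  pcs <- NULL
  if (!is.null(ancestry)) {
    stopifnot(inherits(ancestry, "ancestry_model"))
    idx <- match(ids, ancestry$sample_ids)
    if (anyNA(idx)) stop("ancestry model lacks PCs for some training samples", call. = FALSE)
    pcs <- ancestry$pcs[idx, , drop = FALSE]
  }

  keep_rows <- stats::complete.cases(X) & !is.na(hair_color) &
    (if (is.null(pcs)) TRUE else stats::complete.cases(pcs))
  X <- X[keep_rows, , drop = FALSE]
  y <- hair_color[keep_rows]
  if (!is.null(pcs)) pcs <- pcs[keep_rows, , drop = FALSE]

  design <- if (is.null(pcs)) X else cbind(X, pcs)
  pruned <- prune_multicollinearity(design, snp_ids, vif_threshold)
  kept <- pruned$kept
  if (length(kept) == 0) stop("VIF pruning removed every candidate SNP", call. = FALSE)

  Xk <- X[, kept, drop = FALSE]
  M <- cbind(`(Intercept)` = 1, Xk, pcs)
  fit <- ols_fit(M, y)
  co <- fit$coefficients
  snp_rows <- co[co$term %in% kept, ]
  final_vif <- vif_all(cbind(Xk, pcs))[kept]
  diagnostics <- data.frame(
    snp_id = snp_rows$term, beta = snp_rows$beta, se = snp_rows$se,
    p = snp_rows$p, vif = final_vif[snp_rows$term], stringsAsFactors = FALSE
  )

  selected <- diagnostics$snp_id[diagnostics$p < alpha]
  if (length(selected) < 1) {
    err <- structure(
      class = c("pigbias_no_significant_snps", "error", "condition"),
      list(message = "no SNP reached the selection threshold; diagnostics attached",
           call = sys.call(-1), diagnostics = diagnostics)
    )
    stop(err)
  }
  if (refit_selected) {
    fit2 <- ols_fit(cbind(`(Intercept)` = 1, X[, selected, drop = FALSE], pcs), y)
    co2 <- fit2$coefficients
    weights <- co2$beta[match(selected, co2$term)]
  } else {
    weights <- diagnostics$beta[match(selected, diagnostics$snp_id)]
  }

  dropped <- pruned$dropped
  dropped$reason <- rep("vif", nrow(dropped))
  nonsig <- setdiff(diagnostics$snp_id, selected)
  if (length(nonsig) > 0) {
    dropped <- rbind(dropped, data.frame(snp_id = nonsig, vif = NA_real_,
                                         reason = "nonsignificant",
                                         stringsAsFactors = FALSE))
  }

  ea <- train_gm$snps$effect_allele[match(selected, snp_ids)]
  structure(
    list(
      entries = data.frame(snp_id = selected, effect_allele = ea,
                           weight = weights, stringsAsFactors = FALSE),
      ancestry_adjusted = !is.null(ancestry),
      training_n = fit$n, training_ids = ids,
      diagnostics = diagnostics, dropped = dropped,
      alpha = alpha, vif_threshold = vif_threshold,
      training_adj_r2 = fit$adj_r2
    ),
    class = "score_model"
  )
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("Polygenic hair-colour score: %d SNPs (alpha = %g, %s)\n",
              nrow(x$entries), x$alpha,
              if (x$ancestry_adjusted) "ancestry-adjusted" else "unadjusted"))
  print(x$entries, row.names = FALSE)
  if (nrow(x$dropped) > 0) {
    cat("dropped:", paste(x$dropped$snp_id, " (", x$dropped$reason, ")",
                          sep = "", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compute polygenic scores from a trained model
#'
#' Raw score = sum_j beta_j * dosage_j with dosages aligned to each entry's
#' effect allele (a SNP stored on the opposite allele contributes 2 - dosage;
#' incompatible alleles are an error). Higher score = genetically darker
#' hair. Samples missing any model dosage get a missing score rather than a
#' zero fill. Standardization (mean 0, SD 1) is performed within
#' `standardize_in`.
#'
#' @param gm a `genotype_matrix` containing every model SNP.
#' @param model a `score_model`.
#' @param standardize_in sample ids defining the analysis sample the score is
#'   standardized in; defaults to all samples of `gm`.
#' @param check_split enforce split hygiene: error if any standardization
#'   sample was used in training.
#' @return object of class `score_vector`: data.frame `scores` (`sample_id`,
#'   `raw`, `standardized`) plus the generating model.
#' @export
compute_score <- function(gm, model, standardize_in = NULL, check_split = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(model, "score_model"))
  if (is.null(standardize_in)) standardize_in <- gm$sample_ids
  if (check_split) {
    overlap <- intersect(standardize_in, model$training_ids)
    if (length(overlap) > 0) {
      stop("split hygiene violation: ", length(overlap),
           " sample(s) appear in both the training and scoring sets", call. = FALSE)
    }
  }
  idx <- match(model$entries$snp_id, gm$snps$snp_id)
  if (anyNA(idx)) {
    stop("model SNP(s) absent from genotype matrix: ",
         paste(model$entries$snp_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  D <- gm$dosages[, idx, drop = FALSE]
  for (j in seq_along(idx)) {
    ea_model <- model$entries$effect_allele[j]
    ea_gm <- gm$snps$effect_allele[idx[j]]
    oa_gm <- gm$snps$other_allele[idx[j]]
    if (ea_gm == ea_model) {
      next
    } else if (oa_gm == ea_model) {
      D[, j] <- 2 - D[, j]
    } else {
      stop("allele mismatch for ", model$entries$snp_id[j], ": model effect allele ",
           ea_model, " vs genotypes ", ea_gm, "/", oa_gm, call. = FALSE)
    }
  }
  raw <- drop(D %*% model$entries$weight)
  raw[!stats::complete.cases(D)] <- NA_real_
  names(raw) <- gm$sample_ids

  sidx <- match(standardize_in, gm$sample_ids)
  if (anyNA(sidx)) stop("standardize_in contains unknown sample ids", call. = FALSE)
  std_ref <- raw[sidx]
  std <- tryCatch(standardize(std_ref, "polygenic score"), error = function(e) stop(e))
  z <- (raw - attr(std, "center")) / attr(std, "scale")

  structure(
    list(
      scores = data.frame(sample_id = gm$sample_ids, raw = unname(raw),
                          standardized = unname(z), stringsAsFactors = FALSE),
      standardized_in = standardize_in,
      center = attr(std, "center"), scale = attr(std, "scale"),
      model = model
    ),
    class = "score_vector"
  )
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("Polygenic score for %d samples (standardized in %d); %d missing\n",
              nrow(x$scores), length(x$standardized_in), sum(is.na(x$scores$raw))))
  invisible(x)
}

#' Variance in hair colour explained by the score
#'
#' Simple linear regression of hair colour on the standardized score in the
#' validation sample: reports the adjusted R^2 and the per-SD effect on the
#' colour scale (levels darker per SD of score).
#'
#' @param score a `score_vector`.
#' @param hair_color hair colour (1-7), aligned with `score$scores`.
#' @return list: `adj_r2`, `beta_per_sd`, `se`, `p`, `n`.
#' @export
score_color_r2 <- function(score, hair_color) {
  stopifnot(inherits(score, "score_vector"))
  z <- score$scores$standardized
  keep <- !is.na(z) & !is.na(hair_color) &
    score$scores$sample_id %in% score$standardized_in
  if (sum(keep) < 10) stop("need at least 10 overlapping nonmissing samples", call. = FALSE)
  if (stats::sd(hair_color[keep]) == 0 || stats::sd(z[keep]) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  fit <- ols_fit(cbind(`(Intercept)` = 1, score = z[keep]), hair_color[keep])
  co <- fit$coefficients[fit$coefficients$term == "score", ]
  list(adj_r2 = fit$adj_r2, beta_per_sd = co$beta, se = co$se, p = co$p, n = fit$n)
}

#' Serialize a score model to JSON
#'
#' @param model a `score_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_score_model <- function(model, path) {
  jsonlite::write_json(
    list(entries = model$entries, ancestry_adjusted = model$ancestry_adjusted,
         training_n = model$training_n, alpha = model$alpha,
         vif_threshold = model$vif_threshold, diagnostics = model$diagnostics,
         dropped = model$dropped),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
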