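# Pleiotropy screen: per-SNP associations, darker-hair orientation,
# inverse-variance meta-analysis (Q, I2, REML tau2), Egger asymmetry.
#
# Heterogeneity of the oriented per-SNP outcome effects is used purely as a
# pleiotropy diagnostic: if the pigmentation SNPs affect hair cortisol only
# through hair colour, their oriented effects share one underlying value and
# Q stays near its df; directional pleiotropy additionally shows up as
# funnel-plot asymmetry.

#' Per-SNP hormone association estimates
#'
#' Fits the outcome model for each candidate SNP with the identical covariate
#' structure to the main model, either one model per SNP (`"separate"`) or a
#' single joint model containing all SNPs (`"mutual"`).
#'
#' @param gm `genotype_matrix` holding the candidate SNPs.
#' @param outcome transformed standardized hormone, aligned with `gm` samples.
#' @param covariates data.frame with `sex`, `age_months`, `cs_use` (aligned).
#' @param pcs optional standardized PC matrix (aligned).
#' @param snp_ids SNPs to test; defaults to all SNPs in `gm`.
#' @param mode `"separate"` or `"mutual"`.
#' @return data.frame (`snp_id`, `beta`, `se`, `t`, `p`, `n`) with the list of
#'   full fits in attribute `fits` (one per model).
#' @export
per_snp_associations <- function(gm, outcome, covariates, pcs = NULL,
                                 snp_ids = NULL, mode = c("separate", "mutual")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(snp_ids)) snp_ids <- gm$snps$snp_id
  D <- gm$dosages[, match(snp_ids, gm$snps$snp_id), drop = FALSE]
  if (mode == "separate") {
    fits <- lapply(seq_along(snp_ids), function(j) {
      fit_association(outcome, D[, j], covariates, pcs,
                      predictor_name = snp_ids[j],
                      label = paste0("separate:", snp_ids[j]))
    })
    rows <- lapply(fits, function(f) coef_row(f)[, c("term", "beta", "se", "t", "p")])
    out <- do.call(rbind, rows)
    out$n <- vapply(fits, function(f) f$n, numeric(1))
  } else {
    X <- cbind(`(Intercept)` = 1, D,
               sex = covariates$sex, age_months = covariates$age_months,
               cs_use = covariates$cs_use, pcs)
    fit <- ols_fit(X, outcome)
    co <- fit$coefficients
    out <- co[co$term %in% snp_ids, c("term", "beta", "se", "t", "p")]
    out$n <- fit$n
    fits <- list(fit)
  }
  names(out)[1] <- "snp_id"
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Orient per-SNP estimates to the darker-hair allele
#'
#' Negates an estimate exactly when its SNP's hair-colour weight in the score
#' model is negative, so every oriented effect is expressed per darker-hair
#' allele. Standard errors are unchanged. Orientation is an involution:
#' applying it twice returns the original estimates.
#'
#' @param estimates data.frame with `snp_id`, `beta`, `se`.
#' @param score_model a `score_model` (or any data.frame with `snp_id` and
#'   `weight` columns) supplying the hair-colour weights.
#' @return data.frame (`snp_id`, `beta`, `se`, `flipped`).
#' @export
orient_effects <- function(estimates, score_model) {
  weights <- if (inherits(score_model, "score_model")) score_model$entries else score_model
  idx <- match(estimates$snp_id, weights$snp_id)
  if (anyNA(idx)) {
    stop("SNP(s) absent from score model: ",
         paste(estimates$snp_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  w <- weights$weight[idx]
  flip <- w < 0
  data.frame(
    snp_id = estimates$snp_id,
    beta = ifelse(flip, -estimates$beta, estimates$beta),
    se = estimates$se, flipped = flip, stringsAsFactors = FALSE
  )
}

reml_tau2 <- function(y, v) {
  nll <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  upper <- max(stats::var(y) * 10, max(v) * 10, 1e-6)
  opt <- stats::optimize(nll, c(0, upper), tol = 1e-12)
  if (nll(0) <= opt$objective) 0 else opt$minimum
}

#' Inverse-variance-weighted meta-analysis with heterogeneity statistics
#'
#' Fixed-effect pooling with weights 1/SE^2; Cochran's Q with df = k - 1 and
#' its chi-square p-value; Higgins I2 = max(0, (Q - df)/Q) * 100; and a
#' tau^2-based I2 using the restricted-maximum-likelihood between-study
#' variance, i2_tau = tau2/(tau2 + s2) * 100 with typical within-study
#' variance s2 = (k-1) * sum(w) / ((sum w)^2 - sum(w^2)). Both I2 variants are
#' reported because they can differ noticeably at small k.
#'
#' @param estimates data.frame with `beta` and `se` (e.g. from
#'   [orient_effects()]), or two numeric vectors via `beta`/`se`.
#' @param beta,se alternative vector interface.
#' @return object of class `meta_result`.
#' @export
meta_ivw <- function(estimates = NULL, beta = NULL, se = NULL) {
  if (!is.null(estimates)) {
    beta <- estimates$beta
    se <- estimates$se
  }
  k <- length(beta)
  if (k < 2) stop("meta-analysis needs at least 2 estimates", call. = FALSE)
  if (any(se <= 0)) stop("all standard errors must be positive", call. = FALSE)
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  Q <- sum(w * (beta - pooled)^2)
  df <- k - 1
  p_Q <- stats::pchisq(Q, df, lower.tail = FALSE)
  i2_q <- max(0, (Q - df) / Q) * 100
  if (Q == 0) i2_q <- 0
  s2 <- df * sum(w) / (sum(w)^2 - sum(w^2))
  tau2 <- reml_tau2(beta, se^2)
  i2_tau <- tau2 / (tau2 + s2) * 100
  structure(
    list(k = k, pooled_fixed = c(beta = pooled, se = pooled_se),
         Q = Q, df = df, p_Q = p_Q, i2_q = i2_q,
         tau2_reml = tau2, i2_tau = i2_tau, s2_typical = s2,
         estimates = data.frame(beta = beta, se = se)),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("IVW meta-analysis of %d estimates\n", x$k))
  cat(sprintf("  pooled beta = %.4f (SE %.4f)\n",
              x$pooled_fixed["beta"], x$pooled_fixed["se"]))
  cat(sprintf("  Q = %.2f (df = %d, p = %.3f); I2 = %.1f%% (Q-based), %.1f%% (REML tau2)\n",
              x$Q, x$df, x$p_Q, x$i2_q, x$i2_tau))
  invisible(x)
}

#' Egger funnel-asymmetry test
#'
#' Weighted regression of the effect estimates on their standard errors with
#' weights 1/SE^2 (Egger form; algebraically identical, for the intercept
#' test, to regressing z-scores on precision). A nonzero slope term captures
#' small-study-style asymmetry; here it screens for directional pleiotropy.
#'
#' @param estimates data.frame with `beta` and `se` (k >= 3, SEs not all
#'   identical).
#' @return list: `intercept`, `intercept_se`, `intercept_p` (the limit
#'   estimate as SE -> 0), `slope`, `slope_se`, `slope_p` (the asymmetry
#'   test), `funnel` (data.frame of beta vs SE for plotting).
#' @export
egger_test <- function(estimates) {
  beta <- estimates$beta
  se <- estimates$se
  k <- length(beta)
  if (k < 3) stop("Egger test needs at least 3 estimates", call. = FALSE)
  if (stats::sd(se) < 1e-12) {
    stop("asymmetry untestable: all standard errors identical", call. = FALSE)
  }
  W <- diag(1 / se^2)
  X <- cbind(1, se)
  XtWX <- t(X) %*% W %*% X
  cf <- solve(XtWX, t(X) %*% W %*% beta)
  res <- beta - X %*% cf
  df <- k - 2
  sigma2 <- sum((res^2) / se^2) / df
  vc <- solve(XtWX) * sigma2
  ses <- sqrt(diag(vc))
  tv <- cf / ses
  pv <- 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
  list(intercept = cf[1], intercept_se = ses[1], intercept_p = pv[1],
       slope = cf[2], slope_se = ses[2], slope_p = pv[2],
       df = df, funnel = data.frame(beta = beta, se = se))
}

#' Exhaustive orientation sensitivity analysis
#'
#' When the per-SNP darker-hair orientation is unknown (e.g. effect-allele
#' annotations unavailable), enumerates all 2^(k-1) distinct sign patterns
#' (Q is invariant to a global flip) and returns the heterogeneity statistic
#' of each, so the attainable Q range and the pattern consistent with external
#' information can be identified.
#'
#' @param beta,se per-SNP estimates and standard errors.
#' @return data.frame with one row per pattern: `pattern` (string of +/-),
#'   `Q`, `pooled`; sorted by Q.
#' @export
orientation_search <- function(beta, se) {
  k <- length(beta)
  if (k < 2 || k > 16) stop("orientation_search supports 2..16 estimates", call. = FALSE)
  w <- 1 / se^2
  m <- 0:(2^(k - 1) - 1)
  res <- lapply(m, function(mask) {
    s <- c(1, ifelse(bitwAnd(mask, 2^(0:(k - 2))) > 0, -1, 1))
    b <- s * beta
    pooled <- sum(w * b) / sum(w)
    data.frame(pattern = paste(ifelse(s > 0, "+", "-"), collapse = ""),
               Q = sum(w * (b - pooled)^2), pooled = pooled,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$Q), ]
}
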