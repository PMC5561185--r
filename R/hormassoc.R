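# Hormone outcome models: Box-Cox transformation, association fits,
# variance decomposition, and Cohen's f2 power.

boxcox_loglik <- function(lambda, y, qr_design, logy_sum, n) {
  z <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  rss <- sum(qr.resid(qr_design, z)^2)
  -n / 2 * log(rss / n) + (lambda - 1) * logy_sum
}

# profile log-likelihood on a whole lambda grid at once: transforms for all
# lambdas are built in one outer product and residual sums of squares come
# from a single projection onto the design's orthonormal basis
boxcox_loglik_grid <- function(lambdas, y, Qbasis, logy_sum, n) {
  logy <- log(y)
  n_y <- length(y)
  Z <- exp(outer(logy, lambdas))
  nz <- abs(lambdas) >= 1e-12
  Z[, nz] <- (Z[, nz, drop = FALSE] - 1) * rep(1 / lambdas[nz], each = n_y)
  if (any(!nz)) Z[, !nz] <- logy
  rss <- colSums(Z^2) - colSums(crossprod(Qbasis, Z)^2)
  -n / 2 * log(rss / n) + (lambdas - 1) * logy_sum
}

#' Fit the Box-Cox exponent by profile likelihood
#'
#' Maximizes the Box-Cox regression profile log-likelihood (including the
#' Jacobian term (lambda - 1) * sum(log y)) over the grid `[-2, 2]` in steps
#' of 0.01, then refines the maximum by golden-section search to 1e-4.
#' By default lambda is fitted on the full main model (the supplied design),
#' not just an intercept, matching the practice of choosing the transform for
#' the model actually reported.
#'
#' @param y strictly positive outcomes.
#' @param design covariate matrix including an intercept column; defaults to
#'   intercept only.
#' @return the fitted lambda (scalar), with the profile grid in attribute
#'   `profile`.
#' @export
fit_boxcox_lambda <- function(y, design = NULL) {
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("Box-Cox requires strictly positive outcomes", call. = FALSE)
  }
  n <- length(y)
  if (is.null(design)) design <- matrix(1, n, 1)
  design <- as.matrix(design)
  stopifnot(nrow(design) == n)
  qr_design <- qr(design)
  logy_sum <- sum(log(y))

  grid <- seq(-2, 2, by = 0.01)
  ll <- boxcox_loglik_grid(grid, y, qr.Q(qr_design), logy_sum, n)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(boxcox_loglik, c(lo, hi), y = y, qr_design = qr_design,
                         logy_sum = logy_sum, n = n, maximum = TRUE, tol = 1e-4)
  lambda <- opt$maximum
  attr(lambda, "profile") <- data.frame(lambda = grid, loglik = ll)
  lambda
}

#' Build a Box-Cox transform specification
#'
#' The transform is t(y) = sign_factor * y^lambda (log y at lambda = 0), with
#' sign_factor = -1 exactly when lambda < 0 so the transform is monotone
#' increasing in y for every lambda ("multiplied by -1 to keep
#' directionality"). After standardization this is affinely identical to the
#' canonical (y^lambda - 1)/lambda form. The standardization mean/SD are
#' computed on `y` and frozen into the spec.
#'
#' @param y strictly positive outcomes defining the standardization.
#' @param lambda Box-Cox exponent.
#' @return object of class `transform_spec` with fields `lambda`,
#'   `sign_factor`, `mean`, `sd`.
#' @export
boxcox_spec <- function(y, lambda) {
  if (any(y <= 0)) stop("Box-Cox requires strictly positive outcomes", call. = FALSE)
  lambda <- as.numeric(lambda)
  sign_factor <- if (lambda < 0) -1 else 1
  t <- if (abs(lambda) < 1e-12) log(y) else sign_factor * y^lambda
  s <- stats::sd(t)
  if (!is.finite(s) || s <= 0) stop("zero post-transform variance", call. = FALSE)
  structure(list(lambda = lambda, sign_factor = sign_factor,
                 mean = mean(t), sd = s),
            class = "transform_spec")
}

#' Apply a Box-Cox transform specification
#'
#' @param y strictly positive outcomes.
#' @param spec a `transform_spec` from [boxcox_spec()].
#' @return transformed, standardized outcome (monotone increasing in `y`).
#' @export
transform_outcome <- function(y, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  if (any(!is.na(y) & y <= 0)) stop("Box-Cox requires strictly positive outcomes", call. = FALSE)
  t <- if (abs(spec$lambda) < 1e-12) log(y) else spec$sign_factor * y^spec$lambda
  (t - spec$mean) / spec$sd
}

#' Fit a hormone association model
#'
#' OLS of the transformed, standardized hormone on a predictor (polygenic
#' score, reported hair colour, or a single-SNP dosage) with the standard
#' covariates (sex, age in months, corticosteroid use) and, optionally, 20
#' standardized ancestry PCs. Rows with any missing value are dropped
#' (listwise deletion). Analytic OLS standard errors; the full coefficient
#' table (including every PC term) is returned, together with per-term VIFs.
#'
#' @param outcome transformed standardized hormone vector.
#' @param predictor numeric predictor vector (standardize continuous scores
#'   beforehand), or NULL for a covariates-only model.
#' @param covariates data.frame with `sex`, `age_months`, `cs_use` (aligned).
#' @param pcs optional samples x components matrix of standardized PCs.
#' @param predictor_name label for the predictor row of the table.
#' @param label model label stored in the result.
#' @return object of class `association_fit`: `terms` (term, beta, se, t, p,
#'   vif), `n`, `adj_r2`, `max_vif`, `label`.
#' @export
fit_association <- function(outcome, predictor, covariates, pcs = NULL,
                            predictor_name = "predictor", label = predictor_name) {
  stopifnot(all(c("sex", "age_months", "cs_use") %in% names(covariates)))
  C <- cbind(sex = covariates$sex, age_months = covariates$age_months,
             cs_use = covariates$cs_use)
  X <- cbind(`(Intercept)` = 1,
             if (!is.null(predictor)) matrix(predictor, ncol = 1,
                                             dimnames = list(NULL, predictor_name)),
             C, pcs)
  fit <- ols_fit(X, outcome)
  Xc <- X[fit$kept, -1, drop = FALSE]
  vifs <- vif_all(Xc)
  terms <- fit$coefficients
  terms$vif <- c(NA_real_, vifs)
  structure(
    list(terms = terms, n = fit$n, df = fit$df, adj_r2 = fit$adj_r2, r2 = fit$r2,
         max_vif = max(vifs), label = label),
    class = "association_fit"
  )
}

#' @export
print.association_fit <- function(x, ...) {
  cat(sprintf("Association model '%s' (n = %d, adj R2 = %.3f, max VIF = %.2f)\n",
              x$label, x$n, x$adj_r2, x$max_vif))
  print(utils::head(x$terms, 6), row.names = FALSE, digits = 3)
  if (nrow(x$terms) > 6) cat("  ... ", nrow(x$terms) - 6, " more terms\n")
  invisible(x)
}

#' Extract one coefficient row from an association fit
#'
#' @param fit an `association_fit`.
#' @param term term name (default: the second row, i.e. the predictor).
#' @return one-row data.frame (term, beta, se, t, p, vif).
#' @export
coef_row <- function(fit, term = NULL) {
  if (is.null(term)) return(fit$terms[2, , drop = FALSE])
  row <- fit$terms[fit$terms$term == term, , drop = FALSE]
  if (nrow(row) == 0) stop("no term '", term, "' in the fit", call. = FALSE)
  row
}

#' Adjusted R-squared of named predictor sets
#'
#' One simple OLS of the outcome per named set (e.g. score alone; 20 PCs;
#' origin-group dummies), reporting adjusted R^2 in percent. Character or
#' factor sets are dummy coded with the first level as reference.
#'
#' @param outcome numeric outcome.
#' @param predictor_sets named list; each element a vector, matrix or
#'   data.frame aligned with `outcome`.
#' @return data.frame (`set`, `adj_r2_pct`, `n`).
#' @export
variance_explained <- function(outcome, predictor_sets) {
  stopifnot(is.list(predictor_sets), length(names(predictor_sets)) == length(predictor_sets))
  rows <- lapply(names(predictor_sets), function(nm) {
    x <- predictor_sets[[nm]]
    if (is.null(x) || NROW(x) == 0) stop("empty predictor set: ", nm, call. = FALSE)
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    chr <- vapply(df, function(c) is.character(c) || is.factor(c), logical(1))
    for (j in which(chr)) {
      if (length(unique(df[[j]][!is.na(df[[j]])])) < 2) {
        stop("predictor set '", nm, "' has a single level", call. = FALSE)
      }
      df[[j]] <- factor(df[[j]])
    }
    rownames(df) <- NULL
    keep <- stats::complete.cases(df) & !is.na(outcome)
    mm <- stats::model.matrix(~ ., data = df[keep, , drop = FALSE])
    fit <- ols_fit(mm, outcome[keep])
    data.frame(set = nm, adj_r2_pct = 100 * fit$adj_r2, n = fit$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Local Cohen's f2 of a tested term
#'
#' f2 = (R2_full - R2_reduced) / (1 - R2_full).
#'
#' @param r2_full R^2 of the full model.
#' @param r2_reduced R^2 of the model without the tested term(s).
#' @return f2 (scalar).
#' @export
local_f2 <- function(r2_full, r2_reduced) {
  if (r2_full >= 1) stop("r2_full must be < 1", call. = FALSE)
  if (r2_reduced > r2_full || r2_reduced < 0) {
    stop("need 0 <= r2_reduced <= r2_full", call. = FALSE)
  }
  (r2_full - r2_reduced) / (1 - r2_full)
}

#' Power of the F test for a local Cohen's f2
#'
#' Noncentral-F power with numerator df `u`, denominator df
#' v = n - n_terms - 1, and noncentrality f2 * (u + v + 1) (the conventional
#' Cohen framework). At f2 = 0 the power equals alpha exactly.
#'
#' @param f2 local effect size (>= 0).
#' @param u numerator degrees of freedom.
#' @param n sample size.
#' @param n_terms number of model terms including the tested one (intercept
#'   excluded).
#' @param alpha test level.
#' @return object of class `power_result`: `f2`, `u`, `v`, `alpha`, `power`.
#' @export
power_f2 <- function(f2, u, n, n_terms, alpha = 0.05) {
  if (f2 < 0) stop("f2 must be nonnegative", call. = FALSE)
  v <- n - n_terms - 1
  if (v <= 0) stop("nonpositive denominator df: n too small for the model", call. = FALSE)
  ncp <- f2 * (u + v + 1)
  crit <- stats::qf(1 - alpha, u, v)
  power <- stats::pf(crit, u, v, ncp = ncp, lower.tail = FALSE)
  structure(list(f2 = f2, u = u, v = v, alpha = alpha, power = power),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Power = %.1f%% (f2 = %g, F(%d, %d), alpha = %g)\n",
              100 * x$power, x$f2, x$u, x$v, x$alpha))
  invisible(x)
}
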