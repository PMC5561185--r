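# Shared fixture builders and independent oracles.

# small genotype matrix with explicit dosages (samples x SNPs)
tiny_gm <- function(dosages, effect = NULL, other = NULL, imp_r2 = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(effect)) effect <- rep("A", m)
  if (is.null(other)) other <- rep("G", m)
  if (is.null(imp_r2)) imp_r2 <- rep(NA_real_, m)
  ids <- sprintf("S%03d", seq_len(nrow(dosages)))
  snps <- data.frame(
    snp_id = if (is.null(colnames(dosages))) sprintf("snp%02d", seq_len(m)) else colnames(dosages),
    chrom = "1", pos = seq_len(m) * 100L,
    effect_allele = effect, other_allele = other,
    imputation_r2 = imp_r2, call_rate = 1, stringsAsFactors = FALSE
  )
  new_genotype_matrix(ids, snps, dosages)
}

# brute-force HWE enumeration oracle: exact conditional probabilities of
# every heterozygote count from log-factorials, no recurrence
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n_aa + n_Aa
  rare <- min(n_A, n_a)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hs, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(n_A) + lfactorial(n_a) - lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# normal-equations OLS oracle
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  list(beta = drop(beta), se = se)
}

# a pair of columns with an exact sample correlation r
correlated_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  e <- stats::rnorm(n)
  e <- residuals(stats::lm(e ~ x))
  xs <- drop(scale(x))
  es <- drop(scale(e))
  cbind(x1 = xs, x2 = r * xs + sqrt(1 - r^2) * es)
}

# quick small-cohort configuration for module tests
fast_config <- function(...) {
  args <- list(n_samples = 600L, n_background_snps = 150L, train_fraction = 0.5)
  override <- list(...)
  args[names(override)] <- override
  do.call(scenario_config, args)
}
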