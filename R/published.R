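# Published reference inputs for the pleiotropy screen and power analysis.

#' Published per-SNP hair-cortisol estimates for the nine score SNPs
#'
#' Ancestry-adjusted separate-model association estimates (beta, SE; outcome:
#' standardized Box-Cox hair cortisol, per effect allele) for the nine
#' HIrisPlex pigmentation SNPs retained in a published ancestry-adjusted
#' polygenic hair-colour score, as printed (2 decimals) in the source study's
#' per-SNP association table for its multi-ancestry child sample (n = 1674).
#'
#' The sign of each SNP's hair-colour training weight (`weight_sign`) - which
#' defines the darker-hair orientation of the pleiotropy meta-analysis - was
#' not printed. It is reconstructed here by exhaustive search over all sign
#' patterns ([orientation_search()]): the pattern below is the unique one
#' whose oriented estimates reproduce both the published Cochran Q and the
#' published REML-tau2-based I2, and it is biologically coherent (the flipped
#' SNPs carry known lightening alleles at SLC24A4, KITLG, IRF4, MC1R and the
#' SLC45A2 region).
#'
#' @return data.frame: `snp_id`, `beta`, `se`, `weight_sign` (+1/-1), and
#'   `weight` (= `weight_sign`, for direct use with [orient_effects()]).
#' @export
pigmentation_snp_estimates <- function() {
  d <- data.frame(
    snp_id = c("rs885479", "rs1805008", "rs1805007", "rs28777", "rs12896399",
               "rs1042602", "rs1393350", "rs12821256", "rs12203592"),
    beta = c(-0.01, 0.14, 0.04, -0.10, -0.01, -0.04, 0.08, 0.02, -0.16),
    se = c(0.07, 0.07, 0.08, 0.06, 0.04, 0.04, 0.04, 0.06, 0.06),
    weight_sign = c(-1, 1, 1, -1, -1, 1, 1, -1, -1),
    stringsAsFactors = FALSE
  )
  d$weight <- d$weight_sign
  d
}

#' Published power-analysis parameters
#'
#' The fully adjusted pigmentation effect in the published multi-ancestry
#' analysis had local Cohen's f2 = 0.006 (rounded to one significant digit);
#' the main model has 24 terms (polygenic score + sex + age + corticosteroid
#' use + 20 ancestry PCs, intercept excluded). Cortisol analysis sample sizes:
#' 1674 (multi-ancestry) and 867 (genetically European subsample).
#'
#' @return list: `f2`, `u`, `n_terms`, `n_multi`, `n_european`, `alpha`.
#' @export
published_power_params <- function() {
  list(f2 = 0.006, u = 1, n_terms = 24, n_multi = 1674, n_european = 867,
       alpha = 0.05)
}
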