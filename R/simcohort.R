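# Synthetic admixed-cohort generator.
#
# The generator realizes the three competing explanations of the hair colour /
# hair cortisol association as explicit causal scenarios on simulated data:
#   * "local"          - pigmentation genetic value affects measured hormone in
#                        the hair shaft itself (direct effect),
#   * "stratification" - ancestry affects systemic hormone levels and, through
#                        allele frequencies, hair colour (pure confounding),
#   * "stress"         - membership of a minority group raises hormone levels,
#   * "mixed"          - local + stratification together,
#   * "null"           - neither.
# Allele frequencies follow the Balding-Nichols model; individual ancestry is
# Dirichlet-distributed so the cohort is continuously admixed.

# Marginal hair-colour distribution targeted by the default threshold
# calibration (7 categories, sandy red ... brownish black/black), as observed
# in a multi-ancestry child cohort's hormone sample.
hair_color_targets <- c(0.02, 0.01, 0.26, 0.26, 0.19, 0.15, 0.11)

default_pigment_weights <- c(
  0.40, 0.35, 0.35, 0.30, -0.30, 0.28, -0.25, 0.25, 0.22, -0.20,
  0.18, 0.15, -0.15, 0.12, 0.10, 0.45, 0.42
)

#' Scenario configuration for the synthetic cohort generator
#'
#' Collects every knob of the generative model with defaults emulating a
#' highly admixed child cohort: n = 3262 samples (split about 1565 training /
#' 1697 validation), four ancestral populations at FST 0.1, 17 candidate
#' pigmentation SNPs whose allele frequencies diverge three times more than
#' the genomic background (so hair colour tracks ancestry), 7-category hair
#' colour calibrated to the observed marginal distribution, and right-skewed
#' (lognormal) hormone concentrations in pg/mg.
#'
#' @param scenario one of `"null"`, `"local"`, `"stratification"`, `"stress"`,
#'   `"mixed"`. Selecting a non-null scenario fills in the matching default
#'   effect size unless given explicitly.
#' @param n_samples number of children.
#' @param n_populations number of ancestral populations.
#' @param fst Balding-Nichols divergence of the genomic background, in (0,1).
#' @param admixture_alpha Dirichlet concentration vector (length
#'   `n_populations`); the default gives a ~65% majority-ancestry mean with
#'   heavy admixture.
#' @param n_background_snps genome-wide background SNPs used for ancestry PCA.
#' @param n_pigment_snps candidate pigmentation SNPs (including the LD pair).
#' @param pigment_weights per-SNP liability effects on hair-colour darkness.
#' @param ancestry_color_shift liability shift per SD of non-European ancestry.
#' @param b_local standardized direct hormone effect of the pigmentation
#'   genetic value (log scale).
#' @param b_systemic hormone effect per SD of non-European ancestry
#'   (stratification) or per minority-group membership (stress), log scale.
#' @param hormone_mu,hormone_sigma log-scale location/spread of cortisol
#'   (pg/mg); defaults reproduce observed quartiles 0.91/1.65/3.26.
#' @param cortisone_mu,cortisone_sigma same for cortisone (median 7.78 pg/mg).
#' @param covariate_effects named list of log-scale effects `sex`, `age`
#'   (per month, centred at 74), `cs` (corticosteroid use).
#' @param noise_sd SD of the hair-colour liability noise.
#' @param pigment_fst_multiplier extra allele-frequency divergence of the
#'   pigmentation SNPs relative to `fst`.
#' @param pigment_ancestry_logit_shift directional log-odds shift of each
#'   pigmentation SNP's frequency in the non-European populations, applied in
#'   the direction of its darkness weight (darkening alleles more frequent
#'   outside Europe). This makes hair colour track ancestry consistently, as
#'   in real admixed cohorts where the European subsample is almost entirely
#'   blond/dark blond.
#' @param ld_pair simulate the last two pigmentation SNPs in high LD (exercises
#'   VIF pruning)?
#' @param ld_r2 target squared correlation of the LD pair.
#' @param train_fraction fraction of samples assigned to the training split.
#' @param dosage_noise_sd when > 0, jitter hard genotypes into fractional
#'   dosages in `[0, 2]` (imputation-like data).
#' @param seed master random seed.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("null", "local", "stratification", "stress", "mixed"),
                            n_samples = 3262L,
                            n_populations = 4L,
                            fst = 0.1,
                            admixture_alpha = c(0.8, 0.15, 0.15, 0.15),
                            n_background_snps = 1250L,
                            n_pigment_snps = 17L,
                            pigment_weights = NULL,
                            ancestry_color_shift = 0.5,
                            b_local = NULL,
                            b_systemic = NULL,
                            hormone_mu = log(1.65),
                            hormone_sigma = 1.0,
                            cortisone_mu = log(7.78),
                            cortisone_sigma = 0.70,
                            covariate_effects = list(sex = -0.15, age = 0, cs = 0.3),
                            noise_sd = 1.5,
                            pigment_fst_multiplier = 3,
                            pigment_ancestry_logit_shift = 1.75,
                            ld_pair = TRUE,
                            ld_r2 = 0.92,
                            train_fraction = 1565 / 3262,
                            dosage_noise_sd = 0,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(b_local)) {
    b_local <- if (scenario %in% c("local", "mixed")) 0.08 else 0
  }
  if (is.null(b_systemic)) {
    b_systemic <- if (scenario %in% c("stratification", "stress", "mixed")) 0.35 else 0
  }
  assert_scalar_in(fst, 0, 1, "fst", open = TRUE)
  if (hormone_sigma <= 0 || cortisone_sigma <= 0) stop("hormone_sigma must be > 0", call. = FALSE)
  if (n_samples < 0 || n_populations < 1 || n_background_snps < 1 || n_pigment_snps < 1) {
    stop("all counts must be positive", call. = FALSE)
  }
  if (is.null(pigment_weights)) {
    pigment_weights <- rep_len(default_pigment_weights, n_pigment_snps)
  }
  if (length(pigment_weights) != n_pigment_snps) {
    stop("pigment_weights must have length n_pigment_snps (", n_pigment_snps, ")", call. = FALSE)
  }
  if (length(admixture_alpha) != n_populations) {
    stop("admixture_alpha must have length n_populations", call. = FALSE)
  }
  if (scenario == "null" && (b_local != 0 || b_systemic != 0)) {
    stop("scenario = 'null' requires b_local = b_systemic = 0", call. = FALSE)
  }
  structure(
    list(
      scenario = scenario, n_samples = as.integer(n_samples),
      n_populations = as.integer(n_populations), fst = fst,
      admixture_alpha = admixture_alpha,
      n_background_snps = as.integer(n_background_snps),
      n_pigment_snps = as.integer(n_pigment_snps),
      pigment_weights = pigment_weights,
      ancestry_color_shift = ancestry_color_shift,
      b_local = b_local, b_systemic = b_systemic,
      hormone_mu = hormone_mu, hormone_sigma = hormone_sigma,
      cortisone_mu = cortisone_mu, cortisone_sigma = cortisone_sigma,
      covariate_effects = covariate_effects, noise_sd = noise_sd,
      pigment_fst_multiplier = pigment_fst_multiplier,
      pigment_ancestry_logit_shift = pigment_ancestry_logit_shift,
      ld_pair = isTRUE(ld_pair), ld_r2 = ld_r2,
      train_fraction = train_fraction, dosage_noise_sd = dosage_noise_sd,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario configuration:", x$scenario, "\n")
  cat(sprintf("  n = %d, %d populations, FST = %.3g (pigment x%g)\n",
              x$n_samples, x$n_populations, x$fst, x$pigment_fst_multiplier))
  cat(sprintf("  SNPs: %d pigmentation + %d background; LD pair: %s\n",
              x$n_pigment_snps, x$n_background_snps, x$ld_pair))
  cat(sprintf("  b_local = %g, b_systemic = %g, seed = %d\n",
              x$b_local, x$b_systemic, x$seed))
  invisible(x)
}

qlogis_mat <- function(f) log(f / (1 - f))

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Draw per-population allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are uniform on `[0.05, 0.95]`; each population's
#' frequency is Beta(p(1-F)/F, (1-p)(1-F)/F), i.e. mean p and variance
#' F p (1-p).
#'
#' @param n_snps number of variants.
#' @param n_populations number of populations (rows of the result).
#' @param fst divergence parameter in (0,1).
#' @param seed optional seed (local RNG stream).
#' @return `n_populations` x `n_snps` matrix of frequencies in (0,1), with the
#'   ancestral frequencies in attribute `ancestral`.
#' @export
draw_population_freqs <- function(n_snps, n_populations, fst, seed = NULL) {
  assert_scalar_in(fst, 0, 1, "fst", open = TRUE)
  with_seed(seed, {
    p <- stats::runif(n_snps, 0.05, 0.95)
    shape <- (1 - fst) / fst
    f <- matrix(
      stats::rbeta(n_populations * n_snps,
                   rep(p * shape, each = n_populations),
                   rep((1 - p) * shape, each = n_populations)),
      nrow = n_populations
    )
    f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
    attr(f, "ancestral") <- p
    f
  })
}

#' Simulate admixed genotypes
#'
#' Per-sample admixture proportions are Dirichlet(`admixture_alpha`); the
#' genotype at SNP m is Binomial(2, q' p_m) given the sample's proportions q.
#'
#' @param freqs population x SNP allele-frequency matrix
#'   (from [draw_population_freqs()]).
#' @param admixture_alpha Dirichlet concentration vector, one per population.
#' @param n_samples number of samples (0 gives an empty matrix).
#' @param seed optional seed.
#' @param dosage_noise_sd when > 0, add truncated Gaussian noise so dosages are
#'   fractional in `[0, 2]`.
#' @return list with `dosages` (samples x SNPs) and `ancestry` (samples x
#'   populations, rows summing to 1).
#' @export
simulate_genotypes <- function(freqs, admixture_alpha, n_samples, seed = NULL,
                               dosage_noise_sd = 0) {
  if (!is.matrix(freqs) || nrow(freqs) == 0L || ncol(freqs) == 0L) {
    stop("freqs must be a nonempty population x SNP matrix", call. = FALSE)
  }
  if (length(admixture_alpha) != nrow(freqs)) {
    stop("admixture_alpha must have one entry per population", call. = FALSE)
  }
  m <- ncol(freqs)
  if (n_samples == 0L) {
    return(list(dosages = matrix(numeric(0), 0, m), ancestry = matrix(numeric(0), 0, nrow(freqs))))
  }
  with_seed(seed, {
    q <- rdirichlet(n_samples, admixture_alpha)
    pi <- q %*% freqs
    # Binomial(2, pi) by inversion of a single uniform:
    # P(g = 2) = pi^2, P(g >= 1) = 1 - (1 - pi)^2 = pi (2 - pi)
    u <- matrix(stats::runif(n_samples * m), n_samples)
    g <- (u < pi^2) + (u < pi * (2 - pi))
    storage.mode(g) <- "double"
    if (dosage_noise_sd > 0) {
      g <- pmin(pmax(g + stats::rnorm(length(g), 0, dosage_noise_sd), 0), 2)
    }
    list(dosages = g, ancestry = q)
  })
}

#' Assign 7-category hair colour from a liability model
#'
#' Latent liability = sum_j w_j dosage_j + shift * ancestry score +
#' N(0, noise_sd); categories 1 ("sandy red") to 7 ("brownish black/black")
#' are cut at `thresholds`. With `thresholds = NULL` the six cutpoints are
#' calibrated to the empirical liability quantiles that reproduce the observed
#' marginal distribution (2/1/26/26/19/15/11 percent).
#'
#' @param genotypes samples x pigmentation-SNP dosage matrix.
#' @param pigment_weights per-SNP liability weights.
#' @param ancestry_color_shift liability shift per unit of `ancestry_score`.
#' @param ancestry_score per-sample ancestry score (standardized non-European
#'   ancestry); defaults to 0.
#' @param thresholds six strictly increasing cutpoints, or NULL to calibrate.
#' @param noise_sd liability noise SD.
#' @param seed optional seed.
#' @return integer vector of categories 1-7, with the cutpoints in attribute
#'   `thresholds` and the latent liability in attribute `liability`.
#' @export
simulate_hair_color <- function(genotypes, pigment_weights,
                                ancestry_color_shift = 0, ancestry_score = NULL,
                                thresholds = NULL, noise_sd = 0.6, seed = NULL) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != length(pigment_weights)) {
    stop("pigment_weights must match the number of genotype columns", call. = FALSE)
  }
  n <- nrow(genotypes)
  if (is.null(ancestry_score)) ancestry_score <- rep(0, n)
  liability <- with_seed(seed, {
    drop(genotypes %*% pigment_weights) + ancestry_color_shift * ancestry_score +
      stats::rnorm(n, 0, noise_sd)
  })
  if (is.null(thresholds)) {
    thresholds <- stats::quantile(liability, cumsum(hair_color_targets)[1:6],
                                  names = FALSE, type = 7)
  }
  if (length(thresholds) != 6L || any(diff(thresholds) <= 0)) {
    stop("thresholds must be 6 strictly increasing cutpoints", call. = FALSE)
  }
  color <- 1L + findInterval(liability, thresholds)
  attr(color, "thresholds") <- thresholds
  attr(color, "liability") <- liability
  color
}

#' Simulate hair hormone concentrations (pg/mg)
#'
#' Log-concentration = mu + b_local * standardized pigmentation genetic value
#' + b_systemic * S + covariate terms + sigma * N(0, 1), where S is the
#' standardized non-European ancestry score (scenario `"stratification"`), the
#' minority-group indicator (`"stress"`), or absent (`"local"`, `"null"`;
#' `"mixed"` uses the stratification S).
#'
#' @param config a [scenario_config()].
#' @param pigment_value per-sample latent pigmentation genetic value.
#' @param ancestry samples x populations admixture matrix (column 1 is the
#'   majority/European population).
#' @param covariates data.frame with `sex`, `age_months`, `cs_use`.
#' @param seed optional seed.
#' @param hormone `"cortisol"` or `"cortisone"` (selects mu/sigma).
#' @return vector of strictly positive concentrations.
#' @export
simulate_hormones <- function(config, pigment_value, ancestry, covariates,
                              seed = NULL, hormone = c("cortisol", "cortisone")) {
  hormone <- match.arg(hormone)
  if (!config$scenario %in% c("null", "local", "stratification", "stress", "mixed")) {
    stop("unknown scenario label: ", config$scenario, call. = FALSE)
  }
  mu <- if (hormone == "cortisol") config$hormone_mu else config$cortisone_mu
  sigma <- if (hormone == "cortisol") config$hormone_sigma else config$cortisone_sigma
  n <- length(pigment_value)
  eta <- rep(mu, n)
  if (config$b_local != 0) {
    eta <- eta + config$b_local * standardize(pigment_value, "pigment value")
  }
  if (config$b_systemic != 0) {
    S <- switch(config$scenario,
      stratification = ,
      mixed = standardize(1 - ancestry[, 1], "non-European ancestry"),
      stress = as.numeric(max.col(ancestry) != 1L),
      stop("b_systemic is only meaningful for stratification/stress/mixed scenarios",
           call. = FALSE)
    )
    eta <- eta + config$b_systemic * S
  }
  ce <- config$covariate_effects
  eta <- eta + ce$sex * covariates$sex +
    ce$age * (covariates$age_months - 74) + ce$cs * covariates$cs_use
  with_seed(seed, exp(eta + sigma * stats::rnorm(n)))
}

population_labels <- function(k) {
  base <- c("european", "african", "asian", "turkish", "caribbean")
  if (k <= length(base)) base[seq_len(k)] else c(base, paste0("pop", seq_len(k - length(base))))
}

#' Simulate a full admixed cohort
#'
#' Draws background and pigmentation allele frequencies, admixed genotypes
#' (including an optional high-LD pigmentation SNP pair), covariates, hair
#' colour, cortisol and cortisone under the configured causal scenario, and a
#' training/validation split.
#'
#' @param config a [scenario_config()].
#' @return object of class `simulated_cohort`: `genotypes` (a
#'   `genotype_matrix`), `phenotypes` (one row per sample: `sample_id`,
#'   `hair_color`, `cortisol_pgmg`, `cortisone_pgmg`, `sex`, `age_months`,
#'   `cs_use`, `origin_group`), `truth` (latent pigmentation genetic value,
#'   ancestry proportions, population-of-origin label, colour liability,
#'   training-split flag) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  seeds <- derive_seeds(config$seed, 9)
  K <- config$n_populations
  n <- config$n_samples
  npig <- config$n_pigment_snps
  use_ld <- config$ld_pair && npig >= 2L
  npig_drawn <- if (use_ld) npig - 1L else npig

  fst_pig <- min(config$pigment_fst_multiplier * config$fst, 0.8)
  f_bg <- draw_population_freqs(config$n_background_snps, K, config$fst, seed = seeds[1])
  f_pig <- draw_population_freqs(npig_drawn, K, fst_pig, seed = seeds[2])
  if (config$pigment_ancestry_logit_shift != 0 && K > 1) {
    # darkening alleles are systematically more frequent outside population 1
    delta <- config$pigment_ancestry_logit_shift *
      sign(config$pigment_weights[seq_len(npig_drawn)])
    f_pig[-1, ] <- stats::plogis(sweep(qlogis_mat(f_pig[-1, , drop = FALSE]),
                                       2, delta, "+"))
    f_pig <- pmin(pmax(f_pig, 1e-6), 1 - 1e-6)
  }

  sim <- simulate_genotypes(cbind(f_pig, f_bg), config$admixture_alpha, n,
                            seed = seeds[3])
  q <- sim$ancestry
  g_pig <- sim$dosages[, seq_len(npig_drawn), drop = FALSE]
  g_bg <- sim$dosages[, npig_drawn + seq_len(config$n_background_snps), drop = FALSE]

  if (use_ld) {
    # LD partner of the last drawn pigmentation SNP: each allele is copied
    # with probability rho = sqrt(r2), else redrawn from the sample's own
    # frequency, so cor(dosage, dosage)^2 ~ r2.
    rho <- sqrt(config$ld_r2)
    pi_src <- drop(q %*% f_pig[, npig_drawn])
    src <- g_pig[, npig_drawn]
    partner <- with_seed(seeds[4], {
      stats::rbinom(n, src, rho + (1 - rho) * pi_src) +
        stats::rbinom(n, 2L - src, (1 - rho) * pi_src)
    })
    g_pig <- cbind(g_pig, partner)
  }

  if (config$dosage_noise_sd > 0) {
    g_pig <- with_seed(seeds[9], pmin(pmax(
      g_pig + stats::rnorm(length(g_pig), 0, config$dosage_noise_sd), 0), 2))
  }

  covariates <- with_seed(seeds[5], data.frame(
    sex = stats::rbinom(n, 1, 0.5),
    age_months = stats::rnorm(n, 74, 6),
    cs_use = stats::rbinom(n, 1, 0.08)
  ))

  anc_score <- if (n > 1) standardize(1 - q[, 1], "non-European ancestry") else rep(0, n)
  color <- simulate_hair_color(
    g_pig, config$pigment_weights, config$ancestry_color_shift, anc_score,
    thresholds = NULL, noise_sd = config$noise_sd, seed = seeds[6]
  )
  pigment_value <- drop(g_pig %*% config$pigment_weights)

  cortisol <- simulate_hormones(config, pigment_value, q, covariates,
                                seed = seeds[7], hormone = "cortisol")
  cortisone <- simulate_hormones(config, pigment_value, q, covariates,
                                 seed = seeds[8], hormone = "cortisone")

  ids <- sprintf("S%05d", seq_len(n))
  labels <- population_labels(K)
  pop <- labels[max.col(q, ties.method = "first")]

  snp_ids <- c(sprintf("pig%02d", seq_len(npig)),
               sprintf("bg%04d", seq_len(config$n_background_snps)))
  m <- length(snp_ids)
  alleles <- matrix(c("A", "C", "G", "T")[cbind(
    1 + (seq_len(m) %% 4), 1 + ((seq_len(m) + 1) %% 4))], ncol = 2)
  snps <- data.frame(
    snp_id = snp_ids,
    chrom = as.character(1 + (seq_len(m) - 1) %% 22),
    pos = 1000L * seq_len(m),
    effect_allele = alleles[, 2],  # ALT = counted (effect) allele
    other_allele = alleles[, 1],
    imputation_r2 = NA_real_,
    call_rate = 1,
    stringsAsFactors = FALSE
  )
  # mark a subset of pigmentation SNPs as imputed with synthetic quality values
  imputed <- seq_len(npig) %% 3 == 0
  snps$imputation_r2[seq_len(npig)][imputed] <-
    round(0.6 + 0.4 * (seq_len(sum(imputed)) / (sum(imputed) + 1)), 3)

  dos <- cbind(g_pig, g_bg)
  dimnames(dos) <- list(ids, snp_ids)
  gm <- gm_unchecked(ids, snps, dos)  # generator output is valid by construction

  n_train <- round(config$train_fraction * n)
  in_train <- rep(FALSE, n)
  in_train[with_seed(config$seed + 1L, sample.int(n, n_train))] <- TRUE

  phen <- data.frame(
    sample_id = ids, hair_color = as.integer(color),
    cortisol_pgmg = cortisol, cortisone_pgmg = cortisone,
    sex = covariates$sex, age_months = covariates$age_months,
    cs_use = covariates$cs_use, origin_group = pop,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    sample_id = ids, pigment_value = pigment_value,
    color_liability = attr(color, "liability"),
    ancestry_score = as.numeric(anc_score), pop_label = pop,
    in_training = in_train, stringsAsFactors = FALSE
  )
  qdf <- as.data.frame(q)
  names(qdf) <- paste0("q_", labels)
  truth <- cbind(truth, qdf)

  structure(
    list(genotypes = gm, phenotypes = phen, truth = truth, config = config,
         thresholds = attr(color, "thresholds")),
    class = "simulated_cohort"
  )
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d samples x %d SNPs (scenario '%s')\n",
              nrow(x$phenotypes), ncol(x$genotypes$dosages), x$config$scenario))
  cat(sprintf("  training split: %d / validation: %d\n",
              sum(x$truth$in_training), sum(!x$truth$in_training)))
  invisible(x)
}

#' Write a simulated cohort to standard-format files
#'
#' Writes a VCF v4.2 (FORMAT `DS`, plus `GT` for hard genotypes) together with
#' tab-separated phenotype and truth tables; the files round-trip losslessly
#' through [read_vcf()] / [read_phenotypes()] to 4 decimals.
#'
#' @param cohort a `simulated_cohort`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, named character vector of the three file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(
    vcf = file.path(out_dir, "cohort.vcf"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_vcf(cohort$genotypes, paths[["vcf"]])
  write_tsv_na(cohort$phenotypes, paths[["phenotypes"]])
  write_tsv_na(cohort$truth, paths[["truth"]])
  invisible(paths)
}

write_tsv_na <- function(df, path) {
  # full double precision so a written cohort re-analyses bit-for-bit
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA, sprintf("%.17g", x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}
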