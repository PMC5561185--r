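# End-to-end orchestration: QC -> ancestry PCA -> split -> score training ->
# scoring -> Box-Cox -> outcome models -> per-SNP models -> pleiotropy screen,
# plus multi-replicate scenario experiments quantifying the pigmentation bias.

resolve_input <- function(input, train_fraction, seed) {
  if (inherits(input, "scenario_config")) {
    cohort <- simulate_cohort(input)
    return(list(gm = cohort$genotypes, phen = cohort$phenotypes,
                truth = cohort$truth, config = input))
  }
  if (inherits(input, "simulated_cohort")) {
    return(list(gm = input$genotypes, phen = input$phenotypes,
                truth = input$truth, config = input$config))
  }
  if (is.list(input) && !is.null(input$vcf) && !is.null(input$phenotypes)) {
    gm <- read_vcf(input$vcf)
    phen <- read_phenotypes(input$phenotypes)
    idx <- match(gm$sample_ids, phen$sample_id)
    if (anyNA(idx)) stop("phenotype table lacks some genotyped samples", call. = FALSE)
    phen <- phen[idx, , drop = FALSE]
    rownames(phen) <- NULL
    truth <- NULL
    if (!is.null(input$truth) && file.exists(input$truth)) {
      truth <- utils::read.table(input$truth, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
      truth <- truth[match(gm$sample_ids, truth$sample_id), , drop = FALSE]
      rownames(truth) <- NULL
    }
    return(list(gm = gm, phen = phen, truth = truth, config = NULL))
  }
  stop("input must be a scenario_config, a simulated_cohort, or a list with ",
       "$vcf and $phenotypes paths", call. = FALSE)
}

#' Run the full hair-pigmentation-bias pipeline
#'
#' Executes QC, ancestry PCA (fitted on the whole cohort), the
#' training/validation split, ancestry-adjusted score training with VIF
#' pruning, scoring and standardization in the validation sample, Box-Cox
#' transformation fitted on the main model, the main score model with and
#' without ancestry PCs, the reported-hair-colour models, per-SNP models
#' (separate and mutually adjusted), darker-hair orientation, and the
#' IVW heterogeneity / Egger pleiotropy screen, plus a variance
#' decomposition and the local-f2 power of the score term.
#'
#' @param input a [scenario_config()] (simulated on the fly), a
#'   `simulated_cohort`, or `list(vcf =, phenotypes =, truth =)` file paths.
#' @param candidate_snps ids of the candidate pigmentation SNPs; defaults to
#'   SNP ids starting with `"pig"` (the simulator's naming).
#' @param outcomes hormones to model.
#' @param n_pcs number of ancestry PCs.
#' @param alpha SNP selection threshold in training.
#' @param vif_threshold VIF pruning threshold.
#' @param qc named list overriding [apply_qc()] thresholds.
#' @param train_fraction used only when no training flag is available from
#'   simulation truth.
#' @param comparison_unadjusted_score also train the unadjusted
#'   (no-ancestry-correction) comparison score.
#' @param seed seed for the split when drawn here.
#' @param out_dir when given, report tables (coefficient tables in the layout
#'   of the published study's Tables 2/3, score model JSON, QC report, PC
#'   scores, meta results, a log of seeds and thresholds) are written there.
#' @return object of class `pipeline_result`.
#' @export
run_pipeline <- function(input, candidate_snps = NULL,
                         outcomes = c("cortisol", "cortisone"),
                         n_pcs = 20, alpha = 0.05, vif_threshold = 10,
                         qc = list(), train_fraction = 1565 / 3262,
                         comparison_unadjusted_score = FALSE,
                         seed = 1L, out_dir = NULL) {
  stage <- "input"
  res <- tryCatch({
    dat <- resolve_input(input, train_fraction, seed)
    gm <- dat$gm
    phen <- dat$phen
    if (!identical(gm$sample_ids, phen$sample_id)) {
      stop("genotype and phenotype sample ids disagree", call. = FALSE)
    }
    if (is.null(candidate_snps)) {
      candidate_snps <- grep("^pig", gm$snps$snp_id, value = TRUE)
    }
    if (length(candidate_snps) == 0) stop("no candidate pigmentation SNPs", call. = FALSE)

    stage <- "qc"
    # HWE within the majority origin group: admixture produces genuine
    # Wahlund heterozygote deficits at differentiated loci
    if (is.null(qc$hwe_sample_ids) && "origin_group" %in% names(phen)) {
      major <- names(which.max(table(phen$origin_group)))
      qc$hwe_sample_ids <- phen$sample_id[phen$origin_group %in% major]
    }
    qcr <- do.call(apply_qc, c(list(gm = gm), qc))
    gm <- qcr$genotypes
    phen <- phen[match(gm$sample_ids, phen$sample_id), , drop = FALSE]
    candidate_snps <- intersect(candidate_snps, gm$snps$snp_id)

    stage <- "pca"
    # ancestry PCs come from the genome-wide background panel: at desk scale
    # the handful of strongly differentiated candidate SNPs would otherwise
    # dominate the components and over-adjust the score
    pca_panel <- setdiff(gm$snps$snp_id, candidate_snps)
    if (length(pca_panel) < n_pcs) pca_panel <- gm$snps$snp_id
    pca <- fit_pca(subset_snps(gm, pca_panel), n_components = n_pcs)

    stage <- "split"
    if (!is.null(dat$truth) && !is.null(dat$truth$in_training)) {
      train_ids <- dat$truth$sample_id[dat$truth$in_training]
      train_ids <- intersect(train_ids, gm$sample_ids)
    } else {
      n <- length(gm$sample_ids)
      train_ids <- with_seed(seed, sample(gm$sample_ids, round(train_fraction * n)))
    }
    val_ids <- setdiff(gm$sample_ids, train_ids)

    stage <- "train"
    gm_cand <- subset_snps(gm, candidate_snps)
    gm_train <- subset_samples(gm_cand, train_ids)
    color_train <- phen$hair_color[match(train_ids, phen$sample_id)]
    model <- train_weights(gm_train, color_train, ancestry = pca,
                           alpha = alpha, vif_threshold = vif_threshold)
    model_unadj <- NULL
    if (comparison_unadjusted_score) {
      model_unadj <- tryCatch(
        train_weights(gm_train, color_train, ancestry = NULL,
                      alpha = alpha, vif_threshold = vif_threshold),
        error = function(e) NULL)
    }

    stage <- "score"
    score <- compute_score(gm_cand, model, standardize_in = val_ids)
    vmask <- score$scores$sample_id %in% val_ids
    val_r2 <- score_color_r2(score, ifelse(vmask, phen$hair_color, NA))

    stage <- "outcome_models"
    vidx <- match(val_ids, phen$sample_id)
    pv <- phen[vidx, , drop = FALSE]
    z <- score$scores$standardized[match(val_ids, score$scores$sample_id)]
    pcs_v <- pca$pcs[match(val_ids, pca$sample_ids), , drop = FALSE]
    covars <- pv[, c("sex", "age_months", "cs_use")]

    outcome_results <- list()
    analysis_data <- data.frame(sample_id = val_ids, score = z,
                                hair_color = pv$hair_color,
                                origin_group = pv$origin_group,
                                covars, stringsAsFactors = FALSE)
    for (hz in outcomes) {
      y_raw <- pv[[paste0(hz, "_pgmg")]]
      ok <- !is.na(y_raw) & !is.na(z) & stats::complete.cases(covars) &
        stats::complete.cases(pcs_v)
      # transform chosen under the covariate model, excluding the tested
      # predictor, so exposure inference is untouched by transform selection
      design_cov <- cbind(1, as.matrix(covars), pcs_v)[ok, , drop = FALSE]
      lambda <- fit_boxcox_lambda(y_raw[ok], design_cov)
      spec <- boxcox_spec(y_raw[ok], lambda)
      yt <- rep(NA_real_, nrow(pv))
      yt[!is.na(y_raw)] <- transform_outcome(y_raw[!is.na(y_raw)], spec)

      fits <- list(
        score_adjusted = fit_association(yt, z, covars, pcs_v, "score",
                                         "polygenic score (ancestry correction)"),
        score_unadjusted = fit_association(yt, z, covars, NULL, "score",
                                           "polygenic score (no ancestry correction)"),
        color_adjusted = fit_association(yt, pv$hair_color, covars, pcs_v,
                                         "hair_color", "hair colour (ancestry correction)"),
        color_unadjusted = fit_association(yt, pv$hair_color, covars, NULL,
                                           "hair_color", "hair colour (no ancestry correction)")
      )

      gm_val_snps <- subset_samples(subset_snps(gm, model$entries$snp_id), val_ids)
      per_snp <- list(
        separate_adjusted = per_snp_associations(gm_val_snps, yt, covars, pcs_v,
                                                 mode = "separate"),
        mutual_adjusted = per_snp_associations(gm_val_snps, yt, covars, pcs_v,
                                               mode = "mutual"),
        separate_unadjusted = per_snp_associations(gm_val_snps, yt, covars, NULL,
                                                   mode = "separate"),
        mutual_unadjusted = per_snp_associations(gm_val_snps, yt, covars, NULL,
                                                 mode = "mutual")
      )
      oriented <- orient_effects(per_snp$separate_adjusted, model)
      meta <- meta_ivw(oriented)
      egger <- tryCatch(egger_test(oriented), error = function(e) e)

      ve <- variance_explained(yt, list(
        score = z, ancestry_pcs = pcs_v,
        national_origin = pv$origin_group
      ))

      full <- fits$score_adjusted
      reduced <- fit_association(yt, NULL, covars, pcs_v, label = "reduced (no score)")
      f2 <- local_f2(full$r2, reduced$r2)
      pw <- power_f2(f2, u = 1, n = full$n, n_terms = nrow(full$terms) - 1)

      analysis_data[[hz]] <- yt
      outcome_results[[hz]] <- list(
        lambda = as.numeric(lambda), transform = spec, fits = fits,
        per_snp = per_snp, oriented = oriented, meta = meta, egger = egger,
        variance_explained = ve, f2 = f2, power = pw
      )
    }

    structure(
      list(
        qc_report = qcr$report, pca = pca, score_model = model,
        score_model_unadjusted = model_unadj, score = score,
        validation_r2 = val_r2, outcomes = outcome_results,
        analysis_data = analysis_data, pcs_validation = pcs_v,
        train_ids = train_ids, val_ids = val_ids,
        log = list(seed = seed, alpha = alpha, vif_threshold = vif_threshold,
                   n_pcs = n_pcs, qc = qcr$report$thresholds,
                   scenario = if (!is.null(dat$config)) unclass(dat$config))
      ),
      class = "pipeline_result"
    )
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  training n = %d, validation n = %d, score SNPs = %d\n",
              length(x$train_ids), length(x$val_ids), nrow(x$score_model$entries)))
  cat(sprintf("  validation hair-colour adj R2 = %.3f (%.2f levels darker per SD)\n",
              x$validation_r2$adj_r2, x$validation_r2$beta_per_sd))
  for (hz in names(x$outcomes)) {
    o <- x$outcomes[[hz]]
    b_adj <- coef_row(o$fits$score_adjusted)
    b_un <- coef_row(o$fits$score_unadjusted)
    cat(sprintf("  %s: lambda = %.2f; score beta %.3f (SE %.3f) unadjusted -> %.3f (SE %.3f) with PCs\n",
                hz, o$lambda, b_un$beta, b_un$se, b_adj$beta, b_adj$se))
    cat(sprintf("    pleiotropy: Q = %.2f (p = %.3f), I2(tau) = %.1f%%; power(f2=%.4f) = %.0f%%\n",
                o$meta$Q, o$meta$p_Q, o$meta$i2_tau, o$f2, 100 * o$power$power))
  }
  invisible(x)
}

write_assoc_tsv <- function(fits, path) {
  rows <- lapply(names(fits), function(nm) {
    t <- fits[[nm]]$terms
    t$model <- nm
    t$n <- fits[[nm]]$n
    t
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

write_pipeline_reports <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_qc_report(res$qc_report, out_dir)
  write_pcs(res$pca, file.path(out_dir, "pc_scores.tsv"))
  write_score_model(res$score_model, file.path(out_dir, "score_model.json"))
  utils::write.table(res$score$scores, file.path(out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (hz in names(res$outcomes)) {
    o <- res$outcomes[[hz]]
    write_assoc_tsv(o$fits, file.path(out_dir, paste0("table2_", hz, ".tsv")))
    per <- lapply(names(o$per_snp), function(nm) {
      d <- o$per_snp[[nm]]
      attr(d, "fits") <- NULL
      d$model <- nm
      d
    })
    utils::write.table(do.call(rbind, per),
                       file.path(out_dir, paste0("table3_", hz, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    meta_df <- data.frame(
      k = o$meta$k, pooled_beta = o$meta$pooled_fixed["beta"],
      pooled_se = o$meta$pooled_fixed["se"], Q = o$meta$Q, df = o$meta$df,
      p_Q = o$meta$p_Q, i2_q = o$meta$i2_q, tau2_reml = o$meta$tau2_reml,
      i2_tau = o$meta$i2_tau,
      egger_p = if (inherits(o$egger, "error")) NA else o$egger$slope_p
    )
    utils::write.table(meta_df, file.path(out_dir, paste0("meta_", hz, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(o$oriented, file.path(out_dir, paste0("funnel_", hz, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log <- res$log
  writeLines(c(
    paste0("seed = ", log$seed), paste0("alpha = ", log$alpha),
    paste0("vif_threshold = ", log$vif_threshold), paste0("n_pcs = ", log$n_pcs),
    paste("qc:", paste(names(log$qc), unlist(log$qc), sep = "=", collapse = " ")),
    if (!is.null(log$scenario)) {
      sc <- log$scenario
      keep <- vapply(sc, function(v) is.atomic(v) && length(v) < 30, logical(1))
      paste("scenario:", paste(names(sc)[keep],
            vapply(sc[keep], function(v) paste(v, collapse = ","), ""),
            sep = "=", collapse = " "))
    }
  ), file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

# One lean replicate of the scenario experiment: simulate, QC, PCA, train,
# score, transform, and fit the main model with and without PC adjustment.
replicate_once <- function(config, coverage = FALSE) {
  cohort <- simulate_cohort(config)
  major <- names(which.max(table(cohort$phenotypes$origin_group)))
  qcr <- apply_qc(cohort$genotypes,
                  hwe_sample_ids = cohort$phenotypes$sample_id[
                    cohort$phenotypes$origin_group %in% major])
  gm <- qcr$genotypes
  pca <- fit_pca(subset_snps(gm, grep("^bg", gm$snps$snp_id, value = TRUE)),
                 n_components = 20)
  phen <- cohort$phenotypes[match(gm$sample_ids, cohort$phenotypes$sample_id), ]
  truth <- cohort$truth[match(gm$sample_ids, cohort$truth$sample_id), ]
  cand <- grep("^pig", gm$snps$snp_id, value = TRUE)
  train_ids <- truth$sample_id[truth$in_training]
  val_ids <- setdiff(gm$sample_ids, train_ids)

  gm_cand <- subset_snps(gm, cand)
  gm_train <- subset_samples(gm_cand, train_ids)
  tmask <- match(train_ids, phen$sample_id)
  model <- train_weights(gm_train, phen$hair_color[tmask], ancestry = pca)
  score <- compute_score(gm_cand, model, standardize_in = val_ids)

  vidx <- match(val_ids, phen$sample_id)
  pv <- phen[vidx, ]
  z <- score$scores$standardized[match(val_ids, score$scores$sample_id)]
  pcs_v <- pca$pcs[match(val_ids, pca$sample_ids), , drop = FALSE]
  covars <- pv[, c("sex", "age_months", "cs_use")]
  y <- pv$cortisol_pgmg

  design_cov <- cbind(1, as.matrix(covars), pcs_v)
  lambda <- fit_boxcox_lambda(y, design_cov)
  yt <- transform_outcome(y, boxcox_spec(y, lambda))

  adj <- coef_row(fit_association(yt, z, covars, pcs_v, "score"))
  unadj <- coef_row(fit_association(yt, z, covars, NULL, "score"))

  out <- data.frame(
    beta_adj = adj$beta, se_adj = adj$se, p_adj = adj$p,
    beta_unadj = unadj$beta, se_unadj = unadj$se, p_unadj = unadj$p,
    lambda = as.numeric(lambda), n_selected = nrow(model$entries),
    n_analysis = length(val_ids)
  )
  if (coverage) {
    # weight-recovery check on the continuous pigmentation liability
    mliab <- train_weights(gm_train, truth$color_liability[tmask], ancestry = pca,
                           alpha = 1)
    d <- mliab$diagnostics
    truew <- config$pigment_weights[match(d$snp_id, sprintf("pig%02d", seq_along(config$pigment_weights)))]
    ci_half <- stats::qt(0.975, mliab$training_n - nrow(d) - 21) * d$se
    out$coverage <- mean(abs(d$beta - truew) <= ci_half)
    out$n_cov <- nrow(d)
  }
  out
}

#' Multi-replicate scenario experiment
#'
#' Runs the pipeline's main score test on independent simulated cohorts under
#' one causal scenario, collecting the PC-adjusted and unadjusted score
#' effects per replicate. Replicate seeds are derived from the master seed by
#' a counter-based scheme, so results do not depend on execution order.
#'
#' @param config a [scenario_config()]; its `seed` is the master seed.
#' @param n_replicates number of independent cohorts.
#' @param alpha rejection threshold summarized over replicates.
#' @param coverage also assess 95% CI coverage of the training weights on the
#'   continuous pigmentation liability (no selection, alpha = 1); for a clean
#'   estimand this is normally run with `ld_pair = FALSE`.
#' @return object of class `scenario_summary`: per-replicate table
#'   `replicates`, the seed ledger, and summary statistics (rejection rates,
#'   mean adjusted/unadjusted beta, mean bias versus the true local effect,
#'   attenuation proportion, CI coverage when requested).
#' @export
run_scenario_experiment <- function(config, n_replicates, alpha = 0.05,
                                    coverage = FALSE) {
  stopifnot(inherits(config, "scenario_config"), n_replicates >= 1)
  seeds <- derive_seeds(config$seed, n_replicates)
  reps <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    reps[[i]] <- cbind(replicate = i, seed = seeds[i],
                       replicate_once(cfg_i, coverage = coverage))
  }
  reps <- do.call(rbind, reps)
  summary <- list(
    n_replicates = n_replicates, alpha = alpha, scenario = config$scenario,
    rejection_rate_adjusted = mean(reps$p_adj < alpha),
    rejection_rate_unadjusted = mean(reps$p_unadj < alpha),
    mean_beta_adjusted = mean(reps$beta_adj),
    mean_beta_unadjusted = mean(reps$beta_unadj),
    mean_bias_adjusted = mean(reps$beta_adj) - config$b_local,
    attenuation_proportion = mean(abs(reps$beta_unadj) > abs(reps$beta_adj)),
    mean_lambda = mean(reps$lambda)
  )
  if (coverage) summary$weight_ci_coverage <- stats::weighted.mean(reps$coverage, reps$n_cov)
  structure(list(replicates = reps, summary = summary, master_seed = config$seed,
                 config = config),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Scenario '%s' experiment: %d replicates (alpha = %g)\n",
              s$scenario, s$n_replicates, s$alpha))
  cat(sprintf("  rejection rate: %.3f adjusted, %.3f unadjusted\n",
              s$rejection_rate_adjusted, s$rejection_rate_unadjusted))
  cat(sprintf("  mean score beta: %.4f adjusted, %.4f unadjusted (true local %.3f)\n",
              s$mean_beta_adjusted, s$mean_beta_unadjusted, x$config$b_local))
  cat(sprintf("  |unadjusted| > |adjusted| in %.1f%% of replicates\n",
              100 * s$attenuation_proportion))
  if (!is.null(s$weight_ci_coverage)) {
    cat(sprintf("  training-weight 95%% CI coverage: %.3f\n", s$weight_ci_coverage))
  }
  invisible(x)
}

#' Stratified association runs
#'
#' Repeats the main outcome model within subgroups (e.g. national-origin
#' groups), skipping groups below a sample-size floor with a warning.
#'
#' @param result a `pipeline_result`.
#' @param outcome which modelled outcome to stratify.
#' @param grouping column of the analysis data holding the group labels.
#' @param min_n smallest group size analysed.
#' @param adjust_ancestry include the PC covariates within each group.
#' @return data.frame of per-group score coefficients (group, n, beta, se, p).
#' @export
stratified_runs <- function(result, outcome = "cortisol",
                            grouping = "origin_group", min_n = 30,
                            adjust_ancestry = TRUE) {
  stopifnot(inherits(result, "pipeline_result"))
  ad <- result$analysis_data
  if (!outcome %in% names(ad)) stop("outcome not in analysis data: ", outcome, call. = FALSE)
  groups <- ad[[grouping]]
  if (is.null(groups) || all(is.na(groups))) stop("empty grouping", call. = FALSE)
  out <- list()
  for (g in sort(unique(groups[!is.na(groups)]))) {
    idx <- which(groups == g)
    if (length(idx) < min_n) {
      warning("group '", g, "' skipped (n = ", length(idx), " < ", min_n, ")")
      next
    }
    fit <- tryCatch(
      fit_association(ad[[outcome]][idx], ad$score[idx],
                      ad[idx, c("sex", "age_months", "cs_use")],
                      if (adjust_ancestry) result$pcs_validation[idx, , drop = FALSE],
                      "score", paste0("score in ", g)),
      error = function(e) NULL)
    if (is.null(fit)) next
    row <- coef_row(fit)
    out[[g]] <- data.frame(group = g, n = fit$n, beta = row$beta, se = row$se,
                           p = row$p, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) stop("no group reached the size floor", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
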