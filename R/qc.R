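# Genotype quality control.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts
#' (Wigginton-style enumeration over heterozygote counts of matching parity,
#' using the probability recurrence). The p-value is the summed probability of
#' all genotype configurations no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be nonnegative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)
  n_a <- 2 * n_aa + n_Aa
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_a, n_A)
  if (rare == 0) return(1)  # monomorphic: single possible configuration

  # heterozygote counts share the parity of the rare allele count;
  # recurrence P(h+2)/P(h) = 4 * hom_rare * hom_common / ((h+2)(h+1)),
  # accumulated in log space so large samples cannot overflow
  h_min <- rare %% 2
  hs <- seq(h_min, rare, by = 2)
  if (length(hs) > 1) {
    h <- hs[-length(hs)]
    hom_r <- (rare - h) / 2  # rare-allele homozygotes at het count h
    steps <- log(4 * hom_r * (n - h - hom_r)) - log((h + 2) * (h + 1))
    logp <- c(0, cumsum(steps))
  } else {
    logp <- 0
  }
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Apply genotype quality-control filters
#'
#' Filters are applied in a fixed, recorded order: sample call rate, SNP call
#' rate, imputation quality, minor allele frequency, Hardy-Weinberg
#' equilibrium. "At least" thresholds are inclusive and "below" thresholds
#' exclusive, exactly as conventionally printed: samples kept when call rate
#' >= `sample_cr`; SNPs kept when call rate >= `snp_cr`, excluded when
#' imputation R2 < `imp_r2_min` (directly genotyped SNPs, with absent R2, are
#' never excluded for imputation quality), excluded when MAF < `maf_min`, and
#' excluded when the HWE exact p < `hwe_p_min`. HWE is evaluated on hard
#' genotypes only: dosages are rounded when every non-missing value is within
#' 0.1 of an integer, otherwise the SNP is skipped for HWE.
#'
#' @param gm a `genotype_matrix`.
#' @param sample_cr minimum sample call rate.
#' @param snp_cr minimum SNP call rate.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min HWE exact-test exclusion threshold.
#' @param imp_r2_min minimum imputation quality.
#' @param maf_mode MAF from dosage means (`"dosage"`, works for imputed data)
#'   or from rounded hard calls (`"hard"`).
#' @param hwe_sample_ids optional sample ids on which HWE is evaluated.
#'   In admixed cohorts the Wahlund effect produces genuine
#'   heterozygote deficits at strongly differentiated loci, so HWE is
#'   conventionally assessed within a genetically homogeneous subgroup;
#'   the default (NULL) uses all samples.
#' @return list with the filtered `genotypes` and a `report` (class
#'   `qc_report`) listing every exclusion with its single primary reason.
#' @export
apply_qc <- function(gm, sample_cr = 0.975, snp_cr = 0.95, maf_min = 0.01,
                     hwe_p_min = 1e-7, imp_r2_min = 0.3,
                     maf_mode = c("dosage", "hard"), hwe_sample_ids = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  maf_mode <- match.arg(maf_mode)
  if (length(gm$sample_ids) == 0L || nrow(gm$snps) == 0L) {
    stop("apply_qc needs a nonempty genotype matrix", call. = FALSE)
  }
  dos <- gm$dosages
  has_missing <- anyNA(dos)

  scr <- if (has_missing) rowMeans(!is.na(dos)) else rep(1, nrow(dos))
  bad_samples <- scr < sample_cr
  excl_samples <- data.frame(sample_id = gm$sample_ids[bad_samples],
                             reason = rep("call_rate", sum(bad_samples)),
                             stringsAsFactors = FALSE)
  if (any(bad_samples)) dos <- dos[!bad_samples, , drop = FALSE]
  if (nrow(dos) == 0L) stop("empty after QC: all samples removed", call. = FALSE)

  snp_reason <- rep(NA_character_, nrow(gm$snps))

  ccr <- if (has_missing) colMeans(!is.na(dos)) else rep(1, ncol(dos))
  snp_reason[is.na(snp_reason) & ccr < snp_cr] <- "call_rate"

  r2 <- gm$snps$imputation_r2
  snp_reason[is.na(snp_reason) & !is.na(r2) & r2 < imp_r2_min] <- "imputation"

  freq <- if (maf_mode == "dosage") {
    colMeans(dos, na.rm = TRUE) / 2
  } else {
    colMeans(round(dos), na.rm = TRUE) / 2
  }
  maf <- pmin(freq, 1 - freq)
  snp_reason[is.na(snp_reason) & maf < maf_min] <- "maf"

  if (!is.null(hwe_sample_ids)) {
    hidx <- match(hwe_sample_ids, gm$sample_ids[!bad_samples])
    hidx <- hidx[!is.na(hidx)]
    if (length(hidx) < 2) stop("hwe_sample_ids matches fewer than 2 samples", call. = FALSE)
    hdos <- dos[hidx, , drop = FALSE]
  } else {
    hdos <- dos
  }
  Rd <- round(hdos)
  nonmiss <- colSums(!is.na(hdos))
  hard_ok <- colSums(abs(hdos - Rd) > 0.1, na.rm = TRUE) == 0 & nonmiss > 0
  # genotype counts by arithmetic identities on the rounded dosages
  n2 <- colSums(Rd * (Rd - 1), na.rm = TRUE) / 2
  n1 <- colSums(Rd * (2 - Rd), na.rm = TRUE)
  n0 <- nonmiss - n1 - n2
  # cheap chi-square prescreen: the exact test is only run for SNPs whose
  # asymptotic HWE p is within four orders of magnitude of the threshold
  # (the exact p never crosses hwe_p_min when the chi-square p is 1e4 above)
  nh <- n0 + n1 + n2
  p_hat <- (2 * n2 + n1) / (2 * pmax(nh, 1))
  e2 <- nh * p_hat^2
  e1 <- 2 * nh * p_hat * (1 - p_hat)
  e0 <- nh * (1 - p_hat)^2
  chi2 <- ifelse(e2 > 0 & e1 > 0 & e0 > 0,
                 (n2 - e2)^2 / pmax(e2, 1e-12) + (n1 - e1)^2 / pmax(e1, 1e-12) +
                   (n0 - e0)^2 / pmax(e0, 1e-12), 0)
  chi_cut <- stats::qchisq(min(hwe_p_min * 1e4, 0.5), 1, lower.tail = FALSE)
  for (j in which(is.na(snp_reason) & hard_ok & chi2 > chi_cut)) {
    p <- hwe_exact_test(n2[j], n1[j], n0[j])
    if (p < hwe_p_min) snp_reason[j] <- "hwe"
  }

  excl_snps <- data.frame(snp_id = gm$snps$snp_id[!is.na(snp_reason)],
                          reason = snp_reason[!is.na(snp_reason)],
                          stringsAsFactors = FALSE)
  keep <- is.na(snp_reason)
  if (!any(keep)) stop("empty after QC: all SNPs removed", call. = FALSE)

  s <- gm$snps[keep, , drop = FALSE]
  s$call_rate <- ccr[keep]
  rownames(s) <- NULL
  out <- gm_unchecked(gm$sample_ids[!bad_samples], s, dos[, keep, drop = FALSE])
  report <- structure(
    list(
      excluded_samples = excl_samples, excluded_snps = excl_snps,
      thresholds = list(sample_cr = sample_cr, snp_cr = snp_cr,
                        maf_min = maf_min, hwe_p_min = hwe_p_min,
                        imp_r2_min = imp_r2_min, maf_mode = maf_mode,
                        hwe_n_samples = if (is.null(hwe_sample_ids)) nrow(dos)
                                        else length(hwe_sample_ids)),
      filter_order = c("sample_call_rate", "snp_call_rate", "imputation",
                       "maf", "hwe")
    ),
    class = "qc_report"
  )
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  filter order:", paste(x$filter_order, collapse = " -> "), "\n")
  cat("  samples excluded:", nrow(x$excluded_samples), "\n")
  if (nrow(x$excluded_snps) > 0) {
    tab <- table(x$excluded_snps$reason)
    cat("  SNPs excluded:", nrow(x$excluded_snps),
        paste0("(", paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n"))
  } else cat("  SNPs excluded: 0\n")
  invisible(x)
}

#' Write a QC report as TSV files plus a log
#'
#' @param report a `qc_report`.
#' @param out_dir output directory.
#' @return invisibly, paths written.
#' @export
write_qc_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p1 <- file.path(out_dir, "qc_excluded_samples.tsv")
  p2 <- file.path(out_dir, "qc_excluded_snps.tsv")
  p3 <- file.path(out_dir, "qc_log.txt")
  utils::write.table(report$excluded_samples, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$excluded_snps, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(
    paste("filter order:", paste(report$filter_order, collapse = " -> ")),
    paste(names(report$thresholds), unlist(report$thresholds), sep = " = ")
  ), p3)
  invisible(c(p1, p2, p3))
}
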