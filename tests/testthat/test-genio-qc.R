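make_vcf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "test.vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

test_that("VCF dosages follow the DS-over-GT precedence", {
  # GT only: allele counts
  p <- make_vcf(c(vcf_header(),
                  "1\t100\trsA\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1",
                  "1\t200\trsB\tG\tA\t.\tPASS\t.\tGT\t0/0\t./."))
  gm <- read_vcf(p)
  expect_equal(unname(gm$dosages[, "rsA"]), c(1, 2))
  expect_equal(unname(gm$dosages[, "rsB"]), c(0, NA))
  expect_equal(gm$snps$effect_allele, c("A", "A"))  # ALT is the effect allele

  # DS present alongside GT: DS wins
  p <- make_vcf(c(vcf_header(),
                  "1\t100\trsA\tG\tA\t.\tPASS\tR2=0.87\tGT:DS\t0/1:1.73\t1/1:1.96"))
  gm <- read_vcf(p)
  expect_equal(unname(gm$dosages[, 1]), c(1.73, 1.96))
  expect_equal(gm$snps$imputation_r2, 0.87)
})

test_that("malformed and multi-allelic VCF records are rejected loudly", {
  p <- make_vcf(c(vcf_header(),
                  "1\t100\trsA\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1",
                  "1\t200\trsB\tG\tA\t.\tPASS\t.\tGT\t0/0"))
  expect_error(read_vcf(p), "line 6")

  p <- make_vcf(c(vcf_header(),
                  "1\t100\trsA\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t1/1"))
  expect_error(read_vcf(p), "multi-allelic")
})

test_that("phenotype tables are parsed by header name and validated", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "phen.tsv")
  df <- data.frame(sample_id = c("S1", "S2"), hair_color = c(3L, 7L),
                   cortisol_pgmg = c(1.65, 0.4), cortisone_pgmg = c(7.8, 5.1),
                   sex = c(0L, 1L), age_months = c(70, 78), cs_use = c(0L, 0L),
                   origin_group = c("european", "african"))
  # reordered columns are fine: matching is by name, not position
  write.table(df[, rev(names(df))], path, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- read_phenotypes(path)
  expect_equal(ph$cortisol_pgmg, c(1.65, 0.4))
  expect_equal(names(ph)[1], "sample_id")

  df_bad <- df
  df_bad$hair_color[1] <- 8L
  write.table(df_bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotypes(path), "1..7")

  df_bad <- df
  df_bad$cortisol_pgmg[2] <- -0.2
  write.table(df_bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotypes(path), "positive")

  df_bad <- cbind(df, extra = 1)
  write.table(df_bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotypes(path), "unknown")
})

test_that("QC filters apply the printed thresholds with their exact senses", {
  set.seed(20)
  n <- 400
  g_ok <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  g_rare <- c(rep(1, 7), rep(0, n - 7))   # MAF 7/800 = 0.875%, below 1%
  g_mono <- rep(0, n)                     # monomorphic
  g_imp <- rbinom(n, 2, 0.4)              # fine except poor imputation
  g_hwe <- rep(1, n)                      # all heterozygous: extreme HWE failure
  dos <- cbind(g_ok, maf_low = g_rare, mono = g_mono, imp_bad = g_imp, hwe_bad = g_hwe)
  colnames(dos)[1:3] <- paste0("ok", 1:3)
  gm <- tiny_gm(dos, imp_r2 = c(NA, NA, 0.95, NA, NA, 0.29, NA))

  res <- apply_qc(gm)
  reasons <- setNames(res$report$excluded_snps$reason, res$report$excluded_snps$snp_id)
  expect_equal(reasons[["maf_low"]], "maf")
  expect_equal(reasons[["mono"]], "maf")
  expect_equal(reasons[["imp_bad"]], "imputation")
  expect_equal(reasons[["hwe_bad"]], "hwe")
  expect_identical(res$genotypes$snps$snp_id, paste0("ok", 1:3))

  # idempotence: a second pass excludes nothing and returns the same matrix
  res2 <- apply_qc(res$genotypes)
  expect_identical(res2$genotypes$dosages, res$genotypes$dosages)
  expect_equal(nrow(res2$report$excluded_snps), 0)
  expect_equal(nrow(res2$report$excluded_samples), 0)

  # a matrix passing all thresholds is untouched
  gm_clean <- tiny_gm(g_ok)
  res3 <- apply_qc(gm_clean)
  expect_identical(res3$genotypes$dosages, gm_clean$dosages)
})

test_that("QC boundary senses: >= thresholds keep, < thresholds drop", {
  # MAF exactly at 1% is kept ("minor allele frequency >= 1%")
  n <- 1000
  g_at <- c(rep(1, 20), rep(0, 980))      # dosage mean/2 = 0.01 exactly
  g_below <- c(rep(1, 19), rep(0, 981))
  gm <- tiny_gm(cbind(at = g_at, below = g_below,
                      common = rbinom(n, 2, 0.5)))
  res <- apply_qc(gm, hwe_p_min = 0)  # isolate the MAF filter
  expect_true("at" %in% res$genotypes$snps$snp_id)
  expect_false("below" %in% res$genotypes$snps$snp_id)

  # imputation R2 exactly at 0.3 is kept (excluded only when "< 0.3")
  gm2 <- tiny_gm(matrix(rbinom(2 * n, 2, 0.4), n, 2), imp_r2 = c(0.3, 0.299))
  res2 <- apply_qc(gm2)
  expect_identical(res2$report$excluded_snps$snp_id, "snp02")

  # sample call rate below 97.5% drops the sample first
  dos <- matrix(rbinom(50 * 40, 2, 0.5), 50, 40)
  dos[1, 1:2] <- NA  # 95% call rate for sample 1
  gm3 <- tiny_gm(dos)
  res3 <- apply_qc(gm3)
  expect_identical(res3$report$excluded_samples$sample_id, "S001")
  expect_equal(res3$report$excluded_samples$reason, "call_rate")
})

test_that("HWE exact test matches enumeration and handles edge cases", {
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)   # monomorphic
  expect_lt(hwe_exact_test(0, 50, 0), 1e-7)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 3), "nonnegative")

  # large-sample stability (no overflow), extreme heterozygote excess
  expect_lt(hwe_exact_test(0, 3000, 0), 1e-100)
  expect_gt(hwe_exact_test(750, 1500, 750), 0.5)
})
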