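#!/usr/bin/env Rscript
# Read the cohort files back, apply the genotype QC filters, fit 20 ancestry
# PCs on the background panel, and classify ancestry outliers against the
# majority-population reference by the strict 4-SD rule.

library(pigbias)
stopifnot(file.exists("results/cohort/cohort.vcf"))  # run 01 first
dir.create("results", showWarnings = FALSE)

gm <- read_vcf("results/cohort/cohort.vcf")
phen <- read_phenotypes("results/cohort/phenotypes.tsv")
print(gm)

# HWE within the majority origin group: the admixed whole cohort shows
# genuine Wahlund heterozygote deficits at differentiated loci
major <- names(which.max(table(phen$origin_group)))
qc <- apply_qc(gm, hwe_sample_ids = phen$sample_id[phen$origin_group == major])
print(qc$report)
write_qc_report(qc$report, "results")

bg <- grep("^bg", qc$genotypes$snps$snp_id, value = TRUE)
pca <- fit_pca(subset_snps(qc$genotypes, bg), n_components = 20)
print(pca)
write_pcs(pca, "results/pc_scores.tsv")

# reference group: samples whose reported origin is the European majority
ref <- phen$sample_id[phen$origin_group == "european" &
                        phen$sample_id %in% pca$sample_ids]
labels <- classify_outliers(pca, ref, k_sd = 4, n_check = 4)
cat(sprintf("\n%d of %d samples classified non-European-like (4-SD rule)\n",
            sum(labels == "outlier"), length(labels)))
write.table(data.frame(sample_id = names(labels), label = labels),
            "results/ancestry_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
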