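#!/usr/bin/env Rscript
# Train the ancestry-adjusted polygenic hair-colour score in the training
# split, with VIF pruning of the LD pair, and evaluate it in the validation
# split: adjusted R^2 and levels-darker-per-SD.

library(pigbias)
stopifnot(file.exists("results/cohort/truth.tsv"))

gm <- read_vcf("results/cohort/cohort.vcf")
phen <- read_phenotypes("results/cohort/phenotypes.tsv")
truth <- read.delim("results/cohort/truth.tsv")
major <- names(which.max(table(phen$origin_group)))
qc <- apply_qc(gm, hwe_sample_ids =
                 phen$sample_id[phen$origin_group == major])$genotypes
phen <- phen[match(qc$sample_ids, phen$sample_id), ]
truth <- truth[match(qc$sample_ids, truth$sample_id), ]

pca <- fit_pca(subset_snps(qc, grep("^bg", qc$snps$snp_id, value = TRUE)), 20)

train_ids <- truth$sample_id[truth$in_training]
val_ids <- setdiff(qc$sample_ids, train_ids)
cand <- grep("^pig", qc$snps$snp_id, value = TRUE)
gm_cand <- subset_snps(qc, cand)

model <- train_weights(subset_samples(gm_cand, train_ids),
                       phen$hair_color[match(train_ids, phen$sample_id)],
                       ancestry = pca)
print(model)
write_score_model(model, "results/score_model.json")

# unadjusted comparison score (no ancestry correction in training)
model_unadj <- train_weights(subset_samples(gm_cand, train_ids),
                             phen$hair_color[match(train_ids, phen$sample_id)])

score <- compute_score(gm_cand, model, standardize_in = val_ids)
write.table(score$scores, "results/scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

vmask <- score$scores$sample_id %in% val_ids
r2 <- score_color_r2(score, ifelse(vmask, phen$hair_color, NA))
score_u <- compute_score(gm_cand, model_unadj, standardize_in = val_ids)
r2_u <- score_color_r2(score_u, ifelse(vmask, phen$hair_color, NA))

cat(sprintf("\nAncestry-adjusted score (%d SNPs): validation adj R2 = %.1f%%, %.2f levels darker per SD (SE %.2f)\n",
            nrow(model$entries), 100 * r2$adj_r2, r2$beta_per_sd, r2$se))
cat(sprintf("Unadjusted comparison score (%d SNPs): validation adj R2 = %.1f%%\n",
            nrow(model_unadj$entries), 100 * r2_u$adj_r2))
write.table(
  data.frame(model = c("ancestry_adjusted", "unadjusted"),
             n_snps = c(nrow(model$entries), nrow(model_unadj$entries)),
             adj_r2_pct = 100 * c(r2$adj_r2, r2_u$adj_r2),
             levels_per_sd = c(r2$beta_per_sd, r2_u$beta_per_sd)),
  "results/score_validation.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
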