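test_that("VIF pruning drops one member of a strong-LD pair", {
  pair <- correlated_pair(500, sqrt(0.92), seed = 50)
  colnames(pair) <- c("snpA", "snpB")
  res <- prune_multicollinearity(pair, c("snpA", "snpB"), vif_threshold = 10)
  # both start at the closed-form VIF 1/(1 - 0.92) = 12.5; one is dropped
  expect_equal(res$dropped$vif, 12.5, tolerance = 1e-9)
  expect_length(res$kept, 1)
  expect_true(all(res$vif <= 10))

  # orthogonal (and centred) predictors: all VIFs 1, nothing dropped
  orth <- prcomp(matrix(rnorm(200 * 4), 200, 4))$x
  colnames(orth) <- paste0("o", 1:4)
  res2 <- prune_multicollinearity(orth, colnames(orth))
  expect_equal(unname(res2$vif), rep(1, 4), tolerance = 1e-8)
  expect_equal(nrow(res2$dropped), 0)

  expect_error(prune_multicollinearity(pair, "snpA", vif_threshold = 1), "> 1")
})

test_that("training recovers an exact single-SNP model and holds its level", {
  set.seed(51)
  n <- 300
  g <- cbind(causal = rbinom(n, 2, 0.5), null1 = rbinom(n, 2, 0.3),
             null2 = rbinom(n, 2, 0.4))
  y <- 2 + 0.7 * g[, "causal"]        # zero noise
  gm <- tiny_gm(g)
  m <- train_weights(gm, y)
  expect_true("causal" %in% m$entries$snp_id)
  expect_equal(m$entries$weight[m$entries$snp_id == "causal"], 0.7,
               tolerance = 1e-8)

  # null-SNP selection operates at the nominal alpha level
  set.seed(52)
  hits <- 0L
  trials <- 0L
  for (r in 1:150) {
    g <- matrix(rbinom(120 * 6, 2, 0.5), 120, 6)
    colnames(g) <- c("causal", paste0("null", 1:5))
    y <- 0.8 * g[, 1] + rnorm(120)
    m <- tryCatch(train_weights(tiny_gm(g), y), error = function(e) NULL)
    if (is.null(m)) next
    hits <- hits + sum(paste0("null", 1:5) %in% m$entries$snp_id)
    trials <- trials + 5L
  }
  rate <- hits / trials
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("scores follow the weighted-dosage formula and propagate missingness", {
  gm <- tiny_gm(rbind(c(2, 1), c(0, 2), c(1, NA)))
  m <- structure(list(
    entries = data.frame(snp_id = c("snp01", "snp02"),
                         effect_allele = c("A", "A"),
                         weight = c(0.5, -0.3), stringsAsFactors = FALSE),
    training_ids = character(0)), class = "score_model")
  sv <- compute_score(gm, m)
  expect_equal(sv$scores$raw, c(0.7, -0.6, NA))
  expect_true(is.na(sv$scores$standardized[3]))

  # all-zero weights: standardization must fail loudly
  m0 <- m
  m0$entries$weight <- c(0, 0)
  expect_error(compute_score(gm, m0), "zero or undefined variance")
})

test_that("scores are invariant under allele-strand relabelling", {
  set.seed(53)
  g <- matrix(rbinom(80 * 3, 2, 0.5), 80, 3)
  gm <- tiny_gm(g, effect = c("A", "C", "T"), other = c("G", "G", "G"))
  m <- structure(list(
    entries = data.frame(snp_id = c("snp01", "snp02", "snp03"),
                         effect_allele = c("A", "C", "T"),
                         weight = c(0.4, -0.2, 0.1), stringsAsFactors = FALSE),
    training_ids = character(0)), class = "score_model")
  base <- compute_score(gm, m)

  # relabel snp02 in the genotypes: swap alleles and flip dosages
  gm2 <- gm
  gm2$snps$effect_allele[2] <- "G"
  gm2$snps$other_allele[2] <- "C"
  gm2$dosages[, 2] <- 2 - gm2$dosages[, 2]
  flip_gm <- compute_score(gm2, m)
  expect_equal(flip_gm$scores$standardized, base$scores$standardized, tolerance = 1e-12)

  # relabel snp02 in the model instead: effect allele swapped, weight negated
  m2 <- m
  m2$entries$effect_allele[2] <- "G"
  m2$entries$weight[2] <- -m2$entries$weight[2]
  flip_model <- compute_score(gm, m2)
  expect_equal(flip_model$scores$standardized, base$scores$standardized, tolerance = 1e-12)

  # incompatible alleles are an error
  m3 <- m
  m3$entries$effect_allele[1] <- "T"
  expect_error(compute_score(gm, m3), "allele mismatch")
})

test_that("split hygiene is enforced between training and scoring", {
  set.seed(54)
  g <- matrix(rbinom(100 * 4, 2, 0.4), 100, 4)
  y <- g %*% c(0.5, 0.4, 0.3, 0.2) + rnorm(100, 0, 0.3)
  gm <- tiny_gm(g)
  train <- gm$sample_ids[1:50]
  m <- train_weights(subset_samples(gm, train), y[1:50])
  expect_error(compute_score(gm, m, standardize_in = gm$sample_ids),
               "split hygiene")
  expect_silent(sv <- compute_score(gm, m, standardize_in = gm$sample_ids[51:100]))

  # with alpha = 1 the raw score equals the SNP part of the training fit
  m1 <- train_weights(subset_samples(gm, train), y[1:50], alpha = 1)
  sv1 <- compute_score(gm, m1, check_split = FALSE)
  w_aligned <- m1$entries$weight[match(gm$snps$snp_id, m1$entries$snp_id)]
  expect_equal(sv1$scores$raw, unname(drop(gm$dosages %*% w_aligned)),
               tolerance = 1e-8)
})

test_that("score-colour regression reports adjusted R2 and per-SD effect", {
  set.seed(55)
  color <- sample(1:7, 400, TRUE)
  sv <- structure(list(
    scores = data.frame(sample_id = sprintf("S%03d", 1:400),
                        raw = color, standardized = drop(scale(color))),
    standardized_in = sprintf("S%03d", 1:400)), class = "score_vector")
  perfect <- score_color_r2(sv, color)
  expect_equal(perfect$adj_r2, 1)
  expect_equal(perfect$beta_per_sd, sd(color))

  sv$scores$standardized <- rnorm(400)
  indep <- score_color_r2(sv, color)
  expect_lt(indep$adj_r2, 0.01)
})
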