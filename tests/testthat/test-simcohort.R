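test_that("population frequencies follow the Balding-Nichols divergence", {
  # near-zero FST: population frequencies collapse onto the ancestral ones
  f <- draw_population_freqs(200, 3, 1e-6, seed = 1)
  expect_true(all(abs(sweep(f, 2, attr(f, "ancestral"))) < 0.01))

  # Hudson-style FST estimator over the panel recovers the target divergence
  f <- draw_population_freqs(1000, 2, 0.1, seed = 2)
  num <- (f[1, ] - f[2, ])^2
  den <- f[1, ] * (1 - f[2, ]) + f[2, ] * (1 - f[1, ])
  expect_lt(abs(sum(num) / sum(den) - 0.1), 0.02)

  # determinism and domain
  expect_identical(draw_population_freqs(50, 4, 0.2, seed = 9),
                   draw_population_freqs(50, 4, 0.2, seed = 9))
  expect_true(all(f > 0 & f < 1))
  expect_error(draw_population_freqs(10, 2, 1.2), "fst")
  expect_error(draw_population_freqs(10, 2, 0), "fst")
})

test_that("admixed genotypes have the expected dosage distribution", {
  f <- matrix(0.5, 1, 3)
  g <- simulate_genotypes(f, 1, 10000, seed = 3)$dosages
  expect_lt(abs(mean(g) - 1), 0.03)
  props <- table(factor(g, levels = 0:2)) / length(g)
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 0.02))

  # concentrated admixture: per-sample dosage means track own-population freqs
  f2 <- rbind(pop1 = rep(0.9, 200), pop2 = rep(0.1, 200))
  sim <- simulate_genotypes(f2, c(200, 0.02), 300, seed = 4)
  own <- max.col(sim$ancestry)
  m1 <- mean(sim$dosages[own == 1, ]) / 2
  expect_lt(abs(m1 - 0.9), 0.05)

  # boundary and errors
  empty <- simulate_genotypes(f2, c(1, 1), 0)
  expect_identical(dim(empty$dosages), c(0L, 200L))
  expect_error(simulate_genotypes(matrix(numeric(0), 0, 0), numeric(0), 5), "nonempty")
})

test_that("hair colour categories follow the liability model", {
  # degenerate: no signal, no noise, all mass in the category containing 0
  g <- matrix(sample(0:2, 100, TRUE), 50, 2)
  col <- simulate_hair_color(g, c(0, 0), thresholds = (1:6) - 3.5,
                             noise_sd = 1e-12, seed = 5)
  expect_true(all(col == col[1]))
  expect_equal(unname(unique(1L + findInterval(0, (1:6) - 3.5))), unique(col))

  # a dominant SNP drives the rank ordering
  set.seed(6)
  g1 <- matrix(rbinom(5000, 2, 0.5), ncol = 1)
  col <- simulate_hair_color(g1, 5, noise_sd = 0.3, seed = 7)
  expect_gt(cor(g1[, 1], as.integer(col), method = "spearman"), 0.9)

  # default calibration reproduces the target marginal distribution
  cfg <- scenario_config(n_samples = 20000L, n_background_snps = 5L, seed = 8)
  co <- simulate_cohort(cfg)
  freq <- tabulate(co$phenotypes$hair_color, 7) / 20000
  targets <- c(0.02, 0.01, 0.26, 0.26, 0.19, 0.15, 0.11)
  expect_true(all(abs(freq - targets) < 0.02))

  expect_error(simulate_hair_color(g, c(0, 0), thresholds = c(1, 2, 2, 3, 4, 5)),
               "increasing")
})

test_that("hormone concentrations are lognormal around the configured median", {
  cfg <- scenario_config(seed = 1)
  covs <- data.frame(sex = 0, age_months = 74, cs_use = 0)[rep(1, 50000), ]
  q <- matrix(1, 50000, 1)

  # degenerate spread
  cfg0 <- scenario_config(hormone_sigma = 1e-12, seed = 1)
  y0 <- simulate_hormones(cfg0, rnorm(10), q[1:10, , drop = FALSE], covs[1:10, ], seed = 2)
  expect_true(all(abs(y0 - exp(cfg0$hormone_mu)) < 1e-6))

  # median of the lognormal is exp(mu)
  y <- simulate_hormones(cfg, rnorm(50000), q, covs, seed = 3)
  expect_lt(abs(median(y) / exp(cfg$hormone_mu) - 1), 0.03)
  expect_true(all(y > 0))

  # minority-stress scenario shifts the minority group by b_systemic
  cfgS <- scenario_config("stress", b_systemic = 0.4, seed = 4)
  qs <- rdir <- matrix(c(rep(c(0.9, 0.1), 20000), rep(c(0.1, 0.9), 20000)),
                       ncol = 2, byrow = TRUE)
  covs2 <- covs[1:40000, ]
  ys <- simulate_hormones(cfgS, rnorm(40000), qs, covs2, seed = 5)
  minority <- max.col(qs) != 1
  diff <- mean(log(ys)[minority]) - mean(log(ys)[!minority])
  expect_lt(abs(diff - 0.4), 0.05)

  bad <- cfg
  bad$scenario <- "bogus"
  expect_error(simulate_hormones(bad, rnorm(5), q[1:5, , drop = FALSE], covs[1:5, ]),
               "unknown scenario")
})

test_that("scenario configuration enforces its invariants", {
  expect_error(scenario_config(fst = 1.5), "fst")
  expect_error(scenario_config(n_pigment_snps = 3, pigment_weights = c(1, 2)),
               "length")
  expect_error(scenario_config("null", b_local = 0.1), "b_local = b_systemic = 0")
  expect_silent(cfg <- scenario_config("local"))
  expect_equal(cfg$b_local, 0.08)
})

test_that("simulated cohorts are internally consistent and deterministic", {
  cfg <- fast_config(seed = 42)
  co <- simulate_cohort(cfg)
  expect_identical(co$genotypes$sample_ids, co$phenotypes$sample_id)
  expect_identical(co$phenotypes$sample_id, co$truth$sample_id)
  qcols <- grep("^q_", names(co$truth))
  expect_true(all(abs(rowSums(co$truth[, qcols]) - 1) < 1e-10))

  co2 <- simulate_cohort(cfg)
  expect_identical(co, co2)

  # byte-identical files from identical configs
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  write_cohort(co2, d2)
  for (f in c("cohort.vcf", "phenotypes.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("cohort files round-trip through the readers", {
  cfg <- scenario_config(n_samples = 40L, n_background_snps = 10L, seed = 11)
  co <- simulate_cohort(cfg)
  co$phenotypes$hair_color[3] <- NA  # missing hair colour survives the TSV
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)

  gm <- read_vcf(paths[["vcf"]])
  expect_identical(gm$sample_ids, co$genotypes$sample_ids)
  expect_lt(max(abs(gm$dosages - co$genotypes$dosages)), 1e-4)
  expect_equal(gm$snps$imputation_r2, co$genotypes$snps$imputation_r2)

  ph <- read_phenotypes(paths[["phenotypes"]])
  expect_true(is.na(ph$hair_color[3]))
  expect_equal(ph$cortisol_pgmg, co$phenotypes$cortisol_pgmg, tolerance = 1e-5)

  # VCF shape: one data line per SNP, one genotype column per sample
  lines <- readLines(paths[["vcf"]])
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 27)
  expect_length(strsplit(body[1], "\t")[[1]], 9 + 40)
})

test_that("stratification confounds marginally but not given true ancestry", {
  cfg <- scenario_config("stratification", n_samples = 5000L,
                         n_background_snps = 30L, seed = 13)
  co <- simulate_cohort(cfg)
  color <- co$phenotypes$hair_color
  logc <- log(co$phenotypes$cortisol_pgmg)
  expect_gt(cor(color, logc), 0.05)

  qcols <- as.matrix(co$truth[grep("^q_", names(co$truth))[-1]])
  r_col <- residuals(lm(color ~ qcols))
  r_log <- residuals(lm(logc ~ qcols))
  expect_lt(abs(cor(r_col, r_log)), 0.05)

  # under a local effect the partial correlation stays positive
  cfgL <- scenario_config("local", b_local = 0.15, n_samples = 5000L,
                          n_background_snps = 30L, seed = 14)
  coL <- simulate_cohort(cfgL)
  qL <- as.matrix(coL$truth[grep("^q_", names(coL$truth))[-1]])
  rc <- residuals(lm(coL$phenotypes$hair_color ~ qL))
  rl <- residuals(lm(log(coL$phenotypes$cortisol_pgmg) ~ qL))
  expect_gt(cor(rc, rl), 0.03)
})
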