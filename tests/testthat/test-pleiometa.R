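test_that("separate and mutual per-SNP models coincide for a single SNP", {
  set.seed(70)
  g <- matrix(rbinom(150, 2, 0.4), ncol = 1)
  gm <- tiny_gm(g)
  covs <- data.frame(sex = rbinom(150, 1, 0.5), age_months = rnorm(150, 74, 6),
                     cs_use = rbinom(150, 1, 0.1))
  y <- 0.2 * g[, 1] + rnorm(150)
  sep <- per_snp_associations(gm, y, covs, mode = "separate")
  mut <- per_snp_associations(gm, y, covs, mode = "mutual")
  expect_equal(sep$beta, mut$beta, tolerance = 1e-12)
  expect_equal(sep$se, mut$se, tolerance = 1e-12)

  # perfect LD in the mutual model: singular design reported
  g2 <- cbind(snpA = g[, 1], snpB = g[, 1])
  expect_error(per_snp_associations(tiny_gm(g2), y, covs, mode = "mutual"),
               "singular")
})

test_that("orientation flips negative-weight SNPs and is an involution", {
  est <- data.frame(snp_id = c("a", "b", "c"), beta = c(0.1, -0.1, 0.2),
                    se = c(0.05, 0.04, 0.06), stringsAsFactors = FALSE)
  wpos <- data.frame(snp_id = c("a", "b", "c"), weight = c(1, 2, 0.5))
  expect_equal(orient_effects(est, wpos)$beta, est$beta)

  w <- data.frame(snp_id = c("a", "b", "c"), weight = c(1, -0.4, 0.5))
  o1 <- orient_effects(est, w)
  expect_equal(o1$beta, c(0.1, 0.1, 0.2))
  expect_true(o1$flipped[2])
  # flipping with respect to the same weights twice returns the original
  o2 <- orient_effects(o1[, c("snp_id", "beta", "se")], w)
  expect_equal(o2$beta, est$beta)

  expect_error(orient_effects(est, wpos[1:2, ]), "absent")
})

test_that("IVW meta-analysis reproduces closed-form fixtures", {
  m0 <- meta_ivw(beta = c(0.1, 0.1, 0.1), se = c(0.1, 0.1, 0.1))
  expect_equal(unname(m0$pooled_fixed["beta"]), 0.1)
  expect_equal(m0$Q, 0)
  expect_equal(m0$i2_q, 0)

  # hand computation: w = (100, 100); pooled 0.1; Q = 100*.01*2 = 2
  m1 <- meta_ivw(beta = c(0.0, 0.2), se = c(0.1, 0.1))
  expect_equal(unname(m1$pooled_fixed["beta"]), 0.1, tolerance = 1e-12)
  expect_equal(m1$Q, 2, tolerance = 1e-12)
  expect_equal(m1$df, 1)
  expect_equal(m1$i2_q, 50, tolerance = 1e-12)
  expect_equal(unname(m1$pooled_fixed["se"]), sqrt(1 / 200), tolerance = 1e-12)

  expect_error(meta_ivw(beta = 0.1, se = 0.1), "at least 2")
  expect_error(meta_ivw(beta = c(0.1, 0.2), se = c(0.1, 0)), "positive")
})

test_that("Q is invariant to global sign flips and permutations", {
  set.seed(71)
  beta <- rnorm(9, 0.05, 0.1)
  se <- runif(9, 0.03, 0.1)
  m <- meta_ivw(beta = beta, se = se)
  expect_equal(meta_ivw(beta = -beta, se = se)$Q, m$Q, tolerance = 1e-12)
  perm <- sample(9)
  mp <- meta_ivw(beta = beta[perm], se = se[perm])
  expect_equal(mp$Q, m$Q, tolerance = 1e-12)
  expect_equal(mp$i2_tau, m$i2_tau, tolerance = 1e-8)

  # the Q-based I2 identity holds by construction
  expect_equal(m$i2_q, max(0, (m$Q - m$df) / m$Q) * 100, tolerance = 1e-12)
})

test_that("random-effects quantities match the metafor reference", {
  est <- pigmentation_snp_estimates()
  o <- orient_effects(est, est)
  m <- meta_ivw(o)
  r <- metafor::rma(yi = o$beta, sei = o$se, method = "REML")
  expect_equal(m$tau2_reml, r$tau2, tolerance = 1e-3)
  expect_equal(m$i2_tau, r$I2, tolerance = 1e-3)
  expect_equal(m$Q, unname(r$QE), tolerance = 1e-10)
})

test_that("the Egger regression matches weighted-least-squares oracles", {
  # exact fixture: beta = c * se has slope c and zero intercept
  se <- c(0.02, 0.05, 0.08, 0.11)
  e <- egger_test(data.frame(beta = 3 * se, se = se))
  expect_equal(unname(e$slope), 3, tolerance = 1e-10)
  expect_equal(unname(e$intercept), 0, tolerance = 1e-10)

  # k = 3 fixture against an explicit normal-equations WLS oracle
  est <- data.frame(beta = c(0.12, -0.05, 0.2), se = c(0.04, 0.07, 0.1))
  e3 <- egger_test(est)
  W <- diag(1 / est$se^2)
  X <- cbind(1, est$se)
  cf <- solve(t(X) %*% W %*% X, t(X) %*% W %*% est$beta)
  expect_equal(unname(e3$intercept), cf[1], tolerance = 1e-10)
  expect_equal(unname(e3$slope), cf[2], tolerance = 1e-10)

  # and against metafor's regression test (weighted lm form)
  est9 <- pigmentation_snp_estimates()
  o <- orient_effects(est9, est9)
  e9 <- egger_test(o)
  rt <- metafor::regtest(metafor::rma(yi = o$beta, sei = o$se, method = "FE"),
                         model = "lm")
  expect_equal(unname(e9$slope_p), rt$pval, tolerance = 1e-8)

  expect_error(egger_test(data.frame(beta = c(1, 2), se = c(0.1, 0.2))),
               "at least 3")
  expect_error(egger_test(data.frame(beta = c(1, 2, 3), se = rep(0.1, 3))),
               "untestable")
})

test_that("orientation search enumerates distinct sign patterns", {
  beta <- c(0.1, -0.2, 0.05)
  se <- c(0.05, 0.06, 0.04)
  res <- orientation_search(beta, se)
  expect_equal(nrow(res), 4)  # 2^(k-1) distinct up to global flip
  expect_true(all(res$Q >= 0))
  # the all-aligned pattern minimizes Q for these inputs
  aligned <- meta_ivw(beta = abs(beta), se = se)$Q
  expect_equal(min(res$Q), aligned, tolerance = 1e-12)
})
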