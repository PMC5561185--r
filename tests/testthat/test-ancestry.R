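two_pop_matrix <- function(n_per = 100, m = 2000, fst = 0.2, seed = 30) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  shape <- (1 - fst) / fst
  f1 <- rbeta(m, p * shape, (1 - p) * shape)
  f2 <- rbeta(m, p * shape, (1 - p) * shape)
  g <- rbind(
    matrix(rbinom(n_per * m, 2, rep(f1, each = n_per)), n_per, m),
    matrix(rbinom(n_per * m, 2, rep(f2, each = n_per)), n_per, m)
  )
  list(g = g, pop = rep(1:2, each = n_per))
}

test_that("PC1 separates discrete populations", {
  d <- two_pop_matrix()
  fit <- suppressWarnings(fit_pca(d$g, n_components = 5))  # monomorphic SNPs drop
  expect_gt(abs(cor(fit$pcs[, 1], d$pop)), 0.95)
  # standardized scores: mean 0, SD 1, mutually orthogonal
  expect_true(all(abs(colMeans(fit$pcs)) < 1e-8))
  expect_true(all(abs(apply(fit$pcs, 2, sd) - 1) < 1e-8))
  cc <- crossprod(fit$pcs) / (nrow(fit$pcs) - 1)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
})

test_that("eigen route agrees with brute-force SVD and classical MDS", {
  set.seed(31)
  X <- matrix(rbinom(50 * 100, 2, 0.4), 50, 100)
  X <- X[, apply(X, 2, sd) > 0]
  fit <- fit_pca(X, n_components = 8)

  # SVD oracle on the standardized matrix
  Xs <- scale(X)
  sv <- svd(Xs)
  scores_svd <- sv$u %*% diag(sv$d)
  for (k in 1:8) {
    expect_lt(min(max(abs(fit$pcs[, k] * fit$score_sd[k] + fit$score_mean[k] - scores_svd[, k])),
                  max(abs(fit$pcs[, k] * fit$score_sd[k] + fit$score_mean[k] + scores_svd[, k]))),
              1e-8)
  }

  # Torgerson MDS on Euclidean distances of the standardized matrix
  mds <- cmdscale(dist(Xs), k = 8)
  for (k in 1:8) {
    expect_gt(abs(cor(fit$pcs[, k], mds[, k])), 0.999)
  }
})

test_that("rank-k matrices are reconstructed exactly from k components", {
  set.seed(32)
  A <- matrix(rnorm(40 * 3), 40, 3)
  B <- matrix(rnorm(3 * 25), 3, 25)
  X <- A %*% B
  Xs <- scale(X)
  r <- qr(Xs)$rank
  fit <- fit_pca(X, n_components = r)
  raw_scores <- sweep(sweep(fit$pcs, 2, fit$score_sd, "*"), 2, fit$score_mean, "+")
  recon <- raw_scores %*% t(fit$loadings)
  expect_lt(max(abs(recon - Xs)), 1e-8)
  expect_error(fit_pca(X, n_components = r + 1), "rank")
})

test_that("standardized PCs are invariant to a global dosage rescaling", {
  set.seed(33)
  X <- matrix(rbinom(60 * 80, 2, 0.3), 60, 80)
  X <- X[, apply(X, 2, sd) > 0]
  f1 <- fit_pca(X, n_components = 4)
  f2 <- fit_pca(X * 3.7, n_components = 4)
  expect_equal(f1$pcs, f2$pcs, tolerance = 1e-8)
})

test_that("duplicated samples get identical scores; zero-variance SNPs warn", {
  set.seed(34)
  base <- matrix(rbinom(20 * 50, 2, 0.5), 20, 50)
  X <- rbind(base, base)
  fit <- fit_pca(X, n_components = 3)
  expect_equal(fit$pcs[1:20, ], fit$pcs[21:40, ], tolerance = 1e-10,
               ignore_attr = TRUE)

  X2 <- cbind(X, const = 1)
  expect_warning(fit_pca(X2, n_components = 3), "zero-variance")
})

test_that("the 4-SD reference rule uses strict exceedance per component", {
  set.seed(35)
  d <- two_pop_matrix(n_per = 60, m = 500, seed = 36)
  fit <- suppressWarnings(fit_pca(d$g, n_components = 4))
  ref_ids <- fit$sample_ids <- sprintf("S%03d", seq_len(nrow(fit$pcs)))

  # hand-crafted score geometry around the reference statistics
  ref <- fit$sample_ids[1:30]
  stats_ref <- list(mean = colMeans(fit$pcs[1:30, ]),
                    sd = apply(fit$pcs[1:30, ], 2, sd))
  fit$pcs[31, ] <- stats_ref$mean                               # at the mean
  fit$pcs[32, ] <- stats_ref$mean + c(0, 4, 0, 0) * stats_ref$sd  # exactly 4 SD
  fit$pcs[33, ] <- stats_ref$mean + c(0, 0, 0, 5) * stats_ref$sd  # 5 SD on PC4

  labels <- classify_outliers(fit, ref, k_sd = 4, n_check = 4)
  expect_equal(unname(labels[31]), "reference-like")
  expect_equal(unname(labels[32]), "reference-like")  # strict ">"
  expect_equal(unname(labels[33]), "outlier")
  expect_error(classify_outliers(fit, ref[1]), "size < 2")
})

test_that("subsample refits change the explained-variance structure", {
  d <- two_pop_matrix(n_per = 150, m = 100, fst = 0.3, seed = 41)
  gm <- tiny_gm(d$g)
  full <- suppressWarnings(fit_pca(gm, n_components = 5))
  again <- suppressWarnings(refit_subsample(gm, gm$sample_ids, n_components = 5))
  expect_equal(full$pcs, again$pcs, tolerance = 1e-10)

  # a homogeneous (single-population) subset has less leading structure
  sub <- suppressWarnings(refit_subsample(gm, gm$sample_ids[d$pop == 1],
                                          n_components = 5))
  expect_lt(sub$explained_share[1], full$explained_share[1])
  expect_error(refit_subsample(gm, character(0)), "empty")
})
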