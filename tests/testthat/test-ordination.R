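# ordination: rPCA (ALS matrix completion), automatic rank selection, CTF.

test_that("rpca equals the SVD of the rCLR matrix on zero-free tables", {
  ft <- dense_table(20, 14, lambda = 80, seed = 31)
  rp <- rpca(ft, rank = 3)
  sv <- svd(rclr(ft)$values)
  # principal angle between loading subspaces ~ 0
  cosines <- abs(colSums(rp$feature_loadings * sv$v[, 1:3]) /
                 sqrt(colSums(rp$feature_loadings^2)))
  expect_lt(max(abs(cosines - 1)), 1e-6)
  expect_equal(rp$singular_values, sv$d[1:3], tolerance = 1e-8)
  expect_true(all(diff(rp$proportion_explained) <= 1e-12))
})

test_that("rank-1 structure plus small noise loads on PC1", {
  set.seed(32)
  u <- rnorm(25); v <- rnorm(15)
  m <- round(exp(outer(u, v) * 0.8 + 5 + matrix(rnorm(25 * 15, 0, 0.03),
                                                25)))
  ft <- toy_table(matrix(as.numeric(m), 25, 15))
  rp <- rpca(ft, rank = 2)
  expect_gte(rp$proportion_explained[1], 0.95)
})

test_that("rpca observed-entry loss is non-increasing and handles zeros", {
  sim <- small_cohort(10, 25, seed = 33)
  ft <- filter_rpca(sim$bundle$table)
  expect_gt(sum(ft$counts == 0), 0)
  rp <- rpca(ft, rank = 2)
  expect_true(all(diff(rp$loss_trajectory) <= 1e-8))
  expect_true(all(is.finite(rp$sample_scores)))
  expect_error(rpca(ft, rank = 1000), class = "crcmb_bad_argument")
})

test_that("rpca distances are invariant to sample and feature order", {
  sim <- small_cohort(9, 18, seed = 34)
  ft <- filter_rpca(sim$bundle$table)
  rp1 <- rpca(ft, rank = 2)
  perm <- rev(seq_along(ft$sample_ids))
  fperm <- sample(length(ft$feature_ids))
  ftp <- crcmb:::subset_table(ft, samples = perm, features = fperm)
  rp2 <- rpca(ftp, rank = 2)
  d1 <- as.matrix(dist(rp1$sample_scores))
  d2 <- as.matrix(dist(rp2$sample_scores))[rownames(d1), colnames(d1)]
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("auto_rank recovers the generating rank and shrinks under noise", {
  make_rank_table <- function(k, n = 40, p = 30, seed = 1) {
    set.seed(seed)
    U <- matrix(rnorm(n * k), n); V <- matrix(rnorm(k * p), k)
    m <- exp(U %*% V * 0.5 + 4 + matrix(rnorm(n * p, 0, 0.05), n))
    toy_table(matrix(as.numeric(round(m)), n, p))
  }
  hits2 <- sum(vapply(1:5, function(s) {
    auto_rank(make_rank_table(2, seed = s), 2:5, seed = s) == 2L
  }, logical(1)))
  expect_gte(hits2, 4)
  expect_equal(auto_rank(make_rank_table(3, seed = 7), 2:5, seed = 7), 3L)

  # pure noise: held-out error is monotone in rank -> smallest candidate
  set.seed(35)
  noise <- toy_table(matrix(rpois(40 * 30, 50) + 1, 40, 30))
  expect_equal(auto_rank(noise, 2:4, seed = 2), 2L)
  expect_error(auto_rank(noise, integer(0)), class = "crcmb_bad_argument")
})

test_that("ctf recovers planted rank-2 factors on a complete tensor", {
  # build counts whose rclr is (approximately) a known rank-2 tensor
  set.seed(36)
  n <- 20; p <- 15
  A <- matrix(rnorm(n * 2), n); B <- matrix(runif(4, 0.5, 1.5), 2)
  C <- matrix(rnorm(p * 2), p)
  md <- paired_meta(n)
  counts <- matrix(0, 2 * n, p, dimnames = list(md$sample_id,
                                                sprintf("f%02d", 1:p)))
  for (j in seq_len(n)) for (s in 1:2) {
    eta <- rowSums(sweep(C, 2, A[j, ] * B[s, ], "*"))
    counts[2 * (j - 1) + s, ] <- round(exp(eta - max(eta) + 8))
  }
  ft <- feature_table(counts)
  fit <- ctf(ft, md, k = 2)
  congr <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  # match fitted feature factors to planted ones (either order)
  Cc <- scale(C, scale = FALSE)  # rclr centering removes feature means
  pairs <- rbind(c(1, 1, 2, 2), c(1, 2, 2, 1))
  best <- max(min(congr(fit$feature_loadings[, 1], Cc[, 1]),
                  congr(fit$feature_loadings[, 2], Cc[, 2])),
              min(congr(fit$feature_loadings[, 1], Cc[, 2]),
                  congr(fit$feature_loadings[, 2], Cc[, 1])))
  expect_gte(best, 0.95)
})

test_that("ctf separates subjects and flags a planted tissue effect", {
  sim <- small_cohort(15, 40, seed = 37, subject_sd = 1.5,
                      n_tissue = 12, tissue_lfc_range = c(2, 3),
                      n_interaction = 0)
  ft <- filter_ctf(sim$bundle$table, min_samples = 5, min_total = 50)
  fit <- ctf(ft, sim$bundle$metadata, k = 3)
  expect_equal(nrow(fit$subject_scores), 15L)
  expect_equal(nrow(fit$sample_scores), 30L)

  deltas <- paired_pc_deltas(fit)
  expect_equal(nrow(deltas), 15L)
  ps <- vapply(1:3, function(k) {
    perm_paired_t(deltas[, k], n_perm = 999, seed = 5)$p_value
  }, numeric(1))
  expect_equal(min(ps), 0.001)

  # deterministic refit
  fit2 <- ctf(ft, sim$bundle$metadata, k = 3)
  expect_equal(fit$subject_scores, fit2$subject_scores)

  # silhouette-style check: subject labels beat random labels
  dsamp <- as.matrix(dist(fit$sample_scores))
  subj <- sub("[NT]$", "", rownames(dsamp))
  within_subj <- mean(dsamp[outer(subj, subj, "==") &
                            upper.tri(dsamp)])
  overall <- mean(dsamp[upper.tri(dsamp)])
  expect_lt(within_subj, overall)
})

test_that("subject_distance and paired_pc_deltas follow the geometry", {
  fit <- list(subject_scores = rbind(S1 = c(0, 0), S2 = c(3, 4)),
              sample_scores = rbind(S1N = c(0.5, 1), S1T = c(1, 2),
                                    S2N = c(0, 0), S2T = c(0, 0)),
              subjects = data.frame(subject_id = c("S1", "S2"),
                                    normal = c("S1N", "S2N"),
                                    tumor = c("S1T", "S2T")))
  class(fit) <- "crcmb_ctf"
  d <- subject_distance(fit)
  expect_equal(d$values["S1", "S2"], 5)
  expect_true(isSymmetric(d$values))
  expect_true(all(diag(d$values) == 0))
  deltas <- paired_pc_deltas(fit)
  expect_equal(unname(deltas["S1", ]), c(0.5, 1))
  expect_equal(unname(deltas["S2", ]), c(0, 0))
})

test_that("ctf is invariant to feature reordering", {
  sim <- small_cohort(8, 16, seed = 38)
  ft <- sim$bundle$table
  fit1 <- ctf(ft, sim$bundle$metadata, k = 2)
  fperm <- sample(length(ft$feature_ids))
  fit2 <- ctf(crcmb:::subset_table(ft, features = fperm),
              sim$bundle$metadata, k = 2)
  expect_equal(fit1$subject_scores, fit2$subject_scores,
               tolerance = 1e-6)
  expect_equal(fit1$feature_loadings[ft$feature_ids[fperm], ],
               fit2$feature_loadings, tolerance = 1e-6)
})
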