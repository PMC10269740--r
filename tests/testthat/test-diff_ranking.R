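# diff_ranking: NB mixed-model differentials (MAP and MCMC modes) and the
# greedy extreme-feature cover.

test_that("fit_differentials returns centered log2 differentials with valid ranks", {
  sim <- small_cohort(10, 15, seed = 41, n_tissue = 4, n_interaction = 0)
  ft <- sim$bundle$table
  dr <- fit_differentials(ft, sim$bundle$metadata, design = "tissue",
                          method = "map", seed = 1)
  d <- dr$differentials
  expect_equal(sort(d$rank), seq_len(nrow(d)))
  expect_lt(abs(mean(d$differential)), 1e-8)
  expect_true(all(is.finite(d$sd)))

  # interaction design carries three contrasts
  dr2 <- fit_differentials(ft, sim$bundle$metadata,
                           design = "tissue_x_survival",
                           method = "map", seed = 1, compute_sd = FALSE)
  expect_setequal(unique(dr2$differentials$contrast),
                  c("tissue", "survival", "interaction"))
  for (cn in unique(dr2$differentials$contrast)) {
    dd <- dr2$differentials[dr2$differentials$contrast == cn, ]
    expect_equal(sort(dd$rank), seq_len(nrow(dd)))
    expect_lt(abs(mean(dd$differential)), 1e-8)
  }
})

test_that("planted tissue effects occupy the extremes of the ranking", {
  # |log2 effect| >= 1.5 features should sit in the top decile of their end
  hits <- vapply(1:3, function(s) {
    truth <- synthetic_truth(n_features = 60, n_tissue = 10,
                             tissue_lfc_range = c(1.5, 2),
                             n_interaction = 0, seed = 40 + s)
    sim <- generate_cohort(n_subjects = 30, n_short = 15, truth = truth,
                           seed = 40 + s)
    ft <- filter_dr(sim$bundle$table)
    dr <- fit_differentials(ft, sim$bundle$metadata, design = "tissue",
                            method = "map", seed = s, compute_sd = FALSE)
    d <- dr$differentials
    eff <- truth$tissue_effect[d$feature_id]
    up <- mean(d$rank[eff >= 1.5] / nrow(d))        # tumor extreme
    dn <- mean(d$rank[eff <= -1.5] / nrow(d))       # normal extreme
    up <= 0.10 && dn >= 0.90
  }, logical(1))
  expect_gte(sum(hits), 2)
})

test_that("rank order is invariant to feature and sample relabeling", {
  sim <- small_cohort(8, 12, seed = 42, n_tissue = 3, n_interaction = 0)
  ft <- sim$bundle$table
  md <- sim$bundle$metadata
  dr1 <- fit_differentials(ft, md, "tissue", method = "map", seed = 2,
                           compute_sd = FALSE)
  fperm <- sample(length(ft$feature_ids))
  sperm <- rev(seq_along(ft$sample_ids))
  dr2 <- fit_differentials(crcmb:::subset_table(ft, samples = sperm,
                                                features = fperm),
                           md, "tissue", method = "map", seed = 2,
                           compute_sd = FALSE)
  d1 <- dr1$differentials
  d2 <- dr2$differentials[match(d1$feature_id,
                                dr2$differentials$feature_id), ]
  expect_equal(d1$differential, d2$differential, tolerance = 1e-5)
})

test_that("doubling sequencing depth barely moves the differentials", {
  sim <- small_cohort(25, 12, seed = 43, n_tissue = 4, n_interaction = 0)
  ft <- sim$bundle$table
  md <- sim$bundle$metadata
  d1 <- fit_differentials(ft, md, "tissue", method = "map", seed = 3,
                          compute_sd = FALSE)$differentials
  ft2 <- feature_table(ft$counts * 2)
  d2 <- fit_differentials(ft2, md, "tissue", method = "map", seed = 3,
                          compute_sd = FALSE)$differentials
  expect_lt(max(abs(d1$differential - d2$differential)), 0.1)
})

test_that("mcmc mode agrees with the map approximation on a small cohort", {
  sim <- small_cohort(10, 12, seed = 44, n_tissue = 4,
                      tissue_lfc_range = c(1.5, 2), n_interaction = 0)
  ft <- sim$bundle$table
  md <- sim$bundle$metadata
  dmcmc <- fit_differentials(ft, md, "tissue", iterations = 600,
                             seed = 4, method = "mcmc")$differentials
  dmap <- fit_differentials(ft, md, "tissue", seed = 4,
                            method = "map")$differentials
  expect_gt(cor(dmcmc$differential, dmap$differential), 0.8)
  # deterministic under seed
  dmcmc2 <- fit_differentials(ft, md, "tissue", iterations = 600,
                              seed = 4, method = "mcmc")$differentials
  expect_identical(dmcmc$differential, dmcmc2$differential)
})

test_that("zero interaction truth leaves interaction differentials null", {
  ps <- vapply(1:3, function(s) {
    truth <- synthetic_truth(n_features = 40, n_tissue = 8,
                             n_interaction = 0, seed = 50 + s)
    sim <- generate_cohort(n_subjects = 24, n_short = 12, truth = truth,
                           seed = 50 + s)
    ft <- filter_dr(sim$bundle$table)
    dr <- fit_differentials(ft, sim$bundle$metadata,
                            design = "tissue_x_survival",
                            method = "map", seed = s, compute_sd = FALSE)
    d <- dr$differentials[dr$differentials$contrast == "interaction", ]
    x <- d$differential
    suppressWarnings(stats::ks.test(x / sd(x), "pnorm")$p.value)
  }, numeric(1))
  expect_gt(stats::median(ps), 0.05)
})

test_that("greedy cover replays the literal procedure on a toy fixture", {
  # presence matrix and ranks chosen so the cover needs three features
  pres <- matrix(c(1, 0, 0, 0, 0,
                   0, 1, 0, 0, 0,
                   0, 0, 1, 0, 0,
                   1, 0, 0, 1, 0), 4, 5, byrow = TRUE,
                 dimnames = list(paste0("s", 1:4), paste0("f", 1:5)))
  ft <- feature_table(pres * 3)
  dr <- fake_dr(c(f1 = 2, f2 = 1.5, f3 = 0.5, f4 = -1, f5 = -2))

  # independent oracle: literal step-by-step replay of the quoted greedy
  ord <- c("f1", "f2", "f3", "f4", "f5")
  sel <- character(0)
  for (f in ord) {
    sel <- c(sel, f)
    if (all(rowSums(pres[, sel, drop = FALSE]) > 0)) break
  }
  cover <- select_extreme_cover(dr, ft, direction = "top")
  expect_identical(cover$features, sel)
  expect_identical(cover$features, c("f1", "f2", "f3"))

  # ledger covers every sample; dropping the last feature breaks coverage
  expect_false(anyNA(cover$covered))
  short <- cover$features[-length(cover$features)]
  expect_true(any(rowSums(pres[, short, drop = FALSE]) == 0))

  # bottom direction walks from the other extreme
  cover_b <- select_extreme_cover(dr, ft, direction = "bottom")
  expect_equal(cover_b$features[1], "f5")
})

test_that("cover handles size-1 covers, scopes, and unreachable samples", {
  m <- matrix(c(5, 1, 0,
                3, 0, 2,
                9, 4, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("S01N", "S01T", "S02N"), paste0("f", 1:3)))
  ft <- feature_table(m)
  dr <- fake_dr(c(f1 = 3, f2 = 1, f3 = -1))
  expect_identical(select_extreme_cover(dr, ft, direction = "top")$features,
                   "f1")

  md <- sample_metadata(data.frame(
    sample_id = c("S01N", "S01T", "S02N"),
    subject_id = c("S01", "S01", "S02"),
    tissue = c("normal", "tumor", "normal"),
    survival = "short"))
  tum <- select_extreme_cover(dr, ft, md, direction = "bottom",
                              scope = "same_tissue", tissue = "tumor")
  expect_identical(names(tum$covered), "S01T")

  ft0 <- feature_table(rbind(m, S03T = c(0, 0, 0)))
  err <- expect_error(select_extreme_cover(dr, ft0, direction = "top"),
                      class = "crcmb_cover_unattainable")
  expect_match(conditionMessage(err), "S03T")
})
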