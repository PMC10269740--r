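# survival_models: communality screen, quartile sets, ALR indices, mixed
# and logistic models, stratification.

fake_ordination <- function(loadings) {
  structure(list(feature_loadings = loadings), class = "crcmb_ordination")
}

test_that("communality_select applies sqrt-sum-of-squares with an inclusive threshold", {
  L <- rbind(a = c(0.1, 0, 0),
             b = c(0, 0, 0),
             c = c(0.006, 0.008, 0),   # communality 0.01 exactly
             d = c(0.001, 0.001, 0.001))
  sel <- communality_select(fake_ordination(L), threshold = 0.01)
  expect_setequal(sel, c("a", "c"))
  expect_error(communality_select(fake_ordination(L), threshold = 10),
               class = "crcmb_empty_selection")
})

test_that("loading_quartile_sets matches the hand-computed example", {
  L <- cbind(PC1 = c(-3, -1, 0, 1, 3), PC2 = 0)
  rownames(L) <- paste0("f", 1:5)
  qs <- loading_quartile_sets(fake_ordination(L), pc = 1,
                              candidates = rownames(L))
  expect_identical(qs$upper, "f5")
  expect_identical(qs$lower, "f1")
  expect_equal(c(qs$q1, qs$q3), c(-1, 1))

  # symmetric loadings give equal-size sets; non-candidates never appear
  L2 <- cbind(PC1 = c(-2, -1, 0, 1, 2, 5), PC2 = 0)
  rownames(L2) <- paste0("g", 1:6)
  qs2 <- loading_quartile_sets(fake_ordination(L2), pc = 1,
                               candidates = paste0("g", 1:5))
  expect_equal(length(qs2$upper), length(qs2$lower))
  expect_false("g6" %in% c(qs2$upper, qs2$lower))

  L3 <- cbind(PC1 = rep(1, 5)); rownames(L3) <- paste0("h", 1:5)
  expect_error(loading_quartile_sets(fake_ordination(L3), 1,
                                     rownames(L3)),
               class = "crcmb_degenerate_loadings")
})

test_that("compute_alr matches hand computation and validates sets", {
  m <- matrix(c(3, 4, 7,
                3, 5, 9), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
  ft <- feature_table(m)
  alr <- compute_alr(ft, num = c("f1", "f2"), den = "f3", pseudocount = 1)
  expect_equal(unname(alr$values["s1"]), log2(9 / 8))
  expect_equal(unname(alr$values["s2"]), 0)  # 10/10 after pseudocount

  expect_error(compute_alr(ft, c("f1"), c("f1", "f3")),
               class = "crcmb_bad_argument")
  expect_error(compute_alr(ft, "f1", character(0)),
               class = "crcmb_bad_argument")
  expect_error(compute_alr(ft, "f1", "nope"),
               class = "crcmb_bad_argument")

  # scale invariance at pseudocount 0, order invariance always
  alr0a <- compute_alr(ft, "f1", "f3", pseudocount = 0)
  ft5 <- feature_table(m * 5)
  alr0b <- compute_alr(ft5, "f1", "f3", pseudocount = 0)
  expect_equal(alr0a$values, alr0b$values)
  ftp <- crcmb:::subset_table(ft, samples = 2:1, features = 3:1)
  alrp <- compute_alr(ftp, num = c("f2", "f1"), den = "f3")
  expect_equal(alrp$values[names(alr$values)], alr$values)
})

test_that("lme_alr recovers a planted tissue shift and the paired identity", {
  # direct construction: value = subject intercept + 1.5 * tumor + noise
  set.seed(61)
  md <- paired_meta(40)
  subj_eff <- rnorm(40, 0, 1)
  tumor <- md$tissue == "tumor"
  vals <- setNames(subj_eff[match(md$subject_id,
                                  unique(md$subject_id))] +
                   1.5 * tumor + rnorm(80, 0, 0.3), md$sample_id)
  fit <- lme_alr(vals, md, design = "tissue")
  est <- fit$estimates[fit$estimates$term == "tissuetumor", ]
  expect_lt(abs(est$estimate - 1.5), 0.2)
  expect_gt(fit$ranef_variance, 0.3)

  # balanced paired design: tissue coefficient = mean within-subject diff
  pm <- crcmb:::paired_map(md)
  delta_mean <- mean(vals[pm$tumor] - vals[pm$normal])
  expect_equal(est$estimate, delta_mean, tolerance = 1e-6)
})

test_that("lme_alr interaction design estimates the survival-specific shift", {
  set.seed(62)
  md <- paired_meta(60, n_short = 30)
  subj_eff <- rnorm(60, 0, 1)
  tumor <- md$tissue == "tumor"
  short <- md$survival == "short"
  vals <- setNames(subj_eff[match(md$subject_id,
                                  unique(md$subject_id))] +
                   1 * tumor + 2 * (tumor & short) + rnorm(120, 0, 0.3),
                   md$sample_id)
  fit <- lme_alr(vals, md, design = "tissue_x_survival")
  inter <- fit$estimates[fit$estimates$term == "tissuetumor:survivalshort", ]
  expect_lt(abs(inter$estimate - 2), 0.3)
  expect_lt(inter$p, 0.001)
})

test_that("logistic_survival reproduces the closed-form 2x2 odds ratio", {
  # exposed short=10 long=40; unexposed short=20 long=30
  n <- c(10, 40, 20, 30)
  exposed <- rep(c(1, 1, 0, 0), n)
  surv <- rep(c("short", "long", "short", "long"), n)
  md <- sample_metadata(data.frame(
    sample_id = sprintf("P%03dT", 1:100),
    subject_id = sprintf("P%03d", 1:100),
    tissue = "tumor", survival = surv))
  pred <- setNames(exposed, md$subject_id)
  fit <- logistic_survival(pred, md, adjust = FALSE)
  expect_equal(fit$estimates$or, (10 * 30) / (40 * 20),
               tolerance = 1e-6)
  expect_equal(fit$model, "crude")
})

test_that("logistic_survival adjusts for the clinical covariates and flags separation", {
  sim <- small_cohort(60, 12, seed = 63)
  md <- sim$bundle$metadata
  set.seed(63)
  pred <- setNames(rnorm(60), unique(md$subject_id))
  fit <- logistic_survival(pred, md, adjust = TRUE)
  expect_equal(fit$model, "adjusted")
  expect_true(all(c("age_cat", "sex", "asa", "location", "stage",
                    "differentiation", "period", "radical") %in%
                  fit$covariates))
  expect_true(any(grepl("^x$", fit$estimates$term)))
  # null predictor: CI covers 1
  x <- fit$estimates[fit$estimates$term == "x", ]
  expect_true(x$ci_low < 1 && x$ci_high > 1)

  # perfectly separating predictor errors, Firth fallback works
  surv01 <- as.numeric(crcmb:::per_subject_metadata(md)$survival ==
                       "short")
  sep <- setNames(surv01 * 2 - 1, unique(md$subject_id))
  expect_error(logistic_survival(sep, md), class = "crcmb_separation")
  firth <- logistic_survival(sep, md, penalized = TRUE)
  expect_true(is.finite(firth$estimates$or[1]))
})

test_that("stratify_scores produces the documented groupings", {
  s10 <- setNames(1:10, paste0("S", 1:10))
  ms <- stratify_scores(s10, "median_split")
  expect_equal(as.vector(table(ms)), c(5, 5))
  t9 <- setNames(1:9, paste0("S", 1:9))
  tt <- stratify_scores(t9, "tertiles")
  expect_equal(as.vector(table(tt)), c(3, 3, 3))
  q <- stratify_scores(setNames(1:8, paste0("S", 1:8)),
                       "quadrants", scores2 = setNames(c(1:4, 4:1),
                                                       paste0("S", 1:8)))
  expect_equal(sum(table(q)), 8L)
  expect_equal(nlevels(q), 4L)
  expect_error(stratify_scores(rep(1, 5), "median_split"),
               class = "crcmb_degenerate_scores")
})
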