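# preprocess: the three filter rules (strict-inequality boundaries),
# rarefaction, and the rCLR/CLR transforms.

test_that("filter_ctf honors its prevalence and total-count boundaries", {
  # f1: present in 19 samples, large total -> removed
  # f2: present in 20 samples, total exactly 100 -> retained
  # f3: present everywhere, high total -> retained
  m <- matrix(0, 25, 3)
  m[1:19, 1] <- 30
  m[1:20, 2] <- 5
  m[, 3] <- 50
  ft <- toy_table(m)
  out <- filter_ctf(ft, min_samples = 20, min_total = 100)
  expect_setequal(out$feature_ids, c("f02", "f03"))

  # all features pass -> identical table
  ft2 <- dense_table(25, 4, lambda = 50, seed = 2)
  expect_identical(filter_ctf(ft2)$counts, ft2$counts)
  expect_error(filter_ctf(toy_table(matrix(1, 2, 2))),
               class = "crcmb_all_filtered")
})

test_that("filter_rpca uses the fraction of the table actually passed", {
  m <- matrix(0, 100, 3)
  m[1:9, 1] <- 100    # present in 9/100 < 10% -> removed
  m[1:12, 2] <- 1     # 12% prevalence, total 12 >= 10 -> retained
  m[1:50, 3] <- 20
  ft <- toy_table(m)
  out <- filter_rpca(ft, min_frac = 0.10, min_total = 10)
  expect_setequal(out$feature_ids, c("f02", "f03"))

  # feature with total exactly 10 at 12% prevalence is retained
  m2 <- matrix(5, 25, 2)
  m2[, 1] <- 0; m2[1:3, 1] <- c(4, 3, 3)  # 3/25 = 12%, total 10
  out2 <- filter_rpca(toy_table(m2), min_frac = 0.10, min_total = 10)
  expect_true("f01" %in% out2$feature_ids)

  # no removal -> identity
  ft3 <- dense_table(20, 5, seed = 4)
  expect_identical(filter_rpca(ft3)$counts, ft3$counts)
})

test_that("filter_dr keeps features at the exact 10% prevalence boundary", {
  # 20 samples; feature at rel abundance 0.002 in exactly 2 samples (10%)
  m <- matrix(1000, 20, 2)
  m <- cbind(m, 0)
  m[1:2, 3] <- 4  # 4/2004 ~ 0.002 in 2/20 = 10% of samples
  ft <- toy_table(m)
  out <- filter_dr(ft, rel_threshold = 0.001, min_frac = 0.10)
  expect_true("f03" %in% out$feature_ids)

  # all-zero feature removed; ubiquitous feature retained
  m2 <- cbind(matrix(500, 10, 2), 0)
  out2 <- filter_dr(toy_table(m2))
  expect_setequal(out2$feature_ids, c("f01", "f02"))
})

test_that("filters commute with sample order and never alter counts", {
  ft <- small_cohort(8, 25, seed = 6)$bundle$table
  perm <- sample(length(ft$sample_ids))
  ftp <- crcmb:::subset_table(ft, samples = perm)
  filters <- list(function(x) filter_ctf(x, min_samples = 5,
                                         min_total = 50),
                  filter_rpca, filter_dr)
  for (f in filters) {
    a <- f(ft)
    b <- f(ftp)
    expect_setequal(a$feature_ids, b$feature_ids)
    expect_identical(b$counts[ft$sample_ids[perm], a$feature_ids],
                     a$counts[ft$sample_ids[perm], ])
  }
})

test_that("rarefy subsamples to exact depth, drops shallow samples, is seeded", {
  set.seed(11)
  m <- matrix(rpois(5 * 6, 800), 5, 6)
  m[3, ] <- c(100, 50, 30, 10, 5, 5)  # total 200 < depth
  ft <- toy_table(m)
  r <- rarefy(ft, depth = 2500, seed = 7)
  expect_true(all(rowSums(r$counts) == 2500))
  expect_equal(attr(r, "dropped_samples"), "s03")
  # subsample is a sub-multiset of the original counts
  expect_true(all(r$counts <= ft$counts[r$sample_ids, ]))
  # same seed -> identical; different seed -> different
  r2 <- rarefy(ft, depth = 2500, seed = 7)
  expect_identical(r$counts, r2$counts)
  r3 <- rarefy(ft, depth = 2500, seed = 8)
  expect_false(identical(r$counts, r3$counts))
  expect_error(rarefy(toy_table(matrix(1, 2, 2)), depth = 100, seed = 1),
               class = "crcmb_all_filtered")
})

test_that("rarefaction preserves expected relative abundances", {
  comp <- c(500, 300, 120, 60, 20)
  ft <- toy_table(matrix(comp, 1, 5))
  draws <- vapply(1:300, function(s) {
    rarefy(ft, depth = 250, seed = s)$counts[1, ] / 250
  }, numeric(5))
  p <- comp / sum(comp)
  se <- sqrt(p * (1 - p) / 250) / sqrt(300)
  expect_true(all(abs(rowMeans(draws) - p) < 2 * se + 1e-12))
})

test_that("rclr centers observed entries and leaves zeros missing", {
  ft <- toy_table(matrix(c(5, 5, 5, 5, 0, 5), 2, 3, byrow = TRUE))
  r <- rclr(ft)
  expect_equal(unname(r$values[1, ]), c(0, 0, 0))
  expect_equal(unname(r$values[2, ]), c(0, NA, 0))
  expect_true(all(is.na(r$values) == (ft$counts == 0)))

  # scale invariance
  ft10 <- toy_table(ft$counts * 10)
  expect_equal(rclr(ft10)$values, r$values)

  expect_error(rclr(toy_table(matrix(c(5, 0, 0, 3, 2, 1), 2, 3,
                                     byrow = TRUE))),
               class = "crcmb_degenerate_sample")
})

test_that("clr matches the hand-computed example and centers rows", {
  ft <- toy_table(matrix(c(3, 1, 1, 1), 2, 2, byrow = TRUE))
  v <- clr(ft, pseudocount = 1)$values
  expect_equal(unname(v[2, ]), c(0, 0))
  expect_equal(unname(v[1, ]), c((log(4) - log(2)) / 2,
                                 -(log(4) - log(2)) / 2),
               tolerance = 1e-10)
  big <- clr(dense_table(6, 9, seed = 5))
  expect_true(all(abs(rowMeans(big$values)) < 1e-12))
})

test_that("rclr equals clr with vanishing pseudocount on zero-free tables", {
  ft <- dense_table(8, 10, seed = 12)
  a <- rclr(ft)$values
  b <- clr(ft, pseudocount = 1e-12)$values
  expect_lt(max(abs(a - b)), 1e-9)
})
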