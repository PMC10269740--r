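# Permutation statistics: sign-flip paired t, permutative two-sample
# (Welch or pooled) t, PERMANOVA on a distance matrix, and Cohen's d.
# Every permutation p-value uses the (b+1)/(m+1) estimator, which is a
# strictly valid p-value and gives the familiar floor of 0.001 at 999
# permutations.

new_test_result <- function(test, statistic, p_value, n_perm, seed,
                            effect_size = NA_real_, extra = list()) {
  structure(c(list(test = test, statistic = statistic,
                   effect_size = effect_size, p_value = p_value,
                   n_perm = n_perm, seed = seed), extra),
            class = "crcmb_test")
}

#' @export
print.crcmb_test <- function(x, ...) {
  cat(sprintf("<crcmb_test> %s: statistic = %.4g, p = %.4g (%d permutations)\n",
              x$test, x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Sign-flip permutation paired t test
#'
#' The observed statistic is the classical paired t statistic
#' `mean(d) / (sd(d)/sqrt(n))`.  The null distribution flips the sign of
#' each within-subject difference independently — the exchangeability unit
#' of a paired design — and the two-sided p-value is
#' `(b + 1) / (n_perm + 1)` where `b` counts permuted `|t*| >= |t_obs|`.
#' Differences with zero spread but nonzero mean give an infinite observed
#' statistic; only all-same-sign flips tie it, so such data attain the
#' minimum p-value.
#'
#' @param deltas numeric vector of within-subject differences.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param tail `"two"` (default), `"greater"` or `"less"`.
#' @return a `crcmb_test` with the one-sample Cohen's d as effect size.
#' @export
perm_paired_t <- function(deltas, n_perm = 999, seed = 42,
                          tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  assert_scalar_count(n_perm, "n_perm")
  deltas <- as.numeric(deltas)
  n <- length(deltas)
  if (n < 2 || anyNA(deltas) || any(!is.finite(deltas))) {
    abort_crcmb("need >= 2 finite differences", "crcmb_bad_argument")
  }
  s <- stats::sd(deltas)
  m <- mean(deltas)
  if (s == 0 && m == 0) {
    abort_crcmb("all differences are zero: no variance to test",
                "crcmb_zero_variance")
  }
  t_obs <- if (s == 0) sign(m) * Inf else m / (s / sqrt(n))

  ss <- sum(deltas^2)
  d_sorted <- sort(deltas)  # null is invariant to the order of the deltas
  t_star <- with_seed(derive_seed(seed, 1L), {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm)
    means <- as.vector(signs %*% d_sorted) / n
    vars <- pmax(0, (ss - n * means^2) / (n - 1))
    means / sqrt(vars / n)  # +-Inf when a flip reproduces zero spread
  })
  b <- switch(tail,
              two = sum(abs(t_star) >= abs(t_obs)),
              greater = sum(t_star >= t_obs),
              less = sum(t_star <= t_obs))
  d_eff <- if (s == 0) sign(m) * Inf else m / s
  new_test_result("perm_paired_t", t_obs, (b + 1) / (n_perm + 1),
                  n_perm, seed, effect_size = d_eff,
                  extra = list(tail = tail, n = n))
}

two_sample_t_stat <- function(a, b, var.equal = FALSE) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  md <- mean(a) - mean(b)
  if (var.equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0) return(if (md == 0) 0 else sign(md) * Inf)
    md / sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se2 <- va / na + vb / nb
    if (se2 == 0) return(if (md == 0) 0 else sign(md) * Inf)
    md / sqrt(se2)
  }
}

#' Permutative two-sample t test (Welch by default)
#'
#' Observed statistic is the closed-form Welch (or pooled, with
#' `var.equal = TRUE`) t statistic; the null permutes group labels over the
#' pooled values.  Two groups with zero spread and equal means give
#' statistic 0 and p = 1 by convention.  The two-sample Cohen's d
#' (pooled-SD form) is attached as the effect size.
#'
#' @param a,b numeric vectors for the two groups (each of length >= 2).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param var.equal pooled-variance statistic instead of Welch.
#' @param tail `"two"` (default), `"greater"` or `"less"`.
#' @return a `crcmb_test`.
#' @export
perm_welch_t <- function(a, b, n_perm = 999, seed = 42, var.equal = FALSE,
                         tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  assert_scalar_count(n_perm, "n_perm")
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2 || anyNA(c(a, b))) {
    abort_crcmb("each group needs >= 2 finite values", "crcmb_bad_argument")
  }
  t_obs <- two_sample_t_stat(a, b, var.equal)
  if (t_obs == 0 && stats::var(a) == 0 && stats::var(b) == 0) {
    return(new_test_result("perm_welch_t", 0, 1, n_perm, seed,
                           effect_size = 0,
                           extra = list(tail = tail,
                                        n = c(length(a), length(b)))))
  }
  z <- c(a, b)
  na <- length(a); n <- length(z)
  t_star <- with_seed(derive_seed(seed, 2L), {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, na)
      two_sample_t_stat(z[idx], z[-idx], var.equal)
    }, numeric(1))
  })
  bcount <- switch(tail,
                   two = sum(abs(t_star) >= abs(t_obs)),
                   greater = sum(t_star >= t_obs),
                   less = sum(t_star <= t_obs))
  d <- tryCatch(cohens_d(a, b), error = function(e) NA_real_)
  new_test_result("perm_welch_t", t_obs, (bcount + 1) / (n_perm + 1),
                  n_perm, seed, effect_size = d,
                  extra = list(tail = tail, n = c(length(a), length(b))))
}

#' PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squared distances into among- and
#' within-group components; the pseudo-F statistic is
#' `(SS_among/(g-1)) / (SS_within/(n-g))` and `R^2 = SS_among / SS_total`.
#' The null permutes group labels.
#'
#' @param dm a `crcmb_dist` distance matrix (see [distance_matrix()]) or a
#'   square symmetric matrix.
#' @param grouping vector of group labels, one per sample, in `dm` order.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return a `crcmb_test` with `r_squared` in the result.
#' @export
permanova <- function(dm, grouping, n_perm = 999, seed = 42) {
  assert_scalar_count(n_perm, "n_perm")
  d <- if (inherits(dm, "crcmb_dist")) dm$values else as.matrix(dm)
  n <- nrow(d)
  grouping <- as.factor(grouping)
  if (length(grouping) != n) {
    abort_crcmb("grouping length must match the distance matrix",
                "crcmb_bad_argument")
  }
  g <- nlevels(droplevels(grouping))
  if (g < 2) abort_crcmb("need >= 2 groups", "crcmb_bad_argument")
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n

  levs <- levels(droplevels(grouping))
  ss_within_cols <- function(lab_mat) {
    # lab_mat: n x m matrix of labels; vectorized over permutations via one
    # d2 %*% indicator product per group
    ssw <- numeric(ncol(lab_mat))
    for (lev in levs) {
      P <- (lab_mat == lev) * 1
      ssw <- ssw + colSums(P * (d2 %*% P)) / (2 * colSums(P))
    }
    ssw
  }
  ssw_obs <- ss_within_cols(matrix(as.character(grouping), ncol = 1))
  ssa_obs <- ss_total - ssw_obs
  f_obs <- (ssa_obs / (g - 1)) / (ssw_obs / (n - g))

  f_star <- with_seed(derive_seed(seed, 3L), {
    perms <- vapply(seq_len(n_perm), function(i) {
      as.character(grouping)[sample.int(n)]
    }, character(n))
    ssw <- ss_within_cols(perms)
    ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
  })
  b <- sum(f_star >= f_obs)
  new_test_result("permanova", f_obs, (b + 1) / (n_perm + 1), n_perm, seed,
                  extra = list(r_squared = ssa_obs / ss_total,
                               n = n, n_groups = g))
}

#' Cohen's d effect size
#'
#' One-sample form `mean(a)/sd(a)` when `b` is NULL; two-sample form
#' `(mean(a) - mean(b)) / pooled SD`, pooling the two groups' squared
#' deviations over the total sample size (root-mean-square pooling, so
#' `a = {0, 2}`, `b = {1, 3}` gives exactly -1).
#'
#' @param a numeric vector.
#' @param b optional second group.
#' @return a single number.
#' @export
cohens_d <- function(a, b = NULL) {
  a <- as.numeric(a)
  if (is.null(b)) {
    s <- stats::sd(a)
    if (s == 0) abort_crcmb("zero variance", "crcmb_zero_variance")
    return(mean(a) / s)
  }
  b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb)
  if (sp2 == 0) abort_crcmb("zero pooled variance", "crcmb_zero_variance")
  (mean(a) - mean(b)) / sqrt(sp2)
}
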