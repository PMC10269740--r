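# Shared fixture builders.  Everything is generated in code; no binary or
# stored data.

toy_table <- function(m, samples = NULL, features = NULL) {
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(features)) features <- sprintf("f%02d", seq_len(ncol(m)))
  dimnames(m) <- list(samples, features)
  feature_table(m)
}

# a dense zero-free random count table
dense_table <- function(n = 12, p = 8, lambda = 60, seed = 1) {
  set.seed(seed)
  toy_table(matrix(rpois(n * p, lambda) + 1L, n, p))
}

# minimal paired metadata for n subjects (2 samples each)
paired_meta <- function(n = 6, n_short = floor(n / 2), location = TRUE,
                        seed = 1) {
  set.seed(seed)
  survival <- rep(c("short", "long"), c(n_short, n - n_short))
  df <- do.call(rbind, lapply(seq_len(n), function(j) {
    data.frame(sample_id = sprintf("S%02d%s", j, c("N", "T")),
               subject_id = sprintf("S%02d", j),
               tissue = c("normal", "tumor"),
               survival = survival[j],
               stringsAsFactors = FALSE)
  }))
  if (location) {
    loc <- sample(c("colon right", "colon left", "rectum"), n,
                  replace = TRUE)
    df$location <- loc[match(df$subject_id, sprintf("S%02d", seq_len(n)))]
  }
  sample_metadata(df)
}

# hand-built differential-ranking object (for cover-selection tests)
fake_dr <- function(differentials, contrast = "tissue") {
  structure(list(
    differentials = data.frame(
      feature_id = names(differentials), contrast = contrast,
      differential = unname(differentials), sd = NA_real_,
      rank = rank(-differentials, ties.method = "first"),
      stringsAsFactors = FALSE),
    design = "tissue", method = "map", iterations = 0L, seed = 0L,
    prior_sd = log(5) / 2), class = "crcmb_dr")
}

# small synthetic cohort shortcut
small_cohort <- function(n_subjects = 12, n_features = 20, seed = 1, ...) {
  truth <- synthetic_truth(n_features = n_features, seed = seed, ...)
  generate_cohort(n_subjects = n_subjects,
                  n_short = floor(n_subjects / 2),
                  truth = truth, seed = seed)
}
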