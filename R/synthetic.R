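# Synthetic paired-cohort generator.  Emulates the sampling design the
# analysis assumes: ~100 subjects contributing exactly one tumor and one
# normal biopsy each, strong per-subject microbial identities, a tissue
# effect concentrated in a designated feature subset, a survival x tissue
# interaction in another subset, and negative-binomial counts with variable
# sequencing depth.  Ground truth travels with the cohort so downstream
# stages can be tested for parameter recovery.

#' Ground truth for a synthetic paired cohort
#'
#' Encodes the generative model: per-feature baseline log abundances, a
#' per-subject random intercept SD (natural-log scale, applied per feature
#' so each subject owns a composition), per-feature tumor-vs-normal log2
#' fold changes, per-feature additional log2 fold changes in tumors of
#' short-term survivors (the interaction), a negative-binomial dispersion
#' (the `size` parameter), and a log-normal sequencing-depth distribution.
#'
#' Defaults describe a realistic 16S tissue cohort: 250 features, subject
#' SD 1.0 (natural log) dominating the effects, dispersion 0.5, depths
#' log-normal with median 20,000 reads and sigma 0.5, a tissue effect on 30
#' features at 1-2 log2 in either direction, and an interaction on 38
#' features at +/-1.5 log2.
#'
#' @param n_features number of features (>= 10).
#' @param subject_sd SD of per-subject, per-feature random intercepts
#'   (natural log).
#' @param nb_dispersion negative-binomial dispersion (`size`); smaller is
#'   noisier.
#' @param depth_meanlog,depth_sdlog log-normal parameters of per-sample
#'   sequencing depth.
#' @param n_tissue number of features carrying a tissue effect.
#' @param tissue_lfc_range magnitude range (log2) of tissue effects; signs
#'   alternate.
#' @param n_interaction number of features carrying a tissue x survival
#'   interaction.
#' @param interaction_lfc interaction magnitude (log2); half the features
#'   get `+`, half `-`.
#' @param baseline_sd SD of baseline log abundances (natural log).
#' @param seed integer seed used to draw the per-feature vectors.
#' @return a `crcmb_truth` list.
#' @export
synthetic_truth <- function(n_features = 250, subject_sd = 1.0,
                            nb_dispersion = 0.5,
                            depth_meanlog = log(20000), depth_sdlog = 0.5,
                            n_tissue = 30, tissue_lfc_range = c(1, 2),
                            n_interaction = 38, interaction_lfc = 1.5,
                            baseline_sd = 1.5, seed = 42) {
  if (n_features < 10) {
    abort_crcmb("n_features must be >= 10", "crcmb_bad_argument")
  }
  if (subject_sd < 0 || nb_dispersion <= 0) {
    abort_crcmb("subject_sd must be >= 0 and nb_dispersion > 0",
                "crcmb_bad_truth")
  }
  with_seed(derive_seed(seed, 101L), {
    baseline <- stats::rnorm(n_features, 0, baseline_sd)
    tissue_effect <- numeric(n_features)
    interaction_effect <- numeric(n_features)
    if (n_tissue > 0) {
      idx <- seq_len(min(n_tissue, n_features))
      mag <- stats::runif(length(idx), tissue_lfc_range[1], tissue_lfc_range[2])
      tissue_effect[idx] <- mag * rep_len(c(1, -1), length(idx))
    }
    if (n_interaction > 0) {
      # interaction features sit after the tissue-effect block when possible
      start <- min(n_tissue, n_features) + 1L
      idx <- seq.int(start, length.out = n_interaction)
      idx <- idx[idx <= n_features]
      interaction_effect[idx] <- interaction_lfc *
        rep_len(c(1, -1), length(idx))
    }
    feature_ids <- sprintf("ASV%04d", seq_len(n_features))
    structure(list(
      feature_ids = feature_ids,
      baseline_log_abundance = stats::setNames(baseline, feature_ids),
      subject_sd = subject_sd,
      tissue_effect = stats::setNames(tissue_effect, feature_ids),
      interaction_effect = stats::setNames(interaction_effect, feature_ids),
      nb_dispersion = nb_dispersion,
      depth_distribution = c(meanlog = depth_meanlog, sdlog = depth_sdlog),
      seed = as.integer(seed)
    ), class = "crcmb_truth")
  })
}

validate_truth <- function(truth) {
  if (!inherits(truth, "crcmb_truth")) {
    abort_crcmb("`truth` must be a crcmb_truth object", "crcmb_bad_truth")
  }
  n <- length(truth$feature_ids)
  ok <- truth$subject_sd >= 0 && truth$nb_dispersion > 0 &&
    length(truth$baseline_log_abundance) == n &&
    length(truth$tissue_effect) == n &&
    length(truth$interaction_effect) == n
  if (!ok) abort_crcmb("truth invariants violated", "crcmb_bad_truth")
  invisible(truth)
}

# Default clinical covariate category frequencies.  These are plausible for
# an elderly late-stage surgical CRC cohort; they are configuration, not
# estimates, and are independent of the microbiome unless tied explicitly.
default_covariate_freqs <- function() {
  list(
    age_cat         = c("<60" = 0.15, "60-69" = 0.30, "70-74" = 0.25,
                        ">=75" = 0.30),
    sex             = c(female = 0.45, male = 0.55),
    asa             = c("I" = 0.30, "II" = 0.45, "III-IV" = 0.25),
    location        = c("colon right" = 0.35, "colon left" = 0.30,
                        rectum = 0.35),
    stage           = c("III" = 0.60, "IV" = 0.40),
    differentiation = c(low = 0.25, medium = 0.55, high = 0.20),
    period          = c("1997-2005" = 0.40, "2006-2010" = 0.30,
                        "2011-2017" = 0.30),
    radical         = c(no = 0.15, yes = 0.85)
  )
}

#' Generate a synthetic paired tumor/normal cohort
#'
#' Each subject contributes exactly two samples (normal, tumor).  For
#' sample \eqn{s} of subject \eqn{j}, counts are drawn feature-wise from a
#' negative binomial with mean \eqn{depth_s \times softmax_f(\eta)} where
#' \eqn{\eta_f = baseline_f + u_{jf} + \ln 2\,(tissue_f [tumor] +
#' interaction_f [tumor \wedge short])} and \eqn{u_{jf} \sim N(0,
#' subject\_sd^2)} is shared between the subject's two samples.  The
#' softmax closes the composition so sequencing depth and composition are
#' decoupled, as the compositional analyses downstream assume.
#'
#' @param n_subjects number of subjects (default 101, a typical nested
#'   case-control cohort).
#' @param n_short number of short-term survivors (default 50; the rest are
#'   long-term).
#' @param n_features number of features, used only when `truth` is NULL.
#' @param truth a [synthetic_truth()]; generated from `seed` when NULL.
#' @param covariate_freqs named list of category frequency vectors for the
#'   clinical covariates; defaults are configuration for a late-stage CRC
#'   cohort.
#' @param seed integer seed.
#' @return a list with `bundle` (a `crcmb_cohort`) and `truth` (echoed
#'   unchanged).
#' @export
generate_cohort <- function(n_subjects = 101, n_short = 50,
                            n_features = 250, truth = NULL,
                            covariate_freqs = default_covariate_freqs(),
                            seed = 42) {
  assert_scalar_count(n_subjects, "n_subjects")
  assert_scalar_count(n_short, "n_short", min = 0)
  if (n_short > n_subjects) {
    abort_crcmb("n_short must be <= n_subjects", "crcmb_bad_argument")
  }
  if (is.null(truth)) truth <- synthetic_truth(n_features, seed = seed)
  validate_truth(truth)
  p <- length(truth$feature_ids)

  with_seed(derive_seed(seed, 202L), {
    subj_ids <- sprintf("S%03d", seq_len(n_subjects))
    survival <- rep(c("short", "long"), c(n_short, n_subjects - n_short))

    meta <- do.call(rbind, lapply(seq_len(n_subjects), function(j) {
      data.frame(sample_id = paste0(subj_ids[j], c("N", "T")),
                 subject_id = subj_ids[j],
                 tissue = c("normal", "tumor"),
                 survival = survival[j],
                 stringsAsFactors = FALSE)
    }))
    for (cov in names(covariate_freqs)) {
      freqs <- covariate_freqs[[cov]]
      lev <- names(freqs)
      per_subject <- sample(lev, n_subjects, replace = TRUE, prob = freqs)
      meta[[cov]] <- per_subject[match(meta$subject_id, subj_ids)]
    }

    u <- matrix(stats::rnorm(n_subjects * p, 0, truth$subject_sd),
                nrow = n_subjects)
    depths <- stats::rlnorm(2 * n_subjects,
                            truth$depth_distribution["meanlog"],
                            truth$depth_distribution["sdlog"])

    counts <- matrix(0, nrow = 2 * n_subjects, ncol = p,
                     dimnames = list(meta$sample_id, truth$feature_ids))
    for (i in seq_len(nrow(meta))) {
      j <- match(meta$subject_id[i], subj_ids)
      is_tumor <- meta$tissue[i] == "tumor"
      is_short <- meta$survival[i] == "short"
      eta <- truth$baseline_log_abundance + u[j, ] +
        log(2) * (truth$tissue_effect * is_tumor +
                  truth$interaction_effect * (is_tumor && is_short))
      prob <- exp(eta - max(eta))
      prob <- prob / sum(prob)
      mu <- depths[i] * prob
      counts[i, ] <- stats::rnbinom(p, size = truth$nb_dispersion, mu = mu)
    }

    table <- feature_table(counts)
    metadata <- sample_metadata(meta)
    bundle <- structure(list(
      table = table, metadata = metadata,
      log = list(min_depth = NA_integer_, n_subjects = n_subjects,
                 n_samples = 2L * n_subjects, seed = as.integer(seed),
                 generator = "crcmb synthetic cohort")
    ), class = "crcmb_cohort")
    list(bundle = bundle, truth = truth)
  })
}

#' Write a synthetic cohort and its truth to disk
#'
#' Writes `table.tsv`, `metadata.tsv`, `truth.tsv` (key-value header lines
#' prefixed with `#`, then a per-feature effect table) and `generation.log`
#' into `dir`.  Reading the files back reproduces the bundle exactly.
#'
#' @param bundle a `crcmb_cohort` from [generate_cohort()].
#' @param truth the matching [synthetic_truth()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_fixtures <- function(bundle, truth, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_crcmb(sprintf("cannot create directory %s", dir),
                         "crcmb_unwritable")
  }
  write_feature_table(bundle$table, file.path(dir, "table.tsv"))
  write_metadata(bundle$metadata, file.path(dir, "metadata.tsv"))

  tf <- file.path(dir, "truth.tsv")
  hdr <- c(
    sprintf("# subject_sd=%.10g", truth$subject_sd),
    sprintf("# nb_dispersion=%.10g", truth$nb_dispersion),
    sprintf("# depth_meanlog=%.10g", truth$depth_distribution["meanlog"]),
    sprintf("# depth_sdlog=%.10g", truth$depth_distribution["sdlog"]),
    sprintf("# seed=%d", truth$seed)
  )
  df <- data.frame(feature_id = truth$feature_ids,
                   baseline_log_abundance = truth$baseline_log_abundance,
                   tissue_effect = truth$tissue_effect,
                   interaction_effect = truth$interaction_effect,
                   stringsAsFactors = FALSE)
  con <- file(tf, "w")
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  writeLines(c(sprintf("seed: %s", bundle$log$seed %||% NA),
               sprintf("n_subjects: %d", bundle$log$n_subjects),
               sprintf("n_samples: %d", bundle$log$n_samples)),
             file.path(dir, "generation.log"))
  invisible(dir)
}

#' Read a ground-truth file written by [write_fixtures()]
#'
#' @param path path to `truth.tsv`.
#' @return a `crcmb_truth` list.
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#\\s*", "", hdr), "="))
  vals <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                          stringsAsFactors = FALSE)
  structure(list(
    feature_ids = df$feature_id,
    baseline_log_abundance = stats::setNames(df$baseline_log_abundance,
                                             df$feature_id),
    subject_sd = unname(vals["subject_sd"]),
    tissue_effect = stats::setNames(df$tissue_effect, df$feature_id),
    interaction_effect = stats::setNames(df$interaction_effect,
                                         df$feature_id),
    nb_dispersion = unname(vals["nb_dispersion"]),
    depth_distribution = c(meanlog = unname(vals["depth_meanlog"]),
                           sdlog = unname(vals["depth_sdlog"])),
    seed = as.integer(vals["seed"])
  ), class = "crcmb_truth")
}
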