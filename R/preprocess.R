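# Feature filtering, rarefaction, and the compositional log-ratio
# transforms.  The three filters implement distinct prevalence/abundance
# rules used ahead of CTF, rPCA, and differential ranking; all three read
# their thresholds as strict inequalities ("fewer than", "<"), so
# exact-boundary features are retained.

filter_empty_check <- function(keep, stage) {
  if (!any(keep)) {
    abort_crcmb(sprintf("%s removed every feature", stage),
                "crcmb_all_filtered")
  }
}

#' Prevalence/total-count filter ahead of CTF
#'
#' Removes features present in fewer than `min_samples` samples or with a
#' total count below `min_total`.  Boundary features (present in exactly
#' `min_samples` samples, or with total exactly `min_total`) are retained.
#' Samples are never touched.
#'
#' @param table a [feature_table()].
#' @param min_samples prevalence threshold (default 20).
#' @param min_total total-count threshold (default 100).
#' @return the filtered [feature_table()].
#' @export
filter_ctf <- function(table, min_samples = 20, min_total = 100) {
  prev <- colSums(table$counts > 0)
  tot <- colSums(table$counts)
  keep <- prev >= min_samples & tot >= min_total
  filter_empty_check(keep, "filter_ctf")
  subset_table(table, features = which(keep))
}

#' Prevalence-fraction filter ahead of rPCA
#'
#' Removes features present in fewer than `ceiling(min_frac * n_samples)`
#' samples or with a total count below `min_total`.  The fraction is
#' computed on the table actually passed in, so a tumor-only table uses the
#' tumor sample count.
#'
#' @param table a [feature_table()].
#' @param min_frac prevalence fraction (default 0.10).
#' @param min_total total-count threshold (default 10).
#' @return the filtered [feature_table()].
#' @export
filter_rpca <- function(table, min_frac = 0.10, min_total = 10) {
  n <- length(table$sample_ids)
  min_samples <- ceiling(min_frac * n)
  prev <- colSums(table$counts > 0)
  tot <- colSums(table$counts)
  keep <- prev >= min_samples & tot >= min_total
  filter_empty_check(keep, "filter_rpca")
  subset_table(table, features = which(keep))
}

#' Relative-abundance filter ahead of differential ranking
#'
#' Keeps a feature only if its per-sample relative abundance reaches
#' `rel_threshold` (default 1/1000) in at least `min_frac` (default 10%) of
#' samples; a feature at exactly the 10% prevalence boundary is kept.
#'
#' @param table a [feature_table()].
#' @param rel_threshold relative-abundance threshold.
#' @param min_frac required fraction of samples at or above the threshold.
#' @return the filtered [feature_table()].
#' @export
filter_dr <- function(table, rel_threshold = 0.001, min_frac = 0.10) {
  depths <- sample_depths(table)
  if (any(depths == 0)) {
    abort_crcmb("samples with zero total count cannot be scaled",
                "crcmb_zero_depth")
  }
  rel <- table$counts / depths
  frac_above <- colMeans(rel >= rel_threshold)
  keep <- frac_above >= min_frac
  filter_empty_check(keep, "filter_dr")
  subset_table(table, features = which(keep))
}

# multivariate hypergeometric draw: subsample `depth` reads without
# replacement from one sample's count vector
subsample_counts <- function(counts, depth) {
  total <- sum(counts)
  picked <- sort.int(sample.int(total, depth))
  breaks <- cumsum(counts)
  tabulate(findInterval(picked - 1L, c(0, breaks), left.open = FALSE),
           nbins = length(counts))
}

#' Rarefy a feature table
#'
#' Subsamples every sample without replacement to exactly `depth` reads;
#' samples with fewer reads are dropped and logged in the
#' `dropped_samples` attribute.  Each sample uses a seed sub-stream derived
#' from its ID, so the result does not depend on sample order.
#'
#' @param table a [feature_table()].
#' @param depth target depth (default 2500).
#' @param seed integer seed.
#' @return a rarefied [feature_table()] whose `dropped_samples` attribute
#'   lists exclusions.
#' @export
rarefy <- function(table, depth = 2500, seed = 42) {
  assert_scalar_count(depth, "depth")
  depths <- sample_depths(table)
  keep <- depths >= depth
  if (!any(keep)) {
    abort_crcmb("all samples fall below the rarefaction depth",
                "crcmb_all_filtered")
  }
  kept_ids <- table$sample_ids[keep]
  out <- matrix(0, nrow = length(kept_ids), ncol = length(table$feature_ids),
                dimnames = list(kept_ids, table$feature_ids))
  for (sid in kept_ids) {
    # per-sample stream keyed on the sample ID, not its position
    stream <- sum(utf8ToInt(sid) * seq_along(utf8ToInt(sid)))
    with_seed(derive_seed(seed, stream), {
      out[sid, ] <- subsample_counts(table$counts[sid, ], depth)
    })
  }
  res <- feature_table(out)
  attr(res, "dropped_samples") <- table$sample_ids[!keep]
  attr(res, "rarefaction_depth") <- depth
  attr(res, "seed") <- as.integer(seed)
  res
}

new_transformed <- function(values, transform) {
  structure(list(values = values,
                 sample_ids = rownames(values),
                 feature_ids = colnames(values),
                 transform = transform),
            class = "crcmb_transform")
}

#' Robust centered log-ratio transform
#'
#' Zeros become missing values; every observed entry is `log(count)` minus
#' the mean log over that sample's observed (nonzero) entries.  Each row
#' therefore has mean zero over its observed entries, and zeros carry no
#' information rather than being imputed — the property the matrix
#' completion ordinations rely on.
#'
#' @param table a [feature_table()].
#' @return a `crcmb_transform` with `transform = "rclr"`; missing entries
#'   mark the original zeros.
#' @export
rclr <- function(table) {
  m <- table$counts
  nonzero <- rowSums(m > 0)
  if (any(nonzero < 2)) {
    abort_crcmb(sprintf("sample(s) with < 2 nonzero features: %s",
                        paste(table$sample_ids[nonzero < 2], collapse = ", ")),
                "crcmb_degenerate_sample")
  }
  lm <- log(m)
  lm[!is.finite(lm)] <- NA_real_
  centered <- lm - rowMeans(lm, na.rm = TRUE)
  new_transformed(centered, "rclr")
}

#' Centered log-ratio transform with pseudocount
#'
#' Each entry is `ln(count + pseudocount)` minus the row mean of the same;
#' the default pseudocount of 1 matches the Aitchison-distance convention
#' for unrarefied tables.  Natural log throughout; log2 quantities appear
#' only in the additive log-ratio indices.
#'
#' @param table a [feature_table()].
#' @param pseudocount constant added to every count (default 1).
#' @return a complete `crcmb_transform` with `transform = "clr"`.
#' @export
clr <- function(table, pseudocount = 1) {
  lm <- log(table$counts + pseudocount)
  new_transformed(lm - rowMeans(lm), "clr")
}

#' Write a transformed matrix as TSV (missing entries as NA)
#' @param x a `crcmb_transform`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(x, path) {
  df <- data.frame(sample_id = x$sample_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
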