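# Beta diversity: Bray-Curtis, binary Jaccard and Aitchison distance
# matrices, extraction of within-subject (tumor vs normal) paired
# distances, and the stratified intra- vs inter-individual comparison.

new_dist <- function(values, ids, metric) {
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, metric = metric),
            class = "crcmb_dist")
}

#' @export
print.crcmb_dist <- function(x, ...) {
  cat(sprintf("<crcmb_dist> %s, %d samples\n", x$metric, length(x$ids)))
  invisible(x)
}

#' Pairwise distance matrix
#'
#' Three metrics: `bray_curtis` (`1 - 2 sum(min(x, y)) / sum(x + y)`) and
#' `jaccard_binary` (`1 - |A intersect B| / |A union B|` on presence sets),
#' both intended for a rarefied count table; and `aitchison`, the Euclidean
#' distance between CLR-transformed rows, computed on the unrarefied table
#' with a pseudocount of 1 applied internally.
#'
#' @param table a [feature_table()] (counts); `aitchison` also accepts a
#'   ready-made `clr` transform.
#' @param metric one of `"bray_curtis"`, `"jaccard_binary"`, `"aitchison"`.
#' @param pseudocount pseudocount for the internal CLR (aitchison only).
#' @return a `crcmb_dist`: symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(table,
                            metric = c("bray_curtis", "jaccard_binary",
                                       "aitchison"),
                            pseudocount = 1) {
  metric <- match.arg(metric)
  if (inherits(table, "crcmb_transform")) {
    if (metric != "aitchison" || table$transform != "clr") {
      abort_crcmb("only the aitchison metric accepts a clr transform",
                  "crcmb_metric_mismatch")
    }
    d <- as.matrix(stats::dist(table$values))
    return(new_dist(d, table$sample_ids, metric))
  }
  if (!inherits(table, "crcmb_table")) {
    abort_crcmb("`table` must be a feature table (or clr transform for aitchison)",
                "crcmb_metric_mismatch")
  }
  m <- table$counts
  d <- switch(metric,
    bray_curtis = {
      # sum(|x-y|) / sum(x+y) == 1 - 2 sum(min) / sum(x+y)
      tot <- rowSums(m)
      man <- as.matrix(stats::dist(m, method = "manhattan"))
      denom <- outer(tot, tot, `+`)
      out <- man / denom
      out[denom == 0] <- 0
      out
    },
    jaccard_binary = {
      pres <- (m > 0) * 1
      inter <- tcrossprod(pres)
      sz <- rowSums(pres)
      union <- outer(sz, sz, `+`) - inter
      out <- 1 - inter / union
      out[union == 0] <- 0
      out
    },
    aitchison = as.matrix(stats::dist(clr(table, pseudocount)$values))
  )
  diag(d) <- 0
  new_dist(d, table$sample_ids, metric)
}

#' Write a distance matrix as square TSV with an ID header
#' @param dm a `crcmb_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = dm$ids, dm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Within-subject paired distances
#'
#' For every fully paired subject, the distance between that subject's
#' tumor and normal samples, read straight from the distance matrix.
#'
#' @param dm a `crcmb_dist` covering all paired samples.
#' @param metadata a [sample_metadata()] data.frame.
#' @return named numeric vector, one entry per subject.
#' @export
paired_distances <- function(dm, metadata) {
  metadata <- metadata[metadata$sample_id %in% dm$ids, , drop = FALSE]
  pm <- paired_map(metadata, strict = TRUE)
  missing <- setdiff(c(pm$normal, pm$tumor), dm$ids)
  if (length(missing)) {
    abort_crcmb(sprintf("paired samples absent from distance matrix: %s",
                        paste(missing, collapse = ", ")),
                "crcmb_missing_sample")
  }
  stats::setNames(
    dm$values[cbind(pm$tumor, pm$normal)],
    pm$subject_id)
}

#' Intra- vs inter-individual distance comparison
#'
#' Compares within-subject paired distances (group A) against
#' between-subject distances restricted to sample pairs matched on the
#' stratification columns (group B; default tissue, anatomical location and
#' survival group), using a permutative two-sample t test (Welch by
#' default) with group labels permuted over the pooled distances.
#'
#' @param dm a `crcmb_dist`.
#' @param metadata a [sample_metadata()] data.frame.
#' @param strata metadata columns that inter-individual pairs must match
#'   on; columns absent from the metadata raise an error.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param var.equal use the pooled-variance statistic instead of Welch.
#' @return a `crcmb_test`; `n` holds the two group sizes.
#' @export
intra_inter_test <- function(dm, metadata,
                             strata = c("tissue", "location", "survival"),
                             n_perm = 999, seed = 42, var.equal = FALSE) {
  missing_cols <- setdiff(strata, names(metadata))
  if (length(missing_cols)) {
    abort_crcmb(sprintf("stratum column(s) missing from metadata: %s",
                        paste(missing_cols, collapse = ", ")),
                "crcmb_missing_columns")
  }
  metadata <- metadata[metadata$sample_id %in% dm$ids, , drop = FALSE]
  intra <- paired_distances(dm, metadata)

  idx <- match(metadata$sample_id, dm$ids)
  key <- do.call(paste, c(metadata[strata], sep = "\r"))
  subj <- metadata$subject_id
  inter <- c()
  for (lev in unique(key)) {
    members <- which(key == lev)
    if (length(unique(subj[members])) < 2) {
      warning(sprintf("stratum '%s' has < 2 subjects; skipped",
                      gsub("\r", "/", lev)))
      next
    }
    cmb <- utils::combn(members, 2)
    diff_subj <- subj[cmb[1, ]] != subj[cmb[2, ]]
    if (any(diff_subj)) {
      inter <- c(inter,
                 dm$values[cbind(idx[cmb[1, diff_subj]],
                                 idx[cmb[2, diff_subj]])])
    }
  }
  if (!length(inter)) {
    abort_crcmb("no matched inter-individual pairs in any stratum",
                "crcmb_empty_stratum")
  }
  res <- perm_welch_t(intra, inter, n_perm = n_perm, seed = seed,
                      var.equal = var.equal)
  res$test <- "intra_inter"
  res
}
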