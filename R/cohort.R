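# Cohort validation: intersect table and metadata, apply the sequencing
# depth exclusion, and keep only subjects with a complete tumor/normal pair.

#' Validate a paired cohort
#'
#' Reconciles a feature table with its sample metadata and enforces the
#' paired design: samples below the minimum sequencing depth are excluded,
#' and any subject left without both a tumor and a normal sample is removed
#' entirely (both samples, if present).  Exclusions are logged with counts
#' by reason because paired studies report them per tissue.
#'
#' @param table a [feature_table()].
#' @param metadata a [sample_metadata()] data.frame.
#' @param min_depth minimum per-sample total count; defaults to 2500, the
#'   conventional rarefaction depth for 16S tissue biopsies.
#' @return a `crcmb_cohort` list with elements `table`, `metadata`, and
#'   `log` (filters applied, exclusion counts by reason and tissue).
#' @export
validate_cohort <- function(table, metadata, min_depth = 2500) {
  assert_scalar_count(min_depth, "min_depth", min = 1)
  shared <- intersect(table$sample_ids, metadata$sample_id)
  not_in_meta <- setdiff(table$sample_ids, shared)
  not_in_table <- setdiff(metadata$sample_id, shared)

  table <- subset_table(table, samples = shared)
  metadata <- metadata[metadata$sample_id %in% shared, , drop = FALSE]

  depths <- sample_depths(table)
  low <- names(depths)[depths < min_depth]
  low_tissue <- metadata$tissue[metadata_rows(metadata, low)]

  keep_meta <- metadata[!(metadata$sample_id %in% low), , drop = FALSE]
  pm <- paired_map(keep_meta, strict = FALSE)
  paired <- pm[stats::complete.cases(pm[c("normal", "tumor")]), , drop = FALSE]
  unpaired_subjects <- setdiff(pm$subject_id, paired$subject_id)

  keep_samples <- c(paired$normal, paired$tumor)
  if (!length(keep_samples)) {
    abort_crcmb("no fully paired subjects remain after validation",
                "crcmb_empty_cohort")
  }
  keep_meta <- keep_meta[keep_meta$sample_id %in% keep_samples, , drop = FALSE]
  rownames(keep_meta) <- NULL
  table <- subset_table(table, samples = keep_meta$sample_id)

  log <- list(
    min_depth = min_depth,
    n_subjects = nrow(paired),
    n_samples = length(keep_samples),
    excluded = list(
      not_in_metadata = not_in_meta,
      not_in_table = not_in_table,
      low_depth = low,
      low_depth_by_tissue = table(factor(low_tissue,
                                         levels = crcmb_enums$tissue)),
      unpaired_subjects = unpaired_subjects
    )
  )
  structure(list(table = table, metadata = keep_meta, log = log),
            class = "crcmb_cohort")
}

#' @export
print.crcmb_cohort <- function(x, ...) {
  cat(sprintf("<crcmb_cohort> %d paired subjects (%d samples), min_depth=%d\n",
              x$log$n_subjects, x$log$n_samples, x$log$min_depth))
  ex <- x$log$excluded
  cat(sprintf("  excluded: %d low-depth samples, %d unpaired subjects\n",
              length(ex$low_depth), length(ex$unpaired_subjects)))
  invisible(x)
}
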