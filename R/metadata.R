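# Sample metadata: subject pairing, tissue and survival labels, and the
# clinical covariates used by the adjusted survival models.

# Controlled vocabularies.  Tissue and survival are mandatory; the clinical
# covariates follow the usual late-stage CRC case-control coding: age at
# surgery in four bands, ASA physical-status score collapsed at III-IV
# (V/VI are not operable), anatomical tumor location, TNM stage III/IV
# (late-stage only), differentiation grade, surgery period, and whether the
# resection was radical.
crcmb_enums <- list(
  tissue          = c("normal", "tumor"),
  survival        = c("short", "long"),
  age_cat         = c("<60", "60-69", "70-74", ">=75"),
  sex             = c("female", "male"),
  asa             = c("I", "II", "III-IV"),
  location        = c("colon right", "colon left", "rectum"),
  stage           = c("III", "IV"),
  differentiation = c("low", "medium", "high"),
  period          = c("1997-2005", "2006-2010", "2011-2017"),
  radical         = c("no", "yes")
)

covariate_columns <- setdiff(names(crcmb_enums), c("tissue", "survival"))

#' Construct sample metadata
#'
#' One row per sample.  Required columns: `sample_id`, `subject_id`,
#' `tissue` (`normal`/`tumor`), `survival` (`short`/`long`).  Recognised
#' clinical covariates (`age_cat`, `sex`, `asa`, `location`, `stage`,
#' `differentiation`, `period`, `radical`) are validated against their
#' controlled vocabularies when present; other columns pass through
#' untouched.  Each subject may contribute at most one sample per tissue.
#'
#' @param df a data.frame.
#' @return a validated data.frame of class `crcmb_metadata`.
#' @export
sample_metadata <- function(df) {
  required <- c("sample_id", "subject_id", "tissue", "survival")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort_crcmb(sprintf("metadata is missing columns: %s",
                        paste(missing_cols, collapse = ", ")),
                "crcmb_missing_columns")
  }
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$sample_id)) {
    abort_crcmb("duplicate sample IDs in metadata", "crcmb_duplicate_ids")
  }
  for (col in intersect(names(crcmb_enums), names(df))) {
    vals <- as.character(df[[col]])
    bad <- which(is.na(vals) | !(vals %in% crcmb_enums[[col]]))
    if (length(bad)) {
      abort_crcmb(sprintf(
        "invalid %s value(s) %s in row(s): %s (allowed: %s)",
        col,
        paste(unique(vals[bad]), collapse = ", "),
        paste(df$sample_id[bad], collapse = ", "),
        paste(crcmb_enums[[col]], collapse = ", ")),
        "crcmb_bad_enum")
    }
    df[[col]] <- vals
  }
  dup_state <- duplicated(df[, c("subject_id", "tissue")])
  if (any(dup_state)) {
    abort_crcmb(sprintf("subject(s) with more than one sample per tissue: %s",
                        paste(unique(df$subject_id[dup_state]),
                              collapse = ", ")),
                "crcmb_duplicate_pair")
  }
  class(df) <- c("crcmb_metadata", "data.frame")
  df
}

#' Read sample metadata from TSV
#'
#' @param path path to a tab-separated file with the columns described in
#'   [sample_metadata()].
#' @return a `crcmb_metadata` data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    abort_crcmb(sprintf("metadata file not found: %s", path),
                "crcmb_missing_file")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  sample_metadata(df)
}

#' Write sample metadata as TSV
#'
#' @param metadata a `crcmb_metadata` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# sample_id -> metadata row index lookup with error on absence
metadata_rows <- function(metadata, sample_ids) {
  idx <- match(sample_ids, metadata$sample_id)
  if (anyNA(idx)) {
    abort_crcmb(sprintf("samples missing from metadata: %s",
                        paste(sample_ids[is.na(idx)], collapse = ", ")),
                "crcmb_missing_metadata")
  }
  idx
}

# Returns a data.frame subject_id / normal / tumor of sample IDs for fully
# paired subjects; errors if `strict` and any subject is unpaired.
paired_map <- function(metadata, strict = TRUE) {
  split_ids <- split(seq_len(nrow(metadata)), metadata$subject_id)
  rows <- lapply(names(split_ids), function(subj) {
    i <- split_ids[[subj]]
    tis <- metadata$tissue[i]
    data.frame(
      subject_id = subj,
      normal = if ("normal" %in% tis) metadata$sample_id[i[tis == "normal"]] else NA,
      tumor  = if ("tumor" %in% tis) metadata$sample_id[i[tis == "tumor"]] else NA,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject_id = character(0), normal = character(0),
                      tumor = character(0), stringsAsFactors = FALSE)
  }
  if (strict && anyNA(out[c("normal", "tumor")])) {
    bad <- out$subject_id[!stats::complete.cases(out[c("normal", "tumor")])]
    abort_crcmb(sprintf("subject(s) not fully paired: %s",
                        paste(bad, collapse = ", ")),
                "crcmb_unpaired_subject")
  }
  out
}
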