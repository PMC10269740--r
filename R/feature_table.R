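# Feature tables: the samples x features count matrix at the center of the
# pipeline, plus readers/writers for the plain-text interchange formats.

#' Construct a feature table
#'
#' A feature table is a non-negative integer count matrix with samples as
#' rows and features (e.g. 16S ASVs) as columns, carrying unique sample and
#' feature identifiers.  All pipeline stages consume and produce this
#' container.  Zero-count features are legal and retained; filtering is an
#' explicit, separate step.
#'
#' @param counts numeric matrix of non-negative integers (samples x
#'   features).  Dimnames, if present, seed the identifiers.
#' @param sample_ids,feature_ids character vectors of unique identifiers;
#'   default to the matrix dimnames.
#' @return an object of class `crcmb_table` (a list with elements `counts`,
#'   `sample_ids`, `feature_ids`).
#' @examples
#' m <- matrix(c(0, 5, 2, 7, 1, 0), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
#' ft <- feature_table(m)
#' dim(ft$counts)
#' @export
feature_table <- function(counts, sample_ids = rownames(counts),
                          feature_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(feature_ids)) {
    abort_crcmb("feature table needs sample and feature identifiers",
                "crcmb_missing_ids")
  }
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(counts) ||
      length(feature_ids) != ncol(counts)) {
    abort_crcmb("identifier lengths do not match count matrix dimensions",
                "crcmb_dim_mismatch")
  }
  if (anyDuplicated(sample_ids)) {
    abort_crcmb(sprintf("duplicate sample IDs: %s",
                        paste(unique(sample_ids[duplicated(sample_ids)]),
                              collapse = ", ")),
                "crcmb_duplicate_ids")
  }
  if (anyDuplicated(feature_ids)) {
    abort_crcmb(sprintf("duplicate feature IDs: %s",
                        paste(unique(feature_ids[duplicated(feature_ids)]),
                              collapse = ", ")),
                "crcmb_duplicate_ids")
  }
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != floor(counts))) {
    abort_crcmb("counts must be non-negative integers with no missing values",
                "crcmb_bad_counts")
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(sample_ids, feature_ids)
  structure(list(counts = counts, sample_ids = sample_ids,
                 feature_ids = feature_ids),
            class = "crcmb_table")
}

#' @export
print.crcmb_table <- function(x, ...) {
  cat(sprintf("<crcmb_table> %d samples x %d features, total count %s\n",
              length(x$sample_ids), length(x$feature_ids),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.crcmb_table <- function(x) dim(x$counts)

subset_table <- function(ft, samples = NULL, features = NULL) {
  counts <- ft$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(features)) counts <- counts[, features, drop = FALSE]
  feature_table(counts)
}

sample_depths <- function(ft) rowSums(ft$counts)

#' Read a feature table from disk
#'
#' Two dialects are supported: plain TSV (header row of feature IDs, first
#' column of sample IDs) and the JSON flavor of the BIOM format.  BIOM files
#' store features as rows; they are transposed on import so that samples are
#' always rows internally.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` or `"biom-json"`.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, dialect = c("tsv", "biom-json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_crcmb(sprintf("feature table not found: %s", path),
                "crcmb_missing_file")
  }
  if (dialect == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, row.names = NULL,
                            stringsAsFactors = FALSE, comment.char = "#")
    sample_ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (anyDuplicated(sample_ids)) {
      abort_crcmb(sprintf("duplicate sample IDs in %s", path),
                  "crcmb_duplicate_ids")
    }
    rownames(m) <- sample_ids
    feature_table(m)
  } else {
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # features x samples
    feature_table(t(m))
  }
}

#' Write a feature table as TSV
#'
#' First column `sample_id`, remaining columns one per feature.  Reading the
#' file back with [read_feature_table()] reproduces the table exactly.
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(sample_id = ft$sample_ids, ft$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
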