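# Configuration and pipeline orchestration.  The config file is a flat
# key = value format (TOML-like: '#' comments, optional quotes, commas for
# lists); the pipeline runs the requested stages in dependency order and
# writes per-stage plain-text outputs, each stamped with the seed and
# filter parameters in '#'-prefixed header lines.

#' Read a flat key-value configuration file
#'
#' Recognised keys: `table`, `metadata`, `out_dir`, `stages`
#' (comma-separated subset of validate, preprocess, betadiv, ordinate, dr,
#' index, model), `seed`, `min_depth`, `rarefaction_depth`, `n_perm`,
#' `dr_method`, `dr_iterations`, `ctf_k`, `rpca_rank`.  Unknown keys are
#' kept verbatim.
#'
#' @param path config file path.
#' @param overrides named list merged over the file values.
#' @return a `crcmb_config` list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    table = NULL, metadata = NULL, out_dir = ".",
    stages = c("validate", "preprocess", "betadiv", "ordinate", "dr",
               "index", "model"),
    seed = 42, min_depth = 2500, rarefaction_depth = 2500,
    n_perm = 999, dr_method = "map", dr_iterations = 4000,
    ctf_k = 3, rpca_rank = "auto")
  vals <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort_crcmb(sprintf("config file not found: %s", path),
                  "crcmb_missing_file")
    }
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE)) {
        abort_crcmb(sprintf("malformed config line: '%s'", ln),
                    "crcmb_bad_config")
      }
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      val <- gsub('^"|"$', "", val)
      if (grepl(",", val, fixed = TRUE)) {
        val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
      }
      num <- suppressWarnings(as.numeric(val))
      if (length(num) == 1 && !is.na(num) && key != "rpca_rank") val <- num
      vals[[key]] <- val
    }
  }
  for (key in names(overrides)) vals[[key]] <- overrides[[key]]
  if (!is.null(vals$n_perm) && vals$n_perm < 1) {
    abort_crcmb("permutation count must be >= 1", "crcmb_bad_config")
  }
  if (!is.null(vals$rarefaction_depth) && vals$rarefaction_depth < 1) {
    abort_crcmb("rarefaction depth must be >= 1", "crcmb_bad_config")
  }
  structure(vals, class = "crcmb_config")
}

stamp_header <- function(config, extra = character(0)) {
  c(sprintf("# seed=%s", config$seed),
    sprintf("# min_depth=%s", config$min_depth),
    sprintf("# rarefaction_depth=%s", config$rarefaction_depth),
    extra)
}

write_stamped_table <- function(df, path, config, extra = character(0)) {
  con <- file(path, "w")
  writeLines(stamp_header(config, extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order on the table and
#' metadata named in the config, writing per-stage TSV reports into
#' `out_dir`.  Outputs are a pure function of (config, inputs): a repeated
#' run with the same seed writes byte-identical statistical outputs.
#'
#' @param config a `crcmb_config` from [read_config()].
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stages_all <- c("validate", "preprocess", "betadiv", "ordinate", "dr",
                  "index", "model")
  stages <- intersect(stages_all, config$stages)  # dependency order
  if (is.null(config$table) || is.null(config$metadata)) {
    abort_crcmb("config must name `table` and `metadata` paths",
                "crcmb_bad_config")
  }
  if (!file.exists(config$table)) {
    abort_crcmb(sprintf("stage validate: table not found: %s", config$table),
                "crcmb_missing_file")
  }
  if (!file.exists(config$metadata)) {
    abort_crcmb(sprintf("stage validate: metadata not found: %s",
                        config$metadata), "crcmb_missing_file")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  seed <- as.integer(config$seed)

  table <- read_feature_table(config$table)
  metadata <- read_metadata(config$metadata)
  cohort <- validate_cohort(table, metadata, min_depth = config$min_depth)

  path <- file.path(config$out_dir, "validate.cohort.tsv")
  write_stamped_table(cohort$metadata, path, config,
                      sprintf("# n_subjects=%d", cohort$log$n_subjects))
  out$validate <- path

  filtered_dr <- NULL
  if (any(c("preprocess", "dr", "index", "model") %in% stages)) {
    filtered_dr <- filter_dr(cohort$table)
  }
  if ("preprocess" %in% stages) {
    f_ctf <- filter_ctf(cohort$table)
    f_rpca <- filter_rpca(cohort$table)
    summ <- data.frame(
      filter = c("ctf", "rpca", "dr"),
      features_kept = c(length(f_ctf$feature_ids),
                        length(f_rpca$feature_ids),
                        length(filtered_dr$feature_ids)),
      features_in = length(cohort$table$feature_ids))
    path <- file.path(config$out_dir, "preprocess.filters.tsv")
    write_stamped_table(summ, path, config)
    out$preprocess <- path
  }

  if ("betadiv" %in% stages) {
    rare <- rarefy(cohort$table, depth = config$rarefaction_depth,
                   seed = seed)
    rows <- list()
    for (metric in c("bray_curtis", "jaccard_binary", "aitchison")) {
      tb <- if (metric == "aitchison") cohort$table else rare
      dm <- distance_matrix(tb, metric)
      write_distance_matrix(dm, file.path(
        config$out_dir, sprintf("betadiv.%s.tsv", metric)))
      pd <- paired_distances(dm, cohort$metadata)
      strata <- intersect(c("tissue", "location", "survival"),
                          names(cohort$metadata))
      tst <- intra_inter_test(dm, cohort$metadata, strata = strata,
                              n_perm = config$n_perm, seed = seed)
      rows[[metric]] <- data.frame(
        metric = metric, mean_paired_distance = mean(pd),
        statistic = tst$statistic, p = tst$p_value,
        n_perm = tst$n_perm, seed = seed)
    }
    path <- file.path(config$out_dir, "betadiv.tests.tsv")
    write_stamped_table(do.call(rbind, rows), path, config)
    out$betadiv <- path
  }

  ctf_fit <- NULL
  if (any(c("ordinate", "model") %in% stages)) {
    ctf_fit <- ctf(filter_ctf(cohort$table), cohort$metadata,
                   k = config$ctf_k)
  }
  if ("ordinate" %in% stages) {
    write_ordination(ctf_fit, file.path(config$out_dir,
                                        "ordinate.ctf.txt"))
    tumor_ids <- cohort$metadata$sample_id[
      cohort$metadata$tissue == "tumor"]
    rp <- rpca(filter_rpca(subset_table(cohort$table,
                                        samples = tumor_ids)),
               rank = config$rpca_rank, seed = seed)
    write_ordination(rp, file.path(config$out_dir, "ordinate.rpca.txt"))
    deltas <- paired_pc_deltas(ctf_fit)
    rows <- lapply(colnames(deltas), function(pc) {
      tst <- perm_paired_t(deltas[, pc], n_perm = config$n_perm,
                           seed = seed)
      data.frame(pc = pc, statistic = tst$statistic,
                 effect_size = tst$effect_size, p = tst$p_value,
                 n_perm = tst$n_perm, seed = seed)
    })
    path <- file.path(config$out_dir, "ordinate.delta_tests.tsv")
    write_stamped_table(do.call(rbind, rows), path, config)
    out$ordinate <- path
  }

  dr_fit <- NULL
  if (any(c("dr", "index", "model") %in% stages)) {
    dr_fit <- fit_differentials(filtered_dr, cohort$metadata,
                                design = "tissue",
                                iterations = config$dr_iterations,
                                seed = seed, method = config$dr_method)
  }
  if ("dr" %in% stages) {
    path <- file.path(config$out_dir, "dr.differentials.tsv")
    write_stamped_table(dr_fit$differentials, path, config,
                        sprintf("# method=%s", dr_fit$method))
    out$dr <- path
  }

  alr <- NULL
  if (any(c("index", "model") %in% stages)) {
    top <- select_extreme_cover(dr_fit, filtered_dr, cohort$metadata,
                                direction = "top", contrast = "tissue")
    bottom <- select_extreme_cover(dr_fit, filtered_dr, cohort$metadata,
                                   direction = "bottom",
                                   contrast = "tissue")
    # pooled ALR: normal-tissue-associated features over tumor-associated
    alr <- compute_alr(filtered_dr, num = bottom$features,
                       den = top$features)
  }
  if ("index" %in% stages) {
    path <- file.path(config$out_dir, "index.alr.tsv")
    write_stamped_table(
      data.frame(sample_id = names(alr$values), alr = alr$values,
                 row.names = NULL),
      path, config,
      c(sprintf("# numerator=%s", paste(alr$num, collapse = ",")),
        sprintf("# denominator=%s", paste(alr$den, collapse = ","))))
    out$index <- path
  }

  if ("model" %in% stages) {
    lme <- lme_alr(alr, cohort$metadata, design = "tissue")
    pm <- paired_map(cohort$metadata)
    predictor <- stats::setNames(alr$values[pm$tumor], pm$subject_id)
    crude <- logistic_survival(predictor, cohort$metadata, adjust = FALSE)
    rows <- rbind(
      data.frame(model = "lme_tissue", term = lme$estimates$term,
                 estimate = lme$estimates$estimate,
                 ci_low = lme$estimates$ci_low,
                 ci_high = lme$estimates$ci_high, p = lme$estimates$p),
      data.frame(model = "logistic_crude", term = crude$estimates$term,
                 estimate = log(crude$estimates$or),
                 ci_low = log(crude$estimates$ci_low),
                 ci_high = log(crude$estimates$ci_high),
                 p = crude$estimates$p))
    path <- file.path(config$out_dir, "model.estimates.tsv")
    write_stamped_table(rows, path, config)
    out$model <- path
  }

  info <- file.path(config$out_dir, "run_info.txt")
  writeLines(c(sprintf("seed: %s", config$seed),
               sprintf("min_depth: %s", config$min_depth),
               sprintf("rarefaction_depth: %s", config$rarefaction_depth),
               sprintf("n_perm: %s", config$n_perm),
               sprintf("stages: %s", paste(stages, collapse = ","))),
             info)
  out$run_info <- info
  invisible(out)
}
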