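# Additive log-ratio survival indices and the association models: rPCA
# communality/quartile ALR construction, linear mixed-effects index
# models, crude/adjusted logistic regression for dichotomized survival,
# and score stratification.

#' Communality-based feature screen
#'
#' Communality of a feature is the square root of the sum of its squared
#' loadings across all retained components; features with communality of
#' at least `threshold` (inclusive) become candidates for the ALR.
#'
#' @param ord a `crcmb_ordination` (or any object with a
#'   `feature_loadings` matrix).
#' @param threshold minimum communality (default 0.01).
#' @return character vector of selected feature IDs.
#' @export
communality_select <- function(ord, threshold = 0.01) {
  L <- ord$feature_loadings
  comm <- sqrt(rowSums(L^2))
  sel <- rownames(L)[comm >= threshold]
  if (!length(sel)) {
    abort_crcmb("no feature reaches the communality threshold",
                "crcmb_empty_selection")
  }
  sel
}

#' Quartile-extreme loading sets for the ALR
#'
#' Computes the first and third quartiles (linear-interpolation
#' convention) of the candidate features' loadings on one component; the
#' upper set holds features with loadings strictly above Q3, the lower set
#' those strictly below Q1.
#'
#' @param ord a `crcmb_ordination`.
#' @param pc component index.
#' @param candidates candidate feature IDs (e.g. from
#'   [communality_select()]).
#' @return list with `upper` and `lower` character vectors and the
#'   quartiles.
#' @export
loading_quartile_sets <- function(ord, pc = 1, candidates) {
  if (!length(candidates)) {
    abort_crcmb("empty candidate set", "crcmb_bad_argument")
  }
  L <- ord$feature_loadings
  missing <- setdiff(candidates, rownames(L))
  if (length(missing)) {
    abort_crcmb(sprintf("candidates absent from loadings: %s",
                        paste(missing, collapse = ", ")),
                "crcmb_bad_argument")
  }
  v <- L[candidates, pc]
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2]) {
    abort_crcmb("degenerate loading distribution (Q1 == Q3)",
                "crcmb_degenerate_loadings")
  }
  list(upper = candidates[v > q[2]], lower = candidates[v < q[1]],
       q1 = q[1], q3 = q[2])
}

#' Additive log-ratio index
#'
#' Per-sample `log2( sum(numerator counts + pc) / sum(denominator counts
#' + pc) )`.  The numerator and denominator sets must be disjoint,
#' non-empty, and present in the table.
#'
#' @param table a [feature_table()].
#' @param num,den feature ID sets.
#' @param pseudocount added to every count before summing (default 1).
#' @return a `crcmb_alr`: per-sample `values` plus the defining sets.
#' @export
compute_alr <- function(table, num, den, pseudocount = 1) {
  num <- as.character(num); den <- as.character(den)
  if (!length(num) || !length(den)) {
    abort_crcmb("numerator and denominator sets must be non-empty",
                "crcmb_bad_argument")
  }
  if (length(intersect(num, den))) {
    abort_crcmb(sprintf("numerator/denominator overlap: %s",
                        paste(intersect(num, den), collapse = ", ")),
                "crcmb_bad_argument")
  }
  missing <- setdiff(c(num, den), table$feature_ids)
  if (length(missing)) {
    abort_crcmb(sprintf("features absent from table: %s",
                        paste(missing, collapse = ", ")),
                "crcmb_bad_argument")
  }
  top <- rowSums(table$counts[, num, drop = FALSE] + pseudocount)
  bot <- rowSums(table$counts[, den, drop = FALSE] + pseudocount)
  structure(list(values = stats::setNames(log2(top / bot),
                                          table$sample_ids),
                 num = num, den = den, pseudocount = pseudocount),
            class = "crcmb_alr")
}

#' Linear mixed-effects model for an ALR index
#'
#' Fits `value ~ tissue (+ survival + tissue:survival) + (1 | subject)` by
#' REML; the ALR is on the log2 scale, so coefficients read as log2-fold
#' differences.  Wald 95% CIs.  A singular random-effect fit falls back
#' (with a warning) to ordinary regression on the within-subject
#' tumor-minus-normal differences, which estimates the same contrasts in a
#' balanced paired design.
#'
#' @param alr a `crcmb_alr` (or named per-sample numeric vector).
#' @param metadata a [sample_metadata()] data.frame.
#' @param design `"tissue"` or `"tissue_x_survival"`.
#' @return a `crcmb_lme`: data.frame of estimates (term, estimate, ci_low,
#'   ci_high, p) plus the random-intercept variance.
#' @export
lme_alr <- function(alr, metadata,
                    design = c("tissue", "tissue_x_survival")) {
  design <- match.arg(design)
  values <- if (inherits(alr, "crcmb_alr")) alr$values else alr
  metadata <- metadata[metadata$sample_id %in% names(values), ,
                       drop = FALSE]
  df <- data.frame(
    value = as.numeric(values[metadata$sample_id]),
    tissue = factor(metadata$tissue, levels = crcmb_enums$tissue),
    survival = factor(metadata$survival, levels = c("long", "short")),
    subject = factor(metadata$subject_id))
  form <- if (design == "tissue") {
    value ~ tissue + (1 | subject)
  } else {
    value ~ tissue * survival + (1 | subject)
  }
  fit <- suppressMessages(lme4::lmer(form, data = df, REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("singular random-intercept fit; falling back to regression on within-subject differences")
    pm <- paired_map(metadata, strict = TRUE)
    delta <- values[pm$tumor] - values[pm$normal]
    surv <- metadata$survival[match(pm$subject_id, metadata$subject_id)]
    if (design == "tissue") {
      lmfit <- stats::lm(delta ~ 1)
      terms_keep <- "(Intercept)"
      labels <- "tissuetumor"
    } else {
      sfac <- factor(surv, levels = c("long", "short"))
      lmfit <- stats::lm(delta ~ sfac)
      terms_keep <- c("(Intercept)", "sfacshort")
      labels <- c("tissuetumor", "tissuetumor:survivalshort")
    }
    sm <- summary(lmfit)$coefficients[terms_keep, , drop = FALSE]
    est <- data.frame(term = labels, estimate = sm[, 1],
                      ci_low = sm[, 1] - 1.96 * sm[, 2],
                      ci_high = sm[, 1] + 1.96 * sm[, 2],
                      p = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
    return(structure(list(estimates = est, ranef_variance = 0,
                          design = design, singular = TRUE),
                     class = "crcmb_lme"))
  }
  sm <- summary(fit)$coefficients
  keep <- setdiff(rownames(sm), "(Intercept)")
  est <- data.frame(
    term = keep,
    estimate = sm[keep, "Estimate"],
    ci_low = sm[keep, "Estimate"] - 1.96 * sm[keep, "Std. Error"],
    ci_high = sm[keep, "Estimate"] + 1.96 * sm[keep, "Std. Error"],
    p = 2 * stats::pnorm(-abs(sm[keep, "t value"])),
    row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(estimates = est,
                 ranef_variance = vc$vcov[vc$grp == "subject"],
                 design = design, singular = FALSE),
            class = "crcmb_lme")
}

#' @export
print.crcmb_lme <- function(x, ...) {
  cat(sprintf("<crcmb_lme> %s design%s\n", x$design,
              if (x$singular) " (singular fallback)" else ""))
  print(x$estimates)
  invisible(x)
}

# Firth-penalized logistic regression (Jeffreys prior) for separated data
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    hat <- XW %*% solve(info, t(XW))
    h <- diag(hat)
    score <- as.vector(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(info)))
  list(coef = beta, se = se)
}

per_subject_metadata <- function(metadata) {
  metadata[!duplicated(metadata$subject_id), , drop = FALSE]
}

#' Logistic regression for short-term survival
#'
#' Maximum-likelihood logistic regression of the dichotomized outcome
#' (short-term survival = 1) on a per-subject predictor, crude or adjusted
#' for the standard clinical covariates (age category, sex, ASA score,
#' tumor location, surgery period, TNM stage, radical surgery,
#' differentiation grade; those present in the metadata are used).  ORs
#' are `exp(coef)` with Wald 95% CIs.  Perfect separation raises an error
#' advising the Firth-penalized fallback, available via
#' `penalized = TRUE`.
#'
#' @param predictor named numeric vector or factor, names = subject IDs.
#' @param metadata a [sample_metadata()] data.frame.
#' @param adjust include the clinical covariates.
#' @param penalized use Firth-penalized estimation.
#' @return a `crcmb_logistic`: data.frame (term, or, ci_low, ci_high, p),
#'   model tag, covariates, n.
#' @export
logistic_survival <- function(predictor, metadata, adjust = FALSE,
                              penalized = FALSE) {
  meta <- per_subject_metadata(metadata)
  if (is.null(names(predictor))) {
    abort_crcmb("predictor must be named by subject ID",
                "crcmb_bad_argument")
  }
  idx <- match(meta$subject_id, names(predictor))
  if (anyNA(idx)) {
    abort_crcmb(sprintf("subjects missing a predictor value: %s",
                        paste(meta$subject_id[is.na(idx)], collapse = ", ")),
                "crcmb_bad_argument")
  }
  df <- data.frame(y = as.numeric(meta$survival == "short"),
                   x = predictor[idx])
  covars <- character(0)
  if (adjust) {
    covars <- intersect(covariate_columns, names(meta))
    for (cv in covars) {
      df[[cv]] <- factor(meta[[cv]], levels = crcmb_enums[[cv]])
    }
  }
  form <- stats::as.formula(paste("y ~", paste(c("x", covars),
                                               collapse = " + ")))
  if (penalized) {
    mm <- stats::model.matrix(form, df)
    fit <- firth_logistic(mm, df$y)
    terms <- colnames(mm)[-1]
    coefs <- fit$coef[-1]; ses <- fit$se[-1]
  } else {
    fit <- suppressWarnings(stats::glm(form, df, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    terms <- setdiff(rownames(sm), "(Intercept)")
    coefs <- sm[terms, "Estimate"]
    ses <- sm[terms, "Std. Error"]
    if (any(!is.finite(ses)) || any(ses > 50) || any(abs(coefs) > 15)) {
      abort_crcmb(
        "apparent perfect separation; rerun with penalized = TRUE (Firth) or use an exact method",
        "crcmb_separation")
    }
  }
  res <- data.frame(term = terms,
                    or = exp(coefs),
                    ci_low = exp(coefs - 1.96 * ses),
                    ci_high = exp(coefs + 1.96 * ses),
                    p = 2 * stats::pnorm(-abs(coefs / ses)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(estimates = res,
                 model = if (adjust) "adjusted" else "crude",
                 covariates = covars, n = nrow(df),
                 penalized = penalized),
            class = "crcmb_logistic")
}

#' @export
print.crcmb_logistic <- function(x, ...) {
  cat(sprintf("<crcmb_logistic> %s model, n = %d%s\n", x$model, x$n,
              if (x$penalized) " (Firth)" else ""))
  print(x$estimates)
  invisible(x)
}

#' Stratify per-subject scores
#'
#' `median_split` labels values above the median `"high"` and the rest
#' `"low"`; `tertiles` cuts at the 1/3 and 2/3 quantiles into `"T1"` <
#' `"T2"` < `"T3"`; `quadrants` crosses the median splits of two score
#' vectors into `"low-low"`, `"low-high"`, `"high-low"`, `"high-high"`.
#'
#' @param scores named numeric vector of per-subject scores.
#' @param mode `"median_split"`, `"tertiles"` or `"quadrants"`.
#' @param scores2 second score vector (quadrants only).
#' @return factor of labels, named like `scores`.
#' @export
stratify_scores <- function(scores,
                            mode = c("median_split", "tertiles",
                                     "quadrants"),
                            scores2 = NULL) {
  mode <- match.arg(mode)
  if (length(unique(scores)) < 2) {
    abort_crcmb("all scores tied; nothing to stratify",
                "crcmb_degenerate_scores")
  }
  med_split <- function(v) {
    factor(ifelse(v > stats::median(v), "high", "low"),
           levels = c("low", "high"))
  }
  out <- switch(mode,
    median_split = med_split(scores),
    tertiles = {
      qs <- stats::quantile(scores, c(1, 2) / 3, type = 7, names = FALSE)
      cut(scores, breaks = c(-Inf, qs, Inf), labels = c("T1", "T2", "T3"))
    },
    quadrants = {
      if (is.null(scores2) || length(scores2) != length(scores)) {
        abort_crcmb("quadrants need a second score vector of equal length",
                    "crcmb_bad_argument")
      }
      a <- med_split(scores); b <- med_split(scores2)
      factor(paste(a, b, sep = "-"),
             levels = c("low-low", "low-high", "high-low", "high-high"))
    })
  names(out) <- names(scores)
  out
}
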