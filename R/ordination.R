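# Subject-aware ordination: robust Aitchison PCA (matrix completion on the
# rCLR matrix) with automatic rank selection, and compositional tensor
# factorization (CTF) of the subject x tissue-state x feature tensor for
# paired designs.

# Masked alternating least squares at rank k.  M has NAs where counts were
# zero; the factorization minimizes squared error over observed entries
# only.  Initialized from the SVD of the zero-imputed matrix; the observed
# squared error is non-increasing across iterations by construction of the
# row-wise exact LS solves (a tiny ridge guards rank-deficient rows).
masked_als <- function(M, k, tol = 1e-8, max_iter = 500L) {
  obs <- !is.na(M)
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0)) {
    abort_crcmb("matrix has empty rows/columns after masking",
                "crcmb_degenerate_sample")
  }
  M0 <- M
  M0[!obs] <- 0
  sv <- svd(M0, nu = k, nv = k)
  U <- sv$u %*% diag(sv$d[seq_len(k)], k)
  V <- sv$v
  ridge <- diag(1e-10, k)

  loss <- function() sum((M - tcrossprod(U, V))[obs]^2)
  solve_rows <- function(target_obs, fixed, Mrows) {
    # solve LS for each row of the free factor given the fixed factor
    t(vapply(seq_len(nrow(Mrows)), function(i) {
      w <- target_obs[i, ]
      Fw <- fixed[w, , drop = FALSE]
      y <- Mrows[i, w]
      as.vector(solve(crossprod(Fw) + ridge, crossprod(Fw, y)))
    }, numeric(k)))
  }

  prev <- loss()
  trajectory <- prev
  for (iter in seq_len(max_iter)) {
    U <- solve_rows(obs, V, M)
    V <- solve_rows(t(obs), U, t(M))
    cur <- loss()
    trajectory <- c(trajectory, cur)
    if (prev - cur < tol * max(prev, .Machine$double.eps)) {
      prev <- cur
      break
    }
    prev <- cur
  }
  converged <- iter < max_iter
  if (!converged) {
    warning(sprintf("masked ALS did not converge in %d iterations", max_iter))
  }
  list(U = U, V = V, loss = prev, trajectory = trajectory,
       iterations = iter, converged = converged, n_obs = sum(obs))
}

orient_components <- function(scores, loadings) {
  for (r in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, r]))
    if (loadings[j, r] < 0) {
      loadings[, r] <- -loadings[, r]
      scores[, r] <- -scores[, r]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Robust Aitchison PCA
#'
#' Applies the rCLR transform (zeros become missing) and fits a low-rank
#' factorization minimizing squared error over the observed entries only
#' (alternating least squares, SVD-initialized from the zero-imputed
#' matrix).  On a table with no zeros this reduces exactly to the truncated
#' SVD of the row-centered rCLR matrix.  Components are ordered by singular
#' value and oriented so each component's largest-magnitude feature loading
#' is positive.
#'
#' @param table a [feature_table()], already feature-filtered (see
#'   [filter_rpca()]); at least 3 samples.
#' @param rank number of components, or `"auto"` to pick via [auto_rank()].
#' @param candidate_ranks candidates for `"auto"` (default 2:5).
#' @param tol,max_iter ALS convergence controls.
#' @param seed used only for the `"auto"` held-out masks.
#' @return a `crcmb_ordination`: `sample_scores`, `feature_loadings`,
#'   `singular_values`, `proportion_explained`, `residual` (RMSE over
#'   observed entries), `iterations`, `converged`.
#' @export
rpca <- function(table, rank = "auto", candidate_ranks = 2:5,
                 tol = 1e-8, max_iter = 500L, seed = 42) {
  if (length(table$sample_ids) < 3) {
    abort_crcmb("rpca needs at least 3 samples", "crcmb_bad_argument")
  }
  if (identical(rank, "auto")) {
    rank <- auto_rank(table, candidate_ranks, seed = seed,
                      tol = tol, max_iter = max_iter)
  }
  k <- assert_scalar_count(rank, "rank")
  M <- rclr(table)$values
  if (k >= min(dim(M))) {
    abort_crcmb("rank must be below both matrix dimensions",
                "crcmb_bad_argument")
  }
  fit <- masked_als(M, k, tol = tol, max_iter = max_iter)
  # rotate the converged low-rank fit to principal axes
  X <- tcrossprod(fit$U, fit$V)
  sv <- svd(X, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  scores <- sv$u %*% diag(d, k)
  loadings <- sv$v
  o <- orient_components(scores, loadings)
  rownames(o$scores) <- table$sample_ids
  rownames(o$loadings) <- table$feature_ids
  colnames(o$scores) <- colnames(o$loadings) <- paste0("PC", seq_len(k))
  structure(list(
    sample_scores = o$scores,
    feature_loadings = o$loadings,
    singular_values = d,
    proportion_explained = d^2 / sum(sv$d^2),
    residual = sqrt(fit$loss / fit$n_obs),
    iterations = fit$iterations,
    converged = fit$converged,
    loss_trajectory = fit$trajectory,
    rank = k
  ), class = "crcmb_ordination")
}

#' @export
print.crcmb_ordination <- function(x, ...) {
  cat(sprintf("<crcmb_ordination> rank %d, %d samples x %d features\n",
              x$rank, nrow(x$sample_scores), nrow(x$feature_loadings)))
  cat("  proportion explained:",
      paste(sprintf("%.3f", x$proportion_explained), collapse = " "), "\n")
  invisible(x)
}

#' Automatic rank selection for rPCA
#'
#' Masks a random 10% of the observed rCLR entries, fits each candidate
#' rank on the remainder, and measures reconstruction error on the
#' held-out entries; repeated `n_repeats` times under seed-derived masks.
#' Returns the candidate with the lowest mean held-out error (smallest
#' candidate on ties, which is also what pure noise selects).
#'
#' @param table a [feature_table()].
#' @param candidate_ranks integer candidates, all below `min(dim) - 1`.
#' @param holdout_frac fraction of observed entries held out (default 0.1).
#' @param n_repeats mask repetitions (default 5).
#' @param seed integer seed.
#' @param tol,max_iter ALS controls.
#' @return the selected rank (integer).
#' @export
auto_rank <- function(table, candidate_ranks = 2:5, holdout_frac = 0.1,
                      n_repeats = 5, seed = 42, tol = 1e-8,
                      max_iter = 500L) {
  if (!length(candidate_ranks)) {
    abort_crcmb("empty candidate set", "crcmb_bad_argument")
  }
  M <- rclr(table)$values
  candidate_ranks <- sort(unique(as.integer(candidate_ranks)))
  if (any(candidate_ranks < 1) || any(candidate_ranks >= min(dim(M)))) {
    abort_crcmb("candidate ranks must lie in [1, min(dim) - 1]",
                "crcmb_bad_argument")
  }
  obs_idx <- which(!is.na(M))
  err <- matrix(NA_real_, n_repeats, length(candidate_ranks))
  for (r in seq_len(n_repeats)) {
    hold <- with_seed(derive_seed(seed, 10L + r), {
      sample(obs_idx, max(1, round(holdout_frac * length(obs_idx))))
    })
    Mtrain <- M
    Mtrain[hold] <- NA
    # a held-out mask can empty a row/column; redraw deterministically
    tries <- 0
    while ((any(rowSums(!is.na(Mtrain)) < 2) ||
            any(colSums(!is.na(Mtrain)) < 1)) && tries < 10) {
      tries <- tries + 1
      hold <- with_seed(derive_seed(seed, 100L + 10L * r + tries), {
        sample(obs_idx, max(1, round(holdout_frac * length(obs_idx))))
      })
      Mtrain <- M
      Mtrain[hold] <- NA
    }
    for (ci in seq_along(candidate_ranks)) {
      fit <- withCallingHandlers(
        masked_als(Mtrain, candidate_ranks[ci], tol = tol,
                   max_iter = max_iter),
        warning = function(w) invokeRestart("muffleWarning"))
      X <- tcrossprod(fit$U, fit$V)
      err[r, ci] <- mean((M[hold] - X[hold])^2)
    }
  }
  candidate_ranks[which.min(colMeans(err))]
}

# CP (multilinear) ALS over the observed entries of a 3-way tensor stored
# as a long table: (i, s, f, value).
cp_als <- function(idx_i, idx_s, idx_f, y, dims, k, tol = 1e-8,
                   max_iter = 500L) {
  nI <- dims[1]; nS <- dims[2]; nF <- dims[3]
  # SVD-based init on the subject-mode unfolding (zero-imputed)
  M1 <- matrix(0, nI, nS * nF)
  M1[cbind(idx_i, (idx_f - 1L) * nS + idx_s)] <- y
  A <- svd(M1, nu = k, nv = 0)$u
  M3 <- matrix(0, nF, nS * nI)
  M3[cbind(idx_f, (idx_i - 1L) * nS + idx_s)] <- y
  C <- svd(M3, nu = k, nv = 0)$u
  B <- matrix(1, nS, k)
  ridge <- diag(1e-10, k)

  solve_mode <- function(mode_idx, n_rows, design) {
    out <- matrix(0, n_rows, k)
    for (i in seq_len(n_rows)) {
      rows <- mode_idx == i
      D <- design[rows, , drop = FALSE]
      out[i, ] <- as.vector(solve(crossprod(D) + ridge,
                                  crossprod(D, y[rows])))
    }
    out
  }
  fitted <- function() rowSums(A[idx_i, , drop = FALSE] *
                               B[idx_s, , drop = FALSE] *
                               C[idx_f, , drop = FALSE])
  prev <- sum((y - fitted())^2)
  for (iter in seq_len(max_iter)) {
    A <- solve_mode(idx_i, nI, B[idx_s, , drop = FALSE] *
                               C[idx_f, , drop = FALSE])
    B <- solve_mode(idx_s, nS, A[idx_i, , drop = FALSE] *
                               C[idx_f, , drop = FALSE])
    C <- solve_mode(idx_f, nF, A[idx_i, , drop = FALSE] *
                               B[idx_s, , drop = FALSE])
    cur <- sum((y - fitted())^2)
    if (prev - cur < tol * max(prev, .Machine$double.eps)) {
      prev <- cur
      break
    }
    prev <- cur
  }
  list(A = A, B = B, C = C, loss = prev, iterations = iter,
       converged = iter < max_iter)
}

#' Compositional tensor factorization for paired samples
#'
#' Builds the subject x tissue-state x feature tensor of rCLR values
#' (missing where counts were zero) and fits a k-component CP-style
#' multilinear factorization by alternating least squares over the
#' observed entries.  Subject scores are the subject factors scaled by the
#' component magnitudes; per-(subject, state) sample scores are the CP
#' model's natural per-cell product, `lambda_r * A[i,r] * B[s,r]`, i.e. the
#' state-specific projection of each subject.
#'
#' @param table a [feature_table()], already filtered (see [filter_ctf()]).
#' @param metadata a [sample_metadata()]; all subjects must be fully
#'   paired.
#' @param k number of components (default 3).
#' @param center_states subtract each state slice's per-feature observed
#'   mean before factorization (off by default).
#' @param tol,max_iter ALS controls.
#' @return a `crcmb_ctf`: `subject_scores`, `state_loadings`,
#'   `feature_loadings`, `sample_scores`, `lambda`,
#'   `proportion_explained`, plus fit diagnostics.
#' @export
ctf <- function(table, metadata, k = 3, center_states = FALSE,
                tol = 1e-8, max_iter = 500L) {
  k <- assert_scalar_count(k, "k")
  metadata <- metadata[metadata$sample_id %in% table$sample_ids, ,
                       drop = FALSE]
  pm <- paired_map(metadata, strict = TRUE)
  states <- crcmb_enums$tissue
  R <- rclr(table)$values

  long <- do.call(rbind, lapply(seq_len(nrow(pm)), function(i) {
    do.call(rbind, lapply(seq_along(states), function(s) {
      sid <- pm[[states[s]]][i]
      v <- R[sid, ]
      w <- which(!is.na(v))
      data.frame(i = i, s = s, f = w, y = v[w])
    }))
  }))
  if (center_states) {
    for (s in seq_along(states)) {
      sel <- long$s == s
      mu <- tapply(long$y[sel], long$f[sel], mean)
      long$y[sel] <- long$y[sel] - mu[as.character(long$f[sel])]
    }
  }
  fit <- cp_als(long$i, long$s, long$f, long$y,
                dims = c(nrow(pm), length(states),
                         length(table$feature_ids)),
                k = k, tol = tol, max_iter = max_iter)
  A <- fit$A; B <- fit$B; C <- fit$C
  # normalize factors to unit columns, absorb magnitudes into lambda
  nA <- sqrt(colSums(A^2)); nB <- sqrt(colSums(B^2)); nC <- sqrt(colSums(C^2))
  lam <- nA * nB * nC
  A <- sweep(A, 2, pmax(nA, .Machine$double.eps), "/")
  B <- sweep(B, 2, pmax(nB, .Machine$double.eps), "/")
  C <- sweep(C, 2, pmax(nC, .Machine$double.eps), "/")
  ord <- order(lam, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]; B <- B[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]; lam <- lam[ord]
  # deterministic orientation: feature loadings first, then subjects
  for (r in seq_len(k)) {
    j <- which.max(abs(C[, r]))
    if (C[j, r] < 0) { C[, r] <- -C[, r]; A[, r] <- -A[, r] }
    j <- which.max(abs(A[, r]))
    if (A[j, r] < 0) { A[, r] <- -A[, r]; B[, r] <- -B[, r] }
  }
  pcs <- paste0("PC", seq_len(k))
  subject_scores <- sweep(A, 2, lam, "*")
  dimnames(subject_scores) <- list(pm$subject_id, pcs)
  dimnames(B) <- list(states, pcs)
  dimnames(C) <- list(table$feature_ids, pcs)
  sample_ids <- c(pm$normal, pm$tumor)
  sample_scores <- rbind(
    sweep(A, 2, lam * B["normal", ], "*"),
    sweep(A, 2, lam * B["tumor", ], "*"))
  dimnames(sample_scores) <- list(sample_ids, pcs)
  structure(list(
    subject_scores = subject_scores,
    state_loadings = B,
    feature_loadings = C,
    sample_scores = sample_scores,
    lambda = lam,
    proportion_explained = lam^2 / sum(lam^2),
    subjects = pm,
    loss = fit$loss,
    iterations = fit$iterations,
    converged = fit$converged,
    k = k
  ), class = "crcmb_ctf")
}

#' @export
print.crcmb_ctf <- function(x, ...) {
  cat(sprintf("<crcmb_ctf> k = %d, %d subjects, %d features\n",
              x$k, nrow(x$subject_scores), nrow(x$feature_loadings)))
  invisible(x)
}

#' Euclidean distances between CTF subject coordinates
#'
#' @param ctf_result a `crcmb_ctf`.
#' @return a `crcmb_dist` over subjects.
#' @export
subject_distance <- function(ctf_result) {
  d <- as.matrix(stats::dist(ctf_result$subject_scores))
  new_dist(d, rownames(ctf_result$subject_scores), "ctf_subject_euclidean")
}

#' Per-subject tumor-minus-normal ordination shifts
#'
#' For every paired subject, the difference between the tumor and normal
#' subject-state coordinates along each component (tumor minus normal, so
#' a positive shift means the tumor sample sits higher on that component).
#'
#' @param ctf_result a `crcmb_ctf`.
#' @param metadata optional [sample_metadata()]; defaults to the pairing
#'   recorded in the CTF fit.
#' @return matrix subjects x components.
#' @export
paired_pc_deltas <- function(ctf_result, metadata = NULL) {
  pm <- if (is.null(metadata)) {
    ctf_result$subjects
  } else {
    paired_map(metadata[metadata$sample_id %in%
                          rownames(ctf_result$sample_scores), ,
                        drop = FALSE], strict = TRUE)
  }
  s <- ctf_result$sample_scores
  missing <- setdiff(c(pm$normal, pm$tumor), rownames(s))
  if (length(missing)) {
    abort_crcmb(sprintf("samples missing from CTF result: %s",
                        paste(missing, collapse = ", ")),
                "crcmb_missing_sample")
  }
  out <- s[pm$tumor, , drop = FALSE] - s[pm$normal, , drop = FALSE]
  rownames(out) <- pm$subject_id
  out
}

#' Serialize an ordination result as plain text
#'
#' Writes eigenvalue, proportion-explained, sample-score and
#' feature-loading blocks separated by blank lines.
#'
#' @param ord a `crcmb_ordination` or `crcmb_ctf`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ordination <- function(ord, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(ord, "crcmb_ctf")) {
    vals <- ord$lambda
    scores <- ord$sample_scores
    loadings <- ord$feature_loadings
  } else {
    vals <- ord$singular_values
    scores <- ord$sample_scores
    loadings <- ord$feature_loadings
  }
  writeLines(c("Eigvals", paste(format(vals, digits = 10), collapse = "\t"),
               "", "Proportion explained",
               paste(format(ord$proportion_explained, digits = 10),
                     collapse = "\t"), "", "Sample scores"), con)
  utils::write.table(scores, con, sep = "\t", quote = FALSE,
                     col.names = NA)
  writeLines(c("", "Feature loadings"), con)
  utils::write.table(loadings, con, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
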