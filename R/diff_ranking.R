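# Bayesian negative-binomial differential ranking.  Each feature's counts
# are modeled as NB(mu, phi) with log mu = log(depth) + alpha + beta*[tumor]
# (+ sigma*[short] + gamma*[tumor & short] for the interaction design) +
# u_subject, u ~ N(0, tau^2).  The prior on each contrast coefficient is a
# weakly-informative Normal scaled so a 5-fold change sits at ~2 SD
# (SD = ln(5)/2), a half-Normal(0,1) prior on tau, and logNormal(0,1) on
# the dispersion.  Posterior summaries come either from an adaptive
# random-walk Metropolis sampler (default; `iterations` total draws, half
# warmup) or from the much faster MAP + Laplace approximation
# (`method = "map"`), which shares the same posterior.  Only differences
# between features are identifiable under compositionality, so the log2
# differentials are centered across features before ranking.

nb_log_posterior <- function(theta, y, X, subj, offset, prior_sd,
                             intercept_sd = 10) {
  q <- ncol(X)
  J <- max(subj)
  b <- theta[seq_len(q)]
  u <- theta[q + seq_len(J)]
  logphi <- theta[q + J + 1L]
  ltau <- theta[q + J + 2L]
  phi <- exp(logphi)
  tau <- exp(ltau)
  eta <- offset + as.vector(X %*% b) + u[subj]
  if (any(eta > 40) || abs(logphi) > 30 || abs(ltau) > 30) {
    return(-1e10)  # finite barrier keeps L-BFGS-B inside the sane region
  }
  mu <- exp(eta)
  ll <- sum(lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
            phi * logphi + y * eta - (y + phi) * log(mu + phi))
  lp <- -b[1]^2 / (2 * intercept_sd^2) -
    sum(b[-1]^2) / (2 * prior_sd^2) -
    J * ltau - sum(u^2) / (2 * tau^2) -
    logphi^2 / 2 -
    tau^2 / 2 + ltau            # half-Normal(0,1) on tau, log-scale Jacobian
  out <- ll + lp
  if (!is.finite(out)) -1e10 else out
}

nb_log_posterior_grad <- function(theta, y, X, subj, offset, prior_sd,
                                  intercept_sd = 10) {
  q <- ncol(X)
  J <- max(subj)
  b <- theta[seq_len(q)]
  u <- theta[q + seq_len(J)]
  logphi <- theta[q + J + 1L]
  ltau <- theta[q + J + 2L]
  phi <- exp(logphi)
  tau <- exp(ltau)
  eta <- offset + as.vector(X %*% b) + u[subj]
  if (any(eta > 40) || abs(logphi) > 30 || abs(ltau) > 30) {
    return(numeric(length(theta)))  # inside the barrier region of the fn
  }
  mu <- exp(eta)
  r <- y - (y + phi) * mu / (mu + phi)
  g_b <- as.vector(crossprod(X, r))
  g_b[1] <- g_b[1] - b[1] / intercept_sd^2
  if (q > 1) g_b[-1] <- g_b[-1] - b[-1] / prior_sd^2
  g_u <- as.vector(rowsum(r, subj, reorder = TRUE)) - u / tau^2
  w <- digamma(y + phi) - digamma(phi) + logphi + 1 -
    log(mu + phi) - (y + phi) / (mu + phi)
  g_logphi <- phi * sum(w) - logphi
  g_ltau <- -J + sum(u^2) / tau^2 - tau^2 + 1
  c(g_b, g_u, g_logphi, g_ltau)
}

# Laplace-marginal objective: the subject intercepts are conditionally
# independent given (b, phi, tau) -- each u_j touches only subject j's two
# samples -- so they are profiled out by J one-dimensional Newton solves
# (vectorized across subjects) and integrated by a per-subject Laplace
# approximation.  Optimizing the joint posterior over (u, log tau) instead
# collapses into the hierarchical-MAP funnel at tau -> 0; the marginal is
# well behaved there.
nb_marginal_objective <- function(par, y, X, subj, offset, prior_sd,
                                  intercept_sd = 10, warm = NULL) {
  q <- ncol(X)
  b <- par[seq_len(q)]
  logphi <- par[q + 1L]
  ltau <- par[q + 2L]
  if (abs(logphi) > 30 || abs(ltau) > 30) return(-1e10)
  phi <- exp(logphi)
  tau2 <- exp(2 * ltau)
  eta0 <- offset + as.vector(X %*% b)
  if (any(eta0 > 40)) return(-1e10)
  J <- max(subj)
  u <- if (!is.null(warm) && !is.null(warm$u)) warm$u else numeric(J)
  for (it in 1:50) {
    eta <- eta0 + u[subj]
    mu <- exp(pmin(eta, 40))
    g <- as.vector(rowsum(y - (y + phi) * mu / (mu + phi), subj)) - u / tau2
    h <- as.vector(rowsum((y + phi) * phi * mu / (mu + phi)^2, subj)) +
      1 / tau2
    step <- g / h
    step <- pmin(pmax(step, -2), 2)  # damped Newton
    u <- u + step
    if (max(abs(step)) < 1e-9) break
  }
  eta <- eta0 + u[subj]
  mu <- exp(pmin(eta, 40))
  ll <- sum(lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
            phi * logphi + y * eta - (y + phi) * log(mu + phi))
  h <- as.vector(rowsum((y + phi) * phi * mu / (mu + phi)^2, subj)) +
    1 / tau2
  lap <- -sum(u^2) / (2 * tau2) - 0.5 * sum(log(tau2 * h))
  lp <- -b[1]^2 / (2 * intercept_sd^2)
  if (q > 1) lp <- lp - sum(b[-1]^2) / (2 * prior_sd^2)
  lp <- lp - logphi^2 / 2 - exp(2 * ltau) / 2 + ltau  # half-Normal on tau
  out <- ll + lap + lp
  if (!is.finite(out)) return(-1e10)
  if (!is.null(warm)) warm$u <- u
  out
}

fit_feature_map <- function(y, X, subj, offset, prior_sd,
                            compute_sd = TRUE) {
  q <- ncol(X)
  rel <- (y + 0.5) / exp(offset)
  u0 <- log(tapply(rel, subj, mean))
  init <- c(log(mean(rel)), rep(0, q - 1), 0,
            log(max(stats::sd(u0), 0.1)))
  warm <- new.env(parent = emptyenv())  # inner-Newton warm start cache
  fn <- function(par) -nb_marginal_objective(par, y, X, subj, offset,
                                             prior_sd, warm = warm)
  opt <- stats::optim(init, fn, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-10))
  if (opt$convergence != 0) {
    opt <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-10))
  }
  focal <- 2:q
  if (!compute_sd) {
    return(list(coef = opt$par[focal], sd = rep(NA_real_, q - 1),
                par = opt$par, converged = opt$convergence == 0))
  }
  # Laplace SDs for the contrast coefficients from the numerical Hessian
  # of the (low-dimensional) marginal objective
  p <- length(opt$par)
  eps <- 1e-3
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- numeric(p); ei[i] <- eps
      ej <- numeric(p); ej[j] <- eps
      H[i, j] <- H[j, i] <-
        (nb_marginal_objective(opt$par + ei + ej, y, X, subj, offset,
                               prior_sd, warm = warm) -
         nb_marginal_objective(opt$par + ei - ej, y, X, subj, offset,
                               prior_sd, warm = warm) -
         nb_marginal_objective(opt$par - ei + ej, y, X, subj, offset,
                               prior_sd, warm = warm) +
         nb_marginal_objective(opt$par - ei - ej, y, X, subj, offset,
                               prior_sd, warm = warm)) / (4 * eps^2)
    }
  }
  cov_mat <- tryCatch(solve(-H), error = function(e) NULL)
  sds <- if (is.null(cov_mat)) rep(NA_real_, q - 1) else {
    suppressWarnings(sqrt(diag(cov_mat)[focal]))
  }
  list(coef = opt$par[focal], sd = sds, par = opt$par,
       converged = opt$convergence == 0)
}

conditional_modes <- function(par, y, X, subj, offset) {
  q <- ncol(X)
  phi <- exp(par[q + 1L])
  tau2 <- exp(2 * par[q + 2L])
  eta0 <- offset + as.vector(X %*% par[seq_len(q)])
  u <- numeric(max(subj))
  for (it in 1:50) {
    mu <- exp(pmin(eta0 + u[subj], 40))
    g <- as.vector(rowsum(y - (y + phi) * mu / (mu + phi), subj)) - u / tau2
    h <- as.vector(rowsum((y + phi) * phi * mu / (mu + phi)^2, subj)) +
      1 / tau2
    step <- pmin(pmax(g / h, -2), 2)
    u <- u + step
    if (max(abs(step)) < 1e-9) break
  }
  u
}

fit_feature_mcmc <- function(y, X, subj, offset, prior_sd, iterations,
                             seed) {
  map <- fit_feature_map(y, X, subj, offset, prior_sd)
  q <- ncol(X)
  J <- max(subj)
  u_hat <- conditional_modes(map$par, y, X, subj, offset)
  start <- c(map$par[seq_len(q)], u_hat, map$par[q + 1L], map$par[q + 2L])
  p <- length(start)
  warmup <- floor(iterations / 2)
  step0 <- 2.38 / sqrt(p)
  with_seed(seed, {
    cur <- start
    cur_lp <- nb_log_posterior(cur, y, X, subj, offset, prior_sd)
    scale <- step0
    draws <- matrix(NA_real_, iterations - warmup, q - 1)
    acc_window <- 0
    for (it in seq_len(iterations)) {
      prop <- cur + stats::rnorm(p, 0, scale)
      prop_lp <- nb_log_posterior(prop, y, X, subj, offset, prior_sd)
      if (is.finite(prop_lp) &&
          log(stats::runif(1)) < prop_lp - cur_lp) {
        cur <- prop; cur_lp <- prop_lp
        acc_window <- acc_window + 1
      }
      if (it <= warmup && it %% 50 == 0) {
        rate <- acc_window / 50
        scale <- scale * exp(rate - 0.234)  # aim at RWM optimum
        acc_window <- 0
      }
      if (it > warmup) draws[it - warmup, ] <- cur[2:q]
    }
    list(coef = colMeans(draws), sd = apply(draws, 2, stats::sd),
         converged = TRUE)
  })
}

#' Bayesian negative-binomial differential ranking
#'
#' Fits, feature by feature, a negative-binomial mixed model with a
#' log-depth offset, a subject random intercept, and either a tissue
#' contrast or a tissue/survival interaction design (the latter includes a
#' survival main effect so the interaction is pure).  Posterior mean
#' contrast coefficients are converted to log2, centered across features
#' (only relative differentials are identifiable for compositional
#' counts), and ranked in descending order per contrast.
#'
#' @param table a [feature_table()], already filtered (see [filter_dr()]).
#' @param metadata a [sample_metadata()]; subjects must be fully paired.
#' @param design `"tissue"` or `"tissue_x_survival"`.
#' @param iterations total MCMC draws (half warmup); default 4000.
#' @param seed integer seed.
#' @param method `"mcmc"` (default) or `"map"` for the fast MAP + Laplace
#'   approximation used in simulation-heavy tests.
#' @param prior_sd prior SD (natural log) on the contrast coefficients;
#'   the default `log(5)/2` puts a 5-fold change at ~2 prior SD.
#' @param compute_sd in `"map"` mode, also compute Laplace posterior SDs
#'   (numerical Hessian); disable when only the ranks are needed.
#' @return a `crcmb_dr` with a long `differentials` data.frame (feature,
#'   contrast, differential in log2, sd, rank) and fit metadata.
#' @export
fit_differentials <- function(table, metadata,
                              design = c("tissue", "tissue_x_survival"),
                              iterations = 4000, seed = 42,
                              method = c("mcmc", "map"),
                              prior_sd = log(5) / 2, compute_sd = TRUE) {
  design <- match.arg(design)
  method <- match.arg(method)
  assert_scalar_count(iterations, "iterations", min = 2)
  metadata <- metadata[metadata$sample_id %in% table$sample_ids, ,
                       drop = FALSE]
  paired_map(metadata, strict = TRUE)  # errors on unpaired subjects
  idx <- metadata_rows(metadata, table$sample_ids)
  meta <- metadata[idx, , drop = FALSE]

  tumor <- as.numeric(meta$tissue == "tumor")
  short <- as.numeric(meta$survival == "short")
  X <- if (design == "tissue") {
    cbind(intercept = 1, tissue = tumor)
  } else {
    cbind(intercept = 1, tissue = tumor, survival = short,
          interaction = tumor * short)
  }
  contrasts <- colnames(X)[-1]
  subj <- as.integer(factor(meta$subject_id))
  offset <- log(sample_depths(table))
  nfeat <- length(table$feature_ids)

  coefs <- matrix(NA_real_, nfeat, length(contrasts),
                  dimnames = list(table$feature_ids, contrasts))
  sds <- coefs
  for (f in seq_len(nfeat)) {
    y <- table$counts[, f]
    fit <- if (method == "map") {
      fit_feature_map(y, X, subj, offset, prior_sd,
                      compute_sd = compute_sd)
    } else {
      fit_feature_mcmc(y, X, subj, offset, prior_sd, iterations,
                       derive_seed(seed, 1000L + f))
    }
    coefs[f, ] <- fit$coef
    sds[f, ] <- fit$sd
  }

  rows <- lapply(contrasts, function(cn) {
    diff2 <- coefs[, cn] / log(2)
    diff2 <- diff2 - mean(diff2)
    data.frame(feature_id = table$feature_ids, contrast = cn,
               differential = unname(diff2), sd = unname(sds[, cn] / log(2)),
               rank = rank(-diff2, ties.method = "first"),
               stringsAsFactors = FALSE)
  })
  structure(list(
    differentials = do.call(rbind, rows),
    design = design, method = method,
    iterations = as.integer(iterations), seed = as.integer(seed),
    prior_sd = prior_sd
  ), class = "crcmb_dr")
}

#' @export
print.crcmb_dr <- function(x, ...) {
  cat(sprintf("<crcmb_dr> %s design (%s), %d features\n", x$design,
              x$method, length(unique(x$differentials$feature_id))))
  invisible(x)
}

dr_contrast <- function(ranks, contrast) {
  d <- ranks$differentials[ranks$differentials$contrast == contrast, ,
                           drop = FALSE]
  if (!nrow(d)) {
    abort_crcmb(sprintf("contrast '%s' not in this fit", contrast),
                "crcmb_bad_argument")
  }
  d
}

#' Greedy extreme-feature cover selection
#'
#' Walks the differential ranking from the chosen extreme (`"top"` = most
#' positive differential, `"bottom"` = most negative), adding features in
#' rank order until every sample in scope contains at least one selected
#' feature with a nonzero count.  The stopping rule guarantees the last
#' added feature is necessary: dropping it leaves at least one sample
#' uncovered.
#'
#' @param ranks a `crcmb_dr` from [fit_differentials()].
#' @param table the [feature_table()] the ranks were fit on.
#' @param metadata needed only for `scope = "same_tissue"`.
#' @param direction `"top"` or `"bottom"`.
#' @param contrast which modeled contrast to rank on (default `"tissue"`).
#' @param scope `"all_samples"` (default) or `"same_tissue"`.
#' @param tissue tissue to cover when `scope = "same_tissue"`.
#' @return a `crcmb_cover`: ordered `features`, the `covered` ledger
#'   (sample -> first covering feature), `direction`, `scope`.
#' @export
select_extreme_cover <- function(ranks, table, metadata = NULL,
                                 direction = c("top", "bottom"),
                                 contrast = "tissue",
                                 scope = c("all_samples", "same_tissue"),
                                 tissue = "tumor") {
  direction <- match.arg(direction)
  scope <- match.arg(scope)
  d <- dr_contrast(ranks, contrast)
  shared <- intersect(d$feature_id, table$feature_ids)
  if (!length(shared)) {
    abort_crcmb("ranks and table share no features", "crcmb_bad_argument")
  }
  d <- d[d$feature_id %in% shared, , drop = FALSE]
  ord <- d$feature_id[order(d$differential,
                            decreasing = (direction == "top"))]

  target <- table$sample_ids
  if (scope == "same_tissue") {
    if (is.null(metadata)) {
      abort_crcmb("metadata required for scope = 'same_tissue'",
                  "crcmb_bad_argument")
    }
    rows <- metadata_rows(metadata, target)
    target <- target[metadata$tissue[rows] == tissue]
  }
  pres <- table$counts[target, ord, drop = FALSE] > 0
  unreachable <- target[rowSums(pres) == 0]
  if (length(unreachable)) {
    abort_crcmb(sprintf("sample(s) contain none of the candidate features: %s",
                        paste(unreachable, collapse = ", ")),
                "crcmb_cover_unattainable")
  }
  covered_by <- stats::setNames(rep(NA_character_, length(target)), target)
  selected <- character(0)
  for (f in ord) {
    selected <- c(selected, f)
    hit <- is.na(covered_by) & pres[, f]
    covered_by[hit] <- f
    if (!anyNA(covered_by)) break
  }
  structure(list(features = selected, covered = covered_by,
                 direction = direction, contrast = contrast,
                 scope = scope),
            class = "crcmb_cover")
}

#' @export
print.crcmb_cover <- function(x, ...) {
  cat(sprintf("<crcmb_cover> %s/%s: %d features covering %d samples\n",
              x$contrast, x$direction, length(x$features),
              length(x$covered)))
  invisible(x)
}
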