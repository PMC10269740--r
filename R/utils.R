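# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Statistical stages that need independent randomness (rarefaction per
#' sample, permutation tests, held-out masks) derive per-use seeds from one
#' master seed so that results do not depend on evaluation order.  Seeds are
#' kept in \code{[1, 2^31 - 2]} so they are always valid R integer seeds.
#'
#' @param seed master seed (single integer).
#' @param stream sub-stream index (single non-negative integer).
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # Lehmer-style mixing on the 2^31 - 1 field; deterministic, order-free.
  m <- 2147483647
  x <- (abs(as.double(seed)) %% m)
  x <- (x * 48271 + 1 + 69621 * as.double(stream)) %% m
  as.integer(max(1, x))
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_crcmb <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "crcmb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x)) {
    abort_crcmb(sprintf("`%s` must be a single integer >= %s", name, min),
                "crcmb_bad_argument")
  }
  invisible(as.integer(x))
}
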