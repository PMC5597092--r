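`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream-specific seed from a master seed
#'
#' All stochastic operations in the package accept an explicit integer seed.
#' When one run needs several independent random streams (e.g. the two
#' imputation runs inside [run_sensitivity()]), sub-seeds are derived from the
#' master seed with this deterministic splitting scheme, which keeps every
#' derived seed inside the 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param stream small non-negative integer identifying the stream.
#' @return An integer seed, distinct for distinct `(seed, stream)` pairs
#'   within the documented range (`stream` < 2011).
#' @export
derive_seed <- function(seed, stream) {
  seed <- as.integer(seed)
  stream <- as.integer(stream)
  stopifnot(length(seed) == 1L, length(stream) == 1L, stream >= 0L)
  as.integer((abs(seed) %% 999983L) * 2011 + (stream %% 2011L) + 17)
}

# significance stars with strict thresholds (.05 / .01 / .001)
stars_for_p <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

# row indices grouped by missingness pattern; each element carries the
# observed-column index set and the observed sub-matrix, ready for repeated
# likelihood evaluation
pattern_groups <- function(x) {
  obs <- !is.na(x)
  key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  idx <- split(seq_len(nrow(x)), key)
  lapply(idx, function(rows) {
    o <- which(obs[rows[1L], ])
    list(rows = rows, o = o,
         Y = x[rows, o, drop = FALSE],
         n = length(rows))
  })
}

# multivariate-normal log-likelihood of rows Y at (mu, sigma); NA when sigma
# is not positive definite so callers can apply a penalty instead of crashing
mvn_ll_rows <- function(Y, mu, sigma) {
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  ctr <- Y - rep(mu, each = nrow(Y))
  v <- backsolve(R, t(ctr), transpose = TRUE)
  -0.5 * sum(v * v) -
    nrow(Y) * (0.5 * ncol(Y) * log(2 * pi) + sum(log(diag(R))))
}

# central finite-difference Hessian; step follows 1e-5 * max(|x|, 1)
fd_hessian <- function(f, x, step = NULL) {
  k <- length(x)
  h <- step %||% (1e-5 * pmax(abs(x), 1))
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1L) for (j in seq_len(i - 1L)) {
      ej <- numeric(k); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

# invert an observed-information matrix, falling back to a pseudo-inverse
# with a warning when it is numerically singular
solve_vcov <- function(H) {
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) {
    warning("observed information matrix is singular; ",
            "standard errors use a pseudo-inverse", call. = FALSE)
    V <- MASS::ginv(H)
  }
  (V + t(V)) / 2
}

fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), "", formatC(x, digits = digits, format = "f"))
}
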