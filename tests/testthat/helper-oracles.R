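# Independent oracles and shared fixtures for the test suite.

# multivariate-normal log-density via determinant and solve, independent of
# the package's cholesky-based likelihood path
dmvnorm_log <- function(x, mu, S) {
  k <- length(mu)
  d <- as.numeric(x - mu)
  as.numeric(-0.5 * (k * log(2 * pi) +
                       determinant(S, logarithm = TRUE)$modulus +
                       drop(t(d) %*% solve(S) %*% d)))
}

# brute-force FIML log-likelihood: per-subject marginalisation of the
# implied trivariate normal, row by row
brute_fiml <- function(y, params, spec) {
  imp <- implied_moments(params, spec)
  ll <- 0
  for (i in seq_len(nrow(y))) {
    o <- which(!is.na(y[i, ]))
    ll <- ll + dmvnorm_log(y[i, o], imp$mean[o], imp$cov[o, o, drop = FALSE])
  }
  ll
}

# memoised study-emulation draws shared across test files
study_ds <- local({
  cache <- new.env(parent = emptyenv())
  function(seed, mechanism = "MAR") {
    key <- paste0(mechanism, "_", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- suppressMessages(generate_study_dataset(seed, mechanism))
    cache[[key]]
  }
})

LAM3 <- c(0, 1.17, 2.17)

# a single-group "grouping" for engine-level equivalence checks
one_group_grouping <- function(n) {
  structure(list(group = rep(1L, n), k = 1L, n_g = n, pi_g = 1,
                 N = n, mode = "manual"),
            class = "dropout_grouping")
}
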