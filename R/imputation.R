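#' Joint multivariate-normal multiple imputation
#'
#' Data-augmentation sampler for an unstructured multivariate normal over
#' the outcome waves (optionally joined with the auxiliary variables). The
#' I-step draws each row's missing cells from their conditional normal given
#' the observed cells and the current `(mu, Sigma)`; the P-step draws
#' `(mu, Sigma)` from the posterior under the Jeffreys-style noninformative
#' prior (`Sigma` inverse-Wishart on `n - 1` degrees of freedom, `mu`
#' normal given `Sigma`). One completed dataset is kept every `thin`
#' iterations after `burn_in`. Observed cells are never altered.
#'
#' @param ds a [wide_dataset()].
#' @param m number of completed datasets (>= 2).
#' @param include_aux include the auxiliaries in the imputation model
#'   (analysis models never change); factors enter as dummy codes and
#'   imputed auxiliary values are used unrounded.
#' @param burn_in sampler burn-in iterations.
#' @param thin iterations between retained datasets.
#' @param seed integer seed.
#' @return An object of class `imputation_set`: list with `datasets` (m
#'   completed outcome matrices), `m`, `wave_times`, `variables`,
#'   `settings`, `seed`.
#' @export
mvn_impute <- function(ds, m = 100, include_aux = FALSE,
                       burn_in = 500, thin = 100, seed = NULL) {
  stopifnot(m >= 2)
  nt <- ncol(ds$y)
  X <- ds$y
  if (include_aux) X <- cbind(X, build_aux_matrix(ds))
  n <- nrow(X); p <- ncol(X)
  if (!is.null(seed)) set.seed(seed)

  em <- em_mvn(X)
  if (!em$converged)
    stop("EM for the imputation model did not converge")
  mu <- em$mu; Sigma <- em$sigma

  groups <- pattern_groups(X)
  incomplete <- Filter(function(g) length(g$o) < p, groups)
  any_missing <- length(incomplete) > 0L
  Xc <- X
  keep <- vector("list", m)
  kept <- 0L
  total <- if (any_missing) burn_in + m * thin else 0L

  draw_sigma <- function(S) {
    for (try in 0:5) {
      Sj <- S + diag(try * 1e-8 * max(diag(S)), p)
      W <- tryCatch(stats::rWishart(1L, n - 1L, solve(Sj))[, , 1L],
                    error = function(e) NULL)
      if (!is.null(W)) {
        V <- tryCatch(solve(W), error = function(e) NULL)
        if (!is.null(V) && all(is.finite(V))) return((V + t(V)) / 2)
      }
    }
    stop("imputation sampler diverged (non-positive-definite draw)")
  }

  it <- 0L
  while (kept < m && any_missing) {
    it <- it + 1L
    # I-step
    for (g in incomplete) {
      o <- g$o
      mi <- setdiff(seq_len(p), o)
      R <- chol(Sigma[o, o, drop = FALSE])
      B <- Sigma[mi, o, drop = FALSE] %*% chol2inv(R)
      Em <- rep(mu[mi], each = g$n) +
        (g$Y - rep(mu[o], each = g$n)) %*% t(B)
      Cmm <- Sigma[mi, mi, drop = FALSE] -
        B %*% Sigma[o, mi, drop = FALSE]
      Cmm <- (Cmm + t(Cmm)) / 2
      Rc <- chol(Cmm + diag(1e-12, length(mi)))
      Z <- matrix(stats::rnorm(g$n * length(mi)), g$n) %*% Rc
      Xc[g$rows, mi] <- Em + Z
    }
    # P-step
    xbar <- colMeans(Xc)
    S <- crossprod(sweep(Xc, 2L, xbar))
    Sigma <- draw_sigma(S)
    mu <- xbar + drop(stats::rnorm(p) %*% chol(Sigma / n))
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      keep[[kept]] <- Xc[, seq_len(nt), drop = FALSE]
    }
  }
  if (!any_missing) keep <- replicate(m, X[, seq_len(nt), drop = FALSE],
                                      simplify = FALSE)

  structure(list(datasets = keep, m = m, wave_times = ds$wave_times,
                 variables = colnames(X),
                 settings = list(include_aux = include_aux,
                                 burn_in = burn_in, thin = thin),
                 seed = seed),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("imputation_set: m =", x$m, "completed datasets over",
      length(x$variables), "variables\n")
  cat("  sampler: burn-in", x$settings$burn_in, ", thinning",
      x$settings$thin, if (x$settings$include_aux)
        ", auxiliaries in the imputation model", "\n")
  invisible(x)
}

#' Fit the growth model on each completed dataset
#'
#' Complete-data ML growth fit per imputed dataset, order preserved. Any
#' non-convergent fit is excluded from downstream pooling with a warning.
#'
#' @param imp an [mvn_impute()] result.
#' @param spec a [growth_spec()].
#' @return List of `lgm_fit` objects (attribute `n_dropped` counts excluded
#'   fits).
#' @export
fit_growth_on_imputations <- function(imp, spec) {
  fits <- lapply(seq_len(imp$m), function(i)
    lgm_optimize(imp$datasets[[i]], spec, technique = "MI-replicate"))
  ok <- vapply(fits, `[[`, logical(1), "converged")
  if (any(!ok))
    warning(sum(!ok), " of ", imp$m,
            " per-imputation fits did not converge and were excluded")
  out <- fits[ok]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Pool growth fits over imputations with Rubin's rules
#'
#' Pooled estimate `Qbar` = mean of the per-imputation estimates; within
#' variance `W` = mean squared SE; between variance `B` = sample variance
#' of the estimates; total variance `T = W + (1 + 1/m) B`; degrees of
#' freedom `nu = (m - 1) (1 + W / ((1 + 1/m) B))^2` (classical Rubin, no
#' small-sample correction); p from the t distribution on `nu`.
#'
#' @param fits list of `lgm_fit` objects on a common parameter set.
#' @param technique label for the pooled result (default `"MI"`).
#' @return An object of class `pooled_fit`: `table` (per-parameter `Qbar`,
#'   `W`, `B`, `T`, `se`, `df`, `p`) plus `estimate`, `se`, `z` (the t
#'   ratio), `p` vectors for uniform downstream access, `m`, `technique`.
#' @export
pool_rubin <- function(fits, technique = "MI") {
  m <- length(fits)
  if (m < 2L) stop("Rubin pooling needs at least two fits (B is undefined)")
  nm <- names(fits[[1L]]$estimate)
  if (!all(vapply(fits, function(f) identical(names(f$estimate), nm),
                  logical(1))))
    stop("fits do not share a common parameter set")
  Q <- do.call(rbind, lapply(fits, function(f) f$estimate[nm]))
  S <- do.call(rbind, lapply(fits, function(f) f$se[nm]))
  Qbar <- colMeans(Q)
  W <- colMeans(S^2)
  B <- apply(Q, 2L, stats::var)
  Tt <- W + (1 + 1 / m) * B
  se <- sqrt(Tt)
  nu <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  tstat <- Qbar / se
  pval <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), nu), NA_real_)
  tab <- data.frame(parameter = nm, Qbar = Qbar, W = W, B = B, T = Tt,
                    se = se, df = nu, p = pval, row.names = NULL)
  structure(list(table = tab,
                 estimate = stats::setNames(Qbar, nm),
                 se = stats::setNames(se, nm),
                 z = stats::setNames(tstat, nm),
                 p = stats::setNames(pval, nm),
                 m = m, technique = technique),
            class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("Rubin-pooled growth model [%s], m = %d\n", x$technique, x$m))
  df <- data.frame(parameter = x$table$parameter,
                   estimate = fmt_num(x$table$Qbar),
                   se = fmt_num(x$table$se),
                   stars = stars_for_p(x$table$p))
  print(df, row.names = FALSE)
  invisible(x)
}
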