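#' Linear latent growth model specification
#'
#' The model skeleton: intercept loadings fixed at 1, slope loadings given
#' by `wave_times` (first 0, strictly increasing), per-wave or homogeneous
#' residual variances, and flags for freeing the slope variance and the
#' intercept-slope covariance. Fixing `cov_IS_free = FALSE` sets the latent
#' covariance to zero, the usual convention when a covariance is not
#' reported.
#'
#' @param wave_times slope loadings (years).
#' @param residual `"per-wave"` (default) or `"homogeneous"`.
#' @param cov_IS_free free the intercept-slope covariance (default `TRUE`).
#' @param slope_var_free free the slope variance (default `TRUE`); fixing it
#'   also fixes the covariance to 0.
#' @return An object of class `growth_spec`.
#' @export
growth_spec <- function(wave_times, residual = c("per-wave", "homogeneous"),
                        cov_IS_free = TRUE, slope_var_free = TRUE) {
  residual <- match.arg(residual)
  wave_times <- as.numeric(wave_times)
  if (wave_times[1L] != 0) stop("the first slope loading must be 0")
  if (any(diff(wave_times) <= 0)) stop("loadings must be strictly increasing")
  nt <- length(wave_times)
  n_free <- 2L + 1L + (slope_var_free) + (slope_var_free && cov_IS_free) +
    if (residual == "per-wave") nt else 1L
  if (n_free > nt + nt * (nt + 1L) / 2L)
    stop("more free parameters than observed moments")
  structure(list(wave_times = wave_times, residual = residual,
                 cov_IS_free = cov_IS_free, slope_var_free = slope_var_free),
            class = "growth_spec")
}

# free-parameter layout for a growth model, optionally with q saturated
# auxiliary correlates appended
lgm_parinfo <- function(spec, aux_names = NULL) {
  nt <- length(spec$wave_times)
  q <- length(aux_names)
  nm <- c("mu_I", "mu_S", "psi_II")
  lo <- c(-Inf, -Inf, 1e-8)
  if (spec$slope_var_free) { nm <- c(nm, "psi_SS"); lo <- c(lo, 1e-8) }
  if (spec$slope_var_free && spec$cov_IS_free) {
    nm <- c(nm, "psi_IS"); lo <- c(lo, -Inf)
  }
  if (spec$residual == "per-wave") {
    nm <- c(nm, paste0("theta_", seq_len(nt)))
    lo <- c(lo, rep(1e-8, nt))
  } else { nm <- c(nm, "theta"); lo <- c(lo, 1e-8) }
  if (q > 0L) {
    nm <- c(nm, paste0("nu_", aux_names))
    lo <- c(lo, rep(-Inf, q))
    for (k in seq_len(q)) for (l in k:q) {
      nm <- c(nm, paste0("phi_", k, "_", l))
      lo <- c(lo, if (k == l) 1e-8 else -Inf)
    }
    for (k in seq_len(q)) for (t in seq_len(nt)) {
      nm <- c(nm, paste0("c_", aux_names[k], "_w", t))
      lo <- c(lo, -Inf)
    }
  }
  list(names = nm, lower = stats::setNames(lo, nm), nt = nt, q = q,
       aux_names = aux_names)
}

# expand a free-parameter vector to the full growth parameter list
lgm_expand <- function(par, spec, info) {
  nt <- info$nt
  theta <- if (spec$residual == "per-wave")
    unname(par[paste0("theta_", seq_len(nt))])
  else rep(unname(par["theta"]), nt)
  list(mu_I = unname(par["mu_I"]), mu_S = unname(par["mu_S"]),
       psi_II = unname(par["psi_II"]),
       psi_SS = if (spec$slope_var_free) unname(par["psi_SS"]) else 0,
       psi_IS = if (spec$slope_var_free && spec$cov_IS_free)
         unname(par["psi_IS"]) else 0,
       theta = theta)
}

#' Model-implied moments of the latent growth model
#'
#' Standard growth-model algebra: `mean_t = mu_I + lambda_t * mu_S` and
#' `cov_ts = psi_II + lambda_t*lambda_s*psi_SS + (lambda_t+lambda_s)*psi_IS
#' + [t==s]*theta_t`.
#'
#' @param params list (or [growth_params()]) with `mu_I`, `mu_S`, `psi_II`,
#'   `psi_SS`, `psi_IS`, `theta` (scalar or per wave).
#' @param spec a [growth_spec()].
#' @return List with `mean` (length T) and `cov` (T x T).
#' @export
implied_moments <- function(params, spec) {
  lam <- spec$wave_times
  nt <- length(lam)
  theta <- rep(params$theta, length.out = nt)
  mu <- params$mu_I + lam * params$mu_S
  cov <- params$psi_II + outer(lam, lam) * params$psi_SS +
    (outer(lam, rep(1, nt)) + outer(rep(1, nt), lam)) * params$psi_IS +
    diag(theta, nt)
  list(mean = mu, cov = cov)
}

# implied joint moments over (waves, auxiliaries) for a parameter vector
lgm_implied_par <- function(par, spec, info) {
  full <- lgm_expand(par, spec, info)
  base <- implied_moments(full, spec)
  if (info$q == 0L) return(list(mu = base$mean, sigma = base$cov))
  nt <- info$nt; q <- info$q
  nu <- unname(par[paste0("nu_", info$aux_names)])
  Phi <- matrix(0, q, q)
  for (k in seq_len(q)) for (l in k:q)
    Phi[k, l] <- Phi[l, k] <- par[[paste0("phi_", k, "_", l)]]
  C <- matrix(0, nt, q)
  for (k in seq_len(q)) for (t in seq_len(nt))
    C[t, k] <- par[[paste0("c_", info$aux_names[k], "_w", t)]]
  list(mu = c(base$mean, nu),
       sigma = rbind(cbind(base$cov, C), cbind(t(C), Phi)))
}

#' Full-information ML log-likelihood of a growth model
#'
#' Each subject contributes the multivariate-normal log-density of their
#' observed sub-vector under the corresponding sub-mean and sub-covariance
#' of the model-implied moments; contributions are summed over subjects. A
#' non-positive-definite implied (sub)matrix yields `-Inf` rather than an
#' error, so optimisers treat it as a penalty.
#'
#' @param params parameter list as in [implied_moments()].
#' @param spec a [growth_spec()].
#' @param ds a [wide_dataset()] or numeric matrix (every row with at least
#'   one observed wave).
#' @return The log-likelihood (scalar).
#' @export
fiml_loglik <- function(params, spec, ds) {
  y <- if (inherits(ds, "wide_dataset")) ds$y else as.matrix(ds)
  if (any(rowSums(!is.na(y)) == 0L))
    stop("subjects with no observed wave must be excluded upstream")
  imp <- implied_moments(params, spec)
  ll <- 0
  for (g in pattern_groups(y)) {
    l <- mvn_ll_rows(g$Y, imp$mean[g$o], imp$cov[g$o, g$o, drop = FALSE])
    if (is.na(l)) return(-Inf)
    ll <- ll + l
  }
  ll
}

# negative-loglik factory over a fixed (joint) data matrix, with pattern
# groups precomputed once
make_lgm_objfn <- function(X, spec, info) {
  groups <- pattern_groups(X)
  function(par) {
    imp <- lgm_implied_par(par, spec, info)
    ll <- 0
    for (g in groups) {
      l <- mvn_ll_rows(g$Y, imp$mu[g$o], imp$sigma[g$o, g$o, drop = FALSE])
      if (is.na(l)) return(1e10)
      ll <- ll + l
    }
    -ll
  }
}

# moment-based deterministic starting values
lgm_start <- function(X, spec, info) {
  nt <- info$nt
  em <- tryCatch(suppressWarnings(em_mvn(X, tol = 1e-8, max_iter = 300)),
                 error = function(e) NULL)
  if (is.null(em)) {
    muh <- colMeans(X, na.rm = TRUE)
    Sh <- stats::cov(X, use = "pairwise.complete.obs")
    Sh[is.na(Sh)] <- 0
  } else { muh <- em$mu; Sh <- em$sigma }
  lam <- spec$wave_times
  Xd <- cbind(1, lam)
  b <- solve(crossprod(Xd), crossprod(Xd, muh[seq_len(nt)]))
  if (max(abs(Sh[seq_len(nt), seq_len(nt)])) < 1e-10) {
    # degenerate (noise-free) outcome data: the likelihood is unbounded in
    # the variances, so start them on their lower bounds
    theta0 <- rep(1e-8, nt)
    psiII0 <- psiSS0 <- 1e-8
  } else {
    theta0 <- pmax(0.4 * diag(Sh)[seq_len(nt)], 1e-3)
    psiII0 <- max(Sh[1L, 1L] - theta0[1L], 0.02)
    psiSS0 <- max((Sh[nt, nt] - Sh[1L, 1L]) / lam[nt]^2, 0.01)
  }
  st <- c(mu_I = unname(b[1L]), mu_S = unname(b[2L]), psi_II = psiII0)
  if (spec$slope_var_free) st <- c(st, psi_SS = psiSS0)
  if (spec$slope_var_free && spec$cov_IS_free) {
    psiIS0 <- (Sh[1L, nt] - psiII0) / lam[nt]
    cap <- 0.9 * sqrt(psiII0 * psiSS0)
    st <- c(st, psi_IS = sign(psiIS0) * min(abs(psiIS0), cap))
  }
  st <- if (spec$residual == "per-wave")
    c(st, stats::setNames(theta0, paste0("theta_", seq_len(nt))))
  else c(st, theta = mean(theta0))
  if (info$q > 0L) {
    ai <- nt + seq_len(info$q)
    st <- c(st, stats::setNames(muh[ai], paste0("nu_", info$aux_names)))
    for (k in seq_len(info$q)) for (l in k:info$q)
      st <- c(st, stats::setNames(
        if (k == l) max(Sh[ai[k], ai[k]], 1e-3) else Sh[ai[k], ai[l]],
        paste0("phi_", k, "_", l)))
    for (k in seq_len(info$q)) for (t in seq_len(nt))
      st <- c(st, stats::setNames(Sh[t, ai[k]],
                                  paste0("c_", info$aux_names[k], "_w", t)))
  }
  st[info$names]
}

# core quasi-Newton fit with three deterministic restarts from jittered
# moment-based starts; best log-likelihood wins, ties broken by first
lgm_optimize <- function(X, spec, technique, aux_names = NULL,
                         compute_se = TRUE, restarts = 3) {
  info <- lgm_parinfo(spec, aux_names)
  obj <- make_lgm_objfn(X, spec, info)
  st <- lgm_start(X, spec, info)
  var_idx <- which(info$lower > -Inf)
  best <- NULL
  for (f in c(1, 1.4, 0.6)[seq_len(restarts)]) {
    s <- st
    s[var_idx] <- pmax(s[var_idx] * f, info$lower[var_idx])
    opt <- stats::nlminb(s, obj, lower = info$lower,
                         control = list(iter.max = 2000, eval.max = 4000,
                                        rel.tol = 1e-12, x.tol = 1e-11))
    if (is.null(best) || opt$objective < best$objective - 1e-9) best <- opt
  }
  # polish: one more pass from the winning optimum tightens the last digit
  polish <- stats::nlminb(best$par, obj, lower = info$lower,
                          control = list(iter.max = 500, eval.max = 1000,
                                         rel.tol = 1e-14, x.tol = 1e-12))
  if (polish$objective <= best$objective) {
    polish$message <- best$message
    polish$convergence <- min(polish$convergence, best$convergence)
    best <- polish
  }
  est <- stats::setNames(best$par, info$names)
  se <- z <- p <- rep(NA_real_, length(est))
  vcov <- NULL
  if (compute_se) {
    H <- fd_hessian(obj, est)
    vcov <- solve_vcov(H)
    dimnames(vcov) <- list(info$names, info$names)
    d <- diag(vcov)
    se <- ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_)
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(technique = technique,
                 estimate = est,
                 se = stats::setNames(se, info$names),
                 z = stats::setNames(z, info$names),
                 p = stats::setNames(p, info$names),
                 vcov = vcov,
                 loglik = -best$objective,
                 n_used = nrow(X),
                 # "singular convergence" is nlminb's label for an optimum
                 # with a flat/boundary direction (e.g. a variance at its
                 # bound); the iterates have converged
                 converged = best$convergence == 0 ||
                   grepl("singular convergence", best$message %||% ""),
                 iterations = best$iterations,
                 message = best$message,
                 spec = spec, parinfo = info),
            class = "lgm_fit")
}

#' @export
print.lgm_fit <- function(x, ...) {
  cat(sprintf("latent growth model [%s], n = %d, loglik = %.3f%s\n",
              x$technique, x$n_used, x$loglik,
              if (!x$converged) "  (NOT converged)" else ""))
  show <- intersect(c("mu_I", "mu_S", "psi_II", "psi_SS", "psi_IS",
                      grep("^theta", names(x$estimate), value = TRUE)),
                    names(x$estimate))
  df <- data.frame(parameter = show,
                   estimate = fmt_num(x$estimate[show]),
                   se = fmt_num(x$se[show]),
                   stars = stars_for_p(x$p[show]))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Fit the growth model on complete cases (listwise deletion)
#'
#' ML estimation restricted to subjects observed at every wave. Unbiased
#' only under MCAR; under selective dropout the complete cases are a
#' selected sample, which typically biases the mean intercept and shrinks
#' the intercept variance.
#'
#' @param ds a [wide_dataset()].
#' @param spec a [growth_spec()].
#' @param compute_se compute observed-information standard errors (default
#'   `TRUE`; simulation loops that only need point estimates can switch
#'   them off).
#' @param restarts number of deterministic jittered restarts (default 3).
#' @return An `lgm_fit` with technique label `"LD"` and `n_used` equal to
#'   the complete-case count.
#' @export
fit_lgm_listwise <- function(ds, spec, compute_se = TRUE, restarts = 3) {
  cc <- rowSums(is.na(ds$y)) == 0L
  info <- lgm_parinfo(spec)
  if (sum(cc) <= length(info$names))
    stop("too few complete cases (", sum(cc), ") to estimate ",
         length(info$names), " parameters")
  lgm_optimize(ds$y[cc, , drop = FALSE], spec, "LD",
               compute_se = compute_se, restarts = restarts)
}

#' Fit the growth model by full-information maximum likelihood
#'
#' Maximises [fiml_loglik()] over all retained subjects; each subject
#' contributes through their observed waves only. Standard errors come from
#' the observed information matrix (inverse negative Hessian at the
#' optimum, central finite differences), with normal-theory z and p.
#'
#' @param ds a [wide_dataset()].
#' @param spec a [growth_spec()].
#' @param compute_se compute observed-information standard errors (default
#'   `TRUE`).
#' @param restarts number of deterministic jittered restarts (default 3).
#' @return An `lgm_fit` with technique label `"ML"`.
#' @export
fit_lgm_fiml <- function(ds, spec, compute_se = TRUE, restarts = 3) {
  lgm_optimize(ds$y, spec, "ML", compute_se = compute_se,
               restarts = restarts)
}

#' FIML with saturated-correlates auxiliary variables
#'
#' Joins the auxiliaries to the outcome vector and gives the joint implied
#' moments a saturated auxiliary block: free auxiliary means and
#' covariances and free auxiliary-outcome covariances, while the outcome
#' block keeps the growth structure. FIML then runs over the joint observed
#' data, letting auxiliaries that predict missingness or correlate with the
#' outcome inform the estimates; only the growth parameters are of
#' interest in the output.
#'
#' @param ds a [wide_dataset()] with auxiliaries.
#' @param spec a [growth_spec()].
#' @param aux auxiliary column names (default: all). Factors are expanded
#'   to dummy codes; a constant auxiliary is an error.
#' @return An `lgm_fit` with technique label `"MLaux"`.
#' @export
fit_lgm_fiml_aux <- function(ds, spec, aux = NULL) {
  A <- build_aux_matrix(ds, aux)
  ncc <- sum(rowSums(is.na(ds$y)) == 0L)
  if (ncol(A) > ncc / 3)
    warning("more auxiliaries (", ncol(A), ") than one third of the ",
            "complete cases (", ncc, "); estimates may lose precision",
            call. = FALSE)
  X <- cbind(ds$y, A)
  lgm_optimize(X, spec, "MLaux", aux_names = colnames(A))
}

# numeric auxiliary design: factors to dummies, constants rejected
build_aux_matrix <- function(ds, aux = NULL) {
  if (is.null(ds$aux)) stop("dataset has no auxiliary variables")
  A <- ds$aux[, aux %||% names(ds$aux), drop = FALSE]
  cols <- lapply(names(A), function(nm) {
    v <- A[[nm]]
    if (is.numeric(v)) {
      out <- matrix(v, ncol = 1L, dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      lev <- levels(f)
      if (length(lev) < 2L) stop("constant auxiliary variable: ", nm)
      out <- vapply(lev[-1L], function(l) as.numeric(f == l),
                    numeric(length(f)))
      colnames(out) <- paste0(nm, "_", lev[-1L])
      out[is.na(v), ] <- NA_real_
    }
    out
  })
  M <- do.call(cbind, cols)
  sds <- apply(M, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop("constant auxiliary variable: ",
         paste(colnames(M)[!is.finite(sds) | sds == 0], collapse = ", "))
  M
}

#' Wald summary table for a fitted growth model
#'
#' @param est an `lgm_fit` (or `pooled_fit`).
#' @param level confidence level for the symmetric normal interval
#'   (default 0.95, i.e. estimate +/- 1.96 se).
#' @return Data frame `parameter`, `estimate`, `se`, `z`, `p`, `stars`,
#'   `ci_low`, `ci_high`. Star thresholds are strict (.05/.01/.001).
#' @export
wald_summary <- function(est, level = 0.95) {
  crit <- stats::qnorm(1 - (1 - level) / 2)
  nm <- names(est$estimate)
  data.frame(parameter = nm,
             estimate = unname(est$estimate),
             se = unname(est$se),
             z = unname(est$z),
             p = unname(est$p),
             stars = stars_for_p(est$p),
             ci_low = unname(est$estimate - crit * est$se),
             ci_high = unname(est$estimate + crit * est$se),
             row.names = NULL)
}
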