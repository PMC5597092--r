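#' Assign dropout groups
#'
#' Forms the dropout subgroups a pattern-mixture model stratifies on, either
#' from an administrative label (enrolment records: the trustworthy "true"
#' dropout pattern) or, as a fallback, from each subject's last observed
#' wave. With `k = 2`, group 1 is the persisting/complete group and group 2
#' everyone else; with `k = 3`, group 1 persists to the last wave, group 2
#' drops out at the last wave, group 3 earlier. When administrative labels
#' are used, their cross-tabulation against the response-derived pattern is
#' attached (wave non-response versus attrition need not coincide).
#'
#' @param ds a [wide_dataset()].
#' @param mode `"auto"` (administrative when available), `"administrative"`
#'   or `"last-observed"`.
#' @param k 2 or 3 groups.
#' @return An object of class `dropout_grouping`: `group` (label per
#'   subject), `k`, `n_g`, `pi_g`, `N`, `mode`.
#' @export
assign_dropout_groups <- function(ds, mode = c("auto", "administrative",
                                               "last-observed"), k = 3) {
  mode <- match.arg(mode)
  stopifnot(k %in% c(2L, 3L))
  if (mode == "auto")
    mode <- if (!is.null(ds$dropout_group)) "administrative" else
      "last-observed"
  nt <- ncol(ds$y)
  obs <- !is.na(ds$y)
  last_obs <- apply(obs, 1L, function(r) max(which(r)))
  derived3 <- ifelse(last_obs == nt, 1L, ifelse(last_obs == 1L, 3L, 2L))

  if (mode == "administrative") {
    if (is.null(ds$dropout_group))
      stop("administrative mode needs the dropout_group column")
    g <- ds$dropout_group
    if (k == 2L) g <- ifelse(g == 1L, 1L, 2L)
  } else {
    g <- if (k == 3L) derived3
    else ifelse(rowSums(obs) == nt, 1L, 2L)
  }
  n_g <- vapply(seq_len(k), function(j) sum(g == j), integer(1))
  empty <- which(n_g == 0L)
  if (length(empty))
    stop("empty dropout subgroup: ", paste(empty, collapse = ", "))
  out <- structure(list(group = g, k = k, n_g = n_g,
                        pi_g = n_g / sum(n_g), N = sum(n_g), mode = mode),
                   class = "dropout_grouping")
  if (mode == "administrative")
    attr(out, "crosstab") <- table(administrative = ds$dropout_group,
                                   last_observed = last_obs)
  out
}

#' @export
print.dropout_grouping <- function(x, ...) {
  cat("dropout grouping (", x$mode, ", k = ", x$k, "): N = ", x$N, "\n",
      sep = "")
  print(data.frame(group = seq_len(x$k), n = x$n_g,
                   proportion = round(x$pi_g, 4)), row.names = FALSE)
  invisible(x)
}

# ---- shared multigroup machinery ------------------------------------------

# free parameters: per-group latent means + shared Psi/Theta; group 3's
# slope mean, when restricted, is substituted inside the likelihood
pm_parinfo <- function(spec, n_groups, restrict_g3 = FALSE,
                       shared_theta = TRUE) {
  nt <- length(spec$wave_times)
  nm <- character(0); lo <- numeric(0)
  for (g in seq_len(n_groups)) {
    nm <- c(nm, paste0("mu_I_", g))
    lo <- c(lo, -Inf)
    if (!(restrict_g3 && g == n_groups)) {
      nm <- c(nm, paste0("mu_S_", g))
      lo <- c(lo, -Inf)
    }
  }
  nm <- c(nm, "psi_II"); lo <- c(lo, 1e-8)
  if (spec$slope_var_free) { nm <- c(nm, "psi_SS"); lo <- c(lo, 1e-8) }
  if (spec$slope_var_free && spec$cov_IS_free) {
    nm <- c(nm, "psi_IS"); lo <- c(lo, -Inf)
  }
  theta_base <- if (spec$residual == "per-wave")
    paste0("theta_", seq_len(nt)) else "theta"
  if (shared_theta) {
    nm <- c(nm, theta_base); lo <- c(lo, rep(1e-8, length(theta_base)))
  } else {
    for (g in seq_len(n_groups)) {
      nm <- c(nm, paste0(theta_base, "_g", g))
      lo <- c(lo, rep(1e-8, length(theta_base)))
    }
  }
  list(names = nm, lower = stats::setNames(lo, nm), nt = nt,
       shared_theta = shared_theta)
}

# slope-mean weights (on mu_S_1, mu_S_2) implied by an identifying
# restriction for the wave-1-only subgroup
restriction_weights <- function(restriction, n_g) {
  switch(restriction,
         "complete-case" = c(1, 0),
         "neighbouring-case" = c(0, 1),
         "available-case" = n_g[1:2] / sum(n_g[1:2]),
         stop("unknown restriction: ", restriction))
}

pm_group_means <- function(par, spec, n_groups, restriction = NULL,
                           n_g = NULL) {
  lam <- spec$wave_times
  muI <- par[paste0("mu_I_", seq_len(n_groups))]
  muS <- numeric(n_groups)
  for (g in seq_len(n_groups)) {
    nmS <- paste0("mu_S_", g)
    muS[g] <- if (nmS %in% names(par)) par[[nmS]] else NA_real_
  }
  if (!is.null(restriction)) {
    w <- restriction_weights(restriction, n_g)
    muS[n_groups] <- w[1L] * muS[1L] + w[2L] * muS[2L]
  }
  list(mu_I = unname(muI), mu_S = muS)
}

# implied covariance for group g; `suffix` is "" under shared residual
# variances and "_g<g>" under the per-group option
pm_group_cov <- function(par, spec, suffix = "") {
  nt <- length(spec$wave_times)
  theta <- if (spec$residual == "per-wave")
    unname(par[paste0("theta_", seq_len(nt), suffix)])
  else rep(unname(par[paste0("theta", suffix)]), nt)
  implied_moments(list(
    mu_I = 0, mu_S = 0,
    psi_II = unname(par["psi_II"]),
    psi_SS = if (spec$slope_var_free) unname(par["psi_SS"]) else 0,
    psi_IS = if (spec$slope_var_free && spec$cov_IS_free)
      unname(par["psi_IS"]) else 0,
    theta = theta), spec)$cov
}

make_pm_objfn <- function(y, group, spec, n_groups, restriction = NULL,
                          n_g = NULL, shared_theta = TRUE) {
  lam <- spec$wave_times
  ggroups <- lapply(seq_len(n_groups), function(g)
    pattern_groups(y[group == g, , drop = FALSE]))
  function(par) {
    mg <- pm_group_means(par, spec, n_groups, restriction, n_g)
    cv <- if (shared_theta) pm_group_cov(par, spec)
    ll <- 0
    for (g in seq_len(n_groups)) {
      if (!shared_theta) cv <- pm_group_cov(par, spec, paste0("_g", g))
      mu_g <- mg$mu_I[g] + lam * mg$mu_S[g]
      for (pg in ggroups[[g]]) {
        l <- mvn_ll_rows(pg$Y, mu_g[pg$o], cv[pg$o, pg$o, drop = FALSE])
        if (is.na(l)) return(1e10)
        ll <- ll + l
      }
    }
    -ll
  }
}

pm_start <- function(ds, spec, grouping, info, restrict_g3, base = NULL) {
  base <- base %||% lgm_optimize(ds$y, spec, "start", compute_se = FALSE,
                                 restarts = 1)
  st <- stats::setNames(numeric(length(info$names)), info$names)
  for (nm in info$names) {
    if (grepl("^mu_I_", nm)) st[nm] <- base$estimate["mu_I"]
    else if (grepl("^mu_S_", nm)) st[nm] <- base$estimate["mu_S"]
    else if (grepl("^theta", nm))
      st[nm] <- base$estimate[sub("_g[0-9]+$", "", nm)]
    else st[nm] <- base$estimate[nm]
  }
  st
}

# multinomial covariance of estimated subgroup proportions
multinomial_weight_cov <- function(pi_g, N) {
  (diag(pi_g, length(pi_g)) - pi_g %o% pi_g) / N
}

pm_fit_engine <- function(ds, grouping, spec, n_groups, restriction,
                          technique, compute_se = TRUE, start = NULL,
                          restarts = 3, shared_theta = TRUE) {
  restrict_g3 <- !is.null(restriction)
  if (!shared_theta) {
    obs <- !is.na(ds$y)
    for (g in seq_len(n_groups)) {
      if (any(colSums(obs[grouping$group == g, , drop = FALSE]) < 2L))
        stop("per-group residual variances need every group observed at ",
             "every wave; group ", g, " is not")
    }
  }
  info <- pm_parinfo(spec, n_groups, restrict_g3, shared_theta)
  obj <- make_pm_objfn(ds$y, grouping$group, spec, n_groups, restriction,
                       grouping$n_g, shared_theta)
  st <- pm_start(ds, spec, grouping, info, restrict_g3, base = start)
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
  if (compute_se) {
    H <- fd_hessian(obj, est)
    V <- solve_vcov(H)
  } else {
    V <- matrix(NA_real_, length(est), length(est))
  }
  dimnames(V) <- list(info$names, info$names)

  pi_g <- grouping$pi_g
  N <- grouping$N
  mg <- pm_group_means(est, spec, n_groups, restriction, grouping$n_g)

  # linear maps from the free parameters to the group-level and pooled means
  cvec <- function(coefs) {
    v <- stats::setNames(numeric(length(info$names)), info$names)
    v[names(coefs)] <- coefs
    v
  }
  wI <- cvec(stats::setNames(pi_g, paste0("mu_I_", seq_len(n_groups))))
  if (restrict_g3) {
    w <- restriction_weights(restriction, grouping$n_g)
    sl <- stats::setNames(pi_g[-n_groups], paste0("mu_S_",
                                                  seq_len(n_groups - 1L)))
    sl["mu_S_1"] <- sl["mu_S_1"] + pi_g[n_groups] * w[1L]
    sl["mu_S_2"] <- sl["mu_S_2"] + pi_g[n_groups] * w[2L]
    wS <- cvec(sl)
  } else {
    wS <- cvec(stats::setNames(pi_g, paste0("mu_S_", seq_len(n_groups))))
  }
  Cw <- multinomial_weight_cov(pi_g, N)
  pool_one <- function(wvec, theta_g) {
    estv <- sum(wvec * est)
    v_est <- if (compute_se) drop(t(wvec) %*% V %*% wvec) else NA_real_
    v_w <- drop(t(theta_g) %*% Cw %*% theta_g)
    c(estimate = estv, se = sqrt(v_est + v_w), se_fixed = sqrt(v_est))
  }
  pI <- pool_one(wI, mg$mu_I)
  pS <- pool_one(wS, mg$mu_S)

  shared_nm <- setdiff(info$names,
                       grep("^mu_[IS]_", info$names, value = TRUE))
  pooled <- data.frame(
    parameter = c("mu_I", "mu_S", shared_nm),
    estimate = c(pI["estimate"], pS["estimate"], unname(est[shared_nm])),
    se = c(pI["se"], pS["se"], sqrt(pmax(diag(V)[shared_nm], 0))),
    se_fixed_weights = c(pI["se_fixed"], pS["se_fixed"],
                         sqrt(pmax(diag(V)[shared_nm], 0))),
    row.names = NULL)
  pooled$z <- pooled$estimate / pooled$se
  pooled$p <- 2 * stats::pnorm(-abs(pooled$z))

  # per-group slope-mean SEs (delta method through the restriction map)
  gse <- vapply(seq_len(n_groups), function(g) {
    if (!compute_se) return(NA_real_)
    if (restrict_g3 && g == n_groups) {
      w <- restriction_weights(restriction, grouping$n_g)
      cv <- cvec(c(mu_S_1 = w[1L], mu_S_2 = w[2L]))
      sqrt(drop(t(cv) %*% V %*% cv))
    } else sqrt(max(diag(V)[paste0("mu_S_", g)], 0))
  }, numeric(1))
  group_estimates <- data.frame(
    group = seq_len(n_groups), n = grouping$n_g, pi = pi_g,
    mu_I = mg$mu_I, se_mu_I = sqrt(pmax(
      diag(V)[paste0("mu_I_", seq_len(n_groups))], 0)),
    mu_S = mg$mu_S, se_mu_S = gse, row.names = NULL)

  structure(list(technique = technique,
                 restriction = restriction %||% NA_character_,
                 group_estimates = group_estimates,
                 pooled = pooled,
                 estimate = stats::setNames(pooled$estimate,
                                            pooled$parameter),
                 se = stats::setNames(pooled$se, pooled$parameter),
                 z = stats::setNames(pooled$z, pooled$parameter),
                 p = stats::setNames(pooled$p, pooled$parameter),
                 weights = pi_g,
                 free_estimates = est, vcov = V,
                 loglik = -best$objective,
                 n_used = N,
                 converged = best$convergence == 0 ||
                   grepl("singular convergence", best$message %||% ""),
                 spec = spec),
            class = "pm_fit")
}

#' @export
print.pm_fit <- function(x, ...) {
  cat(sprintf("pattern-mixture growth model [%s]%s, N = %d, loglik = %.3f%s\n",
              x$technique,
              if (!is.na(x$restriction))
                paste0(" (", x$restriction, " restriction)") else "",
              x$n_used, x$loglik,
              if (!x$converged) "  (NOT converged)" else ""))
  cat("per-group estimates:\n")
  print(cbind(x$group_estimates[, c("group", "n", "pi")],
              mu_I = fmt_num(x$group_estimates$mu_I),
              mu_S = fmt_num(x$group_estimates$mu_S)), row.names = FALSE)
  cat("pooled (proportion-weighted):\n")
  print(data.frame(parameter = x$pooled$parameter,
                   estimate = fmt_num(x$pooled$estimate),
                   se = fmt_num(x$pooled$se),
                   stars = stars_for_p(x$pooled$p)), row.names = FALSE)
  invisible(x)
}

#' Two-group shared-variance pattern-mixture model
#'
#' Multigroup FIML with group-specific latent means (completers versus
#' non-completers) and latent (co)variances and residual variances
#' constrained equal across groups, so the completers identify the variance
#' structure the incomplete group cannot. Pooled means are the
#' proportion-weighted averages of the group means, with delta-method
#' standard errors that include the multinomial variability of the group
#' proportions (a fixed-weights SE is also reported).
#'
#' @param ds a [wide_dataset()].
#' @param grouping a `k = 2` [assign_dropout_groups()] result.
#' @param spec a [growth_spec()].
#' @param compute_se compute observed-information standard errors
#'   (default `TRUE`).
#' @param start optional single-group `lgm_fit` used as a warm start.
#' @param restarts number of deterministic jittered restarts (default 3).
#' @param shared_theta share the residual variances across groups (default
#'   `TRUE`, the identifying "borrowing" convention); the per-group option
#'   requires every group to be observed at every wave.
#' @return An object of class `pm_fit` with technique label `"H&G"`.
#' @export
fit_two_group_pm <- function(ds, grouping, spec, compute_se = TRUE,
                             start = NULL, restarts = 3,
                             shared_theta = TRUE) {
  stopifnot(inherits(grouping, "dropout_grouping"))
  if (grouping$k != 2L) stop("the two-group model needs a k = 2 grouping")
  obs <- !is.na(ds$y)
  if (any(colSums(obs[grouping$group == 1L, , drop = FALSE]) < 2L))
    stop("group 1 must provide data at every wave ",
         "(it identifies the shared variance structure)")
  if (sum(rowSums(obs[grouping$group == 2L, , drop = FALSE]) >= 2L) < 2L)
    stop("incomplete-group data are insufficient to estimate its slope mean")
  pm_fit_engine(ds, grouping, spec, n_groups = 2L, restriction = NULL,
                technique = "H&G", compute_se = compute_se, start = start,
                restarts = restarts, shared_theta = shared_theta)
}

#' Identifying-restriction pattern-mixture models
#'
#' Multigroup FIML over three dropout subgroups with shared variance
#' structure. The earliest-dropout subgroup observes wave 1 only, so its
#' slope mean is inestimable; it is substituted inside the likelihood by the
#' identifying restriction (exact reparameterisation, not a penalty):
#' complete-case borrows subgroup 1's slope mean, neighbouring-case borrows
#' subgroup 2's, and available-case uses the case-weighted average
#' `(n1 mu_S1 + n2 mu_S2) / (n1 + n2)`. The complete-case restriction only
#' runs behind an explicit opt-in, since borrowing the completers' trend for
#' the earliest dropouts is usually the least defensible choice when
#' dropout is suspected to be outcome-related.
#'
#' @param ds a [wide_dataset()].
#' @param grouping a `k = 3` [assign_dropout_groups()] result.
#' @param spec a [growth_spec()].
#' @param restriction `"neighbouring-case"`, `"available-case"` or
#'   `"complete-case"`.
#' @param allow_complete_case opt-in flag for the complete-case restriction.
#' @param compute_se compute observed-information standard errors
#'   (default `TRUE`).
#' @param start optional single-group `lgm_fit` used as a warm start.
#' @param restarts number of deterministic jittered restarts (default 3).
#' @param shared_theta share the residual variances across groups (default
#'   `TRUE`); the per-group option requires every group observed at every
#'   wave, which the wave-1-only subgroup never satisfies.
#' @return An object of class `pm_fit`, technique `"Neighbouring"`,
#'   `"Available"` or `"Complete"`.
#' @export
fit_restriction_pm <- function(ds, grouping, spec,
                               restriction = c("neighbouring-case",
                                               "available-case",
                                               "complete-case"),
                               allow_complete_case = FALSE,
                               compute_se = TRUE, start = NULL,
                               restarts = 3, shared_theta = TRUE) {
  restriction <- match.arg(restriction)
  stopifnot(inherits(grouping, "dropout_grouping"))
  if (grouping$k != 3L) stop("restriction models need a k = 3 grouping")
  if (restriction == "complete-case" && !allow_complete_case)
    stop("the complete-case restriction runs only with ",
         "allow_complete_case = TRUE")
  obs <- !is.na(ds$y)
  if (any(colSums(obs[grouping$group == 1L, , drop = FALSE]) < 2L))
    stop("group 1 must provide data at every wave")
  if (sum(rowSums(obs[grouping$group == 2L, , drop = FALSE]) >= 2L) < 2L)
    stop("subgroup 2 provides too little data to estimate its slope mean")
  technique <- c("complete-case" = "Complete",
                 "neighbouring-case" = "Neighbouring",
                 "available-case" = "Available")[[restriction]]
  pm_fit_engine(ds, grouping, spec, n_groups = 3L, restriction = restriction,
                technique = technique, compute_se = compute_se,
                start = start, restarts = restarts,
                shared_theta = shared_theta)
}

#' Pool per-group estimates by subgroup proportions
#'
#' Pooled estimate `sum_g pi_g theta_g` with variance
#' `sum_g pi_g^2 V_g + sum_g sum_h theta_g theta_h C_gh`, where `C` is the
#' multinomial covariance of the estimated proportions
#' (`C_gg = pi_g (1 - pi_g) / N`, `C_gh = -pi_g pi_h / N`) and cross-group
#' estimate covariance is taken as zero (independent samples). With
#' `fixed_weights = TRUE` the multinomial term is dropped.
#'
#' @param estimates per-group parameter estimates `theta_g`.
#' @param weights subgroup proportions `pi_g` (must sum to 1 within 1e-12).
#' @param N total sample size behind the proportions.
#' @param variances per-group estimate variances `V_g` (default 0).
#' @param fixed_weights treat the proportions as known constants.
#' @return List with `estimate` and `se`.
#' @export
pool_pattern_mixture <- function(estimates, weights, N, variances = NULL,
                                 fixed_weights = FALSE) {
  if (abs(sum(weights) - 1) > 1e-12)
    stop("weights must sum to 1 (within 1e-12)")
  if (length(estimates) != length(weights))
    stop("estimates and weights differ in length")
  V <- variances %||% rep(0, length(estimates))
  est <- sum(weights * estimates)
  v <- sum(weights^2 * V)
  if (!fixed_weights) {
    Cw <- multinomial_weight_cov(weights, N)
    v <- v + drop(t(estimates) %*% Cw %*% estimates)
  }
  list(estimate = est, se = sqrt(v))
}
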