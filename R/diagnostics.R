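#' ML estimation of an unstructured multivariate normal with missing data
#'
#' EM algorithm for the mean vector and covariance matrix of a multivariate
#' normal from incomplete rows, valid under MAR. Rows are grouped by
#' missingness pattern; the E-step fills in conditional moments per pattern,
#' the M-step updates the moments with ML divisor `n`. Starts from
#' complete-case moments (available-case moments when too few complete
#' rows); the observed-data log-likelihood trace is retained and is
#' non-decreasing.
#'
#' @param x a [wide_dataset()] or a numeric matrix with `NA` for missing;
#'   every row must have at least one observed value.
#' @param tol relative log-likelihood convergence threshold.
#' @param max_iter iteration cap; non-convergence is flagged, never silent.
#' @return An object of class `mvn_em`: `mu`, `sigma`, `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, `n`.
#' @export
em_mvn <- function(x, tol = 1e-10, max_iter = 5000) {
  y <- if (inherits(x, "wide_dataset")) x$y else as.matrix(x)
  storage.mode(y) <- "double"
  n <- nrow(y); p <- ncol(y)
  obs <- !is.na(y)
  if (any(rowSums(obs) == 0L))
    stop("rows with no observed value cannot contribute")
  groups <- pattern_groups(y)

  cc <- rowSums(obs) == p
  if (sum(cc) > p) {
    mu <- colMeans(y[cc, , drop = FALSE])
    S <- stats::cov(y[cc, , drop = FALSE]) * (sum(cc) - 1) / sum(cc)
  } else {
    mu <- colMeans(y, na.rm = TRUE)
    S <- stats::cov(y, use = "pairwise.complete.obs")
    S[is.na(S)] <- 0
  }
  # guard the start against a (near-)singular covariance
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(abs(ev), 1))
    S <- S + diag(max(abs(ev), 1) * 1e-6, p)

  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    ll <- 0
    for (g in groups) {
      o <- g$o
      m <- setdiff(seq_len(p), o)
      Soo <- S[o, o, drop = FALSE]
      R <- tryCatch(chol(Soo), error = function(e) NULL)
      if (is.null(R))
        stop("singular within-pattern covariance for pattern ",
             paste(as.integer(seq_len(p) %in% o), collapse = ""))
      ctr <- g$Y - rep(mu[o], each = g$n)
      v <- backsolve(R, t(ctr), transpose = TRUE)
      ll <- ll - 0.5 * sum(v * v) -
        g$n * (0.5 * length(o) * log(2 * pi) + sum(log(diag(R))))
      if (length(m) == 0L) {
        T1 <- T1 + colSums(g$Y)
        T2 <- T2 + crossprod(g$Y)
      } else {
        Sooinv <- chol2inv(R)
        B <- S[m, o, drop = FALSE] %*% Sooinv
        Em <- rep(mu[m], each = g$n) + ctr %*% t(B)
        Cmm <- S[m, m, drop = FALSE] - B %*% S[o, m, drop = FALSE]
        full <- matrix(0, g$n, p)
        full[, o] <- g$Y
        full[, m] <- Em
        T1 <- T1 + colSums(full)
        T2 <- T2 + crossprod(full)
        T2[m, m] <- T2[m, m] + g$n * Cmm
      }
    }
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + tol)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
    mu_new <- T1 / n
    S_new <- T2 / n - tcrossprod(mu_new)
    S <- (S_new + t(S_new)) / 2
    mu <- mu_new
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations", call. = FALSE)
  structure(list(mu = stats::setNames(mu, colnames(y)), sigma = S,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 n_iter = iter, converged = converged, n = n),
            class = "mvn_em")
}

#' @export
print.mvn_em <- function(x, ...) {
  cat("EM estimates of an incomplete multivariate normal (n =", x$n, ")\n")
  cat("loglik", fmt_num(x$loglik, 3), "after", x$n_iter, "iterations",
      if (!x$converged) "(NOT converged)", "\n")
  cat("mu:", paste(fmt_num(x$mu), collapse = ", "), "\n")
  invisible(x)
}

#' Little's MCAR test
#'
#' Compares each missingness pattern's observed means against the EM grand
#' means, scaled by the corresponding block of the EM covariance:
#' `chi2 = sum_j n_j (ybar_j - mu_obs(j))' Sigma_obs(j)^{-1}
#' (ybar_j - mu_obs(j))`, with `df = sum_j p_j - p` over the patterns and a
#' chi-square upper-tail p-value. A significant result rejects MCAR; a
#' non-significant one does not establish it. On complete data the test is
#' degenerate (`chi2 = 0`, `df = 0`) and `p` is reported as 1.
#'
#' @param ds a [wide_dataset()] or numeric matrix.
#' @param em optional precomputed [em_mvn()] fit.
#' @return An object of class `little_test`: `chi2`, `df`, `p`,
#'   `contributions` (per-pattern data frame), `n_patterns`.
#' @export
little_mcar_test <- function(ds, em = NULL) {
  y <- if (inherits(ds, "wide_dataset")) ds$y else as.matrix(ds)
  p <- ncol(y)
  em <- em %||% em_mvn(y)
  if (!em$converged)
    warning("EM had not converged; test statistic may be inaccurate")
  groups <- pattern_groups(y)
  chi2 <- 0
  rows <- lapply(groups, function(g) {
    o <- g$o
    d <- colMeans(g$Y) - em$mu[o]
    Soo <- em$sigma[o, o, drop = FALSE]
    Sinv <- tryCatch(chol2inv(chol(Soo)), error = function(e) {
      warning("singular covariance sub-matrix for pattern ",
              paste(as.integer(seq_len(p) %in% o), collapse = ""),
              "; using a pseudo-inverse", call. = FALSE)
      MASS::ginv(Soo)
    })
    contrib <- g$n * drop(t(d) %*% Sinv %*% d)
    data.frame(pattern = paste(as.integer(seq_len(p) %in% o), collapse = ""),
               count = g$n, n_observed = length(o), contribution = contrib)
  })
  contributions <- do.call(rbind, rows)
  rownames(contributions) <- NULL
  chi2 <- sum(contributions$contribution)
  df <- sum(contributions$n_observed) - p
  pval <- if (df == 0L) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p = pval,
                 contributions = contributions,
                 n_patterns = nrow(contributions)),
            class = "little_test")
}

#' @export
print.little_test <- function(x, ...) {
  cat(sprintf("Little's MCAR test: Chi2 = %.3f, df = %d, p = %.3f\n",
              x$chi2, x$df, x$p))
  cat("(", x$n_patterns, "missingness patterns )\n")
  invisible(x)
}

#' One-way ANOVA of a wave's scores across dropout groups
#'
#' Compares subjects observed at the given wave across dropout groups, with
#' Tukey HSD pairwise follow-up. Groups with fewer than two observed values
#' are excluded with a warning.
#'
#' @param ds a [wide_dataset()].
#' @param wave wave index.
#' @param groups group labels per subject; defaults to `ds$dropout_group`.
#' @return An object of class `dropout_anova`: `F`, `df` (numerator,
#'   denominator), `p`, `group_stats`, `pairwise` (Tukey HSD table), `wave`.
#' @export
dropout_group_anova <- function(ds, wave, groups = NULL) {
  g <- groups %||% ds$dropout_group
  if (is.null(g)) stop("no dropout-group labels available")
  yv <- ds$y[, wave]
  keep <- !is.na(yv) & !is.na(g)
  yv <- yv[keep]; g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("group(s) with fewer than two observed values excluded: ",
            paste(small, collapse = ", "))
    keep2 <- !(g %in% as.integer(small))
    yv <- yv[keep2]; g <- g[keep2]
  }
  if (length(unique(g)) < 2L) stop("need at least two groups with data")
  fg <- factor(g)
  fit <- stats::aov(yv ~ fg)
  tab <- summary(fit)[[1L]]
  gs <- data.frame(group = levels(fg),
                   n = as.integer(table(fg)),
                   mean = tapply(yv, fg, mean),
                   sd = tapply(yv, fg, stats::sd))
  rownames(gs) <- NULL
  structure(list(F = tab[1L, "F value"],
                 df = c(tab[1L, "Df"], tab[2L, "Df"]),
                 p = tab[1L, "Pr(>F)"],
                 group_stats = gs,
                 pairwise = stats::TukeyHSD(fit)$fg,
                 wave = wave),
            class = "dropout_anova")
}

#' @export
print.dropout_anova <- function(x, ...) {
  cat(sprintf("wave %d: F(%d,%d) = %.3f, p = %.4g\n",
              x$wave, x$df[1L], x$df[2L], x$F, x$p))
  print(x$group_stats, row.names = FALSE)
  invisible(x)
}

#' Screen auxiliary variables
#'
#' For each wave, assesses how useful the auxiliary variables would be for
#' the missing-data model: (i) a logistic regression of the wave's
#' missingness indicator on all auxiliaries, summarised by Nagelkerke's
#' pseudo-R-squared `[1 - exp((2/n)(LL0 - LL1))] / [1 - exp((2/n) LL0)]`;
#' (ii) a linear regression of the observed outcome on the auxiliaries
#' (R-squared); (iii) the count of auxiliaries correlated at `|r| >= 0.10`
#' with the outcome. Rows with missing auxiliaries are dropped within the
#' screen (count reported). Perfect separation in a logistic fit is flagged
#' and its R-squared treated as an upper limit.
#'
#' @param ds a [wide_dataset()] with auxiliaries.
#' @param aux_columns auxiliary column names (default: all).
#' @return An object of class `aux_screen`: data frame with one row per wave
#'   (`wave`, `r2_missingness`, `separation`, `r2_outcome`, `n_cor_10`),
#'   with the number of screened subjects in attribute `n_used`.
#' @export
screen_auxiliaries <- function(ds, aux_columns = NULL) {
  if (is.null(ds$aux)) stop("dataset has no auxiliary variables")
  A <- ds$aux[, aux_columns %||% names(ds$aux), drop = FALSE]
  used <- which(stats::complete.cases(A))
  X <- stats::model.matrix(~ ., A[used, , drop = FALSE])[, -1L, drop = FALSE]
  n <- length(used)
  nt <- ncol(ds$y)
  rows <- lapply(seq_len(nt), function(t) {
    miss <- as.integer(is.na(ds$y[used, t]))
    if (length(unique(miss)) < 2L) {
      r2n <- NA_real_; sep <- FALSE
    } else {
      f1 <- suppressWarnings(stats::glm(miss ~ X, family = stats::binomial()))
      f0 <- stats::glm(miss ~ 1, family = stats::binomial())
      ll1 <- as.numeric(stats::logLik(f1))
      ll0 <- as.numeric(stats::logLik(f0))
      r2n <- (1 - exp((2 / n) * (ll0 - ll1))) /
             (1 - exp((2 / n) * ll0))
      sep <- any(f1$fitted.values < 1e-8 | f1$fitted.values > 1 - 1e-8)
      if (sep)
        warning("possible separation in the missingness model for wave ", t,
                "; Nagelkerke R2 is an upper limit", call. = FALSE)
    }
    yobs <- ds$y[used, t]
    ok <- !is.na(yobs)
    r2o <- if (sum(ok) > ncol(X) + 1L)
      suppressWarnings(
        summary(stats::lm(yobs[ok] ~ X[ok, , drop = FALSE]))$r.squared)
    else NA_real_
    cors <- suppressWarnings(
      apply(X[ok, , drop = FALSE], 2L, stats::cor, y = yobs[ok]))
    data.frame(wave = t, r2_missingness = r2n, separation = sep,
               r2_outcome = r2o,
               n_cor_10 = sum(abs(cors) >= 0.10, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_used") <- n
  attr(out, "n_dropped_aux") <- nrow(ds$y) - n
  class(out) <- c("aux_screen", "data.frame")
  out
}

#' @export
print.aux_screen <- function(x, ...) {
  cat("auxiliary-variable screen (n =", attr(x, "n_used"), "subjects)\n")
  df <- data.frame(wave = x$wave,
                   `Nagelkerke R2 (%)` = fmt_num(100 * x$r2_missingness, 1),
                   `outcome R2 (%)` = fmt_num(100 * x$r2_outcome, 1),
                   `#|r|>=.10` = x$n_cor_10,
                   check.names = FALSE)
  print(df, row.names = FALSE)
  if (any(x$separation)) cat("note: separation flagged for wave(s) ",
                             paste(x$wave[x$separation], collapse = ", "), "\n")
  invisible(x)
}

#' Per-wave t-test screen for MCAR
#'
#' For each (outcome wave, indicator wave) pair, a Welch two-sample t-test
#' compares the outcome between subjects missing versus observed at the
#' indicator wave. Reported as a descriptive screen; MCAR gating relies on
#' [little_mcar_test()].
#'
#' @param ds a [wide_dataset()].
#' @return Data frame `outcome_wave`, `indicator_wave`, `n_observed`,
#'   `n_missing`, `t`, `df`, `p` (`NA` when a group is smaller than 2).
#' @export
mcar_t_tests <- function(ds) {
  nt <- ncol(ds$y)
  out <- list()
  for (t in seq_len(nt)) for (s in seq_len(nt)) {
    if (s == t) next
    yv <- ds$y[, t]
    ind <- is.na(ds$y[, s])
    ok <- !is.na(yv)
    a <- yv[ok & ind]; b <- yv[ok & !ind]
    if (length(a) >= 2L && length(b) >= 2L) {
      tt <- stats::t.test(a, b)
      row <- data.frame(outcome_wave = t, indicator_wave = s,
                        n_observed = length(b), n_missing = length(a),
                        t = unname(tt$statistic), df = unname(tt$parameter),
                        p = tt$p.value)
    } else {
      row <- data.frame(outcome_wave = t, indicator_wave = s,
                        n_observed = length(b), n_missing = length(a),
                        t = NA_real_, df = NA_real_, p = NA_real_)
    }
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}
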