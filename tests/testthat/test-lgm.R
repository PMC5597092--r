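spec3 <- growth_spec(LAM3)

test_that("implied moments: degenerate cases and a hand-expanded fixture", {
  m0 <- implied_moments(list(mu_I = 3, mu_S = -0.1, psi_II = 0, psi_SS = 0,
                             psi_IS = 0, theta = 0), spec3)
  expect_equal(m0$mean, c(3, 2.883, 2.783))
  expect_true(all(m0$cov == 0))

  m1 <- implied_moments(list(mu_I = 0, mu_S = 0, psi_II = 1, psi_SS = 0,
                             psi_IS = 0, theta = 0), spec3)
  expect_equal(m1$cov, matrix(1, 3, 3))

  # element-by-element symbolic expansion
  pI <- 0.4; pS <- 0.05; pIS <- -0.02; th <- c(0.3, 0.25, 0.2)
  m2 <- implied_moments(list(mu_I = 3, mu_S = -0.1, psi_II = pI,
                             psi_SS = pS, psi_IS = pIS, theta = th), spec3)
  hand <- rbind(
    c(pI + th[1],
      pI + 1.17 * pIS,
      pI + 2.17 * pIS),
    c(pI + 1.17 * pIS,
      pI + 1.17^2 * pS + 2 * 1.17 * pIS + th[2],
      pI + 1.17 * 2.17 * pS + (1.17 + 2.17) * pIS),
    c(pI + 2.17 * pIS,
      pI + 1.17 * 2.17 * pS + (1.17 + 2.17) * pIS,
      pI + 2.17^2 * pS + 2 * 2.17 * pIS + th[3]))
  expect_equal(m2$cov, hand, tolerance = 1e-12)
})

test_that("FIML log-likelihood equals the brute-force marginalised oracle", {
  set.seed(51)
  y <- matrix(rnorm(45, 3, 0.8), 15, 3)
  y[1:3, 3] <- NA
  y[4:5, 2:3] <- NA
  y[6, c(1, 3)] <- NA   # observed at wave 2 only
  y[7, 2] <- NA         # observed at waves 1 and 3
  params <- list(mu_I = 3.1, mu_S = -0.07, psi_II = 0.35, psi_SS = 0.04,
                 psi_IS = -0.015, theta = c(0.3, 0.28, 0.26))
  expect_lt(abs(fiml_loglik(params, spec3, y) -
                  brute_fiml(y, params, spec3)), 1e-10)

  # complete data: plain sum of trivariate normal log-densities
  yc <- y[8:15, ]
  expect_lt(abs(fiml_loglik(params, spec3, yc) -
                  brute_fiml(yc, params, spec3)), 1e-10)

  # rows with no observed wave are rejected upstream
  ybad <- rbind(y, NA)
  expect_error(fiml_loglik(params, spec3, ybad), "excluded upstream")
})

test_that("listwise and FIML coincide on complete data", {
  sim <- simulate_growth(300, LAM3,
                         growth_params(3, -0.1, 0.4, 0.02, 0, 0.3), seed = 5)
  ld <- fit_lgm_listwise(sim$data, spec3)
  ml <- fit_lgm_fiml(sim$data, spec3)
  expect_lt(max(abs(ld$estimate - ml$estimate)), 1e-6)
  expect_lt(abs(ld$loglik - ml$loglik), 1e-6)
  expect_equal(ld$n_used, 300L)
  # and FIML restricted to the complete-case subset equals listwise
  g <- study_ds(1, "MAR")
  cc <- rowSums(is.na(g$data$y)) == 0L
  ds_cc <- wide_dataset(g$data$y[cc, ], LAM3)
  ld2 <- fit_lgm_listwise(g$data, spec3)
  ml2 <- fit_lgm_fiml(ds_cc, spec3)
  expect_lt(max(abs(ld2$estimate - ml2$estimate)), 1e-6)
})

test_that("zero-residual deterministic data is recovered exactly", {
  sim <- simulate_growth(30, LAM3, growth_params(3, -0.1, 0, 0, 0, 0),
                         seed = 6)
  fit <- fit_lgm_listwise(sim$data, spec3, compute_se = FALSE)
  expect_lt(abs(fit$estimate[["mu_I"]] - 3), 1e-4)
  expect_lt(abs(fit$estimate[["mu_S"]] + 0.1), 1e-4)
  expect_lt(fit$estimate[["psi_II"]], 1e-4)
  expect_lt(fit$estimate[["psi_SS"]], 1e-4)
})

test_that("standard errors shrink roughly as 1/sqrt(n)", {
  p <- growth_params(3.2, -0.06, 0.4, 0.02, -0.01, 0.3)
  f1 <- fit_lgm_fiml(simulate_growth(400, LAM3, p, seed = 61)$data, spec3)
  f4 <- fit_lgm_fiml(simulate_growth(1600, LAM3, p, seed = 62)$data, spec3)
  ratio <- f1$se[["mu_I"]] / f4$se[["mu_I"]]
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("under MAR dropout favouring high scorers, listwise deletion
           overestimates the mean intercept", {
  p <- growth_params(3.28, -0.06, 0.41, 0.02, -0.01, 0.30)
  sim <- simulate_growth(4000, LAM3, p, seed = 71)
  sc <- missingness_scenario("MAR", form = "monotone",
                             dropout_rate = c(0, 0.45, 0.45),
                             dropout_coef = -1.5)
  ds <- impose_missingness(sim, sc, seed = 72)$data
  ld <- fit_lgm_listwise(ds, spec3, compute_se = FALSE)
  ml <- fit_lgm_fiml(ds, spec3, compute_se = FALSE)
  expect_gt(ld$estimate[["mu_I"]], ml$estimate[["mu_I"]] + 0.02)
  expect_lt(abs(ml$estimate[["mu_I"]] - 3.28),
            abs(ld$estimate[["mu_I"]] - 3.28))
  expect_lt(ld$estimate[["psi_II"]], 0.41)
})

test_that("saturated-correlates FIML runs, rejects constants, and codes
           factors", {
  sim <- simulate_growth(500, LAM3,
                         growth_params(3, -0.08, 0.4, 0.02, 0, 0.3),
                         seed = 81, aux_cor = c(gpa = 0.4))
  sc <- missingness_scenario("MAR", dropout_rate = c(0, 0.4, 0.35),
                             dropout_coef = 1.2, aux_name = "gpa",
                             intermittent_rate = c(0, 0.1, 0.1))
  ds <- impose_missingness(sim, sc, seed = 82)$data
  fit <- fit_lgm_fiml_aux(ds, spec3)
  expect_true(fit$converged)
  expect_equal(fit$technique, "MLaux")
  expect_true(all(c("mu_I", "mu_S", "nu_gpa", "phi_1_1") %in%
                    names(fit$estimate)))
  expect_true(all(is.finite(fit$se[c("mu_I", "mu_S")])))

  ds$aux$const <- 1
  expect_error(fit_lgm_fiml_aux(ds, spec3, aux = "const"),
               "constant auxiliary")
  ds$aux$const <- NULL
  ds$aux$track <- factor(rep(c("a", "b", "c"), length.out = nrow(ds$y)))
  A <- growthsens:::build_aux_matrix(ds)
  expect_true(all(c("track_b", "track_c") %in% colnames(A)))
})

test_that("homogeneous-residual FIML agrees with an independent
           mixed-model fit", {
  spec_h <- growth_spec(LAM3, residual = "homogeneous")
  sim <- simulate_growth(500, LAM3,
                         growth_params(3, -0.1, 0.4, 0.05, -0.02, 0.3),
                         seed = 9)
  sc <- missingness_scenario("MCAR", dropout_rate = 0.3,
                             intermittent_rate = c(0, 0.1, 0.1))
  ds <- impose_missingness(sim, sc, seed = 10)$data
  fh <- fit_lgm_fiml(ds, spec_h)

  suppressMessages(library(lme4))
  long <- data.frame(id = rep(seq_len(500), 3),
                     t = rep(LAM3, each = 500),
                     y = as.vector(ds$y))
  long <- long[!is.na(long$y), ]
  lmm <- lmer(y ~ t + (t | id), data = long, REML = FALSE)
  expect_lt(abs(fh$loglik - as.numeric(logLik(lmm))), 1e-3)
  expect_lt(abs(fh$estimate[["mu_I"]] - fixef(lmm)[[1]]), 1e-3)
  expect_lt(abs(fh$estimate[["mu_S"]] - fixef(lmm)[[2]]), 1e-3)
  vc <- VarCorr(lmm)$id
  expect_lt(abs(fh$estimate[["psi_II"]] - vc[1, 1]), 1e-3)
  expect_lt(abs(fh$estimate[["theta"]] - sigma(lmm)^2), 1e-3)
})

test_that("Wald summary: z, p, stars with strict thresholds, and CIs", {
  fake <- structure(list(estimate = c(a = 1, b = 0),
                         se = c(a = 0.5, b = 0.5),
                         z = c(a = 2, b = 0),
                         p = c(a = 2 * pnorm(-2), b = 1)),
                    class = "lgm_fit")
  w <- wald_summary(fake)
  expect_equal(w$z[1], 2)
  expect_equal(w$p[1], 0.0455, tolerance = 1e-3)
  expect_equal(w$stars, c("*", ""))
  expect_equal(w$ci_low[1], 1 - qnorm(0.975) * 0.5)

  # boundary p-values: strict inequalities
  fake2 <- structure(list(estimate = c(a = 1, b = 1, c = 1, d = 1, e = 1,
                                       f = 1),
                          se = rep(1, 6), z = rep(1, 6),
                          p = c(0.05, 0.049, 0.01, 0.009, 0.001, 0.0009)),
                     class = "lgm_fit")
  expect_equal(wald_summary(fake2)$stars,
               c("", "*", "*", "**", "**", "***"))
})
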