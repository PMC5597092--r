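spec3 <- growth_spec(LAM3)

test_that("dropout grouping: response-pattern fallback, administrative
           proportions, empty groups", {
  y <- rbind(c(1, 2, 3), c(1, 2, NA), c(1, NA, NA), c(2, 3, 4),
             c(2, NA, 3))
  ds <- wide_dataset(y, c(0, 1, 2))
  gr <- assign_dropout_groups(ds, mode = "last-observed", k = 3)
  expect_equal(gr$group, c(1L, 2L, 3L, 1L, 1L))
  gr2 <- assign_dropout_groups(ds, mode = "last-observed", k = 2)
  expect_equal(gr2$group, c(1L, 2L, 2L, 1L, 2L))

  # printed subgroup sizes give these proportions to 4 decimals
  n_g <- c(395L, 184L, 493L)
  dsa <- wide_dataset(matrix(rnorm(2 * 1072), 1072, 2), c(0, 1),
                      dropout_group = rep(1:3, times = n_g))
  gra <- assign_dropout_groups(dsa, mode = "administrative", k = 3)
  expect_equal(gra$n_g, n_g)
  expect_equal(round(gra$pi_g, 4), c(0.3685, 0.1716, 0.4599))

  # all subjects complete: no second group can be formed
  dsc <- wide_dataset(matrix(rnorm(30), 10, 3), c(0, 1, 2))
  expect_error(assign_dropout_groups(dsc, mode = "last-observed", k = 2),
               "empty dropout subgroup")
})

test_that("pooled means are machine-exact weighted group means and
           restriction constraints hold exactly", {
  g <- study_ds(5, "MNAR")
  gr3 <- assign_dropout_groups(g$data, k = 3)
  for (r in c("neighbouring-case", "available-case")) {
    pm <- fit_restriction_pm(g$data, gr3, spec3, r, compute_se = FALSE)
    expect_equal(pm$estimate[["mu_I"]],
                 sum(pm$group_estimates$pi * pm$group_estimates$mu_I),
                 tolerance = 1e-12)
    expect_equal(pm$estimate[["mu_S"]],
                 sum(pm$group_estimates$pi * pm$group_estimates$mu_S),
                 tolerance = 1e-12)
    target <- if (r == "neighbouring-case") pm$group_estimates$mu_S[2L]
    else (gr3$n_g[1L] * pm$group_estimates$mu_S[1L] +
            gr3$n_g[2L] * pm$group_estimates$mu_S[2L]) / sum(gr3$n_g[1:2])
    expect_lt(abs(pm$group_estimates$mu_S[3L] - target), 1e-10)
  }
  gr2 <- assign_dropout_groups(g$data, k = 2)
  hg <- fit_two_group_pm(g$data, gr2, spec3, compute_se = FALSE)
  expect_equal(hg$estimate[["mu_I"]],
               sum(hg$group_estimates$pi * hg$group_estimates$mu_I),
               tolerance = 1e-12)
})

test_that("available-case restriction with equal subgroup sizes is the
           midpoint of the two slopes", {
  w <- growthsens:::restriction_weights("available-case", c(100L, 100L, 50L))
  expect_equal(w, c(0.5, 0.5))
  expect_equal(growthsens:::restriction_weights("complete-case", c(1, 2, 3)),
               c(1, 0))
  expect_equal(
    growthsens:::restriction_weights("neighbouring-case", c(1, 2, 3)),
    c(0, 1))
  # with known subgroup slopes -0.10 / -0.20 the borrowed slope is -0.15
  expect_equal(sum(w * c(-0.10, -0.20)), -0.15)
})

test_that("proportion-weighted pooling matches the hand expansion", {
  # two groups, zero estimation variance: only the multinomial term remains
  out <- pool_pattern_mixture(c(1, 3), c(0.5, 0.5), N = 100)
  # hand expansion: (1,3) C (1,3)' with C = ((.25,-.25),(-.25,.25))/100
  expect_equal(out$estimate, 2)
  expect_equal(out$se^2, (1 * 1 + 3 * 3 - 2 * 1 * 3) * 0.25 / 100,
               tolerance = 1e-14)
  # equal estimates: multinomial term vanishes (row sums of C are zero)
  out2 <- pool_pattern_mixture(c(2, 2), c(0.3, 0.7), N = 50,
                               variances = c(0.04, 0.09))
  expect_equal(out2$se^2, 0.3^2 * 0.04 + 0.7^2 * 0.09, tolerance = 1e-14)
  # single group
  out3 <- pool_pattern_mixture(1.7, 1, N = 10, variances = 0.25)
  expect_equal(out3$estimate, 1.7)
  expect_equal(out3$se, 0.5)
  expect_error(pool_pattern_mixture(c(1, 2), c(0.6, 0.5), N = 10),
               "sum to 1")
  # fixed-weights mode drops the multinomial term
  out4 <- pool_pattern_mixture(c(1, 3), c(0.5, 0.5), N = 100,
                               fixed_weights = TRUE)
  expect_equal(out4$se, 0)
})

test_that("the multigroup engine with one group reproduces plain FIML", {
  g <- study_ds(7, "MCAR")
  ml <- fit_lgm_fiml(g$data, spec3)
  one <- growthsens:::pm_fit_engine(g$data,
                                    one_group_grouping(nrow(g$data$y)),
                                    spec3, 1L, NULL, "one")
  pars <- c("mu_I", "mu_S", "psi_II", "psi_SS", "psi_IS")
  expect_lt(max(abs(one$estimate[pars] - ml$estimate[pars])), 1e-6)
  expect_lt(abs(one$loglik - ml$loglik), 1e-6)
})

test_that("two-group model under a homogeneous population agrees with
           single-group FIML", {
  g <- study_ds(7, "MCAR")
  ml <- fit_lgm_fiml(g$data, spec3)
  gr2 <- assign_dropout_groups(g$data, k = 2)
  hg <- fit_two_group_pm(g$data, gr2, spec3)
  for (pp in c("mu_I", "mu_S"))
    expect_lt(abs(hg$estimate[[pp]] - ml$estimate[[pp]]),
              2 * sqrt(hg$se[[pp]]^2 + ml$se[[pp]]^2))
  # shared-variance constraint: one set of variance parameters for all
  # groups, present once in the free-parameter vector
  expect_equal(sum(grepl("^psi_II", names(hg$free_estimates))), 1L)
})

test_that("the complete-case restriction requires an explicit opt-in", {
  g <- study_ds(5, "MNAR")
  gr3 <- assign_dropout_groups(g$data, k = 3)
  expect_error(fit_restriction_pm(g$data, gr3, spec3, "complete-case"),
               "allow_complete_case")
  cc <- fit_restriction_pm(g$data, gr3, spec3, "complete-case",
                           allow_complete_case = TRUE, compute_se = FALSE)
  expect_equal(cc$technique, "Complete")
  expect_lt(abs(cc$group_estimates$mu_S[3L] - cc$group_estimates$mu_S[1L]),
            1e-10)
})

test_that("per-group residual variances are available only where every
           group covers every wave", {
  g <- study_ds(5, "MNAR")
  gr2 <- assign_dropout_groups(g$data, mode = "last-observed", k = 2)
  # intermittent returners give the incomplete group wave-3 coverage here
  hg <- fit_two_group_pm(g$data, gr2, spec3, compute_se = FALSE,
                         shared_theta = FALSE)
  expect_true(all(c("theta_1_g1", "theta_1_g2") %in%
                    names(hg$free_estimates)))
  # the wave-1-only subgroup of the administrative 3-group scheme cannot
  # support its own residual variances
  gr3 <- assign_dropout_groups(g$data, k = 3)
  expect_error(
    fit_restriction_pm(g$data, gr3, spec3, "available-case",
                       shared_theta = FALSE),
    "per-group residual variances")
})
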