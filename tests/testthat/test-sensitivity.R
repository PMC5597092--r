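spec3 <- growth_spec(LAM3)

fake_row <- function(tech, par, est, se, p) {
  data.frame(technique = tech, parameter = par, estimate = est, se = se,
             z = est / se, p = p, stars = growthsens:::stars_for_p(p),
             ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
             n_used = 100L)
}
fake_summary <- function(rows, alpha = 0.05) {
  structure(list(table = do.call(rbind, rows), alpha = alpha,
                 scale_label = "fixture"),
            class = "sensitivity_summary")
}

test_that("on complete data LD and ML rows coincide and data-hungry
           techniques are skipped with a warning", {
  sim <- simulate_growth(150, LAM3,
                         growth_params(3, -0.1, 0.4, 0.02, 0, 0.3),
                         seed = 200)
  expect_warning(
    out <- run_sensitivity(sim$data, spec3,
                           config = list(m = 3, burn_in = 5, thin = 1,
                                         techniques = c("LD", "ML", "MI",
                                                        "MLaux", "H&G"))),
    "skipped")
  expect_setequal(names(out$fits), c("LD", "ML", "MI"))
  ld <- out$table[out$table$technique == "LD", "estimate"]
  ml <- out$table[out$table$technique == "ML", "estimate"]
  expect_lt(max(abs(ld - ml)), 1e-6)
})

test_that("the classifier reproduces the canonical reporting patterns", {
  mar_sig <- lapply(c("LD", "ML", "MI", "MLaux", "MIaux"),
                    fake_row, par = "mu_S", est = -0.06, se = 0.02,
                    p = 0.004)
  mnar_ns <- lapply(c("H&G", "Neighbouring", "Available"),
                    fake_row, par = "mu_S", est = -0.01, se = 0.035,
                    p = 0.6)
  cl1 <- classify_agreement(fake_summary(c(mar_sig, mnar_ns)))
  expect_equal(cl1$option, "1")
  expect_match(cl1$guideline, "Present MAR and MNAR")

  all_sig <- lapply(c("LD", "ML", "MI", "MLaux", "MIaux", "H&G",
                      "Neighbouring", "Available"),
                    fake_row, par = "mu_S", est = -0.13, se = 0.03,
                    p = 0.001)
  cl2 <- classify_agreement(fake_summary(all_sig))
  expect_equal(cl2$option, "2")
  expect_equal(cl2$category, "=")
  expect_match(cl2$guideline, "Not contradicted by MNAR")

  ml_only <- c(list(fake_row("LD", "mu_S", 0.01, 0.026, 0.7),
                    fake_row("ML", "mu_S", 0.049, 0.020, 0.014)),
               lapply(c("MI", "MLaux", "MIaux"), fake_row, par = "mu_S",
                      est = 0.02, se = 0.03, p = 0.4),
               lapply(c("H&G", "Neighbouring", "Available"), fake_row,
                      par = "mu_S", est = 0.03, se = 0.034, p = 0.35))
  cl3 <- classify_agreement(fake_summary(ml_only))
  expect_equal(cl3$option, "3")
  expect_match(cl3$guideline, "Opt for the MI")

  # three-way split: MI-class significant, ML at the verge, MNAR not —
  # no option is forced, the raw pattern and borderline flag are reported
  split <- c(list(fake_row("ML", "psi_SS", 0.051, 0.026, 0.056)),
             lapply(c("MI", "MLaux", "MIaux"), fake_row, par = "psi_SS",
                    est = 0.06, se = 0.026, p = 0.02),
             lapply(c("H&G", "Neighbouring", "Available"), fake_row,
                    par = "psi_SS", est = 0.03, se = 0.017, p = 0.08))
  cl4 <- classify_agreement(fake_summary(split))
  expect_true(is.na(cl4$option))
  expect_match(cl4$borderline, "ML")
  expect_match(cl4$sig_pattern, "significant: MI, MLaux, MIaux")

  # listwise flagged when its CI excludes the ML estimate
  ld_off <- c(list(fake_row("LD", "mu_I", 2.57, 0.053, 1e-8),
                   fake_row("ML", "mu_I", 2.87, 0.026, 1e-8)),
              lapply(c("MI", "H&G"), fake_row, par = "mu_I", est = 2.87,
                     se = 0.026, p = 1e-8))
  cl5 <- classify_agreement(fake_summary(ld_off))
  expect_true(cl5$ld_differs)
  expect_equal(cl5$category, "differs")

  # needs both technique classes
  expect_error(classify_agreement(fake_summary(mar_sig)),
               "MNAR-class")
})

test_that("classification is a pure function and rendering is
           byte-deterministic", {
  rows <- c(lapply(c("LD", "ML", "MI"), fake_row, par = "mu_S", est = -0.06,
                   se = 0.02, p = 0.004),
            lapply(c("H&G", "Available"), fake_row, par = "mu_S",
                   est = -0.01, se = 0.035, p = 0.6))
  sm <- fake_summary(rows)
  cl_a <- classify_agreement(sm)
  cl_b <- classify_agreement(sm)
  expect_identical(cl_a, cl_b)

  r1 <- render_report(sm, cl_a, format = "csv")
  r2 <- render_report(sm, cl_a, format = "csv")
  expect_identical(r1, r2)
  expect_match(r1[1], "^scale,technique,parameter")
  t1 <- render_report(sm, cl_a, format = "text")
  expect_identical(t1, render_report(sm, cl_a, format = "text"))

  # single-technique summary renders without a classification section
  solo <- fake_summary(list(fake_row("ML", "mu_S", -0.06, 0.02, 0.004)))
  rs <- render_report(solo, format = "csv")
  expect_length(rs, 2L)
})

test_that("the full eight-technique pipeline runs end to end on emulated
           data", {
  g <- study_ds(6, "MNAR")
  out <- run_sensitivity(g$data, spec3,
                         config = list(m = 5, burn_in = 50, thin = 5,
                                       seed = 6,
                                       scale_label = "emulated"))
  expect_setequal(names(out$fits),
                  c("LD", "ML", "MLaux", "MI", "MIaux", "H&G",
                    "Neighbouring", "Available"))
  expect_length(out$failures, 0L)
  tab <- out$table
  expect_true(all(is.finite(tab$estimate)))
  expect_true(all(tab$se > 0, na.rm = TRUE))
  # every technique reports the growth parameters in a sane range
  mu_i <- tab$estimate[tab$parameter == "mu_I"]
  expect_true(all(mu_i > 2.8 & mu_i < 3.8))
  cl <- classify_agreement(out)
  expect_true(all(unique(tab$parameter) %in% cl$parameter))
  rep_lines <- render_report(out, cl, format = "csv")
  expect_gt(length(rep_lines), nrow(tab))
})
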