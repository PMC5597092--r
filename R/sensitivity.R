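# technique classes used by the classifier
MAR_TECHNIQUES <- c("ML", "MI", "MLaux", "MIaux")
MNAR_TECHNIQUES <- c("H&G", "Neighbouring", "Available", "Complete")

GUIDELINE_TEXT <- c(
  "1" = paste("Present MAR and MNAR; Cautiously choose;",
              "Present findings cautiously."),
  "2" = "MAR models in detail; Add: Not contradicted by MNAR.",
  "3" = paste("Present MAR & MNAR models;",
              "Opt for the MI, MLaux, MIaux & MNAR results."))

#' Run the full missing-data sensitivity analysis
#'
#' Fits the linear latent growth model on one dataset under every
#' applicable technique — listwise deletion (LD), FIML (ML), FIML with
#' saturated-correlates auxiliaries (MLaux), multiple imputation without
#' and with auxiliaries in the imputation model (MI, MIaux), the two-group
#' shared-variance pattern-mixture model (H&G) and the identifying
#' restriction models (Neighbouring, Available; Complete only on opt-in) —
#' and assembles the comparison table. Techniques whose inputs are absent
#' (no auxiliaries, no viable grouping) are skipped with a warning; any
#' technique failure is isolated and recorded, the others proceed.
#'
#' @param ds a [wide_dataset()].
#' @param spec a [growth_spec()].
#' @param aux auxiliary column names (`NULL`: all available; `NA`: none).
#' @param grouping optional `k = 3` [assign_dropout_groups()] result; a
#'   `k = 2` grouping for the two-group model is derived by merging its
#'   groups 2 and 3. Defaults to automatic assignment.
#' @param config list of settings: `alpha` (default 0.05), `m` (imputations,
#'   default 100), `burn_in` (500), `thin` (100), `seed` (1),
#'   `include_complete_case` (FALSE), `scale_label` ("outcome"),
#'   `techniques` (optional subset of labels to run).
#' @return An object of class `sensitivity_summary`: `table` (technique x
#'   parameter rows with estimate, se, z, p, stars, 95% CI), `fits`,
#'   `failures`, `skipped`, `alpha`, `seed`, `dataset_hash`, `scale_label`.
#' @export
run_sensitivity <- function(ds, spec, aux = NULL, grouping = NULL,
                            config = list()) {
  cfg <- utils::modifyList(
    list(alpha = 0.05, m = 100, burn_in = 500, thin = 100, seed = 1L,
         include_complete_case = FALSE, scale_label = "outcome",
         techniques = NULL), config)
  have_aux <- !is.null(ds$aux) && !(length(aux) == 1L && is.na(aux))
  aux_cols <- if (have_aux) (if (is.null(aux)) names(ds$aux) else aux)

  grouping3 <- grouping %||% tryCatch(assign_dropout_groups(ds, k = 3),
                                      error = function(e) NULL)
  grouping2 <- if (!is.null(grouping3)) {
    g2 <- grouping3
    g2$group <- ifelse(grouping3$group == 1L, 1L, 2L)
    g2$k <- 2L
    g2$n_g <- c(grouping3$n_g[1L], sum(grouping3$n_g[-1L]))
    g2$pi_g <- g2$n_g / g2$N
    g2
  }

  steps <- list(
    LD = function() fit_lgm_listwise(ds, spec),
    ML = function() fit_lgm_fiml(ds, spec),
    MLaux = if (have_aux) function() fit_lgm_fiml_aux(ds, spec, aux_cols),
    MI = function() {
      imp <- mvn_impute(ds, m = cfg$m, include_aux = FALSE,
                        burn_in = cfg$burn_in, thin = cfg$thin,
                        seed = derive_seed(cfg$seed, 11L))
      pool_rubin(fit_growth_on_imputations(imp, spec), technique = "MI")
    },
    MIaux = if (have_aux) function() {
      imp <- mvn_impute(ds, m = cfg$m, include_aux = TRUE,
                        burn_in = cfg$burn_in, thin = cfg$thin,
                        seed = derive_seed(cfg$seed, 12L))
      pool_rubin(fit_growth_on_imputations(imp, spec), technique = "MIaux")
    },
    `H&G` = if (!is.null(grouping2))
      function() fit_two_group_pm(ds, grouping2, spec),
    Neighbouring = if (!is.null(grouping3))
      function() fit_restriction_pm(ds, grouping3, spec, "neighbouring-case"),
    Available = if (!is.null(grouping3))
      function() fit_restriction_pm(ds, grouping3, spec, "available-case"),
    Complete = if (!is.null(grouping3) && isTRUE(cfg$include_complete_case))
      function() fit_restriction_pm(ds, grouping3, spec, "complete-case",
                                    allow_complete_case = TRUE))
  # not opting in to the complete-case restriction is a choice, not a
  # missing input
  if (!isTRUE(cfg$include_complete_case)) steps$Complete <- NULL
  if (!is.null(cfg$techniques)) steps <- steps[names(steps) %in% cfg$techniques]
  skipped <- names(steps)[vapply(steps, is.null, logical(1))]
  if (length(skipped))
    warning("technique(s) skipped for lack of inputs: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  steps <- Filter(Negate(is.null), steps)

  fits <- list(); failures <- character(0)
  for (nm in names(steps)) {
    res <- tryCatch(steps[[nm]](), error = function(e) e)
    if (inherits(res, "error")) {
      failures[nm] <- conditionMessage(res)
      warning("technique ", nm, " failed: ", conditionMessage(res),
              call. = FALSE)
    } else fits[[nm]] <- res
  }

  show_pars <- c("mu_I", "mu_S", "psi_II",
                 if (spec$slope_var_free) "psi_SS",
                 if (spec$slope_var_free && spec$cov_IS_free) "psi_IS")
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    pars <- intersect(show_pars, names(f$estimate))
    data.frame(technique = nm, parameter = pars,
               estimate = unname(f$estimate[pars]),
               se = unname(f$se[pars]),
               z = unname(f$z[pars]),
               p = unname(f$p[pars]),
               stars = stars_for_p(f$p[pars]),
               ci_low = unname(f$estimate[pars] - 1.96 * f$se[pars]),
               ci_high = unname(f$estimate[pars] + 1.96 * f$se[pars]),
               n_used = f$n_used %||% NA_integer_,
               row.names = NULL)
  })
  tab <- do.call(rbind, rows)

  hash <- local({
    tf <- tempfile()
    on.exit(unlink(tf))
    saveRDS(list(ds$y, ds$wave_times), tf)
    unname(tools::md5sum(tf))
  })

  structure(list(table = tab, fits = fits, failures = failures,
                 skipped = skipped, alpha = cfg$alpha, seed = cfg$seed,
                 m = cfg$m, dataset_hash = hash,
                 scale_label = cfg$scale_label, spec = spec),
            class = "sensitivity_summary")
}

#' @export
print.sensitivity_summary <- function(x, ...) {
  cat("sensitivity analysis [", x$scale_label, "], techniques: ",
      paste(names(x$fits), collapse = ", "), "\n", sep = "")
  df <- data.frame(technique = unique(x$table$technique))
  for (pp in unique(x$table$parameter)) {
    sub <- x$table[x$table$parameter == pp, ]
    df[[pp]] <- paste0(fmt_num(sub$estimate), " (", fmt_num(sub$se), ")",
                       sub$stars)[match(df$technique, sub$technique)]
  }
  print(df, row.names = FALSE)
  if (length(x$failures))
    cat("failed:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

# CI overlap for all technique pairs on one parameter
all_cis_overlap <- function(sub) {
  k <- nrow(sub)
  if (k < 2L) return(TRUE)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (sub$ci_low[i] > sub$ci_high[j] || sub$ci_low[j] > sub$ci_high[i])
      return(FALSE)
  }
  TRUE
}

#' Classify cross-technique agreement and pick a reporting guideline
#'
#' Applies reporting guidelines to the comparison table, parameter by
#' parameter, based on significance concordance at `alpha` (CI overlap is
#' the secondary magnitude check):
#' \describe{
#'   \item{option 1}{the MAR-class techniques (ML, MI, MLaux, MIaux) and the
#'     MNAR-class techniques (pattern-mixture models) are each internally
#'     consistent but disagree with each other: present both, choose
#'     cautiously.}
#'   \item{option 2}{MAR and MNAR classes agree: report the MAR models in
#'     detail, noting the MNAR models do not contradict them.}
#'   \item{option 3}{ML disagrees while MI, MLaux, MIaux and the MNAR class
#'     agree with each other: prefer the MI/MLaux/MIaux and MNAR results.}
#' }
#' A parameter where every technique agrees in significance and all
#' pairwise 95% CIs overlap is categorised `"="`. Splits that fit no option
#' are reported with the raw significance pattern and no forced option.
#' Listwise deletion is flagged separately when its CI excludes the ML
#' estimate; p-values in [0.05, 0.10) are flagged as borderline ("at the
#' verge"), not significant.
#'
#' @param summary a [run_sensitivity()] result.
#' @param alpha significance level (default: the summary's `alpha`).
#' @return An object of class `agreement_classification`: data frame with
#'   `parameter`, `category`, `option`, `guideline`, `sig_pattern`,
#'   `borderline`, `ld_differs`.
#' @export
classify_agreement <- function(summary, alpha = NULL) {
  alpha <- alpha %||% summary$alpha
  tab <- summary$table
  run <- unique(tab$technique)
  mar <- intersect(MAR_TECHNIQUES, run)
  mnar <- intersect(MNAR_TECHNIQUES, run)
  if (length(mar) < 1L || length(mnar) < 1L)
    stop("classification needs at least one MAR-class and one MNAR-class ",
         "technique")
  uniform <- function(v) length(unique(v)) == 1L

  rows <- lapply(unique(tab$parameter), function(pp) {
    sub <- tab[tab$parameter == pp & !is.na(tab$p), ]
    sig <- stats::setNames(sub$p < alpha, sub$technique)
    border <- sub$technique[sub$p >= 0.05 & sub$p < 0.10]
    sig_pattern <- paste0(
      "significant: ",
      paste(sub$technique[sig], collapse = ", ") %||% "",
      "; not significant: ",
      paste(sub$technique[!sig], collapse = ", "))
    msig <- sig[intersect(mar, names(sig))]
    nsig <- sig[intersect(mnar, names(sig))]
    misig <- sig[intersect(c("MI", "MLaux", "MIaux"), names(sig))]

    option <- NA_character_
    if (length(misig) && "ML" %in% names(sig) &&
        uniform(misig) && length(nsig) && uniform(nsig) &&
        misig[1L] == nsig[1L] && sig[["ML"]] != misig[1L]) {
      option <- "3"
    } else if (length(msig) && length(nsig) &&
               uniform(msig) && uniform(nsig)) {
      option <- if (msig[1L] == nsig[1L]) "2" else "1"
    }

    agree_all <- uniform(sig) && all_cis_overlap(sub)
    category <- if (agree_all) "=" else "differs"
    ld_differs <- FALSE
    if ("LD" %in% sub$technique && "ML" %in% sub$technique) {
      ml_est <- sub$estimate[sub$technique == "ML"]
      ld_differs <- ml_est < sub$ci_low[sub$technique == "LD"] ||
        ml_est > sub$ci_high[sub$technique == "LD"]
    }
    data.frame(parameter = pp, category = category, option = option,
               guideline = if (is.na(option)) NA_character_
                           else GUIDELINE_TEXT[[option]],
               sig_pattern = sig_pattern,
               borderline = paste(border, collapse = ", "),
               ld_differs = ld_differs,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("agreement_classification", "data.frame")
  out
}

#' @export
print.agreement_classification <- function(x, ...) {
  cat("cross-technique agreement (alpha =", attr(x, "alpha"), ")\n")
  print.data.frame(x[, c("parameter", "category", "option", "sig_pattern")],
                   row.names = FALSE)
  invisible(x)
}

#' Render the sensitivity report
#'
#' Deterministic, byte-identical rendering of the comparison table (and the
#' classification, when supplied) as CSV lines or aligned plain text.
#'
#' @param summary a [run_sensitivity()] result.
#' @param classification optional [classify_agreement()] result.
#' @param format `"csv"` or `"text"`.
#' @param file optional path; the lines are also returned invisibly.
#' @return Character vector of report lines (invisibly when `file` is
#'   given).
#' @export
render_report <- function(summary, classification = NULL,
                          format = c("csv", "text"), file = NULL) {
  format <- match.arg(format)
  tab <- summary$table
  lines <- character(0)
  if (format == "csv") {
    lines <- c(lines,
               "scale,technique,parameter,estimate,se,z,p,stars,ci_low,ci_high")
    lines <- c(lines, sprintf(
      "%s,%s,%s,%s,%s,%s,%s,%s,%s,%s",
      summary$scale_label, tab$technique, tab$parameter,
      fmt_num(tab$estimate, 6), fmt_num(tab$se, 6), fmt_num(tab$z, 4),
      fmt_num(tab$p, 6), tab$stars,
      fmt_num(tab$ci_low, 6), fmt_num(tab$ci_high, 6)))
    if (!is.null(classification)) {
      lines <- c(lines, "",
                 "scale,parameter,category,guideline_option,guideline_text")
      lines <- c(lines, sprintf(
        "%s,%s,%s,%s,\"%s\"",
        summary$scale_label, classification$parameter,
        classification$category,
        ifelse(is.na(classification$option), "", classification$option),
        ifelse(is.na(classification$guideline), "",
               classification$guideline)))
    }
  } else {
    lines <- c(lines, paste0("sensitivity analysis: ", summary$scale_label),
               paste0("techniques: ", paste(unique(tab$technique),
                                            collapse = ", ")), "")
    for (pp in unique(tab$parameter)) {
      sub <- tab[tab$parameter == pp, ]
      lines <- c(lines, pp, paste0(
        "  ", formatC(sub$technique, width = 14, flag = "-"),
        fmt_num(sub$estimate, 3), " (", fmt_num(sub$se, 3), ")",
        formatC(sub$stars, width = 4, flag = "-"),
        " CI [", fmt_num(sub$ci_low, 3), ", ", fmt_num(sub$ci_high, 3), "]"))
    }
    if (!is.null(classification)) {
      lines <- c(lines, "", "agreement classification:")
      for (i in seq_len(nrow(classification))) {
        cl <- classification[i, ]
        lines <- c(lines, paste0(
          "  ", formatC(cl$parameter, width = 10, flag = "-"),
          " category ", cl$category,
          if (!is.na(cl$option))
            paste0("; guideline option ", cl$option, ": ", cl$guideline)
          else paste0("; ", cl$sig_pattern)))
      }
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
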