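#' Growth-model population parameters
#'
#' Parameters of the linear latent growth model used by the generator: mean
#' intercept and mean slope (score units, per year), intercept/slope
#' (co)variances of the bivariate-normal latent distribution, and per-wave
#' residual variance.
#'
#' @param mu_I mean intercept.
#' @param mu_S mean slope (score units per year).
#' @param psi_II intercept variance (>= 0).
#' @param psi_SS slope variance (>= 0).
#' @param psi_IS intercept-slope covariance; `|psi_IS| <= sqrt(psi_II*psi_SS)`.
#' @param theta residual variance, scalar or one value per wave (>= 0).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(mu_I, mu_S, psi_II, psi_SS, psi_IS = 0, theta) {
  if (psi_II < 0 || psi_SS < 0 || any(theta < 0))
    stop("variance parameters must be non-negative")
  if (abs(psi_IS) > sqrt(psi_II * psi_SS) + 1e-12)
    stop("latent covariance matrix is not positive semidefinite: ",
         "|psi_IS| exceeds sqrt(psi_II * psi_SS)")
  structure(list(mu_I = mu_I, mu_S = mu_S, psi_II = psi_II,
                 psi_SS = psi_SS, psi_IS = psi_IS, theta = theta),
            class = "growth_params")
}

#' Missingness scenario for the generator
#'
#' Describes how missingness is imposed on a complete simulated dataset.
#' Dropout is a per-wave logistic hazard given survival to that wave
#' (monotone attrition, starting at wave 2); intermittent wave non-response
#' is an independent Bernoulli overlay. The hazard's linear predictor is
#' `qlogis(dropout_rate[t]) + dropout_coef * (predictor - centre)`, where the
#' predictor depends on the mechanism:
#' \describe{
#'   \item{MCAR}{none (`dropout_coef` must be 0): pure chance.}
#'   \item{MAR}{the most recent score that remains observed (or a named
#'     auxiliary via `aux_name`): missingness depends only on observed data.}
#'   \item{MNAR}{the subject's latent slope (`mnar_on = "slope"`) or the
#'     current, to-be-deleted score (`mnar_on = "score"`): missingness
#'     depends on what is unobserved.}
#' }
#'
#' @param mechanism `"MCAR"`, `"MAR"` or `"MNAR"`.
#' @param form `"mixed"` (default: attrition plus intermittent
#'   non-response), `"monotone"` or `"intermittent"`.
#' @param dropout_rate baseline dropout hazard per wave: scalar (applied to
#'   waves 2..T) or length-T vector with first element 0.
#' @param dropout_coef logistic coefficient on the mechanism's predictor.
#' @param mnar_on MNAR predictor: the latent slope or the current score.
#' @param intermittent_rate probability of intermittent non-response per
#'   wave, scalar or length T. Wave-1 non-response is only applied to
#'   subjects retaining at least one other observed wave.
#' @param aux_name optional auxiliary column used as the MAR predictor.
#' @param seed default seed used by [impose_missingness()].
#' @return An object of class `missingness_scenario`.
#' @export
missingness_scenario <- function(mechanism = c("MCAR", "MAR", "MNAR"),
                                 form = c("mixed", "monotone", "intermittent"),
                                 dropout_rate = 0, dropout_coef = 0,
                                 mnar_on = c("slope", "score"),
                                 intermittent_rate = 0, aux_name = NULL,
                                 seed = NULL) {
  mechanism <- match.arg(mechanism)
  form <- match.arg(form)
  mnar_on <- match.arg(mnar_on)
  if (any(dropout_rate < 0 | dropout_rate > 1) ||
      any(intermittent_rate < 0 | intermittent_rate > 1))
    stop("rates must be probabilities in [0, 1]")
  if (mechanism == "MCAR" && dropout_coef != 0)
    stop("MCAR requires dropout_coef = 0")
  if (length(dropout_rate) > 1L && dropout_rate[1L] != 0)
    stop("dropout cannot occur at wave 1 (first dropout_rate must be 0)")
  structure(list(mechanism = mechanism, form = form,
                 dropout_rate = dropout_rate, dropout_coef = dropout_coef,
                 mnar_on = mnar_on, intermittent_rate = intermittent_rate,
                 aux_name = aux_name, seed = seed),
            class = "missingness_scenario")
}

#' Simulate complete growth data
#'
#' Draws `n` trajectories from the linear latent growth model
#' `y_it = I_i + lambda_t * S_i + e_it` with `(I_i, S_i)` bivariate normal
#' and independent normal residuals. Optional auxiliary covariates are
#' standard-normal variables with a chosen correlation to the latent
#' intercept. The per-subject latent intercepts and slopes are returned on a
#' separate channel for oracle checks only and are never part of the
#' dataset handed to estimators.
#'
#' @param n number of subjects.
#' @param wave_times slope loadings (first 0, strictly increasing).
#' @param params a [growth_params()].
#' @param seed integer seed (optional).
#' @param aux_cor named numeric vector of target correlations between each
#'   generated auxiliary and the latent intercept (e.g.
#'   `c(gpa = 0.35)`).
#' @return An object of class `growth_sim`: list with `data` (a complete
#'   [wide_dataset()]) and `latent` (data frame of per-subject `intercept`
#'   and `slope`).
#' @export
simulate_growth <- function(n, wave_times, params, seed = NULL,
                            aux_cor = NULL) {
  stopifnot(n >= 1)
  if (!inherits(params, "growth_params")) params <- do.call(growth_params, params)
  if (!is.null(seed)) set.seed(seed)
  nt <- length(wave_times)
  theta <- rep(params$theta, length.out = nt)
  Psi <- matrix(c(params$psi_II, params$psi_IS,
                  params$psi_IS, params$psi_SS), 2L, 2L)
  ev <- eigen(Psi, symmetric = TRUE)
  if (any(ev$values < -1e-10))
    stop("latent covariance matrix is not positive semidefinite")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2L)
  IS <- matrix(stats::rnorm(2L * n), n, 2L) %*% t(L)
  I <- params$mu_I + IS[, 1L]
  S <- params$mu_S + IS[, 2L]
  eps <- sweep(matrix(stats::rnorm(n * nt), n, nt), 2L, sqrt(theta), `*`)
  y <- outer(I, rep(1, nt)) + outer(S, wave_times) + eps

  aux <- NULL
  if (!is.null(aux_cor)) {
    if (is.null(names(aux_cor)) || any(abs(aux_cor) > 1))
      stop("aux_cor must be a named vector of correlations in [-1, 1]")
    zI <- if (stats::sd(I) > 0) as.numeric(scale(I)) else rep(0, n)
    aux <- as.data.frame(lapply(aux_cor, function(r)
      r * zI + sqrt(1 - r^2) * stats::rnorm(n)))
  }

  list_out <- list(
    data = wide_dataset(y, wave_times, aux = aux, drop_all_missing = FALSE),
    latent = data.frame(intercept = I, slope = S))
  structure(list_out, class = "growth_sim")
}

#' Impose MCAR/MAR/MNAR missingness on complete data
#'
#' Applies a [missingness_scenario()] to a complete simulated dataset.
#' Monotone dropout is drawn wave by wave as a logistic hazard given survival
#' (wave 1 is never deleted by dropout); intermittent non-response is an
#' independent overlay, with wave-1 non-response restricted to subjects that
#' keep at least one later observed wave, so every subject retains at least
#' one observation. The deletion log records, per deleted cell, the cause
#' and the hazard's linear predictor.
#'
#' @param sim a `growth_sim` (from [simulate_growth()]), or a complete
#'   [wide_dataset()] for scenarios that do not need the latent record.
#' @param scenario a [missingness_scenario()].
#' @param seed integer seed; defaults to `scenario$seed`.
#' @return List with `data` (masked [wide_dataset()]) and `log` (data frame
#'   `subject`, `wave`, `cause`, `linear_predictor`).
#' @export
impose_missingness <- function(sim, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "missingness_scenario"))
  if (inherits(sim, "growth_sim")) {
    ds <- sim$data; latent <- sim$latent
  } else if (inherits(sim, "wide_dataset")) {
    ds <- sim; latent <- NULL
  } else stop("sim must be a growth_sim or a wide_dataset")
  y <- ds$y
  n <- nrow(y); nt <- ncol(y)
  if (scenario$mechanism == "MNAR" && scenario$mnar_on == "slope" &&
      is.null(latent))
    stop("MNAR on the latent slope needs the generator's latent record")
  if (scenario$mechanism == "MAR" && is.null(scenario$aux_name) &&
      anyNA(y[, 1L]))
    stop("MAR on the previous score needs wave 1 observed ",
         "(or an auxiliary predictor via aux_name)")
  seed <- seed %||% scenario$seed
  if (!is.null(seed)) set.seed(seed)

  drate <- scenario$dropout_rate
  if (length(drate) == 1L) drate <- c(0, rep(drate, nt - 1L))
  drate <- rep(drate, length.out = nt)
  irate <- rep(scenario$intermittent_rate, length.out = nt)
  if (scenario$form == "monotone") irate[] <- 0
  if (scenario$form == "intermittent") drate[] <- 0

  obs <- !is.na(y)
  log_subject <- log_wave <- integer(0)
  log_cause <- character(0); log_lp <- numeric(0)

  # intermittent draws for waves 2..T first, so the MAR hazard can condition
  # on the most recent score that remains observed in the output
  int_del <- matrix(FALSE, n, nt)
  for (t in 2:nt)
    int_del[, t] <- irate[t] > 0 & stats::runif(n) < irate[t]

  aux_pred <- NULL
  if (scenario$mechanism == "MAR" && !is.null(scenario$aux_name)) {
    aux_pred <- ds$aux[[scenario$aux_name]]
    if (is.null(aux_pred)) stop("aux_name not found among auxiliaries")
    aux_pred <- aux_pred - mean(aux_pred, na.rm = TRUE)
  }

  active <- rep(TRUE, n)          # still in the study (not dropped out)
  used_wave1 <- rep(FALSE, n)     # wave-1 score entered a MAR hazard
  for (t in 2:nt) {
    pred <- rep(0, n)
    if (scenario$mechanism == "MAR") {
      if (!is.null(aux_pred)) pred <- aux_pred
      else {
        # most recent earlier wave not intermittently deleted (wave 1 as
        # fallback is always available at this stage)
        for (i in which(active)) {
          s <- max(which(obs[i, 1:(t - 1L)] & !int_del[i, 1:(t - 1L)]))
          pred[i] <- y[i, s] - mean(y[, s])
          if (s == 1L) used_wave1[i] <- TRUE
        }
      }
    } else if (scenario$mechanism == "MNAR") {
      pred <- if (scenario$mnar_on == "slope") latent$slope - mean(latent$slope)
              else y[, t] - mean(y[, t])
    }
    if (drate[t] <= 0) {
      pr <- rep(0, n); lp <- rep(-Inf, n)
    } else {
      lp <- stats::qlogis(min(max(drate[t], 1e-12), 1 - 1e-12)) +
        scenario$dropout_coef * pred
      pr <- stats::plogis(lp)
    }
    drop_now <- active & stats::runif(n) < pr
    active[drop_now] <- FALSE
    newly <- which(drop_now)
    if (length(newly)) {
      for (tt in t:nt) {
        log_subject <- c(log_subject, newly)
        log_wave <- c(log_wave, rep(tt, length(newly)))
        log_cause <- c(log_cause, rep("dropout", length(newly)))
        log_lp <- c(log_lp, lp[newly])
      }
    }
    obs[!active, t] <- FALSE
  }

  # intermittent overlay, waves 2..T (cells already missing stay missing)
  for (t in 2:nt) {
    hit <- which(obs[, t] & int_del[, t])
    if (length(hit)) {
      obs[hit, t] <- FALSE
      log_subject <- c(log_subject, hit)
      log_wave <- c(log_wave, rep(t, length(hit)))
      log_cause <- c(log_cause, rep("intermittent", length(hit)))
      log_lp <- c(log_lp, rep(NA_real_, length(hit)))
    }
  }
  # wave-1 non-response, only where another observed wave remains and the
  # wave-1 score never served as a MAR hazard predictor
  if (irate[1L] > 0) {
    cand <- which(obs[, 1L] & rowSums(obs[, -1L, drop = FALSE]) > 0 &
                    !used_wave1)
    hit <- cand[stats::runif(length(cand)) < irate[1L]]
    if (length(hit)) {
      obs[hit, 1L] <- FALSE
      log_subject <- c(log_subject, hit)
      log_wave <- c(log_wave, rep(1L, length(hit)))
      log_cause <- c(log_cause, rep("intermittent", length(hit)))
      log_lp <- c(log_lp, rep(NA_real_, length(hit)))
    }
  }

  y[!obs] <- NA_real_
  out <- wide_dataset(y, ds$wave_times, subject_id = ds$subject_id,
                      aux = ds$aux, dropout_group = ds$dropout_group,
                      drop_all_missing = FALSE)
  dlog <- data.frame(subject = log_subject, wave = log_wave,
                     cause = log_cause, linear_predictor = log_lp)
  dlog <- dlog[order(dlog$subject, dlog$wave), ]
  rownames(dlog) <- NULL
  list(data = out, log = dlog)
}

#' Study-emulation preset
#'
#' A frozen generator configuration emulating a three-wave panel of
#' Likert-type subscale scores (plausible range 1-5) in a cohort with heavy
#' attrition: n = 1072 subjects each observed at one wave or more, slope
#' loadings (0, 1.17, 2.17) for unequal 14- and 12-month wave spacings, and
#' dropout plus wave non-response calibrated so that roughly one subject in
#' five provides complete data. The `mechanism` argument selects which
#' selection mechanism drives dropout while keeping the marginal missingness
#' rates comparable; the underlying growth parameters are identical.
#'
#' @param mechanism `"MAR"` (default), `"MCAR"` or `"MNAR"`.
#' @return List with `params` ([growth_params()]), `scenario`
#'   ([missingness_scenario()]), `n`, `wave_times`, and `aux_cor` (the
#'   auxiliary correlations to pass to [simulate_growth()]).
#' @export
study_emulation_preset <- function(mechanism = c("MAR", "MCAR", "MNAR")) {
  mechanism <- match.arg(mechanism)
  params <- growth_params(mu_I = 3.28, mu_S = -0.06,
                          psi_II = 0.41, psi_SS = 0.02, psi_IS = -0.01,
                          theta = 0.30)
  base <- list(MCAR = list(rate = c(0, 0.505, 0.415), coef = 0, aux = NULL),
               MAR  = list(rate = c(0, 0.530, 0.445), coef = 0.90,
                           aux = "gpa"),
               MNAR = list(rate = c(0, 0.515, 0.425), coef = -2.5,
                           aux = NULL))[[mechanism]]
  scenario <- missingness_scenario(
    mechanism = mechanism, form = "mixed",
    dropout_rate = base$rate, dropout_coef = base$coef,
    mnar_on = "slope", aux_name = base$aux,
    intermittent_rate = c(0.090, 0.150, 0.080))
  list(params = params, scenario = scenario, n = 1072L,
       wave_times = c(0, 1.17, 2.17),
       aux_cor = c(gpa = 0.35, engagement = 0.20))
}

#' Generate one study-emulation dataset
#'
#' Convenience wrapper: draws a complete sample from
#' [study_emulation_preset()], imposes the preset's missingness, and attaches
#' an administrative dropout-group label derived from the subject's dropout
#' time (1 = never dropped, 2 = dropped at the last wave, 3 = dropped
#' earlier), mimicking enrolment records that exist independently of which
#' questionnaires were returned.
#'
#' @param seed integer seed.
#' @param mechanism passed to [study_emulation_preset()].
#' @return List with `data` (a [wide_dataset()] with auxiliaries and
#'   `dropout_group`), `latent`, `log`, and `truth` (the generating
#'   [growth_params()]).
#' @export
generate_study_dataset <- function(seed, mechanism = "MAR") {
  preset <- study_emulation_preset(mechanism)
  sim <- simulate_growth(preset$n, preset$wave_times, preset$params,
                         seed = derive_seed(seed, 0L),
                         aux_cor = preset$aux_cor)
  masked <- impose_missingness(sim, preset$scenario,
                               seed = derive_seed(seed, 1L))
  dropped <- masked$log[masked$log$cause == "dropout", ]
  first_drop <- tapply(dropped$wave, dropped$subject, min)
  nt <- length(preset$wave_times)
  grp <- rep(1L, preset$n)
  idx <- as.integer(names(first_drop))
  grp[idx] <- ifelse(first_drop == nt, 2L, 3L)
  ds <- masked$data
  ds$dropout_group <- grp
  list(data = ds, latent = sim$latent, log = masked$log,
       truth = preset$params)
}
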