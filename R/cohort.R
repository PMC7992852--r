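# Synthetic pooled two-trial cohort generator.
#
# Emulates a pooled pair of m-health RCTs: trial A randomised 80/80
# (intervention/control, adults 18-55), trial B 110/55 (adults 45-64),
# giving 190 intervention and 135 control participants. Behaviour is
# generated on raw scales and scored through the ASI module so the full
# scoring path is exercised; follow-up outcomes are linear-Gaussian in the
# scored mediator with known path coefficients, and attrition follows a
# logistic missing-at-random model in age and a baseline outcome.

.outcomes <- c("dass_depression", "dass_anxiety", "dass_stress",
               "qol_physical", "qol_mental", "energy_fatigue")

# Baseline outcome distributions: pooled trial summaries (mean, SD) with
# instrument ranges (DASS-21 subscales on the doubled 0-42 scale, SF-12
# component scores, energy & fatigue 0-100).
.outcome_baseline <- data.frame(
  outcome = .outcomes,
  mean = c(10.7, 6.0, 14.2, 47.2, 42.0, 44.7),
  sd   = c(8.1, 5.5, 6.6, 7.2, 10.2, 18.7),
  lo   = c(0, 0, 0, 10, 10, 0),
  hi   = c(42, 42, 42, 70, 70, 100)
)

# Continuous behaviour dimensions: truncated-normal parameters on fixed
# supports. Means/SDs reflect a physically inactive, poor-sleeping adult
# cohort (eligibility < 90 min MVPA/wk, poor subjective sleep quality).
.behaviour_continuous <- data.frame(
  column = c("mvpa_sessions", "mvpa_minutes", "vigorous_fraction",
             "sitting_minutes", "sleep_midpoint", "sleep_efficiency",
             "sleep_duration_hours"),
  mean  = c(1.3, 50, 0.10, 540, 195, 78, 6.4),
  sd    = c(1.5, 45, 0.15, 160, 75, 9, 1.1),
  lo    = c(0, 0, 0, 60, 0, 40, 3),
  hi    = c(14, 840, 1, 960, 600, 100, 11)
)

# Dimensions that carry the intervention effect on behaviour (sitting is
# reversed: its raw value is shifted down).
.shift_dims <- c(mvpa_sessions = 1, mvpa_minutes = 1,
                 sitting_minutes = -1, sleep_efficiency = 1)

# Ordinal behaviour dimensions: category probabilities at every wave.
.behaviour_ordinal <- list(
  rt_days = list(values = 0:7,
                 prob = c(0.72, 0.10, 0.07, 0.05, 0.03, 0.015, 0.01, 0.005)),
  daytime_sleepiness = list(values = 0:3, prob = c(0.35, 0.35, 0.20, 0.10)),
  sleep_quality = list(values = 0:3, prob = c(0.02, 0.18, 0.55, 0.25)),
  sleep_variability = list(values = 0:8,
                           prob = c(0.03, 0.07, 0.12, 0.17, 0.22, 0.17,
                                    0.12, 0.07, 0.03))
)

#' Configuration for the synthetic pooled-trial cohort
#'
#' Returns the generator settings with defaults matching the pooled two-trial
#' design the package targets: trial A randomises 80 intervention / 80
#' control participants aged 18-55 (mean 41.5, SD 9.9), trial B 110 / 55 aged
#' 45-64 (mean 52.0, SD 6.9), 81.2% female. True mediation paths default to
#' the ASI-12 -> depression analysis scale: `a_true = 3` ASI units,
#' `b_true = -0.10` outcome units per ASI unit, `cprime_true = -0.25`.
#' `b_true` and `cprime_true` may be scalars (recycled over outcomes) or named
#' vectors over the six outcomes.
#'
#' The follow-up outcome model is linear-Gaussian:
#' `Y_w = mu + cprime*group + b*(ASI_w - m_ref) + gamma*(Y_prev - mu) +
#' study_effect*study + e`, with `Y_prev` the baseline value at wave 3 and
#' the wave-3 value at wave 6 (carryover). Attrition at each follow-up is
#' Bernoulli with `logit p_miss = intercept + beta_age*(age - 47) +
#' beta_y0*(Y0_driver - mean)`; intercept defaults are calibrated so expected
#' completion is 84.9% at 3 months and 65.5% at 6 months.
#'
#' @param n_intervention,n_control Group sizes per trial, `c(A, B)`.
#' @param a_true Intervention effect on the ASI-12 mediator at follow-up.
#' @param b_true Mediator -> outcome slope(s), outcome units per ASI unit.
#' @param cprime_true Direct intervention effect(s) on the outcome(s).
#' @param gamma Carryover of the previous wave's outcome (default 0.5).
#' @param study_effect Additive trial-B effect on follow-up outcomes.
#' @param sigma_outcome Residual SDs of follow-up outcomes (named or scalar).
#' @param wave_cor Gaussian-copula correlation of continuous behaviour
#'   dimensions between consecutive waves.
#' @param m_ref Reference (centring) ASI-12 value in the outcome model.
#' @param prop_female Proportion female.
#' @param age Per-trial age distributions: list of `c(mean, sd, min, max)`.
#' @param missingness List: `enabled`, `intercept3`, `intercept6`, `beta_age`
#'   (per year), `beta_y0` (per unit of the driver outcome at baseline),
#'   `driver` (outcome name), `monotone`, `scope` ("wave", "outcome" or
#'   "mediator" -- what gets deleted at a missed follow-up).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_intervention = c(A = 80, B = 110),
                          n_control = c(A = 80, B = 55),
                          a_true = 3.0,
                          b_true = c(dass_depression = -0.10,
                                     dass_anxiety = -0.04,
                                     dass_stress = -0.12,
                                     qol_physical = 0.02,
                                     qol_mental = 0.17,
                                     energy_fatigue = 0.28),
                          cprime_true = c(dass_depression = -0.25,
                                          dass_anxiety = -0.21,
                                          dass_stress = -0.26,
                                          qol_physical = 0.28,
                                          qol_mental = 0.56,
                                          energy_fatigue = 1.15),
                          gamma = 0.5,
                          study_effect = 0,
                          sigma_outcome = c(dass_depression = 7,
                                            dass_anxiety = 4.5,
                                            dass_stress = 5.5,
                                            qol_physical = 6,
                                            qol_mental = 8.5,
                                            energy_fatigue = 15),
                          wave_cor = 0.5,
                          m_ref = 48,
                          prop_female = 0.812,
                          age = list(A = c(mean = 41.5, sd = 9.9, min = 18, max = 55),
                                     B = c(mean = 52.0, sd = 6.9, min = 45, max = 64)),
                          missingness = list(),
                          seed = NULL) {
  miss_default <- list(enabled = TRUE,
                       intercept3 = -1.8986, intercept6 = -1.3138,
                       beta_age = -0.05, beta_y0 = 0.04,
                       driver = "dass_depression",
                       monotone = TRUE, scope = "wave")
  missingness <- modifyList(miss_default, missingness)
  cfg <- list(n_intervention = n_intervention, n_control = n_control,
              a_true = a_true,
              b_true = recycle_outcomes(b_true, "b_true"),
              cprime_true = recycle_outcomes(cprime_true, "cprime_true"),
              gamma = gamma, study_effect = study_effect,
              sigma_outcome = recycle_outcomes(sigma_outcome, "sigma_outcome"),
              wave_cor = wave_cor, m_ref = m_ref,
              prop_female = prop_female, age = age,
              missingness = missingness, seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

recycle_outcomes <- function(x, what) {
  if (length(x) == 1 && is.null(names(x))) {
    return(setNames(rep(as.numeric(x), length(.outcomes)), .outcomes))
  }
  if (is.null(names(x)) || !all(.outcomes %in% names(x))) {
    stop(what, " must be a scalar or a vector named over all six outcomes")
  }
  x[.outcomes]
}

validate_cohort_config <- function(cfg) {
  sizes <- c(cfg$n_intervention, cfg$n_control)
  if (any(!is.finite(sizes)) || any(sizes <= 0) || any(sizes != round(sizes))) {
    stop("cohort configuration error: group sizes must be positive integers")
  }
  if (any(cfg$sigma_outcome <= 0)) {
    stop("cohort configuration error: residual SDs must be positive")
  }
  for (tr in names(cfg$age)) {
    if (cfg$age[[tr]]["sd"] <= 0) {
      stop("cohort configuration error: age SD must be positive")
    }
  }
  if (!(cfg$missingness$scope %in% c("wave", "outcome", "mediator"))) {
    stop("cohort configuration error: missingness scope must be wave/outcome/mediator")
  }
  invisible(cfg)
}

# truncated-normal CDF on [lo, hi]
ptnorm <- function(x, mu, sigma, lo, hi) {
  pa <- pnorm(lo, mu, sigma)
  pb <- pnorm(hi, mu, sigma)
  pmin(pmax((pnorm(x, mu, sigma) - pa) / (pb - pa), 0), 1)
}

# Expected observed (min, max) of m pooled draws where a fraction w_shift
# comes from the location-shifted distribution: order-statistic quantile
# approximation E[min] ~ Q(1/(m+1)), E[max] ~ Q(m/(m+1)) of the mixture.
expected_obs_range <- function(mu, sigma, lo, hi, delta, w_shift, m) {
  Fm <- function(x) {
    (1 - w_shift) * ptnorm(x, mu, sigma, lo, hi) +
      w_shift * ptnorm(x, mu + delta, sigma, lo, hi)
  }
  qmix <- function(p) {
    uniroot(function(x) Fm(x) - p, lower = lo, upper = hi,
            tol = 1e-9, extendInt = "no")$root
  }
  c(qmix(1 / (m + 1)), qmix(m / (m + 1)))
}

.shift_cache <- new.env(parent = emptyenv())

# Raw per-dimension mean shifts that induce an ASI-12 shift of a_true,
# spread equally over the shifted dimensions. Scores use observed pooled
# min/max, so each raw shift targets (a_true/K) * E[observed range]/10 on
# the post-truncation mean; the expected observed range depends on the shift
# itself, hence the short fixed-point iteration.
behaviour_shifts <- function(a_true, n_int, n_con) {
  key <- paste(a_true, n_int, n_con)
  if (!is.null(.shift_cache[[key]])) return(.shift_cache[[key]])
  per_dim <- a_true / length(.shift_dims)
  m <- 3 * (n_int + n_con)            # draws pooled over three waves
  w_shift <- 2 * n_int / m            # intervention follow-up draws
  out <- setNames(numeric(length(.shift_dims)), names(.shift_dims))
  for (iter in 1:3) {
    for (d in names(.shift_dims)) {
      p <- .behaviour_continuous[.behaviour_continuous$column == d, ]
      rng <- expected_obs_range(p$mean, p$sd, p$lo, p$hi, out[d], w_shift, m)
      target <- .shift_dims[[d]] * per_dim * (rng[2] - rng[1]) / 10
      out[d] <- tnorm_shift_for_delta(p$mean, p$sd, p$lo, p$hi, target)
    }
  }
  .shift_cache[[key]] <- out
  out
}

#' Simulate a pooled two-trial cohort with known mediation structure
#'
#' Generates one long-format dataset (one row per participant-wave at 0, 3
#' and 6 months): demographics, the twelve raw behaviour dimensions, and the
#' six outcome scales. Intervention participants' continuous behaviour
#' dimensions are mean-shifted at follow-up so the induced ASI-12 difference
#' equals `a_true`; follow-up outcomes are linear in the scored ASI-12 with
#' slope `b_true` plus the direct effect `cprime_true`. When
#' `config$missingness$enabled`, follow-up waves are deleted by
#' [apply_missingness()].
#'
#' Identical config and seed give byte-identical output.
#'
#' @param config A [cohort_config()].
#' @return Long tibble with attributes `cohort_config` and `asi_bounds`
#'   (bounds realised during internal scoring, pre-missingness).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)

  # participants
  grid <- rbind(
    data.frame(trial = "A", group = 1, n = config$n_intervention[["A"]]),
    data.frame(trial = "A", group = 0, n = config$n_control[["A"]]),
    data.frame(trial = "B", group = 1, n = config$n_intervention[["B"]]),
    data.frame(trial = "B", group = 0, n = config$n_control[["B"]])
  )
  ppl <- grid[rep(seq_len(nrow(grid)), grid$n), c("trial", "group")]
  n <- nrow(ppl)
  ppl$id <- sprintf("P%04d", seq_len(n))
  ppl$study <- as.numeric(ppl$trial == "B")
  ppl$sex <- ifelse(runif(n) < config$prop_female, "female", "male")
  ppl$age <- NA_real_
  for (tr in c("A", "B")) {
    i <- ppl$trial == tr
    a <- config$age[[tr]]
    ppl$age[i] <- rtnorm(sum(i), a["mean"], a["sd"], a["min"], a["max"])
  }

  # continuous behaviour dimensions: copula latents across waves,
  # exact truncated-normal marginals, intervention mean-shift at follow-up
  shifts <- behaviour_shifts(config$a_true,
                             sum(config$n_intervention),
                             sum(config$n_control))
  rho <- config$wave_cor
  prof <- vector("list", 3)
  waves <- c(0, 3, 6)
  z_prev <- NULL
  for (w in seq_along(waves)) {
    z <- matrix(rnorm(n * nrow(.behaviour_continuous)), n)
    if (!is.null(z_prev)) z <- rho * z_prev + sqrt(1 - rho^2) * z
    z_prev <- z
    u <- pnorm(z)
    pw <- data.frame(id = ppl$id, wave = waves[w])
    for (j in seq_len(nrow(.behaviour_continuous))) {
      p <- .behaviour_continuous[j, ]
      mu <- rep(p$mean, n)
      if (waves[w] > 0 && p$column %in% names(shifts)) {
        mu <- mu + shifts[[p$column]] * ppl$group
      }
      pw[[p$column]] <- qtnorm(u[, j], mu, p$sd, p$lo, p$hi)
    }
    for (d in names(.behaviour_ordinal)) {
      o <- .behaviour_ordinal[[d]]
      pw[[d]] <- sample(o$values, n, replace = TRUE, prob = o$prob)
    }
    prof[[w]] <- pw
  }
  long <- dplyr::bind_rows(prof)
  long <- dplyr::left_join(long, tibble::as_tibble(ppl), by = "id")

  # score internally so outcomes are generated from the actual composite
  bounds <- compute_bounds(long)
  scored <- score_asi(long, bounds)
  asi <- matrix(scored$asi12, n, 3,
                dimnames = list(NULL, paste0("w", waves)))

  # baseline outcomes (truncated to instrument ranges), follow-ups
  # linear-Gaussian in the scored mediator
  y <- array(NA_real_, c(n, length(.outcomes), 3),
             dimnames = list(NULL, .outcomes, paste0("w", waves)))
  for (k in seq_along(.outcomes)) {
    ob <- .outcome_baseline[k, ]
    y[, k, 1] <- rtnorm(n, ob$mean, ob$sd, ob$lo, ob$hi)
    for (w in 2:3) {
      prev <- y[, k, w - 1]
      y[, k, w] <- ob$mean +
        config$cprime_true[[.outcomes[k]]] * ppl$group +
        config$b_true[[.outcomes[k]]] * (asi[, w] - config$m_ref) +
        config$gamma * (prev - ob$mean) +
        config$study_effect * ppl$study +
        rnorm(n, 0, config$sigma_outcome[[.outcomes[k]]])
    }
  }
  for (k in seq_along(.outcomes)) long[[.outcomes[k]]] <- NA_real_
  for (w in 1:3) {
    iw <- long$wave == waves[w]
    for (k in seq_along(.outcomes)) long[[.outcomes[k]]][iw] <-
        y[match(long$id[iw], ppl$id), k, w]
  }

  long$observed <- TRUE
  long <- tibble::as_tibble(
    long[order(long$id, long$wave),
         c("id", "trial", "study", "group", "sex", "age", "wave", "observed",
           setdiff(names(long), c("id", "trial", "study", "group", "sex",
                                  "age", "wave", "observed")))]
  )
  attr(long, "cohort_config") <- config
  attr(long, "asi_bounds") <- bounds
  if (isTRUE(config$missingness$enabled)) {
    long <- apply_missingness(long, config)
  }
  long
}

#' Delete follow-up observations under a logistic MAR model
#'
#' Each participant's 3-month (and 6-month) assessment is deleted with
#' probability `plogis(intercept + beta_age*(age - 47) + beta_y0*(Y0 -
#' mean))`, where `Y0` is the baseline value of the configured driver
#' outcome: younger participants and those with worse baseline scores are
#' likelier to drop out, the mechanism observed in the source trials.
#' Baseline is never deleted. With `monotone = TRUE` (default) a participant
#' missing at 3 months is also missing at 6 months and `intercept6` is the
#' conditional dropout logit among 3-month completers. `scope` controls what
#' is deleted at a missed follow-up: the whole wave (default), only the
#' outcome scales, or only the behaviour (mediator) dimensions.
#'
#' @param data Long cohort data with complete follow-up waves.
#' @param config A [cohort_config()]; only its `missingness` element is used.
#' @return `data` with deleted cells set to `NA`, `observed` flags updated,
#'   and an attribute `missingness_rate` (marginal deletion rate per wave).
#' @export
apply_missingness <- function(data, config = attr(data, "cohort_config")) {
  mc <- config$missingness
  base <- data[data$wave == 0, ]
  drv <- base[[mc$driver]]
  if (any(!is.finite(base$age)) || any(!is.finite(drv))) {
    stop("apply_missingness(): non-finite age or baseline driver values")
  }
  drv_mean <- .outcome_baseline$mean[.outcome_baseline$outcome == mc$driver]
  lin3 <- mc$intercept3 + mc$beta_age * (base$age - 47) +
    mc$beta_y0 * (drv - drv_mean)
  miss3 <- runif(nrow(base)) < plogis(lin3)
  lin6 <- mc$intercept6 + mc$beta_age * (base$age - 47) +
    mc$beta_y0 * (drv - drv_mean)
  miss6_new <- runif(nrow(base)) < plogis(lin6)
  miss6 <- if (isTRUE(mc$monotone)) miss3 | miss6_new else miss6_new

  beh_cols <- intersect(c(.behaviour_continuous$column,
                          names(.behaviour_ordinal),
                          "activity_type", "sleep_timing", "sleep_duration_ok"),
                        names(data))
  del_cols <- switch(mc$scope,
                     wave = c(beh_cols, .outcomes),
                     outcome = .outcomes,
                     mediator = beh_cols)
  out <- data
  for (wv in c(3, 6)) {
    miss <- if (wv == 3) miss3 else miss6
    rows <- which(out$wave == wv & out$id %in% base$id[miss])
    out[rows, del_cols] <- NA_real_
    out$observed[rows] <- FALSE
  }
  attr(out, "cohort_config") <- config
  attr(out, "asi_bounds") <- attr(data, "asi_bounds")
  attr(out, "missingness_rate") <- c(wave3 = mean(miss3), wave6 = mean(miss6))
  out
}

#' Calibrate a missingness intercept to a target completion rate
#'
#' Solves for the logistic intercept giving an expected marginal missingness
#' of `1 - target_completion` over the configured age and baseline-outcome
#' distributions (by large-sample Monte Carlo integration under a fixed
#' internal seed, so the result is reproducible).
#'
#' @param config A [cohort_config()].
#' @param target_completion Desired expected completion proportion.
#' @param n_mc Monte-Carlo sample size for the integration.
#' @return The calibrated intercept (numeric scalar).
#' @export
calibrate_missingness <- function(config = cohort_config(),
                                  target_completion = 0.849,
                                  n_mc = 2e5) {
  mc <- config$missingness
  n_tot <- sum(config$n_intervention) + sum(config$n_control)
  w <- c(A = (config$n_intervention[["A"]] + config$n_control[["A"]]) / n_tot,
         B = (config$n_intervention[["B"]] + config$n_control[["B"]]) / n_tot)
  drv <- .outcome_baseline[.outcome_baseline$outcome == mc$driver, ]
  sim <- withr_seed(20210325, {
    tr <- sample(c("A", "B"), n_mc, TRUE, prob = w)
    age <- numeric(n_mc)
    for (t in c("A", "B")) {
      a <- config$age[[t]]
      age[tr == t] <- rtnorm(sum(tr == t), a["mean"], a["sd"], a["min"], a["max"])
    }
    y0 <- rtnorm(n_mc, drv$mean, drv$sd, drv$lo, drv$hi)
    list(age = age, y0 = y0)
  })
  lin <- mc$beta_age * (sim$age - 47) + mc$beta_y0 * (sim$y0 - drv$mean)
  f <- function(b0) mean(plogis(b0 + lin)) - (1 - target_completion)
  uniroot(f, lower = -20, upper = 20, tol = 1e-8)$root
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
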