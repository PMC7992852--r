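# Single-mediator product-of-coefficients analysis.
#
# Paths (all OLS, unstandardised):
#   a : M_w ~ group + M_0 + study
#   b, c' : Y_w ~ group + M_w + <baseline covariates> + study
#   c : Y_w ~ group + Y_0 + study
# ab = a*b is the mediated effect; its 95% CI comes from a bias-corrected
# (BC, no acceleration) bootstrap over whole participants.

#' Specify one mediation analysis
#'
#' @param outcome Outcome column name (e.g. `"dass_depression"`).
#' @param mediator `"asi12"` or `"asi6"` (any scored column works).
#' @param wave Follow-up wave: 3 or 6 (months).
#' @param covariates Covariate convention for the b/c' outcome model:
#'   `"footnote"` (default) adjusts for study, baseline mediator and baseline
#'   outcome; `"methods"` for study and baseline outcome only; `"matched"`
#'   uses the identical covariate set (baseline mediator + baseline outcome +
#'   study) in all three models so the decomposition `c = c' + ab` is exact.
#' @param boot Bootstrap replicates for the BC interval (default 5000).
#' @param conf Confidence level (default 0.95).
#' @param missing `"fiml"` (default) fits path estimates by full-information
#'   maximum likelihood; `"complete"` uses listwise-complete OLS.
#' @return A list of class `mediation_spec`.
#' @export
mediation_spec <- function(outcome, mediator = c("asi12", "asi6"),
                           wave = 3,
                           covariates = c("footnote", "methods", "matched"),
                           boot = 5000, conf = 0.95,
                           missing = c("fiml", "complete")) {
  mediator <- if (is.character(mediator) && length(mediator) > 1)
    match.arg(mediator) else mediator
  stopifnot(is.character(outcome), length(outcome) == 1)
  if (!wave %in% c(3, 6)) stop("wave must be 3 or 6")
  if (boot < 1) stop("boot must be >= 1")
  if (conf <= 0 || conf >= 1) stop("conf must be in (0, 1)")
  structure(list(outcome = outcome, mediator = mediator, wave = wave,
                 covariates = match.arg(covariates), boot = boot,
                 conf = conf, missing = match.arg(missing)),
            class = "mediation_spec")
}

#' Reshape scored long data into one row per participant for mediation
#'
#' @param data Scored long data ([score_asi()] output) with `id`, `group`,
#'   `study`, `age`, `wave`, the mediator column and the outcome column.
#' @param spec A [mediation_spec()].
#' @return Wide tibble with columns `id, group, study, age, m0, y0, mw, yw`.
#' @export
pivot_mediation <- function(data, spec) {
  need <- c("id", "group", "study", "wave", spec$mediator, spec$outcome)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("pivot_mediation(): missing column(s): ",
                         paste(miss, collapse = ", "))
  b <- data[data$wave == 0, ]
  w <- data[data$wave == spec$wave, ]
  if (!nrow(b) || !nrow(w)) stop("pivot_mediation(): no rows at wave 0 or ",
                                 spec$wave)
  j <- match(b$id, w$id)
  tibble::tibble(
    id = b$id, group = b$group, study = b$study,
    age = if ("age" %in% names(b)) b$age else NA_real_,
    m0 = b[[spec$mediator]], y0 = b[[spec$outcome]],
    mw = w[[spec$mediator]][j], yw = w[[spec$outcome]][j]
  )
}

# predictor sets per model given the covariate convention
path_terms <- function(covariates) {
  switch(covariates,
    footnote = list(a = c("group", "m0", "study"),
                    b = c("group", "mw", "m0", "y0", "study"),
                    c = c("group", "y0", "study")),
    methods  = list(a = c("group", "m0", "study"),
                    b = c("group", "mw", "y0", "study"),
                    c = c("group", "y0", "study")),
    matched  = list(a = c("group", "m0", "y0", "study"),
                    b = c("group", "mw", "m0", "y0", "study"),
                    c = c("group", "m0", "y0", "study"))
  )
}

# OLS with rank check; returns coefficients, SEs, n
fit_path_model <- function(terms, response, data) {
  d <- data[, c(response, terms)]
  d <- d[complete.cases(d), ]
  if (!nrow(d)) stop("no usable rows for model on ", response)
  f <- stats::reformulate(if (length(terms)) terms else "1",
                          response = response)
  fit <- lm(f, data = d)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  s <- summary(fit)$coefficients
  list(coef = s[, 1], se = s[, 2], p = s[, 4], n = nrow(d), fit = fit)
}

#' Estimate mediation path coefficients (complete-case OLS)
#'
#' Fits the three regressions of the single-mediator model and returns the
#' unstandardised paths: `a` (intervention -> mediator), `b` (mediator ->
#' outcome, adjusted), `c_prime` (direct effect), `c_total` (total effect),
#' the product `ab = a*b` with its Sobel standard error, and the proportion
#' mediated `100*ab/c_total` (reported only when `|c_total|` exceeds a small
#' floor; the ratio is unstable near zero).
#'
#' @param data Scored long data, or an already-pivoted wide frame (with an
#'   `mw` column).
#' @param spec A [mediation_spec()].
#' @return A list of class `path_estimates`.
#' @export
estimate_paths <- function(data, spec) {
  wide <- if ("mw" %in% names(data)) data else pivot_mediation(data, spec)
  tm <- path_terms(spec$covariates)
  fa <- fit_path_model(tm$a, "mw", wide)
  fb <- fit_path_model(tm$b, "yw", wide)
  fc <- fit_path_model(tm$c, "yw", wide)
  make_path_estimates(
    a = fa$coef[["group"]], se_a = fa$se[["group"]], p_a = fa$p[["group"]],
    b = fb$coef[["mw"]], se_b = fb$se[["mw"]], p_b = fb$p[["mw"]],
    c_prime = fb$coef[["group"]], se_cprime = fb$se[["group"]],
    p_cprime = fb$p[["group"]],
    c_total = fc$coef[["group"]], se_c = fc$se[["group"]], p_c = fc$p[["group"]],
    n = c(a = fa$n, b = fb$n, c = fc$n),
    spec = spec, method = "complete-case OLS"
  )
}

make_path_estimates <- function(a, se_a, p_a, b, se_b, p_b, c_prime,
                                se_cprime, p_cprime, c_total, se_c, p_c,
                                n, spec, method, c_floor = 1e-8) {
  ab <- a * b
  se_ab <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)  # Sobel, first order
  prop <- if (abs(c_total) > c_floor) 100 * ab / c_total else NA_real_
  structure(list(
    a = a, se_a = se_a, p_a = p_a,
    b = b, se_b = se_b, p_b = p_b,
    c_prime = c_prime, se_cprime = se_cprime, p_cprime = p_cprime,
    c_total = c_total, se_c = se_c, p_c = p_c,
    ab = ab, se_ab = se_ab,
    prop_mediated = prop,
    sign_consistent = sign(ab) == sign(c_total),
    ci = NULL, conf = spec$conf, n = n, spec = spec, method = method
  ), class = "path_estimates")
}

#' @export
print.path_estimates <- function(x, ...) {
  cat(sprintf("Mediation of %s via %s at %d months (%s)\n",
              x$spec$outcome, x$spec$mediator, x$spec$wave, x$method))
  cat(sprintf("  A %8.3f (%.3f)   B %8.3f (%.3f)\n", x$a, x$se_a, x$b, x$se_b))
  cat(sprintf("  Direct %8.3f (%.3f)   C %8.3f (%.3f)\n",
              x$c_prime, x$se_cprime, x$c_total, x$se_c))
  ci <- if (!is.null(x$ci))
    sprintf(" [%.3f, %.3f]", x$ci[1], x$ci[2]) else ""
  cat(sprintf("  AB %7.3f (%.3f)%s\n", x$ab, x$se_ab, ci))
  if (!is.na(x$prop_mediated)) {
    note <- if (!isTRUE(x$sign_consistent))
      "  (ab and c differ in sign; read descriptively)" else ""
    cat(sprintf("  proportion mediated: %s%%%s\n",
                format_percent(x$prop_mediated), note))
  }
  invisible(x)
}

# reporting convention: round half away from zero
format_percent <- function(x, digits = 0) {
  p <- 10^digits
  sprintf(paste0("%.", digits, "f"), sign(x) * floor(abs(x) * p + 0.5) / p)
}

#' Bias-corrected bootstrap confidence interval for the mediated effect
#'
#' Resamples whole participants (rows of the wide frame, with replacement,
#' both trials pooled) `B` times, recomputes `ab` each time, and forms the
#' bias-corrected percentile interval: `z0 = qnorm(#\{ab* < ab_hat\}/B)`
#' (ties counted half below), endpoints at the bootstrap quantiles
#' `pnorm(2*z0 +/- z_(1+conf)/2)` using the type-6 empirical quantile rule.
#' No acceleration constant is used (BC, not BCa).
#'
#' @param data Scored long data or pivoted wide frame.
#' @param spec A [mediation_spec()] (supplies `boot` and `conf`).
#' @param seed Optional integer seed for the resampling.
#' @param engine `"complete"` (fast listwise OLS refits, default) or
#'   `"fiml"` (refits the FIML likelihood in every resample).
#' @param return_samples Keep the vector of bootstrap `ab*` values.
#' @return List with `lower`, `upper`, `z0`, `ab`, `B`, `conf` (and
#'   `samples` when requested).
#' @export
bc_bootstrap_ci <- function(data, spec, seed = NULL,
                            engine = c("complete", "fiml"),
                            return_samples = FALSE) {
  engine <- match.arg(engine)
  wide <- if ("mw" %in% names(data)) data else pivot_mediation(data, spec)
  if (!is.null(seed)) set.seed(seed)
  B <- spec$boot
  tm <- path_terms(spec$covariates)

  if (engine == "complete") {
    vars <- unique(c("mw", "yw", tm$a, tm$b))
    cc <- wide[complete.cases(wide[, vars]), ]
    n <- nrow(cc)
    if (!n) stop("no usable rows for bootstrap")
    Xa <- cbind(1, as.matrix(cc[, tm$a]))
    Xb <- cbind(1, as.matrix(cc[, tm$b]))
    ia <- 1 + match("group", tm$a)
    ib <- 1 + match("mw", tm$b)
    mwv <- cc$mw
    ywv <- cc$yw
    ab_hat <- .lm.fit(Xa, mwv)$coefficients[ia] *
      .lm.fit(Xb, ywv)$coefficients[ib]
    ab_star <- vapply(seq_len(B), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      .lm.fit(Xa[idx, , drop = FALSE], mwv[idx])$coefficients[ia] *
        .lm.fit(Xb[idx, , drop = FALSE], ywv[idx])$coefficients[ib]
    }, numeric(1))
  } else {
    n <- nrow(wide)
    ab_hat <- fiml_fit(wide, spec)$ab
    ab_star <- vapply(seq_len(B), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      fiml_fit(wide[idx, ], spec)$ab
    }, numeric(1))
  }

  if (length(unique(ab_star)) == 1) {
    warning("degenerate bootstrap distribution: all resampled ab identical")
    ci <- c(ab_star[1], ab_star[1])
    return(list(lower = ci[1], upper = ci[2], z0 = 0, ab = ab_hat, B = B,
                conf = spec$conf,
                samples = if (return_samples) ab_star else NULL))
  }
  p0 <- (sum(ab_star < ab_hat) + 0.5 * sum(ab_star == ab_hat)) / B
  if (p0 <= 0 || p0 >= 1) {
    stop("bias correction undefined: all bootstrap estimates on one side of ",
         "the point estimate; increase the number of bootstrap samples")
  }
  z0 <- qnorm(p0)
  za <- qnorm((1 + spec$conf) / 2)
  probs <- pnorm(c(2 * z0 - za, 2 * z0 + za))
  ci <- unname(quantile(ab_star, probs, type = 6))
  list(lower = ci[1], upper = ci[2], z0 = z0, ab = ab_hat, B = B,
       conf = spec$conf, samples = if (return_samples) ab_star else NULL)
}

#' Exposure-mediator interaction check
#'
#' Augments the outcome model with a `group x mediator` product term; the
#' no-interaction assumption of the product-of-coefficients approach holds
#' when this term is compatible with zero.
#'
#' @inheritParams estimate_paths
#' @return One-row tibble: coefficient, SE, t statistic, p-value, n.
#' @export
interaction_check <- function(data, spec) {
  wide <- if ("mw" %in% names(data)) data else pivot_mediation(data, spec)
  tm <- path_terms(spec$covariates)
  d <- wide[, unique(c("yw", tm$b))]
  d <- d[complete.cases(d), ]
  if (!nrow(d)) stop("no usable rows")
  f <- stats::reformulate(c(tm$b, "group:mw"), response = "yw")
  fit <- lm(f, data = d)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  s <- summary(fit)$coefficients["group:mw", ]
  tibble::tibble(term = "group:mw", estimate = s[1], se = s[2],
                 statistic = s[3], p_value = s[4], n = nrow(d))
}

#' Full mediation analysis: paths, BC interval, interaction check
#'
#' Point estimates use the spec's missing-data strategy (FIML by default;
#' identical to OLS on complete data), the `ab` confidence interval comes
#' from [bc_bootstrap_ci()], and the exposure-mediator interaction check is
#' reported alongside.
#'
#' @inheritParams estimate_paths
#' @param seed Optional seed for the bootstrap resampling.
#' @param boot_engine Bootstrap refit engine, see [bc_bootstrap_ci()].
#' @return A `path_estimates` object with `ci` filled in and an
#'   `interaction` element.
#' @export
mediate <- function(data, spec, seed = NULL,
                    boot_engine = c("complete", "fiml")) {
  boot_engine <- match.arg(boot_engine)
  wide <- if ("mw" %in% names(data)) data else pivot_mediation(data, spec)
  est <- if (spec$missing == "fiml") fiml_fit(wide, spec)
         else estimate_paths(wide, spec)
  ci <- bc_bootstrap_ci(wide, spec, seed = seed, engine = boot_engine)
  est$ci <- c(ci$lower, ci$upper)
  est$z0 <- ci$z0
  est$interaction <- interaction_check(wide, spec)
  est
}
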