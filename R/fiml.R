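# Full-information maximum likelihood for the two-equation path model.
#
# Conditional on the complete exogenous covariates x (group, study, baseline
# mediator/outcome), the follow-up pair (M_w, Y_w) is bivariate normal:
#   M_w = x_a' theta + e_m,                e_m ~ N(0, sm^2)
#   Y_w = x_y' gamma + b * M_w + e_y,      e_y ~ N(0, sy^2)
# Each missingness pattern contributes its marginal normal log-density:
# both observed -> f(M|x) f(Y|M,x); mediator only -> f(M|x); outcome only ->
# the implied marginal N(x_y'gamma + b * x_a'theta, b^2 sm^2 + sy^2).

#' Fit mediation paths by full-information maximum likelihood
#'
#' Maximises the observed-data log-likelihood of the linear-Gaussian path
#' model over all follow-up missingness patterns, so participants with a
#' missing 3- or 6-month mediator or outcome still contribute their observed
#' information. Exogenous covariates (group, study, baselines) must be
#' complete; rows missing them are dropped with a warning. With no missing
#' follow-up data the estimates equal the complete-case OLS solution to
#' optimizer tolerance (the optimizer is always run; there is no shortcut).
#'
#' Standard errors come from the inverse observed information (numerical
#' Hessian at the optimum). The total effect `c` is estimated from its own
#' regression of the observed outcomes (its maximum-likelihood solution,
#' since rows with a missing response contribute nothing to that model).
#'
#' @inheritParams estimate_paths
#' @param max_iter Maximum BFGS iterations.
#' @param reltol Relative log-likelihood convergence tolerance.
#' @return A `path_estimates` object (`method = "FIML"`), with an extra
#'   `patterns` element counting rows per missingness pattern.
#' @export
fiml_fit <- function(data, spec, max_iter = 500, reltol = 1e-10) {
  wide <- if ("mw" %in% names(data)) data else pivot_mediation(data, spec)
  tm <- path_terms(spec$covariates)
  exo <- unique(c(tm$a, setdiff(tm$b, "mw"), tm$c))
  ok <- complete.cases(wide[, exo])
  if (!all(ok)) {
    warning(sum(!ok), " row(s) with incomplete exogenous covariates dropped")
    wide <- wide[ok, ]
  }
  if (!nrow(wide)) stop("no usable rows")

  Xa <- cbind(`(Intercept)` = 1, as.matrix(wide[, tm$a]))
  xyv <- setdiff(tm$b, "mw")
  Xy <- cbind(`(Intercept)` = 1, as.matrix(wide[, xyv]))
  mw <- wide$mw
  yw <- wide$yw
  obs_m <- !is.na(mw)
  obs_y <- !is.na(yw)
  pat <- c(both = sum(obs_m & obs_y), mediator_only = sum(obs_m & !obs_y),
           outcome_only = sum(!obs_m & obs_y), none = sum(!obs_m & !obs_y))

  pa <- ncol(Xa)
  py <- ncol(Xy)
  i_group_a <- match("group", tm$a) + 1L
  i_group_y <- match("group", xyv) + 1L

  # starting values: complete-case OLS on each equation
  cc_a <- .lm.fit(Xa[obs_m, , drop = FALSE], mw[obs_m])
  bo <- obs_m & obs_y
  Xb <- cbind(Xy[bo, , drop = FALSE], mw = mw[bo])
  cc_b <- .lm.fit(Xb, yw[bo])
  start <- c(cc_a$coefficients,
             cc_b$coefficients[seq_len(py)],
             cc_b$coefficients[py + 1],
             log(sd(cc_a$residuals)), log(sd(cc_b$residuals)))

  nll <- function(par) {
    theta <- par[seq_len(pa)]
    gam <- par[pa + seq_len(py)]
    b <- par[pa + py + 1]
    sm <- exp(par[pa + py + 2])
    sy <- exp(par[pa + py + 3])
    mu_m <- drop(Xa %*% theta)
    mu_y_base <- drop(Xy %*% gam)
    ll <- 0
    i <- obs_m & obs_y
    if (any(i)) {
      ll <- ll + sum(dnorm(mw[i], mu_m[i], sm, log = TRUE)) +
        sum(dnorm(yw[i], mu_y_base[i] + b * mw[i], sy, log = TRUE))
    }
    i <- obs_m & !obs_y
    if (any(i)) ll <- ll + sum(dnorm(mw[i], mu_m[i], sm, log = TRUE))
    i <- !obs_m & obs_y
    if (any(i)) {
      ll <- ll + sum(dnorm(yw[i], mu_y_base[i] + b * mu_m[i],
                           sqrt(b^2 * sm^2 + sy^2), log = TRUE))
    }
    -ll
  }

  ngr <- function(par) {
    theta <- par[seq_len(pa)]
    gam <- par[pa + seq_len(py)]
    b <- par[pa + py + 1]
    sm <- exp(par[pa + py + 2])
    sy <- exp(par[pa + py + 3])
    mu_m <- drop(Xa %*% theta)
    mu_y_base <- drop(Xy %*% gam)
    g_th <- numeric(pa); g_ga <- numeric(py)
    g_b <- g_lsm <- g_lsy <- 0
    i <- obs_m
    if (any(i)) {  # mediator equation (both + mediator-only patterns)
      rm_ <- (mw[i] - mu_m[i]) / sm^2
      g_th <- g_th + drop(crossprod(Xa[i, , drop = FALSE], rm_))
      g_lsm <- g_lsm + sum((mw[i] - mu_m[i])^2 / sm^2 - 1)
    }
    i <- obs_m & obs_y
    if (any(i)) {  # outcome equation given the observed mediator
      ry <- yw[i] - mu_y_base[i] - b * mw[i]
      g_ga <- g_ga + drop(crossprod(Xy[i, , drop = FALSE], ry / sy^2))
      g_b <- g_b + sum(ry * mw[i]) / sy^2
      g_lsy <- g_lsy + sum(ry^2 / sy^2 - 1)
    }
    i <- !obs_m & obs_y
    if (any(i)) {  # marginal outcome density when the mediator is missing
      v <- b^2 * sm^2 + sy^2
      r <- yw[i] - mu_y_base[i] - b * mu_m[i]
      dv <- -1 / (2 * v) + r^2 / (2 * v^2)
      g_th <- g_th + drop(crossprod(Xa[i, , drop = FALSE], b * r / v))
      g_ga <- g_ga + drop(crossprod(Xy[i, , drop = FALSE], r / v))
      g_b <- g_b + sum(r * mu_m[i]) / v + sum(dv) * 2 * b * sm^2
      g_lsm <- g_lsm + sum(dv) * 2 * b^2 * sm^2
      g_lsy <- g_lsy + sum(dv) * 2 * sy^2
    }
    -c(g_th, g_ga, g_b, g_lsm, g_lsy)
  }

  opt <- optim(start, nll, gr = ngr, method = "BFGS",
               control = list(maxit = max_iter, reltol = reltol))
  if (opt$convergence != 0) {
    g <- ngr(opt$par)
    stop("FIML did not converge (code ", opt$convergence,
         "); final gradient norm ", format(sqrt(sum(g^2)), digits = 4))
  }
  # Newton polish: BFGS stops on the likelihood scale, which can leave the
  # flattest coefficients several decimals short of the stationary point
  par <- opt$par
  H <- stats::optimHess(par, nll, ngr)
  for (k in 1:5) {
    g <- ngr(par)
    if (sqrt(sum(g^2)) < 1e-9) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- par - step
    if (!is.finite(nll(cand)) || nll(cand) > nll(par) + 1e-6) break
    par <- cand
    H <- stats::optimHess(par, nll, ngr)
  }
  opt$par <- par
  opt$value <- nll(par)
  opt$hessian <- H
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    stop("FIML information matrix is singular (implied covariance not ",
         "positive definite?)")
  })
  se <- sqrt(pmax(diag(vc), 0))

  a_hat <- opt$par[i_group_a]
  se_a <- se[i_group_a]
  cpr <- opt$par[pa + i_group_y]
  se_cpr <- se[pa + i_group_y]
  b_hat <- opt$par[pa + py + 1]
  se_b <- se[pa + py + 1]

  fc <- fit_path_model(tm$c, "yw", wide)
  est <- make_path_estimates(
    a = a_hat, se_a = se_a, p_a = 2 * pnorm(-abs(a_hat / se_a)),
    b = b_hat, se_b = se_b, p_b = 2 * pnorm(-abs(b_hat / se_b)),
    c_prime = cpr, se_cprime = se_cpr,
    p_cprime = 2 * pnorm(-abs(cpr / se_cpr)),
    c_total = fc$coef[["group"]], se_c = fc$se[["group"]], p_c = fc$p[["group"]],
    n = c(a = sum(obs_m), b = sum(obs_m & obs_y), c = fc$n,
          fiml = nrow(wide)),
    spec = spec, method = "FIML"
  )
  est$patterns <- pat
  est$logLik <- -opt$value
  est
}

num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
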