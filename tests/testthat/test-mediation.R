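# Path estimation, the OLS decomposition identity, and the bias-corrected
# bootstrap for the mediated effect.

test_that("path coefficients match an explicit normal-equations solution", {
  # tiny hand-checkable mediation frame; oracle solves (X'X)^-1 X'y directly
  set.seed(31)
  n <- 12
  wide <- tibble::tibble(
    id = as.character(1:n),
    group = rep(0:1, each = n / 2),
    study = rep(c(0, 1), n / 2),
    age = 40 + 1:n,
    m0 = rnorm(n, 50, 5), y0 = rnorm(n, 10, 3),
    mw = rnorm(n, 52, 6), yw = rnorm(n, 9, 3))
  spec <- quick_spec()
  est <- estimate_paths(wide, spec)
  ols <- function(X, y) solve(crossprod(X), crossprod(X, y))
  Xa <- cbind(1, wide$group, wide$m0, wide$study)
  Xb <- cbind(1, wide$group, wide$mw, wide$m0, wide$y0, wide$study)
  Xc <- cbind(1, wide$group, wide$y0, wide$study)
  expect_equal(est$a, ols(Xa, wide$mw)[2], tolerance = 1e-10)
  expect_equal(est$b, ols(Xb, wide$yw)[3], tolerance = 1e-10)
  expect_equal(est$c_prime, ols(Xb, wide$yw)[2], tolerance = 1e-10)
  expect_equal(est$c_total, ols(Xc, wide$yw)[2], tolerance = 1e-10)
  expect_equal(est$ab, est$a * est$b)
})

test_that("a response equal to a design column recovers the unit coefficient", {
  set.seed(77)
  wide <- tibble::tibble(
    group = rep(0:1, 10), study = rep(c(0, 0, 1, 1), 5),
    m0 = rnorm(20), y0 = rnorm(20), mw = rnorm(20))
  wide$yw <- wide$y0
  # the exact fit makes summary() grumble about perfect residuals
  est <- suppressWarnings(estimate_paths(wide, quick_spec()))
  expect_equal(est$b, 0, tolerance = 1e-12)
  expect_equal(est$c_prime, 0, tolerance = 1e-12)
  expect_equal(est$c_total, 0, tolerance = 1e-12)
  # and an intercept-only fit returns the mean of the response
  f0 <- asimed:::fit_path_model(character(0), "yw",
                                tibble::tibble(yw = c(1, 4, 7)))
  expect_equal(unname(f0$coef[1]), 4)
})

test_that("matched covariate sets give the exact effect decomposition", {
  for (i in 1:5) {
    s <- quick_scored(quick_config(seed = 40 + i))
    est <- estimate_paths(s, quick_spec(covariates = "matched"))
    expect_lt(abs(est$c_total - (est$c_prime + est$ab)), 1e-10)
  }
  # the footnote covariate sets do not admit the identity in general
  s <- quick_scored(quick_config(seed = 46))
  est <- estimate_paths(s, quick_spec(covariates = "footnote"))
  expect_gt(abs(est$c_total - (est$c_prime + est$ab)), 1e-10)
})

test_that("proportion mediated is guarded near a null total effect", {
  s <- quick_scored(quick_config(seed = 50))
  est <- estimate_paths(s, quick_spec())
  expect_equal(est$prop_mediated, 100 * est$ab / est$c_total)
  # degenerate: an exactly-null total effect reports a missing proportion
  pe <- asimed:::make_path_estimates(
    a = 1, se_a = 0.1, p_a = 0.01, b = 0.5, se_b = 0.1, p_b = 0.01,
    c_prime = -0.5, se_cprime = 0.1, p_cprime = 0.5,
    c_total = 0, se_c = 0.1, p_c = 1, n = c(a = 10, b = 10, c = 10),
    spec = quick_spec(), method = "test")
  expect_true(is.na(pe$prop_mediated))
})

test_that("rank-deficient designs fail loudly", {
  wide <- tibble::tibble(group = rep(0:1, 10), study = rep(0:1, 10),
                         m0 = rnorm(20), y0 = rnorm(20),
                         mw = rnorm(20), yw = rnorm(20))
  expect_error(estimate_paths(wide, quick_spec()), "collinear")
  # constant mediator: interaction model cannot be identified
  wide2 <- tibble::tibble(group = rep(0:1, 10), study = rep(c(0, 1), 10),
                          m0 = rnorm(20), y0 = rnorm(20),
                          mw = rep(3, 20), yw = rnorm(20))
  expect_error(interaction_check(wide2, quick_spec()), "collinear")
})

test_that("BC bootstrap matches an independently coded resampling loop", {
  s <- quick_scored(quick_config(n_int = c(A = 15, B = 15),
                                 n_con = c(A = 10, B = 10), seed = 8))
  spec <- quick_spec(boot = 200)
  res <- bc_bootstrap_ci(s, spec, seed = 123, return_samples = TRUE)

  # oracle: plain lm() refits under the same documented resampling rule
  wide <- pivot_mediation(s, spec)
  vars <- c("mw", "yw", "group", "m0", "study", "y0")
  cc <- wide[complete.cases(wide[, vars]), ]
  n <- nrow(cc)
  ab_hat <- coef(lm(mw ~ group + m0 + study, cc))["group"] *
    coef(lm(yw ~ group + mw + m0 + y0 + study, cc))["mw"]
  set.seed(123)
  ab_star <- replicate(200, {
    d <- cc[sample.int(n, n, replace = TRUE), ]
    unname(coef(lm(mw ~ group + m0 + study, d))["group"] *
             coef(lm(yw ~ group + mw + m0 + y0 + study, d))["mw"])
  })
  z0 <- qnorm((sum(ab_star < ab_hat) + 0.5 * sum(ab_star == ab_hat)) / 200)
  probs <- pnorm(2 * z0 + c(-1, 1) * qnorm(0.975))
  ci <- unname(quantile(ab_star, probs, type = 6))
  expect_equal(res$samples, ab_star, tolerance = 1e-12)
  expect_equal(res$z0, z0, tolerance = 1e-12)
  expect_equal(c(res$lower, res$upper), ci, tolerance = 1e-12)
})

test_that("bootstrap determinism and degenerate cases", {
  s <- quick_scored(quick_config(seed = 12))
  spec <- quick_spec(boot = 80)
  r1 <- bc_bootstrap_ci(s, spec, seed = 5)
  r2 <- bc_bootstrap_ci(s, spec, seed = 5)
  expect_identical(r1[c("lower", "upper", "z0")], r2[c("lower", "upper", "z0")])

  # B = 1: single resample, degenerate interval at that resample's ab
  spec1 <- quick_spec(boot = 1)
  expect_warning(r <- bc_bootstrap_ci(s, spec1, seed = 5), "degenerate")
  expect_equal(r$lower, r$upper)

  # symmetric bootstrap distribution about ab_hat: z0 = 0 and the BC
  # interval reduces to the percentile interval (checked via the formula)
  ab_star <- c(-2, -1, 0, 1, 2)
  z0 <- qnorm((sum(ab_star < 0) + 0.5 * sum(ab_star == 0)) / 5)
  expect_equal(z0, 0)
})

test_that("interaction check is well calibrated without an interaction", {
  p <- sapply(1:20, function(i) {
    s <- quick_scored(quick_config(seed = 900 + i))
    interaction_check(s, quick_spec())$p_value
  })
  # under H0 p-values are uniform: at 20 draws the mean is within ~3 SE
  expect_lt(abs(mean(p) - 0.5), 3 * sqrt(1 / 12 / 20))
})

test_that("mediate() assembles estimates, interval and interaction check", {
  s <- quick_scored(quick_config(seed = 60))
  spec <- quick_spec(boot = 99, missing = "complete")
  fit <- mediate(s, spec, seed = 4)
  expect_s3_class(fit, "path_estimates")
  expect_length(fit$ci, 2)
  expect_lte(fit$ci[1], fit$ci[2])
  expect_s3_class(fit$interaction, "tbl_df")
  out <- capture.output(print(fit))
  expect_true(any(grepl("AB", out)))
})
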