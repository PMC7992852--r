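# Scoring of the composite index: rescaling formula, pooled bounds,
# dimension derivation, additivity and the short form.

test_that("rescaling hits the endpoints and the reversed midpoint", {
  expect_equal(rescale_dimension(2, min = 2, max = 8), 0)
  expect_equal(rescale_dimension(8, min = 2, max = 8), 10)
  expect_equal(rescale_dimension(5, min = 2, max = 8, reversed = TRUE), 5)
  # clipping to frozen bounds
  expect_equal(rescale_dimension(100, min = 2, max = 8), 10)
  expect_equal(rescale_dimension(-5, min = 2, max = 8), 0)
  # degenerate bounds score n/2, loudly
  expect_warning(v <- rescale_dimension(c(3, 3), min = 3, max = 3), "degenerate")
  expect_equal(v, c(5, 5))
  expect_error(rescale_dimension(Inf, 0, 1), "non-finite")
})

test_that("pooled bounds scan all waves and ignore missing values", {
  p <- toy_profile(3)
  p$mvpa_minutes <- c(1, NA, 5)
  p$sitting_minutes <- c(2, 8, 5)
  b <- compute_bounds(p)
  expect_s3_class(b, "asi_bounds")
  expect_equal(b$min[b$column == "mvpa_minutes"], 1)
  expect_equal(b$max[b$column == "mvpa_minutes"], 5)
  expect_equal(unname(unlist(b[b$column == "sitting_minutes", c("min", "max")])),
               c(2, 8))
  # single profile: min == max everywhere
  b1 <- compute_bounds(toy_profile(1))
  expect_true(all(b1$min == b1$max))
  # a dimension with no observed values is a hard error naming it
  p$sleep_efficiency <- NA_real_
  expect_error(compute_bounds(p), "sleep_efficiency")
})

test_that("questionnaire fields map onto the twelve dimensions", {
  raw <- tibble::tibble(
    walking_minutes = 60, moderate_minutes = 60, vigorous_minutes = 30,
    mvpa_sessions = 4, rt_days = 0, sitting_minutes = 500,
    daytime_sleepiness = 1, sleep_quality = 2, bed_time = "23:00",
    sleep_duration_hours = 8, time_in_bed_hours = 9,
    bedtime_variability = 2, waketime_variability = 1)
  d <- derive_dimensions(raw)
  expect_equal(d$mvpa_minutes, 150)
  expect_equal(d$vigorous_fraction, 0.2)
  expect_equal(d$activity_type, 1)            # MVPA but no RT
  expect_equal(d$sleep_midpoint, 180)         # 23:00 + 4 h = 03:00
  expect_equal(d$sleep_timing, 1)             # inside the 02:00-04:00 window
  expect_equal(d$sleep_variability, 3)
  expect_equal(d$sleep_duration_ok, 1)

  # sleep efficiency 7.5/9 h = 83.33%
  raw$sleep_duration_hours <- 7.5
  expect_equal(derive_dimensions(raw)$sleep_efficiency, 83.33333333,
               tolerance = 1e-8)

  # no activity at all
  raw0 <- raw
  raw0$walking_minutes <- 0; raw0$moderate_minutes <- 0
  raw0$vigorous_minutes <- 0; raw0$rt_days <- 0
  d0 <- derive_dimensions(raw0)
  expect_equal(d0$activity_type, 0)
  expect_equal(d0$vigorous_fraction, 0)       # defined as 0 at zero MVPA

  raw$bed_time <- "25:99"
  expect_error(derive_dimensions(raw), "clock")
})

test_that("index range: best-case profile scores 120, worst-case 0", {
  hi <- within(toy_profile(1), {
    mvpa_sessions <- 10; rt_days <- 7; vigorous_fraction <- 0.9
    mvpa_minutes <- 600; sitting_minutes <- 200; daytime_sleepiness <- 0
    sleep_quality <- 0; sleep_midpoint <- 180; sleep_variability <- 0
    sleep_efficiency <- 98; sleep_duration_hours <- 8
  })
  lo <- within(toy_profile(1), {
    mvpa_sessions <- 0; rt_days <- 0; vigorous_fraction <- 0
    mvpa_minutes <- 0; sitting_minutes <- 700; daytime_sleepiness <- 3
    sleep_quality <- 3; sleep_midpoint <- 500; sleep_variability <- 8
    sleep_efficiency <- 50; sleep_duration_hours <- 4
  })
  b <- compute_bounds(dplyr::bind_rows(toy_profile(1), hi, lo))
  best <- lapply(seq_len(nrow(b)), function(i)
    if (b$reversed[i]) b$min[i] else b$max[i])
  worst <- lapply(seq_len(nrow(b)), function(i)
    if (b$reversed[i]) b$max[i] else b$min[i])
  names(best) <- names(worst) <- b$column
  sb <- compose_asi(tibble::as_tibble(best), b)
  sw <- compose_asi(tibble::as_tibble(worst), b)
  expect_equal(sb$asi12, 120)
  expect_equal(sb$asi6, 60)
  expect_equal(sw$asi12, 0)
  expect_equal(sw$asi6, 0)
  # half best / half worst sums to 60 by additivity
  mixed <- best
  flip <- b$column[seq_len(6)]
  mixed[flip] <- worst[flip]
  expect_equal(compose_asi(tibble::as_tibble(mixed), b)$asi12, 60)
})

test_that("scored data satisfies additivity, range and subset invariants", {
  s <- quick_scored()
  sc <- as.matrix(s[, paste0("score_", asi_dimensions()$dimension)])
  expect_true(all(sc >= 0 & sc <= 10, na.rm = TRUE))
  expect_equal(s$asi12, rowSums(sc))
  expect_true(all(s$asi12 >= 0 & s$asi12 <= 120, na.rm = TRUE))
  sub <- asi_dimensions()
  expect_equal(s$asi6,
               rowSums(sc[, paste0("score_", sub$dimension[sub$in_asi6])]))
  expect_true(all(s$asi6 <= s$asi12, na.rm = TRUE))
  # ASI-6 uses exactly six dimensions
  expect_equal(sum(sub$in_asi6), 6)
})

test_that("a missing dimension makes the wave's index missing, not pro-rated", {
  d <- simulate_cohort(quick_config())
  d$sleep_efficiency[5] <- NA
  s2 <- score_asi(d, compute_bounds(d))
  expect_true(is.na(s2$asi12[5]))
  expect_true(is.na(s2$asi6[5]))
  expect_false(is.na(s2$score_sitting[5]))  # other dimensions still scored
})

test_that("monotonicity and affine invariance of the rescaling", {
  set.seed(42)
  for (rep in 1:5) {
    x <- sort(runif(20, 0, 50))
    sc <- rescale_dimension(x, min(x), max(x))
    expect_true(all(diff(sc) >= 0))
    rv <- rescale_dimension(x, min(x), max(x), reversed = TRUE)
    expect_true(all(diff(rv) <= 0))
    # affine re-expression of units with recomputed bounds changes nothing
    y <- 3.7 * x - 12
    expect_equal(rescale_dimension(y, min(y), max(y)), sc, tolerance = 1e-12)
  }
})

test_that("dimension correlations are rank correlations with midranks", {
  # hand-computed Spearman for a 4-point set with one tie:
  # y = (2,1,2,4) has midranks (2.5, 1, 2.5, 4); r = 3/sqrt(5*4.5)
  s <- tibble::tibble(score_a = 1:4, score_b = c(2, 1, 2, 4))
  m <- dimension_correlations(s, include_total = FALSE)
  expect_equal(dim(m), c(2, 2))
  expect_equal(unname(diag(m)), c(1, 1))
  expect_equal(m["score_a", "score_b"], 3 / sqrt(22.5), tolerance = 1e-12)
  # strictly monotone pair
  s2 <- tibble::tibble(score_a = 1:6, score_b = exp(1:6))
  expect_equal(dimension_correlations(s2, include_total = FALSE)[1, 2], 1)
  # constant column: undefined, reported missing
  s3 <- tibble::tibble(score_a = 1:5, score_b = rep(2, 5))
  expect_true(is.na(dimension_correlations(s3, include_total = FALSE)[1, 2]))
  expect_error(dimension_correlations(s[0, ]), "3 complete rows")
})

test_that("bounds survive a JSON round trip", {
  b <- compute_bounds(quick_scored())
  f <- tempfile(fileext = ".json")
  write_bounds_json(b, f)
  b2 <- read_bounds_json(f)
  expect_equal(b2$min, b$min)
  expect_equal(b2$max, b$max)
  expect_equal(b2$reversed, b$reversed)
  unlink(f)
})
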