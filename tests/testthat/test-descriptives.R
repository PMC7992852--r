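# Effect sizes, severity banding, change coding, and completer comparisons.

test_that("Cohen's d uses the pooled SD and behaves under symmetry", {
  es <- cohens_d(12, 4, 30, 10, 4, 30)
  expect_equal(es$d, 0.5)
  expect_equal(es$s_pooled, 4)
  # equal means give zero
  expect_equal(cohens_d(5, 2, 20, 5, 3, 25)$d, 0)
  # antisymmetric under group swap
  es2 <- cohens_d(10, 4, 30, 12, 4, 30)
  expect_equal(es2$d, -es$d)
  expect_equal(es2$ci, -rev(es$ci))
  # invariant under common affine rescaling
  es3 <- cohens_d(2 * 12 + 7, 2 * 4, 30, 2 * 10 + 7, 2 * 4, 30)
  expect_equal(es3$d, es$d)
  expect_error(cohens_d(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("vector interface agrees with the summary-statistic interface", {
  set.seed(21)
  x <- rnorm(40, 1); y <- rnorm(30)
  es <- cohens_d_data(x, y)
  expect_equal(es$d,
               cohens_d(mean(x), sd(x), 40, mean(y), sd(y), 30)$d)
})

test_that("severity bands partition the score line, closed on the left", {
  expect_equal(as.character(classify_severity(0, "depression")), "normal")
  expect_equal(as.character(classify_severity(9, "depression")), "normal")
  expect_equal(as.character(classify_severity(10, "depression")), "mild")
  expect_equal(as.character(classify_severity(14, "depression")), "moderate")
  expect_equal(as.character(classify_severity(21, "depression")), "severe")
  expect_equal(as.character(classify_severity(28, "depression")),
               "extremely severe")
  expect_equal(as.character(classify_severity(8, "anxiety")), "mild")
  expect_equal(as.character(classify_severity(15, "stress")), "mild")
  # monotone in the score
  sc <- seq(0, 42, by = 0.5)
  bands <- classify_severity(sc, "stress")
  expect_true(all(diff(as.integer(bands)) >= 0))
  expect_error(classify_severity(-1, "depression"), "negative")
  # halved thresholds for raw 0-21 scores
  th <- dass_thresholds(doubled = FALSE)
  expect_equal(th$depression, c(0, 5, 7, 10.5, 14))
})

test_that("severity change codes improvement as any band reduction", {
  b <- function(s) classify_severity(s, "depression")
  expect_equal(as.character(classify_change(b(15), b(11))), "improved")
  expect_equal(as.character(classify_change(b(15), b(2))), "improved")
  expect_equal(as.character(classify_change(b(2), b(2))),
               "no-change-or-worsened")
  expect_equal(as.character(classify_change(b(11), b(25))),
               "no-change-or-worsened")
})

test_that("completer comparisons use t and chi-square machinery correctly", {
  # identical groups: t = 0, p = 1
  g <- c(1, 2, 3, 4)
  tt <- t.test(g, g, var.equal = TRUE)
  expect_equal(unname(tt$statistic), 0)
  expect_equal(tt$p.value, 1)
  # hand-computed chi-square without continuity correction:
  # (30,10;10,30): all expected cells 20, X2 = 4 * (10^2/20) = 20
  tab <- matrix(c(30, 10, 10, 30), 2)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(unname(ct$statistic), 20)
  # balanced table gives exactly zero
  ct0 <- suppressWarnings(chisq.test(matrix(c(10, 10, 10, 10), 2),
                                     correct = FALSE))
  expect_equal(unname(ct0$statistic), 0)

  d <- simulate_cohort(cohort_config(seed = 81))
  cmp <- compare_completers(d)
  expect_true(all(c("age", "dass_depression", "sex") %in% cmp$variable))
  comp <- attr(cmp, "completion")
  expect_equal(unname(comp["completers"] + (325 - comp["completers"])), 325)
  expect_equal(unname(comp["rate"]), unname(comp["completers"] / 325))
  # attrition is MAR on age and baseline severity: both show up
  age_row <- cmp[cmp$variable == "age", ]
  expect_gt(age_row$completers, age_row$non_completers)
})

test_that("ASI change differs by responder status when built to differ", {
  s <- quick_scored(quick_config(n_int = c(A = 300, B = 300),
                                 n_con = c(A = 200, B = 200), seed = 82,
                                 b_true = -0.3))
  es <- asi_change_by_response(s, "depression")
  expect_s3_class(es, "effect_size")
  # a strongly negative b makes improvers' index rise more
  expect_gt(es$d, 0)
  expect_equal(nrow(es$groups), 2)

  # degenerate: nobody improves -> warning and NA
  s0 <- s
  s0$dass_depression[s0$wave == 3] <- s0$dass_depression[s0$wave == 0][
    match(s0$id[s0$wave == 3], s0$id[s0$wave == 0])] + 20
  expect_warning(r <- asi_change_by_response(s0, "depression"), "fewer than 2")
  expect_true(is.na(r))
})

test_that("baseline characteristics table sums and percentages add up", {
  d <- simulate_cohort(cohort_config(seed = 84))
  tab <- baseline_characteristics(d)
  n <- attr(tab, "n")
  expect_equal(unname(n), c(190, 135, 325))
  age <- tab[tab$variable == "age", ]
  b0 <- d[d$wave == 0, ]
  expect_equal(age$total, mean(b0$age))
  sexes <- tab[tab$variable == "sex", ]
  expect_equal(sum(sexes$total), 325)
  expect_equal(sum(sexes$total_sd), 100)
  dep <- tab[tab$variable == "dass_depression_category", ]
  expect_equal(nrow(dep), 5)
  expect_equal(sum(dep$intervention), 190)
})

test_that("group descriptive table mirrors the scored data", {
  s <- quick_scored(quick_config(seed = 83))
  tab <- asi_descriptives(s)
  r <- tab[tab$variable == "asi12" & tab$wave == 3, ]
  w3 <- s[s$wave == 3, ]
  expect_equal(r$mean_int, mean(w3$asi12[w3$group == 1], na.rm = TRUE))
  expect_equal(r$n_con, sum(w3$group == 0 & !is.na(w3$asi12)))
  es <- cohens_d_data(w3$asi12[w3$group == 1], w3$asi12[w3$group == 0])
  expect_equal(r$d, es$d)
  expect_true(is.na(tab$d[tab$wave == 0][1]))  # no baseline effect size
})
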