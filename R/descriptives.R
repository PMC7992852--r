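# Descriptive statistics: standardized group differences, DASS-21 severity
# banding and change coding, completer/non-completer comparisons, and the
# exploratory index-change-by-responder analysis.

#' Cohen's d from group summary statistics
#'
#' Standardized mean difference `(mean1 - mean2) / s_pooled` with
#' `s_pooled^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2)`. By convention
#' group 1 is the intervention arm, so positive d favours intervention. The
#' confidence interval uses the large-sample variance
#' `(n1+n2)/(n1*n2) + d^2 / (2*(n1+n2))`.
#'
#' @param mean1,sd1,n1 Summary statistics for group 1 (intervention).
#' @param mean2,sd2,n2 Summary statistics for group 2 (control).
#' @param conf Confidence level for the interval.
#' @return A list of class `effect_size`: `d`, `ci`, the inputs, `s_pooled`.
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2, conf = 0.95) {
  if (n1 < 2 || n2 < 2) stop("cohens_d(): each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("cohens_d(): SDs must be positive")
  s_pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  d <- (mean1 - mean2) / s_pooled
  v <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  za <- qnorm((1 + conf) / 2)
  structure(list(d = d, ci = c(d - za * sqrt(v), d + za * sqrt(v)),
                 mean1 = mean1, sd1 = sd1, n1 = n1,
                 mean2 = mean2, sd2 = sd2, n2 = n2,
                 s_pooled = s_pooled, conf = conf),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.2f (%.2f, %.2f)\n", x$d, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Cohen's d from two vectors of observations
#' @param x,y Numeric vectors (intervention, control); `NA` dropped.
#' @param conf Confidence level.
#' @return See [cohens_d()].
#' @export
cohens_d_data <- function(x, y, conf = 0.95) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  cohens_d(mean(x), sd(x), length(x), mean(y), sd(y), length(y), conf = conf)
}

.dass_cache <- new.env(parent = emptyenv())

#' DASS-21 severity threshold table
#'
#' Band cutpoints (closed on the left) for the doubled 0-42 DASS-21 subscale
#' scores, read from the editable JSON resource shipped with the package so
#' the thresholds are data, not code. Pass `doubled = FALSE` for raw 0-21
#' subscale sums (cutpoints halved).
#'
#' @param doubled Are scores on the conventional doubled scale?
#' @param path Override the JSON resource path.
#' @return Named list of numeric cutpoint vectors plus a `bands` attribute.
#' @export
dass_thresholds <- function(doubled = TRUE, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dass21_severity.json", package = "asimed")
  }
  key <- paste0(path, doubled)
  if (is.null(.dass_cache[[key]])) {
    raw <- jsonlite::fromJSON(path)
    th <- lapply(raw$thresholds, function(v) if (doubled) v else v / 2)
    attr(th, "bands") <- raw$bands
    .dass_cache[[key]] <- th
  }
  .dass_cache[[key]]
}

#' Classify a DASS-21 subscale score into a severity band
#'
#' @param score Non-negative subscale score(s).
#' @param subscale `"depression"`, `"anxiety"` or `"stress"`.
#' @param thresholds Threshold table, see [dass_thresholds()].
#' @return Ordered factor (normal < mild < moderate < severe <
#'   extremely severe); `NA` scores stay `NA`.
#' @export
classify_severity <- function(score, subscale = c("depression", "anxiety", "stress"),
                              thresholds = dass_thresholds()) {
  subscale <- match.arg(subscale)
  if (any(score < 0, na.rm = TRUE)) stop("classify_severity(): negative score")
  bands <- attr(thresholds, "bands")
  cuts <- thresholds[[subscale]]
  idx <- findInterval(score, cuts)  # closed-left: boundary enters upper band
  factor(bands[idx], levels = bands, ordered = TRUE)
}

#' Code severity change between two assessments
#'
#' Improvement is a reduction of at least one severity level (e.g. moderate
#' to mild or normal); anything else is no change/worsening.
#'
#' @param band_baseline,band_followup Ordered severity bands from
#'   [classify_severity()].
#' @return Factor with levels `improved`, `no-change-or-worsened`.
#' @export
classify_change <- function(band_baseline, band_followup) {
  out <- ifelse(band_followup < band_baseline, "improved",
                "no-change-or-worsened")
  factor(out, levels = c("improved", "no-change-or-worsened"))
}

#' Compare survey completers with non-completers at a follow-up wave
#'
#' Non-completers are participants whose follow-up assessment at `wave` is
#' missing (the `observed` flag). Continuous baseline characteristics are
#' compared with independent t-tests and categorical ones with chi-square
#' tests (no continuity correction).
#'
#' @param data Long cohort data with `id`, `wave`, `observed`.
#' @param wave Follow-up wave defining completion (default 3).
#' @param continuous,categorical Baseline variables to compare.
#' @return Tibble (variable, type, statistic, df, p_value, completer/
#'   non-completer summaries) with attribute `completion` (completers,
#'   baseline n, rate).
#' @export
compare_completers <- function(data, wave = 3,
                               continuous = c("age", .outcomes),
                               categorical = "sex") {
  base <- data[data$wave == 0, ]
  fw <- data[data$wave == wave, ]
  comp <- fw$id[fw$observed]
  base$completer <- base$id %in% comp
  if (all(base$completer) || !any(base$completer)) {
    stop("compare_completers(): one of the groups is empty")
  }
  rows <- list()
  for (v in continuous) {
    tt <- t.test(base[[v]][base$completer], base[[v]][!base$completer],
                 var.equal = TRUE)
    rows[[v]] <- tibble::tibble(
      variable = v, type = "continuous",
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value,
      completers = mean(base[[v]][base$completer], na.rm = TRUE),
      non_completers = mean(base[[v]][!base$completer], na.rm = TRUE))
  }
  for (v in categorical) {
    tab <- table(base[[v]], base$completer)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    rows[[v]] <- tibble::tibble(
      variable = v, type = "categorical",
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p_value = ct$p.value, completers = NA_real_, non_completers = NA_real_)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "completion") <- c(completers = length(unique(comp)),
                               baseline_n = nrow(base),
                               rate = length(unique(comp)) / nrow(base))
  out
}

#' ASI change by symptom-severity response
#'
#' Exploratory comparison of the ASI-12 change from baseline to 3 months
#' between participants whose severity band improved and those with no
#' change or worsening on the chosen subscale.
#'
#' @param scored Scored long data ([score_asi()]) with the DASS columns.
#' @param subscale `"depression"`, `"anxiety"` or `"stress"`.
#' @param mediator Index column to difference (default `asi12`).
#' @param thresholds Severity table, see [dass_thresholds()].
#' @return An `effect_size` (Cohen's d, improved minus not-improved) with
#'   per-group change summaries attached; `NA` with a warning when a
#'   response group is empty or has a single member.
#' @export
asi_change_by_response <- function(scored,
                                   subscale = c("depression", "anxiety", "stress"),
                                   mediator = "asi12",
                                   thresholds = dass_thresholds()) {
  subscale <- match.arg(subscale)
  col <- paste0("dass_", subscale)
  b <- scored[scored$wave == 0, ]
  f <- scored[scored$wave == 3, ]
  j <- match(b$id, f$id)
  change <- f[[mediator]][j] - b[[mediator]]
  # scores below the instrument floor are banded at the floor
  resp <- classify_change(
    classify_severity(pmax(b[[col]], 0), subscale, thresholds),
    classify_severity(pmax(f[[col]][j], 0), subscale, thresholds))
  keep <- !is.na(change) & !is.na(resp)
  ch_i <- change[keep & resp == "improved"]
  ch_n <- change[keep & resp == "no-change-or-worsened"]
  if (length(ch_i) < 2 || length(ch_n) < 2) {
    warning("asi_change_by_response(): a response group has fewer than 2 ",
            "members; returning NA")
    return(NA)
  }
  es <- cohens_d_data(ch_i, ch_n)
  es$groups <- tibble::tibble(
    response = c("improved", "no-change-or-worsened"),
    n = c(length(ch_i), length(ch_n)),
    mean_change = c(mean(ch_i), mean(ch_n)),
    sd_change = c(sd(ch_i), sd(ch_n)))
  es
}

#' Baseline characteristics by randomised group
#'
#' Sample-description table: age, sex, and every outcome scale at baseline
#' as mean (SD) or n (%) per arm and pooled, plus DASS-21 severity-category
#' counts per subscale.
#'
#' @param data Long cohort data with a wave-0 row per participant.
#' @param thresholds Severity table for the category counts.
#' @return Tibble: variable, level (`NA` for continuous rows), statistic
#'   (`"mean_sd"` or `"n_pct"`), and per-group/total summary columns.
#' @export
baseline_characteristics <- function(data, thresholds = dass_thresholds()) {
  b <- data[data$wave == 0, ]
  rows <- list()
  cont_row <- function(var) {
    x1 <- b[[var]][b$group == 1]; x0 <- b[[var]][b$group == 0]
    tibble::tibble(variable = var, level = NA_character_,
                   statistic = "mean_sd",
                   intervention = mean(x1, na.rm = TRUE),
                   intervention_sd = sd(x1, na.rm = TRUE),
                   control = mean(x0, na.rm = TRUE),
                   control_sd = sd(x0, na.rm = TRUE),
                   total = mean(b[[var]], na.rm = TRUE),
                   total_sd = sd(b[[var]], na.rm = TRUE))
  }
  cat_rows <- function(var, values) {
    dplyr::bind_rows(lapply(values, function(v) {
      n1 <- sum(b[[var]][b$group == 1] == v, na.rm = TRUE)
      n0 <- sum(b[[var]][b$group == 0] == v, na.rm = TRUE)
      tibble::tibble(variable = var, level = as.character(v),
                     statistic = "n_pct",
                     intervention = n1,
                     intervention_sd = 100 * n1 / sum(b$group == 1),
                     control = n0,
                     control_sd = 100 * n0 / sum(b$group == 0),
                     total = n1 + n0,
                     total_sd = 100 * (n1 + n0) / nrow(b))
    }))
  }
  rows$age <- cont_row("age")
  rows$sex <- cat_rows("sex", sort(unique(b$sex)))
  for (o in intersect(.outcomes, names(b))) rows[[o]] <- cont_row(o)
  for (sub in c("depression", "anxiety", "stress")) {
    col <- paste0("dass_", sub)
    if (!col %in% names(b)) next
    b[[paste0(col, "_category")]] <-
      as.character(classify_severity(pmax(b[[col]], 0), sub, thresholds))
    rows[[paste0(col, "_cat")]] <-
      cat_rows(paste0(col, "_category"), attr(thresholds, "bands"))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n") <- c(intervention = sum(b$group == 1),
                      control = sum(b$group == 0), total = nrow(b))
  out
}

#' Group-by-wave descriptive table for the ASI and its dimensions
#'
#' Mean (SD) of ASI-12 and every rescaled dimension by group at each wave,
#' with the unadjusted between-group Cohen's d at follow-up waves.
#'
#' @param scored Scored long data.
#' @return Tibble: variable, wave, per-group mean/sd/n, d and its CI.
#' @export
asi_descriptives <- function(scored) {
  vars <- c("asi12", "asi6", grep("^score_", names(scored), value = TRUE))
  out <- list()
  for (v in vars) {
    for (w in sort(unique(scored$wave))) {
      sw <- scored[scored$wave == w & !is.na(scored[[v]]), ]
      gi <- sw[[v]][sw$group == 1]
      gc <- sw[[v]][sw$group == 0]
      row <- tibble::tibble(
        variable = v, wave = w,
        mean_int = mean(gi), sd_int = sd(gi), n_int = length(gi),
        mean_con = mean(gc), sd_con = sd(gc), n_con = length(gc),
        d = NA_real_, d_lower = NA_real_, d_upper = NA_real_)
      if (w > 0 && length(gi) >= 2 && length(gc) >= 2) {
        es <- cohens_d_data(gi, gc)
        row$d <- es$d
        row$d_lower <- es$ci[1]
        row$d_upper <- es$ci[2]
      }
      out[[paste(v, w)]] <- row
    }
  }
  dplyr::bind_rows(out)
}
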