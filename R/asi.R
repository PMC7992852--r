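#' The twelve Activity-Sleep Index dimensions
#'
#' Registry of the dimensions that make up the composite Activity-Sleep Index:
#' six physical-activity dimensions (frequency of MVPA sessions, frequency of
#' resistance training, intensity as the vigorous fraction of MVPA, activity
#' type, MVPA duration, sitting time) and six sleep-health dimensions (daytime
#' alertness, overall sleep quality, sleep timing, sleep regularity, sleep
#' efficiency, meeting the adult sleep-duration guideline).
#'
#' Each dimension is min-max rescaled to 0-10 with high scores reflecting
#' lower-risk behaviour, so dimensions where a higher raw value means higher
#' risk (sitting time, trouble staying awake, worse quality rating, more
#' variable bed/wake times) are flagged `reversed`. The short-form ASI-6 keeps
#' the resistance-training, MVPA-duration, sitting, sleep-quality,
#' sleep-efficiency and sleep-duration dimensions.
#'
#' @param timing How the sleep-timing dimension is expressed before rescaling:
#'   `"binary"` (default) scores 1 when the sleep midpoint falls between 02:00
#'   and 04:00, else 0; `"graded"` uses the distance in minutes from that
#'   window (a reversed dimension).
#' @return A tibble with columns `dimension`, `column` (input column the raw
#'   value comes from), `reversed`, `in_asi6`, `label`.
#' @export
asi_dimensions <- function(timing = c("binary", "graded")) {
  timing <- match.arg(timing)
  d <- tibble::tribble(
    ~dimension,         ~column,              ~reversed, ~in_asi6, ~label,
    "mvpa_frequency",   "mvpa_sessions",      FALSE,     FALSE,    "Frequency of MVPA (sessions/wk)",
    "rt_frequency",     "rt_days",            FALSE,     TRUE,     "Frequency of resistance training (days/wk)",
    "mvpa_intensity",   "vigorous_fraction",  FALSE,     FALSE,    "Proportion of MVPA that was vigorous",
    "activity_type",    "activity_type",      FALSE,     FALSE,    "Engagement in MVPA, resistance training, or both",
    "mvpa_duration",    "mvpa_minutes",       FALSE,     TRUE,     "Duration of MVPA (min/wk)",
    "sitting",          "sitting_minutes",    TRUE,      TRUE,     "Sitting time (min/day)",
    "daytime_alertness","daytime_sleepiness", TRUE,      FALSE,    "Trouble staying awake during the day",
    "sleep_quality",    "sleep_quality",      TRUE,      TRUE,     "Overall sleep quality rating",
    "sleep_timing",     "sleep_timing",       FALSE,     FALSE,    "Sleep midpoint between 02:00 and 04:00",
    "sleep_regularity", "sleep_variability",  TRUE,      FALSE,    "Variability in bed and wake times",
    "sleep_efficiency", "sleep_efficiency",   FALSE,     TRUE,     "Sleep efficiency (%)",
    "sleep_duration",   "sleep_duration_ok",  FALSE,     TRUE,     "Meeting the sleep-duration guideline"
  )
  if (timing == "graded") {
    d$reversed[d$dimension == "sleep_timing"] <- TRUE
  }
  attr(d, "timing") <- timing
  d
}

# Sleep-midpoint window considered low-risk, minutes after midnight.
.timing_window <- c(120, 240)

#' Derive scoreable behaviour dimensions from questionnaire-level fields
#'
#' Maps raw survey fields (activity questionnaire minutes, resistance-training
#' days, sitting time, sleep-diary style items) onto the behaviour-profile
#' columns consumed by [compute_bounds()] and [score_asi()].
#'
#' Derivations: weekly MVPA minutes are the sum of walking, moderate and
#' vigorous minutes (capped at `mvpa_cap`); the vigorous fraction is vigorous
#' over total MVPA minutes, defined as 0 when no MVPA was reported; activity
#' type is 0/1/2 for engagement in neither, one, or both of MVPA and
#' resistance training; the sleep midpoint is bed time plus half the sleep
#' duration, modulo 24 h; sleep efficiency is sleep duration over time in bed
#' times 100; sleep regularity is the sum of the two bed/wake-time variability
#' items; the duration guideline indicator is 1 when sleep duration lies in
#' `duration_range` hours (the 7-9 h adult guideline).
#'
#' @param raw A data frame with columns `walking_minutes`, `moderate_minutes`,
#'   `vigorous_minutes`, `mvpa_sessions`, `rt_days`, `sitting_minutes`,
#'   `daytime_sleepiness`, `sleep_quality`, `bed_time` (clock time "HH:MM"),
#'   `sleep_duration_hours`, `time_in_bed_hours`, `bedtime_variability`,
#'   `waketime_variability`. Other columns (ids, waves, age) pass through.
#' @param mvpa_cap Truncation for weekly MVPA minutes before scoring
#'   (default 840, the activity-questionnaire convention), `Inf` to disable.
#' @param duration_range Guideline band for sleep duration in hours.
#' @return The input with the behaviour-profile columns added.
#' @export
derive_dimensions <- function(raw, mvpa_cap = 840, duration_range = c(7, 9)) {
  need <- c("walking_minutes", "moderate_minutes", "vigorous_minutes",
            "mvpa_sessions", "rt_days", "sitting_minutes",
            "daytime_sleepiness", "sleep_quality", "bed_time",
            "sleep_duration_hours", "time_in_bed_hours",
            "bedtime_variability", "waketime_variability")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("derive_dimensions(): missing raw fields: ", paste(miss, collapse = ", "))
  }
  out <- tibble::as_tibble(raw)
  out$mvpa_minutes <- pmin(out$walking_minutes + out$moderate_minutes +
                             out$vigorous_minutes, mvpa_cap)
  out$vigorous_fraction <- ifelse(out$mvpa_minutes > 0,
                                  out$vigorous_minutes / out$mvpa_minutes, 0)
  bed_min <- parse_clock(out$bed_time)
  out$sleep_midpoint <- (bed_min + out$sleep_duration_hours * 60 / 2) %% 1440
  out$sleep_efficiency <- out$sleep_duration_hours / out$time_in_bed_hours * 100
  out$sleep_variability <- out$bedtime_variability + out$waketime_variability
  prepare_profile(out, duration_range = duration_range, mvpa_cap = mvpa_cap)
}

# "HH:MM" (24 h) -> minutes after midnight; informative error otherwise.
parse_clock <- function(x) {
  x <- as.character(x)
  ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x) | is.na(x)
  if (!all(ok)) {
    stop("unparseable clock time(s): ",
         paste(unique(x[!ok]), collapse = ", "),
         " (expected 24-hour HH:MM)")
  }
  h <- as.numeric(sub(":.*", "", x))
  m <- as.numeric(sub(".*:", "", x))
  h * 60 + m
}

#' Prepare a behaviour profile for scoring
#'
#' Fills in the dimensions that are deterministic transforms of other profile
#' fields: the activity-type membership score, the sleep-timing dimension
#' (from the sleep midpoint), the sleep-duration guideline indicator, the
#' vigorous-fraction convention at zero MVPA, and the MVPA-minutes cap.
#' Called automatically by [compute_bounds()] and [score_asi()] when the
#' derived columns are absent, so generators and CSV readers may supply either
#' form.
#'
#' @param data Data frame with behaviour-profile columns (see
#'   [asi_dimensions()]); needs `sleep_midpoint` and `sleep_duration_hours`.
#' @param timing See [asi_dimensions()].
#' @param duration_range Guideline band (hours) for the duration indicator.
#' @param mvpa_cap Weekly MVPA minutes truncation before scoring.
#' @return `data` with `activity_type`, `sleep_timing`, `sleep_duration_ok`
#'   columns present.
#' @export
prepare_profile <- function(data, timing = c("binary", "graded"),
                            duration_range = c(7, 9), mvpa_cap = 840) {
  timing <- match.arg(timing)
  out <- tibble::as_tibble(data)
  has <- function(col) col %in% names(out)
  if (has("mvpa_minutes")) {
    out$mvpa_minutes <- pmin(out$mvpa_minutes, mvpa_cap)
  }
  if (has("vigorous_fraction") && has("mvpa_minutes")) {
    out$vigorous_fraction[!is.na(out$mvpa_minutes) & out$mvpa_minutes == 0] <- 0
  }
  if (!has("activity_type")) {
    out$activity_type <- as.numeric(out$mvpa_minutes > 0) +
      as.numeric(out$rt_days > 0)
  }
  if (!has("sleep_timing")) {
    m <- out$sleep_midpoint
    inside <- m >= .timing_window[1] & m <= .timing_window[2]
    if (timing == "binary") {
      out$sleep_timing <- as.numeric(inside)
    } else {
      out$sleep_timing <- pmax(.timing_window[1] - m, m - .timing_window[2], 0)
    }
  }
  if (!has("sleep_duration_ok")) {
    h <- out$sleep_duration_hours
    out$sleep_duration_ok <- as.numeric(h >= duration_range[1] &
                                          h <= duration_range[2])
  }
  out
}

#' Pooled rescaling bounds for the ASI dimensions
#'
#' Computes, for every dimension, the minimum and maximum raw value observed
#' over *all* assessment points and both groups. These pooled bounds are
#' frozen before any scoring call so that scores from different waves and
#' groups share one scale.
#'
#' @param data Long behaviour data (any number of waves stacked); missing
#'   values are ignored when scanning for extrema.
#' @param dimensions Dimension registry, defaults to [asi_dimensions()].
#' @param ... Passed to [prepare_profile()].
#' @return An object of class `asi_bounds`: the registry tibble with `min`
#'   and `max` columns added.
#' @export
compute_bounds <- function(data, dimensions = asi_dimensions(), ...) {
  data <- prepare_profile(data, timing = attr(dimensions, "timing") %||% "binary", ...)
  miss <- setdiff(dimensions$column, names(data))
  if (length(miss)) {
    stop("compute_bounds(): data lacks dimension column(s): ",
         paste(miss, collapse = ", "))
  }
  rng <- lapply(dimensions$column, function(col) {
    x <- data[[col]]
    x <- x[is.finite(x)]
    if (!length(x)) {
      stop("compute_bounds(): dimension '", col, "' has no observed values")
    }
    range(x)
  })
  out <- dimensions
  out$min <- vapply(rng, `[`, numeric(1), 1)
  out$max <- vapply(rng, `[`, numeric(1), 2)
  class(out) <- c("asi_bounds", class(out))
  out
}

#' Min-max rescale one dimension to the 0-n risk scale
#'
#' Applies `((x - min) / (max - min)) * n`, then reflects to `n - score` for
#' reversed (higher raw = higher risk) dimensions, so that high scores always
#' mean lower-risk behaviour. Values outside the frozen bounds are clipped to
#' them; degenerate bounds (`max == min`) return `n/2` with a warning since
#' the dimension then carries no information.
#'
#' @param x Raw values (missing values propagate as `NA`).
#' @param min,max Frozen pooled bounds for the dimension.
#' @param reversed Is a higher raw value higher-risk?
#' @param n Upper limit of the rescaled score (default 10).
#' @return Numeric vector of scores in `[0, n]`.
#' @export
rescale_dimension <- function(x, min, max, reversed = FALSE, n = 10) {
  if (any(is.nan(x) | is.infinite(x))) {
    stop("rescale_dimension(): non-finite raw values")
  }
  if (max < min) stop("rescale_dimension(): max < min")
  if (max == min) {
    warning("degenerate bounds (max == min); scoring dimension as n/2")
    out <- rep(n / 2, length(x))
    out[is.na(x)] <- NA_real_
    return(out)
  }
  x <- pmin(pmax(x, min), max)
  score <- (x - min) / (max - min) * n
  if (reversed) n - score else score
}

#' Score the Activity-Sleep Index
#'
#' Rescales every dimension against the frozen pooled bounds and sums the
#' scores into ASI-12 (range 0-120) and the six-dimension short form ASI-6
#' (range 0-60). A wave with any missing dimension gets a missing index (no
#' pro-rating): partially answered questionnaires would otherwise change the
#' meaning of the composite.
#'
#' @param data Long behaviour data, one row per participant-wave.
#' @param bounds Frozen [compute_bounds()] result.
#' @param n Upper limit per dimension score.
#' @param ... Passed to [prepare_profile()].
#' @return `data` with `score_<dimension>` columns plus `asi12` and `asi6`.
#' @export
score_asi <- function(data, bounds, n = 10, ...) {
  stopifnot(inherits(bounds, "asi_bounds"))
  data <- prepare_profile(data, timing = attr(bounds, "timing") %||% "binary", ...)
  scores <- matrix(NA_real_, nrow(data), nrow(bounds),
                   dimnames = list(NULL, paste0("score_", bounds$dimension)))
  for (i in seq_len(nrow(bounds))) {
    scores[, i] <- rescale_dimension(data[[bounds$column[i]]],
                                     bounds$min[i], bounds$max[i],
                                     bounds$reversed[i], n)
  }
  out <- dplyr::bind_cols(data, tibble::as_tibble(scores))
  out$asi12 <- rowSums(scores)
  out$asi6 <- rowSums(scores[, paste0("score_", bounds$dimension[bounds$in_asi6]),
                             drop = FALSE])
  out
}

#' Score a single behaviour profile
#'
#' Convenience wrapper around [score_asi()] for one participant-wave.
#'
#' @param profile One-row data frame (or coercible list) of raw dimensions.
#' @param bounds Frozen [compute_bounds()] result.
#' @param n Upper limit per dimension score.
#' @return A list of class `asi_score` with elements `scores` (named
#'   12-vector), `asi12` and `asi6`.
#' @export
compose_asi <- function(profile, bounds, n = 10) {
  scored <- score_asi(tibble::as_tibble(profile), bounds, n = n)
  sc <- unlist(scored[1, paste0("score_", bounds$dimension)])
  names(sc) <- bounds$dimension
  structure(list(scores = sc, asi12 = scored$asi12[1], asi6 = scored$asi6[1]),
            class = "asi_score")
}

#' @export
print.asi_score <- function(x, ...) {
  cat("Activity-Sleep Index\n")
  cat(sprintf("  ASI-12: %.2f (0-120)   ASI-6: %.2f (0-60)\n", x$asi12, x$asi6))
  print(round(x$scores, 2))
  invisible(x)
}

#' Spearman correlations between rescaled ASI dimensions
#'
#' Rank correlation (midranks for ties) between every pair of rescaled
#' dimension scores, and optionally the ASI-12 total, using pairwise-complete
#' observations. Constant columns yield `NA` entries (correlation undefined).
#'
#' @param scored Output of [score_asi()], needing at least 3 complete rows.
#' @param include_total Append the `asi12` column.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
dimension_correlations <- function(scored, include_total = TRUE) {
  cols <- grep("^score_", names(scored), value = TRUE)
  if (!length(cols)) stop("no score_* columns; run score_asi() first")
  if (include_total && "asi12" %in% names(scored)) cols <- c(cols, "asi12")
  m <- as.matrix(scored[, cols])
  if (sum(complete.cases(m)) < 3) {
    stop("dimension_correlations(): need at least 3 complete rows")
  }
  suppressWarnings(cor(m, method = "spearman", use = "pairwise.complete.obs"))
}

#' Export rescaling bounds as a JSON sidecar
#'
#' @param bounds [compute_bounds()] result.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_bounds_json <- function(bounds, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(bounds)), function(i) {
      list(dimension = bounds$dimension[i], column = bounds$column[i],
           min = bounds$min[i], max = bounds$max[i],
           reversed = bounds$reversed[i], in_asi6 = bounds$in_asi6[i])
    }),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a bounds sidecar written by [write_bounds_json()]
#' @param path JSON file.
#' @return An `asi_bounds` object.
#' @export
read_bounds_json <- function(path) {
  raw <- jsonlite::fromJSON(path)
  out <- tibble::as_tibble(raw)
  reg <- asi_dimensions()
  out <- out[match(reg$dimension, out$dimension), ]
  out$label <- reg$label
  class(out) <- c("asi_bounds", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
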