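#' Kolmogorov-Smirnov normality check for a similarity set
#'
#' Tests the centroid-similarity values against a normal distribution
#' whose mean and standard deviation are estimated from the sample.
#' `mode = "plugin"` feeds the estimates straight into the one-sample KS
#' test; `mode = "lilliefors"` applies the Lilliefors correction for
#' estimated parameters, which is statistically preferable but more
#' conservative. The plug-in mode is the default because it mirrors the
#' most literal screening procedure.
#'
#' @param C A `"tds_similarity_set"` (or numeric vector of similarities),
#'   `n >= 5`.
#' @param mode `"plugin"` (default) or `"lilliefors"`.
#' @return The test p-value.
#' @export
ks_normality <- function(C, mode = c("plugin", "lilliefors")) {
  mode <- match.arg(mode)
  x <- similarity_values(C)
  if (length(x) < 5L) {
    abort("Need n >= 5 values for the normality check.",
      class = "tdsim_error_domain"
    )
  }
  if (sd(x) == 0) {
    abort("All similarity values identical: distribution is degenerate.",
      class = "tdsim_error_degenerate"
    )
  }
  if (mode == "plugin") {
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  } else {
    nortest::lillie.test(x)$p.value
  }
}

similarity_values <- function(C) {
  if (is.numeric(C)) {
    return(as.numeric(C))
  }
  if (is.data.frame(C) && "similarity" %in% names(C)) {
    return(C$similarity)
  }
  abort("Expected a similarity set or numeric vector.",
    class = "tdsim_error_validation"
  )
}

screen_tbl <- function(C, flagged_ids, screen, threshold, extra = list()) {
  tbl <- if (is.data.frame(C)) {
    tibble(trial_id = C$trial_id, similarity = C$similarity)
  } else {
    tibble(
      trial_id = sprintf("x%d", seq_along(C)),
      similarity = as.numeric(C)
    )
  }
  tbl$flagged <- tbl$trial_id %in% flagged_ids
  attributes(tbl) <- c(
    attributes(tbl),
    list(screen = screen, threshold = threshold), extra
  )
  class(tbl) <- c("tds_screen", class(tibble()))
  tbl
}

#' One-sided normal-range outlier screen
#'
#' Flags trials whose similarity to the centroid falls strictly below
#' `mu - 1.64 * sigma` (95% coverage) or `mu - 2.33 * sigma` (99%), with
#' `mu` the sample mean and `sigma` the sample standard deviation
#' (`n - 1` divisor) over all entries. The screen is one-sided: trials
#' with unusually *high* similarity represent the panel well and are
#' never flagged. A value exactly at the threshold is an inlier.
#'
#' @inheritParams ks_normality
#' @param coverage `0.95` (default) or `0.99`.
#' @param robust Use the robust location/scale from
#'   [robust_location_scale()] instead of the sample moments?
#' @return A tibble of class `"tds_screen"` with columns `trial_id`,
#'   `similarity`, `flagged` and attributes `threshold`, `mu`, `sigma`,
#'   `coverage`, `screen = "normal"`.
#' @export
detect_outliers_normal <- function(C, coverage = 0.95, robust = FALSE) {
  x <- similarity_values(C)
  if (length(x) < 5L) {
    abort("Need n >= 5 values to screen.", class = "tdsim_error_domain")
  }
  if (!coverage %in% c(0.95, 0.99)) {
    abort("`coverage` must be 0.95 or 0.99.", class = "tdsim_error_domain")
  }
  k <- if (coverage == 0.95) 1.64 else 2.33
  if (robust) {
    ls <- robust_location_scale(x)
    mu <- ls$location
    sigma <- ls$scale
  } else {
    mu <- mean(x)
    sigma <- sd(x)
  }
  if (sigma == 0) {
    warn("All similarity values identical; nothing can be flagged.")
    return(screen_tbl(C, character(0), "normal", mu,
      extra = list(mu = mu, sigma = 0, coverage = coverage)
    ))
  }
  threshold <- mu - k * sigma
  ids <- if (is.data.frame(C)) C$trial_id else sprintf("x%d", seq_along(x))
  flagged <- ids[x < threshold]
  screen_tbl(C, flagged, "normal", threshold,
    extra = list(mu = mu, sigma = sigma, coverage = coverage)
  )
}

#' One-sided interquartile-range outlier screen
#'
#' Fallback for similarity sets that fail the normality check: flags
#' entries strictly below `Q1 - k * IQR`. Quartiles use the
#' linear-interpolation convention (R's default, type 7). Consistent with
#' the normal screen, entries above `Q3 + k * IQR` are never flagged.
#'
#' @inheritParams ks_normality
#' @param k Whisker multiplier, default 1.5.
#' @return A `"tds_screen"` tibble (see [detect_outliers_normal()]) with
#'   attributes `q1`, `q3`, `threshold`, `screen = "iqr"`.
#' @export
detect_outliers_iqr <- function(C, k = 1.5) {
  x <- similarity_values(C)
  if (length(x) < 5L) {
    abort("Need n >= 5 values to screen.", class = "tdsim_error_domain")
  }
  stopifnot_scalar_number(k, "k", positive = TRUE)
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  threshold <- q[1L] - k * (q[2L] - q[1L])
  ids <- if (is.data.frame(C)) C$trial_id else sprintf("x%d", seq_along(x))
  flagged <- ids[x < threshold]
  screen_tbl(C, flagged, "iqr", threshold,
    extra = list(q1 = q[1L], q3 = q[2L])
  )
}

#' Robust location and scale of a similarity set
#'
#' A univariate analog of the minimum covariance determinant: among all
#' contiguous windows of `ceiling((n + 1) / 2)` order statistics, takes
#' the one with the smallest variance (equivalently, for the location,
#' the shortest half of the sample) and rescales its standard deviation
#' by the factor that makes it consistent at the normal distribution
#' (the central half of a standard normal has variance
#' `1 - 2 q phi(q) / 0.5` with `q` the upper quartile, so the factor is
#' about 2.65). Useful when the plain mean and standard deviation are
#' themselves dragged by the outliers being screened for.
#'
#' @inheritParams ks_normality
#' @return A tibble with columns `location` and `scale`.
#' @export
robust_location_scale <- function(C) {
  x <- similarity_values(C)
  n <- length(x)
  if (n < 10L) {
    abort("Need n >= 10 values for a robust estimate.",
      class = "tdsim_error_domain"
    )
  }
  h <- ceiling((n + 1) / 2)
  xs <- sort(x)
  nw <- n - h + 1L
  vars <- vapply(seq_len(nw), function(j) stats::var(xs[j:(j + h - 1L)]), numeric(1))
  j <- which.min(vars)
  win <- xs[j:(j + h - 1L)]
  qn <- qnorm(0.75)
  consistency <- 1 / sqrt(1 - 2 * qn * stats::dnorm(qn) / 0.5)
  tibble(location = mean(win), scale = sd(win) * consistency)
}

#' Multi-R outlier analysis of a trial set
#'
#' The full screening pipeline, repeated for each requested dynamic
#' level: build the set of centroid similarities, test it for normality
#' with the KS check, and apply the one-sided normal-range screen when
#' normality is not rejected (`p > alpha`) or the one-sided IQR screen
#' otherwise. Trials flagged only at small `R` deviate in *which*
#' attributes they dwell on; trials flagged only at large `R` deviate in
#' *when*.
#'
#' @inheritParams similarity_set
#' @param R_values Dynamic levels to screen at (distinct positive
#'   integers).
#' @param coverage `0.95` or `0.99` (normal screen only).
#' @param ks_mode Passed to [ks_normality()].
#' @param alpha Normality-gate level, default 0.05.
#' @param robust Use robust location/scale in the normal screen?
#' @param iqr_k Whisker multiplier for the IQR fallback.
#' @return A tibble of class `"tds_outlier_report"`, one row per `R`, with
#'   columns `R`, `n`, `mu`, `sigma`, `ks_p`, `screen`, `coverage`,
#'   `threshold`, `n_flagged`, `flagged` (list column of trial ids);
#'   attribute `flags` holds the long trial-by-R flag table. Use
#'   [flag_matrix()] for the trials-by-R "+" matrix.
#' @export
outlier_analysis <- function(trials, R_values, coverage = 0.95,
                             metric = c("euclidean", "manhattan"),
                             ks_mode = c("plugin", "lilliefors"),
                             alpha = 0.05, robust = FALSE, iqr_k = 1.5) {
  metric <- match.arg(metric)
  ks_mode <- match.arg(ks_mode)
  if (!length(R_values) || anyDuplicated(R_values) ||
    any(R_values < 1 | R_values != floor(R_values))) {
    abort("`R_values` must be distinct positive integers.",
      class = "tdsim_error_domain"
    )
  }
  R_values <- as.integer(R_values)
  rows <- list()
  flags <- list()
  sets <- list()
  for (R in R_values) {
    C <- tryCatch(similarity_set(trials, R, metric), error = function(e) {
      abort(sprintf("R = %d: %s", R, conditionMessage(e)), class = class(e)[1L])
    })
    sets[[as.character(R)]] <- C
    x <- C$similarity
    if (sd(x) == 0) {
      scr <- suppressWarnings(detect_outliers_normal(C, coverage, robust = FALSE))
      p <- NA_real_
    } else {
      p <- ks_normality(C, ks_mode)
      scr <- if (p > alpha) {
        detect_outliers_normal(C, coverage, robust = robust)
      } else {
        detect_outliers_iqr(C, k = iqr_k)
      }
    }
    rows[[as.character(R)]] <- tibble(
      R = R, n = nrow(C), mu = mean(x), sigma = sd(x), ks_p = p,
      screen = attr(scr, "screen"), coverage = coverage,
      threshold = attr(scr, "threshold"),
      n_flagged = sum(scr$flagged),
      flagged = list(scr$trial_id[scr$flagged])
    )
    flags[[as.character(R)]] <- tibble(
      trial_id = scr$trial_id, R = R,
      similarity = scr$similarity, flagged = scr$flagged
    )
  }
  out <- dplyr::bind_rows(rows)
  structure(
    out,
    flags = dplyr::bind_rows(flags), sets = sets,
    class = c("tds_outlier_report", class(tibble()))
  )
}

#' @export
print.tds_outlier_report <- function(x, ...) {
  cat(sprintf(
    "<tds_outlier_report> R in {%s}; %d trial(s)\n",
    paste(x$R, collapse = ", "),
    length(unique(attr(x, "flags")$trial_id))
  ))
  NextMethod()
}

#' @export
tidy.tds_outlier_report <- function(x, ...) {
  as_tibble(attr(x, "flags"))
}

#' @export
glance.tds_outlier_report <- function(x, ...) {
  fl <- attr(x, "flags")
  tibble(
    n_trials = length(unique(fl$trial_id)),
    n_levels = nrow(x),
    n_ever_flagged = length(unique(fl$trial_id[fl$flagged])),
    coverage = x$coverage[1L]
  )
}

#' Trials-by-R flag matrix
#'
#' The screening report reshaped as one row per trial and one column per
#' dynamic level, with `"+"` marking a flagged trial — the layout used to
#' eyeball which trials are outliers only at small, large or every `R`.
#'
#' @param report A `"tds_outlier_report"`.
#' @param all_trials Include rows for never-flagged trials? Default
#'   `FALSE`.
#' @return A tibble with `trial_id` and one character column per `R`.
#' @export
flag_matrix <- function(report, all_trials = FALSE) {
  fl <- as_tibble(attr(report, "flags"))
  fl$mark <- ifelse(fl$flagged, "+", "")
  wide <- tidyr::pivot_wider(fl[c("trial_id", "R", "mark")],
    names_from = "R", values_from = "mark", names_prefix = "R"
  )
  if (!all_trials) {
    keep <- rowSums(wide[-1L] == "+") > 0
    wide <- wide[keep, , drop = FALSE]
  }
  wide
}

#' Histograms of centroid similarities per dynamic level
#'
#' @param object A `"tds_outlier_report"`.
#' @param binwidth Histogram bin width on the similarity axis, default
#'   0.025.
#' @param ... Unused.
#' @return A ggplot object, one facet per `R`, with the screening
#'   threshold drawn as a dashed line.
#' @export
autoplot.tds_outlier_report <- function(object, binwidth = 0.025, ...) {
  fl <- as_tibble(attr(object, "flags"))
  thr <- as_tibble(object)[c("R", "threshold")]
  ggplot2::ggplot(fl, ggplot2::aes(x = .data$similarity)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
      fill = "grey70", colour = "grey30"
    ) +
    ggplot2::geom_vline(
      data = thr, ggplot2::aes(xintercept = .data$threshold),
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::facet_wrap(~R, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "similarity to centroid", y = "trials") +
    ggplot2::theme_minimal()
}
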