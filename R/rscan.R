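#' Per-trial similarity to the panel centroid (the set C_R)
#'
#' Scores every trial's similarity index against the centroid — the
#' discretized panel-mean dominance proportions — at dynamic level `R`.
#' The scored trial is included in the centroid by default (the centroid
#' is the mean of all `n` trials); `leave_one_out = TRUE` instead scores
#' each trial against the mean of the other `n - 1`.
#'
#' @param trials A [tds_trialset()] with `n >= 2` (the centroid of a
#'   single trial is the trial itself, making similarity identically 1).
#' @param R Dynamic level (positive integer).
#' @inheritParams dissimilarity
#' @param leave_one_out Exclude each trial from its own centroid?
#'   Default `FALSE`.
#' @return A tibble of class `"tds_similarity_set"` with columns
#'   `trial_id` and `similarity` (in `[0, 1]`), plus attributes `R` and
#'   `metric`.
#' @export
similarity_set <- function(trials, R, metric = c("euclidean", "manhattan"),
                           leave_one_out = FALSE) {
  if (!inherits(trials, "tds_trialset")) {
    abort("`trials` must be a tds_trialset.", class = "tdsim_error_validation")
  }
  metric <- match.arg(metric)
  n <- n_trials(trials)
  if (n < 2L) {
    abort("Need at least 2 trials to form a panel centroid.",
      class = "tdsim_error_domain"
    )
  }
  R <- check_R(R)
  d <- discretize(trials, R)
  ids <- trial_ids(trials)
  mats <- lapply(ids, function(id) discretized_matrix(d, id))
  P <- Reduce(`+`, mats) / n
  sim <- vapply(seq_along(ids), function(j) {
    cen <- if (leave_one_out) (P * n - mats[[j]]) / (n - 1) else P
    1 - dissimilarity(mats[[j]], cen, metric)
  }, numeric(1))
  structure(
    tibble(trial_id = ids, similarity = sim),
    R = R, metric = metric,
    class = c("tds_similarity_set", class(tibble()))
  )
}

#' @export
print.tds_similarity_set <- function(x, ...) {
  cat(sprintf("<tds_similarity_set> R = %d, n = %d\n", attr(x, "R"), nrow(x)))
  NextMethod()
}

#' Pearson correlation between two similarity sets
#'
#' Correlates the per-trial similarity values of two dynamic levels,
#' matching entries by `trial_id`. Sample moments are used with matching
#' normalization in numerator and denominator (standard Pearson
#' product-moment correlation), so the coefficient lies in `[-1, 1]`.
#'
#' @param C1,C2 `"tds_similarity_set"` objects (or tibbles with
#'   `trial_id` and `similarity`) over the same trials, `n >= 3`.
#' @return The correlation coefficient.
#' @export
correlate_sets <- function(C1, C2) {
  for (C in list(C1, C2)) {
    if (!all(c("trial_id", "similarity") %in% names(C))) {
      abort("Similarity sets need `trial_id` and `similarity` columns.",
        class = "tdsim_error_validation"
      )
    }
  }
  if (!setequal(C1$trial_id, C2$trial_id) || nrow(C1) != nrow(C2)) {
    abort("Similarity sets cover different trials.", class = "tdsim_error_validation")
  }
  if (nrow(C1) < 3L) {
    abort("Need at least 3 matched trials to correlate.",
      class = "tdsim_error_domain"
    )
  }
  x <- C1$similarity
  y <- C2$similarity[match(C1$trial_id, C2$trial_id)]
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: a similarity set has zero variance.",
      class = "tdsim_error_degenerate"
    )
  }
  cor(x, y)
}

#' Cross-R correlation grid of similarity sets
#'
#' Computes the set of centroid similarities at every requested dynamic
#' level and the full symmetric grid of Pearson correlations between
#' levels. Nearby levels score trials near-identically while distant ones
#' diverge, so the grid shows how much the choice of `R` matters for a
#' given panel.
#'
#' @inheritParams similarity_set
#' @param R_values Distinct positive integers.
#' @return A tibble of class `"tds_corgrid"` with columns `R1`, `R2`, `r`
#'   (one row per ordered pair), plus attributes `R_values`, `matrix`
#'   (the `R x R` correlation matrix) and `sets` (the per-R similarity
#'   sets).
#' @export
correlation_grid <- function(trials, R_values,
                             metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (length(R_values) < 2L || anyDuplicated(R_values) ||
    any(R_values < 1 | R_values != floor(R_values))) {
    abort("`R_values` must be >= 2 distinct positive integers.",
      class = "tdsim_error_domain"
    )
  }
  R_values <- as.integer(R_values)
  sets <- lapply(R_values, function(R) similarity_set(trials, R, metric))
  names(sets) <- as.character(R_values)
  m <- length(R_values)
  r <- diag(1, m)
  dimnames(r) <- list(R_values, R_values)
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      val <- tryCatch(correlate_sets(sets[[a]], sets[[b]]), error = function(e) {
        abort(sprintf(
          "Correlation failed for (R1 = %d, R2 = %d): %s",
          R_values[a], R_values[b], conditionMessage(e)
        ), class = class(e)[1L])
      })
      r[a, b] <- r[b, a] <- val
    }
  }
  long <- tibble(
    R1 = rep(R_values, each = m),
    R2 = rep(R_values, times = m),
    r = as.vector(t(r))
  )
  structure(
    long,
    R_values = R_values, matrix = r, sets = sets, metric = metric,
    class = c("tds_corgrid", class(tibble()))
  )
}

#' @export
print.tds_corgrid <- function(x, ...) {
  cat(sprintf(
    "<tds_corgrid> R in {%s}\n",
    paste(attr(x, "R_values"), collapse = ", ")
  ))
  print(round(attr(x, "matrix"), 3))
  invisible(x)
}

#' @export
tidy.tds_corgrid <- function(x, ...) {
  out <- as_tibble(x)
  out[out$R1 <= out$R2, ]
}

#' @export
glance.tds_corgrid <- function(x, ...) {
  tibble(
    n_levels = length(attr(x, "R_values")),
    min_offdiag = min(x$r[x$R1 != x$R2]),
    mean_offdiag = mean(x$r[x$R1 != x$R2]),
    recommended_R = recommend_R(x)
  )
}

#' Plot a correlation grid
#'
#' Correlation against `R1`, one line per `R2`, on a log `R1` axis.
#'
#' @param object A `"tds_corgrid"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tds_corgrid <- function(object, ...) {
  df <- as_tibble(object)
  df$R2 <- factor(df$R2)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$R1, y = .data$r, colour = .data$R2, group = .data$R2
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "R1 (log scale)", y = "correlation of similarity sets",
      colour = "R2"
    ) +
    ggplot2::theme_minimal()
}

#' Recommend a dynamic level from a correlation grid
#'
#' Formalizes the idea that a good `R` agrees with both duration-focused
#' (small `R`) and timing-focused (large `R`) scorings: picks the level
#' whose off-diagonal correlations with every other level maximize the
#' minimum (default) or the mean. Ties break toward smaller `R` for
#' parsimony.
#'
#' @param grid A `"tds_corgrid"`.
#' @param criterion `"max-min"` (default) or `"max-mean"`.
#' @return A single integer from the grid's `R_values`.
#' @export
recommend_R <- function(grid, criterion = c("max-min", "max-mean")) {
  criterion <- match.arg(criterion)
  if (!inherits(grid, "tds_corgrid")) {
    abort("`grid` must be a tds_corgrid.", class = "tdsim_error_validation")
  }
  r <- attr(grid, "matrix")
  Rv <- attr(grid, "R_values")
  if (is.null(r) || nrow(r) < 2L || any(!is.finite(r))) {
    abort("Degenerate correlation grid.", class = "tdsim_error_degenerate")
  }
  score <- vapply(seq_along(Rv), function(a) {
    off <- r[a, -a]
    if (criterion == "max-min") min(off) else mean(off)
  }, numeric(1))
  ord <- order(Rv)  # tie-break toward smaller R
  best <- ord[which.max(score[ord])]
  Rv[best]
}

#' Dynamic level from the minimum switch interval
#'
#' An alternative, behaviorally grounded choice of `R`: panelists rarely
#' switch attributes faster than about a second, so discretizing finer
#' than the shortest observed inter-selection gap adds no information.
#' Takes a low quantile (default the 5th percentile, robust to a single
#' anomalous double-press) of all inter-selection gaps in seconds and
#' returns `floor(mean task duration / that gap)`.
#'
#' @param trials A [tds_trialset()]; at least one trial must have two or
#'   more selections and a known `duration_seconds`.
#' @param gap_quantile Quantile of the gap distribution to use (default
#'   0.05; 0 gives the literal minimum).
#' @return A positive integer `R`.
#' @export
R_from_min_switch_interval <- function(trials, gap_quantile = 0.05) {
  if (!inherits(trials, "tds_trialset")) {
    abort("`trials` must be a tds_trialset.", class = "tdsim_error_validation")
  }
  ev <- as_tibble(trials)
  ev <- ev[ev$attribute != "none", ]
  ev <- ev[!is.na(ev$duration_seconds), ]
  gaps <- unlist(lapply(split(ev, ev$trial_id), function(rows) {
    if (nrow(rows) < 2L) {
      return(numeric(0))
    }
    diff(sort(rows$onset)) * rows$duration_seconds[1L]
  }), use.names = FALSE)
  if (!length(gaps)) {
    abort(paste(
      "No trial has >= 2 timed selections with a known duration;",
      "use recommend_R() on a correlation grid instead."
    ), class = "tdsim_error_domain")
  }
  dur <- trial_durations(trials)$duration_seconds
  mean_dur <- mean(dur, na.rm = TRUE)
  gap <- as.numeric(quantile(gaps, gap_quantile, type = 7))
  max(1L, as.integer(floor(mean_dur / gap)))
}
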