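#' Dominance proportions (TDS curve) of a trial set
#'
#' At every normalized time `t` the proportion of trials in which attribute
#' `i` is dominant is the average of the per-trial binary dominance
#' functions. Because every trial is a step function, the average is itself
#' piecewise constant on the union of all trials' onsets; this function
#' returns it exactly, segment by segment, with no smoothing.
#'
#' @param trials A [tds_trialset()] with `n >= 1` trials.
#' @return A tibble of class `"tds_curve"` with columns `t_left`,
#'   `t_right`, `attribute`, `p`: one row per segment and attribute
#'   (including `"none"`). Within each segment the `p` values sum to 1 and
#'   are multiples of `1/n`.
#' @seealso [smooth_curve()] for presentation smoothing; all similarity and
#'   outlier computations use the unsmoothed curve.
#' @export
dominance_proportions <- function(trials) {
  if (!inherits(trials, "tds_trialset")) {
    abort("`trials` must be a tds_trialset.", class = "tdsim_error_validation")
  }
  n <- n_trials(trials)
  lev <- lexicon_levels(lexicon(trials))
  breaks <- sort(unique(c(0, as_tibble(trials)$onset, 1)))
  lefts <- breaks[-length(breaks)]
  dom <- dominant_at(trials, lefts)
  counts <- dplyr::count(dom, .data$t, .data$attribute)
  counts$attribute <- factor(counts$attribute, levels = lev)
  grid <- tidyr::complete(counts,
    t = lefts, attribute = factor(lev, levels = lev),
    fill = list(n = 0L)
  )
  grid <- dplyr::arrange(grid, .data$t, .data$attribute)
  out <- tibble(
    t_left = grid$t,
    t_right = breaks[-1L][match(grid$t, lefts)],
    attribute = grid$attribute,
    p = grid$n / n
  )
  new_curve(out, lexicon(trials), n)
}

new_curve <- function(tbl, lexicon, n_trials) {
  structure(
    as_tibble(tbl),
    lexicon = lexicon, n_trials = n_trials,
    class = c("tds_curve", class(tibble()))
  )
}

#' @export
print.tds_curve <- function(x, ...) {
  cat(sprintf(
    "<tds_curve> %d segment(s), %d attribute(s) + \"none\", n = %s\n",
    length(unique(x$t_left)), length(lexicon(x)),
    attr(x, "n_trials") %||% "?"
  ))
  NextMethod()
}

# Segment matrix view: list(breaks = length-(m+1) vector, V = m x (q+1)
# matrix, columns ordered "none", lexicon...).
curve_matrix <- function(curve) {
  lev <- lexicon_levels(lexicon(curve))
  wide <- tidyr::pivot_wider(as_tibble(curve),
    names_from = "attribute", values_from = "p"
  )
  wide <- dplyr::arrange(wide, .data$t_left)
  V <- as.matrix(wide[lev])
  list(breaks = c(wide$t_left, 1), V = V, levels = lev)
}

#' Smooth a dominance curve for presentation
#'
#' Applies a centered moving average of the given normalized-time width on
#' a uniform resampling of the curve. Near the boundaries the window
#' shrinks to its intersection with `[0, 1]`, so every attribute is
#' averaged over the same window and each output segment still sums to 1.
#' Smoothing is purely cosmetic: similarity and outlier computations always
#' use the unsmoothed step functions.
#'
#' @param curve A `tds_curve`.
#' @param window Window width in normalized time, in `[0, 1]`; `0` returns
#'   the input unchanged.
#' @param n_grid Number of uniform resampling cells (default 512).
#' @return A `tds_curve` on a uniform grid (or the input when
#'   `window = 0`).
#' @export
smooth_curve <- function(curve, window, n_grid = 512L) {
  if (!inherits(curve, "tds_curve")) {
    abort("`curve` must be a tds_curve.", class = "tdsim_error_validation")
  }
  stopifnot_scalar_number(window, "window")
  if (window < 0 || window > 1) {
    abort("`window` must lie in [0, 1] (normalized time).",
      class = "tdsim_error_domain"
    )
  }
  if (window == 0) {
    return(curve)
  }
  cm <- curve_matrix(curve)
  mid <- (seq_len(n_grid) - 0.5) / n_grid
  idx <- findInterval(mid, cm$breaks, rightmost.closed = TRUE)
  V <- cm$V[idx, , drop = FALSE]
  half_cells <- max(1L, round(window / 2 * n_grid))
  cs <- rbind(0, apply(V, 2L, cumsum))
  lo <- pmax(seq_len(n_grid) - half_cells, 1L)
  hi <- pmin(seq_len(n_grid) + half_cells, n_grid)
  sm <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  out <- tibble(
    t_left = rep((seq_len(n_grid) - 1L) / n_grid, times = ncol(sm)),
    t_right = rep(seq_len(n_grid) / n_grid, times = ncol(sm)),
    attribute = factor(rep(cm$levels, each = n_grid), levels = cm$levels),
    p = as.vector(sm)
  )
  out <- dplyr::arrange(out, .data$t_left, .data$attribute)
  new_curve(out, lexicon(curve), attr(curve, "n_trials"))
}

#' Plot a TDS curve
#'
#' Draws dominance proportion against normalized time, one step line per
#' attribute, in the style sensory scientists use for TDS curves.
#'
#' @param object A `tds_curve`.
#' @param include_none Show the implicit `"none"` state too? Default
#'   `FALSE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tds_curve <- function(object, include_none = FALSE, ...) {
  df <- as_tibble(object)
  if (!include_none) df <- df[df$attribute != "none", ]
  closing <- df[df$t_right == max(df$t_right), ]
  closing$t_left <- closing$t_right
  df <- dplyr::bind_rows(df, closing)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$t_left, y = .data$p, colour = .data$attribute
  )) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::labs(
      x = "normalized time", y = "dominance proportion",
      colour = "attribute"
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tds_curve
#' @param curve A `tds_curve`.
#' @export
plot_tds_curve <- function(curve, include_none = FALSE) {
  autoplot(curve, include_none = include_none)
}
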