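#' Exact discretization of trials into R intervals
#'
#' Splits normalized time `[0, 1]` into `R` equal intervals (the "dynamic
#' level") and computes, for every attribute `i` and interval `k`, `R`
#' times the integral of the binary dominance function over the interval —
#' i.e. the fraction of the interval during which attribute `i` was
#' dominant. Because dominance functions are piecewise constant, the
#' integral is evaluated in closed form as interval-overlap arithmetic; no
#' numerical quadrature is involved. Each interval's values sum to 1 across
#' the attributes (including `"none"`), and their mean over `k` recovers
#' the whole-trial dominance durations.
#'
#' @param trials A [tds_trialset()].
#' @param R Number of discretization intervals (positive integer). `R = 1`
#'   compares only dominance durations; large `R` compares timing.
#' @return A tibble of class `"tds_discretized"` with columns `trial_id`,
#'   `attribute`, `k` (interval index, `0..R-1`) and `X`, plus attributes
#'   `R` and `lexicon`.
#' @examples
#' lex <- tds_lexicon(c("sweet", "sour"))
#' tr <- tds_trial(data.frame(attribute = c("sweet", "sour"), time = c(0, 15)),
#'   start = 0, stop = 30, trial_id = "A1", lexicon = lex
#' )
#' discretize(tr, R = 2)
#' @export
discretize <- function(trials, R) {
  if (!inherits(trials, "tds_trialset")) {
    abort("`trials` must be a tds_trialset.", class = "tdsim_error_validation")
  }
  R <- check_R(R)
  lev <- lexicon_levels(lexicon(trials))
  seg <- trial_segments(trials)
  out <- lapply(trial_ids(trials), function(tid) {
    s <- seg[seg$trial_id == tid, ]
    X <- overlap_matrix(s$t_left, s$t_right, match(s$attribute, lev), length(lev), R)
    tibble(
      trial_id = tid,
      attribute = factor(rep(lev, times = R), levels = lev),
      k = rep(0:(R - 1L), each = length(lev)),
      X = as.vector(X)
    )
  })
  new_discretized(dplyr::bind_rows(out), R, lexicon(trials))
}

# Exact overlap of segments [left_j, right_j) carrying one-hot (or
# fractional, via `weights`) attribute rows with the R uniform intervals.
# Returns a (n_levels x R) matrix scaled by R.
overlap_matrix <- function(lefts, rights, attr_idx, n_levels, R) {
  X <- matrix(0, nrow = n_levels, ncol = R)
  for (j in seq_along(lefts)) {
    k_lo <- floor(lefts[j] * R)
    k_hi <- min(ceiling(rights[j] * R) - 1, R - 1)
    if (k_hi < k_lo) next
    ks <- k_lo:k_hi
    ov <- pmin(rights[j], (ks + 1) / R) - pmax(lefts[j], ks / R)
    X[attr_idx[j], ks + 1L] <- X[attr_idx[j], ks + 1L] + R * ov
  }
  X
}

new_discretized <- function(tbl, R, lexicon) {
  structure(
    as_tibble(tbl),
    R = R, lexicon = lexicon,
    class = c("tds_discretized", class(tibble()))
  )
}

#' @export
print.tds_discretized <- function(x, ...) {
  cat(sprintf(
    "<tds_discretized> R = %d, %d unit(s)\n",
    attr(x, "R"), length(unique(x$trial_id))
  ))
  NextMethod()
}

#' Discretize a dominance-proportion curve (the panel centroid)
#'
#' The same interval-averaging used for single trials, applied to a
#' piecewise-constant dominance curve. By linearity of the integral, the
#' discretized curve of a trial set equals the element-wise mean of the
#' trials' discretized matrices, exactly.
#'
#' @param curve A `tds_curve` from [dominance_proportions()].
#' @param R Number of intervals.
#' @return A `"tds_discretized"` tibble whose single unit has
#'   `trial_id = ".centroid"`.
#' @export
discretize_curve <- function(curve, R) {
  if (!inherits(curve, "tds_curve")) {
    abort("`curve` must be a tds_curve.", class = "tdsim_error_validation")
  }
  R <- check_R(R)
  cm <- curve_matrix(curve)
  n_seg <- nrow(cm$V)
  lev <- cm$levels
  X <- matrix(0, nrow = length(lev), ncol = R)
  for (j in seq_len(n_seg)) {
    lft <- cm$breaks[j]
    rgt <- cm$breaks[j + 1L]
    k_lo <- floor(lft * R)
    k_hi <- min(ceiling(rgt * R) - 1, R - 1)
    if (k_hi < k_lo) next
    ks <- k_lo:k_hi
    ov <- pmin(rgt, (ks + 1) / R) - pmax(lft, ks / R)
    X[, ks + 1L] <- X[, ks + 1L] + R * outer(cm$V[j, ], ov)
  }
  out <- tibble(
    trial_id = ".centroid",
    attribute = factor(rep(lev, times = R), levels = lev),
    k = rep(0:(R - 1L), each = length(lev)),
    X = as.vector(X)
  )
  new_discretized(out, R, lexicon(curve))
}

#' Matrix view of a discretized unit
#'
#' @param d A `"tds_discretized"`.
#' @param id Which unit; may be omitted when `d` holds exactly one.
#' @return A `(q+1) x R` matrix, rows named by attribute (`"none"`
#'   first), each column summing to 1.
#' @export
discretized_matrix <- function(d, id = NULL) {
  ids <- unique(d$trial_id)
  if (is.null(id)) {
    if (length(ids) != 1L) {
      abort("Discretized set holds several trials; name one.",
        class = "tdsim_error_validation"
      )
    }
    id <- ids
  }
  lev <- lexicon_levels(attr(d, "lexicon", exact = TRUE))
  R <- attr(d, "R", exact = TRUE)
  rows <- d[d$trial_id == id, ]
  rows <- rows[order(rows$k, match(rows$attribute, lev)), ]
  matrix(rows$X, nrow = length(lev), ncol = R,
    dimnames = list(lev, NULL)
  )
}
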