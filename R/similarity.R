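#' Similarity and dissimilarity between discretized TDS trials
#'
#' The dissimilarity between two trials (or a trial and the panel
#' centroid) at dynamic level `R` is the average per-interval distance
#' between their discretized matrices, normalized so its maximum value is
#' 1. With the default Euclidean metric it is
#' \deqn{D = \frac{1}{\sqrt{2}\,R} \sum_{k=0}^{R-1}
#'   \sqrt{\sum_{i=0}^{q} (X^{(a)}_i[k] - X^{(b)}_i[k])^2},}
#' since two intervals dominated by different single attributes are
#' `sqrt(2)` apart. The similarity index is `S = 1 - D`, in `[0, 1]`.
#' The Manhattan option normalizes by `2R` instead. The `"none"` state
#' participates in the sum, so a late first press genuinely differs from
#' an immediate one. Both inputs must share the same `R` and lexicon;
#' comparisons across different `R` are rejected, not resampled.
#'
#' @param A,B `"tds_discretized"` objects each holding a single unit (a
#'   trial or a centroid), or bare `(q+1) x R` matrices with identical
#'   dimensions.
#' @param metric `"euclidean"` (default, the index as defined) or
#'   `"manhattan"`.
#' @return A single number in `[0, 1]`.
#' @examples
#' lex <- tds_lexicon(c("sweet", "sour"))
#' a <- tds_trial(data.frame(attribute = "sweet", time = 0), 0, 30, "a", lexicon = lex)
#' b <- tds_trial(data.frame(attribute = "sour", time = 0), 0, 30, "b", lexicon = lex)
#' dissimilarity(discretize(a, 1), discretize(b, 1)) # maximal: 1
#' @export
dissimilarity <- function(A, B, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  XA <- as_discretized_matrix(A)
  XB <- as_discretized_matrix(B)
  if (!identical(dim(XA), dim(XB))) {
    abort(sprintf(
      "Shape mismatch: %d x %d vs %d x %d (same R and lexicon required).",
      nrow(XA), ncol(XA), nrow(XB), ncol(XB)
    ), class = "tdsim_error_shape")
  }
  if (inherits(A, "tds_discretized") && inherits(B, "tds_discretized") &&
    !identical(attr(A, "R", exact = TRUE), attr(B, "R", exact = TRUE))) {
    abort("Discretized inputs use different R values.", class = "tdsim_error_shape")
  }
  D <- XA - XB
  R <- ncol(XA)
  switch(metric,
    euclidean = sum(sqrt(colSums(D^2))) / (sqrt(2) * R),
    manhattan = sum(abs(D)) / (2 * R)
  )
}

#' @rdname dissimilarity
#' @export
similarity <- function(A, B, metric = c("euclidean", "manhattan")) {
  1 - dissimilarity(A, B, metric)
}

as_discretized_matrix <- function(x) {
  if (is.matrix(x)) {
    return(x)
  }
  if (inherits(x, "tds_discretized")) {
    return(discretized_matrix(x))
  }
  abort("Expected a tds_discretized object or a matrix.",
    class = "tdsim_error_validation"
  )
}

#' All pairwise similarities within a trial set
#'
#' @param trials A [tds_trialset()].
#' @param R Dynamic level.
#' @inheritParams dissimilarity
#' @return A tibble with columns `trial_a`, `trial_b`, `similarity`, one
#'   row per unordered pair.
#' @export
similarity_pairs <- function(trials, R, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  d <- discretize(trials, R)
  ids <- trial_ids(trials)
  mats <- lapply(ids, function(id) discretized_matrix(d, id))
  names(mats) <- ids
  pairs <- utils::combn(ids, 2L)
  tibble(
    trial_a = pairs[1L, ],
    trial_b = pairs[2L, ],
    similarity = purrr::map2_dbl(
      pairs[1L, ], pairs[2L, ],
      function(a, b) 1 - dissimilarity(mats[[a]], mats[[b]], metric)
    )
  )
}

#' Seconds per discretization interval
#'
#' For tasks averaging `mean_duration_s` seconds, one of the `R` intervals
#' spans `mean_duration_s / R` seconds — e.g. about 1.5 s per interval at
#' `R = 20` for 30-second tasks.
#'
#' @param mean_duration_s Mean task duration in seconds (positive).
#' @param R Dynamic level (positive).
#' @return Interval length in seconds.
#' @export
interval_seconds <- function(mean_duration_s, R) {
  stopifnot_scalar_number(mean_duration_s, "mean_duration_s", positive = TRUE)
  stopifnot_scalar_number(R, "R", positive = TRUE)
  mean_duration_s / R
}
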