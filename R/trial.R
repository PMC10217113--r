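#' TDS trial sets as tidy event tables
#'
#' A trial set holds `n` TDS trials sharing one attribute lexicon, as a
#' tibble with one row per dominance segment start: columns `trial_id`,
#' `panel_id`, `replicate`, `attribute`, `onset` (normalized time in
#' `[0, 1)`) and `duration_seconds` (the raw task length, `NA` if unknown).
#' Every trial starts with a row at `onset = 0`; if the first button press
#' happened after the task start that row carries the implicit `"none"`
#' state. Between one row's onset and the next (or 1 for the last row) the
#' row's attribute is the dominant one, so each trial is a right-continuous
#' step function and at every time exactly one attribute is dominant.
#'
#' @param events A data frame with columns `trial_id`, `attribute`, `onset`
#'   (normalized), and optionally `panel_id`, `replicate`,
#'   `duration_seconds`.
#' @param lexicon A [tds_lexicon()] (or character vector coerced to one).
#'
#' @return A tibble of class `"tds_trialset"` with the lexicon stored as an
#'   attribute.
#' @seealso [tds_trial()] to build a trial from raw second-valued
#'   timestamps, [simulate_panel()] for synthetic trial sets.
#' @export
tds_trialset <- function(events, lexicon) {
  lexicon <- as_tds_lexicon(lexicon)
  events <- as_tibble(events)
  required <- c("trial_id", "attribute", "onset")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols)) {
    abort(sprintf(
      "`events` lacks column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ), class = "tdsim_error_validation")
  }
  if (!"panel_id" %in% names(events)) events$panel_id <- events$trial_id
  if (!"replicate" %in% names(events)) events$replicate <- 1L
  if (!"duration_seconds" %in% names(events)) events$duration_seconds <- NA_real_
  events <- events[c(
    "trial_id", "panel_id", "replicate", "attribute", "onset",
    "duration_seconds"
  )]
  events$trial_id <- as.character(events$trial_id)
  events$panel_id <- as.character(events$panel_id)
  events$replicate <- as.integer(events$replicate)
  events$attribute <- as.character(events$attribute)
  events$onset <- as.numeric(events$onset)
  events$duration_seconds <- as.numeric(events$duration_seconds)
  if (nrow(events) == 0L) {
    abort("A trial set needs at least one trial.", class = "tdsim_error_validation")
  }
  check_attributes(events$attribute, lexicon, allow_none = TRUE)

  events <- dplyr::arrange(events, .data$trial_id, .data$onset)
  split_idx <- split(seq_len(nrow(events)), events$trial_id)
  for (ids in split_idx) {
    tid <- events$trial_id[ids[1L]]
    on <- events$onset[ids]
    at <- events$attribute[ids]
    if (anyNA(on) || any(on < 0) || any(on >= 1)) {
      abort(sprintf("Trial '%s': onsets must lie in [0, 1).", tid),
        class = "tdsim_error_validation"
      )
    }
    if (any(diff(on) <= 0)) {
      k <- which(diff(on) <= 0)[1L] + 1L
      abort(sprintf(
        "Trial '%s': onsets not strictly increasing at event %d (onset %g).",
        tid, k, on[k]
      ), class = "tdsim_error_validation")
    }
    if (on[1L] != 0) {
      abort(sprintf(
        "Trial '%s': first row must start at onset 0 (use tds_trial() to normalize raw events).",
        tid
      ), class = "tdsim_error_validation")
    }
    if (any(at[-1L] == "none")) {
      abort(sprintf(
        "Trial '%s': \"none\" may only occur before the first attribute selection.",
        tid
      ), class = "tdsim_error_validation")
    }
    if (any(at[-1L] == at[-length(at)])) {
      abort(sprintf(
        "Trial '%s': consecutive duplicate attributes (collapse re-presses first).",
        tid
      ), class = "tdsim_error_validation")
    }
    if (length(unique(events$panel_id[ids])) > 1L ||
      length(unique(events$replicate[ids])) > 1L) {
      abort(sprintf("Trial '%s': inconsistent panel_id/replicate.", tid),
        class = "tdsim_error_validation"
      )
    }
  }
  dup <- duplicated(unique(events[c("trial_id", "panel_id", "replicate")])$trial_id)
  if (any(dup)) {
    abort("trial_id values must identify trials uniquely.",
      class = "tdsim_error_validation"
    )
  }
  new_trialset(events, lexicon)
}

new_trialset <- function(events, lexicon) {
  structure(
    as_tibble(events),
    lexicon = lexicon,
    class = c("tds_trialset", class(tibble()))
  )
}

#' Build one TDS trial from raw button-press timestamps
#'
#' Timestamps in seconds are mapped affinely onto normalized time
#' `[0, 1]`: `onset = (time - start) / (stop - start)`. Consecutive
#' re-presses of the already-selected button are no-ops and are collapsed.
#' A trial with no selections at all is accepted (the `"none"` state holds
#' throughout) with a warning, since such degenerate trials are legitimate
#' data and natural outlier candidates.
#'
#' @param events A data frame with columns `attribute` and `time` (seconds),
#'   or `NULL`/zero rows for a selection-free trial.
#' @param start,stop Task start and stop times in seconds (`stop > start`).
#' @param trial_id,panel_id,replicate Trial identity; `panel_id` defaults to
#'   `trial_id`.
#' @param lexicon A [tds_lexicon()].
#'
#' @return A one-trial [tds_trialset()].
#' @examples
#' lex <- tds_lexicon(c("sweet", "sour"))
#' tds_trial(data.frame(attribute = c("sweet", "sour"), time = c(5, 20)),
#'   start = 0, stop = 30, trial_id = "A1", lexicon = lex
#' )
#' @export
tds_trial <- function(events, start, stop, trial_id, panel_id = trial_id,
                      replicate = 1L, lexicon) {
  lexicon <- as_tds_lexicon(lexicon)
  stopifnot_scalar_number(start, "start")
  stopifnot_scalar_number(stop, "stop")
  if (stop <= start) {
    abort(sprintf("`stop` (%g) must exceed `start` (%g).", stop, start),
      class = "tdsim_error_domain"
    )
  }
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    warn(sprintf(
      "Trial '%s' has no attribute selections; \"none\" is dominant throughout.",
      trial_id
    ))
    ev <- tibble(
      trial_id = as.character(trial_id), panel_id = as.character(panel_id),
      replicate = as.integer(replicate), attribute = "none", onset = 0,
      duration_seconds = stop - start
    )
    return(new_trialset(ev, lexicon))
  }
  events <- as_tibble(events)
  if (!all(c("attribute", "time") %in% names(events))) {
    abort("`events` needs columns `attribute` and `time` (seconds).",
      class = "tdsim_error_validation"
    )
  }
  check_attributes(events$attribute, lexicon)
  tm <- as.numeric(events$time)
  if (any(diff(tm) <= 0)) {
    k <- which(diff(tm) <= 0)[1L] + 1L
    abort(sprintf(
      "Trial '%s': non-monotone timestamp at event %d ('%s' at %g s).",
      trial_id, k, events$attribute[k], tm[k]
    ), class = "tdsim_error_validation")
  }
  if (any(tm < start | tm > stop)) {
    k <- which(tm < start | tm > stop)[1L]
    abort(sprintf(
      "Trial '%s': event %d ('%s' at %g s) outside [start, stop] = [%g, %g].",
      trial_id, k, events$attribute[k], tm[k], start, stop
    ), class = "tdsim_error_validation")
  }
  att <- as.character(events$attribute)
  keep <- c(TRUE, att[-1L] != att[-length(att)])
  att <- att[keep]
  tm <- tm[keep]
  onset <- (tm - start) / (stop - start)
  # a press exactly at the stop instant selects for zero time; drop it
  keep2 <- onset < 1
  att <- att[keep2]
  onset <- onset[keep2]
  if (length(att) == 0L) {
    return(tds_trial(NULL, start, stop, trial_id, panel_id, replicate, lexicon))
  }
  if (onset[1L] > 0) {
    att <- c("none", att)
    onset <- c(0, onset)
  }
  ev <- tibble(
    trial_id = as.character(trial_id), panel_id = as.character(panel_id),
    replicate = as.integer(replicate), attribute = att, onset = onset,
    duration_seconds = stop - start
  )
  new_trialset(ev, lexicon)
}

#' Combine trial sets sharing a lexicon
#'
#' @param ... `tds_trialset` objects with identical lexicons and disjoint
#'   trial ids.
#' @return A single [tds_trialset()].
#' @export
bind_trials <- function(...) {
  sets <- list(...)
  if (!length(sets)) abort("Nothing to bind.", class = "tdsim_error_domain")
  lex <- lexicon(sets[[1L]])
  for (s in sets) {
    if (!inherits(s, "tds_trialset")) {
      abort("All arguments must be tds_trialset objects.",
        class = "tdsim_error_validation"
      )
    }
    if (!identical(unclass(lexicon(s)), unclass(lex))) {
      abort("Trial sets use different lexicons.", class = "tdsim_error_lexicon")
    }
  }
  ids <- unlist(lapply(sets, trial_ids))
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "trial_id collision across sets: %s.",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ), class = "tdsim_error_validation")
  }
  tds_trialset(dplyr::bind_rows(lapply(sets, as_tibble)), lex)
}

#' @export
print.tds_trialset <- function(x, ...) {
  cat(sprintf(
    "<tds_trialset> %d trial(s), %d attribute(s) + \"none\"\n",
    n_trials(x), length(lexicon(x))
  ))
  NextMethod()
}

#' Accessors for trial sets
#'
#' @param x A [tds_trialset()].
#' @return `lexicon()` the [tds_lexicon()]; `trial_ids()` a character
#'   vector; `n_trials()` an integer; `trial_durations()` a tibble with
#'   `trial_id` and `duration_seconds`.
#' @export
lexicon <- function(x) attr(x, "lexicon", exact = TRUE)

#' @rdname lexicon
#' @export
trial_ids <- function(x) unique(x$trial_id)

#' @rdname lexicon
#' @export
n_trials <- function(x) length(trial_ids(x))

#' @rdname lexicon
#' @export
trial_durations <- function(x) {
  dplyr::distinct(as_tibble(x)[c("trial_id", "panel_id", "replicate", "duration_seconds")])
}

# Per-trial partition of [0, 1] into dominance segments:
# tibble(trial_id, attribute, t_left, t_right).
trial_segments <- function(x) {
  ev <- as_tibble(x)
  ev <- dplyr::arrange(ev, .data$trial_id, .data$onset)
  ev <- dplyr::group_by(ev, .data$trial_id)
  ev <- dplyr::mutate(ev,
    t_left = .data$onset,
    t_right = dplyr::lead(.data$onset, default = 1)
  )
  dplyr::ungroup(ev)[c("trial_id", "attribute", "t_left", "t_right")]
}

#' Dominant attribute at given times
#'
#' Evaluates each trial's step function at normalized times `t` under the
#' half-open segment convention `[onset_k, onset_{k+1})`; `t = 1` returns
#' the final segment's attribute.
#'
#' @param trials A [tds_trialset()].
#' @param t Numeric vector of normalized times in `[0, 1]`.
#' @return A tibble with columns `trial_id`, `t`, `attribute`.
#' @export
dominant_at <- function(trials, t) {
  if (!is.numeric(t) || anyNA(t) || any(t < 0 | t > 1)) {
    abort("`t` must be numeric in [0, 1].", class = "tdsim_error_domain")
  }
  ev <- as_tibble(trials)
  res <- lapply(trial_ids(trials), function(tid) {
    rows <- ev[ev$trial_id == tid, ]
    rows <- rows[order(rows$onset), ]
    idx <- findInterval(t, rows$onset)  # onset[1] == 0, so idx >= 1
    tibble(trial_id = tid, t = t, attribute = rows$attribute[idx])
  })
  dplyr::bind_rows(res)
}

#' Per-trial dominance durations
#'
#' The total normalized time each attribute (including the `"none"` state)
#' is dominant within each trial. Durations per trial sum to 1; this equals
#' the single-interval discretization of the trial.
#'
#' @param trials A [tds_trialset()].
#' @return A tibble with columns `trial_id`, `attribute` (a factor over
#'   `"none"` and the lexicon), and `duration`, complete over all
#'   attributes.
#' @export
dominance_durations <- function(trials) {
  lev <- lexicon_levels(lexicon(trials))
  seg <- trial_segments(trials)
  seg$len <- seg$t_right - seg$t_left
  out <- dplyr::summarise(
    dplyr::group_by(seg, .data$trial_id, .data$attribute),
    duration = sum(.data$len), .groups = "drop"
  )
  out$attribute <- factor(out$attribute, levels = lev)
  out <- tidyr::complete(out, .data$trial_id, .data$attribute,
    fill = list(duration = 0)
  )
  dplyr::arrange(out, .data$trial_id, .data$attribute)
}
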