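#' Read and write TDS trial sets
#'
#' Two interchange formats are supported. The CSV dialect is a long event
#' log — one row per button press with columns `trial_id`, `panel_id`,
#' `replicate`, `attribute`, `onset_seconds` — where each trial's rows
#' are delimited by sentinel attributes `"START"` and `"STOP"` whose
#' `onset_seconds` give the task start and stop times; timestamps are
#' normalized on read. The JSON document carries full fidelity (lexicon
#' embedded, times either in seconds with a duration or pre-normalized
#' with `"normalized": true`). CSV is the default because sensory
#' scientists live in spreadsheets. Trials without a recorded duration
#' are written to CSV on the normalized scale (`STOP` at 1), so their
#' duration reads back as 1; use JSON to preserve an unknown duration.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; the default guesses from the file
#'   extension.
#' @param lexicon A [tds_lexicon()]; required for CSV, optional for JSON
#'   (which embeds it).
#' @param trials A [tds_trialset()].
#' @return `read_trials()` a [tds_trialset()]; `write_trials()` the path,
#'   invisibly.
#' @export
read_trials <- function(path, format = c("auto", "csv", "json"),
                        lexicon = NULL) {
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") read_tds_csv(path, lexicon) else read_tds_json(path, lexicon)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") write_tds_csv(trials, path) else write_tds_json(trials, path)
}

resolve_format <- function(format, path) {
  if (format != "auto") {
    return(format)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}

#' @rdname read_trials
#' @export
write_tds_csv <- function(trials, path) {
  if (!inherits(trials, "tds_trialset")) {
    abort("`trials` must be a tds_trialset.", class = "tdsim_error_validation")
  }
  ev <- as_tibble(trials)
  rows <- lapply(trial_ids(trials), function(tid) {
    tr <- ev[ev$trial_id == tid, ]
    dur <- tr$duration_seconds[1L]
    if (is.na(dur)) dur <- 1
    sel <- tr[tr$attribute != "none", ]
    dplyr::bind_rows(
      tibble(
        trial_id = tid, panel_id = tr$panel_id[1L],
        replicate = tr$replicate[1L], attribute = "START", onset_seconds = 0
      ),
      tibble(
        trial_id = tid, panel_id = tr$panel_id[1L],
        replicate = tr$replicate[1L], attribute = sel$attribute,
        onset_seconds = sel$onset * dur
      ),
      tibble(
        trial_id = tid, panel_id = tr$panel_id[1L],
        replicate = tr$replicate[1L], attribute = "STOP", onset_seconds = dur
      )
    )
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' @rdname read_trials
#' @export
read_tds_csv <- function(path, lexicon) {
  if (is.null(lexicon)) {
    abort("CSV files carry no lexicon; pass `lexicon`.",
      class = "tdsim_error_lexicon"
    )
  }
  lexicon <- as_tds_lexicon(lexicon)
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      trial_id = readr::col_character(),
      panel_id = readr::col_character(),
      replicate = readr::col_integer(),
      attribute = readr::col_character(),
      onset_seconds = readr::col_double()
    )
  )
  required <- c("trial_id", "panel_id", "replicate", "attribute", "onset_seconds")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(sprintf(
      "%s: missing column(s) %s.", path,
      paste(missing_cols, collapse = ", ")
    ), class = "tdsim_error_parse")
  }
  raw$line <- seq_len(nrow(raw)) + 1L # header is line 1
  sets <- lapply(split(raw, factor(raw$trial_id, levels = unique(raw$trial_id))),
    function(tr) {
      tid <- tr$trial_id[1L]
      if (tr$attribute[1L] != "START" || tail(tr$attribute, 1L) != "STOP" ||
        sum(tr$attribute %in% c("START", "STOP")) != 2L) {
        abort(sprintf(
          "Trial '%s' (lines %d-%d): rows must be START, events..., STOP.",
          tid, tr$line[1L], tail(tr$line, 1L)
        ), class = "tdsim_error_parse")
      }
      start <- tr$onset_seconds[1L]
      stop <- tail(tr$onset_seconds, 1L)
      body <- tr[-c(1L, nrow(tr)), ]
      if (any(diff(tr$onset_seconds) < 0)) {
        k <- which(diff(tr$onset_seconds) < 0)[1L] + 1L
        abort(sprintf(
          "Trial '%s', line %d: decreasing timestamp (%g s).",
          tid, tr$line[k], tr$onset_seconds[k]
        ), class = "tdsim_error_parse")
      }
      ev <- if (nrow(body)) {
        tibble(attribute = body$attribute, time = body$onset_seconds)
      } else {
        NULL
      }
      tds_trial(ev, start, stop, tid,
        panel_id = tr$panel_id[1L],
        replicate = tr$replicate[1L], lexicon = lexicon
      )
    }
  )
  tds_trialset(dplyr::bind_rows(lapply(sets, as_tibble)), lexicon)
}

#' @rdname read_trials
#' @export
write_tds_json <- function(trials, path) {
  if (!inherits(trials, "tds_trialset")) {
    abort("`trials` must be a tds_trialset.", class = "tdsim_error_validation")
  }
  ev <- as_tibble(trials)
  doc <- list(
    lexicon = as.character(lexicon(trials)),
    normalized = TRUE,
    trials = lapply(trial_ids(trials), function(tid) {
      tr <- ev[ev$trial_id == tid, ]
      sel <- tr[tr$attribute != "none", ]
      list(
        trial_id = tid,
        panel_id = tr$panel_id[1L],
        replicate = tr$replicate[1L],
        duration_seconds = tr$duration_seconds[1L],
        events = lapply(seq_len(nrow(sel)), function(i) {
          list(attribute = sel$attribute[i], onset = sel$onset[i])
        })
      )
    })
  )
  jsonlite::write_json(doc, path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname read_trials
#' @export
read_tds_json <- function(path, lexicon = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lex <- if (!is.null(lexicon)) {
    as_tds_lexicon(lexicon)
  } else if (!is.null(doc$lexicon)) {
    tds_lexicon(unlist(doc$lexicon))
  } else {
    abort(sprintf("%s: no lexicon in document and none supplied.", path),
      class = "tdsim_error_lexicon"
    )
  }
  normalized <- isTRUE(doc$normalized)
  sets <- lapply(doc$trials, function(tr) {
    if (is.null(tr$trial_id)) {
      abort(sprintf("%s: a trial lacks trial_id.", path),
        class = "tdsim_error_parse"
      )
    }
    events <- tr$events %||% list()
    att <- vapply(events, function(e) as.character(e$attribute), character(1))
    onset <- vapply(events, function(e) as.numeric(e$onset), numeric(1))
    dur <- if (is.null(tr$duration_seconds)) {
      NA_real_
    } else {
      suppressWarnings(as.numeric(tr$duration_seconds))
    }
    if (normalized) {
      stop_s <- 1
      start_s <- 0
      tm <- onset
    } else {
      if (is.na(dur)) {
        abort(sprintf(
          "%s: trial '%s' has second-valued times but no duration_seconds.",
          path, tr$trial_id
        ), class = "tdsim_error_parse")
      }
      stop_s <- dur
      start_s <- 0
      tm <- onset
    }
    out <- tds_trial(
      if (length(att)) tibble(attribute = att, time = tm) else NULL,
      start_s, stop_s, tr$trial_id,
      panel_id = tr$panel_id %||% tr$trial_id,
      replicate = tr$replicate %||% 1L, lexicon = lex
    )
    # normalized documents still carry the true duration separately
    tbl <- as_tibble(out)
    tbl$duration_seconds <- dur
    tbl
  })
  tds_trialset(dplyr::bind_rows(sets), lex)
}

#' Tabular exports in the shapes used for reporting
#'
#' `write_corgrid_csv()` writes a correlation grid as a square matrix
#' with the R values as header row and column. `write_flags_csv()`
#' writes the trials-by-R flag matrix with `"+"` marks.
#' `write_discretized_csv()` writes one discretized unit wide: rows are
#' attributes (including `"none"`), columns the R intervals.
#'
#' @param grid A `"tds_corgrid"`.
#' @param report A `"tds_outlier_report"`.
#' @param d A `"tds_discretized"`.
#' @param path Output path.
#' @param all_trials Passed to [flag_matrix()].
#' @return The path, invisibly.
#' @export
write_corgrid_csv <- function(grid, path) {
  m <- attr(grid, "matrix")
  out <- as_tibble(as.data.frame(m), rownames = "R")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_corgrid_csv
#' @export
write_flags_csv <- function(report, path, all_trials = FALSE) {
  readr::write_csv(flag_matrix(report, all_trials = all_trials), path)
  invisible(path)
}

#' @rdname write_corgrid_csv
#' @export
write_discretized_csv <- function(d, path) {
  X <- as_discretized_matrix(d)
  out <- as_tibble(as.data.frame(X), rownames = "attribute")
  names(out)[-1L] <- sprintf("k%d", seq_len(ncol(X)) - 1L)
  readr::write_csv(out, path)
  invisible(path)
}
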