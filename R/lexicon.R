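#' Attribute lexicon for TDS tasks
#'
#' A TDS task presents the panelist with `q` labelled attribute buttons.
#' The lexicon records those `q` labels in button order (indices `1..q`);
#' index `0` is always the implicit `"none"` state that holds before the
#' first button press and is never a user-supplied label.
#'
#' @param names Character vector of `q >= 1` unique, non-empty attribute
#'   labels. The reserved labels `"none"`, `"START"` and `"STOP"` are
#'   rejected.
#'
#' @return A character vector of class `"tds_lexicon"`.
#' @examples
#' tds_lexicon(c("sweet", "sour"))
#' @export
tds_lexicon <- function(names) {
  names <- as.character(names)
  if (length(names) < 1L) {
    abort("A lexicon needs at least one attribute (q >= 1).",
      class = "tdsim_error_lexicon"
    )
  }
  if (anyNA(names) || any(!nzchar(names))) {
    abort("Attribute labels must be non-empty and non-missing.",
      class = "tdsim_error_lexicon"
    )
  }
  if (anyDuplicated(names)) {
    abort(sprintf(
      "Duplicate attribute labels: %s.",
      paste(unique(names[duplicated(names)]), collapse = ", ")
    ), class = "tdsim_error_lexicon")
  }
  reserved <- intersect(names, c("none", "START", "STOP"))
  if (length(reserved)) {
    abort(sprintf(
      "Reserved labels cannot be attributes: %s.",
      paste(reserved, collapse = ", ")
    ), class = "tdsim_error_lexicon")
  }
  structure(names, class = "tds_lexicon")
}

#' @export
print.tds_lexicon <- function(x, ...) {
  cat(sprintf(
    "<tds_lexicon> q = %d: %s (+ implicit \"none\")\n",
    length(x), paste(unclass(x), collapse = ", ")
  ))
  invisible(x)
}

# Attribute labels including the implicit "none" state (index 0 first).
lexicon_levels <- function(lexicon) c("none", as.character(lexicon))

as_tds_lexicon <- function(x) {
  if (inherits(x, "tds_lexicon")) x else tds_lexicon(x)
}

check_attributes <- function(attribute, lexicon, allow_none = FALSE) {
  ok <- if (allow_none) lexicon_levels(lexicon) else as.character(lexicon)
  bad <- setdiff(unique(as.character(attribute)), ok)
  if (length(bad)) {
    abort(sprintf(
      "Attribute(s) not in lexicon: %s. Lexicon has: %s.",
      paste(bad, collapse = ", "), paste(as.character(lexicon), collapse = ", ")
    ), class = "tdsim_error_lexicon")
  }
  invisible(attribute)
}
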