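# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All exported stochastic functions route through
# this so no global random state leaks.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing integer.", class = "tdsim_error_domain")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds derived from a master seed; keeps every child
# below 2^31 so they remain valid R integers.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name), class = "tdsim_error_domain")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive (got %g).", name, x),
      class = "tdsim_error_domain"
    )
  }
  invisible(x)
}

check_R <- function(R) {
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R < 1 || R != floor(R)) {
    abort("`R` must be a single positive integer.", class = "tdsim_error_domain")
  }
  as.integer(R)
}
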