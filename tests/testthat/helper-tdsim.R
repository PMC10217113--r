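# Shared fixtures, generated in code.

test_lex <- tds_lexicon(c("sweet", "sour", "fruity", "green"))

# A random valid trial: 0..max_events selections at uniform times, no
# consecutive duplicates. Deterministic given `seed`.
random_trial <- function(seed, trial_id = "T", lexicon = test_lex,
                         max_events = 6, duration = 30) {
  tdsim:::with_seed(seed, {
    m <- sample(0:max_events, 1L)
    if (m == 0L) {
      return(suppressWarnings(
        tds_trial(NULL, 0, duration, trial_id, lexicon = lexicon)
      ))
    }
    times <- sort(runif(m, 0, duration * 0.99))
    times <- times[c(TRUE, diff(times) > 1e-9)]
    atts <- character(length(times))
    prev <- ""
    for (i in seq_along(times)) {
      atts[i] <- sample(setdiff(as.character(lexicon), prev), 1L)
      prev <- atts[i]
    }
    tds_trial(data.frame(attribute = atts, time = times), 0, duration,
      trial_id,
      lexicon = lexicon
    )
  })
}

random_trialset <- function(seed, n, lexicon = test_lex, ...) {
  seeds <- tdsim:::child_seeds(seed, n)
  sets <- lapply(seq_len(n), function(i) {
    random_trial(seeds[i], trial_id = sprintf("T%02d", i), lexicon = lexicon, ...)
  })
  do.call(bind_trials, sets)
}

# Independent midpoint-rule quadrature of the discretization integral:
# returns the matrix of plain integrals (closed form / R), on a uniform
# grid of the given step. Works straight off the event table, not the
# overlap arithmetic under test.
riemann_discretize <- function(trial, R, grid = 1e-5) {
  ev <- tibble::as_tibble(trial)
  ev <- ev[order(ev$onset), ]
  lev <- c("none", as.character(lexicon(trial)))
  G <- round(1 / grid)
  mids <- (seq_len(G) - 0.5) / G
  att <- match(ev$attribute[findInterval(mids, ev$onset)], lev)
  bin <- pmin(floor(mids * R), R - 1L)
  counts <- tabulate(att + bin * length(lev), nbins = length(lev) * R)
  matrix(counts / G, nrow = length(lev), dimnames = list(lev, NULL))
}

# Simple two-attribute trial switching at a given normalized time.
switch_trial <- function(t_switch, trial_id = "S", lexicon = test_lex,
                         a = "sweet", b = "sour", duration = 30) {
  tds_trial(
    data.frame(attribute = c(a, b), time = c(0, t_switch * duration)),
    0, duration, trial_id,
    lexicon = lexicon
  )
}

# Whole-trial single-attribute trial.
const_trial <- function(attribute, trial_id = attribute,
                        lexicon = test_lex, duration = 30) {
  tds_trial(data.frame(attribute = attribute, time = 0), 0, duration,
    trial_id,
    lexicon = lexicon
  )
}
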