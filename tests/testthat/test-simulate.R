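test_that("spec validation names the offending row or parameter", {
  lex2 <- tds_lexicon(c("a", "b"))
  ok_T <- rbind(c(0, 1), c(1, 0))
  expect_s3_class(
    semi_markov_spec(lex2, c(0.5, 0.5), ok_T),
    "tds_sm_spec"
  )
  expect_error(
    semi_markov_spec(lex2, c(0.7, 0.5), ok_T),
    "probability vector", class = "tdsim_error_spec"
  )
  expect_error(
    semi_markov_spec(lex2, c(0.5, 0.5), rbind(c(0, 0.6), c(1, 0))),
    "row\\(s\\) 1", class = "tdsim_error_spec"
  )
  expect_error(
    semi_markov_spec(lex2, c(0.5, 0.5), rbind(c(0.5, 0.5), c(1, 0))),
    "zero diagonal", class = "tdsim_error_spec"
  )
  expect_error(
    semi_markov_spec(lex2, c(0.5, 0.5), ok_T, sojourn_mean = -1),
    class = "tdsim_error_spec"
  )
})

test_that("degenerate specs simulate the exact trial they describe", {
  # one attribute, no lead-in: dominant throughout
  lex1 <- tds_lexicon("only")
  s1 <- semi_markov_spec(lex1, 1, matrix(0, 1, 1),
    duration_mean = 30, duration_sd = 0
  )
  tr <- simulate_trial(s1, seed = 4)
  ev <- tibble::as_tibble(tr)
  expect_equal(ev$attribute, "only")
  expect_equal(ev$onset, 0)

  # two states, deterministic alternation, constant sojourn = half the task
  lex2 <- tds_lexicon(c("a", "b"))
  s2 <- semi_markov_spec(lex2, c(1, 0), rbind(c(0, 1), c(1, 0)),
    sojourn_mean = 15, sojourn_sd = 0, duration_mean = 30, duration_sd = 0
  )
  ev2 <- tibble::as_tibble(simulate_trial(s2, seed = 4))
  expect_equal(ev2$attribute, c("a", "b"))
  expect_equal(ev2$onset, c(0, 0.5))
})

test_that("panels have the letter-digit id convention and are seed-deterministic", {
  spec <- strawberry_spec()
  panel <- simulate_panel(spec, seed = 2)
  expect_equal(n_trials(panel), 51L)
  expect_true(all(c("A1", "A2", "A3", "Q3") %in% trial_ids(panel)))
  expect_equal(n_trials(simulate_panel(spec, seed = 2, n_panels = 1, replicates = 1)), 1L)

  again <- simulate_panel(spec, seed = 2)
  expect_identical(tibble::as_tibble(panel), tibble::as_tibble(again))
  other <- simulate_panel(spec, seed = 3)
  expect_false(identical(tibble::as_tibble(panel), tibble::as_tibble(other)))

  # per-panelist random effects stay deterministic and validly structured
  het <- simulate_panel(spec, seed = 2, n_panels = 4, replicates = 2,
    panel_effect_sd = 0.3
  )
  het2 <- simulate_panel(spec, seed = 2, n_panels = 4, replicates = 2,
    panel_effect_sd = 0.3
  )
  expect_identical(tibble::as_tibble(het), tibble::as_tibble(het2))
  expect_equal(n_trials(het), 8L)
})

test_that("simulated trials satisfy the trial model by construction", {
  panel <- simulate_panel(strawberry_spec(), seed = 6, n_panels = 10)
  # re-validation passes and durations sum to 1
  revalidated <- tds_trialset(tibble::as_tibble(panel), lexicon(panel))
  expect_equal(n_trials(revalidated), 30L)
  dd <- dominance_durations(panel)
  sums <- tapply(dd$duration, dd$trial_id, sum)
  expect_equal(as.numeric(sums), rep(1, 30), tolerance = 1e-12)
})

test_that("empirical sojourns and durations recover the spec parameters", {
  lex2 <- tds_lexicon(c("a", "b"))
  spec <- semi_markov_spec(lex2, c(0.5, 0.5), rbind(c(0, 1), c(1, 0)),
    sojourn_mean = 3, sojourn_sd = 1.5,
    duration_mean = 300, duration_sd = 0
  )
  panel <- simulate_panel(spec, seed = 8, n_panels = 40, replicates = 1)
  ev <- tibble::as_tibble(panel)
  gaps <- unlist(lapply(split(ev, ev$trial_id), function(tr) {
    diff(tr$onset[tr$attribute != "none"]) * 300
  }))
  se <- 1.5 / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 3), 3 * se)
})

test_that("the strawberry preset shows the early-sweet / late-sour signature", {
  panel <- simulate_panel(strawberry_spec(),
    seed = 12,
    n_panels = 334, replicates = 3
  )
  curve <- dominance_proportions(panel)
  df <- tibble::as_tibble(curve)
  df$len <- df$t_right - df$t_left
  phase_mean <- function(att, lo, hi) {
    rows <- df$attribute == att & df$t_left >= lo & df$t_right <= hi + 1e-12
    sum(df$p[rows] * df$len[rows]) / sum(df$len[rows])
  }
  expect_gt(phase_mean("sweet", 0, 1 / 3), phase_mean("sweet", 2 / 3, 1))
  expect_gt(phase_mean("sour", 2 / 3, 1), phase_mean("sour", 0, 1 / 3))
  expect_gt(
    phase_mean("aromatic", 1 / 3, 2 / 3),
    max(phase_mean("aromatic", 0, 1 / 3), 1e-9)
  )
})

test_that("outlier injection replaces only the target trial", {
  panel <- simulate_panel(strawberry_spec(), seed = 14, n_panels = 6)
  out <- inject_outlier(panel, "single_attribute", "C2", attribute = "sour")
  dd <- dominance_durations(out)
  c2 <- dd[dd$trial_id == "C2", ]
  expect_equal(sum(c2$duration > 0), 1L)
  expect_equal(c2$duration[c2$attribute == "sour"], 1)

  before <- tibble::as_tibble(panel)
  after <- tibble::as_tibble(out)
  expect_identical(
    before[before$trial_id != "C2", ],
    after[after$trial_id != "C2", ]
  )
  expect_error(
    inject_outlier(panel, "single_attribute", "nope", attribute = "sour"),
    class = "tdsim_error_validation"
  )
})

test_that("time-shifted injection preserves durations but not timing", {
  panel <- simulate_panel(strawberry_spec(), seed = 15, n_panels = 6)
  out <- inject_outlier(panel, "time_shifted", "A1")
  d_before <- dominance_durations(panel)
  d_after <- dominance_durations(out)
  expect_equal(
    d_before$duration[d_before$trial_id == "A1"],
    d_after$duration[d_after$trial_id == "A1"],
    tolerance = 1e-12
  )
  X0 <- discretized_matrix(discretize(panel, 100), "A1")
  X1 <- discretized_matrix(discretize(out, 100), "A1")
  expect_lt(1 - dissimilarity(X0, X1), 0.75) # timing visibly changed
})

test_that("rare-attribute injection dwells on the panel's least-used attributes", {
  spec <- strawberry_spec()
  panel <- simulate_panel(spec, seed = 16, n_panels = 6)
  out <- inject_outlier(panel, "rare_attributes", "B1", spec = spec, seed = 99)
  dd <- dominance_durations(out)
  b1 <- dd[dd$trial_id == "B1" & dd$duration > 0, ]
  used <- setdiff(as.character(b1$attribute), "none")
  expect_true(all(used %in% c("green", "light", "aromatic")))
  expect_gt(length(used), 0L)
})
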