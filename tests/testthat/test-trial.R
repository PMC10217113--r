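test_that("raw timestamps are normalized affinely onto [0, 1)", {
  lex <- tds_lexicon(c("sweet", "sour"))
  tr <- tds_trial(
    data.frame(attribute = c("sweet", "sour"), time = c(5, 20)),
    start = 0, stop = 30, trial_id = "A1", lexicon = lex
  )
  ev <- tibble::as_tibble(tr)
  expect_equal(ev$attribute, c("none", "sweet", "sour"))
  expect_equal(ev$onset, c(0, 1 / 6, 2 / 3))
  expect_equal(ev$duration_seconds, rep(30, 3))

  shifted <- tds_trial(
    data.frame(attribute = c("sweet", "sour"), time = c(15, 30)),
    start = 10, stop = 40, trial_id = "A2", lexicon = lex
  )
  expect_equal(tibble::as_tibble(shifted)$onset, c(0, 1 / 6, 2 / 3))
})

test_that("re-pressing the selected button is a no-op", {
  tr <- tds_trial(
    data.frame(attribute = c("sweet", "sweet", "sour"), time = c(5, 12, 20)),
    0, 30, "A1",
    lexicon = test_lex
  )
  expect_equal(sum(tibble::as_tibble(tr)$attribute != "none"), 2L)
})

test_that("selection-free trials are accepted with a warning and are all none", {
  expect_warning(
    tr <- tds_trial(NULL, 0, 30, "Z1", lexicon = test_lex),
    "no attribute selections"
  )
  dd <- dominance_durations(tr)
  expect_equal(dd$duration[dd$attribute == "none"], 1)
  expect_equal(sum(dd$duration), 1)
})

test_that("malformed trials are rejected with informative errors", {
  expect_error(
    tds_trial(data.frame(attribute = c("sweet", "sour"), time = c(20, 5)),
      0, 30, "B1",
      lexicon = test_lex
    ),
    "non-monotone", class = "tdsim_error_validation"
  )
  expect_error(
    tds_trial(data.frame(attribute = "umami", time = 5), 0, 30, "B2",
      lexicon = test_lex
    ),
    "not in lexicon", class = "tdsim_error_lexicon"
  )
  expect_error(
    tds_trial(data.frame(attribute = "sweet", time = 5), 30, 30, "B3",
      lexicon = test_lex
    ),
    class = "tdsim_error_domain"
  )
  expect_error(
    tds_trial(data.frame(attribute = "sweet", time = 40), 0, 30, "B4",
      lexicon = test_lex
    ),
    "outside", class = "tdsim_error_validation"
  )
})

test_that("lexicon validation rejects duplicates, empties and reserved labels", {
  expect_error(tds_lexicon(character(0)), class = "tdsim_error_lexicon")
  expect_error(tds_lexicon(c("a", "a")), class = "tdsim_error_lexicon")
  expect_error(tds_lexicon(c("a", "")), class = "tdsim_error_lexicon")
  expect_error(tds_lexicon(c("a", "none")), class = "tdsim_error_lexicon")
})

test_that("evaluation uses half-open segments, right-continuous, closed at 1", {
  tr <- tds_trial(data.frame(attribute = "sweet", time = 6), 0, 30, "E1",
    lexicon = test_lex
  )
  got <- dominant_at(tr, c(0.1, 0.2, 0.5, 1))
  expect_equal(got$attribute, c("none", "sweet", "sweet", "sweet"))
  expect_error(dominant_at(tr, 1.5), class = "tdsim_error_domain")
})

test_that("exactly one attribute is dominant at any time (random trials)", {
  set <- random_trialset(101, 8)
  ts <- tdsim:::with_seed(42, runif(50))
  dom <- dominant_at(set, ts)
  # one well-defined attribute per (trial, t): n_trials * n_t rows, no NAs
  expect_equal(nrow(dom), 8L * 50L)
  expect_false(anyNA(dom$attribute))
  counts <- dplyr::count(dom, trial_id, t)
  expect_true(all(counts$n == 1L))
})

test_that("dominance durations sum to one on random trials", {
  for (s in 1:20) {
    dd <- dominance_durations(random_trial(s))
    expect_equal(sum(dd$duration), 1, tolerance = 1e-12)
    expect_true(all(dd$duration >= 0))
  }
})

test_that("dominance proportions match pointwise averaging of indicators", {
  set <- random_trialset(7, 5)
  curve <- dominance_proportions(set)
  ts <- tdsim:::with_seed(9, runif(100))
  dom <- dominant_at(set, ts)
  cm <- tdsim:::curve_matrix(curve)
  for (t in ts) {
    seg <- findInterval(t, cm$breaks, rightmost.closed = TRUE)
    manual <- table(factor(dom$attribute[dom$t == t], levels = cm$levels)) / 5
    expect_equal(unname(cm$V[seg, ]), as.vector(manual), tolerance = 1e-12)
  }
  # segment values sum to 1 and are multiples of 1/n
  sums <- tapply(curve$p, curve$t_left, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  expect_equal(curve$p * 5, round(curve$p * 5), tolerance = 1e-9)
})

test_that("a single-trial curve reproduces the trial's indicators", {
  tr <- switch_trial(0.4)
  curve <- dominance_proportions(tr)
  expect_true(all(curve$p %in% c(0, 1)))
  d1 <- discretized_matrix(discretize(tr, 7))
  d2 <- discretized_matrix(discretize_curve(curve, 7))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("smoothing preserves the per-segment simplex and constants", {
  set <- random_trialset(11, 6)
  curve <- dominance_proportions(set)
  expect_identical(smooth_curve(curve, 0), curve)
  sm <- smooth_curve(curve, 0.1)
  sums <- tapply(sm$p, sm$t_left, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  expect_true(all(sm$p >= -1e-15))
  expect_error(smooth_curve(curve, 1.5), class = "tdsim_error_domain")

  # a constant curve is a fixed point of smoothing
  flat <- dominance_proportions(bind_trials(
    const_trial("sweet", "c1"), const_trial("sour", "c2")
  ))
  smf <- smooth_curve(flat, 0.3)
  expect_true(all(abs(smf$p[smf$attribute == "sweet"] - 0.5) < 1e-12))
})

test_that("smoothing a step matches direct moving-average convolution", {
  tr <- switch_trial(0.5)
  curve <- dominance_proportions(tr)
  n_grid <- 512L
  sm <- smooth_curve(curve, 0.1, n_grid = n_grid)
  # direct oracle on the same grid
  mid <- (seq_len(n_grid) - 0.5) / n_grid
  x_sweet <- as.numeric(mid < 0.5)
  half <- max(1L, round(0.05 * n_grid))
  oracle <- vapply(seq_len(n_grid), function(j) {
    w <- max(1L, j - half):min(n_grid, j + half)
    mean(x_sweet[w])
  }, numeric(1))
  got <- sm$p[sm$attribute == "sweet"][order(sm$t_left[sm$attribute == "sweet"])]
  expect_equal(got, oracle, tolerance = 1e-12)
  # ramp of width ~0.1 around the step
  expect_true(all(got[mid < 0.44] == 1) && all(got[mid > 0.56] == 0))
  expect_true(any(got > 0 & got < 1))
})
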