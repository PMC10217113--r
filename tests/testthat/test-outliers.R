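test_that("KS normality check accepts near-normal and rejects two-point samples", {
  x <- qnorm((1:30) / 31)
  expect_gt(ks_normality(x), 0.5)
  y <- tdsim:::with_seed(1, sample(c(0, 1), 50, replace = TRUE))
  expect_lt(ks_normality(y), 0.05)
  expect_error(ks_normality(rep(0.5, 20)), class = "tdsim_error_degenerate")
  expect_error(ks_normality(c(0.1, 0.2)), class = "tdsim_error_domain")
  # the Lilliefors mode is more conservative but agrees on the extremes
  expect_gt(ks_normality(x, "lilliefors"), 0.1)
  expect_lt(ks_normality(y, "lilliefors"), 0.05)
})

test_that("the normal screen flags strictly below mu - k sigma, low side only", {
  C <- tibble::tibble(
    trial_id = paste0("t", 1:5),
    similarity = c(0.8, 0.8, 0.8, 0.8, 0.2)
  )
  scr <- detect_outliers_normal(C, 0.95)
  expect_equal(attr(scr, "mu"), 0.68)
  expect_equal(attr(scr, "sigma"), sqrt(0.072), tolerance = 1e-12)
  expect_equal(attr(scr, "threshold"), 0.68 - 1.64 * sqrt(0.072), tolerance = 1e-12)
  expect_equal(round(attr(scr, "threshold"), 3), 0.24)
  expect_equal(scr$trial_id[scr$flagged], "t5")

  # the 99% screen is stricter: flags are a subset of the 95% flags
  scr99 <- detect_outliers_normal(C, 0.99)
  expect_true(all(scr99$trial_id[scr99$flagged] %in% scr$trial_id[scr$flagged]))

  # an unusually HIGH similarity is never an outlier
  high <- tibble::tibble(
    trial_id = paste0("t", 1:5),
    similarity = c(0.5, 0.5, 0.5, 0.5, 0.99)
  )
  expect_equal(sum(detect_outliers_normal(high, 0.95)$flagged), 0L)

  # flagging is strictly-below: values at or above the threshold stay in
  expect_identical(scr$flagged, scr$similarity < attr(scr, "threshold"))

  expect_warning(flat <- detect_outliers_normal(rep(0.7, 6), 0.95), "identical")
  expect_equal(sum(flat$flagged), 0L)
  expect_error(detect_outliers_normal(C, 0.9), class = "tdsim_error_domain")
})

test_that("the IQR screen is one-sided with type-7 quartiles", {
  sym <- tibble::tibble(
    trial_id = paste0("t", 1:7),
    similarity = c(0.4, 0.45, 0.5, 0.55, 0.6, 0.65, 0.7)
  )
  expect_equal(sum(detect_outliers_iqr(sym)$flagged), 0L)

  C <- tibble::tibble(
    trial_id = paste0("t", 1:10),
    similarity = c(rep(0.8, 9), 0.1)
  )
  scr <- detect_outliers_iqr(C)
  expect_equal(scr$trial_id[scr$flagged], "t10")
  expect_equal(attr(scr, "threshold"), 0.8) # Q1 = Q3 = 0.8, IQR = 0

  # a gross HIGH value is never flagged
  hi <- tibble::tibble(
    trial_id = paste0("t", 1:10),
    similarity = c(seq(0.4, 0.6, length.out = 9), 0.99)
  )
  expect_equal(sum(detect_outliers_iqr(hi)$flagged), 0L)
})

test_that("robust location/scale resists low contamination", {
  x <- tdsim:::with_seed(13, rnorm(200, mean = 0.6, sd = 0.05))
  rob <- robust_location_scale(x)
  expect_lt(abs(rob$location - mean(x)) / abs(mean(x)), 0.15)
  expect_lt(abs(rob$scale - sd(x)) / sd(x), 0.15)

  contam <- c(x, rep(0.1, 22)) # ~10% gross low outliers
  rob_c <- robust_location_scale(contam)
  expect_lt(abs(rob_c$location - mean(x)), abs(mean(contam) - mean(x)))

  const <- robust_location_scale(rep(0.4, 12))
  expect_equal(const$location, 0.4)
  expect_equal(const$scale, 0)
  expect_error(robust_location_scale(1:5), class = "tdsim_error_domain")
})

test_that("the null flag rate of the 95% screen is near 5%", {
  rate <- tdsim:::with_seed(77, {
    hits <- 0L
    draws <- 0L
    for (b in 1:40) {
      x <- rnorm(50)
      scr <- detect_outliers_normal(x, 0.95)
      hits <- hits + sum(scr$flagged)
      draws <- draws + 50L
    }
    hits / draws
  })
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("multi-R analysis gates on normality and reports per-R screens", {
  panel <- simulate_panel(strawberry_spec(), seed = 5)
  rep <- outlier_analysis(panel, c(1, 10, 100))
  expect_equal(rep$R, c(1L, 10L, 100L))
  expect_true(all(rep$screen %in% c("normal", "iqr")))
  norm_rows <- rep$screen == "normal"
  expect_true(all(rep$ks_p[norm_rows] > 0.05))
  expect_equal(
    rep$threshold[norm_rows],
    (rep$mu - 1.64 * rep$sigma)[norm_rows],
    tolerance = 1e-12
  )
  fm <- flag_matrix(rep, all_trials = TRUE)
  expect_equal(nrow(fm), 51L)
  expect_named(fm, c("trial_id", "R1", "R10", "R100"))

  # identical trials: degenerate set, nothing flagged anywhere
  same <- bind_trials(
    switch_trial(0.4, "s1"), switch_trial(0.4, "s2"),
    switch_trial(0.4, "s3"), switch_trial(0.4, "s4"), switch_trial(0.4, "s5")
  )
  rep0 <- suppressWarnings(outlier_analysis(same, c(1, 10)))
  expect_equal(rep0$n_flagged, c(0L, 0L))
})

test_that("flags depend only on the similarity values, not trial order", {
  panel <- simulate_panel(strawberry_spec(), seed = 9, n_panels = 6)
  rep1 <- outlier_analysis(panel, c(1, 50))
  ev <- tibble::as_tibble(panel)
  shuffled <- tds_trialset(
    ev[order(rev(ev$trial_id), ev$onset), ],
    lexicon(panel)
  )
  rep2 <- outlier_analysis(shuffled, c(1, 50))
  expect_setequal(rep1$flagged[[1]], rep2$flagged[[1]])
  expect_setequal(rep1$flagged[[2]], rep2$flagged[[2]])
  expect_equal(rep1$threshold, rep2$threshold, tolerance = 1e-12)
})

test_that("planted archetypes are recovered at the R that matches their nature", {
  panel <- simulate_panel(strawberry_spec(), seed = 21)
  with_n1 <- inject_outlier(panel, "single_attribute", "N1", attribute = "sour")
  r1 <- outlier_analysis(with_n1, 1)
  expect_true("N1" %in% r1$flagged[[1]])

  d <- discretize(panel, 100)
  shift <- vapply(trial_ids(panel), function(id) {
    X <- discretized_matrix(d, id)
    dissimilarity(X, X[, ncol(X):1])
  }, numeric(1))
  target <- trial_ids(panel)[which.max(shift)]
  with_ts <- inject_outlier(panel, "time_shifted", target)
  rts <- outlier_analysis(with_ts, c(1, 100))
  expect_false(target %in% rts$flagged[[1]])
  # at R = 100 the reversal visibly lowers the target's centroid
  # similarity, pushing it into the panel's low tail (detection power
  # across many seeds is asserted elsewhere)
  before <- similarity_set(panel, 100)
  C100 <- attr(rts, "sets")[["100"]]
  expect_lt(
    C100$similarity[C100$trial_id == target],
    before$similarity[before$trial_id == target] - 0.02
  )
  z <- (C100$similarity - mean(C100$similarity)) / sd(C100$similarity)
  expect_lt(z[C100$trial_id == target], -1)
})
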