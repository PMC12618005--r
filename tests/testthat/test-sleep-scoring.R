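make_trace <- function(v, frame_rate = 1, ...) {
  velocity_trace(subject_id = "t", time = (seq_along(v) - 1) / frame_rate,
                 velocity = v, frame_rate = frame_rate, ...)
}

test_that("immobility is a strict threshold on velocity", {
  cfg <- scoring_config()
  expect_true(all(binarize_mobility(make_trace(rep(0, 50)), cfg)))
  expect_false(any(binarize_mobility(make_trace(rep(10, 50)), cfg)))
  # ties at the cut-off count as active swimming
  expect_false(any(binarize_mobility(make_trace(rep(6, 10)), cfg)))
  set.seed(8)
  v <- runif(1000, 0, 12)
  expect_identical(binarize_mobility(make_trace(v), cfg), v < 6)
})

test_that("missing frames follow the nan policy", {
  v <- c(0, 0, NA, 0, 0)
  brk <- binarize_mobility(make_trace(v), scoring_config(nan_policy = "break"))
  expect_identical(brk, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  fill <- binarize_mobility(make_trace(v),
                            scoring_config(nan_policy = "fill_short"))
  expect_identical(fill, rep(TRUE, 5))
  # gaps longer than 1 s always break
  v2 <- c(0, 0, NA, NA, 0) # 2 s gap at 1 Hz
  fill2 <- binarize_mobility(make_trace(v2),
                             scoring_config(nan_policy = "fill_short"))
  expect_identical(fill2, c(TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("the 60 s rule is a closed lower bound on bout duration", {
  expect_equal(nrow(detect_sleep_bouts(rep(TRUE, 59), 1)), 0L)
  b <- detect_sleep_bouts(rep(TRUE, 60), 1)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration, 60)
  # same boundary at 10 Hz: 599 vs 600 frames
  expect_equal(nrow(detect_sleep_bouts(rep(TRUE, 599), 10)), 0L)
  expect_equal(nrow(detect_sleep_bouts(rep(TRUE, 600), 10)), 1L)
})

test_that("bout detection matches the run-length oracle on random input", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(10:2000, 1)
    fr <- sample(c(1, 5, 10, 30), 1)
    flags <- runif(n) < runif(1, 0.3, 0.95)
    cfg <- scoring_config(min_bout_s = sample(c(10, 30, 60), 1),
                          max_gap_s = sample(c(0, 1, 2), 1))
    got <- as_plain_bouts(detect_sleep_bouts(flags, fr, cfg))
    want <- oracle_bouts(flags, fr, cfg$min_bout_s, cfg$max_gap_s)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("windowed metrics use overlap for totals and onset for counts", {
  expect_equal(
    compute_sleep_metrics(data.frame(start = numeric(0), end = numeric(0),
                                     duration = numeric(0)), c(0, 100)),
    data.frame(total_sleep_min = 0, bout_number = 0L,
               mean_bout_length_s = NA_real_))
  b <- data.frame(start = 100, end = 400, duration = 300)
  m <- compute_sleep_metrics(b, c(0, 10800))
  expect_equal(m$total_sleep_min, 5)
  expect_equal(m$bout_number, 1L)
  expect_equal(m$mean_bout_length_s, 300)
  # bout straddling the window end: overlap counts 100 s, the bout counts
  # once at its full 200 s length
  b2 <- data.frame(start = 10700, end = 10900, duration = 200)
  m2 <- compute_sleep_metrics(b2, c(0, 10800))
  expect_equal(m2$total_sleep_min, 100 / 60)
  expect_equal(m2$bout_number, 1L)
  expect_equal(m2$mean_bout_length_s, 200)
  expect_error(compute_sleep_metrics(b, c(100, 100)), "positive length")
})

test_that("profiles apportion sleep by overlap and conserve totals", {
  b <- data.frame(start = 120, end = 180, duration = 60)
  pr <- compute_sleep_profile(b, 0, 3600, bin_min = 10)
  expect_equal(pr$sleep_min, c(1, rep(0, 5)))
  # bout spanning a bin boundary splits 0.5 / 0.5
  b2 <- data.frame(start = 570, end = 630, duration = 60)
  pr2 <- compute_sleep_profile(b2, 0, 3600, bin_min = 10)
  expect_equal(pr2$sleep_min[1:2], c(0.5, 0.5))
  # conservation against windowed totals on a simulated day
  tr <- simulate_locomotor_trace(
    locomotor_params(0.02, 0.02, duration = 86400, seed = 13))
  bouts <- score_sleep(tr)
  pr3 <- compute_sleep_profile(bouts, 0, 86400, bin_min = 10)
  tot <- compute_sleep_metrics(bouts, c(0, 86400))$total_sleep_min
  expect_equal(sum(pr3$sleep_min), tot, tolerance = 1e-12)
  expect_equal(pr3$zt_start_h[1:3], c(0, 1, 2) / 6)
  expect_error(compute_sleep_profile(b, 0, 300, bin_min = 10), "shorter")
})

test_that("scoring is monotone in its thresholds", {
  set.seed(17)
  v <- runif(5000, 0, 12)
  tr <- make_trace(v)
  total_at <- function(thr) {
    cfg <- scoring_config(velocity_threshold = thr, min_bout_s = 10)
    compute_sleep_metrics(score_sleep(tr, cfg), c(0, 5000))$total_sleep_min
  }
  thr <- c(2, 4, 6, 8, 10)
  expect_true(all(diff(vapply(thr, total_at, numeric(1))) >= 0))
  bouts_at <- function(mb) {
    cfg <- scoring_config(min_bout_s = mb)
    nrow(score_sleep(tr, cfg))
  }
  expect_true(all(diff(vapply(c(10, 30, 60, 120), bouts_at, numeric(1))) <= 0))
})

test_that("transition probabilities follow the epoch-pair estimator", {
  # all-wake window: no doze transitions observed, wake pressure undefined
  tp0 <- transition_probabilities(c(0, 100), flags = rep(FALSE, 100),
                                  frame_rate = 1)
  expect_equal(tp0$p_doze, 0)
  expect_true(is.na(tp0$p_wake))
  # 600 s window, one interior 120 s bout: 480 wake epochs (479 with a
  # successor, the last epoch is wake) and 120 sleep epochs, one
  # transition each way
  bt <- data.frame(start = 100, end = 220, duration = 120)
  tp <- transition_probabilities(c(0, 600), bouts = bt)
  expect_equal(tp$p_doze, 1 / 479)
  expect_equal(tp$p_wake, 1 / 120)
  expect_error(transition_probabilities(c(0, 1.5), bouts = bt), "2 epochs")
})

test_that("flag-labelled epochs recover the generator's probabilities", {
  p <- locomotor_params(0.01, 0.05, duration = 86400, seed = 29)
  tr <- simulate_locomotor_trace(p)
  fl <- binarize_mobility(tr)
  tp <- transition_probabilities(c(0, 86400), flags = fl, frame_rate = 1)
  expect_lt(abs(tp$p_doze - 0.01) / 0.01, 0.2)
  expect_lt(abs(tp$p_wake - 0.05) / 0.05, 0.2)
})

test_that("scoring never mutates the trace's ground-truth labels", {
  p <- locomotor_params(0.05, 0.05, duration = 2000, seed = 2)
  tr <- simulate_locomotor_trace(p)
  st <- tr$state
  invisible(score_sleep(tr))
  invisible(cohort_sleep_metrics(
    structure(list(tr), class = "locomotor_cohort"), c(0, 2000)))
  expect_identical(tr$state, st)
})
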