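test_that("latent cross-correlation normalization and sign convention", {
  s <- lapply(1:5, function(i)
    simulate_joint_latent(rbind(c(0.9, 0.1), c(0.1, 0.9)), c(0.5, 0.5),
                          300, seed = i))
  px <- make_path(s)
  # y = x: unit correlation at zero lag
  cc <- cc_hmm(px, px, max_lag_ms = 100)
  expect_equal(cc$values[cc$lag_ms == 0], 1, tolerance = 1e-12)
  expect_true(all(abs(cc$values) <= 1 + 1e-12))

  # y delayed by +30 ms (y later) -> peak at +30; y advanced -> peak at -30
  delay_bins <- 3
  y_late <- lapply(s, function(p) c(p[1:delay_bins],
                                    p[1:(length(p) - delay_bins)]))
  cc_late <- cc_hmm(px, make_path(y_late), max_lag_ms = 100)
  expect_equal(cc_late$lag_ms[which.max(cc_late$values)], 30)
  y_early <- lapply(s, function(p) c(p[(delay_bins + 1):length(p)],
                                     p[rep(length(p), delay_bins)]))
  cc_early <- cc_hmm(px, make_path(y_early), max_lag_ms = 100)
  expect_equal(cc_early$lag_ms[which.max(cc_early$values)], -30)
})

test_that("shuffle predictor removes event-locked common structure", {
  # common event-locked signal: every trial switches On at bin 50
  common <- c(rep(1, 50), rep(2, 50))
  set.seed(91)
  jitter_path <- function(seed) {
    s <- common
    flip <- onoffstate:::with_substream(seed, "flip",
      sample(100, 10))
    s[flip] <- 3 - s[flip]
    s
  }
  xs <- lapply(1:20, function(i) jitter_path(i))
  ys <- lapply(1:20, function(i) jitter_path(100 + i))
  px <- make_path(xs); py <- make_path(ys)
  cc <- cc_hmm(px, py, max_lag_ms = 200, n_shuffles = 50, seed = 3)
  raw_peak <- max(abs(cc$values))
  corr_peak <- max(abs(cc$corrected))
  expect_gt(raw_peak, 0.5)     # event-locked correlation dominates raw CC
  expect_lt(corr_peak, raw_peak / 3) # removed by the predictor

  # y identical on all trials: predictor equals the raw CC
  y_const <- make_path(lapply(1:20, function(i) common))
  cc2 <- cc_hmm(px, y_const, max_lag_ms = 100)
  pred2 <- shuffle_predictor(px, y_const, n_shuffles = 5, seed = 1,
                             max_lag_ms = 100)
  expect_equal(pred2$values, cc2$values, tolerance = 1e-12)

  # reproducible given the seed
  p1 <- shuffle_predictor(px, py, n_shuffles = 5, seed = 7)
  p2 <- shuffle_predictor(px, py, n_shuffles = 5, seed = 7)
  expect_identical(p1$values, p2$values)
  expect_error(shuffle_predictor(make_path(list(xs[[1]])),
                                 make_path(list(ys[[1]]))), "2 trials")
})

test_that("independent areas give a flat shuffle-subtracted CC", {
  P <- rbind(c(0.95, 0.05), c(0.05, 0.95))
  xs <- lapply(1:60, function(i)
    simulate_joint_latent(P, c(0.5, 0.5), 200, seed = i))
  ys <- lapply(1:60, function(i)
    simulate_joint_latent(P, c(0.5, 0.5), 200, seed = 1000 + i))
  cc <- cc_hmm(make_path(xs), make_path(ys), max_lag_ms = 300,
               n_shuffles = 40, seed = 2)
  se <- sd(cc$corrected) # empirical spread across lags
  expect_lt(max(abs(cc$corrected)), 4 * se + 0.05)
  expect_lt(mean(abs(cc$corrected)), 0.05)
})

test_that("AUC split is trapezoidal with tau = 0 excluded", {
  cc <- onoffstate:::new_cross_corr(seq(-50, 50, 10),
                                    c(rep(0, 4), 1, 2, 1, rep(0, 4)))
  a <- auc_split(cc)
  expect_equal(a$auc_neg, a$auc_pos) # even-symmetric curve
  cc2 <- onoffstate:::new_cross_corr(seq(-30, 30, 10),
                                     c(0, 1, 0, 0, 0, 0, 0))
  a2 <- auc_split(cc2)
  expect_gt(a2$auc_neg, 0)
  expect_equal(a2$auc_pos, 0)
})

test_that("event cross-correlogram counts coincidences per event", {
  events <- tibble::tibble(trial = rep(1:10, each = 2),
                           t = rep(c(500, 1500), 10))
  trans <- dplyr::mutate(events, t = t + 60)
  cc <- cc_events(trans, events, max_lag_ms = 200, bin_ms = 20)
  # each event has exactly one transition 60 ms later within range; pairs
  # across the two events are 1000 ms apart, outside the 200 ms window
  expect_equal(sum(cc$values), 1)
  expect_equal(cc$values[cc$lag_ms == 70], 1)

  # doubling events with identical structure leaves normalization unchanged
  ev2 <- dplyr::bind_rows(events, dplyr::mutate(events, t = t + 5000))
  tr2 <- dplyr::mutate(ev2, t = t + 60)
  cc2 <- cc_events(tr2, ev2, max_lag_ms = 200, bin_ms = 20)
  expect_equal(cc2$values[cc2$lag_ms == 70], 1)
  expect_error(cc_events(trans, events[0, ]), "no events")
})

test_that("transition-triggered average recovers a constructed rate step", {
  # counts step from low to high exactly at each transition
  n_trials <- 30
  mats <- list(); trans <- list()
  set.seed(17)
  for (i in 1:n_trials) {
    t_step <- sample(60:140, 1)
    lam <- c(rep(0.2, t_step), rep(1.0, 200 - t_step))
    mats[[i]] <- matrix(rpois(200, lam), 1)
    trans[[i]] <- tibble::tibble(trial = i, t = t_step * 10)
  }
  bc <- binned_counts(mats)
  tr <- dplyr::bind_rows(trans)
  a <- tta(bc, tr, window_ms = 200, isolation_ms = 100)
  expect_equal(a$n_transitions, n_trials)
  pre <- mean(a$trace[a$lag_ms < -20])
  post <- mean(a$trace[a$lag_ms > 20])
  expect_gt(post - pre, 50) # ~80 Hz step recovered (rate in spikes/s)

  # isolation filter removes transitions with a close neighbor
  tr_close <- dplyr::bind_rows(tr,
                               dplyr::mutate(tr, t = t + 50))
  expect_warning(a2 <- tta(bc, tr_close, window_ms = 200,
                           isolation_ms = 100), "no isolated")
  expect_equal(a2$n_transitions, 0)
})

test_that("two-line crossing recovers kinks, flags degenerate traces", {
  x <- seq(-100, 100, 10)
  y <- ifelse(x < -20, 0, 0.5 * (x + 20)) # kink at -20
  expect_equal(two_line_crossing(tibble::tibble(lag_ms = x, value = y)),
               -20, tolerance = 1e-9)
  expect_equal(two_line_crossing(tibble::tibble(lag_ms = x, value = y),
                                 method = "independent"),
               -20, tolerance = 1e-9)
  for (m in c("hinge", "independent"))
    expect_true(is.na(two_line_crossing(
      tibble::tibble(lag_ms = x, value = rep(1, 21)), method = m)))

  # noisy recovery within one bin: rate step completed over ~50 ms,
  # noise SD 10% of the step size
  set.seed(5)
  x2 <- seq(-200, 50, 10)
  step <- 80
  y2 <- ifelse(x2 < -20, 0, step / 50 * (x2 + 20))
  hits <- 0
  for (i in 1:60) {
    yn <- y2 + rnorm(length(y2), 0, 0.1 * step)
    est <- two_line_crossing(tibble::tibble(lag_ms = x2, value = yn))
    if (!is.na(est) && abs(est - (-20)) <= 10) hits <- hits + 1
  }
  expect_gte(hits, 54) # >= 90% here; the 95% bar is checked at n = 200
})
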