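test_that("common average reference removes the channel mean and is idempotent", {
  set.seed(11)
  lfp <- lfp_array(list(`1` = matrix(rnorm(4 * 100), 4)), fs = 1000)
  car <- common_average_reference(lfp)
  expect_lt(max(abs(colMeans(car$v[[1]]))), 1e-12)
  car2 <- common_average_reference(car)
  expect_equal(car2$v[[1]], car$v[[1]], tolerance = 1e-12)

  # identical channels cancel entirely
  same <- lfp_array(list(`1` = matrix(rep(sin(1:50), each = 3), 3,
                                      byrow = FALSE)), fs = 1000)
  expect_lt(max(abs(common_average_reference(same)$v[[1]])), 1e-12)
  expect_error(common_average_reference(
    lfp_array(list(`1` = matrix(0, 1, 10)), fs = 1000)), "2 channels")
})

test_that("bipolar derivation differences neighbors along depth", {
  m <- matrix(rep(1:4, 10), 4) # linear depth ramp, constant in time
  lfp <- lfp_array(list(`1` = m), fs = 1000, depth_um = (1:4) * 150)
  bp <- bipolar_reref(lfp)
  expect_equal(nrow(bp$v[[1]]), 3)
  expect_true(all(bp$v[[1]] == -1)) # superficial minus deep
  expect_equal(bp$depth_um, c(225, 375, 525))

  const <- lfp_array(list(`1` = matrix(5, 4, 10)), fs = 1000)
  expect_true(all(bipolar_reref(const)$v[[1]] == 0))
})

test_that("MUAe envelope behaves as a rectified low-pass", {
  fs <- 30000
  # DC input passes through with unit gain after settling
  dc <- muae(rep(2, 3000), fs)
  expect_equal(mean(tail(dc, 500)), 2, tolerance = 1e-3)
  # pure tone: envelope settles at the mean of the rectified samples,
  # which approaches 2A/pi
  t <- seq(0, 0.2, by = 1 / fs)
  x <- 3 * sin(2 * pi * 5050 * t)
  tone <- muae(x, fs)
  expect_equal(mean(tail(tone, 1000)), mean(abs(x)), tolerance = 0.02)
  expect_equal(mean(abs(x)), 2 * 3 / pi, tolerance = 0.01)
  expect_error(muae(rnorm(10), fs = 500), "600")
})

test_that("energy is the sum of squares with quadratic scaling", {
  expect_equal(energy(c(2, 2, 2)), 12)
  expect_equal(energy(numeric(5)), 0)
  v <- rnorm(20)
  expect_equal(energy(3 * v), 9 * energy(v))
})

test_that("finite-difference CSD is exact on quadratic depth profiles", {
  x <- (1:8) * 150
  expect_true(all(abs(csd_fd(0.5 + 2 * x)) < 1e-15)) # linear -> zero
  csd <- csd_fd(x^2)
  expect_equal(csd, rep(2, 6), tolerance = 1e-9) # exact second difference
  expect_error(csd_fd(c(1, 2)), "3 channels")
  # matrix input: one CSD trace per interior channel
  m <- matrix(rnorm(8 * 5), 8)
  expect_equal(dim(csd_fd(m)), c(6, 5))
})

test_that("SNR windows and the > 3 inclusion boundary", {
  fs <- 1000
  n <- 1000; onset <- 400
  t_ms <- (0:(n - 1)) - onset
  base <- ifelse(t_ms < 0, 1, 1) # flat
  set.seed(3)
  mk_trial <- function(amp) {
    resp <- ifelse(t_ms >= 40 & t_ms < 120, amp, 0)
    rbind(1 + resp + rnorm(n, 0, 0.1),   # responsive channel
          1 + rnorm(n, 0, 0.1))          # flat channel
  }
  trials <- lapply(1:20, function(i) mk_trial(2))
  r <- snr_channels(trials, fs, onset)
  expect_true(r$summary$included[1])
  expect_false(r$summary$included[2])
  expect_equal(nrow(r$by_window), 16) # 8 windows x 2 channels

  # exact boundary: SNR equal to 3 is not > 3
  expect_identical(tibble::tibble(snr_max = 3) |>
                     dplyr::mutate(included = snr_max > 3) |>
                     dplyr::pull(included), FALSE)

  # zero baseline SD -> NA and excluded
  flat <- lapply(1:3, function(i) matrix(1, 1, n))
  r2 <- snr_channels(flat, fs, onset)
  expect_true(is.na(r2$summary$snr_max[1]))
  expect_false(r2$summary$included[1])
})

test_that("latency fit recovers known parameters and the closed form", {
  fs <- 1000
  t_ms <- seq(0, 300, by = 1)
  truth <- list(mu = 60, sigma = 8, alpha = 0.02, c = 5, d = 3)
  y <- onoffstate:::latency_model(t_ms, truth$mu, truth$sigma, truth$alpha,
                                  truth$c, truth$d)
  fit <- latency_fit(y, fs, t_ms = t_ms)
  expect_true(fit$converged)
  expect_equal(fit$params$mu, truth$mu, tolerance = 0.01)
  expect_equal(fit$params$sigma, truth$sigma, tolerance = 0.01)
  expect_equal(fit$params$c, truth$c, tolerance = 0.01)

  # pure cumulative Gaussian: crossing at mu + sigma * qnorm(0.33)
  y2 <- onoffstate:::latency_model(t_ms, 100, 10, 0.02, 4, 0)
  fit2 <- latency_fit(y2, fs, t_ms = t_ms)
  expect_equal(fit2$latency_ms, 100 + 10 * qnorm(0.33), tolerance = 0.5)

  # flat trace: no crossing
  expect_true(is.na(latency_fit(rep(0, 100), fs)$latency_ms))
})

test_that("multitaper spectra localize an injected tone, flat for noise", {
  fs <- 1000
  # single state covering whole trials; 1024-sample segments
  n <- 1024
  set.seed(21)
  tone <- sin(2 * pi * 60 * (0:(n - 1)) / fs) + rnorm(n, 0, 0.1)
  p <- onoffstate:::mt_power(tone, fs, nw = 4, k = 7, pad_to = 1024)
  freq <- (0:1023) * fs / 1024
  sel <- freq >= 4 & freq <= 200
  expect_equal(freq[sel][which.max(p[sel])], 60, tolerance = fs / 1024)

  # white noise: no frequency dominates grossly
  wn <- rnorm(n)
  pw <- onoffstate:::mt_power(wn, fs, 4, 7, 1024)[sel]
  expect_lt(max(pw) / mean(pw), 12)
})

test_that("state-conditioned spectra separate On and Off content", {
  fs <- 1000; bin <- 10
  n_bins <- 300
  # alternating 1.5 s epochs: Off has 10 Hz, On has 80 Hz
  path <- rep(rep(c(1L, 2L), each = 150), length.out = n_bins)
  t <- (0:(n_bins * bin - 1)) / 1000
  gate <- rep(path, each = bin)
  set.seed(31)
  v <- 2 * sin(2 * pi * 10 * t) * (gate == 1) +
    2 * sin(2 * pi * 80 * t) * (gate == 2) + rnorm(length(t), 0, 0.2)
  lfp <- lfp_array(list(`1` = rbind(v, v)), fs = fs)
  paths <- make_path(list(path))
  spec <- state_spectra(lfp, paths, min_epoch_ms = 250)
  expect_equal(spec$n_segments[1], spec$n_segments[2])
  peak_off <- spec$freq[which.max(spec$power[[1]][1, ])]
  peak_on <- spec$freq[which.max(spec$power[[2]][1, ])]
  expect_equal(peak_off, 10, tolerance = 2)
  expect_equal(peak_on, 80, tolerance = 2)
  pc <- spectra_percent_change(spec)
  expect_gt(pc$pct_change[which.min(abs(pc$freq - 80))[1]], 100)
  expect_lt(pc$pct_change[which.min(abs(pc$freq - 10))[1]], -50)
})

test_that("a 250 ms epoch at 1 kHz pads to exactly 1024 samples", {
  segs <- onoffstate:::split_segment(1, 250, 1024, 250)
  expect_equal(segs, list(c(1, 250)))
  # padding happens inside mt_power; verify the FFT length via frequency grid
  x <- rnorm(250)
  p <- onoffstate:::mt_power(x, 1000, 4, 7, 1024)
  expect_equal(length(p), 1024)
  # long epochs split into non-overlapping 1024 blocks
  segs2 <- onoffstate:::split_segment(1, 2500, 1024, 250)
  expect_equal(segs2[[1]], c(1, 1024))
  expect_equal(segs2[[2]], c(1025, 2048))
  expect_equal(segs2[[3]], c(2049, 2500)) # remainder still >= 250
})

test_that("BH FDR matches the brute-force step-up on random inputs", {
  expect_true(all(fdr_correct(c(0.01, 0.02, 0.03, 0.04), 0.05)))
  expect_false(any(fdr_correct(rep(1, 5), 0.05)))
  expect_true(fdr_correct(0.04, 0.05))
  set.seed(41)
  for (i in 1:1000) {
    m <- sample(1:20, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_identical(fdr_correct(p, 0.05), bh_bruteforce(p, 0.05))
  }
})

test_that("RF summaries combine z-maps and measure overlap/separation", {
  z <- matrix(0, 9, 12); z[3:5, 4:6] <- 10
  r <- rf_summary(z, z)
  expect_equal(r$overlap, 1)
  expect_equal(r$separation, 0)

  z2 <- matrix(0, 9, 12); z2[6:8, 8:10] <- 10
  r2 <- rf_summary(z, z2)
  expect_equal(r2$overlap, 0)
  expect_gt(r2$separation, 3)

  # Stouffer sqrt(k) default vs mean variant
  maps <- list(z, z)
  r3 <- rf_summary(maps, maps)
  expect_equal(max(r3$map_v1), 20 / sqrt(2))
  r4 <- rf_summary(maps, maps, mode = "mean")
  expect_equal(max(r4$map_v1), 10)

  # single supra-threshold cell is its own center
  z5 <- matrix(0, 5, 5); z5[2, 4] <- 5
  r5 <- rf_summary(z5, z5)
  expect_equal(unname(r5$center_v1), c(2, 4))
  # empty region -> missing
  expect_true(is.na(rf_summary(matrix(0, 3, 3), z5)$overlap))
})
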