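test_that("latent chain sampling is correct and reproducible", {
  # identity matrix keeps the chain in its start state
  P_id <- diag(4)
  s <- simulate_joint_latent(P_id, c(0, 0, 1, 0), 50, seed = 1)
  expect_true(all(s == 3))

  # same seed -> identical; different seed -> different
  P <- make_joint_P()
  s1 <- simulate_joint_latent(P, n_bins = 500, seed = 7)
  s2 <- simulate_joint_latent(P, n_bins = 500, seed = 7)
  s3 <- simulate_joint_latent(P, n_bins = 500, seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))

  # law of large numbers: empirical transition frequencies approach P
  long <- simulate_joint_latent(P, n_bins = 1e6, seed = 3)
  emp <- matrix(0, 4, 4)
  for (i in 1:4) {
    from <- which(long[-length(long)] == i)
    emp[i, ] <- tabulate(long[from + 1], 4) / length(from)
  }
  expect_lt(max(abs(emp - P)), 0.005)

  expect_error(simulate_joint_latent(matrix(0.3, 4, 4), n_bins = 10),
               "sum to 1")
})

test_that("count emission is Poisson at the state rate", {
  path <- rep(2L, 1e5)
  lam <- matrix(c(20, 60), 1, 2)
  m <- simulate_counts(path, lam, 10, seed = 4)
  expect_equal(mean(m), 0.60, tolerance = 0.01 / 0.6)
  expect_equal(var(as.double(m)) / mean(m), 1, tolerance = 0.02)

  # zero-rate column emits nothing
  m0 <- simulate_counts(rep(1L, 100), matrix(c(0, 50), 1, 2), 10, seed = 1)
  expect_true(all(m0 == 0))
  expect_error(simulate_counts(path, matrix(-1, 1, 1), 10), "non-negative")
})

test_that("sessions respect configured delays and are seed-deterministic", {
  cfg <- gen_config(n_trials = 8, channels_per_area = 4,
                    msacc = list(enabled = FALSE),
                    pupil = list(enabled = FALSE), seed = 31)
  b <- simulate_session(cfg)
  b2 <- simulate_session(cfg)
  expect_identical(b$counts$cue_to_dim1$counts, b2$counts$cue_to_dim1$counts)
  expect_identical(b$trials$rt_ms, b2$trials$rt_ms)

  d <- b$trials
  expect_true(all(d$t_stim_on == 614))
  expect_true(all(d$t_cue_on - d$t_stim_on >= 618 &
                    d$t_cue_on - d$t_stim_on <= 1131))
  expect_true(all(d$t_dim1 - d$t_cue_on >= 1162 &
                    d$t_dim1 - d$t_cue_on <= 2133))
  dd <- d$t_dim2 - d$t_dim1
  expect_true(all(is.na(dd) | (dd >= 792 & dd <= 1331)))
})

test_that("ground-truth paths align with the analysis-window count bins", {
  cfg <- gen_config(n_trials = 4, channels_per_area = 4,
                    off_hz = 5, on_hz = 400,
                    msacc = list(enabled = FALSE),
                    pupil = list(enabled = FALSE), seed = 17)
  b <- simulate_session(cfg)
  bc <- b$counts$cue_to_dim1
  expect_equal(lengths(b$ground_truth$paths_window),
               unname(bc$windows$n_bins))
  # V1 channels fire at the On rate exactly when the V1 phase is On
  gt1 <- lapply(b$ground_truth$paths_window, function(s) c(1, 2, 1, 2)[s])
  on_counts <- unlist(purrr::map2(bc$counts, gt1, function(m, g)
    m[1, g == 2]))
  off_counts <- unlist(purrr::map2(bc$counts, gt1, function(m, g)
    m[1, g == 1]))
  expect_gt(mean(on_counts), 10 * max(mean(off_counts), 0.01))
})

test_that("attention condition shapes the generated transition statistics", {
  cfg <- gen_config(n_trials = 25, channels_per_area = 2, seed = 23,
                    msacc = list(enabled = FALSE),
                    pupil = list(enabled = FALSE))
  b <- simulate_session(cfg)
  # V4-lead ordering 1->3 over 1->2 in empirical ground-truth transitions
  count_tr <- function(paths, from, to) {
    sum(vapply(paths, function(p)
      sum(p[-length(p)] == from & p[-1] == to), 0))
  }
  paths <- b$ground_truth$paths_full
  expect_gt(count_tr(paths, 1, 3), count_tr(paths, 1, 2))
  expect_gt(count_tr(paths, 4, 2), count_tr(paths, 4, 3))
})

test_that("RT offsets drive RT differences by state (and vanish when zero)", {
  cfg0 <- gen_config(n_trials = 40, channels_per_area = 2,
                     conditions = "attend_RF",
                     rt = list(offsets_ms = c(0, 0, 0, 0), sd_ms = 1),
                     msacc = list(enabled = FALSE),
                     pupil = list(enabled = FALSE), seed = 41)
  b0 <- simulate_session(cfg0)
  expect_lt(diff(range(b0$trials$rt_ms)), 10) # pure noise around base

  cfg1 <- gen_config(n_trials = 40, channels_per_area = 2,
                     conditions = "attend_RF",
                     rt = list(offsets_ms = c(200, 100, 50, 0), sd_ms = 1),
                     msacc = list(enabled = FALSE),
                     pupil = list(enabled = FALSE), seed = 41)
  b1 <- simulate_session(cfg1)
  expect_gt(diff(range(b1$trials$rt_ms)), 40)
})

test_that("microsaccade machinery injects exactly what was asked", {
  cfg <- gen_config(n_trials = 3, channels_per_area = 2,
                    conditions = "attend_RF",
                    msacc = list(enabled = TRUE, rate_hz = 0),
                    pupil = list(enabled = FALSE), seed = 6)
  b <- simulate_session(cfg)
  expect_equal(nrow(b$ground_truth$msacc), 0)

  cfg2 <- gen_config(n_trials = 3, channels_per_area = 2,
                     conditions = "attend_RF",
                     msacc = list(enabled = TRUE, rate_hz = 2),
                     pupil = list(enabled = FALSE), seed = 6)
  b2 <- simulate_session(cfg2)
  expect_gt(nrow(b2$ground_truth$msacc), 0)
  expect_true(all(b2$ground_truth$msacc$amplitude_deg > 0))
})
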