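test_that("epochs tile the window and carry censoring flags", {
  p <- make_path(c(1, 1, 1, 2, 2, 2, 1))
  ep <- epochs_from_path(p)
  expect_equal(ep$duration_ms, c(30, 30, 10))
  expect_equal(ep$state, c(1, 2, 1))
  expect_equal(ep$censored_left, c(TRUE, FALSE, FALSE))
  expect_equal(ep$censored_right, c(FALSE, FALSE, TRUE))
  expect_equal(sum(ep$duration_ms), 70) # tiles the window

  # constant path: one fully censored epoch
  ep2 <- epochs_from_path(make_path(rep(2, 5)))
  expect_equal(nrow(ep2), 1)
  expect_true(ep2$censored_left & ep2$censored_right)
})

test_that("uncensored epoch durations follow the geometric mean w/(1-p)", {
  P <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  s <- simulate_joint_latent(P, c(0.5, 0.5), 1e5, seed = 19)
  ep <- epochs_from_path(make_path(list(s)))
  durs <- ep$duration_ms[ep$state == 1 & !ep$censored_left &
                           !ep$censored_right]
  expect_equal(mean(durs), 100, tolerance = 0.05)
})

test_that("occupancy equals duration-weighted epoch fractions exactly", {
  p <- make_path(list(c(1, 1, 2, 2, 2), c(2, 2, 2, 2, 1)))
  occ <- occupancy(p)
  ep <- epochs_from_path(p)
  frac2 <- sum(ep$duration_ms[ep$state == 2]) / sum(ep$duration_ms)
  expect_equal(occ$fraction[2], frac2)
  expect_equal(sum(occ$fraction), 1)
})

test_that("attention modulation index follows its definition", {
  expect_equal(att_mi(2, 1), 1 / 3)
  expect_equal(att_mi(1, 1), 0)
  expect_equal(att_mi(3, 0), 1)
  expect_true(is.na(att_mi(0, 0)))
  expect_equal(att_mi(c(2, 1), c(1, 1)), c(1 / 3, 0))
  expect_error(att_mi(-1, 1), "non-negative")
})

test_that("transition PDF normalizes to transitions per second per trial", {
  # 10 trials, one Off->On transition in 5 of them inside one 100 ms bin
  paths <- lapply(1:10, function(i) {
    if (i <= 5) c(rep(1, 12), rep(2, 8)) else rep(1, 20)
  })
  p <- make_path(paths)
  pdf <- transition_pdf(p, "off_on", w_ms = 100)
  expect_equal(max(pdf$density), 5 / (0.1 * 10))
  expect_equal(sum(pdf$n_transitions), 5)

  # time-homogeneous chain: flat PDF, attMI ~ 0 between identical halves
  s <- lapply(1:60, function(i)
    simulate_joint_latent(rbind(c(0.9, 0.1), c(0.1, 0.9)), c(0.5, 0.5),
                          100, seed = i))
  pp <- make_path(s)
  pdf2 <- transition_pdf(pp, "off_on", w_ms = 100)
  expect_lt(sd(pdf2$density) / mean(pdf2$density), 0.35)
})

test_that("rate matching thins to the minimum condition mean", {
  d1 <- sim_flat(10, 100, J = 3, rate_hz = 80, seed = 81)
  d2 <- sim_flat(10, 100, J = 3, rate_hz = 40, seed = 82)
  out <- rate_match(list(a = d1, b = d2), seed = 4)
  m_a <- rowMeans(do.call(cbind, out$a$counts))
  m_b <- rowMeans(do.call(cbind, out$b$counts))
  expect_true(all(abs(m_a / m_b - 1) < 0.1)) # equalized (binomial noise)
  # thinned counts never exceed originals bin-wise
  for (i in seq_along(out$a$counts))
    expect_true(all(out$a$counts[[i]] <= d1$counts[[i]]))
  # lower-rate condition untouched
  expect_identical(out$b$counts, d2$counts)
  # roughly half the spikes removed from the 2x condition
  expect_equal(sum(unlist(out$a$counts)) / sum(unlist(d1$counts)), 0.5,
               tolerance = 0.05)
  # thinning preserves the Poisson character (FF ~ 1)
  ff <- rmax2(out$a)$fano
  expect_true(all(abs(ff - 1) < 0.1))

  # equal-rate conditions come back identical
  out2 <- rate_match(list(a = d1, b = d1), seed = 4)
  expect_identical(out2$a$counts, d1$counts)
})

test_that("pupil coupling recovers a linear relation exactly", {
  paths <- lapply(1:12, function(i)
    c(rep(1, 5), rep(2, i + 2), rep(1, 5)))
  p <- make_path(paths)
  ep <- epochs_from_path(p)
  dur <- ep |>
    dplyr::filter(state == 2) |>
    dplyr::group_by(trial) |>
    dplyr::summarise(d = mean(duration_ms))
  trials <- tibble::tibble(trial = 1:12,
                           pupil_baseline = 0.5 + 0.01 * dur$d)
  r <- pupil_coupling(trials, ep, state = 2)
  expect_equal(r$r, 1, tolerance = 1e-12)

  # constant pupil -> undefined
  trials2 <- tibble::tibble(trial = 1:12, pupil_baseline = 1)
  expect_true(is.na(pupil_coupling(trials2, ep)$r))
})

test_that("state_at_event uses the half-open bin convention", {
  p <- make_path(c(1, 1, 2, 2), start = 1400)
  expect_equal(state_at_event(p, tibble::tibble(trial = 1, t_ms = 1405))$state,
               1L)
  expect_equal(state_at_event(p, tibble::tibble(trial = 1, t_ms = 1420))$state,
               2L)
  expect_error(state_at_event(p, tibble::tibble(trial = 1, t_ms = 1300)),
               "outside")
})

test_that("RT-by-state table links RTs to the decoded state at dimming", {
  cfg <- gen_config(n_trials = 30, channels_per_area = 2,
                    conditions = "attend_RF",
                    rt = list(base_ms = 400,
                              offsets_ms = c(150, 100, 50, 0), sd_ms = 5),
                    msacc = list(enabled = FALSE),
                    pupil = list(enabled = FALSE), seed = 83)
  b <- simulate_session(cfg)
  # decode = ground truth here (scoring the table machinery, not the HMM)
  p <- state_path(b$ground_truth$paths_window,
                  b$counts$cue_to_dim1$windows, 10, 4)
  r <- rt_by_state(b$trials, p)
  expect_true(all(c("trial", "condition", "state", "rt_ms") %in%
                    names(r$table)))
  # only trials whose target dimming fell inside the decoded window qualify
  expect_true(all(r$table$trial %in%
                    b$trials$trial[b$trials$target_dim == 1]))
  m <- r$means[order(r$means$state), ]
  if (nrow(m) >= 2)
    expect_true(all(diff(m$mean_rt) < 0)) # offsets decrease with state
})
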