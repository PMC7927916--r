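test_that("Poisson emission log-pmf matches direct evaluation", {
  expect_equal(emission_logpmf(0, 1), -1)
  expect_equal(emission_logpmf(0, 0), 0)
  expect_equal(emission_logpmf(1, 0), -Inf)
  expect_equal(emission_logpmf(2, 2), log(2 * exp(-2)))
  expect_equal(emission_logpmf(0:5, 1.3), dpois(0:5, 1.3, log = TRUE))
  expect_error(emission_logpmf(-1, 1), "non-negative")
})

test_that("forward-backward matches exhaustive enumeration", {
  for (i in 1:40) {
    inst <- random_hmm_instance(T = sample(2:6, 1), K = sample(2:4, 1),
                                J = sample(1:3, 1), seed = 100 + i)
    bc <- binned_counts(list(inst$N))
    params <- hmm_params(inst$pi0, inst$P, inst$lambda)
    fb <- forward_backward(bc, params)
    expect_equal(fb$loglik,
                 enum_loglik(inst$N, inst$pi0, inst$P, inst$lambda),
                 tolerance = 1e-10)
    expect_equal(rowSums(fb$posteriors[[1]]),
                 rep(1, ncol(inst$N)), tolerance = 1e-12)
  }
})

test_that("K = 1 log-likelihood reduces to the plain Poisson sum", {
  set.seed(3)
  N <- matrix(rpois(40, 0.7), 2)
  bc <- binned_counts(list(N))
  params <- hmm_params(1, matrix(1, 1, 1), matrix(c(0.5, 0.9), 2, 1))
  fb <- forward_backward(bc, params)
  expect_equal(fb$loglik,
               sum(dpois(N[1, ], 0.5, log = TRUE)) +
                 sum(dpois(N[2, ], 0.9, log = TRUE)))
})

test_that("Viterbi equals the brute-force most probable path", {
  for (i in 1:60) {
    inst <- random_hmm_instance(T = sample(2:8, 1), K = sample(2:4, 1),
                                J = sample(1:3, 1), seed = 500 + i)
    bc <- binned_counts(list(inst$N))
    params <- hmm_params(inst$pi0, inst$P, inst$lambda)
    p <- viterbi(bc, params)
    expect_identical(p$paths[[1]],
                     enum_viterbi(inst$N, inst$pi0, inst$P, inst$lambda))
  }
})

test_that("identical emission rates leave the decode to pi0 and P", {
  set.seed(1)
  N <- matrix(rpois(30, 1), 1)
  bc <- binned_counts(list(N))
  params <- hmm_params(c(0.2, 0.8),
                       matrix(0.5, 2, 2),
                       matrix(c(1, 1), 1, 2))
  p <- viterbi(bc, params)
  # every path starting at argmax pi0 is jointly most probable; the decode
  # must pick one of them (starts at state 2) and achieve the maximum
  expect_equal(p$paths[[1]][1], 2L)
  lp_dec <- path_logprob(p$paths[[1]], N, params$pi0, params$P,
                         params$lambda)
  lp_best <- path_logprob(rep(2L, 30), N, params$pi0, params$P,
                          params$lambda)
  expect_equal(lp_dec, lp_best)
})

test_that("EM: monotone likelihood, exact K = 1 closed form, recovery", {
  d <- sim_2state(20, 120, J = 6, seed = 21)
  fit <- em_fit(d$counts, 2, n_restarts = 3, seed = 4)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))

  # K = 1: emission equals per-channel mean count exactly
  fit1 <- em_fit(d$counts, 1, n_restarts = 2, seed = 4)
  mu <- rowMeans(do.call(cbind, d$counts$counts))
  expect_equal(as.double(fit1$params$lambda), mu, tolerance = 1e-12)

  # M-step preserves stochasticity exactly
  expect_equal(rowSums(fit$params$P), c(1, 1), tolerance = 1e-12)
  expect_equal(sum(fit$params$pi0), 1, tolerance = 1e-12)

  # canonical labeling: state 2 is the high-rate (On) phase
  expect_true(mean(fit$params$lambda[, 2]) > mean(fit$params$lambda[, 1]))
})

test_that("decoded path matches ground truth with well-separated rates", {
  d <- sim_2state(15, 200, J = 8, off_hz = 10, on_hz = 500, seed = 33)
  fit <- em_fit(d$counts, 2, n_restarts = 3, seed = 5)
  p <- viterbi(d$counts, fit)
  agree <- mean(unlist(p$paths) == unlist(d$paths))
  expect_gt(agree, 0.99)
})

test_that("log-space recursions survive long sequences", {
  d <- sim_2state(1, 10000, J = 4, seed = 8)
  params <- hmm_params(c(0.5, 0.5), d$P, d$lambda_hz * 10 / 1000)
  fb <- forward_backward(d$counts, params)
  expect_true(is.finite(fb$loglik))
  p <- viterbi(d$counts, params)
  expect_equal(length(p$paths[[1]]), 10000)
})

test_that("per-condition fitting returns one independent fit per condition", {
  cfg <- gen_config(n_trials = 5, channels_per_area = 4,
                    msacc = list(enabled = FALSE),
                    pupil = list(enabled = FALSE), seed = 12)
  b <- simulate_session(cfg)
  res <- fit_all(b, K = 2, n_restarts = 2, seed = 3)
  expect_named(res, cfg$conditions, ignore.order = TRUE)
  expect_s3_class(res$attend_RF$fit, "hmm_fit")
  expect_equal(length(res$attend_RF$path$paths), 5)
})

test_that("restarts are reproducible from the master seed", {
  d <- sim_2state(6, 80, J = 4, seed = 51)
  f1 <- em_fit(d$counts, 2, n_restarts = 2, seed = 99)
  f2 <- em_fit(d$counts, 2, n_restarts = 2, seed = 99)
  expect_identical(f1$params$lambda, f2$params$lambda)
  expect_identical(f1$restart_logliks, f2$restart_logliks)
})

test_that("tidy and glance views expose the fitted model", {
  d <- sim_2state(6, 80, J = 4, seed = 52)
  fit <- em_fit(d$counts, 2, n_restarts = 2, seed = 1)
  tr <- tidy(fit, "rates")
  expect_equal(nrow(tr), 8)
  expect_true(all(c("channel", "state", "rate_hz") %in% names(tr)))
  expect_equal(sum(tidy(fit, "initial")$probability), 1)
  expect_equal(glance(fit)$K, 2)
})
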