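# Shared fixtures: small simulated datasets with known ground truth.

# Two-state counts from a known chain; rates in spikes/s.
sim_2state <- function(n_trials, n_bins, J = 8, p_stay_off = 0.97,
                       p_stay_on = 0.95, off_hz = 20, on_hz = 100,
                       bin_ms = 10, seed = 1) {
  P <- rbind(c(p_stay_off, 1 - p_stay_off), c(1 - p_stay_on, p_stay_on))
  lam <- cbind(rep(off_hz, J), rep(on_hz, J))
  paths <- lapply(seq_len(n_trials), function(i)
    simulate_joint_latent(P, c(0.5, 0.5), n_bins,
                          seed = onoffstate:::substream(seed, paste0("p", i))))
  mats <- lapply(seq_len(n_trials), function(i)
    simulate_counts(paths[[i]], lam, bin_ms,
                    seed = onoffstate:::substream(seed, paste0("c", i))))
  list(counts = binned_counts(mats, bin_ms), paths = paths, P = P,
       lambda_hz = lam)
}

# Homogeneous Poisson counts (no latent structure).
sim_flat <- function(n_trials, n_bins, J = 8, rate_hz = 60, bin_ms = 10,
                     seed = 1) {
  lam <- matrix(rate_hz, J, 1)
  mats <- lapply(seq_len(n_trials), function(i)
    simulate_counts(rep(1L, n_bins), lam, bin_ms,
                    seed = onoffstate:::substream(seed, paste0("f", i))))
  binned_counts(mats, bin_ms)
}

# One trial of eye data with injected raised-cosine saccades, mirroring the
# generator's event model.
make_eye_trial <- function(trial, dur_ms = 2000, fs = 220, noise_sd = 0.02,
                           events = NULL, seed = 1) {
  n <- ceiling(dur_ms / 1000 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  set.seed(seed)
  bf <- signal::butter(2, 0.05, type = "low")
  x <- as.double(signal::filtfilt(bf, rnorm(n, 0, noise_sd)))
  y <- as.double(signal::filtfilt(bf, rnorm(n, 0, noise_sd)))
  if (!is.null(events)) {
    for (r in seq_len(nrow(events))) {
      rel <- (t_ms - events$t_ms[r]) / 20
      prof <- ifelse(rel <= 0, 0, ifelse(rel >= 1, 1,
                                         (1 - cos(pi * rel)) / 2))
      th <- events$direction_deg[r] * pi / 180
      x <- x + events$amplitude_deg[r] * cos(th) * prof
      y <- y + events$amplitude_deg[r] * sin(th) * prof
    }
  }
  tibble::tibble(trial = trial, t_ms = t_ms, x = x, y = y)
}

make_path <- function(states, bin_ms = 10, start = 0, K = NULL) {
  states <- lapply(if (is.list(states)) states else list(states), as.integer)
  if (is.null(K)) K <- max(unlist(states))
  nb <- lengths(states)
  start <- rep(start, length.out = length(states))
  state_path(states,
             tibble::tibble(trial = seq_along(states), start = start,
                            end = start + nb * bin_ms, n_bins = nb),
             bin_ms, K)
}
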