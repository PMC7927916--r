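#' Joint two-area transition matrix with a configurable V4 lead
#'
#' Builds a 4 x 4 row-stochastic matrix over the canonical joint states
#' (1 = V1off-V4off, 2 = V1on-V4off, 3 = V1off-V4on, 4 = V1on-V4on). The
#' `lead` parameter makes V4 the leading area: from both-Off,
#' `P(1 -> 3) = a + lead > P(1 -> 2) = a` (V4 switches On first), and from
#' both-On, `P(4 -> 2) = b + lead > P(4 -> 3) = b` (V4 switches Off first).
#'
#' @param a Baseline rate of leaving both-Off toward a single-On state.
#' @param b Baseline rate of leaving both-On toward a single-On state.
#' @param lead V4-lead asymmetry added to the V4-first transitions.
#' @param cross Probability of a simultaneous double switch.
#' @param join Probability that the lagging area joins from a split state.
#' @param drop Probability that the leading area falls back from a split
#'   state.
#' @return A 4 x 4 transition matrix.
#' @export
make_joint_P <- function(a = 0.015, b = 0.015, lead = 0.02, cross = 0.002,
                         join = 0.05, drop = 0.02) {
  P <- rbind(
    c(1 - (2 * a + lead + cross), a, a + lead, cross),
    c(drop, 1 - (drop + cross + join), cross, join),
    c(drop, cross, 1 - (drop + cross + join), join),
    c(cross, b + lead, b, 1 - (2 * b + lead + cross)))
  if (any(P < 0)) abort("transition parameters imply negative probabilities")
  P
}

stationary_dist <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Generator configuration for synthetic sessions
#'
#' Defines the statistical structure of a simulated two-area recording:
#' channels per area, On/Off firing rates, per-condition joint transition
#' matrices (attend-RF trials spend more time On via `att_on_leave` /
#' `att_off_leave` hazard factors), uniform task-delay ranges, the
#' state-dependent reaction-time model, pupil coupling to On-epoch duration,
#' the microsaccade process, and the laminar LFP surrogate. All stochastic
#' draws flow from `seed` through named substreams, so equal configurations
#' reproduce sessions bit for bit.
#'
#' @param n_trials Trials per attention condition.
#' @param channels_per_area Channels in each area (default 16).
#' @param bin_ms Latent/count bin width (ms).
#' @param off_hz,on_hz Off/On firing rates (spikes/s) per channel.
#' @param rate_jitter Multiplicative SD of per-channel rate variation
#'   (default 0 = identical channels).
#' @param conditions Condition labels; the first is treated as attend-RF.
#' @param P4 Optional named list of 4 x 4 transition matrices per condition;
#'   default built from [make_joint_P()] with `v4_lead` and the attention
#'   factors.
#' @param v4_lead V4-lead asymmetry passed to [make_joint_P()].
#' @param att_on_leave,att_off_leave Multipliers (< 1 and > 1) applied to
#'   the On-leaving and Off-leaving hazards of the attend-RF condition.
#' @param delays Task-delay spec (ms): fixed `fix_to_stim`, and uniform
#'   ranges `stim_to_cue`, `cue_to_dim1`, `dim_to_dim`.
#' @param rt Reaction-time model: `base_ms`, `offsets_ms` (length 4, one per
#'   joint state at target dimming), `sd_ms` (Gaussian noise; RT truncated
#'   at 0).
#' @param pupil Baseline-pupil model: `enabled`, `p0`, `coupling` (units per
#'   ms of mean On-epoch duration), `sd`.
#' @param msacc Microsaccade/eye model: `enabled`, `rate_hz`, amplitude
#'   log-normal (`amp_meanlog`, `amp_sdlog`), position drift `noise_sd`
#'   (deg), `fs` (Hz), and optional coupling placing a fraction
#'   `couple_frac` of V1 Off-to-On transitions `couple_lag_ms` after an
#'   injected microsaccade.
#' @param lfp Laminar LFP surrogate: `enabled`, `n_channels`, `fs`, a
#'   low-frequency component (`low_hz`, `amp_low`) gated to the V1 Off
#'   phase, a high-frequency component (`high_hz`, `amp_high`) gated On,
#'   pink background `noise_sd`, and a stimulus-evoked mid-layer dipole
#'   (`dipole_amp`, `dipole_channel`).
#' @param seed Master seed.
#' @return A `gen_config` list.
#' @export
gen_config <- function(n_trials = 30, channels_per_area = 16, bin_ms = 10,
                       off_hz = 20, on_hz = 100, rate_jitter = 0,
                       conditions = c("attend_RF", "attend_away1",
                                      "attend_away2"),
                       P4 = NULL, v4_lead = 0.02, att_on_leave = 0.6,
                       att_off_leave = 1.4,
                       delays = list(fix_to_stim = 614,
                                     stim_to_cue = c(618, 1131),
                                     cue_to_dim1 = c(1162, 2133),
                                     dim_to_dim = c(792, 1331)),
                       rt = list(base_ms = 350,
                                 offsets_ms = c(60, 40, 20, 0), sd_ms = 30),
                       pupil = list(enabled = TRUE, p0 = 1, coupling = 0.001,
                                    sd = 0.05),
                       msacc = list(enabled = TRUE, rate_hz = 0.9,
                                    amp_meanlog = log(0.45), amp_sdlog = 0.5,
                                    noise_sd = 0.02, fs = 220,
                                    couple_frac = 0, couple_lag_ms = 60),
                       lfp = list(enabled = FALSE, n_channels = 16,
                                  fs = 1000, low_hz = 5, high_hz = 60,
                                  amp_low = 6, amp_high = 2, noise_sd = 1,
                                  dipole_amp = 30, dipole_channel = 8),
                       seed = 1) {
  defaults <- list(
    delays = list(fix_to_stim = 614, stim_to_cue = c(618, 1131),
                  cue_to_dim1 = c(1162, 2133), dim_to_dim = c(792, 1331)),
    rt = list(base_ms = 350, offsets_ms = c(60, 40, 20, 0), sd_ms = 30),
    pupil = list(enabled = TRUE, p0 = 1, coupling = 0.001, sd = 0.05),
    msacc = list(enabled = TRUE, rate_hz = 0.9, amp_meanlog = log(0.45),
                 amp_sdlog = 0.5, noise_sd = 0.02, fs = 220,
                 couple_frac = 0, couple_lag_ms = 60),
    lfp = list(enabled = FALSE, n_channels = 16, fs = 1000, low_hz = 5,
               high_hz = 60, amp_low = 6, amp_high = 2, noise_sd = 1,
               dipole_amp = 30, dipole_channel = 8))
  delays <- utils::modifyList(defaults$delays, delays)
  rt <- utils::modifyList(defaults$rt, rt)
  pupil <- utils::modifyList(defaults$pupil, pupil)
  msacc <- utils::modifyList(defaults$msacc, msacc)
  lfp <- utils::modifyList(defaults$lfp, lfp)
  if (is.null(P4)) {
    P4 <- lapply(seq_along(conditions), function(i) {
      if (i == 1)
        make_joint_P(a = 0.015 * att_off_leave, b = 0.015 * att_on_leave,
                     lead = v4_lead, join = 0.05 * att_off_leave,
                     drop = 0.02 * att_on_leave)
      else make_joint_P(lead = v4_lead)
    })
    names(P4) <- conditions
  }
  for (P in P4) {
    if (any(abs(rowSums(P) - 1) > 1e-9))
      abort("transition matrix rows must sum to 1")
    if (any(P < 0)) abort("transition probabilities must be non-negative")
  }
  if (off_hz < 0 || on_hz < 0) abort("rates must be non-negative")
  for (rg in delays[c("stim_to_cue", "cue_to_dim1", "dim_to_dim")])
    if (rg[1] > rg[2]) abort("delay ranges must have low <= high")
  structure(list(n_trials = n_trials,
                 channels_per_area = channels_per_area, bin_ms = bin_ms,
                 off_hz = off_hz, on_hz = on_hz, rate_jitter = rate_jitter,
                 conditions = conditions, P4 = P4, v4_lead = v4_lead,
                 delays = delays, rt = rt, pupil = pupil, msacc = msacc,
                 lfp = lfp, seed = seed), class = "gen_config")
}

#' Sample a joint latent Markov chain
#'
#' @param P4 Row-stochastic transition matrix (any K).
#' @param pi0 Initial distribution (default: stationary distribution of
#'   `P4`).
#' @param n_bins Chain length.
#' @param seed RNG seed; the path is deterministic given the seed.
#' @return Integer state sequence (1-based).
#' @export
simulate_joint_latent <- function(P4, pi0 = NULL, n_bins, seed = 1) {
  if (any(abs(rowSums(P4) - 1) > 1e-9))
    abort("transition matrix rows must sum to 1 (within 1e-9)")
  K <- nrow(P4)
  pi0 <- pi0 %||% stationary_dist(P4)
  with_substream(seed, "latent", {
    s <- integer(n_bins)
    cumP <- t(apply(P4, 1, cumsum))
    u <- runif(n_bins)
    s[1] <- findInterval(u[1], cumsum(pi0), left.open = TRUE) + 1L
    for (t in 2:n_bins)
      s[t] <- findInterval(u[t], cumP[s[t - 1], ], left.open = TRUE) + 1L
    s
  })
}

#' Poisson spike counts given a latent path
#'
#' `counts[j, t] ~ Poisson(lambda[j, s_t] * bin_ms / 1000)`, independent
#' across channels and bins given the path.
#'
#' @param path Integer state sequence.
#' @param lambda_hz Channels x states rate matrix (spikes/s), >= 0.
#' @param bin_ms Bin width (ms).
#' @param seed RNG seed.
#' @return Integer channels x bins count matrix.
#' @export
simulate_counts <- function(path, lambda_hz, bin_ms = 10, seed = 1) {
  lambda_hz <- as.matrix(lambda_hz)
  if (any(lambda_hz < 0)) abort("rates must be non-negative")
  J <- nrow(lambda_hz)
  with_substream(seed, "counts", {
    mu <- lambda_hz[, path, drop = FALSE] * bin_ms / 1000
    matrix(rpois(length(mu), mu), nrow = J)
  })
}

draw_delay <- function(range, bin_ms) {
  if (length(range) == 1) return(range)
  steps <- seq(ceiling(range[1] / bin_ms), floor(range[2] / bin_ms))
  steps[sample.int(length(steps), 1)] * bin_ms
}

# V1/V4 marginal phase of a joint state (1 = Off, 2 = On)
v1_phase <- function(s) c(1L, 2L, 1L, 2L)[s]
v4_phase <- function(s) c(1L, 1L, 2L, 2L)[s]

#' Simulate a full synthetic session
#'
#' Generates one two-area recording with known ground truth: per trial, task
#' event times drawn from the configured uniform ranges (discretized to the
#' latent bin grid so ground-truth states align exactly with count bins), a
#' joint 4-state latent path sampled over the whole trial, Poisson spike
#' counts for both areas, a reaction time driven by the joint state at
#' target dimming, a baseline pupil value coupled to the trial's mean
#' On-epoch duration, eye traces with injected raised-cosine microsaccades,
#' and (optionally) a laminar LFP surrogate whose low-frequency power is
#' gated to the Off phase, high-frequency power to the On phase, with a
#' stimulus-evoked mid-layer dipole.
#'
#' @param cfg A [gen_config()].
#' @return A [session_bundle()] with counts for the `cue_to_dim1` window and
#'   ground truth (latent paths, microsaccade times, generator parameters)
#'   in `$ground_truth`.
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  bin <- cfg$bin_ms
  J <- cfg$channels_per_area
  ch_tbl <- tibble::tibble(
    channel = seq_len(2 * J),
    area = rep(c("V1", "V4"), each = J),
    included = TRUE)
  rates <- with_substream(cfg$seed, "rates", {
    jit <- function(n) if (cfg$rate_jitter > 0)
      exp(rnorm(n, 0, cfg$rate_jitter)) else rep(1, n)
    list(off = cfg$off_hz * jit(2 * J), on = cfg$on_hz * jit(2 * J))
  })
  # channels x 4 joint-state rates honoring the tying structure
  lambda_hz <- matrix(0, 2 * J, 4)
  for (j in seq_len(2 * J)) {
    ph <- if (ch_tbl$area[j] == "V1") c(1, 2, 1, 2) else c(1, 1, 2, 2)
    lambda_hz[j, ] <- ifelse(ph == 2, rates$on[j], rates$off[j])
  }
  n_tot <- cfg$n_trials * length(cfg$conditions)
  trials <- list(); spikes <- list(); gt_paths <- list(); gt_full <- list()
  eye <- list(); msacc_truth <- list(); lfp_v <- list()
  trial_id <- 0
  for (ci in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[ci]
    P4 <- cfg$P4[[cond]]
    pst <- stationary_dist(P4)
    for (k in seq_len(cfg$n_trials)) {
      trial_id <- trial_id + 1
      sseed <- substream(cfg$seed, paste0("trial_", trial_id))
      ev <- with_substream(sseed, "delays", {
        t_stim <- cfg$delays$fix_to_stim
        t_cue <- t_stim + draw_delay(cfg$delays$stim_to_cue, bin)
        t_dim1 <- t_cue + draw_delay(cfg$delays$cue_to_dim1, bin)
        target <- sample.int(3, 1)
        t_dim2 <- if (target >= 2) t_dim1 +
          draw_delay(cfg$delays$dim_to_dim, bin) else NA_real_
        t_dim3 <- if (target >= 3) t_dim2 +
          draw_delay(cfg$delays$dim_to_dim, bin) else NA_real_
        list(t_stim = t_stim, t_cue = t_cue, t_dim1 = t_dim1,
             t_dim2 = t_dim2, t_dim3 = t_dim3, target = target)
      })
      t_target <- c(ev$t_dim1, ev$t_dim2, ev$t_dim3)[ev$target]
      t_end <- t_target + 400
      n_bins <- ceiling(t_end / bin)
      path <- simulate_joint_latent(P4, pst, n_bins,
                                    seed = substream(sseed, "path"))
      counts <- simulate_counts(path, lambda_hz, bin,
                                seed = substream(sseed, "spikes"))
      # spike times uniform within each bin, consistent with the counts
      sp <- with_substream(sseed, "times", {
        nz <- which(counts > 0, arr.ind = TRUE)
        if (nrow(nz) == 0) {
          tibble::tibble(trial = integer(), channel = integer(),
                         time_ms = double())
        } else {
          reps <- counts[nz]
          tibble::tibble(
            trial = trial_id,
            channel = rep(nz[, 1], reps),
            time_ms = rep((nz[, 2] - 1) * bin, reps) + runif(sum(reps)) * bin)
        }
      })
      spikes[[trial_id]] <- sp
      # reaction time from the joint state at target dimming
      s_dim <- path[floor(t_target / bin) + 1]
      rt <- with_substream(sseed, "rt", {
        max(0, cfg$rt$base_ms + cfg$rt$offsets_ms[s_dim] +
              rnorm(1, 0, cfg$rt$sd_ms))
      })
      # baseline pupil coupled to the trial's mean On-epoch duration (V1)
      pupil <- NA_real_
      if (isTRUE(cfg$pupil$enabled)) {
        r <- rle(v1_phase(path))
        on_durs <- r$lengths[r$values == 2] * bin
        mean_on <- if (length(on_durs)) mean(on_durs) else 0
        pupil <- with_substream(sseed, "pupil",
          cfg$pupil$p0 + cfg$pupil$coupling * mean_on +
            rnorm(1, 0, cfg$pupil$sd))
      }
      # eye traces with injected microsaccades
      if (isTRUE(cfg$msacc$enabled)) {
        et <- simulate_eye_trial(cfg, sseed, t_end, path, trial_id)
        eye[[trial_id]] <- et$trace
        msacc_truth[[trial_id]] <- et$events
      }
      if (isTRUE(cfg$lfp$enabled)) {
        lfp_v[[as.character(trial_id)]] <-
          simulate_lfp_trial(cfg, sseed, t_end, path, ev$t_stim, bin)
      }
      trials[[trial_id]] <- tibble::tibble(
        trial = trial_id, condition = cond, t_fixation = 0,
        t_stim_on = ev$t_stim, t_cue_on = ev$t_cue, t_dim1 = ev$t_dim1,
        t_dim2 = ev$t_dim2, t_dim3 = ev$t_dim3, target_dim = ev$target,
        rt_ms = rt, pupil_baseline = pupil)
      gt_full[[trial_id]] <- path
    }
  }
  trial_tbl <- dplyr::bind_rows(trials)
  sts <- spike_train_set(dplyr::bind_rows(spikes), ch_tbl)
  win <- analysis_window(trial_tbl, "cue_to_dim1")
  bc <- bin_spikes(sts, win, bin)
  # ground-truth path over the analysis window (bin-aligned by design)
  gt_paths <- lapply(seq_len(n_tot), function(i) {
    b0 <- win$start[i] / bin
    gt_full[[i]][(b0 + 1):(b0 + bc$windows$n_bins[i])]
  })
  lfp <- NULL
  if (isTRUE(cfg$lfp$enabled))
    lfp <- lfp_array(lfp_v, fs = cfg$lfp$fs,
                     depth_um = seq_len(cfg$lfp$n_channels) * 150)
  session_bundle(
    spikes = sts, trials = trial_tbl,
    counts = list(cue_to_dim1 = bc),
    eye = if (length(eye)) dplyr::bind_rows(eye) else NULL,
    lfp = lfp,
    ground_truth = list(
      paths_window = gt_paths, paths_full = gt_full,
      P4 = cfg$P4, lambda_hz = lambda_hz,
      stationary = lapply(cfg$P4, stationary_dist),
      msacc = if (length(msacc_truth)) dplyr::bind_rows(msacc_truth)
              else NULL,
      rt = cfg$rt, pupil = cfg$pupil),
    meta = list(seed = cfg$seed, bin_ms = bin,
                conditions = cfg$conditions,
                n_trials = cfg$n_trials))
}

# Eye trace for one trial: smooth drift plus raised-cosine microsaccades at
# Poisson times; optionally extra events preceding V1 Off->On transitions.
simulate_eye_trial <- function(cfg, sseed, t_end, path, trial_id) {
  fs <- cfg$msacc$fs
  n <- ceiling(t_end / 1000 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  with_substream(sseed, "eye", {
    bf <- signal::butter(2, 0.05, type = "low")
    drift <- function() as.double(signal::filtfilt(bf, rnorm(n, 0,
                                                   cfg$msacc$noise_sd)))
    x <- drift(); y <- drift()
    onsets <- if (cfg$msacc$rate_hz > 0) {
      tt <- cumsum(rexp(100 + ceiling(t_end / 1000 * cfg$msacc$rate_hz * 4),
                        cfg$msacc$rate_hz / 1000))
      tt[tt < t_end - 30]
    } else numeric(0)
    if (cfg$msacc$couple_frac > 0) {
      p2 <- v1_phase(path)
      tr_t <- (which(diff(p2) == 1)) * cfg$bin_ms
      pick <- runif(length(tr_t)) < cfg$msacc$couple_frac
      extra <- tr_t[pick] - cfg$msacc$couple_lag_ms
      onsets <- sort(c(onsets, extra[extra > 0 & extra < t_end - 30]))
    }
    events <- tibble::tibble(trial = rep(trial_id, length(onsets)),
                             t_ms = onsets,
                             amplitude_deg = exp(rnorm(length(onsets),
                                                       cfg$msacc$amp_meanlog,
                                                       cfg$msacc$amp_sdlog)),
                             direction_deg = runif(length(onsets), 0, 360))
    dur <- 20
    for (i in seq_len(nrow(events))) {
      rel <- (t_ms - events$t_ms[i]) / dur
      prof <- ifelse(rel <= 0, 0, ifelse(rel >= 1, 1,
                                         (1 - cos(pi * rel)) / 2))
      th <- events$direction_deg[i] * pi / 180
      x <- x + events$amplitude_deg[i] * cos(th) * prof
      y <- y + events$amplitude_deg[i] * sin(th) * prof
    }
    list(trace = tibble::tibble(trial = trial_id, t_ms = t_ms, x = x, y = y),
         events = events)
  })
}

# Laminar LFP surrogate: pink background, Off-gated low-frequency and
# On-gated high-frequency components (V1 phase), and a stimulus-evoked
# dipole with a Gaussian depth profile centered on dipole_channel.
simulate_lfp_trial <- function(cfg, sseed, t_end, path, t_stim, bin) {
  fs <- cfg$lfp$fs
  n <- ceiling(t_end / 1000 * fs)
  t_s <- (seq_len(n) - 1) / fs
  nch <- cfg$lfp$n_channels
  gate_on <- (v1_phase(path) == 2)[pmin(length(path),
                                        floor(t_s * 1000 / bin) + 1)]
  with_substream(sseed, "lfp", {
    phase_lo <- runif(1, 0, 2 * pi); phase_hi <- runif(1, 0, 2 * pi)
    lo <- cfg$lfp$amp_low * sin(2 * pi * cfg$lfp$low_hz * t_s + phase_lo) *
      (!gate_on)
    hi <- cfg$lfp$amp_high * sin(2 * pi * cfg$lfp$high_hz * t_s + phase_hi) *
      gate_on
    bump <- cfg$lfp$dipole_amp *
      exp(-((t_s * 1000 - t_stim - 60)^2) / (2 * 20^2))
    depth_prof <- exp(-((seq_len(nch) - cfg$lfp$dipole_channel)^2) / 2)
    m <- matrix(0, nch, n)
    for (j in seq_len(nch)) {
      m[j, ] <- pink_noise(n, cfg$lfp$noise_sd) + lo + hi -
        depth_prof[j] * bump
    }
    m
  })
}

pink_noise <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  X <- fft(rnorm(n))
  f <- pmin(0:(n - 1), n - (0:(n - 1)))
  sc <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(fft(X * sc, inverse = TRUE)) / n
  x / sd(x) * sd
}
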