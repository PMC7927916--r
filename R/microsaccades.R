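#' Eye velocity from position traces
#'
#' Central-difference velocity of each gaze component (one-sided at the
#' ends), low-pass filtered at `cutoff_hz` with a 2nd-order zero-phase
#' Butterworth filter so detected onsets are not biased late.
#'
#' @param eye Tibble `trial`, `t_ms`, `x`, `y` (gaze in degrees).
#' @param fs Sampling rate (Hz, default 220).
#' @param cutoff_hz Low-pass cutoff (default 20 Hz).
#' @return Tibble `trial`, `t_ms`, `vx`, `vy` (deg/s).
#' @export
eye_velocity <- function(eye, fs = 220, cutoff_hz = 20) {
  eye <- tibble::as_tibble(eye)
  stopifnot(all(c("trial", "t_ms", "x", "y") %in% names(eye)))
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  cdiff <- function(p) {
    n <- length(p)
    if (n < 5) abort("trial too short for velocity estimation (need >= 5)")
    v <- numeric(n)
    v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) * fs / 2
    v[1] <- (p[2] - p[1]) * fs
    v[n] <- (p[n] - p[n - 1]) * fs
    as.double(signal::filtfilt(bf, v))
  }
  eye |>
    dplyr::group_by(.data$trial) |>
    dplyr::mutate(vx = cdiff(.data$x), vy = cdiff(.data$y)) |>
    dplyr::ungroup() |>
    dplyr::select("trial", "t_ms", "vx", "vy")
}

#' Detect microsaccades with an adaptive velocity threshold
#'
#' Per trial, each velocity component gets a robust scale estimate
#' `sigma = sqrt(median(v^2) - median(v)^2)`; a microsaccade is a run of at
#' least `min_samples` consecutive samples exceeding the elliptical
#' criterion `(vx / (mult sigma_x))^2 + (vy / (mult sigma_y))^2 > 1`.
#' Events closer than `merge_ms` are merged. Amplitude and direction are
#' the gaze displacement between onset and offset; peak velocity is the
#' maximal speed within the event. Trials with a zero scale estimate are
#' skipped with a warning.
#'
#' @param eye Tibble `trial`, `t_ms`, `x`, `y`.
#' @param fs,cutoff_hz Passed to [eye_velocity()].
#' @param mult Threshold multiplier (default 6).
#' @param min_samples Minimum consecutive supra-threshold samples
#'   (default 3).
#' @param merge_ms Events separated by less than this are merged
#'   (default 20 ms).
#' @param mode Apply the median estimator to the `"velocity"` components
#'   (default, standard practice) or to the `"position"` channels.
#' @return Tibble `trial`, `onset_ms`, `offset_ms`, `amplitude_deg`,
#'   `peak_velocity`, `direction_deg` (in [0, 360)).
#' @export
detect_microsaccades <- function(eye, fs = 220, cutoff_hz = 20, mult = 6,
                                 min_samples = 3, merge_ms = 20,
                                 mode = c("velocity", "position")) {
  mode <- match.arg(mode)
  vel <- eye_velocity(eye, fs, cutoff_hz)
  d <- dplyr::inner_join(tibble::as_tibble(eye), vel,
                         by = c("trial", "t_ms"))
  med_sigma <- function(v) {
    s2 <- median(v^2) - median(v)^2
    if (s2 <= 0) 0 else sqrt(s2)
  }
  out <- d |>
    dplyr::group_by(.data$trial) |>
    dplyr::group_map(function(g, key) {
      sx <- if (mode == "velocity") med_sigma(g$vx) else med_sigma(g$x)
      sy <- if (mode == "velocity") med_sigma(g$vy) else med_sigma(g$y)
      if (sx == 0 || sy == 0) {
        warn(paste0("zero velocity scale in trial ", key$trial,
                    "; detection skipped"))
        return(NULL)
      }
      crit <- (g$vx / (mult * sx))^2 + (g$vy / (mult * sy))^2 > 1
      r <- rle(crit)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- r$values & r$lengths >= min_samples
      if (!any(keep)) return(NULL)
      on <- starts[keep]; off <- ends[keep]
      # merge events separated by less than merge_ms
      if (length(on) > 1) {
        gap_ms <- (g$t_ms[on[-1]] - g$t_ms[off[-length(off)]])
        grp <- cumsum(c(1, as.integer(gap_ms >= merge_ms)))
        on <- tapply(on, grp, min)
        off <- tapply(off, grp, max)
      }
      purrr::map2_dfr(on, off, function(a, b) {
        dx <- g$x[b] - g$x[a]; dy <- g$y[b] - g$y[a]
        tibble::tibble(trial = key$trial,
                       onset_ms = g$t_ms[a], offset_ms = g$t_ms[b],
                       amplitude_deg = sqrt(dx^2 + dy^2),
                       peak_velocity = max(sqrt(g$vx[a:b]^2 + g$vy[a:b]^2)),
                       direction_deg = (atan2(dy, dx) * 180 / pi) %% 360)
      })
    }) |>
    purrr::list_rbind()
  if (nrow(out) == 0)
    out <- tibble::tibble(trial = integer(), onset_ms = double(),
                          offset_ms = double(), amplitude_deg = double(),
                          peak_velocity = double(), direction_deg = double())
  out
}

#' Summary statistics of detected microsaccades
#'
#' @param events A [detect_microsaccades()] table.
#' @param trial_durations Tibble `trial`, `duration_ms` of analyzed time per
#'   trial (including trials without events).
#' @return One-row tibble: `n_events`, `rate_hz` (events per second of
#'   analyzed time), `frac_trials` (fraction of trials with >= 1 event),
#'   `mean_amplitude`, `sd_amplitude`, `mean_peak_velocity`, `mean_iei_ms`
#'   (mean inter-event interval on trials with several events).
#' @export
msacc_stats <- function(events, trial_durations) {
  total_s <- sum(trial_durations$duration_ms) / 1000
  ieis <- events |>
    dplyr::group_by(.data$trial) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(iei = list(diff(.data$onset_ms)), .groups = "drop")
  tibble::tibble(
    n_events = nrow(events),
    rate_hz = nrow(events) / total_s,
    frac_trials = mean(trial_durations$trial %in% events$trial),
    mean_amplitude = if (nrow(events)) mean(events$amplitude_deg) else NA,
    sd_amplitude = if (nrow(events) > 1) sd(events$amplitude_deg) else NA,
    mean_peak_velocity = if (nrow(events)) mean(events$peak_velocity) else NA,
    mean_iei_ms = if (nrow(ieis)) mean(unlist(ieis$iei)) else NA_real_)
}

#' Microsaccade direction histogram aligned to the RF
#'
#' Bins event directions after rotating so the receptive-field direction is
#' 0 degrees. If transition times are supplied, also reports the fraction of
#' events in each direction bin followed by a transition within
#' `follow_ms`.
#'
#' @param events A [detect_microsaccades()] table.
#' @param rf_direction_deg Direction of the RF location (degrees).
#' @param n_bins Number of direction bins (default 8).
#' @param transitions Optional tibble `trial`, `t` of state transitions.
#' @param follow_ms Window for "followed by" (default 200 ms).
#' @return Tibble `bin_center_deg`, `n_events`, and (with transitions)
#'   `n_followed`, `frac_followed`.
#' @export
direction_analysis <- function(events, rf_direction_deg = 0, n_bins = 8,
                               transitions = NULL, follow_ms = 200) {
  width <- 360 / n_bins
  rel <- (events$direction_deg - rf_direction_deg + width / 2) %% 360
  bin <- floor(rel / width) + 1
  centers <- (seq_len(n_bins) - 1) * width
  followed <- rep(NA, nrow(events))
  if (!is.null(transitions)) {
    followed <- vapply(seq_len(nrow(events)), function(i) {
      tt <- transitions$t[transitions$trial == events$trial[i]]
      any(tt > events$onset_ms[i] & tt <= events$onset_ms[i] + follow_ms)
    }, TRUE)
  }
  out <- tibble::tibble(bin = factor(bin, levels = seq_len(n_bins)),
                        followed = followed) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(n_events = dplyr::n(),
                     n_followed = sum(.data$followed), .groups = "drop")
  out$bin_center_deg <- centers[as.integer(out$bin)]
  out$frac_followed <- ifelse(out$n_events > 0,
                              out$n_followed / out$n_events, NA_real_)
  out[c("bin_center_deg", "n_events", "n_followed", "frac_followed")]
}

#' Trials free of microsaccades in their analysis window
#'
#' Control analyses rerun the pipeline on trials in which no microsaccade
#' occurred during the analyzed period; this builds that trial mask.
#'
#' @param events A [detect_microsaccades()] table.
#' @param windows Tibble `trial`, `start`, `end` (ms).
#' @return Tibble `trial`, `clean` (TRUE = no event onset in the window).
#'   Warns if every trial is masked out.
#' @export
microsaccade_free_mask <- function(events, windows) {
  clean <- vapply(seq_len(nrow(windows)), function(i) {
    ev <- events[events$trial == windows$trial[i], ]
    !any(ev$onset_ms >= windows$start[i] & ev$onset_ms < windows$end[i])
  }, TRUE)
  if (!any(clean)) warn("every trial contains a microsaccade in its window")
  tibble::tibble(trial = windows$trial, clean = clean)
}
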