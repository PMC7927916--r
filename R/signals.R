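#' Laminar voltage container
#'
#' @param v List of per-trial voltage matrices (channels x samples).
#' @param fs Sampling rate in Hz (default 1000).
#' @param depth_um Per-channel depths in micrometers, monotone along the
#'   probe.
#' @param ref Reference scheme tag (`"raw"`, `"CAR"`, `"bipolar"`).
#' @return An object of class `lfp_array`.
#' @export
lfp_array <- function(v, fs = 1000, depth_um = NULL, ref = "raw") {
  if (is.matrix(v)) v <- list(`1` = v)
  ns <- unique(vapply(v, ncol, 0L))
  nch <- unique(vapply(v, nrow, 0L))
  if (length(nch) != 1) abort("all trials must have the same channel count")
  depth_um <- depth_um %||% (seq_len(nch) * 150)
  if (length(depth_um) != nch) abort("depth_um length must match channels")
  if (!(all(diff(depth_um) > 0) || all(diff(depth_um) < 0)))
    abort("depths must be monotone")
  structure(list(v = v, fs = fs, depth_um = depth_um, ref = ref),
            class = "lfp_array")
}

#' @export
print.lfp_array <- function(x, ...) {
  cat("<lfp_array> ", length(x$v), " trials x ", nrow(x$v[[1]]),
      " channels @ ", x$fs, " Hz (", x$ref, ")\n", sep = "")
  invisible(x)
}

#' Common average reference
#'
#' Removes noise common to all channels by subtracting, at every sample, the
#' across-channel mean from each channel. Idempotent.
#'
#' @param lfp An [lfp_array()] with at least 2 channels.
#' @return The re-referenced `lfp_array` (ref tag `"CAR"`).
#' @export
common_average_reference <- function(lfp) {
  stopifnot(inherits(lfp, "lfp_array"))
  if (nrow(lfp$v[[1]]) < 2) abort("CAR requires at least 2 channels")
  lfp$v <- lapply(lfp$v, function(m) sweep(m, 2, colMeans(m)))
  lfp$ref <- "CAR"
  lfp
}

#' Bipolar re-referencing
#'
#' The bipolar derivation: each output channel is the difference between two
#' neighboring contacts (superficial minus deep), suppressing signals common
#' to multiple channels. n channels give n - 1 outputs at the midpoint
#' depths.
#'
#' @param lfp An [lfp_array()] with depth-ordered channels.
#' @return An `lfp_array` with one fewer channel (ref tag `"bipolar"`).
#' @export
bipolar_reref <- function(lfp) {
  stopifnot(inherits(lfp, "lfp_array"))
  n <- nrow(lfp$v[[1]])
  if (n < 2) abort("bipolar derivation requires at least 2 channels")
  if (any(diff(lfp$depth_um) <= 0)) abort("channels must be depth-ordered")
  lfp$v <- lapply(lfp$v, function(m)
    m[-n, , drop = FALSE] - m[-1, , drop = FALSE])
  lfp$depth_um <- (lfp$depth_um[-n] + lfp$depth_um[-1]) / 2
  lfp$ref <- "bipolar"
  lfp
}

#' Multiunit activity envelope
#'
#' The MUA envelope (MUAe): the rectified high-pass spiking-band signal,
#' low-pass filtered below 300 Hz with a fifth-order Butterworth filter
#' (-3 dB at 300 Hz).
#'
#' @param v Voltage vector or channels x samples matrix (0.6-9 kHz band).
#' @param fs Sampling rate (Hz), must exceed 600.
#' @return The envelope, same shape as `v`.
#' @export
muae <- function(v, fs) {
  if (fs <= 600) abort("sampling rate must exceed 600 Hz")
  bf <- signal::butter(5, 300 / (fs / 2), type = "low")
  lp <- function(x) as.double(signal::filter(bf, abs(x)))
  if (is.matrix(v)) t(apply(v, 1, lp)) else lp(v)
}

#' Signal energy
#'
#' Sum of squared values of a voltage trace, used to screen recording
#' stability.
#'
#' @param v Numeric vector.
#' @return `sum(v^2)`.
#' @export
energy <- function(v) sum(v^2)

#' Finite-difference current source density
#'
#' Second spatial difference of the laminar voltage profile,
#' `CSD(x) = (phi(x + h) - 2 phi(x) + phi(x - h)) / h^2`, with `h` the
#' electrode spacing. Sinks and sources follow the raw sign of the formula
#' (no conductivity factor). Exact on depth profiles that are polynomials of
#' degree <= 2.
#'
#' @param phi Depth profile: vector (one value per channel) or channels x
#'   samples matrix.
#' @param h_um Electrode spacing in micrometers (default 150).
#' @return CSD with 2 fewer channels, in units of `phi` per square
#'   micrometer.
#' @export
csd_fd <- function(phi, h_um = 150) {
  m <- if (is.matrix(phi)) phi else matrix(phi, ncol = 1)
  n <- nrow(m)
  if (n < 3) abort("CSD requires at least 3 channels")
  out <- (m[-(1:2), , drop = FALSE] - 2 * m[-c(1, n), , drop = FALSE] +
            m[-((n - 1):n), , drop = FALSE]) / h_um^2
  if (is.matrix(phi)) out else as.double(out)
}

#' Stimulus-onset signal-to-noise ratio and channel inclusion
#'
#' `SNR = (Signal - Noise) / sd(noise)`, where Signal is the trial-averaged
#' MUAe amplitude in one of eight 50 ms response windows (starting 30 to
#' 100 ms after stimulus onset in 10 ms steps) and Noise is the average over
#' the baseline 200 to 50 ms before onset. A channel is included iff its
#' maximum SNR across the eight windows exceeds 3.
#'
#' @param muae_trials List of per-trial MUAe matrices (channels x samples).
#' @param fs Sampling rate (Hz).
#' @param onset_ms Stimulus onset relative to the first sample (ms).
#' @return List with `by_window` (tibble `channel`, `window_start_ms`,
#'   `snr`) and `summary` (tibble `channel`, `snr_max`, `included`).
#'   Channels with zero baseline variability get `NA` and are excluded.
#' @export
snr_channels <- function(muae_trials, fs, onset_ms) {
  avg <- Reduce(`+`, muae_trials) / length(muae_trials)
  J <- nrow(avg)
  t_ms <- (seq_len(ncol(avg)) - 1) / fs * 1000 - onset_ms
  base <- t_ms >= -200 & t_ms < -50
  if (!any(base)) abort("baseline window (-200 to -50 ms) outside trial")
  starts <- seq(30, 100, by = 10)
  by_window <- purrr::map_dfr(starts, function(s) {
    win <- t_ms >= s & t_ms < s + 50
    if (!any(win)) abort("response window outside trial")
    snr <- vapply(seq_len(J), function(j) {
      sdn <- sd(avg[j, base])
      if (sdn == 0) return(NA_real_)
      (mean(avg[j, win]) - mean(avg[j, base])) / sdn
    }, 0)
    tibble::tibble(channel = seq_len(J), window_start_ms = s, snr = snr)
  })
  summary <- by_window |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(snr_max = suppressWarnings(max(.data$snr, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::mutate(snr_max = ifelse(is.finite(.data$snr_max), .data$snr_max,
                                   NA_real_),
                  included = !is.na(.data$snr_max) & .data$snr_max > 3)
  list(by_window = by_window, summary = summary)
}

# Visual-response model: dissipating (exponentially modified Gaussian) plus
# sustained (cumulative Gaussian) component.
latency_model <- function(t, mu, sigma, alpha, c, d) {
  d * exp(mu * alpha + 0.5 * sigma^2 * alpha^2 - alpha * t) *
    pnorm(t, mu + sigma^2 * alpha, sigma) + c * pnorm(t, mu, sigma)
}

#' Visual response latency from the MUAe time course
#'
#' Fits the trial-averaged (baseline-subtracted) MUAe as the sum of an
#' exponentially modified Gaussian (the dissipating transient) and a
#' cumulative Gaussian (the sustained response) by nonlinear least squares
#' from a grid of starting values. The latency is the earliest time the
#' fitted curve reaches 33% of the maximum of the sustained (cumulative
#' Gaussian) component, i.e. 0.33 c; for a pure cumulative Gaussian this is
#' `mu + sigma * qnorm(0.33)`.
#'
#' @param y Baseline-subtracted response trace.
#' @param fs Sampling rate (Hz).
#' @param t_ms Optional time axis (ms, relative to stimulus onset); default
#'   `(0:(n-1)) / fs * 1000`.
#' @return List with `params` (tibble mu, sigma, alpha, c, d), `latency_ms`
#'   (`NA` with diagnostics if the fit fails or never crosses), and
#'   `converged`.
#' @export
latency_fit <- function(y, fs, t_ms = NULL) {
  t_ms <- t_ms %||% ((seq_along(y) - 1) / fs * 1000)
  if (sd(y) == 0)
    return(list(params = NULL, latency_ms = NA_real_, converged = FALSE))
  df <- data.frame(t = t_ms, y = y)
  best <- NULL; best_rss <- Inf
  ymax <- max(y)
  for (mu0 in quantile(t_ms, c(0.2, 0.4, 0.6))) {
    for (a0 in c(0.005, 0.02, 0.05)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ latency_model(t, mu, sigma, alpha, c, d), data = df,
          start = list(mu = as.double(mu0), sigma = 10, alpha = a0,
                       c = ymax, d = ymax / 2),
          lower = c(mu = min(t_ms), sigma = 0.5, alpha = 1e-5, c = 0, d = 0),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::residuals(fit)^2)
        if (rss < best_rss) { best_rss <- rss; best <- fit }
      }
    }
  }
  if (is.null(best))
    return(list(params = NULL, latency_ms = NA_real_, converged = FALSE))
  p <- as.list(coef(best))
  tt <- seq(min(t_ms), max(t_ms), length.out = 4000)
  yy <- latency_model(tt, p$mu, p$sigma, p$alpha, p$c, p$d)
  thr <- 0.33 * p$c
  cross <- which(yy >= thr)
  latency <- if (length(cross) == 0 || thr <= 0) NA_real_ else tt[cross[1]]
  list(params = tibble::tibble(mu = p$mu, sigma = p$sigma, alpha = p$alpha,
                               c = p$c, d = p$d),
       latency_ms = latency, converged = TRUE)
}

# Discrete prolate spheroidal sequences via the symmetric tridiagonal
# eigenproblem; returns an n x k matrix of unit-energy tapers.
dpss_tapers <- function(n, nw, k) {
  w <- nw / n
  t0 <- 0:(n - 1)
  d <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  e <- t0[-1] * (n - t0[-1]) / 2
  A <- matrix(0, n, n)
  diag(A) <- d
  A[cbind(2:n, 1:(n - 1))] <- e
  A[cbind(1:(n - 1), 2:n)] <- e
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    V[, i] <- V[, i] / sqrt(sum(V[, i]^2))
    if (sum(V[, i]) < 0) V[, i] <- -V[, i]
  }
  V
}

.dpss_cache <- new.env(parent = emptyenv())

dpss_cached <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (is.null(.dpss_cache[[key]]))
    .dpss_cache[[key]] <- dpss_tapers(n, nw, k)
  .dpss_cache[[key]]
}

# Multitaper power of one segment, zero-padded to pad_to points.
mt_power <- function(x, fs, nw, k, pad_to) {
  n <- length(x)
  tap <- dpss_cached(n, nw, k)
  xt <- tap * x
  nf <- pad_to
  P <- 0
  for (i in seq_len(k)) {
    X <- fft(c(xt[, i], rep(0, nf - n)))
    P <- P + Mod(X)^2
  }
  P / k / fs
}

#' State-conditioned multitaper power spectra of the LFP
#'
#' Splits each trial's field potential into segments according to the
#' decoded latent state, keeps epochs longer than `min_epoch_ms`, zero-pads
#' every segment to `pad_to` samples (epochs longer than that are cut into
#' non-overlapping `pad_to`-sample pieces, the remainder kept if it still
#' qualifies), and estimates power with `k_tapers` DPSS tapers
#' (time-bandwidth product `nw`). Power is averaged over a state's segments
#' per channel.
#'
#' @param lfp An [lfp_array()] (typically bipolar re-referenced), time axis
#'   starting at each trial's window start used by `paths`.
#' @param paths A `state_path` aligned to the same trials; state epochs are
#'   cut from the LFP using the path windows (`t = 0` in each LFP trial
#'   matrix corresponds to that trial's window start).
#' @param min_epoch_ms Minimum epoch duration (default 250 ms, strict).
#' @param k_tapers Number of DPSS tapers (default 7).
#' @param nw Time-bandwidth product (default 4, consistent with 7 tapers).
#' @param pad_to Zero-padded segment length (default 1024).
#' @param f_range Frequency range retained (default 4 to 200 Hz).
#' @return An object of class `spectrum_set`: `freq`, `power` (list per
#'   state of channels x frequency matrices), `n_segments` per state.
#'   States with no qualifying epoch are missing with a warning.
#' @export
state_spectra <- function(lfp, paths, min_epoch_ms = 250, k_tapers = 7,
                          nw = 4, pad_to = 1024, f_range = c(4, 200)) {
  stopifnot(inherits(lfp, "lfp_array"), inherits(paths, "state_path"))
  fs <- lfp$fs
  freq_all <- (0:(pad_to - 1)) * fs / pad_to
  sel <- freq_all >= f_range[1] & freq_all <= f_range[2]
  ep <- epochs_from_path(paths)
  J <- nrow(lfp$v[[1]])
  acc <- lapply(seq_len(paths$K), function(k) matrix(0, J, sum(sel)))
  nseg <- integer(paths$K)
  min_n <- ceiling(min_epoch_ms / 1000 * fs)
  for (r in seq_len(nrow(ep))) {
    if (ep$duration_ms[r] <= min_epoch_ms) next
    i <- match(ep$trial[r], paths$windows$trial)
    m <- lfp$v[[i]]
    s0 <- floor((ep$start_ms[r] - paths$windows$start[i]) / 1000 * fs) + 1
    s1 <- min(ncol(m), floor((ep$end_ms[r] - paths$windows$start[i]) /
                               1000 * fs))
    if (s1 - s0 + 1 < min_n) next
    segs <- split_segment(s0, s1, pad_to, min_n)
    for (sg in segs) {
      for (j in seq_len(J)) {
        acc[[ep$state[r]]][j, ] <- acc[[ep$state[r]]][j, ] +
          mt_power(m[j, sg[1]:sg[2]], fs, nw, k_tapers, pad_to)[sel]
      }
      nseg[ep$state[r]] <- nseg[ep$state[r]] + 1L
    }
  }
  power <- vector("list", paths$K)
  for (k in seq_len(paths$K)) {
    if (nseg[k] == 0) {
      warn(paste0("no qualifying epochs for state ", k))
      power[k] <- list(NULL)
    } else power[[k]] <- acc[[k]] / nseg[k]
  }
  structure(list(freq = freq_all[sel], power = power, n_segments = nseg,
                 fs = fs, K = paths$K), class = "spectrum_set")
}

split_segment <- function(s0, s1, pad_to, min_n) {
  len <- s1 - s0 + 1
  if (len <= pad_to) return(list(c(s0, s1)))
  n_full <- floor(len / pad_to)
  segs <- lapply(seq_len(n_full), function(i)
    c(s0 + (i - 1) * pad_to, s0 + i * pad_to - 1))
  rem0 <- s0 + n_full * pad_to
  if (s1 - rem0 + 1 >= min_n) segs <- c(segs, list(c(rem0, s1)))
  segs
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", length(x$freq), " frequencies (",
      min(x$freq), "-", max(x$freq), " Hz), segments per state: ",
      paste(x$n_segments, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn state_spectra Long-format view: state, channel, frequency,
#'   power.
#' @export
tidy.spectrum_set <- function(x, ...) {
  purrr::map_dfr(seq_len(x$K), function(k) {
    if (is.null(x$power[[k]])) return(NULL)
    m <- x$power[[k]]
    tibble::tibble(state = k,
                   channel = rep(seq_len(nrow(m)), times = ncol(m)),
                   freq = rep(x$freq, each = nrow(m)),
                   power = as.double(m))
  })
}

#' Percent power change between states
#'
#' `100 * (On - Off) / Off` per channel and frequency; for the joint model,
#' pass the state indices forming each side (e.g. within-area contrasts
#' between the two On states of one area).
#'
#' @param spec A [state_spectra()] result.
#' @param on_states,off_states State indices averaged on each side
#'   (defaults 2 and 1).
#' @return Tibble `channel`, `freq`, `pct_change`.
#' @export
spectra_percent_change <- function(spec, on_states = 2L, off_states = 1L) {
  avg <- function(ks) {
    ms <- spec$power[ks]
    if (any(vapply(ms, is.null, TRUE))) abort("missing state spectra")
    Reduce(`+`, ms) / length(ms)
  }
  on <- avg(on_states); off <- avg(off_states)
  tibble::tibble(channel = rep(seq_len(nrow(on)), times = ncol(on)),
                 freq = rep(spec$freq, each = nrow(on)),
                 pct_change = as.double(100 * (on - off) / off))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up procedure at level `q`: the largest i with
#' `p_(i) <= i q / m` and all smaller ordered p-values are rejected.
#'
#' @param p P-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return Logical rejection mask aligned with `p`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH") <= q
}

#' Population receptive-field map summary for two areas
#'
#' Combines per-channel z-scored stimulus-response maps into a population
#' map with Stouffer's method (`sum(Z)/sqrt(k)` by default; `mode = "mean"`
#' uses `sum(Z)/k`), thresholds it at `threshold` to outline the RF, and
#' reports the RF centers (supra-threshold centroid), the overlap of the two
#' areas' RFs as a proportion of the first (V1) RF area, and the
#' center-to-center separation.
#'
#' @param z_v1,z_v4 Per-area z-maps: a matrix, or a list of per-channel
#'   matrices on a common grid.
#' @param threshold Z threshold outlining the RF (default 3).
#' @param mode Stouffer combination variant.
#' @param grid_spacing Physical spacing of grid cells (default 1).
#' @return List with `overlap`, `separation`, `center_v1`, `center_v4`,
#'   `map_v1`, `map_v4`. Empty supra-threshold regions give `NA` fields.
#' @export
rf_summary <- function(z_v1, z_v4, threshold = 3,
                       mode = c("sqrt", "mean"), grid_spacing = 1) {
  mode <- match.arg(mode)
  combine <- function(z) {
    if (is.matrix(z)) z <- list(z)
    k <- length(z)
    S <- Reduce(`+`, z)
    if (mode == "sqrt") S / sqrt(k) else S / k
  }
  m1 <- combine(z_v1); m4 <- combine(z_v4)
  region <- function(m) m > threshold
  centroid <- function(mask) {
    if (!any(mask)) return(c(NA_real_, NA_real_))
    idx <- which(mask, arr.ind = TRUE)
    colMeans(idx) * grid_spacing
  }
  r1 <- region(m1); r4 <- region(m4)
  c1 <- centroid(r1); c4 <- centroid(r4)
  overlap <- if (!any(r1)) NA_real_ else sum(r1 & r4) / sum(r1)
  separation <- if (anyNA(c(c1, c4))) NA_real_ else
    sqrt(sum((c1 - c4)^2))
  list(overlap = overlap, separation = separation, center_v1 = c1,
       center_v4 = c4, map_v1 = m1, map_v4 = m4)
}
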