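new_cross_corr <- function(lag_ms, values, shuffle = NULL, n = NA_integer_,
                           unit = "correlation") {
  corrected <- if (!is.null(shuffle)) values - shuffle else NULL
  structure(list(lag_ms = lag_ms, values = values, shuffle = shuffle,
                 corrected = corrected, n = n, unit = unit),
            class = "cross_corr")
}

#' @export
print.cross_corr <- function(x, ...) {
  cat("<cross_corr> lags ", min(x$lag_ms), "..", max(x$lag_ms), " ms (",
      x$unit, ")", if (!is.null(x$shuffle)) ", shuffle-subtracted", "\n",
      sep = "")
  invisible(x)
}

#' @describeIn cc_hmm Long-format view of a cross-correlation.
#' @export
tidy.cross_corr <- function(x, ...) {
  tibble::tibble(lag_ms = x$lag_ms, value = x$values,
                 shuffle = x$shuffle %||% NA_real_,
                 corrected = x$corrected %||% NA_real_)
}

# Normalized cross-correlation of two lists of equal-length per-trial series;
# mean-subtraction and normalization are per trial, then trials averaged.
# FFT-based: c(L) = sum_t x(t) y(t + L) for L in -max_lag..max_lag.
cc_core <- function(xs, ys, max_lag) {
  acc <- numeric(2 * max_lag + 1)
  n_used <- 0
  for (i in seq_along(xs)) {
    x <- xs[[i]] - mean(xs[[i]])
    y <- ys[[i]] - mean(ys[[i]])
    dx <- sum(x^2); dy <- sum(y^2)
    if (dx == 0 || dy == 0) next
    acc <- acc + xcorr_fft(x, y, max_lag) / sqrt(dx * dy)
    n_used <- n_used + 1
  }
  if (n_used == 0) abort("all trials have zero-variance series")
  list(cc = acc / n_used, n = n_used)
}

xcorr_fft <- function(x, y, max_lag) {
  T <- length(x)
  N <- stats::nextn(T + max_lag, 2)
  X <- fft(c(x, rep(0, N - T)))
  Y <- fft(c(y, rep(0, N - T)))
  r <- Re(fft(Conj(X) * Y, inverse = TRUE)) / N # r[L+1] = sum x(t) y(t+L)
  c(r[(N - max_lag + 1):N], r[1:(max_lag + 1)])
}

paths_series <- function(paths) lapply(paths$paths, as.numeric)

#' Cross-correlation of latent On-Off time series between two areas
#'
#' Per trial, both decoded state series are mean-subtracted and their
#' cross-correlation is normalized so the zero-lag autocorrelation of each
#' series is 1 (per-trial denominators); trials are then averaged. Sign
#' convention: `x` is the V1 series, `y` the V4 series, and
#' `CC(tau) = <x(t) y(t + tau)>`, so mass at negative lags means that y (V4)
#' transitions lead x (V1). Zero-variance trials are skipped with a warning.
#'
#' @param x,y Trial-matched `state_path` objects with equal per-trial
#'   lengths.
#' @param max_lag_ms Maximum lag (default 500 ms).
#' @param n_shuffles If > 0, also compute and attach the trial-shuffle
#'   predictor via [shuffle_predictor()].
#' @param seed Seed for the shuffles.
#' @return A `cross_corr` object.
#' @export
cc_hmm <- function(x, y, max_lag_ms = 500, n_shuffles = 0, seed = 1) {
  stopifnot(inherits(x, "state_path"), inherits(y, "state_path"))
  lens_x <- lengths(x$paths); lens_y <- lengths(y$paths)
  if (length(lens_x) != length(lens_y) || !all(lens_x == lens_y))
    abort("x and y must be trial-matched with equal per-trial lengths")
  max_lag <- as.integer(round(max_lag_ms / x$bin_ms))
  xs <- paths_series(x); ys <- paths_series(y)
  n_zero <- sum(vapply(seq_along(xs), function(i)
    sd(xs[[i]]) == 0 || sd(ys[[i]]) == 0, TRUE))
  if (n_zero > 0)
    warn(paste0(n_zero, " zero-variance trial(s) skipped"))
  r <- cc_core(xs, ys, max_lag)
  out <- new_cross_corr((-max_lag:max_lag) * x$bin_ms, r$cc, n = r$n)
  if (n_shuffles > 0) {
    pred <- shuffle_predictor(x, y, n_shuffles = n_shuffles, seed = seed,
                              max_lag_ms = max_lag_ms)
    out <- new_cross_corr(out$lag_ms, out$values, shuffle = pred$values,
                          n = r$n)
  }
  out
}

#' Trial-shuffle predictor of the cross-correlation
#'
#' The cross-correlation expected from task-locked (event-locked) structure
#' alone: y's trials are randomly re-paired against unshuffled x trials (a
#' derangement, so no trial is paired with itself), the cross-correlation is
#' computed as in [cc_hmm()], and the result is averaged over `n_shuffles`
#' permutations. Subtracting it removes correlations shared by all trials.
#'
#' @inheritParams cc_hmm
#' @param n_shuffles Number of random derangements to average (default 100).
#' @return A `cross_corr` holding the predictor curve.
#' @export
shuffle_predictor <- function(x, y, n_shuffles = 100, seed = 1,
                              max_lag_ms = 500) {
  stopifnot(inherits(x, "state_path"), inherits(y, "state_path"))
  M <- length(x$paths)
  if (M < 2) abort("shuffle predictor needs at least 2 trials")
  max_lag <- as.integer(round(max_lag_ms / x$bin_ms))
  xs <- paths_series(x); ys <- paths_series(y)
  lens <- lengths(xs)
  acc <- NULL
  with_substream(seed, "shuffle_predictor", {
    for (s in seq_len(n_shuffles)) {
      perm <- derangement(M, lens)
      r <- cc_core(xs, ys[perm], max_lag)
      acc <- if (is.null(acc)) r$cc else acc + r$cc
    }
  })
  new_cross_corr((-max_lag:max_lag) * x$bin_ms, acc / n_shuffles,
                 unit = "correlation (predictor)")
}

# Random permutation with no fixed point, constrained so paired trials have
# equal lengths (required for per-trial products).
derangement <- function(M, lens = rep(1, M)) {
  perm <- integer(M)
  for (idx in split(seq_len(M), lens)) {
    if (length(idx) == 1) { perm[idx] <- idx; next }
    p <- idx
    for (i in 1:1000) {
      p <- sample(idx)
      if (!any(p == idx)) break
    }
    perm[idx] <- p
  }
  perm
}

#' Area under the cross-correlation for negative vs positive lags
#'
#' Trapezoidal areas of the (shuffle-subtracted, if available) curve over
#' `tau < 0` and `tau > 0`; the zero-lag point is excluded from both halves.
#' A larger negative-side area indicates that the y series (V4, under the
#' [cc_hmm()] convention) leads.
#'
#' @param cc A `cross_corr`.
#' @return One-row tibble `auc_neg`, `auc_pos`, `difference`
#'   (`auc_neg - auc_pos`).
#' @export
auc_split <- function(cc) {
  v <- cc$corrected %||% cc$values
  l <- cc$lag_ms
  trap <- function(xx, yy) if (length(xx) < 2) 0 else
    sum(diff(xx) * (head(yy, -1) + tail(yy, -1)) / 2)
  tibble::tibble(auc_neg = trap(l[l < 0], v[l < 0]),
                 auc_pos = trap(l[l > 0], v[l > 0]),
                 difference = trap(l[l < 0], v[l < 0]) -
                   trap(l[l > 0], v[l > 0]))
}

#' Cross-correlogram of state transitions around events
#'
#' Histogram of transition times relative to each event (e.g. microsaccade
#' onsets), normalized by the number of events, so values are coincidences of
#' transitions per event per lag bin. Positive lags mean the transition
#' follows the event. An optional trial-shuffle predictor (re-pairing event
#' trials against transition trials) is subtracted to remove task-locked
#' structure.
#'
#' @param transitions Tibble `trial`, `t` (ms), e.g. from 2-state paths.
#' @param events Tibble `trial`, `t` (ms).
#' @param max_lag_ms Maximum lag (default 500).
#' @param bin_ms Lag bin width (default 10).
#' @param n_shuffles Shuffles for the predictor (0 = none).
#' @param seed Seed for the shuffles.
#' @return A `cross_corr` in coincidences per event.
#' @export
cc_events <- function(transitions, events, max_lag_ms = 500, bin_ms = 10,
                      n_shuffles = 0, seed = 1) {
  if (nrow(events) == 0) abort("no events")
  edges <- seq(-max_lag_ms, max_lag_ms, by = bin_ms)
  centers <- head(edges, -1) + bin_ms / 2
  count_pairs <- function(trans, ev) {
    cts <- numeric(length(centers))
    trials <- unique(ev$trial)
    for (tr in trials) {
      tt <- trans$t[trans$trial == tr]
      et <- ev$t[ev$trial == tr]
      if (!length(tt) || !length(et)) next
      d <- as.vector(outer(tt, et, `-`))
      d <- d[d >= -max_lag_ms & d < max_lag_ms]
      if (length(d))
        cts <- cts + tabulate(floor((d + max_lag_ms) / bin_ms) + 1,
                              nbins = length(centers))
    }
    cts
  }
  raw <- count_pairs(transitions, events) / nrow(events)
  shuffle <- NULL
  if (n_shuffles > 0) {
    trials <- sort(unique(c(events$trial, transitions$trial)))
    M <- length(trials)
    if (M >= 2) {
      acc <- numeric(length(centers))
      with_substream(seed, "cc_events_shuffle", {
        for (s in seq_len(n_shuffles)) {
          perm <- derangement(M)
          ev2 <- events
          ev2$trial <- trials[perm][match(events$trial, trials)]
          acc <- acc + count_pairs(transitions, ev2) / nrow(events)
        }
      })
      shuffle <- acc / n_shuffles
    }
  }
  new_cross_corr(centers, raw, shuffle = shuffle, n = nrow(events),
                 unit = "coincidences per event")
}

#' Transition-triggered average of spiking activity
#'
#' Mean activity in one area around the latent-state transition times of the
#' other area. Only isolated transitions -- no neighboring transition within
#' `isolation_ms` before or after -- are used. Per channel, the trial-mean
#' count is subtracted (cross covariance) and the sum over transitions is
#' divided by the number of transitions; values are converted to spikes/s.
#' An optional trial-shuffle predictor is subtracted.
#'
#' @param counts [bin_spikes()] counts of the area whose rates are averaged.
#' @param transitions Tibble `trial`, `t` of alignment transitions.
#' @param all_transitions Optional tibble of all transitions used for the
#'   isolation criterion (defaults to `transitions`).
#' @param window_ms Half-window around each transition (default 200).
#' @param isolation_ms Minimum separation from neighboring transitions
#'   (default 100).
#' @param n_shuffles Shuffles for the predictor (0 = none).
#' @param seed Seed for the shuffles.
#' @return An object of class `tta`: `lag_ms`, per-channel matrix `rate`
#'   (channels x lags, spikes/s, mean-subtracted), population `trace`,
#'   shuffle-corrected `corrected`, and `n_transitions`. Empty (with a
#'   warning) if no transition is isolated.
#' @export
tta <- function(counts, transitions, all_transitions = NULL, window_ms = 200,
                isolation_ms = 100, n_shuffles = 0, seed = 1) {
  stopifnot(inherits(counts, "binned_counts"))
  all_tr <- all_transitions %||% transitions
  iso <- isolated_transitions(transitions, all_tr, isolation_ms)
  bin <- counts$bin_ms
  half <- as.integer(round(window_ms / bin))
  lag_ms <- (-half:(half - 1)) * bin + bin / 2
  accumulate <- function(trans) {
    J <- nrow(counts$channels)
    acc <- matrix(0, J, 2 * half)
    n_used <- 0
    for (r in seq_len(nrow(trans))) {
      i <- match(trans$trial[r], counts$windows$trial)
      if (is.na(i)) next
      m <- counts$counts[[i]]
      mu <- rowMeans(m)
      b0 <- floor((trans$t[r] - counts$windows$start[i]) / bin)
      idx <- (b0 - half + 1):(b0 + half)
      if (idx[1] < 1 || idx[length(idx)] > ncol(m)) next
      acc <- acc + (m[, idx, drop = FALSE] - mu)
      n_used <- n_used + 1
    }
    list(acc = acc, n = n_used)
  }
  a <- accumulate(iso)
  if (a$n == 0) {
    warn("no isolated transitions with full windows; empty TTA")
    return(structure(list(lag_ms = lag_ms, rate = NULL, trace = NULL,
                          corrected = NULL, n_transitions = 0),
                     class = "tta"))
  }
  rate <- a$acc / a$n * (1000 / bin)
  trace <- colMeans(rate)
  corrected <- NULL
  if (n_shuffles > 0) {
    trials <- counts$windows$trial
    M <- length(trials)
    accs <- matrix(0, nrow(counts$channels), 2 * half)
    ns <- 0
    with_substream(seed, "tta_shuffle", {
      for (s in seq_len(n_shuffles)) {
        perm <- derangement(M)
        sh <- iso
        sh$trial <- trials[perm][match(iso$trial, trials)]
        r2 <- accumulate(sh)
        if (r2$n > 0) { accs <- accs + r2$acc / r2$n; ns <- ns + 1 }
      }
    })
    if (ns > 0) {
      pred <- accs / ns * (1000 / bin)
      corrected <- colMeans(rate - pred)
    }
  }
  structure(list(lag_ms = lag_ms, rate = rate, trace = trace,
                 corrected = corrected, n_transitions = a$n),
            class = "tta")
}

#' @export
print.tta <- function(x, ...) {
  cat("<tta> ", x$n_transitions, " transitions, lags ",
      min(x$lag_ms), "..", max(x$lag_ms), " ms\n", sep = "")
  invisible(x)
}

#' @describeIn tta Long-format view of the population TTA trace.
#' @export
tidy.tta <- function(x, ...) {
  tibble::tibble(lag_ms = x$lag_ms,
                 rate = x$trace %||% NA_real_,
                 corrected = x$corrected %||% NA_real_)
}

isolated_transitions <- function(transitions, all_transitions, isolation_ms) {
  keep <- vapply(seq_len(nrow(transitions)), function(r) {
    others <- all_transitions$t[all_transitions$trial ==
                                  transitions$trial[r]]
    others <- others[abs(others - transitions$t[r]) > 1e-9]
    !any(abs(others - transitions$t[r]) <= isolation_ms)
  }, TRUE)
  transitions[keep, ]
}

#' Two-line crossing-point fit of a transition-aligned trace
#'
#' Estimates when the firing rate in one area changes relative to latent
#' transitions in the other by fitting two straight lines to the
#' transition-aligned trace and returning their crossing time (ms).
#'
#' The default (`method = "hinge"`) fits, for a fine grid of candidate
#' crossing points, two lines constrained to meet at the candidate
#' (a broken-stick least-squares fit using all points) and returns the
#' candidate with the smallest squared error; this localizes the kink much
#' more stably than unconstrained lines. `method = "independent"` instead
#' fits, per candidate breakpoint, unconstrained least-squares lines to the
#' left and right parts and intersects the best-SSE pair (intersections far
#' from their breakpoint are rejected as degenerate).
#'
#' @param trace A `tta` object (its corrected trace if available), or a data
#'   frame with columns `lag_ms` and `value`.
#' @param method `"hinge"` (default) or `"independent"`.
#' @return Crossing time (ms), or `NA` if the fitted lines are parallel or
#'   the trace is degenerate (flat).
#' @export
two_line_crossing <- function(trace, method = c("hinge", "independent")) {
  method <- match.arg(method)
  if (inherits(trace, "tta")) {
    v <- trace$corrected %||% trace$trace
    trace <- tibble::tibble(lag_ms = trace$lag_ms, value = v)
  }
  x <- trace$lag_ms; y <- trace$value
  n <- length(x)
  if (n < 4) abort("need at least 4 points for a two-line fit")
  if (sd(y) == 0) return(NA_real_)
  if (method == "hinge") {
    grid <- sort(unique(c(seq(x[2], x[n - 1], length.out = max(200, 4 * n)),
                          x[2:(n - 1)])))
    best <- NA_real_; best_sse <- Inf
    for (c0 in grid) {
      X <- cbind(1, x - c0, pmax(x - c0, 0))
      f <- stats::lm.fit(X, y)
      sse <- sum(f$residuals^2)
      if (sse < best_sse && abs(f$coefficients[3]) > 1e-12) {
        best_sse <- sse
        best <- c0
      }
    }
    return(best)
  }
  cand <- matrix(NA_real_, n, 3) # sse, crossing, breakpoint midpoint
  for (b in 2:(n - 2)) {
    f1 <- lm(y[1:b] ~ x[1:b])
    f2 <- lm(y[(b + 1):n] ~ x[(b + 1):n])
    m1 <- coef(f1)[2]; m2 <- coef(f2)[2]
    cross <- if (!is.finite(m1) || !is.finite(m2) ||
                 abs(m1 - m2) < 1e-12) NA_real_
             else as.double((coef(f1)[1] - coef(f2)[1]) / (m2 - m1))
    cand[b, ] <- c(sum(f1$residuals^2) + sum(f2$residuals^2), cross,
                   (x[b] + x[b + 1]) / 2)
  }
  span <- x[n] - x[1]
  for (i in order(cand[, 1])) {
    cr <- cand[i, 2]
    if (!is.na(cr) && abs(cr - cand[i, 3]) <= span / 4) return(cr)
  }
  NA_real_
}
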