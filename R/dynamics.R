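#' Phase epochs from a decoded state path
#'
#' Maximal runs of constant state become epochs with start/end times in ms.
#' Epochs touching the window edges are flagged censored (their true duration
#' is unknown); censored epochs are excluded from mean-duration statistics
#' downstream but still count toward occupancy.
#'
#' @param paths A `state_path`.
#' @return Tibble `trial`, `state`, `start_ms`, `end_ms`, `duration_ms`,
#'   `censored_left`, `censored_right`.
#' @export
epochs_from_path <- function(paths) {
  stopifnot(inherits(paths, "state_path"))
  purrr::map2_dfr(paths$paths, seq_along(paths$paths), function(p, i) {
    r <- rle(as.integer(p))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    w0 <- paths$windows$start[i]
    tibble::tibble(
      trial = paths$windows$trial[i],
      state = r$values,
      start_ms = w0 + (starts - 1) * paths$bin_ms,
      end_ms = w0 + ends * paths$bin_ms,
      duration_ms = r$lengths * paths$bin_ms,
      censored_left = seq_along(r$values) == 1,
      censored_right = seq_along(r$values) == length(r$values))
  })
}

#' Mean epoch duration per state, censored epochs excluded
#'
#' @param epochs An [epochs_from_path()] table.
#' @return Tibble `state`, `mean_duration_ms`, `n_epochs`.
#' @export
epoch_durations <- function(epochs) {
  epochs |>
    dplyr::filter(!.data$censored_left, !.data$censored_right) |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(mean_duration_ms = mean(.data$duration_ms),
                     n_epochs = dplyr::n(), .groups = "drop")
}

#' @rdname time_in_states
#' @export
occupancy <- function(paths) time_in_states(paths)

#' Attention modulation index
#'
#' `attMI = (A_RF - A_out) / (A_RF + A_out)`, in [-1, 1]; positive values
#' mean higher activity with attention directed toward the receptive field.
#' Vectorized; undefined (NA) when both inputs are zero.
#'
#' @param a_rf Activity in the attend-RF condition (>= 0).
#' @param a_out Activity in an attend-away condition (>= 0).
#' @return Numeric index values.
#' @export
att_mi <- function(a_rf, a_out) {
  if (any(a_rf < 0, na.rm = TRUE) || any(a_out < 0, na.rm = TRUE))
    abort("attMI inputs must be non-negative")
  ifelse(a_rf + a_out == 0, NA_real_, (a_rf - a_out) / (a_rf + a_out))
}

#' Time-resolved transition probability density
#'
#' Counts Off-to-On (or On-to-Off) transitions in bins of width `w_ms`
#' aligned to a common task event and normalizes to transitions per second
#' per trial: `v_t = c_t / (w * n_trials)` with `w` in seconds, so conditions
#' with different trial counts are comparable.
#'
#' @param paths A 2-state `state_path` whose window times are already
#'   relative to the alignment event (or use `align_ms` to shift).
#' @param direction `"off_on"` (1 -> 2) or `"on_off"` (2 -> 1).
#' @param w_ms Histogram bin width (default 100 ms).
#' @param align_ms Per-trial alignment times subtracted from transition
#'   times (default 0).
#' @return Tibble `t_ms` (bin center), `density` (transitions / s / trial),
#'   `n_transitions`.
#' @export
transition_pdf <- function(paths, direction = c("off_on", "on_off"),
                           w_ms = 100, align_ms = 0) {
  direction <- match.arg(direction)
  stopifnot(inherits(paths, "state_path"))
  n_trials <- length(paths$paths)
  if (n_trials == 0) abort("no trials")
  from <- if (direction == "off_on") 1L else 2L
  tt <- transition_times(paths, from = from)
  tt$t <- tt$t - rep(align_ms, length.out = n_trials)[match(tt$trial,
                                                  paths$windows$trial)]
  lo <- min(paths$windows$start - align_ms)
  hi <- max(paths$windows$end - align_ms)
  edges <- seq(floor(lo / w_ms) * w_ms, ceiling(hi / w_ms) * w_ms, by = w_ms)
  cts <- if (nrow(tt)) graphics::hist(tt$t, breaks = edges,
                                      plot = FALSE)$counts
         else rep(0L, length(edges) - 1)
  tibble::tibble(t_ms = head(edges, -1) + w_ms / 2,
                 density = cts / ((w_ms / 1000) * n_trials),
                 n_transitions = cts)
}

# Transition times (ms): time of the first bin of the new state, for
# transitions leaving `from` (or any transition if from = NULL).
transition_times <- function(paths, from = NULL, to = NULL) {
  purrr::map2_dfr(paths$paths, seq_along(paths$paths), function(p, i) {
    if (length(p) < 2) return(tibble::tibble(trial = integer(), t = double(),
                                             from = integer(),
                                             to = integer()))
    ch <- which(diff(p) != 0)
    keep <- rep(TRUE, length(ch))
    if (!is.null(from)) keep <- keep & p[ch] == from
    if (!is.null(to)) keep <- keep & p[ch + 1] == to
    ch <- ch[keep]
    tibble::tibble(trial = paths$windows$trial[i],
                   t = paths$windows$start[i] + ch * paths$bin_ms,
                   from = p[ch], to = p[ch + 1])
  })
}

#' Equate firing rates across conditions by random spike deletion
#'
#' For each channel, the target rate is the minimum condition mean; spikes in
#' higher-rate conditions are deleted independently (binomial thinning of the
#' bin counts) with probability `1 - target/current`. Thinned counts never
#' exceed the originals bin-wise, and thinning a Poisson process leaves it
#' Poisson at the target rate.
#'
#' @param counts_by_condition Named list of [bin_spikes()] results, one per
#'   condition, with identical channels.
#' @param seed RNG seed.
#' @return Named list of thinned `binned_counts` in the same order.
#' @export
rate_match <- function(counts_by_condition, seed = 1) {
  stopifnot(length(counts_by_condition) >= 2)
  means <- vapply(counts_by_condition, function(cc)
    rowMeans(do.call(cbind, cc$counts)), numeric(nrow(
      counts_by_condition[[1]]$channels)))
  means <- matrix(means, ncol = length(counts_by_condition))
  target <- apply(means, 1, min)
  out <- counts_by_condition
  for (ci in seq_along(out)) {
    keep_p <- ifelse(means[, ci] > 0, pmin(1, target / means[, ci]), 1)
    out[[ci]]$counts <- with_substream(seed, paste0("thin_", ci),
      lapply(out[[ci]]$counts, function(m) {
        thinned <- m
        for (j in seq_len(nrow(m))) {
          if (keep_p[j] < 1)
            thinned[j, ] <- rbinom(ncol(m), m[j, ], keep_p[j])
        }
        thinned
      }))
  }
  out
}

#' Correlation of baseline pupil diameter with mean epoch duration
#'
#' Per recording, computes the Pearson correlation across trials between the
#' baseline pupil value and the trial's mean duration of epochs in a given
#' state (censored epochs excluded; trials without any uncensored epoch of
#' that state are dropped).
#'
#' @param trials Trial table with `trial` and `pupil_baseline`.
#' @param epochs An [epochs_from_path()] table.
#' @param state State whose epoch durations to use (default 2 = On).
#' @return One-row tibble `state`, `r`, `n_trials`; `r` is `NA` if the pupil
#'   is constant or fewer than 3 trials qualify.
#' @export
pupil_coupling <- function(trials, epochs, state = 2L) {
  if (!"pupil_baseline" %in% names(trials) || all(is.na(trials$pupil_baseline)))
    abort("trial table has no pupil_baseline values")
  per_trial <- epochs |>
    dplyr::filter(.data$state == !!state, !.data$censored_left,
                  !.data$censored_right) |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(mean_dur = mean(.data$duration_ms), .groups = "drop")
  d <- dplyr::inner_join(per_trial,
                         trials[c("trial", "pupil_baseline")], by = "trial")
  d <- d[complete.cases(d), ]
  r <- if (nrow(d) < 3 || sd(d$pupil_baseline) == 0 || sd(d$mean_dur) == 0)
    NA_real_ else cor(d$pupil_baseline, d$mean_dur)
  tibble::tibble(state = state, r = r, n_trials = nrow(d))
}

#' Latent state at a task event
#'
#' Returns the decoded state of the bin containing each event time
#' (half-open bins, so an event exactly on a bin edge belongs to the bin
#' starting there).
#'
#' @param paths A `state_path`.
#' @param events Tibble `trial`, `t_ms` (or a single numeric time applied to
#'   all trials).
#' @return Tibble `trial`, `t_ms`, `state`.
#' @export
state_at_event <- function(paths, events) {
  stopifnot(inherits(paths, "state_path"))
  if (is.numeric(events))
    events <- tibble::tibble(trial = paths$windows$trial, t_ms = events)
  out <- purrr::pmap_dfr(events, function(trial, t_ms, ...) {
    i <- match(trial, paths$windows$trial)
    if (is.na(i)) abort(paste0("trial ", trial, " has no decoded path"))
    b <- floor((t_ms - paths$windows$start[i]) / paths$bin_ms) + 1
    if (b < 1 || b > paths$windows$n_bins[i])
      abort(paste0("event at ", t_ms, " ms outside decoded window of trial ",
                   trial))
    tibble::tibble(trial = trial, t_ms = t_ms,
                   state = as.integer(paths$paths[[i]][b]))
  })
  out
}

#' Reaction time by latent state at target dimming
#'
#' Builds the tidy table linking each qualifying trial's reaction time to the
#' decoded state at the moment its target dimmed: one row per trial with the
#' condition, the state at dimming and the RT, ready for a mixed-model fit
#' (`RT ~ attention * state` with recording as a random intercept, fit with
#' standard tools), plus per-(condition, state) mean RTs for nonparametric
#' comparisons.
#'
#' Qualifying trials have a recorded RT and a decoded path covering the
#' target dimming time. The dimming time is taken from `t_dim1`/`t_dim2`/
#' `t_dim3` according to `target_dim` (default 1 when absent).
#'
#' @param trials Trial table.
#' @param paths Decoded `state_path` (2-state or joint 4-state).
#' @return List with `table` (tibble `trial`, `condition`, `state`, `rt_ms`)
#'   and `means` (tibble `condition`, `state`, `mean_rt`, `n`). Empty with a
#'   warning if no trials qualify.
#' @export
rt_by_state <- function(trials, paths) {
  trials <- tibble::as_tibble(trials)
  if (!"rt_ms" %in% names(trials)) abort("trial table lacks rt_ms")
  td <- if ("target_dim" %in% names(trials)) trials$target_dim else 1L
  dim_col <- paste0("t_dim", td)
  dim_t <- vapply(seq_len(nrow(trials)),
                  function(i) trials[[dim_col[min(i, length(dim_col))]]][i],
                  0)
  ok <- !is.na(trials$rt_ms) & trials$trial %in% paths$windows$trial
  wi <- match(trials$trial, paths$windows$trial)
  inside <- !is.na(wi) & dim_t >= paths$windows$start[wi] &
    dim_t < paths$windows$start[wi] + paths$windows$n_bins[wi] * paths$bin_ms
  ok <- ok & inside
  if (!any(ok)) {
    warn("no qualifying trials (RT present and dimming inside decoded window)")
    return(list(table = tibble::tibble(trial = integer(),
                                       condition = character(),
                                       state = integer(), rt_ms = double()),
                means = tibble::tibble(condition = character(),
                                       state = integer(), mean_rt = double(),
                                       n = integer())))
  }
  st <- state_at_event(paths, tibble::tibble(trial = trials$trial[ok],
                                             t_ms = dim_t[ok]))
  tab <- tibble::tibble(trial = trials$trial[ok],
                        condition = trials$condition[ok],
                        state = st$state, rt_ms = trials$rt_ms[ok])
  means <- tab |>
    dplyr::group_by(.data$condition, .data$state) |>
    dplyr::summarise(mean_rt = mean(.data$rt_ms), n = dplyr::n(),
                     .groups = "drop")
  list(table = tab, means = means)
}
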