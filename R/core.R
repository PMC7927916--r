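#' Build a spike train set
#'
#' Bundles spike event times recorded on multiple channels across trials with
#' the channel-to-area map. Times are in milliseconds relative to trial start
#' (fixation onset). Spikes are sorted within each (trial, channel) on
#' construction so downstream binning is independent of input order.
#'
#' @param spikes A data frame with columns `trial`, `channel`, `time_ms`.
#' @param channels A data frame with columns `channel`, `area`, and optionally
#'   a logical `included` column (channel inclusion mask, e.g. from SNR or
#'   depth criteria; defaults to `TRUE`).
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes, channels) {
  spikes <- tibble::as_tibble(spikes)
  channels <- tibble::as_tibble(channels)
  stopifnot(all(c("trial", "channel", "time_ms") %in% names(spikes)),
            all(c("channel", "area") %in% names(channels)))
  if (anyDuplicated(channels$channel))
    abort("every channel must map to exactly one area")
  if (nrow(spikes) > 0 && any(spikes$time_ms < 0))
    abort("spike times must be non-negative (trial-relative ms)")
  if (nrow(spikes) > 0 && !all(spikes$channel %in% channels$channel))
    abort("spikes reference channels absent from the channel map")
  if (!"included" %in% names(channels)) channels$included <- TRUE
  spikes <- dplyr::arrange(spikes, .data$trial, .data$channel, .data$time_ms)
  structure(list(spikes = spikes, channels = channels),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat("<spike_train_set> ", nrow(x$spikes), " spikes, ",
      length(unique(x$spikes$trial)), " trials, ",
      nrow(x$channels), " channels (",
      paste(unique(x$channels$area), collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Validate a trial event table
#'
#' A trial table is a tibble with one row per trial: `trial`, `condition`
#' (one of `attend_RF`, `attend_away1`, `attend_away2`), event times in
#' trial-relative ms (`t_fixation`, `t_stim_on`, `t_cue_on`, `t_dim1`, and
#' optionally `t_dim2`, `t_dim3`), `target_dim` (which dimming was the
#' target), `rt_ms` (reaction time, `NA` on non-response trials) and
#' `pupil_baseline` (arbitrary units, optional).
#'
#' @param trials A data frame of per-trial events.
#' @return The validated tibble, invisibly usable in pipelines.
#' @export
as_trial_table <- function(trials) {
  trials <- tibble::as_tibble(trials)
  need <- c("trial", "condition", "t_fixation", "t_stim_on", "t_cue_on", "t_dim1")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    abort(paste0("trial table lacks columns: ", paste(miss, collapse = ", ")))
  ev_cols <- intersect(
    c("t_fixation", "t_stim_on", "t_cue_on", "t_dim1", "t_dim2", "t_dim3"),
    names(trials))
  ev <- as.matrix(trials[ev_cols])
  bad <- apply(ev, 1L, function(r) {
    r <- r[!is.na(r)]
    any(diff(r) <= 0)
  })
  if (any(bad))
    abort(paste0("event times not strictly increasing in trials: ",
                 paste(trials$trial[bad], collapse = ", ")))
  trials
}

#' Compute per-trial analysis windows
#'
#' Maps a named task epoch onto per-trial half-open time windows `[start, end)`
#' in trial-relative ms:
#' \describe{
#'   \item{`fixation`}{fixation onset to stimulus onset.}
#'   \item{`cue_to_dim1`}{400 ms after cue onset to 30 ms after the first
#'     dimming event.}
#'   \item{`cue_to_dim2`}{as `cue_to_dim1` but extended to 30 ms after the
#'     second dimming event, for trials that have one.}
#' }
#'
#' @param trials A trial table (see [as_trial_table()]).
#' @param spec Window name.
#' @return A tibble with columns `trial`, `start`, `end`.
#' @export
analysis_window <- function(trials,
                            spec = c("cue_to_dim1", "cue_to_dim2", "fixation")) {
  spec <- match.arg(spec)
  trials <- tibble::as_tibble(trials)
  need_event <- function(col) {
    if (!col %in% names(trials) || anyNA(trials[[col]]))
      abort(paste0("window '", spec, "' requires event '", col,
                   "' for all trials; missing in trials: ",
                   paste(trials$trial[!col %in% names(trials) |
                                        is.na(trials[[col]] %||% NA)],
                         collapse = ", ")))
    trials[[col]]
  }
  w <- switch(spec,
    fixation = tibble::tibble(trial = trials$trial,
                              start = need_event("t_fixation"),
                              end = need_event("t_stim_on")),
    cue_to_dim1 = tibble::tibble(trial = trials$trial,
                                 start = need_event("t_cue_on") + 400,
                                 end = need_event("t_dim1") + 30),
    cue_to_dim2 = {
      if (!"t_dim2" %in% names(trials))
        abort("window 'cue_to_dim2' requires event 't_dim2'")
      keep <- !is.na(trials$t_dim2)
      tibble::tibble(trial = trials$trial[keep],
                     start = trials$t_cue_on[keep] + 400,
                     end = trials$t_dim2[keep] + 30)
    })
  w
}

#' Bin spikes into fixed-width count bins
#'
#' Discretizes spike times into non-overlapping half-open bins
#' `[start + b*w, start + (b+1)*w)` within each trial's analysis window.
#' The number of bins is `floor((end - start) / bin_ms)`; a trailing partial
#' bin is dropped so every bin has equal width. Spikes outside the window
#' (including at or after the last full bin's end) are discarded. Channels
#' flagged `included = FALSE` in the channel map are dropped at binning time.
#'
#' @param spikes A [spike_train_set()].
#' @param window A data frame with columns `trial`, `start`, `end` (ms), e.g.
#'   from [analysis_window()].
#' @param bin_ms Bin width in ms (default 10).
#' @return An object of class `binned_counts`: per-trial integer matrices
#'   (channels x bins) plus window and channel metadata.
#' @export
bin_spikes <- function(spikes, window, bin_ms = 10) {
  stopifnot(inherits(spikes, "spike_train_set"), bin_ms > 0)
  window <- tibble::as_tibble(window)
  stopifnot(all(c("trial", "start", "end") %in% names(window)))
  chans <- dplyr::filter(spikes$channels, .data$included)
  ch_ids <- chans$channel
  n_bins <- floor((window$end - window$start) / bin_ms)
  if (any(n_bins < 1))
    abort(paste0("window shorter than one bin in trials: ",
                 paste(window$trial[n_bins < 1], collapse = ", ")))
  sp <- dplyr::filter(spikes$spikes, .data$channel %in% ch_ids)
  counts <- vector("list", nrow(window))
  names(counts) <- as.character(window$trial)
  for (i in seq_len(nrow(window))) {
    tr <- window$trial[i]
    st <- window$start[i]
    nb <- n_bins[i]
    m <- matrix(0L, nrow = length(ch_ids), ncol = nb,
                dimnames = list(as.character(ch_ids), NULL))
    sp_i <- sp[sp$trial == tr, ]
    if (nrow(sp_i)) {
      b <- floor((sp_i$time_ms - st) / bin_ms)
      ok <- b >= 0 & b < nb
      if (any(ok)) {
        tab <- table(factor(as.character(sp_i$channel[ok]),
                            levels = as.character(ch_ids)),
                     factor(b[ok], levels = 0:(nb - 1)))
        m <- matrix(as.integer(tab), nrow = length(ch_ids),
                    dimnames = list(as.character(ch_ids), NULL))
      }
    }
    counts[[i]] <- m
  }
  new_binned_counts(counts,
                    windows = tibble::tibble(trial = window$trial,
                                             start = window$start,
                                             end = window$end,
                                             n_bins = n_bins),
                    bin_ms = bin_ms, channels = chans)
}

#' Construct binned counts directly from matrices
#'
#' Convenience constructor when counts already exist as matrices (e.g. from
#' a simulation): one channels x bins integer matrix per trial.
#'
#' @param counts List of channels x bins matrices (equal channel counts).
#' @param bin_ms Bin width (ms).
#' @param channels Optional channel map tibble (`channel`, `area`,
#'   `included`); defaults to sequential channels in one area.
#' @param start Per-trial window starts (ms, recycled; default 0).
#' @return A `binned_counts` object.
#' @export
binned_counts <- function(counts, bin_ms = 10, channels = NULL, start = 0) {
  stopifnot(is.list(counts), length(counts) > 0)
  J <- unique(vapply(counts, nrow, 0L))
  if (length(J) != 1) abort("all trials must have the same channel count")
  if (any(unlist(counts) < 0) || any(unlist(counts) != round(unlist(counts))))
    abort("counts must be non-negative integers")
  channels <- channels %||% tibble::tibble(channel = seq_len(J), area = "V1",
                                           included = TRUE)
  if (!"included" %in% names(channels)) channels$included <- TRUE
  nb <- vapply(counts, ncol, 0L)
  start <- rep(start, length.out = length(counts))
  windows <- tibble::tibble(trial = seq_along(counts), start = start,
                            end = start + nb * bin_ms, n_bins = nb)
  names(counts) <- as.character(windows$trial)
  new_binned_counts(counts, windows, bin_ms, tibble::as_tibble(channels))
}

new_binned_counts <- function(counts, windows, bin_ms, channels) {
  structure(list(counts = counts, windows = windows, bin_ms = bin_ms,
                 channels = channels),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat("<binned_counts> ", length(x$counts), " trials x ",
      nrow(x$channels), " channels, ", x$bin_ms, " ms bins (",
      sum(x$windows$n_bins), " bins total)\n", sep = "")
  invisible(x)
}

#' @describeIn bin_spikes Long-format view of binned counts: one row per
#'   (trial, channel, bin) with the bin start time.
#' @param x A `binned_counts` object.
#' @param ... Unused.
#' @export
tidy.binned_counts <- function(x, ...) {
  purrr::map2_dfr(x$counts, seq_along(x$counts), function(m, i) {
    tibble::tibble(
      trial = x$windows$trial[i],
      channel = rep(x$channels$channel, times = ncol(m)),
      area = rep(x$channels$area, times = ncol(m)),
      bin = rep(seq_len(ncol(m)), each = nrow(m)),
      t_ms = x$windows$start[i] + (rep(seq_len(ncol(m)), each = nrow(m)) - 1) *
        x$bin_ms,
      count = as.integer(m))
  })
}

#' Subset binned counts by channel or trial
#'
#' @param counts A `binned_counts` object.
#' @param channels Channel ids to keep (default all).
#' @param trials Trial ids to keep (default all).
#' @return A `binned_counts` with the requested slice.
#' @export
subset_counts <- function(counts, channels = NULL, trials = NULL) {
  stopifnot(inherits(counts, "binned_counts"))
  ch_keep <- if (is.null(channels)) counts$channels$channel else channels
  idx <- match(ch_keep, counts$channels$channel)
  if (anyNA(idx)) abort("unknown channel id in subset")
  tr_keep <- if (is.null(trials)) counts$windows$trial else trials
  ti <- match(tr_keep, counts$windows$trial)
  if (anyNA(ti)) abort("unknown trial id in subset")
  new_binned_counts(
    lapply(counts$counts[ti], function(m) m[idx, , drop = FALSE]),
    windows = counts$windows[ti, ], bin_ms = counts$bin_ms,
    channels = counts$channels[idx, ])
}

#' Assemble a session bundle
#'
#' Container tying together everything recorded or simulated in one session:
#' spike trains, binned counts per analysis window, the trial table, and
#' optional eye traces, LFP arrays and ground truth (for synthetic sessions).
#'
#' @param spikes A [spike_train_set()] or `NULL`.
#' @param trials A trial table.
#' @param counts Named list of [bin_spikes()] results, keyed by window name.
#' @param eye Optional tibble of eye samples (`trial`, `t_ms`, `x`, `y`).
#' @param lfp Optional list with elements `v` (list of channel x sample
#'   matrices per trial), `fs` (Hz), `depth_um` (per channel), `area`.
#' @param ground_truth Optional list (latent paths, event times, generator
#'   parameters) for synthetic sessions.
#' @param meta List of provenance fields (seed, config).
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(spikes = NULL, trials, counts = list(), eye = NULL,
                           lfp = NULL, ground_truth = NULL, meta = list()) {
  trials <- as_trial_table(trials)
  for (nm in names(counts)) {
    cw <- counts[[nm]]$windows$trial
    if (!all(cw %in% trials$trial))
      abort(paste0("counts window '", nm, "' references trials absent from ",
                   "the trial table"))
  }
  structure(list(spikes = spikes, trials = trials, counts = counts, eye = eye,
                 lfp = lfp, ground_truth = ground_truth, meta = meta),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("<session_bundle> ", nrow(x$trials), " trials; windows: ",
      paste(names(x$counts), collapse = ", "), "\n", sep = "")
  if (!is.null(x$ground_truth)) cat("  with ground truth (synthetic)\n")
  invisible(x)
}

#' Write / read a session bundle as a plain-text directory
#'
#' Serializes a bundle to a directory of CSV and JSON files (`spikes.csv`,
#' `channels.csv`, `trials.csv`, `counts_<window>.csv` with matching
#' `windows_<window>.csv`, `eye.csv`, `lfp.csv`, `ground_truth.json`,
#' `meta.json`). The round trip is lossless for integer fields and exact to
#' double precision for floats.
#'
#' @param bundle A [session_bundle()].
#' @param path Directory to create or read.
#' @return `write_bundle` returns `path` invisibly; `read_bundle` a bundle.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, file)
    utils::write.csv(format_df_full(df), file.path(path, file),
                     row.names = FALSE, quote = TRUE)
  if (!is.null(bundle$spikes)) {
    wcsv(bundle$spikes$spikes, "spikes.csv")
    wcsv(bundle$spikes$channels, "channels.csv")
  }
  wcsv(bundle$trials, "trials.csv")
  for (nm in names(bundle$counts)) {
    bc <- bundle$counts[[nm]]
    wcsv(tidy.binned_counts(bc)[c("trial", "channel", "bin", "count")],
         paste0("counts_", nm, ".csv"))
    wcsv(dplyr::mutate(bc$windows, bin_ms = bc$bin_ms),
         paste0("windows_", nm, ".csv"))
    wcsv(bc$channels, paste0("count_channels_", nm, ".csv"))
  }
  if (!is.null(bundle$eye)) wcsv(bundle$eye, "eye.csv")
  if (!is.null(bundle$lfp)) {
    lf <- bundle$lfp
    long <- purrr::imap_dfr(lf$v, function(m, tr) {
      tibble::tibble(trial = as.integer(tr),
                     channel = rep(seq_len(nrow(m)), times = ncol(m)),
                     sample = rep(seq_len(ncol(m)), each = nrow(m)),
                     v = as.double(m))
    })
    wcsv(long, "lfp.csv")
    jsonlite::write_json(list(fs = lf$fs, depth_um = lf$depth_um,
                              area = lf$area),
                         file.path(path, "lfp_meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(bundle$ground_truth))
    jsonlite::write_json(bundle$ground_truth,
                         file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(bundle$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

format_df_full <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  df
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  if (!dir.exists(path)) abort(paste0("no bundle directory at ", path))
  rcsv <- function(file) {
    f <- file.path(path, file)
    if (!file.exists(f)) return(NULL)
    tibble::as_tibble(utils::read.csv(f, stringsAsFactors = FALSE))
  }
  trials <- rcsv("trials.csv")
  if (is.null(trials)) abort("bundle lacks trials.csv (trial table)")
  spikes <- NULL
  sp <- rcsv("spikes.csv")
  ch <- rcsv("channels.csv")
  if (!is.null(sp) && !is.null(ch)) spikes <- spike_train_set(sp, ch)
  counts <- list()
  cfiles <- list.files(path, pattern = "^counts_.*\\.csv$")
  for (cf in cfiles) {
    nm <- sub("^counts_(.*)\\.csv$", "\\1", cf)
    long <- rcsv(cf)
    win <- rcsv(paste0("windows_", nm, ".csv"))
    cch <- rcsv(paste0("count_channels_", nm, ".csv"))
    if (is.null(win) || is.null(cch))
      abort(paste0("bundle counts group '", nm, "' lacks window or channel ",
                   "metadata"))
    cch$included <- as.logical(cch$included)
    mats <- lapply(seq_len(nrow(win)), function(i) {
      li <- long[long$trial == win$trial[i], ]
      m <- matrix(0L, nrow(cch), win$n_bins[i],
                  dimnames = list(as.character(cch$channel), NULL))
      m[cbind(match(as.character(li$channel), as.character(cch$channel)),
              li$bin)] <- as.integer(li$count)
      m
    })
    names(mats) <- as.character(win$trial)
    counts[[nm]] <- new_binned_counts(mats, windows = win[c("trial", "start",
                                                            "end", "n_bins")],
                                      bin_ms = win$bin_ms[1], channels = cch)
  }
  eye <- rcsv("eye.csv")
  lfp <- NULL
  lf <- rcsv("lfp.csv")
  if (!is.null(lf)) {
    lm_ <- jsonlite::read_json(file.path(path, "lfp_meta.json"),
                               simplifyVector = TRUE)
    v <- lapply(split(lf, lf$trial), function(d) {
      matrix(d$v[order(d$sample, d$channel)], nrow = max(d$channel))
    })
    lfp <- list(v = v, fs = lm_$fs, depth_um = lm_$depth_um, area = lm_$area)
  }
  gt <- NULL
  if (file.exists(file.path(path, "ground_truth.json")))
    gt <- jsonlite::read_json(file.path(path, "ground_truth.json"),
                              simplifyVector = TRUE)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  session_bundle(spikes = spikes, trials = trials, counts = counts, eye = eye,
                 lfp = lfp, ground_truth = gt, meta = meta)
}
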