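#' Leave-one-channel-out cross-validation error
#'
#' Trials are split into `n_folds` random folds. For each fold the model is
#' fit on the remaining trials; on every held-out trial and for every held-out
#' channel j, the most likely state path is decoded from all channels except
#' j, and the squared prediction error `sum_t (n_tj - lambda_j[s_t])^2` is
#' accumulated. Errors are summed over folds.
#'
#' @param counts A [bin_spikes()] result.
#' @param K Number of phases.
#' @param n_folds Number of cross-validation folds (default 4).
#' @param seed Seed for the fold partition and EM restarts.
#' @param n_restarts EM restarts per fold fit.
#' @param ... Passed to [em_fit()].
#' @return Tibble with `channel` and `cvvar` (summed squared error).
#' @export
cv_error <- function(counts, K, n_folds = 4, seed = 1, n_restarts = 10, ...) {
  stopifnot(inherits(counts, "binned_counts"))
  trials <- counts$windows$trial
  if (length(trials) < n_folds)
    abort("fewer trials than cross-validation folds")
  folds <- with_substream(seed, "cv_folds",
                          split(sample(trials),
                                rep(seq_len(n_folds),
                                    length.out = length(trials))))
  J <- nrow(counts$channels)
  cvvar <- numeric(J)
  for (f in seq_len(n_folds)) {
    test_tr <- folds[[f]]
    train_tr <- setdiff(trials, test_tr)
    fit <- em_fit(subset_counts(counts, trials = train_tr), K,
                  n_restarts = n_restarts,
                  seed = substream(seed, paste0("cv_fit_", f)), ...)
    test <- subset_counts(counts, trials = test_tr)
    lam <- fit$params$lambda
    for (j in seq_len(J)) {
      if (J > 1) {
        held <- subset_counts(test,
                              channels = counts$channels$channel[-j])
        pj <- hmm_params(fit$params$pi0, fit$params$P,
                         lam[-j, , drop = FALSE], fit$params$bin_ms)
        path <- viterbi(held, pj)
      } else {
        path <- viterbi(test, fit$params)
      }
      for (i in seq_along(test$counts)) {
        s <- path$paths[[i]]
        nj <- test$counts[[i]][j, ]
        cvvar[j] <- cvvar[j] + sum((nj - lam[j, s])^2)
      }
    }
  }
  tibble::tibble(channel = counts$channels$channel, cvvar = cvvar)
}

#' Cross-validation error curve across model orders
#'
#' Runs [cv_error()] for each number of phases `K = 1..k_max` and normalizes
#' the channel-mean error to the 1-phase model, averaging across channels,
#' folds and (optionally) conditions.
#'
#' @param counts A [bin_spikes()] result, or a list of them (one per
#'   condition) whose normalized curves are averaged.
#' @param k_max Largest model order (default 8).
#' @param n_folds,seed,n_restarts,... As in [cv_error()].
#' @return An object of class `cv_report`: list with `curve` (tibble `K`,
#'   `norm_error`; `norm_error[K == 1]` is 1 by construction) and
#'   `per_channel` (tibble `condition`, `channel`, `K`, `cvvar`).
#' @export
cv_sweep <- function(counts, k_max = 8, n_folds = 4, seed = 1,
                     n_restarts = 10, ...) {
  if (inherits(counts, "binned_counts")) counts <- list(all = counts)
  per_channel <- purrr::imap_dfr(counts, function(cc, cond) {
    purrr::map_dfr(seq_len(k_max), function(k) {
      dplyr::mutate(cv_error(cc, k, n_folds = n_folds,
                             seed = substream(seed, paste0(cond, "_k", k)),
                             n_restarts = n_restarts, ...),
                    K = k, condition = cond)
    })
  })
  curve <- per_channel |>
    dplyr::group_by(.data$condition, .data$K) |>
    dplyr::summarise(err = mean(.data$cvvar), .groups = "drop_last") |>
    dplyr::mutate(norm_error = .data$err / .data$err[.data$K == 1]) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$K) |>
    dplyr::summarise(norm_error = mean(.data$norm_error), .groups = "drop")
  structure(list(curve = curve, per_channel = per_channel),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> normalized CV error by K:\n")
  print(x$curve)
  invisible(x)
}

#' Elbow-rule model selection on the CV error curve
#'
#' A recording is classified as two-phase iff the normalized cross-validation
#' error drops by at least `drop_threshold` when adding the second phase, and
#' by less than `drop_threshold` for every further phase. Recordings whose
#' error keeps dropping past K = 2 (a 3- or 4-phase pattern) are flagged
#' excluded.
#'
#' Incremental drops are measured, by default, on the curve normalized to the
#' 1-phase error (differences of consecutive normalized values);
#' `relative_to = "previous"` instead measures each drop relative to the
#' previous model order's error.
#'
#' @param report A [cv_sweep()] result, or a numeric vector of normalized
#'   errors starting at K = 1.
#' @param drop_threshold Minimal meaningful error reduction (default 0.10).
#' @param relative_to `"k1"` (default) or `"previous"`.
#' @return One-row tibble: `selected_k`, `two_phase`, `included`.
#' @export
select_k <- function(report, drop_threshold = 0.10,
                     relative_to = c("k1", "previous")) {
  relative_to <- match.arg(relative_to)
  e <- if (inherits(report, "cv_report")) {
    report$curve$norm_error[order(report$curve$K)]
  } else as.double(report)
  if (length(e) < 2) abort("need errors for at least K = 1 and K = 2")
  if (abs(e[1] - 1) > 1e-9 && !inherits(report, "cv_report"))
    e <- e / e[1]
  drops <- if (relative_to == "k1") -diff(e) else -diff(e) / head(e, -1)
  big <- drops >= drop_threshold
  selected_k <- if (!any(big)) 1L else max(which(big)) + 1L
  two_phase <- isTRUE(big[1]) && !any(big[-1])
  tibble::tibble(selected_k = selected_k, two_phase = two_phase,
                 included = two_phase)
}

#' Fano factor and maximal explainable variance
#'
#' The Fano factor is the spike-count variance over its mean (unbiased
#' variance estimator), computed per channel over all bins at the requested
#' integration window. Under the model's assumptions -- Poisson spiking around
#' a perfectly known two-level rate -- the residual variance cannot fall below
#' the Poisson variance, so the maximal explainable variance is
#' `Rmax^2 = 1 - 1/FF`.
#'
#' @param counts A [bin_spikes()] result, or a numeric vector of Fano
#'   factors.
#' @param window_ms Integration window (ms); must be a multiple of the bin
#'   width. Default: the native bin width.
#' @return Tibble `channel`, `fano`, `rmax2` (or, for numeric input, the
#'   `rmax2` values). Channels with zero mean count give `NA`.
#' @export
rmax2 <- function(counts, window_ms = NULL) {
  if (is.numeric(counts)) return(1 - 1 / counts)
  stopifnot(inherits(counts, "binned_counts"))
  pooled <- pool_bins(counts, window_ms %||% counts$bin_ms)
  X <- do.call(cbind, pooled) # J x total pooled bins
  mu <- rowMeans(X)
  v <- apply(X, 1, var)
  ff <- ifelse(mu > 0, v / mu, NA_real_)
  tibble::tibble(channel = counts$channels$channel, fano = ff,
                 rmax2 = 1 - 1 / ff)
}

# Regroup counts into non-overlapping integration windows of window_ms,
# dropping trailing partial windows.
pool_bins <- function(counts, window_ms) {
  fac <- window_ms / counts$bin_ms
  if (abs(fac - round(fac)) > 1e-9)
    abort("integration window must be a multiple of the bin width")
  fac <- as.integer(round(fac))
  lapply(counts$counts, function(m) {
    nb <- floor(ncol(m) / fac)
    if (nb == 0) return(m[, 0, drop = FALSE])
    grp <- rep(seq_len(nb), each = fac)
    t(rowsum(t(m[, seq_len(nb * fac), drop = FALSE]), grp))
  })
}

#' Cross-validated fraction of variance explained
#'
#' Two-fold cross-validation: the HMM is fit on a random half of the trials
#' and the most likely state sequence is decoded on the held-out half. For
#' each channel, `R^2 = 1 - sum_t (n_t - lambda_{s_t})^2 /
#' sum_t (n_t - mean(n))^2` on the test bins. The timescale sweep pools
#' consecutive bins into integration windows from 50 to 500 ms; the predicted
#' count in a window is the sum of the per-bin rates the model predicts
#' (equivalently the window-mean predicted rate times its length).
#'
#' For single units (`mode = "SU"`), unit On/Off rates are not model
#' parameters: they are estimated as the unit's mean rate during the On and
#' Off phases of the path decoded from the multiunit activity on training
#' trials, and then scored on test trials against the test path (also decoded
#' from the MUA).
#'
#' @param counts Multiunit [bin_spikes()] counts used to fit and decode.
#' @param K Phases (default 2).
#' @param mode `"MUA"` (score the fitted channels) or `"SU"` (score
#'   `unit_counts`).
#' @param unit_counts Single-unit counts aligned to the same bins (SU mode).
#' @param n_folds Folds (default 2).
#' @param windows_ms Integration windows (default 50 to 500 by 50).
#' @param seed,n_restarts,... Fitting controls.
#' @return Tibble `channel`, `window_ms`, `r2`, `fano`, `rmax2` (the last
#'   two computed on the full data at that window). Channels with zero test
#'   variance give `NA`.
#' @export
r2_explained <- function(counts, K = 2, mode = c("MUA", "SU"),
                         unit_counts = NULL, n_folds = 2,
                         windows_ms = seq(50, 500, by = 50), seed = 1,
                         n_restarts = 10, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "binned_counts"))
  if (mode == "SU" && is.null(unit_counts))
    abort("SU mode requires unit_counts")
  score <- if (mode == "MUA") counts else unit_counts
  trials <- counts$windows$trial
  folds <- with_substream(seed, "r2_folds",
                          split(sample(trials),
                                rep(seq_len(n_folds),
                                    length.out = length(trials))))
  J <- nrow(score$channels)
  acc <- list() # per window: list(res = J, tot sums)
  for (w in as.character(windows_ms))
    acc[[w]] <- list(res = numeric(J), obs = vector("list", J))
  for (f in seq_len(n_folds)) {
    test_tr <- folds[[f]]
    train_tr <- setdiff(trials, test_tr)
    fit <- em_fit(subset_counts(counts, trials = train_tr), K,
                  n_restarts = n_restarts,
                  seed = substream(seed, paste0("r2_fit_", f)), ...)
    test_mua <- subset_counts(counts, trials = test_tr)
    test_path <- viterbi(test_mua, fit)
    lam <- if (mode == "MUA") fit$params$lambda else {
      train_path <- viterbi(subset_counts(counts, trials = train_tr), fit)
      su_state_rates(subset_counts(score, trials = train_tr), train_path, K)
    }
    test_score <- subset_counts(score, trials = test_tr)
    for (w in windows_ms) {
      fac <- as.integer(round(w / counts$bin_ms))
      for (i in seq_along(test_score$counts)) {
        m <- test_score$counts[[i]]
        s <- test_path$paths[[i]]
        pred <- lam[, s, drop = FALSE]
        nb <- floor(ncol(m) / fac)
        if (nb == 0) next
        grp <- rep(seq_len(nb), each = fac)
        for (j in seq_len(J)) {
          nobs <- as.double(tapply(m[j, seq_len(nb * fac)], grp, sum))
          npred <- as.double(tapply(pred[j, seq_len(nb * fac)], grp, sum))
          wch <- as.character(w)
          acc[[wch]]$res[j] <- acc[[wch]]$res[j] + sum((nobs - npred)^2)
          acc[[wch]]$obs[[j]] <- c(acc[[wch]]$obs[[j]], nobs)
        }
      }
    }
  }
  out <- purrr::map_dfr(as.character(windows_ms), function(wch) {
    a <- acc[[wch]]
    r2 <- vapply(seq_len(J), function(j) {
      tot <- sum((a$obs[[j]] - mean(a$obs[[j]]))^2)
      if (tot == 0) NA_real_ else 1 - a$res[j] / tot
    }, 0)
    tibble::tibble(channel = score$channels$channel,
                   window_ms = as.double(wch), r2 = r2)
  })
  dplyr::left_join(out,
                   purrr::map_dfr(windows_ms, function(w)
                     dplyr::mutate(rmax2(score, w), window_ms = w)),
                   by = c("channel", "window_ms"))
}

# Mean rate per state for scored units, from counts and a decoded path.
su_state_rates <- function(score, path, K) {
  J <- nrow(score$channels)
  num <- matrix(0, J, K); den <- numeric(K)
  for (i in seq_along(score$counts)) {
    s <- path$paths[[i]]
    for (k in seq_len(K)) {
      sel <- s == k
      if (any(sel)) {
        num[, k] <- num[, k] + rowSums(score$counts[[i]][, sel, drop = FALSE])
        den[k] <- den[k] + sum(sel)
      }
    }
  }
  lam <- num
  for (k in seq_len(K)) lam[, k] <- if (den[k] > 0) num[, k] / den[k] else 0
  lam
}
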