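#' Emission-tying map for the two-area four-state model
#'
#' In the joint model the four states enumerate both areas' phases in the
#' canonical order 1 = V1off-V4off, 2 = V1on-V4off, 3 = V1off-V4on,
#' 4 = V1on-V4on. A channel's emission rate is constrained to be equal across
#' the two states in which its own area is in the same phase: V1 channels are
#' tied across \{1,3\} (Off) and \{2,4\} (On); V4 channels across \{1,2\} and
#' \{3,4\}.
#'
#' @param channels Channel map tibble with `channel` and `area` columns; the
#'   two areas are taken in sorted order (first = "V1"-like, second =
#'   "V4"-like) unless exactly named `V1`/`V4`.
#' @return Integer matrix (channels x 4) of tying group ids (1 = that area's
#'   Off pair, 2 = its On pair).
#' @export
tying_map <- function(channels) {
  areas <- sort(unique(channels$area))
  if (length(areas) != 2)
    abort("tied 4-state model requires channels from exactly 2 areas")
  if (all(c("V1", "V4") %in% areas)) areas <- c("V1", "V4")
  tie <- matrix(0L, nrow(channels), 4)
  for (j in seq_len(nrow(channels))) {
    tie[j, ] <- if (channels$area[j] == areas[1]) c(1L, 2L, 1L, 2L)
                else c(1L, 1L, 2L, 2L)
  }
  rownames(tie) <- as.character(channels$channel)
  tie
}

#' Fit the tied 4-state two-area HMM
#'
#' Same EM procedure as [em_fit()] but with emission rates constrained by the
#' tying map: the M-step pools expected counts and occupancies across tied
#' states, the exact maximizer under the equality constraints, so tied rates
#' are equal to machine precision. Initialization honors the ties (one draw
#' per tied group). After fitting, states are permuted to the canonical
#' order with [canonicalize_states()].
#'
#' @param counts A [bin_spikes()] result whose channels span two areas.
#' @param n_restarts,seed,max_iter,tol_ll,tol_par As in [em_fit()].
#' @return An `hmm_fit` with `K = 4`, canonical state order, and the tying
#'   map stored in `$tying`.
#' @export
em_fit_tied <- function(counts, n_restarts = 10, seed = 1, max_iter = 500,
                        tol_ll = 1e-3, tol_par = 1e-5) {
  stopifnot(inherits(counts, "binned_counts"))
  tie <- tying_map(counts$channels)
  mats <- counts$counts
  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- with_substream(seed, paste0("em_restart_", r),
                           random_init(mats, 4, tie = tie))
    fits[[r]] <- em_engine(mats, 4, init, max_iter, tol_ll, tol_par,
                           tie = tie)
  }
  lls <- vapply(fits, `[[`, 0, "loglik")
  best <- which.max(lls)
  f <- fits[[best]]
  if (!f$converged)
    warn("EM did not meet both termination criteria before max_iter")
  fit <- structure(list(
    params = hmm_params(f$pi0, f$P, f$lambda, counts$bin_ms),
    loglik = f$loglik, loglik_trace = f$trace, restart = best,
    converged = f$converged, n_iter = f$n_iter, restart_logliks = lls,
    n_trials = length(mats), n_bins = sum(counts$windows$n_bins),
    channels = counts$channels, tying = tie), class = "hmm_fit")
  canonicalize_states(fit)
}

#' Map arbitrary EM state labels onto the canonical joint order
#'
#' EM restarts label states arbitrarily. For a tied 4-state fit, each area's
#' "On" phase is identified as its higher-rate tied pair, and states are
#' permuted so that 1 = V1off-V4off, 2 = V1on-V4off, 3 = V1off-V4on,
#' 4 = V1on-V4on. Exactly tied (degenerate) area rates are broken by state
#' index and flagged via the `degenerate` field.
#'
#' @param fit A tied `hmm_fit` with `K = 4`.
#' @return The fit with permuted `params` and a logical `degenerate` flag.
#' @export
canonicalize_states <- function(fit) {
  stopifnot(inherits(fit, "hmm_fit"), fit$params$K == 4)
  areas <- sort(unique(fit$channels$area))
  if (all(c("V1", "V4") %in% areas)) areas <- c("V1", "V4")
  lam <- fit$params$lambda
  lvl <- function(area) colMeans(lam[fit$channels$area == area, , drop = FALSE])
  a1 <- lvl(areas[1]); a2 <- lvl(areas[2])
  on_flag <- function(v) {
    u <- sort(unique(round(v, 12)))
    if (length(u) < 2) return(rep(NA, length(v)))
    v >= max(v) - (max(v) - min(v)) / 2
  }
  on1 <- on_flag(a1); on2 <- on_flag(a2)
  degenerate <- anyNA(on1) || anyNA(on2)
  if (degenerate) {
    warn("degenerate (equal) area rates; canonical order broken by index")
    perm <- seq_len(4)
  } else {
    canon <- 1L + as.integer(on1) + 2L * as.integer(on2)
    if (anyDuplicated(canon)) {
      warn("ambiguous state identities; canonical order broken by index")
      perm <- seq_len(4)
      degenerate <- TRUE
    } else {
      perm <- order(canon) # perm[c] = fitted state playing canonical role c
    }
  }
  p <- fit$params
  fit$params <- hmm_params(p$pi0[perm], p$P[perm, perm, drop = FALSE],
                           p$lambda[, perm, drop = FALSE], p$bin_ms)
  fit$degenerate <- degenerate
  fit
}

#' Which-area-leads scenario contrasts of the joint transition matrix
#'
#' From the both-Off state, is the first area to switch On more likely to be
#' V4 than V1? The contrast `P(1 -> 3) - P(1 -> 2)` is positive when V4
#' leads. Leaving the both-On state, `P(4 -> 2) - P(4 -> 3)` is positive
#' when V4 turns Off first. When an `attend_RF` condition and one or more
#' away conditions are present, their difference (attend RF minus the mean of
#' the away conditions) is reported for both contrasts along with the full
#' 4 x 4 difference matrix.
#'
#' @param fits Named list of canonical 4-state `hmm_fit`s, keyed by
#'   condition.
#' @return List with `by_condition` (tibble: condition, the two contrasts),
#'   `attention` (tibble of attend-RF-minus-away differences, or `NULL`),
#'   and `diff_matrix` (4 x 4, or `NULL`).
#' @export
scenario_contrasts <- function(fits) {
  if (inherits(fits, "hmm_fit")) fits <- list(all = fits)
  by_cond <- purrr::imap_dfr(fits, function(f, cond) {
    P <- f$params$P
    tibble::tibble(condition = cond,
                   v4_leads_from_off = P[1, 3] - P[1, 2],
                   v4_leads_from_on = P[4, 2] - P[4, 3])
  })
  attention <- NULL; diff_matrix <- NULL
  rf <- grep("RF$", names(fits), value = TRUE)
  away <- setdiff(names(fits), rf)
  if (length(rf) == 1 && length(away) >= 1) {
    Prf <- fits[[rf]]$params$P
    Paway <- Reduce(`+`, lapply(fits[away], function(f) f$params$P)) /
      length(away)
    diff_matrix <- Prf - Paway
    r <- by_cond[by_cond$condition == rf, ]
    a <- by_cond[by_cond$condition %in% away, ]
    attention <- tibble::tibble(
      contrast = c("v4_leads_from_off", "v4_leads_from_on"),
      attend_RF = c(r$v4_leads_from_off, r$v4_leads_from_on),
      attend_away = c(mean(a$v4_leads_from_off), mean(a$v4_leads_from_on)),
      difference = c(r$v4_leads_from_off - mean(a$v4_leads_from_off),
                     r$v4_leads_from_on - mean(a$v4_leads_from_on)))
  }
  list(by_condition = by_cond, attention = attention,
       diff_matrix = diff_matrix)
}

#' Fraction of time spent in each latent state
#'
#' Occupancy fractions over all analyzed bins of a decoded path set.
#'
#' @param paths A `state_path` (any K).
#' @return Tibble with `state` and `fraction` (sums to 1).
#' @export
time_in_states <- function(paths) {
  stopifnot(inherits(paths, "state_path"))
  all_states <- unlist(paths$paths, use.names = FALSE)
  if (length(all_states) == 0) abort("empty path set")
  tab <- tabulate(all_states, nbins = paths$K)
  tibble::tibble(state = seq_len(paths$K), fraction = tab / sum(tab))
}

#' Combine two per-area 2-phase decodes into a joint 4-state path
#'
#' Inverse of [marginal_path()]: given trial-matched V1 and V4 On-Off paths,
#' returns the canonical joint state `1 + (V1 on) + 2 (V4 on)`.
#'
#' @param v1,v4 Trial-matched 2-state `state_path` objects.
#' @return A 4-state `state_path`.
#' @export
combine_area_paths <- function(v1, v4) {
  stopifnot(inherits(v1, "state_path"), inherits(v4, "state_path"),
            v1$K == 2, v4$K == 2)
  if (!all(lengths(v1$paths) == lengths(v4$paths)))
    abort("paths must be trial-matched with equal lengths")
  joint <- purrr::map2(v1$paths, v4$paths, function(a, b)
    1L + (a - 1L) + 2L * (b - 1L))
  state_path(joint, v1$windows, v1$bin_ms, 4L)
}

#' Marginalize a joint 4-state path onto one area's 2-phase path
#'
#' @param paths A 4-state `state_path` in canonical order.
#' @param area `"V1"` or `"V4"` (first/second area of the canonical order).
#' @return A 2-state `state_path` (1 = Off, 2 = On for that area).
#' @export
marginal_path <- function(paths, area = c("V1", "V4")) {
  area <- match.arg(area)
  stopifnot(inherits(paths, "state_path"), paths$K == 4)
  map <- if (area == "V1") c(1L, 2L, 1L, 2L) else c(1L, 1L, 2L, 2L)
  state_path(lapply(paths$paths, function(p) map[p]), paths$windows,
             paths$bin_ms, 2L)
}
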