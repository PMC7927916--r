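#' Poisson HMM parameter set
#'
#' @param pi0 Initial-state probabilities (length K, sums to 1).
#' @param P Row-stochastic K x K transition matrix; `P[i, j]` is the
#'   probability of moving from state `i` to state `j` at the next bin.
#' @param lambda Emission-rate matrix (channels x K), expected spike counts
#'   per bin. Convert to spikes/s by multiplying with `1000 / bin_ms`.
#' @param bin_ms Bin width the rates refer to (ms).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(pi0, P, lambda, bin_ms = 10) {
  pi0 <- as.double(pi0)
  P <- as.matrix(P)
  lambda <- as.matrix(lambda)
  K <- length(pi0)
  stopifnot(nrow(P) == K, ncol(P) == K, ncol(lambda) == K)
  if (abs(sum(pi0) - 1) > 1e-9) abort("pi0 must sum to 1")
  if (any(abs(rowSums(P) - 1) > 1e-9))
    abort("every row of the transition matrix must sum to 1")
  if (any(lambda < 0)) abort("emission rates must be non-negative")
  structure(list(pi0 = pi0, P = P, lambda = lambda, K = K, bin_ms = bin_ms),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> K =", x$K, ",", nrow(x$lambda), "channels,",
      x$bin_ms, "ms bins\n")
  invisible(x)
}

#' Poisson log-probability of a spike count
#'
#' `log P(n | lambda) = n log(lambda) - lambda - log(n!)`, with the degenerate
#' convention that a zero rate gives probability 1 to a zero count and
#' probability 0 to any positive count.
#'
#' @param n Non-negative integer count(s).
#' @param lambda Expected count(s) per bin, >= 0.
#' @return Log-probabilities, vectorized over the longer argument.
#' @export
emission_logpmf <- function(n, lambda) {
  if (any(n < 0)) abort("counts must be non-negative")
  if (any(lambda < 0)) abort("rates must be non-negative")
  k <- max(length(n), length(lambda))
  n <- rep_len(n, k)
  lambda <- rep_len(lambda, k)
  ifelse(lambda > 0,
         n * log(pmax(lambda, .Machine$double.xmin)) - lambda -
           lgamma(n + 1),
         ifelse(n == 0, 0, -Inf))
}

# T x K log emission matrix for one trial's J x T count matrix, channels
# conditionally independent given the state. Zero-rate states get -Inf on
# bins where any tied channel spiked.
log_emission_matrix <- function(N, lambda) {
  lsafe <- ifelse(lambda > 0, log(lambda), 0)
  logB <- crossprod(N, lsafe)
  logB <- sweep(logB, 2, colSums(lambda), "-") - colSums(lgamma(N + 1))
  zero <- lambda == 0
  if (any(zero)) {
    for (k in which(colSums(zero) > 0)) {
      bad <- colSums(N[zero[, k], , drop = FALSE]) > 0
      logB[bad, k] <- -Inf
    }
  }
  logB
}

check_counts_params <- function(counts, params) {
  stopifnot(inherits(counts, "binned_counts"), inherits(params, "hmm_params"))
  if (nrow(counts$channels) != nrow(params$lambda))
    abort("channel count of data and emission matrix differ")
}

#' Forward-backward inference
#'
#' Exact log-domain Baum-Welch E-step quantities for each trial: per-bin state
#' posteriors, summed pairwise transition posteriors, and the data
#' log-likelihood.
#'
#' @param counts A [bin_spikes()] result.
#' @param params An [hmm_params()] object.
#' @return List with `posteriors` (per trial, bins x K; rows sum to 1),
#'   `pairwise` (per trial, K x K summed over bin pairs), `loglik_trial`, and
#'   total `loglik`.
#' @export
forward_backward <- function(counts, params) {
  check_counts_params(counts, params)
  logpi <- ifelse(params$pi0 > 0, log(params$pi0), -Inf)
  logP <- ifelse(params$P > 0, log(params$P), -Inf)
  res <- lapply(counts$counts, function(N)
    fb_one_cpp(log_emission_matrix(N, params$lambda), logpi, logP))
  list(posteriors = lapply(res, `[[`, "gamma"),
       pairwise = lapply(res, `[[`, "xi"),
       loglik_trial = vapply(res, `[[`, 0, "loglik"),
       loglik = sum(vapply(res, `[[`, 0, "loglik")))
}

# Shared EM engine. mats: list of J x T count matrices. tie: optional integer
# matrix (J x K) of tying groups; states sharing a group id within a channel
# row are constrained to one emission rate (pooled M-step, the exact
# maximizer under the equality constraints).
em_engine <- function(mats, K, init, max_iter = 500, tol_ll = 1e-3,
                      tol_par = 1e-5, tie = NULL) {
  pi0 <- init$pi0; P <- init$P; lambda <- init$lambda
  N_all <- do.call(cbind, mats)
  J <- nrow(N_all)
  trace <- numeric(0)
  ll_old <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logB <- lapply(mats, function(N) log_emission_matrix(N, lambda))
    r <- fb_all_cpp(logB, ifelse(pi0 > 0, log(pi0), -Inf),
                    ifelse(P > 0, log(P), -Inf))
    ll <- r$loglik
    trace <- c(trace, ll)
    pi0_new <- r$gamma1 / sum(r$gamma1)
    rs <- rowSums(r$xi)
    P_new <- P
    ok <- rs > 0
    P_new[ok, ] <- r$xi[ok, , drop = FALSE] / rs[ok]
    num <- N_all %*% r$gamma        # J x K expected counts per state
    den <- colSums(r$gamma)         # expected occupancy per state
    lambda_new <- lambda
    if (is.null(tie)) {
      nz <- den > 0
      lambda_new[, nz] <- sweep(num[, nz, drop = FALSE], 2, den[nz], "/")
    } else {
      for (j in seq_len(J)) {
        for (g in unique(tie[j, ])) {
          ks <- which(tie[j, ] == g)
          d <- sum(den[ks])
          if (d > 0) lambda_new[j, ks] <- sum(num[j, ks]) / d
        }
      }
    }
    dpar <- max(abs(P_new - P), abs(lambda_new - lambda))
    pi0 <- pi0_new; P <- P_new; lambda <- lambda_new
    if (!is.na(ll_old)) {
      rel <- abs(ll - ll_old) / abs(ll_old)
      if (rel < tol_ll && dpar < tol_par) { converged <- TRUE; break }
    }
    ll_old <- ll
  }
  list(pi0 = pi0, P = P, lambda = lambda, loglik = trace[length(trace)],
       trace = trace, n_iter = length(trace), converged = converged)
}

# Random initialization per the fitting recipe: flat Dirichlet for pi0 and the
# rows of P, emission rates uniform on (0, 2 * channel mean count). A tying
# map makes one draw per tied group.
random_init <- function(mats, K, tie = NULL) {
  J <- nrow(mats[[1]])
  rdirichlet1 <- function(n) { g <- rgamma(n, 1); g / sum(g) }
  pi0 <- rdirichlet1(K)
  P <- t(vapply(seq_len(K), function(i) rdirichlet1(K), numeric(K)))
  mu <- rowMeans(do.call(cbind, mats))
  lambda <- matrix(0, J, K)
  if (is.null(tie)) {
    lambda[] <- runif(J * K, 0, 2 * rep(mu, K))
  } else {
    for (j in seq_len(J)) {
      for (g in unique(tie[j, ])) {
        lambda[j, tie[j, ] == g] <- runif(1, 0, 2 * mu[j])
      }
    }
  }
  list(pi0 = pi0, P = P, lambda = lambda)
}

#' Fit a K-phase Poisson HMM by EM with random restarts
#'
#' Baum-Welch EM on multichannel spike counts, treating trials as independent
#' sequences that share the initial distribution, transition matrix and
#' emission rates. The procedure is restarted `n_restarts` times from random
#' initializations (flat Dirichlet for `pi0` and the rows of `P`; rates
#' uniform on (0, 2 x channel mean)) and the restart with the highest final
#' log-likelihood is kept. EM terminates when the relative log-likelihood
#' change falls below `tol_ll` *and* the maximum absolute change of the
#' transition and emission matrices falls below `tol_par`, or after
#' `max_iter` iterations (then flagged unconverged with a warning).
#'
#' States are relabeled post-fit so that population-mean rate increases with
#' the state index; for K = 2 state 1 is therefore "Off" and state 2 "On".
#'
#' @param counts A [bin_spikes()] result.
#' @param K Number of latent phases (>= 1).
#' @param n_restarts Number of EM restarts (default 10).
#' @param seed Master seed; each restart draws from its own substream.
#' @param max_iter,tol_ll,tol_par Termination controls (defaults 500, 1e-3,
#'   1e-5).
#' @return An object of class `hmm_fit` with elements `params`
#'   ([hmm_params()]), `loglik`, `loglik_trace`, `restart`, `converged`,
#'   `n_iter`, and `restart_logliks`.
#' @export
em_fit <- function(counts, K, n_restarts = 10, seed = 1, max_iter = 500,
                   tol_ll = 1e-3, tol_par = 1e-5) {
  stopifnot(inherits(counts, "binned_counts"), K >= 1)
  if (length(counts$counts) == 0) abort("no trials to fit")
  mats <- counts$counts
  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- with_substream(seed, paste0("em_restart_", r),
                           random_init(mats, K))
    fits[[r]] <- em_engine(mats, K, init, max_iter, tol_ll, tol_par)
  }
  lls <- vapply(fits, `[[`, 0, "loglik")
  best <- which.max(lls)
  f <- fits[[best]]
  if (!f$converged)
    warn("EM did not meet both termination criteria before max_iter")
  ord <- order(colSums(f$lambda))
  fit <- structure(list(
    params = hmm_params(f$pi0[ord], f$P[ord, ord, drop = FALSE],
                        f$lambda[, ord, drop = FALSE], counts$bin_ms),
    loglik = f$loglik, loglik_trace = f$trace, restart = best,
    converged = f$converged, n_iter = f$n_iter, restart_logliks = lls,
    n_trials = length(mats), n_bins = sum(counts$windows$n_bins),
    channels = counts$channels, tying = NULL), class = "hmm_fit")
  fit
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("<hmm_fit> K =", x$params$K, ", logLik =", format(x$loglik),
      ", iterations =", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @describeIn em_fit Emission rates as a tibble (one row per channel and
#'   state, in counts/bin and spikes/s); `type` selects `"rates"`,
#'   `"transitions"` or `"initial"`.
#' @param x An `hmm_fit`.
#' @param type Component to tabulate.
#' @param ... Unused.
#' @export
tidy.hmm_fit <- function(x, type = c("rates", "transitions", "initial"), ...) {
  type <- match.arg(type)
  p <- x$params
  switch(type,
    rates = tibble::tibble(
      channel = rep(x$channels$channel, times = p$K),
      area = rep(x$channels$area, times = p$K),
      state = rep(seq_len(p$K), each = nrow(p$lambda)),
      rate_per_bin = as.double(p$lambda),
      rate_hz = as.double(p$lambda) * 1000 / p$bin_ms),
    transitions = tibble::tibble(
      from = rep(seq_len(p$K), times = p$K),
      to = rep(seq_len(p$K), each = p$K),
      probability = as.double(p$P)),
    initial = tibble::tibble(state = seq_len(p$K), probability = p$pi0))
}

#' @describeIn em_fit One-row model summary.
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble::tibble(K = x$params$K, logLik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, restart = x$restart,
                 n_trials = x$n_trials, n_bins = x$n_bins)
}

#' Viterbi decoding of the most likely latent trajectory
#'
#' Computes, independently per trial, the jointly most probable state
#' sequence under the fitted model. Ties are broken toward the lower state
#' index so the decode is deterministic.
#'
#' @param counts A [bin_spikes()] result.
#' @param params An [hmm_params()] or an `hmm_fit` (its params are used).
#' @return A `state_path` object: per-trial integer state vectors (1-based)
#'   aligned to the count bins, with the window table and bin width attached.
#' @export
viterbi <- function(counts, params) {
  if (inherits(params, "hmm_fit")) params <- params$params
  check_counts_params(counts, params)
  logpi <- ifelse(params$pi0 > 0, log(params$pi0), -Inf)
  logP <- ifelse(params$P > 0, log(params$P), -Inf)
  paths <- lapply(counts$counts, function(N)
    viterbi_one_cpp(log_emission_matrix(N, params$lambda), logpi, logP))
  state_path(paths, counts$windows, counts$bin_ms, params$K)
}

#' Construct a state path container
#'
#' @param paths List of per-trial integer state vectors (1-based).
#' @param windows Tibble `trial`, `start`, `end`, `n_bins`.
#' @param bin_ms Bin width (ms).
#' @param K Number of states.
#' @return A `state_path` object.
#' @export
state_path <- function(paths, windows, bin_ms, K) {
  stopifnot(length(paths) == nrow(windows))
  lens <- lengths(paths)
  if (!all(lens == windows$n_bins))
    abort("path lengths do not match bin counts per trial")
  names(paths) <- as.character(windows$trial)
  structure(list(paths = paths, windows = windows, bin_ms = bin_ms, K = K),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat("<state_path> ", length(x$paths), " trials, K = ", x$K, ", ",
      x$bin_ms, " ms bins\n", sep = "")
  invisible(x)
}

#' @describeIn state_path Long-format view: one row per (trial, bin).
#' @param x A `state_path`.
#' @param ... Unused.
#' @export
tidy.state_path <- function(x, ...) {
  purrr::map2_dfr(x$paths, seq_along(x$paths), function(p, i) {
    tibble::tibble(trial = x$windows$trial[i], bin = seq_along(p),
                   t_ms = x$windows$start[i] + (seq_along(p) - 1) * x$bin_ms,
                   state = as.integer(p))
  })
}

#' Fit the HMM separately per attention condition
#'
#' Splits the session's trials by condition, fits one independent model per
#' condition on the requested analysis window, and decodes each condition's
#' trials with its own parameters. Conditions with fewer than two trials are
#' skipped with a warning.
#'
#' @param bundle A [session_bundle()] whose `counts` contain `window`.
#' @param window Window name present in `bundle$counts`.
#' @param K Number of phases.
#' @param n_restarts,seed,... Passed to [em_fit()].
#' @return Named list (by condition) of lists with elements `fit` and `path`.
#' @export
fit_all <- function(bundle, window = "cue_to_dim1", K = 2, n_restarts = 10,
                    seed = 1, ...) {
  stopifnot(inherits(bundle, "session_bundle"))
  if (!window %in% names(bundle$counts))
    abort(paste0("bundle has no counts for window '", window, "'"))
  counts <- bundle$counts[[window]]
  out <- list()
  for (cond in unique(bundle$trials$condition)) {
    tr <- bundle$trials$trial[bundle$trials$condition == cond]
    tr <- intersect(tr, counts$windows$trial)
    if (length(tr) < 2) {
      warn(paste0("condition '", cond, "' has fewer than 2 trials; skipped"))
      next
    }
    cc <- subset_counts(counts, trials = tr)
    fit <- em_fit(cc, K, n_restarts = n_restarts,
                  seed = substream(seed, cond), ...)
    out[[cond]] <- list(fit = fit, path = viterbi(cc, fit))
  }
  out
}
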