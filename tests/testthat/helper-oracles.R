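# Independent brute-force oracles for HMM inference: exhaustive enumeration
# over all K^T latent paths (feasible for T <= 8).

enum_paths <- function(K, T) {
  as.matrix(expand.grid(rep(list(seq_len(K)), T)))
}

path_logprob <- function(s, N, pi0, P, lambda) {
  lp <- log(pi0[s[1]])
  if (length(s) > 1)
    for (t in 2:length(s)) lp <- lp + log(P[s[t - 1], s[t]])
  for (t in seq_along(s))
    lp <- lp + sum(dpois(N[, t], lambda[, s[t]], log = TRUE))
  lp
}

enum_loglik <- function(N, pi0, P, lambda) {
  S <- enum_paths(ncol(lambda), ncol(N))
  lps <- apply(S, 1, path_logprob, N = N, pi0 = pi0, P = P, lambda = lambda)
  m <- max(lps)
  m + log(sum(exp(lps - m)))
}

enum_viterbi <- function(N, pi0, P, lambda) {
  S <- enum_paths(ncol(lambda), ncol(N))
  lps <- apply(S, 1, path_logprob, N = N, pi0 = pi0, P = P, lambda = lambda)
  as.integer(S[which.max(lps), ])
}

random_hmm_instance <- function(T, K, J, seed) {
  set.seed(seed)
  pi0 <- rgamma(K, 1); pi0 <- pi0 / sum(pi0)
  P <- t(apply(matrix(rgamma(K * K, 1), K), 1, function(r) r / sum(r)))
  lambda <- matrix(runif(J * K, 0.05, 3), J, K)
  N <- matrix(rpois(J * T, 1), J, T)
  list(N = N, pi0 = pi0, P = P, lambda = lambda)
}

# BH step-up by the textbook definition.
bh_bruteforce <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= (seq_len(m) / m) * q)
  rej <- logical(m)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}
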