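# Shared fixtures and independent oracles.

# Fully specified small HMM used across tests (CU-favoring binding state).
toy_hmm <- function() {
  e1 <- rep(0.2 / 56, 64); names(e1) <- triplet_alphabet()
  e1[c("UCU", "CUC", "UUC", "CUU", "UCC", "CCU", "UUU", "CCC")] <- 0.8 / 8
  label_binding_state(hmm_parameters(
    initial = c(0.6, 0.4),
    transition = rbind(c(0.9, 0.1), c(0.2, 0.8)),
    emission = rbind(e1, rep(1 / 64, 64))))
}

uniform_hmm <- function() {
  hmm_parameters(initial = c(0.5, 0.5),
                 transition = matrix(0.5, 2, 2),
                 emission = matrix(1 / 64, 2, 64),
                 binding_state = 1)
}

# Brute-force likelihood: sum over all 2^T state paths.
brute_force_loglik <- function(params, obs) {
  T_ <- length(obs)
  total <- 0
  for (k in 0:(2^T_ - 1)) {
    s <- as.integer(intToBits(k))[1:T_] + 1L
    p <- params$initial[s[1]] * params$emission[s[1], obs[1]]
    if (T_ > 1) for (t in 2:T_)
      p <- p * params$transition[s[t - 1], s[t]] * params$emission[s[t], obs[t]]
    total <- total + p
  }
  log(total)
}

# Brute-force Viterbi: enumerate all paths, return the best log-prob (the
# argmax path may tie; the probability is the invariant quantity).
brute_force_viterbi_logprob <- function(params, obs) {
  T_ <- length(obs)
  best <- -Inf
  for (k in 0:(2^T_ - 1)) {
    s <- as.integer(intToBits(k))[1:T_] + 1L
    lp <- log(params$initial[s[1]]) + log(params$emission[s[1], obs[1]])
    if (T_ > 1) for (t in 2:T_)
      lp <- lp + log(params$transition[s[t - 1], s[t]]) +
        log(params$emission[s[t], obs[t]])
    if (lp > best) best <- lp
  }
  best
}

# Log-probability of a specific decoded path (state names -> indices).
path_logprob <- function(params, obs, path_states) {
  bs <- params$binding_state
  s <- ifelse(path_states == "binding", bs, 3 - bs)
  lp <- log(params$initial[s[1]]) + log(params$emission[s[1], obs[1]])
  if (length(obs) > 1) for (t in 2:length(obs))
    lp <- lp + log(params$transition[s[t - 1], s[t]]) +
      log(params$emission[s[t], obs[t]])
  lp
}

# Concordant-pair AUC oracle (ties count 1/2).
pair_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Planted spec for parameter-recovery runs (token space).
planted_recovery_hmm <- toy_hmm

# match estimated states to planted states, return max emission TV and
# max abs transition error
recovery_errors <- function(fit, planted) {
  tv <- function(p, q) 0.5 * sum(abs(p - q))
  perm_err <- function(pm)
    max(tv(fit$emission[pm[1], ], planted$emission[1, ]),
        tv(fit$emission[pm[2], ], planted$emission[2, ]))
  perms <- list(c(1, 2), c(2, 1))
  errs <- vapply(perms, perm_err, 0)
  pm <- perms[[which.min(errs)]]
  list(emission_tv = min(errs),
       transition_err = max(abs(fit$transition[pm, pm] - planted$transition)))
}
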