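# Two-hidden-state HMM over overlapping nucleotide triplets: the binding
# model at the core of the package. States are indexed 1/2; after training
# the state with the larger emission mass on the 8 pyrimidine-only triplets
# ({C,U}^3) is labelled the binding state.

#' Triplet alphabet
#'
#' The 64 triplets in lexicographic order over A < C < G < U ("AAA" first,
#' "UUU" last). Token indices throughout the package are 1-based positions
#' into this vector.
#'
#' @return character vector of length 64.
#' @export
triplet_alphabet <- function() {
  b <- c("A", "C", "G", "U")
  paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
}

PYRIMIDINE_TRIPLETS <- c("CCC", "CCU", "CUC", "CUU", "UCC", "UCU", "UUC", "UUU")

#' Encode a sequence as overlapping triplet tokens
#'
#' A sequence of length L yields the L-2 overlapping 3-mers, one token per
#' position; token i covers residues i..i+2. Indices are 1..64 into
#' [triplet_alphabet()].
#'
#' @param seq RNA string (length >= 3).
#' @return integer vector of token indices.
#' @export
encode_triplets <- function(seq) {
  seq <- normalize_rna(seq)
  L <- nchar(seq)
  if (L < 3) stopf("too-short error: need length >= 3, got %d", L)
  base_idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], RNA_BASES)
  n <- L - 2L
  as.integer(16L * (base_idx[1:n] - 1L) + 4L * (base_idx[2:(n + 1L)] - 1L) +
               base_idx[3:(n + 2L)])
}

decode_triplets <- function(tokens) triplet_alphabet()[tokens]

#' Construct and validate HMM parameters
#'
#' @param initial length-2 initial state distribution.
#' @param transition 2x2 row-stochastic transition matrix.
#' @param emission 2x64 row-stochastic emission matrix over triplets.
#' @param binding_state index (1 or 2) of the binding state, or NA before
#'   labelling.
#' @return object of class \code{ptb_hmm}.
#' @export
hmm_parameters <- function(initial, transition, emission, binding_state = NA) {
  initial <- as.numeric(initial)
  transition <- matrix(as.numeric(transition), 2, 2)
  emission <- matrix(as.numeric(emission), 2, 64)
  stopifnot(length(initial) == 2)
  check_row <- function(p, what) {
    if (any(p < 0)) stopf("%s has negative probability", what)
    if (abs(sum(p) - 1) > 1e-9) stopf("%s does not sum to 1 (%.3g)", what, sum(p))
  }
  check_row(initial, "initial distribution")
  for (i in 1:2) {
    check_row(transition[i, ], sprintf("transition row %d", i))
    check_row(emission[i, ], sprintf("emission row %d", i))
  }
  if (!is.na(binding_state)) stopifnot(binding_state %in% 1:2)
  colnames(emission) <- triplet_alphabet()
  structure(list(initial = initial, transition = transition,
                 emission = emission, binding_state = binding_state),
            class = "ptb_hmm")
}

#' @export
print.ptb_hmm <- function(x, ...) {
  cat("Two-state triplet HMM\n")
  cat(sprintf("  initial: %.4f %.4f\n", x$initial[1], x$initial[2]))
  cat(sprintf("  transition: [%.4f %.4f; %.4f %.4f]\n",
              x$transition[1, 1], x$transition[1, 2],
              x$transition[2, 1], x$transition[2, 2]))
  bs <- x$binding_state
  cat(sprintf("  binding state: %s\n", if (is.na(bs)) "unlabelled" else bs))
  top <- sort(x$emission[if (is.na(bs)) 1 else bs, ], decreasing = TRUE)[1:5]
  cat("  top emissions (state ", if (is.na(bs)) 1 else bs, "): ",
      paste(sprintf("%s=%.3f", names(top), top), collapse = " "), "\n", sep = "")
  invisible(x)
}

# Forward recursion in log space for a single observation vector.
# Returns list(alpha = T x 2 matrix of log forward variables, loglik).
forward_pass <- function(params, obs) {
  T_ <- length(obs)
  logE <- log(params$emission)
  logA <- log(params$transition)
  alpha <- matrix(NA_real_, T_, 2)
  alpha[1, ] <- log(params$initial) + logE[, obs[1]]
  if (T_ > 1) for (t in 2:T_) {
    for (j in 1:2)
      alpha[t, j] <- logsumexp2(alpha[t - 1, 1] + logA[1, j],
                                alpha[t - 1, 2] + logA[2, j]) + logE[j, obs[t]]
  }
  list(alpha = alpha, loglik = logsumexp(alpha[T_, ]))
}

backward_pass <- function(params, obs) {
  T_ <- length(obs)
  logE <- log(params$emission)
  logA <- log(params$transition)
  beta <- matrix(0, T_, 2)
  if (T_ > 1) for (t in (T_ - 1):1) {
    for (i in 1:2)
      beta[t, i] <- logsumexp2(logA[i, 1] + logE[1, obs[t + 1]] + beta[t + 1, 1],
                               logA[i, 2] + logE[2, obs[t + 1]] + beta[t + 1, 2])
  }
  beta
}

#' Forward log-likelihood of an observation sequence
#'
#' log P(obs | params), computed with log-space recursions so long inputs do
#' not underflow. Natural-log units.
#'
#' @param params a \code{ptb_hmm}.
#' @param obs integer token vector from [encode_triplets()].
#' @return log-probability (scalar).
#' @export
forward_loglik <- function(params, obs) {
  if (length(obs) == 0) stopf("empty observation sequence")
  stopifnot(inherits(params, "ptb_hmm"), all(obs >= 1 & obs <= 64))
  forward_pass(params, obs)$loglik
}

#' Posterior state probabilities (forward-backward)
#'
#' @inheritParams forward_loglik
#' @return T x 2 matrix; rows sum to 1.
#' @export
posterior_state_probs <- function(params, obs) {
  if (length(obs) == 0) stopf("empty observation sequence")
  fw <- forward_pass(params, obs)
  bw <- backward_pass(params, obs)
  g <- fw$alpha + bw - fw$loglik
  exp(g - apply(g, 1, logsumexp))  # row-renormalize residual fp error
}

#' Label the binding state of a trained model
#'
#' The binding state is the state with the larger summed emission mass over
#' the 8 pyrimidine-only triplets. Relabelling changes no likelihood or
#' score. An exact tie picks state 1 with a warning.
#'
#' @param params a \code{ptb_hmm}.
#' @return the model with \code{binding_state} set.
#' @export
label_binding_state <- function(params) {
  pyr <- match(PYRIMIDINE_TRIPLETS, triplet_alphabet())
  mass <- rowSums(params$emission[, pyr, drop = FALSE])
  if (mass[1] == mass[2]) {
    warnf("pyrimidine emission mass tied between states; labelling state 1")
    params$binding_state <- 1L
  } else {
    params$binding_state <- which.max(mass)
  }
  params
}

#' Viterbi decoding
#'
#' Maximum-probability state path; ties at each backtrack step are broken
#' toward the binding state, so output is deterministic.
#'
#' @inheritParams forward_loglik
#' @return character vector over \{"binding", "nonbinding"\} (or
#'   \{"state1","state2"\} for unlabelled models), one per token.
#' @export
viterbi_path <- function(params, obs) {
  if (length(obs) == 0) stopf("empty observation sequence")
  T_ <- length(obs)
  logE <- log(params$emission)
  logA <- log(params$transition)
  bs <- if (is.na(params$binding_state)) 1L else as.integer(params$binding_state)
  delta <- matrix(-Inf, T_, 2)
  psi <- matrix(1L, T_, 2)
  delta[1, ] <- log(params$initial) + logE[, obs[1]]
  if (T_ > 1) for (t in 2:T_) {
    for (j in 1:2) {
      cand <- delta[t - 1, ] + logA[, j]
      # prefer the binding state on exact ties
      best <- if (cand[bs] >= cand[3 - bs]) bs else (3 - bs)
      psi[t, j] <- best
      delta[t, j] <- cand[best] + logE[j, obs[t]]
    }
  }
  states <- integer(T_)
  states[T_] <- if (delta[T_, bs] >= delta[T_, 3 - bs]) bs else (3 - bs)
  if (T_ > 1) for (t in (T_ - 1):1) states[t] <- psi[t + 1, states[t + 1]]
  if (is.na(params$binding_state)) {
    paste0("state", states)
  } else {
    ifelse(states == params$binding_state, "binding", "nonbinding")
  }
}

# --- vectorized forward-backward across sequences of equal length ----------
# obs_mat: N x T integer matrix. Returns per-sequence logliks plus expected
# sufficient statistics (initial counts, transition counts, emission counts).
fb_group <- function(initial, transition, emission, obs_mat) {
  N <- nrow(obs_mat); T_ <- ncol(obs_mat)
  logE <- log(emission); logA <- log(transition); logpi <- log(initial)
  alpha <- array(NA_real_, c(N, 2, T_))
  Eobs1 <- t(logE[, obs_mat[, 1], drop = FALSE])  # N x 2
  alpha[, , 1] <- sweep(Eobs1, 2, logpi, "+")
  if (T_ > 1) for (t in 2:T_) {
    Et <- t(logE[, obs_mat[, t], drop = FALSE])
    for (j in 1:2)
      alpha[, j, t] <- logsumexp2(alpha[, 1, t - 1] + logA[1, j],
                                  alpha[, 2, t - 1] + logA[2, j]) + Et[, j]
  }
  ll <- logsumexp2(alpha[, 1, T_], alpha[, 2, T_])

  beta <- array(0, c(N, 2, T_))
  if (T_ > 1) for (t in (T_ - 1):1) {
    Et1 <- t(logE[, obs_mat[, t + 1], drop = FALSE])
    for (i in 1:2)
      beta[, i, t] <- logsumexp2(logA[i, 1] + Et1[, 1] + beta[, 1, t + 1],
                                 logA[i, 2] + Et1[, 2] + beta[, 2, t + 1])
  }

  init_counts <- c(0, 0)
  trans_counts <- matrix(0, 2, 2)
  emit_counts <- matrix(0, 2, 64)
  for (t in 1:T_) {
    g <- alpha[, , t] + beta[, , t] - ll          # N x 2 log gamma
    gn <- exp(g - logsumexp2(g[, 1], g[, 2]))     # renormalized gamma
    if (t == 1) init_counts <- colSums(gn)
    for (s in 1:2) {
      cnt <- rowsum(gn[, s], group = obs_mat[, t])
      idx <- as.integer(rownames(cnt))
      emit_counts[s, idx] <- emit_counts[s, idx] + cnt[, 1]
    }
    if (t < T_) {
      Et1 <- t(logE[, obs_mat[, t + 1], drop = FALSE])
      for (i in 1:2) for (j in 1:2) {
        lx <- alpha[, i, t] + logA[i, j] + Et1[, j] + beta[, j, t + 1] - ll
        trans_counts[i, j] <- trans_counts[i, j] + sum(exp(lx))
      }
    }
  }
  list(loglik = sum(ll), init = init_counts, trans = trans_counts,
       emit = emit_counts)
}

random_hmm_init <- function() {
  rdir <- function(n) { x <- stats::rexp(n); x / sum(x) }
  hmm_parameters(initial = rdir(2),
                 transition = rbind(rdir(2), rdir(2)),
                 emission = rbind(rdir(64), rdir(64)))
}

#' Train the two-state triplet HMM by Baum-Welch
#'
#' Expectation-maximization over a set of cluster sequences, restarted from
#' several random initializations to avoid local maxima; the restart with the
#' best total log-likelihood wins. Emission counts receive a 1e-6 pseudocount
#' per triplet so no state freezes on an exact zero. Clusters shorter than 3
#' nt are dropped with a message.
#'
#' @param clusters named character vector of RNA sequences, or a list of
#'   pre-encoded integer token vectors.
#' @param n_restarts number of random restarts (default 10).
#' @param seed integer RNG seed; restarts and initializations are
#'   reproducible under it.
#' @param tol relative log-likelihood change convergence threshold.
#' @param max_iter maximum EM iterations per restart.
#' @return a labelled \code{ptb_hmm} with attributes \code{loglik_trace}
#'   (winning restart), \code{loglik} and \code{training} metadata.
#' @export
baum_welch_train <- function(clusters, n_restarts = 10, seed = 1,
                             tol = 1e-6, max_iter = 500) {
  stopifnot(n_restarts >= 1, tol > 0, max_iter >= 1)
  if (is.character(clusters)) {
    lens <- nchar(clusters)
    n_drop <- sum(lens < 3)
    if (n_drop > 0)
      message(sprintf("dropping %d cluster(s) shorter than 3 nt", n_drop))
    clusters <- clusters[lens >= 3]
    if (length(clusters) == 0) stopf("all clusters too short to encode")
    obs_list <- lapply(clusters, encode_triplets)
  } else {
    obs_list <- clusters
    if (length(obs_list) == 0) stopf("no training observations")
  }
  # group by length for vectorized forward-backward
  groups <- split(obs_list, lengths(obs_list))
  obs_mats <- lapply(groups, function(g) do.call(rbind, g))

  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    par <- random_hmm_init()
    trace <- numeric(0)
    prev <- -Inf
    for (it in seq_len(max_iter)) {
      stats_all <- lapply(obs_mats, function(m)
        fb_group(par$initial, par$transition, par$emission, m))
      ll <- sum(vapply(stats_all, `[[`, 0, "loglik"))
      if (!is.finite(ll))
        stopf("numerical error: non-finite likelihood in restart %d", r)
      trace <- c(trace, ll)
      init <- Reduce(`+`, lapply(stats_all, `[[`, "init"))
      trans <- Reduce(`+`, lapply(stats_all, `[[`, "trans"))
      emit <- Reduce(`+`, lapply(stats_all, `[[`, "emit")) + 1e-6
      par <- hmm_parameters(initial = init / sum(init),
                            transition = trans / rowSums(trans),
                            emission = emit / rowSums(emit))
      if (is.finite(prev) && abs(ll - prev) <= tol * abs(prev)) break
      prev <- ll
    }
    if (is.null(best) || trace[length(trace)] > best$ll) {
      best <- list(par = par, ll = trace[length(trace)], trace = trace,
                   restart = r)
    }
  }
  out <- label_binding_state(best$par)
  attr(out, "loglik") <- best$ll
  attr(out, "loglik_trace") <- best$trace
  attr(out, "training") <- list(n_sequences = length(obs_list),
                                n_restarts = n_restarts, seed = seed,
                                tol = tol, max_iter = max_iter,
                                best_restart = best$restart)
  out
}

# --- backgrounds and log-odds ----------------------------------------------

#' Background model for log-odds scoring
#'
#' \code{uniform} assigns every triplet probability 1/64 (the default and the
#' most accurate in practice). \code{mono}/\code{di} score the query against
#' an exact-composition shuffle of itself (see [shuffle_sequence()]).
#' \code{gene_matched} scores against the empirical triplet frequencies of a
#' user-supplied background sequence pool.
#'
#' @param kind one of "uniform", "mono", "di", "gene_matched".
#' @param pool character vector of background sequences (gene_matched only).
#' @param seed RNG seed for the shuffle kinds.
#' @return object of class \code{ptb_background}.
#' @export
background_model <- function(kind = c("uniform", "mono", "di", "gene_matched"),
                             pool = NULL, seed = 1) {
  kind <- match.arg(kind)
  freqs <- NULL
  if (kind == "gene_matched") {
    if (is.null(pool) || length(pool) == 0)
      stopf("gene_matched background needs a sequence pool")
    toks <- unlist(lapply(pool, encode_triplets))
    freqs <- (tabulate(toks, 64) + 1) / (length(toks) + 64)
  }
  structure(list(kind = kind, freqs = freqs, seed = seed),
            class = "ptb_background")
}

background_logprob <- function(background, params, seq, obs) {
  switch(background$kind,
    uniform = length(obs) * log(1 / 64),
    gene_matched = sum(log(background$freqs[obs])),
    mono = ,
    di = {
      shuf <- shuffle_sequence(seq, order = background$kind,
                               seed = background$seed)
      forward_loglik(params, encode_triplets(shuf))
    })
}

#' Log-odds binding score of a sequence
#'
#' \code{log P(seq | HMM) - log P(seq | background)}, in log-base-2 units by
#' default. z-scores downstream are base-invariant.
#'
#' @param params trained \code{ptb_hmm}.
#' @param seq RNA string of length >= 3.
#' @param background a \code{ptb_background} (default uniform).
#' @param log_base base of the reported logarithm.
#' @return raw log-odds score (scalar).
#' @export
log_odds_score <- function(params, seq, background = background_model("uniform"),
                           log_base = 2) {
  if (is.character(background))
    background <- background_model(background)
  obs <- encode_triplets(seq)
  (forward_loglik(params, obs) -
     background_logprob(background, params, seq, obs)) / log(log_base)
}

#' Score many sequences
#'
#' @inheritParams log_odds_score
#' @param seqs character vector of sequences.
#' @return numeric vector of raw scores.
#' @export
log_odds_scores <- function(params, seqs,
                            background = background_model("uniform"),
                            log_base = 2) {
  vapply(seqs, log_odds_score, 0, params = params, background = background,
         log_base = log_base, USE.NAMES = !is.null(names(seqs)))
}

# --- serialization ---------------------------------------------------------

#' Serialize a trained HMM to JSON
#'
#' @param params a \code{ptb_hmm}.
#' @param path output path.
#' @export
write_hmm_json <- function(params, path) {
  doc <- list(alphabet = triplet_alphabet(),
              initial = params$initial,
              transition = params$transition,
              emission = unname(params$emission),
              binding_state = params$binding_state,
              log_base = 2,
              training = attr(params, "training"))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized HMM
#'
#' @param path JSON path written by [write_hmm_json()].
#' @return a \code{ptb_hmm}.
#' @export
read_hmm_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- hmm_parameters(doc$initial, as.matrix(doc$transition),
                        as.matrix(doc$emission),
                        binding_state = doc$binding_state %||% NA)
  attr(par, "training") <- doc$training
  par
}
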