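# Normalization of raw log-odds scores: random-sequence nulls for fixed-length
# probes, length-binned z-scores for genome-scale sequence sets, empirical
# p-values, and the score-vs-affinity correlation.

#' Build an empirical null score distribution from random sequences
#'
#' Scores \code{n} i.i.d. random sequences of the given length under the
#' trained model (uniform background). Defaults mirror the binding-probe
#' protocol: 100,000 sequences of 69 nt, uniform base frequencies. The 69-nt
#' probe length accommodates one 6-nt element for each of the four RRM
#' domains separated by three 15-nt gaps.
#'
#' @param params trained \code{ptb_hmm}.
#' @param length sequence length in nt (>= 3).
#' @param n number of random sequences (>= 2).
#' @param seed RNG seed; reruns are bit-identical.
#' @param base_freqs length-4 base frequency vector (A,C,G,U), summing to 1.
#' @param log_base log base for raw scores.
#' @return object of class \code{ptb_null}: scores, n, mean, sd, length, seed.
#' @export
build_null_distribution <- function(params, length = 69, n = 100000, seed = 1,
                                    base_freqs = rep(0.25, 4), log_base = 2) {
  stopifnot(length >= 3)
  if (n < 2) stopf("need n >= 2 null sequences, got %d", n)
  seqs <- gen_random_sequences(n, length, base_freqs, seed)
  scores <- score_sequences_fast(params, seqs, log_base = log_base)
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0)
    stopf("degenerate null: all %d scores equal (%.6g)", n, scores[1])
  structure(list(scores = scores, n = n, mean = mean(scores), sd = s,
                 length = length, seed = seed, base_freqs = base_freqs,
                 log_base = log_base),
            class = "ptb_null")
}

# Uniform-background log-odds for many equal-length sequences at once,
# sharing one vectorized forward pass (orders of magnitude faster than
# per-sequence scoring for 1e5-sequence nulls).
score_sequences_fast <- function(params, seqs, log_base = 2) {
  lens <- nchar(seqs)
  stopifnot(all(lens >= 3))
  out <- numeric(length(seqs))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    obs_mat <- encode_triplets_mat(seqs[idx])
    ll <- forward_loglik_mat(params, obs_mat)
    out[idx] <- (ll - ncol(obs_mat) * log(1 / 64)) / log(log_base)
  }
  names(out) <- names(seqs)
  out
}

# vectorized token encoding for equal-length sequences: N x (L-2) matrix
encode_triplets_mat <- function(seqs) {
  n <- length(seqs); L <- nchar(seqs[[1]])
  stopifnot(all(nchar(seqs) == L), L >= 3)
  chars <- matrix(unlist(strsplit(unname(seqs), "", fixed = TRUE),
                         use.names = FALSE), nrow = n, byrow = TRUE)
  bi <- matrix(match(chars, RNA_BASES), nrow = n)
  if (anyNA(bi)) stopf("alphabet error: invalid residue in bulk encoding")
  16L * (bi[, 1:(L - 2), drop = FALSE] - 1L) +
    4L * (bi[, 2:(L - 1), drop = FALSE] - 1L) + bi[, 3:L, drop = FALSE]
}

# vectorized forward log-likelihood over an N x T token matrix
forward_loglik_mat <- function(params, obs_mat) {
  logE <- log(params$emission); logA <- log(params$transition)
  a1 <- log(params$initial[1]) + logE[1, obs_mat[, 1]]
  a2 <- log(params$initial[2]) + logE[2, obs_mat[, 1]]
  T_ <- ncol(obs_mat)
  if (T_ > 1) for (t in 2:T_) {
    n1 <- logsumexp2(a1 + logA[1, 1], a2 + logA[2, 1]) + logE[1, obs_mat[, t]]
    n2 <- logsumexp2(a1 + logA[1, 2], a2 + logA[2, 2]) + logE[2, obs_mat[, t]]
    a1 <- n1; a2 <- n2
  }
  logsumexp2(a1, a2)
}

#' @export
print.ptb_null <- function(x, ...) {
  cat(sprintf("Null distribution: n=%d, length=%d nt, mean=%.4f, sd=%.4f\n",
              x$n, x$length, x$mean, x$sd))
  invisible(x)
}

#' z-score a raw score against a null
#'
#' The null mean maps to zero; the z-score is the deviation in null standard
#' deviations. An affine map, so score order is preserved exactly.
#'
#' @param raw raw log-odds score(s).
#' @param null a \code{ptb_null} (or any list with \code{mean} and \code{sd}).
#' @return numeric z-score(s).
#' @export
z_score <- function(raw, null) {
  stopifnot(is.finite(null$sd), null$sd > 0)
  (raw - null$mean) / null$sd
}

#' Empirical p-value of a raw score against a null
#'
#' \code{p = #\{null scores >= raw\} / n} ("equal or greater"; no pseudocount
#' by default, so 500 of 100,000 at-or-above gives exactly 0.005).
#' \code{pseudocount = TRUE} switches to (k+1)/(n+1) for multiple-testing use.
#'
#' @inheritParams z_score
#' @param pseudocount use the (k+1)/(n+1) estimator.
#' @return p in [0, 1].
#' @export
empirical_p_value <- function(raw, null, pseudocount = FALSE) {
  k <- vapply(raw, function(r) sum(null$scores >= r), 0, USE.NAMES = FALSE)
  if (pseudocount) (k + 1) / (null$n + 1) else k / null$n
}

#' Length-bin normalization for genome-scale score sets
#'
#' Exons and flanking introns differ in length and base composition, and raw
#' log-odds grow with length; scores are therefore normalized within region
#' class. Within each class, sequences are sorted by length (ties by input
#' order) and cut into consecutive bins of \code{bin_size} sequences; each
#' sequence's z-score uses its own bin's mean and sd. A final partial bin
#' smaller than \code{merge_below} is merged into its predecessor.
#'
#' @param scored data.frame with columns \code{region_class}, \code{length},
#'   \code{raw} (and optionally an id column, preserved).
#' @param bin_size sequences per bin (default 1000).
#' @param merge_below merge the final partial bin when smaller than this.
#' @return list with \code{scored} (input plus \code{z} and \code{bin}
#'   columns, original row order) and \code{bins} (per-bin stats data.frame),
#'   class \code{ptb_length_bins}.
#' @export
length_bin_normalize <- function(scored, bin_size = 1000, merge_below = 500) {
  stopifnot(all(c("region_class", "length", "raw") %in% names(scored)))
  scored$z <- NA_real_
  scored$bin <- NA_character_
  bins <- list()
  for (cls in unique(scored$region_class)) {
    idx <- which(scored$region_class == cls)
    if (length(idx) < 2)
      stopf("region class '%s' has < 2 sequences", cls)
    ord <- idx[order(scored$length[idx])]   # stable: ties keep input order
    nb <- max(1L, floor(length(ord) / bin_size))
    starts <- (seq_len(nb) - 1L) * bin_size + 1L
    ends <- c(starts[-1] - 1L, length(ord))
    # split off a trailing partial bin only if large enough
    if (length(ord) - nb * bin_size >= merge_below) {
      starts <- c(starts, nb * bin_size + 1L)
      ends <- c(ends[-nb], nb * bin_size, length(ord))
      ends <- ends[seq_along(starts)]
      nb <- nb + 1L
    }
    for (b in seq_len(nb)) {
      members <- ord[starts[b]:ends[b]]
      m <- mean(scored$raw[members]); s <- stats::sd(scored$raw[members])
      if (!is.finite(s) || s == 0)
        stopf("degenerate bin: sd = 0 in bin %d of region class '%s'", b, cls)
      bid <- sprintf("%s.%d", cls, b)
      scored$z[members] <- (scored$raw[members] - m) / s
      scored$bin[members] <- bid
      bins[[bid]] <- data.frame(bin = bid, region_class = cls, n = length(members),
                                min_length = min(scored$length[members]),
                                max_length = max(scored$length[members]),
                                mean = m, sd = s, stringsAsFactors = FALSE)
    }
  }
  structure(list(scored = scored,
                 bins = do.call(rbind, c(bins, list(make.row.names = FALSE)))),
            class = "ptb_length_bins")
}

#' z-score a new sequence against fitted length bins
#'
#' Looks up the bin of a region class whose length range covers the query
#' (nearest bin by length-range midpoint if none covers it) and applies that
#' bin's mean/sd.
#'
#' @param bins a \code{ptb_length_bins}.
#' @param region_class one of the fitted classes.
#' @param length sequence length in nt.
#' @param raw raw score.
#' @return z-score (scalar).
#' @export
bin_z <- function(bins, region_class, length, raw) {
  tab <- bins$bins[bins$bins$region_class == region_class, , drop = FALSE]
  if (nrow(tab) == 0) stopf("no bins for region class '%s'", region_class)
  hit <- which(tab$min_length <= length & length <= tab$max_length)
  b <- if (length(hit) > 0) hit[1] else
    which.min(abs((tab$min_length + tab$max_length) / 2 - length))
  (raw - tab$mean[b]) / tab$sd[b]
}

#' Shuffle a sequence preserving mono- or dinucleotide composition
#'
#' \code{mono}: an exact permutation of the residues. \code{di}: an
#' Altschul-Erickson Euler-path shuffle that preserves the exact
#' dinucleotide multiset (and hence first/last residue). If a di-shuffle is
#' impossible (degenerate short inputs) the input is returned with a warning.
#'
#' @param seq RNA string.
#' @param order "mono" or "di".
#' @param seed RNG seed.
#' @return shuffled sequence (character scalar).
#' @export
shuffle_sequence <- function(seq, order = c("mono", "di"), seed = 1) {
  order <- match.arg(order)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (order == "mono") {
    if (n < 2) stopf("too-short error: mono shuffle needs length >= 2")
    set.seed(seed)
    return(paste(sample(chars), collapse = ""))
  }
  if (n < 3) stopf("too-short error: di shuffle needs length >= 3")
  set.seed(seed)
  # Altschul-Erickson: pick, for every vertex except the terminal one, a
  # random "last exit" edge such that the last-exit edges form a tree into
  # the terminal vertex; then shuffle each vertex's remaining exits and walk.
  verts <- unique(chars)
  edges <- split(chars[-1], chars[-n])            # exits per vertex
  term <- chars[n]
  for (attempt in 1:100) {
    last_exit <- vapply(names(edges), function(v)
      if (v == term && length(edges[[v]]) == 0) NA_character_
      else edges[[v]][sample.int(length(edges[[v]]), 1)], "")
    # check the last-exit edges (excluding the terminal's) form a tree to term
    ok <- TRUE
    for (v in setdiff(verts, term)) {
      cur <- v; seen <- character(0)
      repeat {
        if (cur == term) break
        if (cur %in% seen || is.na(last_exit[cur])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_exit[cur]
      }
      if (!ok) break
    }
    if (ok) {
      pools <- edges
      for (v in setdiff(names(pools), term)) {
        pool <- pools[[v]]
        drop <- match(last_exit[v], pool)
        pool <- pool[-drop]
        pools[[v]] <- c(sample(pool), last_exit[v])
      }
      if (!is.null(pools[[term]]))
        pools[[term]] <- sample(pools[[term]])
      out <- character(n)
      out[1] <- chars[1]
      ptr <- stats::setNames(rep(1L, length(pools)), names(pools))
      for (i in 2:n) {
        v <- out[i - 1]
        out[i] <- pools[[v]][ptr[v]]
        ptr[v] <- ptr[v] + 1L
      }
      if (!anyNA(out)) return(paste(out, collapse = ""))
    }
  }
  warnf("di-shuffle failed; returning input unchanged")
  seq
}

#' Pearson correlation between binding z-scores and measured affinities
#'
#' Affinities (apparent dissociation constants, nM) are measured externally
#' and consumed as input. The plain correlation with Kd is the default; set
#' \code{log_kd = TRUE} to correlate with log(Kd).
#'
#' @param z numeric vector of binding z-scores.
#' @param kd numeric vector of apparent Kd values (> 0), same length.
#' @param log_kd correlate against log(Kd) instead.
#' @return Pearson correlation coefficient.
#' @export
correlate_score_affinity <- function(z, kd, log_kd = FALSE) {
  stopifnot(length(z) == length(kd))
  if (length(z) < 3) stopf("need >= 3 probe records")
  if (any(kd <= 0)) stopf("Kd values must be positive")
  if (stats::sd(z) == 0 || stats::sd(kd) == 0)
    stopf("undefined correlation: constant vector")
  stats::cor(z, if (log_kd) log(kd) else kd)
}
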