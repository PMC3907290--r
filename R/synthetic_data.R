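# Synthetic-data generators with recorded ground truth: every input the
# pipeline consumes can be simulated. All generators are pure functions of
# (spec, seed) and return truth alongside data; no test reads truth back out
# of the data.
#
# Two cluster generators exist on purpose: gen_hmm_observation_clusters emits
# tokens directly from the HMM's generative law (overlapping triplets from a
# real sequence are NOT independent given the state path, so token space is
# the only space where the planted model is exactly the estimand -- it serves
# the Baum-Welch recovery oracle), while gen_planted_tract_sequences plants
# pyrimidine-rich tracts in nucleotide space for end-to-end tests.

#' Random i.i.d. RNA sequences
#'
#' @param n number of sequences.
#' @param length sequence length in nt.
#' @param base_freqs length-4 frequencies (A,C,G,U) summing to 1.
#' @param seed RNG seed; output is bit-reproducible.
#' @return named character vector ("rand1"..).
#' @export
gen_random_sequences <- function(n, length, base_freqs = rep(0.25, 4),
                                 seed = 1) {
  stopifnot(n >= 1, length >= 1)
  if (abs(sum(base_freqs) - 1) > 1e-9)
    stopf("base frequencies must sum to 1 (got %.6f)", sum(base_freqs))
  if (any(base_freqs < 0)) stopf("negative base frequency")
  set.seed(seed)
  draws <- matrix(sample(RNA_BASES, n * length, replace = TRUE,
                         prob = base_freqs), nrow = n)
  seqs <- do.call(paste0, lapply(seq_len(length), function(j) draws[, j]))
  names(seqs) <- paste0("rand", seq_len(n))
  seqs
}

#' Token-space clusters from a planted two-state HMM
#'
#' Samples a state path from the initial/transition distributions and one
#' triplet token per step from the state's emission row: exactly the model's
#' generative law, suitable as a Baum-Welch estimation oracle.
#'
#' @param params planted \code{ptb_hmm}.
#' @param n number of clusters.
#' @param n_tokens tokens per cluster (scalar or length-2 range sampled
#'   uniformly).
#' @param seed RNG seed.
#' @return list(observations = list of integer token vectors,
#'   state_paths = list of integer state vectors).
#' @export
gen_hmm_observation_clusters <- function(params, n, n_tokens = 28, seed = 1) {
  stopifnot(inherits(params, "ptb_hmm"), n >= 1)
  set.seed(seed)
  lens <- if (length(n_tokens) == 2)
    sample(n_tokens[1]:n_tokens[2], n, replace = TRUE) else rep(n_tokens, n)
  obs <- vector("list", n); paths <- vector("list", n)
  for (i in seq_len(n)) {
    T_ <- lens[i]
    s <- integer(T_); o <- integer(T_)
    s[1] <- sample(1:2, 1, prob = params$initial)
    o[1] <- sample(1:64, 1, prob = params$emission[s[1], ])
    if (T_ > 1) for (t in 2:T_) {
      s[t] <- sample(1:2, 1, prob = params$transition[s[t - 1], ])
      o[t] <- sample(1:64, 1, prob = params$emission[s[t], ])
    }
    obs[[i]] <- o; paths[[i]] <- s
  }
  list(observations = obs, state_paths = paths)
}

#' Default pyrimidine-tract composition
#'
#' CU-rich with tolerated interspersed G: the planted analogue of a
#' polypyrimidine binding tract.
#'
#' @param g_fraction fraction of interspersed G.
#' @return length-4 frequency vector (A,C,G,U).
#' @export
tract_composition <- function(g_fraction = 0.10) {
  cu <- 1 - g_fraction - 0.02
  # C and U in equal parts: canonical binding elements are CU repeats
  # (UCU/CUC) with no consistent C/U skew; an asymmetric tract invites the
  # two HMM states to split C-rich from U-rich triplets instead of tract
  # from background (see the methods vignette)
  c(A = 0.02, C = cu * 0.5, G = g_fraction, U = cu * 0.5)
}

#' Nucleotide sequences with planted pyrimidine-rich tracts
#'
#' Each sequence carries one tract of \code{tract_length} nt at a recorded
#' uniform-random position, drawn from \code{tract_freqs} (default CU-rich
#' with 10% interspersed G); the rest is background.
#'
#' @param n number of sequences.
#' @param length sequence length.
#' @param tract_length planted tract length (<= length).
#' @param tract_freqs tract base frequencies (A,C,G,U).
#' @param background_freqs background base frequencies.
#' @param seed RNG seed.
#' @return list(sequences = named character vector, tract_start = 0-based
#'   starts, tract_length).
#' @export
gen_planted_tract_sequences <- function(n, length, tract_length,
                                        tract_freqs = tract_composition(),
                                        background_freqs = rep(0.25, 4),
                                        seed = 1) {
  if (tract_length > length)
    stopf("impossible geometry: tract_length %d > length %d",
          tract_length, length)
  stopifnot(abs(sum(tract_freqs) - 1) < 1e-9,
            abs(sum(background_freqs) - 1) < 1e-9)
  set.seed(seed)
  starts <- sample.int(length - tract_length + 1L, n, replace = TRUE) - 1L
  seqs <- character(n)
  for (i in seq_len(n)) {
    bg <- sample(RNA_BASES, length, replace = TRUE, prob = background_freqs)
    tr <- sample(RNA_BASES, tract_length, replace = TRUE, prob = tract_freqs)
    bg[(starts[i] + 1):(starts[i] + tract_length)] <- tr
    seqs[i] <- paste(bg, collapse = "")
  }
  names(seqs) <- paste0("tract", seq_len(n))
  list(sequences = seqs, tract_start = starts, tract_length = tract_length)
}

#' Labelled exon feature tables from a planted multinomial-logit world
#'
#' Two modes. \code{class_conditional}: features drawn from per-class
#' Gaussians with the stated means (labels fixed by class). \code{generative}:
#' features drawn from a shared Gaussian and labels sampled from the planted
#' multinomial-logit probabilities -- the estimand of coefficient-recovery
#' tests.
#'
#' @param n_per_class counts per class, named or ordered
#'   (non_regulated, repressed, enhanced); a scalar recycles. In generative
#'   mode the total count is used.
#' @param mode "class_conditional" or "generative".
#' @param class_means 3 x p matrix of per-class feature means
#'   (class_conditional mode); rows in REGULATION_CLASSES order.
#' @param sds feature standard deviations (recycled over features).
#' @param beta 2 x (p+1) planted coefficient matrix (generative mode), rows
#'   repressed/enhanced, first column the intercept.
#' @param seed RNG seed.
#' @return list(features = data.frame(exon_id, x1..), labels, truth).
#' @export
gen_exon_dataset <- function(n_per_class = c(69, 68, 37),
                             mode = c("class_conditional", "generative"),
                             class_means = NULL, sds = 1, beta = NULL,
                             seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (mode == "class_conditional") {
    if (is.null(class_means)) {
      # x1 weaker 3'ss and higher regional binding for regulated classes
      class_means <- rbind(non_regulated = c(0, 0, 0, 0),
                           repressed = c(-1, 1.5, 0.8, 0.8),
                           enhanced = c(-1, 0, -0.5, 1.2))
    }
    p <- ncol(class_means)
    n_per_class <- rep(n_per_class, length.out = 3)
    labels <- rep(REGULATION_CLASSES, times = n_per_class)
    X <- do.call(rbind, lapply(1:3, function(k)
      matrix(stats::rnorm(n_per_class[k] * p,
                          mean = rep(class_means[k, ], each = n_per_class[k]),
                          sd = rep(rep(sds, length.out = p),
                                   each = n_per_class[k])),
             ncol = p)))
    truth <- list(mode = mode, class_means = class_means, sds = sds)
  } else {
    if (is.null(beta))
      beta <- rbind(repressed = c(-0.5, -0.8, 1.2, 0.6, 0.5),
                    enhanced = c(-1.0, -0.5, 0.0, -0.4, 0.9))
    p <- ncol(beta) - 1
    n <- sum(rep(n_per_class, length.out = 3))
    X <- matrix(stats::rnorm(n * p), ncol = p)
    P <- mlogit_probs(beta, cbind(1, X))
    u <- stats::runif(n)
    cum <- t(apply(P[, REGULATION_CLASSES], 1, cumsum))
    labels <- REGULATION_CLASSES[1 + (u > cum[, 1]) + (u > cum[, 2])]
    truth <- list(mode = mode, beta = beta)
  }
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  features <- data.frame(exon_id = sprintf("ex%04d", seq_len(nrow(X))), X,
                         stringsAsFactors = FALSE)
  list(features = features, labels = labels, truth = truth)
}

#' Synthetic PSI tables with planted per-class dPSI
#'
#' Control PSI is drawn uniformly from a mid-range; knockdown PSI adds
#' Normal(+mu_repressed, sd) for repressed exons, Normal(-mu_enhanced, sd)
#' for enhanced, Normal(0, sd) for controls, then clips to [0, 100]
#' (clipping counted in the truth record).
#'
#' @param n_per_class exons per class (non_regulated, repressed, enhanced).
#' @param mu_repressed,mu_enhanced planted |dPSI| means, percent.
#' @param sd dPSI noise standard deviation, percent.
#' @param ctrl_range control-PSI sampling range, percent.
#' @param seed RNG seed.
#' @return list(psi = data.frame(exon_id, psi_control, psi_knockdown,
#'   alternative), truth = data.frame(exon_id, class), n_clipped).
#' @export
gen_psi_table <- function(n_per_class = c(69, 68, 37), mu_repressed = 40,
                          mu_enhanced = 40, sd = 2, ctrl_range = c(20, 60),
                          seed = 1) {
  if (sd < 0) stopf("negative noise sd")
  set.seed(seed)
  n_per_class <- rep(n_per_class, length.out = 3)
  cls <- rep(REGULATION_CLASSES, times = n_per_class)
  n <- length(cls)
  ctrl <- stats::runif(n, ctrl_range[1], ctrl_range[2])
  # enhanced exons need headroom to drop; start them higher
  ctrl[cls == "enhanced"] <- stats::runif(sum(cls == "enhanced"),
                                          max(ctrl_range[1], 50),
                                          max(ctrl_range[2], 80))
  shift <- ifelse(cls == "repressed", mu_repressed,
                  ifelse(cls == "enhanced", -mu_enhanced, 0))
  kd_raw <- ctrl + shift + stats::rnorm(n, 0, sd)
  kd <- pmin(100, pmax(0, kd_raw))
  n_clipped <- sum(kd != kd_raw)
  if (n_clipped > 0)
    message(sprintf("PSI clipping applied to %d exon(s)", n_clipped))
  ids <- sprintf("ex%04d", seq_len(n))
  list(psi = data.frame(exon_id = ids, psi_control = ctrl,
                        psi_knockdown = kd, alternative = TRUE,
                        stringsAsFactors = FALSE),
       truth = data.frame(exon_id = ids, class = cls,
                          stringsAsFactors = FALSE),
       n_clipped = n_clipped)
}

#' Synthetic genome of cassette exons with planted regulatory signal
#'
#' Builds one chromosome per exon: 600 nt of upstream intron, an exon
#' (default 120 nt), and 400 nt of downstream intron, on the + strand.
#' "Repressed" exons get a CU-rich tract spanning most of the 250-nt
#' upstream window plus a weak (pyrimidine-poor) 3' splice-site tail;
#' "neutral" exons get background sequence with a conventional strong
#' polypyrimidine 3'ss tail. Truth labels are returned.
#'
#' @param n_repressed,n_neutral,n_enhanced exon counts per class.
#' @param exon_length exon length in nt.
#' @param seed RNG seed.
#' @return list(genome = named chromosome vector, exons = interval
#'   data.frame, truth = data.frame(exon_id, class, planted)).
#' @export
gen_regulated_exon_genome <- function(n_repressed = 100, n_neutral = 100,
                                      n_enhanced = 0, exon_length = 120,
                                      seed = 1) {
  set.seed(seed)
  cls <- rep(c("repressed", "neutral", "enhanced"),
             c(n_repressed, n_neutral, n_enhanced))
  n <- length(cls)
  up_len <- 600L; dn_len <- 400L
  genome <- character(n); chroms <- paste0("chr", seq_len(n))
  draw <- function(k, freqs) paste(sample(RNA_BASES, k, replace = TRUE,
                                          prob = freqs), collapse = "")
  bg <- rep(0.25, 4)
  strong_tail <- function() paste0(draw(12, c(0.02, 0.43, 0.05, 0.50)), "AG")
  weak_tail <- function() paste0(draw(12, c(0.40, 0.10, 0.40, 0.10)), "AG")
  for (i in seq_len(n)) {
    up <- draw(up_len, bg)
    if (cls[i] == "repressed") {
      tract <- draw(200, tract_composition())
      # tract occupies most of the 250-nt upstream window, ending 20 nt
      # before the 3'ss so the (weak) splice-site tail stays distinct
      substr(up, up_len - 220 + 1, up_len - 20) <- tract
      substr(up, up_len - 13, up_len) <- weak_tail()
    } else if (cls[i] == "enhanced") {
      substr(up, up_len - 13, up_len) <- weak_tail()
    } else {
      substr(up, up_len - 13, up_len) <- strong_tail()
    }
    ex <- draw(exon_length, bg)
    dn <- draw(dn_len, bg)
    if (cls[i] %in% c("repressed", "enhanced")) {
      dtr <- draw(60, tract_composition())
      substr(dn, 11, 70) <- dtr
    }
    genome[i] <- paste0(up, ex, dn)
  }
  names(genome) <- chroms
  exons <- genomic_intervals(chroms, up_len, up_len + exon_length,
                             sprintf("ex%04d", seq_len(n)), "+")
  list(genome = genome, exons = exons,
       truth = data.frame(exon_id = exons$name, class = cls,
                          planted = cls == "repressed",
                          stringsAsFactors = FALSE))
}
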