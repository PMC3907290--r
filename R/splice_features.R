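# Splice-site strength from position-weight matrices (min-max-scaled
# Shapiro-Senapathy-style scoring) and assembly of the four-feature vector
# x1..x4 used by the regulation model:
#   x1 = 3' splice-site strength
#   x2 = upstream-intron (250 nt) binding z-score
#   x3 = exon binding z-score
#   x4 = downstream-intron (100 nt) binding z-score

# Default splice-site windows (offsets relative to the junction):
# 3'ss: last 14 intronic bases + first exonic base; 5'ss: last 3 exonic +
# first 6 intronic. Conventional windows; configurable at matrix build time.
SS_WINDOWS <- list(`3ss` = list(intron = 14L, exon = 1L),
                   `5ss` = list(exon = 3L, intron = 6L))

#' Build a splice-site position-weight matrix from observed junctions
#'
#' Per-position nucleotide frequencies over a set of aligned junction
#' sequences, with a pseudocount so every frequency is positive.
#'
#' @param junction_seqs character vector of equal-length junction windows
#'   (RNA alphabet), e.g. 15-nt 3'ss windows.
#' @param site_kind "3ss" or "5ss" (metadata only).
#' @param pseudocount added per base per position before normalization.
#' @return object of class \code{ptb_ss_matrix}: positions x 4 frequency
#'   matrix (columns A,C,G,U) plus metadata.
#' @export
build_splice_site_matrix <- function(junction_seqs, site_kind = c("3ss", "5ss"),
                                     pseudocount = 0.5) {
  site_kind <- match.arg(site_kind)
  junction_seqs <- normalize_rna(junction_seqs)
  w <- unique(nchar(junction_seqs))
  if (length(w) != 1) stopf("junction sequences must share one length")
  chars <- do.call(rbind, strsplit(junction_seqs, "", fixed = TRUE))
  freq <- t(apply(chars, 2, function(col) {
    cnt <- table(factor(col, levels = RNA_BASES)) + pseudocount
    as.numeric(cnt / sum(cnt))
  }))
  colnames(freq) <- RNA_BASES
  structure(list(freq = freq, site_kind = site_kind, width = w,
                 n_junctions = length(junction_seqs)),
            class = "ptb_ss_matrix")
}

#' Write / read a splice-site matrix as TSV
#'
#' Columns: position (1-based within the window), A, C, G, U.
#' @param matrix a \code{ptb_ss_matrix}.
#' @param path file path.
#' @export
write_splice_site_matrix <- function(matrix, path) {
  df <- data.frame(position = seq_len(matrix$width), matrix$freq,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_splice_site_matrix
#' @param site_kind site kind recorded on read.
#' @export
read_splice_site_matrix <- function(path, site_kind = "3ss") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  freq <- as.matrix(df[, RNA_BASES])
  freq <- freq / rowSums(freq)
  # re-apply a floor so every frequency is positive
  freq <- pmax(freq, 1e-9); freq <- freq / rowSums(freq)
  structure(list(freq = freq, site_kind = site_kind, width = nrow(freq),
                 n_junctions = NA), class = "ptb_ss_matrix")
}

#' Score a junction sequence against a splice-site matrix
#'
#' The min-max-scaled weight-matrix score
#' \code{100 * (S - S_min) / (S_max - S_min)} with
#' \code{S = sum of per-position frequencies of the observed bases}: the
#' per-position consensus scores 100, the worst possible sequence 0.
#'
#' @param seq junction window (length = matrix width).
#' @param matrix a \code{ptb_ss_matrix}.
#' @return strength in [0, 100].
#' @export
score_splice_site <- function(seq, matrix) {
  seq <- normalize_rna(seq)
  if (nchar(seq) != matrix$width)
    stopf("junction sequence length %d does not match matrix width %d",
          nchar(seq), matrix$width)
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], RNA_BASES)
  S <- sum(matrix$freq[cbind(seq_len(matrix$width), idx)])
  smin <- sum(apply(matrix$freq, 1, min))
  smax <- sum(apply(matrix$freq, 1, max))
  100 * (S - smin) / (smax - smin)
}

#' Define the regulatory regions flanking an exon
#'
#' The 250 nt of intron upstream of the exon's 3' splice site, the exon
#' itself, and the first 100 nt of intron downstream of its 5' splice site,
#' strand-aware (upstream means upstream in the transcript). Regions are
#' clipped at chromosome edges with truncation flags.
#'
#' @param exon one-row interval data.frame.
#' @param chrom_length chromosome length in nt.
#' @param upstream_nt,downstream_nt region extents.
#' @return list with interval data.frames \code{upstream_intron},
#'   \code{exon}, \code{downstream_intron} and logical \code{truncated} per
#'   region.
#' @export
define_regulatory_regions <- function(exon, chrom_length,
                                      upstream_nt = 250, downstream_nt = 100) {
  stopifnot(nrow(exon) == 1)
  if (exon$start < 0 || exon$end > chrom_length)
    stopf("exon outside chromosome bounds")
  clip <- function(s, e) {
    cs <- max(0, s); ce <- min(chrom_length, e)
    list(start = cs, end = ce, truncated = (cs != s || ce != e))
  }
  if (exon$strand == "+") {
    up <- clip(exon$start - upstream_nt, exon$start)
    dn <- clip(exon$end, exon$end + downstream_nt)
  } else {
    up <- clip(exon$end, exon$end + upstream_nt)
    dn <- clip(exon$start - downstream_nt, exon$start)
  }
  mk <- function(r, suffix) genomic_intervals(exon$chrom, r$start, r$end,
                                              paste0(exon$name, suffix),
                                              exon$strand)
  list(upstream_intron = mk(up, ".up"), exon = exon[, names(exon) != "score"],
       downstream_intron = mk(dn, ".dn"),
       truncated = c(upstream_intron = up$truncated, exon = FALSE,
                     downstream_intron = dn$truncated))
}

# 3'ss junction window of an exon: last `intron_nt` intronic + first
# `exon_nt` exonic bases, in transcript orientation.
extract_3ss_window <- function(exon, genome, intron_nt = 14, exon_nt = 1) {
  L <- nchar(genome[[exon$chrom]])
  if (exon$strand == "+") {
    region <- genomic_intervals(exon$chrom, max(0, exon$start - intron_nt),
                                min(L, exon$start + exon_nt),
                                paste0(exon$name, ".3ss"), "+")
  } else {
    region <- genomic_intervals(exon$chrom, max(0, exon$end - exon_nt),
                                min(L, exon$end + intron_nt),
                                paste0(exon$name, ".3ss"), "-")
  }
  extract_region_sequence(genome, region)
}

#' Compute the four-feature vector of an exon
#'
#' x1 is the 3' splice-site strength; x2..x4 are length-bin z-scores of the
#' upstream-intron, exon and downstream-intron raw binding scores. When
#' \code{ref_stats} (per-feature mean/sd from a reference internal-exon
#' population) is supplied, features are standardized against it.
#'
#' @param exon one-row interval data.frame.
#' @param genome named character vector of chromosome sequences.
#' @param hmm trained \code{ptb_hmm}.
#' @param bins \code{ptb_length_bins} fitted on a reference sequence set.
#' @param ss_matrix 3'ss \code{ptb_ss_matrix}.
#' @param ref_stats optional data.frame(feature, mean, sd).
#' @return one-row data.frame exon_id, x1..x4, truncated flag.
#' @export
compute_exon_features <- function(exon, genome, hmm, bins, ss_matrix,
                                  ref_stats = NULL) {
  if (!exon$chrom %in% names(genome))
    stopf("lookup error: unknown chrom '%s'", exon$chrom)
  regs <- define_regulatory_regions(exon, nchar(genome[[exon$chrom]]))
  seqs <- lapply(regs[c("upstream_intron", "exon", "downstream_intron")],
                 function(r) extract_region_sequence(genome, r))
  truncated <- any(regs$truncated) ||
    any(vapply(seqs, function(s) isTRUE(attr(s, "truncated")), TRUE))
  x1 <- score_splice_site(
    extract_3ss_window(exon, genome,
                       intron_nt = SS_WINDOWS$`3ss`$intron,
                       exon_nt = SS_WINDOWS$`3ss`$exon), ss_matrix)
  cls <- c("upstream_intron", "exon", "downstream_intron")
  zs <- vapply(seq_along(cls), function(i) {
    s <- as.character(seqs[[i]])
    raw <- log_odds_score(hmm, s)
    bin_z(bins, cls[i], nchar(s), raw)
  }, 0)
  out <- data.frame(exon_id = exon$name, x1 = x1, x2 = zs[1], x3 = zs[2],
                    x4 = zs[3], truncated = truncated,
                    stringsAsFactors = FALSE)
  if (!is.null(ref_stats)) out <- standardize_features(out, ref_stats)
  out
}

#' Standardize feature columns against reference statistics
#'
#' @param features data.frame with x1..x4 columns.
#' @param ref_stats data.frame(feature, mean, sd).
#' @return features with standardized columns and attribute
#'   \code{standardized = TRUE}.
#' @export
standardize_features <- function(features, ref_stats) {
  for (i in seq_len(nrow(ref_stats))) {
    f <- ref_stats$feature[i]
    if (f %in% names(features))
      features[[f]] <- (features[[f]] - ref_stats$mean[i]) / ref_stats$sd[i]
  }
  attr(features, "standardized") <- TRUE
  features
}

#' Reference feature statistics from a population feature table
#'
#' @param features data.frame with x1..x4 columns (a reference internal-exon
#'   population).
#' @return data.frame(feature, mean, sd).
#' @export
reference_feature_stats <- function(features) {
  cols <- intersect(c("x1", "x2", "x3", "x4"), names(features))
  data.frame(feature = cols,
             mean = vapply(cols, function(c) mean(features[[c]]), 0),
             sd = vapply(cols, function(c) stats::sd(features[[c]]), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Feature table for a set of exons
#'
#' Scores all three regulatory regions of every exon, fits length bins on
#' this population (the reference internal-exon set), computes x1..x4 per
#' exon and optionally standardizes against the population itself.
#'
#' @param exons interval data.frame of exons.
#' @param genome named character vector of chromosome sequences.
#' @param hmm trained \code{ptb_hmm}.
#' @param ss_matrix 3'ss matrix.
#' @param bin_size length-bin size (see [length_bin_normalize()]); small
#'   populations use a single bin per region class.
#' @param standardize standardize x1..x4 against this population.
#' @return list(features, bins, ref_stats).
#' @export
build_exon_feature_table <- function(exons, genome, hmm, ss_matrix,
                                     bin_size = 1000, standardize = TRUE) {
  stopifnot(nrow(exons) >= 2)
  cls <- c("upstream_intron", "exon", "downstream_intron")
  rows <- list(); x1 <- numeric(nrow(exons)); trunc <- logical(nrow(exons))
  region_seq <- vector("list", nrow(exons))
  for (i in seq_len(nrow(exons))) {
    exon <- exons[i, , drop = FALSE]
    regs <- define_regulatory_regions(exon, nchar(genome[[exon$chrom]]))
    seqs <- lapply(regs[cls], function(r) extract_region_sequence(genome, r))
    region_seq[[i]] <- vapply(seqs, as.character, "")
    trunc[i] <- any(regs$truncated)
    x1[i] <- score_splice_site(
      extract_3ss_window(exon, genome, SS_WINDOWS$`3ss`$intron,
                         SS_WINDOWS$`3ss`$exon), ss_matrix)
  }
  scored <- do.call(rbind, lapply(seq_len(nrow(exons)), function(i)
    data.frame(exon_id = exons$name[i], region_class = cls,
               length = nchar(region_seq[[i]]),
               raw = log_odds_scores(hmm, unname(region_seq[[i]])),
               stringsAsFactors = FALSE)))
  bins <- length_bin_normalize(scored, bin_size = bin_size)
  z <- bins$scored
  get_z <- function(id, cl) z$z[z$exon_id == id & z$region_class == cl]
  feats <- data.frame(exon_id = exons$name,
                      x1 = x1,
                      x2 = vapply(exons$name, get_z, 0, "upstream_intron"),
                      x3 = vapply(exons$name, get_z, 0, "exon"),
                      x4 = vapply(exons$name, get_z, 0, "downstream_intron"),
                      truncated = trunc, row.names = NULL,
                      stringsAsFactors = FALSE)
  ref <- reference_feature_stats(feats)
  if (standardize) feats <- standardize_features(feats, ref)
  list(features = feats, bins = bins, ref_stats = ref)
}
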