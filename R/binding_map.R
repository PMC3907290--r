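# From Viterbi state paths to per-base binding tracks, sliding-window density
# profiles, group-averaged RNA maps, per-exon heatmaps and crosslink-anchored
# state-frequency profiles.

#' Per-base binding labels from a triplet state path
#'
#' A path over L-2 overlapping triplets is spread onto L bases: base i takes
#' the state of the triplet starting at i; the final two bases inherit the
#' last token's state.
#'
#' @param path character vector over \{"binding","nonbinding"\} (length L-2).
#' @param seq_length L, the source sequence length.
#' @return logical vector of length L; TRUE = binding.
#' @export
per_base_state_labels <- function(path, seq_length) {
  if (seq_length < 3) stopf("sequence too short for any triplet token")
  if (length(path) != seq_length - 2)
    stopf("length mismatch: path has %d tokens, expected %d",
          length(path), seq_length - 2)
  lab <- c(path, path[length(path)], path[length(path)]) == "binding"
  lab
}

#' Sliding-window binding density
#'
#' Windows of \code{window} nt advance by \code{window - overlap} nt
#' (defaults 24 and 8, i.e. a 16-nt step); only full windows are emitted.
#' Density is the fraction of binding-labelled bases in the window.
#'
#' @param track logical per-base track from [per_base_state_labels()].
#' @param window window size in nt.
#' @param overlap overlap between adjacent windows in nt.
#' @return data.frame(window_start, density); window_start is 0-based. A
#'   track shorter than one window yields an empty profile with a warning.
#' @export
window_density <- function(track, window = 24, overlap = 8) {
  stopifnot(window > overlap, overlap >= 0)
  step <- window - overlap
  L <- length(track)
  if (L < window) {
    warnf("track (%d nt) shorter than window (%d nt); empty profile", L, window)
    return(data.frame(window_start = integer(0), density = numeric(0)))
  }
  starts <- seq(0L, L - window, by = step)
  cs <- c(0, cumsum(track))
  density <- (cs[starts + window + 1] - cs[starts + 1]) / window
  data.frame(window_start = as.integer(starts), density = density)
}

#' Group-averaged RNA map around a set of exons
#'
#' Averages sliding-window binding densities across exons, anchored at the
#' splice sites: upstream-intron windows are right-aligned to the 3' splice
#' site (positions counted back from the exon), downstream-intron windows
#' left-aligned to the 5' splice site, and exons of variable length
#' contribute a fixed number of windows anchored at each exon end (no length
#' scaling). Windows absent in shorter sequences are dropped from that
#' window's denominator, which is always reported.
#'
#' @param exon_tracks list; each element a list with logical tracks
#'   \code{upstream}, \code{exon}, \code{downstream}.
#' @param window,overlap window geometry (see [window_density()]).
#' @param exon_windows_each_end number of exon-anchored windows kept from
#'   each exon end.
#' @return data.frame(region, offset, mean_density, n): offset is the window
#'   start relative to the anchoring splice site (negative = upstream of it).
#' @export
group_average_map <- function(exon_tracks, window = 24, overlap = 8,
                              exon_windows_each_end = 2) {
  if (length(exon_tracks) == 0) stopf("empty exon group")
  step <- window - overlap
  acc <- new.env(parent = emptyenv())
  add <- function(region, offset, d) {
    key <- sprintf("%s|%d", region, offset)
    prev <- acc[[key]] %||% c(0, 0)
    acc[[key]] <- prev + c(d, 1)
  }
  for (ex in exon_tracks) {
    up <- ex$upstream; e <- ex$exon; dn <- ex$downstream
    if (!is.null(up) && length(up) >= window) {
      # right-align: windows counted back from the 3' splice site
      Lu <- length(up)
      prof <- suppressWarnings(window_density(rev(up), window, overlap))
      for (i in seq_len(nrow(prof)))
        add("upstream_intron", -(prof$window_start[i] + window), prof$density[i])
    }
    if (!is.null(e) && length(e) >= window) {
      prof <- suppressWarnings(window_density(e, window, overlap))
      k <- min(exon_windows_each_end, nrow(prof))
      for (i in seq_len(k))
        add("exon_start", prof$window_start[i], prof$density[i])
      rprof <- suppressWarnings(window_density(rev(e), window, overlap))
      for (i in seq_len(min(exon_windows_each_end, nrow(rprof))))
        add("exon_end", -(rprof$window_start[i] + window), rprof$density[i])
    }
    if (!is.null(dn) && length(dn) >= window) {
      prof <- suppressWarnings(window_density(dn, window, overlap))
      for (i in seq_len(nrow(prof)))
        add("downstream_intron", prof$window_start[i], prof$density[i])
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0) stopf("no track long enough for a single window")
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(region = vapply(parts, `[`, "", 1),
                    offset = as.integer(vapply(parts, `[`, "", 2)),
                    mean_density = vapply(keys, function(k) acc[[k]][1] / acc[[k]][2], 0),
                    n = vapply(keys, function(k) acc[[k]][2], 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$region, out$offset), ]
}

#' Per-exon binding-score heatmap matrix with clustering order
#'
#' Rows (exons) are ordered by hierarchical clustering of their score
#' profiles (Euclidean distance, average linkage). Plotting is left to the
#' caller (e.g. \code{pheatmap} on \code{$matrix[$order, ]}).
#'
#' @param mat numeric matrix, one row per exon (rownames = exon ids),
#'   columns e.g. upstream/exon/downstream z-scores or windowed scores.
#' @return list(matrix, order, hclust) of class \code{ptb_heatmap}.
#' @export
region_heatmap <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stopf("need >= 2 exons to cluster")
  if (any(!is.finite(mat))) stopf("non-finite cell in heatmap matrix")
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "average")
  structure(list(matrix = mat, order = hc$order, hclust = hc),
            class = "ptb_heatmap")
}

#' Binding-state frequency profile around anchor positions
#'
#' For each offset in [-half_width, +half_width], the fraction of tracks
#' whose base at (anchor + offset) is binding-labelled. Offsets falling
#' outside a track are excluded from that offset's denominator; denominators
#' are reported.
#'
#' @param tracks list of logical per-base tracks.
#' @param anchors integer vector, one 0-based anchor position per track.
#' @param half_width profile half-width in nt.
#' @return data.frame(offset, frequency, n).
#' @export
anchor_state_frequency <- function(tracks, anchors, half_width = 30) {
  if (length(tracks) == 0 || length(anchors) == 0) stopf("no anchors given")
  stopifnot(length(tracks) == length(anchors), half_width >= 0)
  offsets <- (-half_width):half_width
  hits <- numeric(length(offsets)); n <- numeric(length(offsets))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    if (anchors[i] < 0 || anchors[i] >= length(tr))
      stopf("anchor %d outside track %d", anchors[i], i)
    pos <- anchors[i] + offsets          # 0-based
    ok <- pos >= 0 & pos < length(tr)
    n[ok] <- n[ok] + 1
    hits[ok] <- hits[ok] + tr[pos[ok] + 1]
  }
  if (any(n == 0))
    warnf("%d offset(s) have empty denominators", sum(n == 0))
  data.frame(offset = offsets, frequency = ifelse(n > 0, hits / n, NA_real_),
             n = n)
}

#' Export a per-base binding track as BED intervals of binding runs
#'
#' @param track logical per-base track.
#' @param chrom chromosome name.
#' @param chrom_start 0-based start of the track on the chromosome.
#' @param name_prefix run name prefix.
#' @return interval data.frame of maximal binding runs.
#' @export
binding_runs_bed <- function(track, chrom, chrom_start = 0,
                             name_prefix = "bind") {
  r <- rle(track)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- which(r$values)
  if (length(keep) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  genomic_intervals(chrom, chrom_start + starts[keep],
                    chrom_start + ends[keep],
                    paste0(name_prefix, seq_along(keep)), "+")
}
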