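RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases, maps T to U and validates that only A/C/G/U remain. All
#' sequences inside the package are RNA; DNA is converted once at ingest.
#'
#' @param x character vector of sequences.
#' @param ids record identifiers used in error messages (recycled).
#' @return character vector over \{A,C,G,U\}.
#' @export
normalize_rna <- function(x, ids = names(x) %||% seq_along(x)) {
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- regexpr("[^ACGU]", out)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stopf("alphabet error: record '%s' has invalid residue '%s' at position %d",
          ids[i], substr(out[i], bad[i], bad[i]), bad[i])
  }
  names(out) <- names(x)
  out
}

#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Parsing is delegated to \code{Biostrings::readBStringSet}; residues are
#' then normalized to the RNA alphabet (T mapped to U, case folded). A record
#' containing any residue outside A/C/G/T/U raises an alphabet error naming
#' the record and position.
#'
#' @param path path to a FASTA file.
#' @return named character vector: names are record ids, values RNA strings.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("FASTA format error in %s: %s",
                                            path, conditionMessage(e)))
  if (length(set) == 0) stopf("FASTA format error: %s is empty", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stopf("FASTA format error: empty record id in %s", path)
  seqs <- as.character(set)
  names(seqs) <- ids
  normalize_rna(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a table of genomic intervals
#'
#' Coordinates are BED-style 0-based half-open throughout the package.
#'
#' @param chrom,start,end,name,strand interval columns.
#' @return data.frame with columns chrom, start, end, name, strand.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              strand = "+") {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), name = as.character(name),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (any(df$start < 0) || any(df$start >= df$end))
    stopf("coordinate error: need 0 <= start < end")
  if (!all(df$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  df
}

#' Read BED intervals (BED3/BED6)
#'
#' Intervals are kept 0-based half-open. A missing strand column defaults to
#' "+" with a warning.
#'
#' @param path BED file path.
#' @return interval data.frame (see [genomic_intervals()]).
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) stopf("BED format error: %s has no intervals", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) stopf("BED format error: line with < 3 columns")
  getf <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start_chr <- getf(2); end_chr <- getf(3)
  if (any(!grepl("^[0-9]+$", start_chr)) || any(!grepl("^[0-9]+$", end_chr)))
    stopf("BED format error: non-integer coordinates")
  start <- as.numeric(start_chr); end <- as.numeric(end_chr)
  if (any(start >= end)) stopf("coordinate error: start >= end in %s", path)
  name <- getf(4)
  name[is.na(name)] <- paste0("iv", which(is.na(name)))
  strand <- getf(6)
  if (any(is.na(strand) | !(strand %in% c("+", "-")))) {
    warnf("BED strand missing for %d interval(s); defaulting to '+'",
          sum(is.na(strand) | !(strand %in% c("+", "-"))))
    strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "+"
  }
  genomic_intervals(getf(1), start, end, name, strand)
}

reverse_complement_rna <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1]]),
          collapse = ""), "", USE.NAMES = FALSE)
}

#' Extract the strand-aware sequence of a genomic region
#'
#' Minus-strand regions return the reverse complement. A region exceeding the
#' chromosome bounds is truncated, never rejected: the returned string carries
#' attribute \code{truncated = TRUE} (250-nt upstream windows routinely fall
#' off contig edges).
#'
#' @param genome named character vector of chromosome sequences (RNA alphabet).
#' @param region one-row interval data.frame.
#' @return character scalar with attributes \code{id} and \code{truncated}.
#' @export
extract_region_sequence <- function(genome, region) {
  stopifnot(is.data.frame(region), nrow(region) == 1)
  chrom <- region$chrom
  if (!chrom %in% names(genome)) stopf("lookup error: unknown chrom '%s'", chrom)
  L <- nchar(genome[[chrom]])
  s0 <- max(0, region$start); e0 <- min(L, region$end)
  truncated <- (s0 != region$start) || (e0 != region$end)
  if (s0 >= e0) {
    seq <- ""
    truncated <- TRUE
  } else {
    seq <- substr(genome[[chrom]], s0 + 1, e0)
  }
  if (identical(region$strand, "-")) seq <- reverse_complement_rna(seq)
  structure(seq, id = region$name, truncated = truncated)
}

#' Write a bedGraph track
#'
#' Emits the bedGraph dialect: an optional \code{track} header followed by
#' \code{chrom<TAB>start<TAB>end<TAB>value} lines (0-based half-open, values
#' printed with 4 decimals). Overlapping intervals on one chromosome are
#' browser-legal but flagged with a warning.
#'
#' @param intervals interval data.frame with a numeric \code{score} column.
#' @param path output path.
#' @param track_name optional track name; \code{NULL} omits the header.
#' @export
write_bedgraph_track <- function(intervals, path, track_name = NULL) {
  if (nrow(intervals) > 0) {
    if (any(!is.finite(intervals$score)))
      stopf("bedGraph error: non-finite score")
    o <- order(intervals$chrom, intervals$start)
    iv <- intervals[o, , drop = FALSE]
    same <- iv$chrom[-1] == iv$chrom[-nrow(iv)]
    if (nrow(iv) > 1 && any(same & iv$start[-1] < iv$end[-nrow(iv)]))
      warnf("bedGraph: overlapping intervals on the same chrom")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  if (nrow(intervals) > 0)
    writeLines(sprintf("%s\t%d\t%d\t%.4f", intervals$chrom,
                       as.integer(intervals$start), as.integer(intervals$end),
                       intervals$score), con)
  invisible(path)
}
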