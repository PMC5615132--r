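#' @include AllClasses.R
NULL

#' Tetranucleotide-frequency vectors over contig windows
#'
#' Computes L1-normalized tetranucleotide (4-mer) frequency vectors in
#' non-overlapping 5-kbp windows tiling a contig, the compositional
#' signature used for binning diagnostics. 4-mers are counted with single-
#' base offset (overlapping k-mers); 4-mers containing `N` are skipped. A
#' trailing window shorter than `min_tail_bp` is merged into the previous
#' window; a contig shorter than `min_tail_bp` yields no usable vector
#' (empty result with a warning). In canonical mode each 4-mer is merged
#' with its reverse complement, giving 136 components, so the vector is
#' strand-independent.
#'
#' @param sequence DNA as a character scalar or [Biostrings::DNAString]
#'   (alphabet `A`,`C`,`G`,`T`,`N`).
#' @param window_bp Window size in bp (default 5000).
#' @param min_tail_bp Minimum length for a trailing (or only) window,
#'   default 1000.
#' @param canonical Merge reverse-complement 4-mer pairs (default FALSE:
#'   raw 256-dimensional vectors).
#' @param contig_id Label used to build fragment ids (`<contig_id>:<k>`).
#' @return List with `freq` (windows x 256 or 136 matrix; rows sum to 1 for
#'   valid windows, all-zero when a window has no valid 4-mer) and `windows`
#'   (data.frame: `fragment_id`, `start`, `end`, `width`, `valid`).
#' @export
tnfWindows <- function(sequence, window_bp = 5000L, min_tail_bp = 1000L,
                       canonical = FALSE, contig_id = "contig") {
  seq <- Biostrings::DNAString(toupper(as.character(sequence)))
  len <- length(seq)
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4L)
  ncolf <- if (canonical) 136L else 256L
  empty <- list(freq = matrix(numeric(0), ncol = ncolf),
                windows = data.frame(fragment_id = character(0),
                                     start = integer(0), end = integer(0),
                                     width = integer(0), valid = logical(0)))
  if (len < min_tail_bp) {
    warning("sequence shorter than ", min_tail_bp, " bp: no TNF window")
    return(empty)
  }
  starts <- seq.int(1L, len, by = window_bp)
  ends <- pmin(starts + window_bp - 1L, len)
  if (length(starts) > 1L &&
      (ends[length(ends)] - starts[length(starts)] + 1L) < min_tail_bp) {
    # merge the short trailing fragment into the previous window
    ends[length(ends) - 1L] <- len
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
  }
  views <- Biostrings::Views(seq, start = starts, end = ends)
  counts <- Biostrings::oligonucleotideFrequency(views, width = 4L)
  if (canonical) {
    km <- colnames(counts)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
    canon <- pmin(km, rc)
    counts <- t(rowsum(t(counts), group = canon))
  }
  tot <- rowSums(counts)
  freq <- counts / ifelse(tot > 0, tot, 1)
  rownames(freq) <- paste0(contig_id, ":", seq_along(starts))
  list(freq = freq,
       windows = data.frame(fragment_id = rownames(freq),
                            start = starts, end = ends,
                            width = ends - starts + 1L,
                            valid = tot > 0, stringsAsFactors = FALSE))
}

#' TNF matrix for a set of contigs
#'
#' @param contigs Named [Biostrings::DNAStringSet] or named character vector.
#' @param ... Passed to [tnfWindows()].
#' @return List with stacked `freq` matrix and `windows` data.frame
#'   (fragment ids are `<contig>:<window index>`).
#' @export
tnfMatrix <- function(contigs, ...) {
  res <- lapply(names(contigs), function(nm)
    tnfWindows(as.character(contigs[[nm]]), contig_id = nm, ...))
  list(freq = do.call(rbind, lapply(res, `[[`, "freq")),
       windows = do.call(rbind, lapply(res, `[[`, "windows")))
}

#' Trim gappy columns from a multiple alignment
#'
#' Removes alignment columns in which the gap character `-` occupies more
#' than `max_gap_fraction` of the sequences (strictly greater: a column with
#' exactly the threshold fraction is retained). Row order is preserved and
#' the removed column indices are reported in the `"removed_columns"`
#' attribute. The operation is idempotent.
#'
#' @param aln Equal-length aligned sequences: character vector,
#'   [Biostrings::AAStringSet] or [Biostrings::DNAStringSet].
#' @param max_gap_fraction Maximum tolerated gap fraction per column
#'   (default 0.30).
#' @return Object of the same class as `aln`, with attribute
#'   `removed_columns` (integer indices into the input columns).
#' @examples
#' a <- c("AC-D", "A--D", "ACCD")
#' trimAlignment(a)  # column 3 has 2/3 gaps > 0.3 -> removed
#' @export
trimAlignment <- function(aln, max_gap_fraction = 0.30) {
  chr <- as.character(aln)
  widths <- nchar(chr)
  if (length(unique(widths)) != 1L)
    stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(chr, ""))
  gap_frac <- colMeans(m == "-")
  drop <- which(gap_frac > max_gap_fraction)
  keep <- setdiff(seq_len(ncol(m)), drop)
  trimmed <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (is(aln, "XStringSet")) {
    out <- as(trimmed, class(aln))
    names(out) <- names(aln)
    metadata(out)$removed_columns <- as.integer(drop)
  } else {
    out <- trimmed
    names(out) <- names(aln)
    attr(out, "removed_columns") <- as.integer(drop)
  }
  out
}

#' Removed-column report of a trimmed alignment
#'
#' @param aln Result of [trimAlignment()].
#' @return Integer vector of removed column indices (in input coordinates).
#' @export
removedColumns <- function(aln) {
  if (is(aln, "XStringSet")) metadata(aln)$removed_columns
  else attr(aln, "removed_columns")
}
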