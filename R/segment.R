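# Segmentation of contigs at splitter occurrences, segment classification
# (spt-2 / spt-1 / spt-0), orientation normalization, spt-0 bucketing.

#' Split a contig into segments at splitter occurrences
#'
#' Scans the contig left to right; every position whose canonical k-mer is a
#' splitter ends the current segment (the splitter's k bases included) and
#' starts the next segment at the splitter's start, so neighbouring segments
#' share a k-base overlap.  A contig without any splitter occurrence (or
#' shorter than k) is a single spt-0 segment.
#'
#' @param contig a single upper-cased sequence
#' @param splitters character vector of splitter k-mers in id order
#' @param params a [pgarc_params()] object
#' @return data frame with one row per segment: `start`, `end` (1-based,
#'   inclusive), `left`, `right` (splitter ids, NA at contig boundaries),
#'   `overlap` (bases shared with the previous segment: k or 0) and `type`
#'   (`"spt-2"`, `"spt-1"`, `"spt-0"`)
#' @export
split_contig <- function(contig, splitters, params = pgarc_params()) {
  k <- params$k
  n <- nchar(contig)
  hits <- if (length(splitters) > 0L && n >= k)
    cpp_split_positions(contig, splitters, k)
  else list(pos = integer(0), id = integer(0))
  m <- length(hits$pos)
  if (m == 0L) {
    return(data.frame(start = 1L, end = n, left = NA_integer_,
                      right = NA_integer_, overlap = 0L, type = "spt-0"))
  }
  p <- hits$pos  # 0-based splitter start positions, ascending
  id <- hits$id
  start <- c(1L, p + 1L)
  end <- c(p + k, n)
  left <- c(NA_integer_, id)
  right <- c(id, NA_integer_)
  overlap <- c(0L, rep(k, m))
  type <- ifelse(is.na(left) | is.na(right), "spt-1", "spt-2")
  data.frame(start = start, end = end, left = left, right = right,
             overlap = overlap, type = type)
}

#' Normalize a segment's orientation
#'
#' Makes group identity strand-free: an spt-2 segment is reverse-complemented
#' iff the canonical form of its right splitter is lexicographically smaller
#' than that of its left splitter (so the smaller splitter leads); when both
#' canonical forms are equal the orientation with the lexicographically
#' smaller whole sequence is kept.  An spt-1 segment is flipped iff its
#' splitter sits at the end.  spt-0 segments are returned unchanged.
#' Normalization is idempotent.  Segments containing U are never flipped
#' (complementation is not invertible on U), at a compression -- not a
#' correctness -- cost.
#'
#' @param seq segment sequence (contig orientation)
#' @param left,right canonical splitter k-mers terminating the segment
#'   (`NULL`/`NA` for an absent side)
#' @return list with `seq` (stored orientation), `is_rc` (was it flipped?),
#'   `left`, `right` (splitters in stored orientation)
#' @export
normalize_segment <- function(seq, left = NULL, right = NULL) {
  if (length(left) == 0L || is.na(left)) left <- NULL
  if (length(right) == 0L || is.na(right)) right <- NULL
  flip <- FALSE
  if (!is.null(left) && !is.null(right)) {
    if (cpp_lex_lt(right, left)) flip <- TRUE
    else if (!cpp_lex_lt(left, right) && left == right)
      flip <- cpp_lex_lt(cpp_revcomp(seq), seq)
  } else if (is.null(left) && !is.null(right)) {
    flip <- TRUE
  } else if (is.null(left) && is.null(right)) {
    return(list(seq = seq, is_rc = FALSE, left = NULL, right = NULL))
  }
  if (flip && has_u(seq)) flip <- FALSE
  if (flip)
    list(seq = cpp_revcomp(seq), is_rc = TRUE, left = right, right = left)
  else
    list(seq = seq, is_rc = FALSE, left = left, right = right)
}

has_u <- function(x) grepl("U", x, fixed = TRUE)

#' Deterministic bucket for a splitter-free segment
#'
#' spt-0 segments are distributed over 16 groups by a stable 64-bit FNV-1a
#' hash of the lexicographically smaller of the segment and its reverse
#' complement, mod 16 -- independent of insertion order, platform and
#' process, and identical for a segment and its reverse complement.
#'
#' @param x character vector of segment sequences
#' @return integer vector of bucket indices in 0..15
#' @export
spt0_bucket <- function(x) cpp_spt0_bucket(x)
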