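# Stages 1 and 2 of compression: unique candidate k-mers of the reference,
# then splitters spaced by approximately segment_size along its contigs.

#' Find candidate k-mers of a reference genome
#'
#' Scans all reference contigs and returns the canonical k-mers whose total
#' occurrence count (over canonical forms, i.e. a k-mer and its reverse
#' complement counted as one entity) is exactly one.  Windows containing any
#' non-ACGT symbol are skipped.  These candidates are the pool from which
#' splitters are drawn.
#'
#' @param reference genome (named character vector of contigs) or FASTA path
#' @param k k-mer length (<= 32)
#' @return sorted character vector of canonical k-mers
#' @examples
#' find_candidate_kmers(c(ctg = "AACCG"), k = 3)
#' @export
find_candidate_kmers <- function(reference, k) {
  reference <- as_genome(reference)
  k <- as.integer(k)
  if (k < 1L || k > 32L) stop("k must be in 1..32")
  out <- cpp_find_candidates(unname(reference), k)
  if (length(out) == 0L) warning("no candidate k-mers found (empty or repetitive reference)")
  out
}

#' Select splitters from the candidate pool
#'
#' Walks each reference contig left to right: the first candidate occurrence
#' becomes a splitter, scanning resumes `segment_size` bases after it, and so
#' on; the last candidate occurrence of each contig is also a splitter.  The
#' result is deduplicated by canonical form, in insertion order (which fixes
#' the splitter ids).
#'
#' @param reference genome or FASTA path
#' @param candidates canonical k-mers as returned by [find_candidate_kmers()]
#' @param params a [pgarc_params()] object (uses `k` and `segment_size`)
#' @return character vector of splitter k-mers in id order
#' @export
determine_splitters <- function(reference, candidates, params = pgarc_params()) {
  reference <- as_genome(reference)
  cpp_determine_splitters(unname(reference), candidates,
                          params$k, params$segment_size)
}
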