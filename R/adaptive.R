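# Adaptive mode: for collections too divergent for the reference's
# splitters, each sample's splitter-free contigs seed new splitters.

#' Extend the splitter set from a sample's unmatched contigs
#'
#' Computes sample-candidate k-mers -- canonical k-mers occurring exactly
#' once within the buffered contigs, minus every k-mer present in the
#' reference genome (at any count) and minus the existing splitters -- and
#' selects new splitters from them with the same spaced walk used on the
#' reference (first candidate, skip `segment_size` bases, last candidate of
#' each contig).  In adaptive archives this runs once per added sample, and
#' the buffered contigs are then re-segmented a single time with the
#' extended set; splitters are never removed and ids never reused.
#'
#' @param buffered character vector of splitter-free contigs of the current
#'   sample
#' @param reference character vector of reference contigs
#' @param existing current splitter k-mers
#' @param params a [pgarc_params()] object
#' @return character vector of new splitter k-mers (insertion order), never
#'   colliding with `existing`
#' @export
extend_splitters_from_sample <- function(buffered, reference, existing,
                                         params = pgarc_params()) {
  if (length(buffered) == 0L) return(character(0))
  cand <- cpp_adaptive_candidates(buffered, reference, existing, params$k)
  if (length(cand) == 0L) return(character(0))
  cpp_determine_splitters(buffered, cand, params$k, params$segment_size)
}
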