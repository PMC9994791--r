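# Alphabet handling: 16-letter IUPAC nucleotide code (A C G T U R Y S W K M
# B D H V N), upper-cased at ingestion, nothing else transformed.

#' Reverse complement of IUPAC sequences
#'
#' Complements every symbol of the 16-letter IUPAC nucleotide alphabet
#' (A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H, S, W, N self-complementary,
#' U -> A) and reverses.  Because U complements to A while A complements to
#' T, the operation is an involution on every IUPAC string that does not
#' contain U; U-bearing sequences are therefore never orientation-flipped
#' for storage inside archives.
#'
#' @param x character vector of upper-case IUPAC sequences
#' @return character vector of reverse complements
#' @examples
#' reverse_complement(c("ACGT", "RYN"))
#' @export
reverse_complement <- function(x) cpp_revcomp(x)

#' Canonical form of a k-mer
#'
#' The lexicographically smaller of a k-mer and its reverse complement.
#' Only strictly ACGT k-mers are canonicalizable; a window containing any
#' other symbol signals an error (scanning code skips such windows).
#'
#' @param x character vector of ACGT k-mers
#' @return character vector of canonical k-mers
#' @examples
#' canonical_kmer(c("TTT", "CGT"))
#' @export
canonical_kmer <- function(x) cpp_canonical(x)

#' Ingest sequences: upper-case and validate the alphabet
#'
#' Maps lower-case symbols to upper-case and verifies that only the 16
#' IUPAC symbols remain; no other transformation is applied.
#'
#' @param x character vector of sequences (names preserved)
#' @return upper-cased, validated character vector
#' @export
ingest_sequence <- function(x) cpp_ingest(x)

#' Pack symbols into bytes by alphabet size
#'
#' Radix-packs a sequence at 4, 3, 2 or 1 symbols per byte depending on its
#' own distinct-symbol count sigma (sigma <= 4, <= 6, <= 16, otherwise).
#' The returned descriptor (the sorted distinct symbols) makes
#' [unpack_symbols()] exact.
#'
#' @param x a single sequence
#' @return list with `bytes` (raw payload), `symbols` (descriptor string),
#'   `per_byte` (packing tier) and `n` (sequence length)
#' @examples
#' p <- pack_symbols("ACGTACGT")   # 4 symbols/byte -> 2 payload bytes
#' unpack_symbols(p)
#' @export
pack_symbols <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  p <- cpp_pack_seq(x)
  p$n <- nchar(x)
  p
}

#' @rdname pack_symbols
#' @param packed a list as returned by [pack_symbols()]
#' @export
unpack_symbols <- function(packed) {
  cpp_unpack_seq(packed$bytes, packed$symbols, packed$n)
}

# Byte size of a sequence under radix packing (used as the raw-storage cost
# a parsed description must beat).
packed_size <- function(x) {
  sigma <- cpp_nsym(x)
  per_byte <- if (sigma <= 4L) 4L else if (sigma <= 6L) 3L else if (sigma <= 16L) 2L else 1L
  ceiling(nchar(x) / per_byte)
}
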