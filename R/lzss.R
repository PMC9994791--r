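# LZSS codec: greedy parse of a segment against its group's reference
# segment, compact token serialization, exact decode.
#
# Serialization (pinned; parameters recorded in the archive header):
#   0x00                               terminator
#   0x01 varint(runlen) <raw symbols>  literal run
#   0x02 varint(zigzag(offset - cursor)) varint(len - min_match)  match
# The implicit reference cursor starts at 0, becomes offset+len after each
# match and advances by the run length after each literal run, so matches
# that resume where the last one left off cost one byte of offset.  Matches
# refer to the forward orientation of the reference only; strand is handled
# once per segment by normalization.

#' LZSS-parse a sequence against a reference
#'
#' Greedy left-to-right parse: at each position the longest reference match
#' of length >= `min_match` is taken (leftmost reference occurrence on tie,
#' among the first 128 candidate anchor positions), otherwise a literal is
#' emitted.  Identical inputs always yield byte-identical streams.
#'
#' @param x sequence to describe
#' @param reference reference sequence the matches point into
#' @param params a [pgarc_params()] (uses `min_match` and `mmer`)
#' @return raw vector: the serialized token stream, terminator included
#' @examples
#' r <- strrep("ACGT", 25)
#' tok <- lzss_parse(r, r)
#' identical(lzss_decode(tok, r), r)
#' @export
lzss_parse <- function(x, reference, params = pgarc_params()) {
  cpp_lzss_parse(x, reference, params$min_match, params$mmer)
}

#' Decode an LZSS token stream
#'
#' Exact inverse of [lzss_parse()] against the same reference.  A match
#' window falling outside the reference, an unknown flag or a truncated
#' stream signals a corrupt-stream error.
#'
#' @param tokens raw token stream
#' @param reference the reference sequence used at parse time
#' @inheritParams lzss_parse
#' @return the reconstructed sequence
#' @export
lzss_decode <- function(tokens, reference, params = pgarc_params()) {
  cpp_lzss_decode(tokens, reference, params$min_match)
}

#' Storage cost of a parse, in bytes
#'
#' The exact serialized byte length (terminator included) of the greedy
#' parse of `x` against `reference`; the quantity minimized when choosing a
#' group for a single-splitter segment or a division point for a segment
#' spanning a missing splitter.
#'
#' @inheritParams lzss_parse
#' @return numeric byte count
#' @export
lzss_cost <- function(x, reference, params = pgarc_params()) {
  cpp_lzss_cost(x, reference, params$min_match, params$mmer)
}

#' List the tokens of a serialized stream
#'
#' Debug/inspection helper: decodes the serialization into a data frame of
#' tokens without touching the reference.
#'
#' @param tokens raw token stream
#' @inheritParams lzss_parse
#' @return data frame with columns `type` ("literal"/"match"), `length`,
#'   `offset` (NA for literal runs)
#' @export
lzss_tokens <- function(tokens, params = pgarc_params()) {
  buf <- tokens
  at <- 0
  expected <- 0
  type <- character(0); len <- integer(0); off <- numeric(0)
  repeat {
    flag <- as.integer(buf[at + 1]); at <- at + 1
    if (flag == 0L) break
    if (flag == 1L) {
      d <- cpp_leb128_decode(buf, at, 1L); at <- d$at
      type <- c(type, "literal"); len <- c(len, d$values); off <- c(off, NA_real_)
      at <- at + d$values
      expected <- expected + d$values
    } else if (flag == 2L) {
      d <- cpp_leb128_decode(buf, at, 2L); at <- d$at
      z <- d$values[1]
      delta <- if (z %% 2 == 0) z / 2 else -(z + 1) / 2   # un-zigzag
      this_off <- expected + delta
      this_len <- d$values[2] + params$min_match
      type <- c(type, "match")
      len <- c(len, this_len)
      off <- c(off, this_off)
      expected <- this_off + this_len
    } else stop("corrupt stream: unknown token flag ", flag)
  }
  data.frame(type = type, length = len, offset = off)
}

#' Best division point of a segment between two group references
#'
#' For a segment whose splitter pair has no group but whose splitters each
#' pair with a common third splitter, returns the cut index i (0-based, so
#' the parts are `substr(x, 1, i)` and `substr(x, i + 1, n)`) minimizing
#' `lzss_cost(prefix, refA) + lzss_cost(suffix, refB)`.  Prefix costs come
#' from one forward pass and suffix costs from one backward pass; results
#' are exactly those of exhaustively re-parsing every cut, with ties broken
#' toward the smallest i.
#'
#' @param x the segment spanning the missing splitter
#' @param refA reference of the group the prefix will join
#' @param refB reference of the group the suffix will join
#' @param imin,imax optional restriction of the cut range
#' @inheritParams lzss_parse
#' @return integer cut index in `[imin, imax]`
#' @export
find_division_point <- function(x, refA, refB, params = pgarc_params(),
                                imin = 0L, imax = nchar(x)) {
  cpp_find_division(x, refA, refB, params$min_match, params$mmer,
                    as.integer(imin), as.integer(imax))$i
}
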