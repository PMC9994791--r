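# Random-access decompression: contig, contig range, sample, collection,
# listings and statistics.  Only the frames holding the requested segments
# (their groups' reference segments and containing blocks) are decompressed.

find_sample <- function(ar, sample) {
  si <- ar$sample_ids[[sample]]
  if (is.null(si)) {
    all <- vapply(ar$samples, `[[`, "", "name")
    stop("unknown sample '", sample, "'", suggest_names(sample, all))
  }
  si
}

suggest_names <- function(x, pool) {
  if (length(pool) == 0L) return("")
  d <- utils::adist(x, pool)
  near <- pool[d <= 2]
  if (length(near) == 0L) ""
  else paste0("; did you mean ", paste(sQuote(near), collapse = ", "), "?")
}

# Decode one stored segment (stored orientation).
decode_segment <- function(ar, gid, sid) {
  g <- ar$groups[[gid]]
  if (sid == 0) return(group_ref(ar, g))
  bs <- ar$params$block_size
  bi <- (sid - 1) %/% bs + 1
  wi <- (sid - 1) %% bs + 1
  nb <- length(g$blocks)
  if (bi <= nb) {
    blk <- g$blocks[[bi]]
    bytes <- frame_bytes(ar, blk$off, blk$size)
    ends <- blk$ends
  } else if (length(g$tail_streams) >= wi && bi == nb + 1) {
    return(cpp_lzss_decode(g$tail_streams[[wi]], group_ref(ar, g),
                           ar$params$min_match))
  } else if (!is.null(g$tail_frame) && bi == nb + 1) {
    bytes <- frame_bytes(ar, g$tail_frame[1], g$tail_frame[2])
    ends <- g$tail_ends
  } else {
    stop("corrupt archive: segment id ", sid, " beyond group ", gid)
  }
  starts <- c(0, ends)
  tokens <- bytes[(starts[wi] + 1):ends[wi]]
  cpp_lzss_decode(tokens, group_ref(ar, g), ar$params$min_match)
}

#' Extract a contig or contig range
#'
#' Reconstructs a contig (or the half of it you ask for) by decompressing
#' only the groups and blocks its segments live in: per touched segment, the
#' group's reference-segment frame and the one block frame containing its
#' description.  Coordinates are 1-based and inclusive.
#'
#' @param ar an open archive (or archive path)
#' @param sample sample name
#' @param contig contig name
#' @param start,end optional 1-based inclusive range; defaults to the whole
#'   contig.  `start = n + 1, end = n` yields the empty sequence.
#' @return the requested sequence (upper-cased, as ingested)
#' @export
get_contig <- function(ar, sample, contig, start = NULL, end = NULL) {
  if (is.character(ar)) ar <- archive_open(ar)
  si <- find_sample(ar, sample)
  ctgs <- ar$samples[[si]]$contigs
  cnames <- vapply(ctgs, `[[`, "", "name")
  ci <- match(contig, cnames)
  if (is.na(ci))
    stop("unknown contig '", contig, "' in sample '", sample, "'",
         suggest_names(contig, cnames))
  ctg <- ctgs[[ci]]
  n <- ctg$len
  a <- if (is.null(start)) 1 else as.numeric(start)
  b <- if (is.null(end)) n else as.numeric(end)
  if (a < 1 || b > n || a > b + 1)
    stop("range ", a, "-", b, " out of bounds for contig '", contig,
         "' of length ", n)
  if (a == b + 1) return("")
  recs <- ctg$recs
  lens <- recs[, "len"]
  ovs <- recs[, "ov"]
  contrib <- lens - ovs
  ends <- cumsum(contrib)
  cstarts <- ends - contrib + 1          # first base this segment contributes
  needed <- which(contrib > 0 & cstarts <= b & ends >= a)
  pieces <- character(length(needed))
  for (j in seq_along(needed)) {
    i <- needed[j]
    sseq <- decode_segment(ar, recs[i, "gid"], recs[i, "sid"])
    if (recs[i, "rc"] == 1) sseq <- cpp_revcomp(sseq)
    # segment covers contig coords [ends[i] - len + 1, ends[i]]
    seg_start <- ends[i] - lens[i] + 1
    lo <- max(a, cstarts[i])
    hi <- min(b, ends[i])
    pieces[j] <- substr(sseq, lo - seg_start + 1, hi - seg_start + 1)
  }
  paste(pieces, collapse = "")
}

#' Extract a whole sample
#'
#' All contigs of a sample, in original order; only the blocks holding that
#' sample's segments are decompressed.
#'
#' @inheritParams get_contig
#' @return named character vector of contigs
#' @export
get_sample <- function(ar, sample) {
  if (is.character(ar)) ar <- archive_open(ar)
  si <- find_sample(ar, sample)
  ctgs <- ar$samples[[si]]$contigs
  out <- vapply(ctgs, function(ctg)
    get_contig(ar, sample, ctg$name), "")
  names(out) <- vapply(ctgs, `[[`, "", "name")
  out
}

#' Extract the whole collection
#'
#' @inheritParams get_contig
#' @return named list of genomes, in insertion order
#' @export
get_collection <- function(ar) {
  if (is.character(ar)) ar <- archive_open(ar)
  nms <- vapply(ar$samples, `[[`, "", "name")
  out <- lapply(nms, function(s) get_sample(ar, s))
  names(out) <- nms
  out
}

#' List sample names
#'
#' @inheritParams get_contig
#' @return character vector of sample names in insertion order
#' @export
list_samples <- function(ar) {
  if (is.character(ar)) ar <- archive_open(ar)
  vapply(ar$samples, `[[`, "", "name")
}

#' List contig names
#'
#' @inheritParams get_contig
#' @param sample optional sample name to restrict to
#' @return data frame with columns `sample` and `contig`
#' @export
list_contigs <- function(ar, sample = NULL) {
  if (is.character(ar)) ar <- archive_open(ar)
  smps <- if (is.null(sample)) ar$samples else ar$samples[find_sample(ar, sample)]
  do.call(rbind, lapply(smps, function(smp)
    data.frame(sample = smp$name,
               contig = vapply(smp$contigs, `[[`, "", "name"))))
}

#' Archive statistics
#'
#' Counts of samples, contigs, splitters, groups by kind, segments stored in
#' spt-0 buckets, blocks, and section sizes of the archive file.
#'
#' @inheritParams get_contig
#' @return a list of statistics
#' @export
archive_info <- function(ar) {
  if (is.character(ar)) ar <- archive_open(ar)
  kinds <- vapply(ar$groups, `[[`, "", "kind")
  members <- vapply(ar$groups, `[[`, 0L, "n_members")
  sealed <- vapply(ar$groups, function(g) length(g$blocks), 0L)
  tails <- vapply(ar$groups, function(g)
    (!is.null(g$tail_frame)) || length(g$tail_streams) > 0L, NA)
  sz <- if (file.exists(ar$path)) file.size(ar$path) else NA_real_
  list(
    path = ar$path,
    params = ar$params,
    n_samples = length(ar$samples),
    n_contigs = sum(vapply(ar$samples, function(s) length(s$contigs), 0L)),
    n_splitters = length(ar$splitters),
    n_groups = length(ar$groups),
    groups_by_kind = c(pair = sum(kinds == "pair"),
                       single = sum(kinds == "single"),
                       bucket = sum(kinds == "bucket")),
    n_segments = sum(members),
    spt0_segments = sum(members[kinds == "bucket"]),
    n_blocks_sealed = sum(sealed),
    n_blocks_open = sum(tails),
    file_size = sz,
    sealed_region_bytes = ar$immutable_end - 8
  )
}
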