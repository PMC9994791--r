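# The in-memory side of an archive: the splitter registry, the group
# registry (pair / single / bucket keys), segment placement, and blocked
# accumulation of LZSS descriptions.  Disk layout lives in archive-io.R.

ARCHIVE_MAGIC <- "PGARC001"
ARCHIVE_VERSION <- 1

new_archive_env <- function(path, params, mode) {
  ar <- new.env(parent = emptyenv())
  ar$path <- path
  ar$mode <- mode                 # "create" | "append" | "read"
  ar$params <- params
  ar$splitters <- character(0)
  ar$splitter_ids <- new.env(parent = emptyenv())
  ar$groups <- list()
  ar$group_keys <- new.env(parent = emptyenv())
  ar$by_splitter <- new.env(parent = emptyenv())
  ar$samples <- list()
  ar$sample_ids <- new.env(parent = emptyenv())
  ar$immutable_end <- 8           # past the magic; sealed frames live below this
  ar$cache <- new.env(parent = emptyenv())
  ar$io <- new.env(parent = emptyenv())
  ar$io$frames <- 0
  ar$io$bytes <- 0
  ar$reference_contigs <- NULL    # kept for adaptive mode
  class(ar) <- "pgarc_archive"
  ar
}

#' @export
print.pgarc_archive <- function(x, ...) {
  cat(sprintf("pgarc archive [%s] %s: %d sample(s), %d group(s), %d splitter(s)\n",
              x$mode, x$path, length(x$samples), length(x$groups),
              length(x$splitters)))
  invisible(x)
}

register_splitters <- function(ar, kmers) {
  if (length(kmers) == 0L) return(invisible(ar))
  base <- length(ar$splitters)
  ar$splitters <- c(ar$splitters, kmers)
  for (i in seq_along(kmers))
    assign(kmers[i], base + i, envir = ar$splitter_ids)
  invisible(ar)
}

# Pair keys are ordered by splitter k-mer (lexicographic), so a segment and
# its reverse complement map to the same key.
pair_key <- function(ar, a, b) {
  if (cpp_lex_lt(ar$splitters[b], ar$splitters[a])) { t <- a; a <- b; b <- t }
  paste0("P", a, "_", b)
}

group_new <- function(ar, kind, a, b = NA_integer_, ref_seq) {
  g <- new.env(parent = emptyenv())
  g$id <- length(ar$groups) + 1L
  g$kind <- kind
  if (kind == "pair" && cpp_lex_lt(ar$splitters[b], ar$splitters[a])) {
    t <- a; a <- b; b <- t
  }
  g$a <- a
  g$b <- b
  g$ref_seq <- ref_seq
  g$ref_len <- nchar(ref_seq)
  g$ref_symbols <- NULL
  g$ref_frame <- NULL             # c(off, size) once written
  g$n_members <- 1L               # the reference is member 0
  g$blocks <- list()              # sealed blocks
  g$tail_streams <- list()        # open block (raw token streams)
  g$tail_frame <- NULL            # on-disk tail not yet loaded (append mode)
  g$tail_count <- 0L
  g$tail_ends <- numeric(0)
  ar$groups[[g$id]] <- g
  key <- switch(kind,
                pair = paste0("P", a, "_", b),
                single = NA_character_,
                bucket = paste0("B", a))
  if (!is.na(key)) assign(key, g$id, envir = ar$group_keys)
  if (kind %in% c("pair", "single")) {
    ka <- as.character(a)
    ar$by_splitter[[ka]] <- c(ar$by_splitter[[ka]], g$id)
    if (kind == "pair" && b != a) {
      kb <- as.character(b)
      ar$by_splitter[[kb]] <- c(ar$by_splitter[[kb]], g$id)
    }
  }
  g
}

# Reference segment of a group, decompressing lazily in append/read mode.
group_ref <- function(ar, g) {
  if (is.null(g$ref_seq)) {
    bytes <- frame_bytes(ar, g$ref_frame[1], g$ref_frame[2])
    g$ref_seq <- cpp_unpack_seq(bytes, g$ref_symbols, g$ref_len)
  }
  g$ref_seq
}

# Load the on-disk tail (open) block of a group, lazily, before appending.
group_load_tail <- function(ar, g) {
  if (!is.null(g$tail_frame)) {
    bytes <- frame_bytes(ar, g$tail_frame[1], g$tail_frame[2])
    ends <- g$tail_ends
    starts <- c(0, head(ends, -1L))
    g$tail_streams <- lapply(seq_len(g$tail_count), function(i)
      bytes[(starts[i] + 1):ends[i]])
    g$tail_frame <- NULL
  }
  invisible(g)
}

seal_block <- function(g) {
  streams <- g$tail_streams
  ends <- cumsum(vapply(streams, length, 0L))
  comp <- memCompress(do.call(c, streams), "xz")
  g$blocks[[length(g$blocks) + 1L]] <- list(
    off = NA_real_, size = length(comp), count = length(streams),
    ends = as.numeric(ends), comp = comp)
  g$tail_streams <- list()
  g$tail_count <- 0L
  g$tail_ends <- numeric(0)
  invisible(g)
}

# Append a member segment (already in its stored orientation); returns its
# in-group segment id (the reference is id 0).
group_append_member <- function(ar, g, stored_seq) {
  ref <- group_ref(ar, g)
  tokens <- cpp_lzss_parse(stored_seq, ref, ar$params$min_match, ar$params$mmer)
  group_load_tail(ar, g)
  g$tail_streams[[length(g$tail_streams) + 1L]] <- tokens
  sid <- g$n_members
  g$n_members <- g$n_members + 1L
  if (length(g$tail_streams) == ar$params$block_size) seal_block(g)
  sid
}

# ---------------------------------------------------------------- placement --

rec_row <- function(gid, sid, rc, len, ov) {
  c(gid = gid, sid = sid, rc = as.numeric(rc), len = len, ov = ov)
}

place_spt0 <- function(ar, sseq) {
  bucket <- cpp_spt0_bucket(sseq)
  key <- paste0("B", bucket)
  gid <- ar$group_keys[[key]]
  if (is.null(gid)) {
    g <- group_new(ar, "bucket", bucket, NA_integer_, sseq)
    rec_row(g$id, 0, FALSE, nchar(sseq), 0)
  } else {
    g <- ar$groups[[gid]]
    sid <- group_append_member(ar, g, sseq)
    rec_row(gid, sid, FALSE, nchar(sseq), 0)
  }
}

# Best existing group containing splitter s for a normalized spt-1 segment;
# both orientations tried, the cheaper kept, ties to the forward orientation
# and the older group.  Joins only if the description costs less than
# new_group_threshold (0.5) of storing the segment packed.
place_spt1 <- function(ar, sseq, s, norm_rc, ov) {
  u <- has_u(sseq)
  cand <- ar$by_splitter[[as.character(s)]]
  n <- nchar(sseq)
  if (!is.null(cand)) {
    cand <- sort(cand)
    best_cost <- Inf; best_g <- NULL; best_rc <- FALSE
    rcseq <- if (u) NULL else cpp_revcomp(sseq)
    for (gid in cand) {
      g <- ar$groups[[gid]]
      ref <- group_ref(ar, g)
      cf <- cpp_lzss_cost(sseq, ref, ar$params$min_match, ar$params$mmer)
      if (cf < best_cost) { best_cost <- cf; best_g <- g; best_rc <- FALSE }
      if (!is.null(rcseq)) {
        cr <- cpp_lzss_cost(rcseq, ref, ar$params$min_match, ar$params$mmer)
        if (cr < best_cost) { best_cost <- cr; best_g <- g; best_rc <- TRUE }
      }
    }
    if (best_cost < 0.5 * packed_size(sseq)) {
      stored <- if (best_rc) rcseq else sseq
      sid <- group_append_member(ar, best_g, stored)
      return(rec_row(best_g$id, sid, xor(norm_rc, best_rc), n, ov))
    }
  }
  g <- group_new(ar, "single", s, NA_integer_, sseq)
  rec_row(g$id, 0, norm_rc, n, ov)
}

pair_partners <- function(ar, s) {
  gids <- ar$by_splitter[[as.character(s)]]
  out <- integer(0)
  for (gid in gids) {
    g <- ar$groups[[gid]]
    if (g$kind == "pair") out <- c(out, if (g$a == s) g$b else g$a)
  }
  out
}

# spt-2 placement: (a) join the (s1,s2) group; (b) if absent but a common
# partner s3 bridges (s1,s3) and (s3,s2), split at the cost-optimal division
# point into two parts appended to those groups (junction overlap 0);
# (c) otherwise found a new group with this segment as its reference.
place_spt2 <- function(ar, sseq, left, right, ov) {
  spl <- ar$splitters
  k <- ar$params$k
  n <- nchar(sseq)
  u <- has_u(sseq)
  ka <- spl[left]; kb <- spl[right]
  flip <- if (cpp_lex_lt(kb, ka)) TRUE
          else if (ka == kb) cpp_lex_lt(cpp_revcomp(sseq), sseq)
          else FALSE
  if (u) flip <- FALSE
  norm <- if (flip) cpp_revcomp(sseq) else sseq
  s1 <- if (flip) right else left    # leading splitter of the normalized segment
  s2 <- if (flip) left else right
  key <- pair_key(ar, left, right)
  gid <- ar$group_keys[[key]]
  if (!is.null(gid)) {
    g <- ar$groups[[gid]]
    sid <- group_append_member(ar, g, norm)
    return(rec_row(gid, sid, flip, n, ov))
  }
  if (n >= 2 * k) {
    s3s <- sort(intersect(pair_partners(ar, s1), pair_partners(ar, s2)))
    s3s <- setdiff(s3s, c(s1, s2))
    if (length(s3s) > 0L) {
      best <- NULL
      for (s3 in s3s) {
        gA <- ar$groups[[ar$group_keys[[pair_key(ar, s1, s3)]]]]
        gB <- ar$groups[[ar$group_keys[[pair_key(ar, s3, s2)]]]]
        flipA <- cpp_lex_lt(spl[s3], spl[s1])   # group ref leads with s3
        flipB <- cpp_lex_lt(spl[s2], spl[s3])   # group ref ends with s3
        refA <- group_ref(ar, gA); if (flipA) refA <- cpp_revcomp(refA)
        refB <- group_ref(ar, gB); if (flipB) refB <- cpp_revcomp(refB)
        div <- cpp_find_division(norm, refA, refB, ar$params$min_match,
                                 ar$params$mmer, k, n - k)
        if (is.null(best) || div$cost < best$cost)
          best <- list(cost = div$cost, i = div$i, gA = gA, gB = gB,
                       flipA = flipA, flipB = flipB)
      }
      i <- best$i
      sub1 <- substr(norm, 1L, i)
      sub2 <- substr(norm, i + 1L, n)
      f1 <- best$flipA && !has_u(sub1)
      f2 <- best$flipB && !has_u(sub2)
      sid1 <- group_append_member(ar, best$gA, if (f1) cpp_revcomp(sub1) else sub1)
      sid2 <- group_append_member(ar, best$gB, if (f2) cpp_revcomp(sub2) else sub2)
      r1 <- rec_row(best$gA$id, sid1, xor(flip, f1), i, if (flip) 0 else ov)
      r2 <- rec_row(best$gB$id, sid2, xor(flip, f2), n - i, if (flip) ov else 0)
      # contig order: the normalized prefix is the contig-level tail when flipped
      return(if (flip) rbind(r2, r1) else rbind(r1, r2))
    }
  }
  g <- group_new(ar, "pair", left, right, norm)
  rec_row(g$id, 0, flip, n, ov)
}

place_segment <- function(ar, sseq, left, right, ov) {
  if (is.na(left) && is.na(right)) return(rbind(place_spt0(ar, sseq)))
  if (is.na(left) || is.na(right)) {
    s <- if (is.na(left)) right else left
    norm_rc <- is.na(left) && !has_u(sseq)    # splitter at the end: flip to front
    norm <- if (norm_rc) cpp_revcomp(sseq) else sseq
    return(rbind(place_spt1(ar, norm, s, norm_rc, ov)))
  }
  place_spt2(ar, sseq, left, right, ov)
}

process_contig <- function(ar, seq) {
  segs <- split_contig(seq, ar$splitters, ar$params)
  rows <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    sseq <- substr(seq, segs$start[i], segs$end[i])
    rows[[i]] <- place_segment(ar, sseq, segs$left[i], segs$right[i],
                               segs$overlap[i])
  }
  do.call(rbind, rows)
}

# ----------------------------------------------------------- archive ops ----

#' Create a new archive from a reference genome
#'
#' Runs the first two compression stages on the reference (candidate k-mer
#' determination and splitter selection), then adds the reference itself as
#' the first sample.  Returns an open archive; add further samples with
#' [add_genome()] and finalize with [archive_seal()]; [pgarc_create()] wraps
#' all three.
#'
#' @param path output file path
#' @param reference genome (named character vector) or FASTA path
#' @param params a [pgarc_params()] object
#' @param reference_name sample name for the reference (derived from the
#'   FASTA path when one is given)
#' @return an open archive object
#' @export
create_archive <- function(path, reference, params = pgarc_params(),
                           reference_name = NULL) {
  if (is.null(reference_name))
    reference_name <- if (is.character(reference) && is.null(names(reference)))
      sample_name_from_path(reference) else "reference"
  reference <- as_genome(reference)
  ar <- new_archive_env(path, params, "create")
  candidates <- cpp_find_candidates(unname(reference), params$k)
  register_splitters(ar, cpp_determine_splitters(unname(reference), candidates,
                                                 params$k, params$segment_size))
  ar$reference_contigs <- unname(reference)
  add_genome(ar, reference, reference_name)
  ar
}

#' Add a genome to an open archive
#'
#' Segments every contig at splitter occurrences, places each segment into a
#' group (creating groups as needed), and appends its LZSS description to
#' the group's open block.  In adaptive mode, contigs without any splitter
#' occurrence are buffered, the splitter set is extended from their k-mers,
#' and the buffered contigs are re-segmented once before storage.
#'
#' @param ar an open archive from [create_archive()] or
#'   [archive_open_append()]
#' @param genome genome (named character vector) or FASTA path
#' @param name sample name; must not already be present
#' @return the archive, invisibly
#' @export
add_genome <- function(ar, genome, name = NULL) {
  if (ar$mode == "read") stop("archive is open read-only")
  if (is.null(name))
    name <- if (is.character(genome) && is.null(names(genome)))
      sample_name_from_path(genome) else stop("a sample name is required")
  if (!is.null(ar$sample_ids[[name]]))
    stop("duplicate sample name: '", name, "' is already in the archive")
  genome <- as_genome(genome)
  is_reference <- length(ar$samples) == 0L
  adaptive <- ar$params$adaptive && !is_reference
  cn <- names(genome)
  recs <- vector("list", length(genome))
  buffered <- integer(0)
  for (i in seq_along(genome)) {
    if (adaptive) {
      segs <- split_contig(genome[[i]], ar$splitters, ar$params)
      if (nrow(segs) == 1L && segs$type[1L] == "spt-0") {
        buffered <- c(buffered, i)
        next
      }
    }
    recs[[i]] <- process_contig(ar, genome[[i]])
  }
  if (length(buffered) > 0L) {
    new_spl <- extend_splitters_from_sample(unname(genome[buffered]),
                                            reference_contigs(ar),
                                            ar$splitters, ar$params)
    register_splitters(ar, new_spl)
    for (i in buffered) recs[[i]] <- process_contig(ar, genome[[i]])
  }
  contigs <- lapply(seq_along(genome), function(i)
    list(name = cn[i], len = nchar(genome[[i]]), recs = recs[[i]]))
  ar$samples[[length(ar$samples) + 1L]] <- list(name = name, contigs = contigs)
  assign(name, length(ar$samples), envir = ar$sample_ids)
  invisible(ar)
}

# Reference contigs for adaptive candidate exclusion; decompressed from
# sample 1 when appending to an existing archive.
reference_contigs <- function(ar) {
  if (is.null(ar$reference_contigs))
    ar$reference_contigs <- unname(get_sample(ar, ar$samples[[1L]]$name))
  ar$reference_contigs
}

#' Create an archive in one call
#'
#' Convenience wrapper: [create_archive()], [add_genome()] for each sample,
#' then [archive_seal()].
#'
#' @inheritParams create_archive
#' @param samples named list of genomes, or character vector of FASTA paths
#' @return the archive path, invisibly
#' @export
pgarc_create <- function(path, reference, samples = list(),
                         params = pgarc_params(), reference_name = NULL) {
  ar <- create_archive(path, reference, params, reference_name)
  add_all(ar, samples)
  archive_seal(ar)
  invisible(path)
}

#' Append samples to an existing archive
#'
#' @param path path of a sealed archive
#' @param samples named list of genomes, or character vector of FASTA paths
#' @return the archive path, invisibly
#' @export
pgarc_append <- function(path, samples) {
  ar <- archive_open_append(path)
  add_all(ar, samples)
  archive_seal(ar)
  invisible(path)
}

add_all <- function(ar, samples) {
  if (is.character(samples)) {
    for (p in samples) add_genome(ar, read_fasta(p), sample_name_from_path(p))
  } else {
    nm <- names(samples)
    if (length(samples) > 0L && (is.null(nm) || any(nm == "")))
      stop("samples must be named (or given as FASTA paths)")
    for (i in seq_along(samples)) add_genome(ar, samples[[i]], nm[i])
  }
  invisible(ar)
}
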