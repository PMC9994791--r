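# On-disk layout (single file, little-endian, LEB128 varints, xz frames):
#
#   [magic "PGARC001"]
#   [sealed frames: group reference segments and full blocks, append-only]
#   [tail frames: one per group with an open block]        \
#   [metadata frame: xz-compressed section described below]  rewritten on
#   [footer: u64 meta_off, u64 meta_size, magic]           / every seal
#
# Appending truncates at the end of the sealed region, appends any newly
# sealed frames there, and rewrites tails + metadata + footer; sealed frame
# bytes and offsets never change.

read_file_raw <- function(path, off, size) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  seek(con, off)
  readBin(con, "raw", n = size)
}

# Decompress a frame with caching and instrumentation (every actual
# decompression counts as one frame touched).
frame_bytes <- function(ar, off, size) {
  key <- as.character(off)
  hit <- ar$cache[[key]]
  if (!is.null(hit)) return(hit)
  comp <- read_file_raw(ar$path, off, size)
  bytes <- memDecompress(comp, "xz")
  ar$io$frames <- ar$io$frames + 1
  ar$io$bytes <- ar$io$bytes + size
  ar$cache[[key]] <- bytes
  bytes
}

#' Frame-access statistics of an open archive
#'
#' Counters of compressed frames decompressed (and their on-disk bytes)
#' since the archive was opened or the counters were last reset.  Used to
#' verify access locality: the number of frames a query touches depends on
#' the number of segments in the query, not on the collection size.
#'
#' @param ar an open archive
#' @return list with `frames` and `bytes`
#' @export
io_stats <- function(ar) list(frames = ar$io$frames, bytes = ar$io$bytes)

#' @rdname io_stats
#' @export
reset_io_stats <- function(ar) {
  ar$io$frames <- 0
  ar$io$bytes <- 0
  rm(list = ls(ar$cache), envir = ar$cache)
  if (ar$mode == "read")
    for (g in ar$groups) if (!is.null(g$ref_frame)) g$ref_seq <- NULL
  invisible(ar)
}

# ------------------------------------------------------------- serializer --

vint <- function(x) cpp_leb128_encode(as.numeric(x))
vstr <- function(s) {
  b <- charToRaw(s)
  c(cpp_leb128_encode(length(b)), b)
}

# Zigzag mapping so deltas of either sign become small varints.
zz <- function(d) ifelse(d >= 0, 2 * d, -2 * d - 1)
unzz <- function(z) ifelse(z %% 2 == 0, z / 2, -(z + 1) / 2)

# Segment-record columns are stored as deltas against cheap predictors:
# group ids mostly walk the reference's group sequence (predictor: previous
# id + 1), in-group segment ids are near-constant within one sample
# (predictor: previous value), segment lengths hover around
# segment_size + k.  The xz stage then sees mostly zero bytes.
encode_recs <- function(recs, params) {
  gid <- recs[, "gid"]; sid <- recs[, "sid"]; len <- recs[, "len"]
  c(nrow(recs),
    zz(gid - c(0, head(gid, -1L)) - 1),
    zz(sid - c(0, head(sid, -1L))),
    recs[, "rc"],
    zz(len - (params$segment_size + params$k)),
    recs[, "ov"])
}

decode_recs <- function(v, ns, params) {
  gid <- cumsum(unzz(v[seq_len(ns)]) + 1)
  sid <- cumsum(unzz(v[ns + seq_len(ns)]))
  len <- unzz(v[3 * ns + seq_len(ns)]) + params$segment_size + params$k
  cbind(gid = gid, sid = sid, rc = v[2 * ns + seq_len(ns)],
        len = len, ov = v[4 * ns + seq_len(ns)])
}

serialize_meta <- function(ar) {
  p <- ar$params
  chunks <- list(
    vint(ARCHIVE_VERSION),
    vint(c(p$k, p$segment_size, p$block_size, as.numeric(p$adaptive),
           p$min_match, p$mmer, 1, 2)),      # spt-0 hash id, frame codec id
    vint(length(ar$splitters)),
    cpp_kmers_pack(ar$splitters, p$k),
    vint(length(ar$groups)))
  for (g in ar$groups) {
    kind <- match(g$kind, c("pair", "single", "bucket")) - 1L
    b <- if (is.na(g$b)) 0 else g$b - 1
    a <- if (g$kind == "bucket") g$a else g$a - 1
    chunks[[length(chunks) + 1L]] <-
      vint(c(kind, a, b, g$ref_len, g$ref_frame[1], g$ref_frame[2],
             g$n_members, length(g$blocks)))
    chunks[[length(chunks) + 1L]] <- vstr(g$ref_symbols)
    for (blk in g$blocks)
      chunks[[length(chunks) + 1L]] <-
        vint(c(blk$off, blk$size, blk$count, blk$ends))
    if (!is.null(g$tail_frame)) {
      chunks[[length(chunks) + 1L]] <-
        vint(c(1, g$tail_frame[1], g$tail_frame[2], g$tail_count, g$tail_ends))
    } else {
      chunks[[length(chunks) + 1L]] <- vint(0)
    }
  }
  chunks[[length(chunks) + 1L]] <- vint(length(ar$samples))
  for (smp in ar$samples) {
    chunks[[length(chunks) + 1L]] <- vstr(smp$name)
    chunks[[length(chunks) + 1L]] <- vint(length(smp$contigs))
    for (ctg in smp$contigs) {
      chunks[[length(chunks) + 1L]] <- vstr(ctg$name)
      chunks[[length(chunks) + 1L]] <- vint(encode_recs(ctg$recs, p))
    }
  }
  chunks[[length(chunks) + 1L]] <- vint(ar$immutable_end)
  do.call(c, chunks)
}

deserialize_meta <- function(ar, raw) {
  at <- 0
  rd <- function(n) {
    d <- cpp_leb128_decode(raw, at, n)
    at <<- d$at
    d$values
  }
  rstr <- function() {
    n <- rd(1L)
    s <- rawToChar(raw[(at + 1):(at + n)])
    at <<- at + n
    s
  }
  version <- rd(1L)
  if (version != ARCHIVE_VERSION)
    stop("archive format version ", version, " not supported (expected ",
         ARCHIVE_VERSION, ")")
  pv <- rd(8L)
  ar$params <- pgarc_params(k = pv[1], segment_size = pv[2], block_size = pv[3],
                            adaptive = pv[4] == 1, min_match = pv[5],
                            mmer = pv[6])
  nspl <- rd(1L)
  kraw <- raw[(at + 1):(at + 8 * nspl)]
  if (nspl == 0) kraw <- raw(0)
  at <- at + 8 * nspl
  register_splitters(ar, cpp_kmers_unpack(kraw, ar$params$k))
  ngroups <- rd(1L)
  for (gi in seq_len(ngroups)) {
    h <- rd(8L)
    kind <- c("pair", "single", "bucket")[h[1] + 1]
    a <- if (kind == "bucket") h[2] else as.integer(h[2]) + 1L
    b <- if (kind == "pair") as.integer(h[3]) + 1L else NA_integer_
    g <- new.env(parent = emptyenv())
    g$id <- gi
    g$kind <- kind
    g$a <- a
    g$b <- b
    g$ref_seq <- NULL
    g$ref_len <- h[4]
    g$ref_frame <- c(h[5], h[6])
    g$n_members <- as.integer(h[7])
    g$ref_symbols <- rstr()
    nb <- h[8]
    g$blocks <- vector("list", nb)
    for (bi in seq_len(nb)) {
      hh <- rd(3L)
      ends <- rd(hh[3])
      g$blocks[[bi]] <- list(off = hh[1], size = hh[2], count = hh[3],
                             ends = ends, comp = NULL)
    }
    tf <- rd(1L)
    g$tail_streams <- list()
    if (tf == 1) {
      hh <- rd(3L)
      g$tail_frame <- c(hh[1], hh[2])
      g$tail_count <- as.integer(hh[3])
      g$tail_ends <- rd(hh[3])
    } else {
      g$tail_frame <- NULL
      g$tail_count <- 0L
      g$tail_ends <- numeric(0)
    }
    ar$groups[[gi]] <- g
    key <- switch(kind, pair = paste0("P", a, "_", b),
                  single = NA_character_, bucket = paste0("B", a))
    if (!is.na(key)) assign(key, gi, envir = ar$group_keys)
    if (kind %in% c("pair", "single")) {
      ka <- as.character(a)
      ar$by_splitter[[ka]] <- c(ar$by_splitter[[ka]], gi)
      if (kind == "pair" && b != a) {
        kb <- as.character(b)
        ar$by_splitter[[kb]] <- c(ar$by_splitter[[kb]], gi)
      }
    }
  }
  nsamples <- rd(1L)
  for (si in seq_len(nsamples)) {
    name <- rstr()
    nctg <- rd(1L)
    contigs <- vector("list", nctg)
    for (ci in seq_len(nctg)) {
      cname <- rstr()
      ns <- rd(1L)
      v <- rd(5 * ns)
      recs <- decode_recs(v, ns, ar$params)
      contigs[[ci]] <- list(name = cname,
                            len = sum(recs[, "len"] - recs[, "ov"]),
                            recs = recs)
    }
    ar$samples[[si]] <- list(name = name, contigs = contigs)
    assign(name, si, envir = ar$sample_ids)
  }
  ar$immutable_end <- rd(1L)
  invisible(ar)
}

# ------------------------------------------------------------------ sealing --

#' Seal an open archive to disk
#'
#' Compresses and writes all pending frames (new group references, newly
#' filled blocks), writes the tail (open) blocks, the xz-compressed metadata
#' section and the footer.  Sealed frames written by earlier seals are never
#' rewritten: appending truncates the file after them and continues.  The
#' archive object remains open for further [add_genome()] calls.
#'
#' @param ar an open archive
#' @return the archive, invisibly
#' @export
archive_seal <- function(ar) {
  if (ar$mode == "read") stop("archive is open read-only")
  cursor <- ar$immutable_end
  pend_off <- numeric(0)
  pend_raw <- list()
  push <- function(comp) {
    pend_off[length(pend_off) + 1L] <<- cursor
    pend_raw[[length(pend_raw) + 1L]] <<- comp
    cursor <<- cursor + length(comp)
  }
  for (g in ar$groups) {
    if (is.null(g$ref_frame)) {
      p <- cpp_pack_seq(g$ref_seq)
      g$ref_symbols <- p$symbols
      comp <- memCompress(p$bytes, "xz")
      g$ref_frame <- c(cursor, length(comp))
      push(comp)
    }
    for (bi in seq_along(g$blocks)) {
      blk <- g$blocks[[bi]]
      if (!is.null(blk$comp)) {
        blk$off <- cursor
        push(blk$comp)
        blk$comp <- NULL
        g$blocks[[bi]] <- blk
      }
    }
  }
  new_immutable_end <- cursor
  for (g in ar$groups) {
    if (length(g$tail_streams) > 0L) {
      lens <- vapply(g$tail_streams, length, 0L)
      comp <- memCompress(do.call(c, g$tail_streams), "xz")
      g$tail_frame <- c(cursor, length(comp))
      g$tail_count <- length(lens)
      g$tail_ends <- as.numeric(cumsum(lens))
      push(comp)
    } else if (!is.null(g$tail_frame)) {
      # untouched on-disk tail: carry the compressed bytes over verbatim
      comp <- read_file_raw(ar$path, g$tail_frame[1], g$tail_frame[2])
      g$tail_frame <- c(cursor, length(comp))
      push(comp)
    }
  }
  old_end <- ar$immutable_end
  ar$immutable_end <- new_immutable_end
  meta_off <- cursor
  meta <- memCompress(serialize_meta(ar), "xz")
  fresh <- ar$mode == "create"
  con <- file(ar$path, open = if (fresh) "wb" else "r+b")
  on.exit(close(con))
  if (fresh) {
    writeBin(charToRaw(ARCHIVE_MAGIC), con)
  } else {
    seek(con, old_end, rw = "write")
    truncate(con)
  }
  for (comp in pend_raw) writeBin(comp, con)
  writeBin(meta, con)
  writeBin(as.numeric(meta_off), con, size = 8, endian = "little")
  writeBin(as.numeric(length(meta)), con, size = 8, endian = "little")
  writeBin(charToRaw(ARCHIVE_MAGIC), con)
  ar$mode <- "append"
  rm(list = ls(ar$cache), envir = ar$cache)
  invisible(ar)
}

# ------------------------------------------------------------------ opening --

open_archive_env <- function(path, mode) {
  if (!file.exists(path)) stop("archive not found: ", path)
  sz <- file.size(path)
  if (sz < 8 + 24) stop("truncated archive: ", path)
  head <- read_file_raw(path, 0, 8)
  if (!identical(rawToChar(head), ARCHIVE_MAGIC))
    stop("not a pgarc archive (bad magic): ", path)
  foot <- read_file_raw(path, sz - 24, 24)
  if (!identical(rawToChar(foot[17:24]), ARCHIVE_MAGIC))
    stop("corrupt archive footer: ", path)
  meta_off <- readBin(foot[1:8], "numeric", size = 8, endian = "little")
  meta_size <- readBin(foot[9:16], "numeric", size = 8, endian = "little")
  if (meta_off + meta_size + 24 != sz)
    stop("corrupt archive: metadata section does not reach the footer")
  meta <- memDecompress(read_file_raw(path, meta_off, meta_size), "xz")
  ar <- new_archive_env(path, pgarc_params(), mode)
  deserialize_meta(ar, meta)
  ar
}

#' Open a sealed archive read-only
#'
#' Loads the header, metadata and group directory; compressed frames are
#' read and decompressed lazily as queries touch them.
#'
#' @param path archive path
#' @return an open archive object
#' @export
archive_open <- function(path) open_archive_env(path, "read")

#' Open a sealed archive for appending
#'
#' Like [archive_open()], but subsequent [add_genome()] calls are allowed;
#' each group's open (tail) block is decompressed lazily on first touch.
#' Sealed frames of the existing archive are never rewritten.
#'
#' @param path archive path
#' @return an open archive object
#' @export
archive_open_append <- function(path) open_archive_env(path, "append")
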