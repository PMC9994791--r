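# FASTA ingestion and emission.  A "genome" is a named character vector of
# upper-cased contig sequences; a collection is a named list of genomes.

#' Read a genome from a FASTA file
#'
#' Reads a (possibly gzipped) multi-record FASTA file.  The contig name is
#' the first whitespace-delimited token of each header; sequences are
#' upper-cased and validated against the IUPAC alphabet.
#'
#' @param path path to a FASTA file (plain or gzipped)
#' @return named character vector of contig sequences
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file has no records: ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig name in ", path, ": ",
         names(seqs)[duplicated(names(seqs))][1L])
  ingest_sequence(seqs)
}

#' Write a genome to a FASTA file
#'
#' Emits 80-column FASTA, one record per contig, in the given order.
#'
#' @param genome named character vector of contig sequences
#' @param path output path; `""` writes to stdout
#' @return the path, invisibly
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::BStringSet(genome)
  if (identical(path, "") || identical(path, "-")) {
    con <- stdout()
    for (i in seq_along(genome)) {
      writeLines(paste0(">", names(genome)[i]), con)
      s <- genome[[i]]
      n <- nchar(s)
      if (n > 0L)
        writeLines(substring(s, seq(1L, n, 80L), pmin(seq(1L, n, 80L) + 79L, n)), con)
    }
  } else {
    Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  }
  invisible(path)
}

# Derive a sample name from a FASTA path: basename minus .fa/.fasta/.fna/.gz.
sample_name_from_path <- function(path) {
  b <- basename(path)
  b <- sub("\\.gz$", "", b)
  sub("\\.(fa|fasta|fna)$", "", b)
}

# Accept a genome object or a FASTA path.
as_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x))
    return(read_fasta(x))
  if (!is.character(x) || is.null(names(x)) || any(names(x) == ""))
    stop("a genome must be a named character vector of contigs or a FASTA path")
  ingest_sequence(x)
}
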