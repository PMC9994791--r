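# Synthetic pangenome collections with controlled divergence: a random
# reference plus mutated copies (SNPs, short indels, block inversions,
# translocations), fragmented into contigs, with optional lower-case and N
# runs and IUPAC ambiguity codes.  Generation is a pure function of the
# spec: one global RNG stream, event order pinned (SNPs -> indels ->
# inversions -> translocations -> fragmentation -> casing/N runs).

#' Specification of a synthetic collection
#'
#' Rates are per base of the reference.  Indel, inversion and translocation
#' lengths are geometric with the stated means.  Each sample is fragmented
#' into contigs at a uniform 0..`max_breakpoints` random breakpoints.
#' `lowercase_fraction` of each sample is soft-masked in runs;
#' `n_run_rate`/`n_run_len` overwrite runs with N; `ambig_rate` substitutes
#' single bases with IUPAC ambiguity codes.  Defaults emulate a
#' bacterial-scale collection of near-identical haplotype assemblies
#' (1 Mb, 10 samples, 0.1% SNP divergence).
#'
#' @param seed RNG seed; generation is deterministic given the spec
#' @param ref_len reference length in bases
#' @param n_samples number of derived samples
#' @param snp_rate substitution probability per base
#' @param indel_rate indel event probability per base
#' @param indel_mean mean indel length (geometric, >= 1)
#' @param inversion_rate inversion event probability per base
#' @param inversion_len mean inverted block length
#' @param translocation_rate translocation event probability per base
#' @param translocation_len mean translocated block length
#' @param max_breakpoints contig fragmentation: breakpoints drawn uniformly
#'   from 0..max_breakpoints per sample
#' @param lowercase_fraction fraction of bases soft-masked (lower-cased)
#' @param n_run_rate N-run event probability per base
#' @param n_run_len mean N-run length
#' @param ambig_rate IUPAC ambiguity substitution probability per base
#' @return an object of class `pgarc_sim_spec`
#' @export
sim_spec <- function(seed = 1L, ref_len = 1e6, n_samples = 10L,
                     snp_rate = 0.001, indel_rate = 1e-4, indel_mean = 3,
                     inversion_rate = 2e-6, inversion_len = 1000,
                     translocation_rate = 1e-6, translocation_len = 1000,
                     max_breakpoints = 4L, lowercase_fraction = 0.02,
                     n_run_rate = 2e-6, n_run_len = 200,
                     ambig_rate = 1e-5) {
  spec <- list(seed = as.integer(seed), ref_len = as.numeric(ref_len),
               n_samples = as.integer(n_samples), snp_rate = snp_rate,
               indel_rate = indel_rate, indel_mean = indel_mean,
               inversion_rate = inversion_rate, inversion_len = inversion_len,
               translocation_rate = translocation_rate,
               translocation_len = translocation_len,
               max_breakpoints = as.integer(max_breakpoints),
               lowercase_fraction = lowercase_fraction,
               n_run_rate = n_run_rate, n_run_len = n_run_len,
               ambig_rate = ambig_rate)
  rates <- c(spec$snp_rate, spec$indel_rate, spec$inversion_rate,
             spec$translocation_rate, spec$lowercase_fraction,
             spec$n_run_rate, spec$ambig_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  if (spec$ref_len < 1) stop("ref_len must be positive")
  if (spec$indel_mean < 1 || spec$indel_mean >= spec$ref_len)
    stop("indel_mean must be in [1, ref_len)")
  structure(spec, class = "pgarc_sim_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rgeom_len <- function(n, mean) {
  if (n == 0L) return(numeric(0))
  1 + stats::rgeom(n, 1 / max(mean, 1))
}

# Splice `repl` over positions [at, at + remove - 1] of s (1-based).
splice <- function(s, at, remove, repl) {
  paste0(substr(s, 1, at - 1), repl, substr(s, at + remove, nchar(s)))
}

mutate_sequence <- function(ref, spec, events = NULL) {
  s <- ref
  n <- nchar(s)
  truth <- list()
  # SNPs (transversion-free uniform choice among the 3 alternatives)
  nsnp <- stats::rbinom(1, n, spec$snp_rate)
  if (nsnp > 0) {
    pos <- sort(sample.int(n, nsnp))
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    bases <- c("A", "C", "G", "T")
    old <- match(x[pos], bases)
    x[pos] <- bases[((old - 1 + sample(1:3, nsnp, replace = TRUE)) %% 4) + 1]
    s <- paste(x, collapse = "")
    truth$snp <- pos
  }
  # indels
  nind <- stats::rbinom(1, n, spec$indel_rate)
  if (nind > 0) {
    pos <- sort(sample.int(nchar(s), nind), decreasing = TRUE)
    lens <- rgeom_len(nind, spec$indel_mean)
    ins <- stats::runif(nind) < 0.5
    for (i in seq_len(nind)) {
      if (ins[i]) s <- splice(s, pos[i], 0, random_dna(lens[i]))
      else s <- splice(s, pos[i], min(lens[i], nchar(s) - pos[i] + 1), "")
    }
    truth$indel <- data.frame(pos = pos, len = lens, insertion = ins)
  }
  # inversions
  ninv <- stats::rpois(1, nchar(s) * spec$inversion_rate)
  if (ninv > 0) {
    for (i in seq_len(ninv)) {
      len <- min(rgeom_len(1, spec$inversion_len), nchar(s) %/% 2)
      at <- sample.int(max(nchar(s) - len, 1), 1)
      block <- substr(s, at, at + len - 1)
      s <- splice(s, at, len, cpp_revcomp(block))
      truth$inversion <- rbind(truth$inversion, data.frame(pos = at, len = len))
    }
  }
  # translocations
  ntr <- stats::rpois(1, nchar(s) * spec$translocation_rate)
  if (ntr > 0) {
    for (i in seq_len(ntr)) {
      len <- min(rgeom_len(1, spec$translocation_len), nchar(s) %/% 2)
      at <- sample.int(max(nchar(s) - len, 1), 1)
      block <- substr(s, at, at + len - 1)
      s <- splice(s, at, len, "")
      to <- sample.int(nchar(s) + 1, 1)
      s <- splice(s, to, 0, block)
      truth$translocation <- rbind(truth$translocation,
                                   data.frame(from = at, to = to, len = len))
    }
  }
  list(seq = s, truth = truth)
}

fragment_sequence <- function(s, nbp, prefix) {
  n <- nchar(s)
  if (nbp == 0L || n < 2) {
    out <- s
    names(out) <- paste0(prefix, "_ctg1")
    return(out)
  }
  bp <- sort(unique(sample.int(n - 1, min(nbp, n - 1))))
  starts <- c(1, bp + 1)
  ends <- c(bp, n)
  out <- substring(s, starts, ends)
  names(out) <- paste0(prefix, "_ctg", seq_along(out))
  out
}

apply_masking <- function(ctg, spec) {
  n <- nchar(ctg)
  # N runs
  nrun <- stats::rpois(1, n * spec$n_run_rate)
  if (nrun > 0) {
    for (i in seq_len(nrun)) {
      len <- min(rgeom_len(1, spec$n_run_len), n)
      at <- sample.int(max(n - len + 1, 1), 1)
      substr(ctg, at, at + len - 1) <- strrep("N", len)
    }
  }
  # IUPAC ambiguity codes at single positions
  namb <- stats::rbinom(1, n, spec$ambig_rate)
  if (namb > 0) {
    pos <- sample.int(n, namb)
    codes <- sample(c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V"),
                    namb, replace = TRUE)
    for (i in seq_len(namb)) substr(ctg, pos[i], pos[i]) <- codes[i]
  }
  # lower-case runs totalling about lowercase_fraction of the contig
  target <- n * spec$lowercase_fraction
  covered <- 0
  while (covered < target) {
    len <- min(rgeom_len(1, 500), n)
    at <- sample.int(max(n - len + 1, 1), 1)
    run <- substr(ctg, at, at + len - 1)
    substr(ctg, at, at + len - 1) <- tolower(run)
    covered <- covered + len
  }
  ctg
}

#' Simulate a pangenome collection
#'
#' Generates a uniform random ACGT reference of the stated length plus
#' `n_samples` mutated copies per the spec's rates, each fragmented into
#' contigs, optionally soft-masked and N-run/ambiguity decorated.  Output is
#' deterministic given the spec (one global RNG stream, pinned event order).
#'
#' @param spec a [sim_spec()] object
#' @return list with `reference` (named character vector), `samples` (named
#'   list of genomes `S01`, `S02`, ...) and `truth` (per-sample applied
#'   events)
#' @export
simulate_collection <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "pgarc_sim_spec"))
  set.seed(spec$seed)
  reference <- c(ref_ctg1 = random_dna(spec$ref_len))
  samples <- vector("list", spec$n_samples)
  truth <- vector("list", spec$n_samples)
  nm <- sprintf("S%02d", seq_len(spec$n_samples))
  for (i in seq_len(spec$n_samples)) {
    mut <- mutate_sequence(reference[[1]], spec)
    nbp <- sample.int(spec$max_breakpoints + 1L, 1) - 1L
    ctgs <- fragment_sequence(mut$seq, nbp, nm[i])
    for (j in seq_along(ctgs)) ctgs[j] <- apply_masking(ctgs[j], spec)
    samples[[i]] <- ctgs
    mut$truth$breakpoints <- nbp
    truth[[i]] <- mut$truth
  }
  names(samples) <- nm
  names(truth) <- nm
  list(reference = reference, samples = samples, truth = truth)
}

#' Simulate a two-clade collection
#'
#' Two references at the stated mutual divergence (substitutions at rate
#' `divergence_between`, plus the spec's indel process); half the samples
#' derive from each.  Only the clade-A reference is meant to be passed to
#' [create_archive()], which makes the clade-B half exercise the adaptive
#' splitter extension.  `divergence_between = 0` degenerates to a single
#' clade.
#'
#' @param spec a [sim_spec()] object; `n_samples` counts both clades
#' @param divergence_between substitution rate between the clade references
#' @return list with `reference` (clade A), `reference_b`, `samples` (clade
#'   A samples first) and `clade` (a factor labelling each sample)
#' @export
two_clade_collection <- function(spec = sim_spec(), divergence_between = 0.3) {
  stopifnot(inherits(spec, "pgarc_sim_spec"))
  if (divergence_between < 0 || divergence_between > 1)
    stop("divergence_between must be in [0, 1]")
  set.seed(spec$seed)
  ref_a <- random_dna(spec$ref_len)
  ref_b <- if (divergence_between == 0) ref_a else {
    bspec <- spec
    bspec$snp_rate <- divergence_between
    mutate_sequence(ref_a, bspec)$seq
  }
  n_a <- ceiling(spec$n_samples / 2)
  n_b <- spec$n_samples - n_a
  nm <- sprintf("S%02d", seq_len(spec$n_samples))
  samples <- vector("list", spec$n_samples)
  for (i in seq_len(spec$n_samples)) {
    base <- if (i <= n_a) ref_a else ref_b
    mut <- mutate_sequence(base, spec)
    nbp <- sample.int(spec$max_breakpoints + 1L, 1) - 1L
    samples[[i]] <- fragment_sequence(mut$seq, nbp, nm[i])
  }
  names(samples) <- nm
  list(reference = c(refA_ctg1 = ref_a),
       reference_b = c(refB_ctg1 = ref_b),
       samples = samples,
       clade = factor(rep(c("A", "B"), c(n_a, n_b))))
}
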