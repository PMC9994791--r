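# Shared fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

rnd_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Many random fixed-length sequences, cut from one long random string.
rnd_dna_many <- function(count, len) {
  long <- rnd_dna(count * len)
  substring(long, seq(1, count * len, len), seq(len, count * len, len))
}

# Independent oracle for candidate k-mers: enumerate every window by
# substring, canonicalize via the complement table, count, keep singletons.
oracle_candidates <- function(contigs, k) {
  kmers <- unlist(lapply(contigs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0L) return(character(0))
  canon <- pmin(kmers, reverse_complement(kmers))
  tab <- table(canon)
  sort(names(tab)[tab == 1])
}

# A small mutated collection plus archives built from it, shared by the
# archive/query tests.
fx_small_sim <- function() fx("small_sim", function() {
  simulate_collection(sim_spec(seed = 101, ref_len = 40000, n_samples = 4,
                               snp_rate = 0.002, indel_rate = 2e-4,
                               max_breakpoints = 2, lowercase_fraction = 0.05,
                               n_run_rate = 5e-5, n_run_len = 60,
                               ambig_rate = 5e-5))
})

fx_small_params <- function() pgarc_params(k = 17, segment_size = 2000,
                                           block_size = 5)

fx_small_archive <- function() fx("small_archive", function() {
  sim <- fx_small_sim()
  path <- tempfile(fileext = ".pgarc")
  pgarc_create(path, sim$reference, sim$samples, params = fx_small_params(),
               reference_name = "ref")
  path
})

expect_genome_equal <- function(got, genome) {
  want <- ingest_sequence(genome)
  expect_identical(unname(got), unname(want))
  expect_identical(names(got), names(want))
}
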