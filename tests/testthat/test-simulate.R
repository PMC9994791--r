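test_that("a mutation-free sample is the reference split into contigs", {
  spec <- sim_spec(seed = 70, ref_len = 10000, n_samples = 2, snp_rate = 0,
                   indel_rate = 0, inversion_rate = 0, translocation_rate = 0,
                   max_breakpoints = 1, lowercase_fraction = 0,
                   n_run_rate = 0, ambig_rate = 0)
  sim <- simulate_collection(spec)
  for (smp in sim$samples) {
    expect_lte(length(smp), 2L)
    expect_identical(paste(smp, collapse = ""), sim$reference[[1]])
  }
})

test_that("substitution counts follow the binomial expectation", {
  spec <- sim_spec(seed = 71, ref_len = 2e5, n_samples = 3, snp_rate = 0.001,
                   indel_rate = 0, inversion_rate = 0, translocation_rate = 0,
                   max_breakpoints = 0, lowercase_fraction = 0,
                   n_run_rate = 0, ambig_rate = 0)
  sim <- simulate_collection(spec)
  expected <- 2e5 * 0.001
  sigma <- sqrt(2e5 * 0.001 * 0.999)
  for (i in seq_along(sim$samples)) {
    smp <- sim$samples[[i]][[1]]
    diffs <- sum(strsplit(smp, "")[[1]] != strsplit(sim$reference[[1]], "")[[1]])
    expect_lt(abs(diffs - expected), 3 * sigma + 1)
    # the truth table pinpoints the substituted positions exactly
    expect_identical(which(strsplit(smp, "")[[1]] !=
                           strsplit(sim$reference[[1]], "")[[1]]),
                     sort(sim$truth[[i]]$snp))
  }
})

test_that("generation is deterministic, down to FASTA bytes", {
  spec <- sim_spec(seed = 72, ref_len = 20000, n_samples = 2)
  s1 <- simulate_collection(spec)
  s2 <- simulate_collection(spec)
  expect_identical(s1, s2)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(s1$samples$S01, f1)
  write_fasta(s2$samples$S01, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("generated genomes exercise the full ingestion alphabet", {
  spec <- sim_spec(seed = 73, ref_len = 50000, n_samples = 2,
                   lowercase_fraction = 0.1, n_run_rate = 1e-4,
                   n_run_len = 50, ambig_rate = 1e-3)
  sim <- simulate_collection(spec)
  all_seq <- paste(unlist(sim$samples), collapse = "")
  expect_true(grepl("[acgt]", all_seq))          # soft-masked runs
  expect_true(grepl("NN", all_seq))              # N runs
  expect_true(grepl("[RYSWKMBDHV]", all_seq))    # ambiguity codes
  expect_no_error(ingest_sequence(unlist(sim$samples)))
})

test_that("two-clade references are as divergent as requested", {
  spec <- sim_spec(seed = 74, ref_len = 30000, n_samples = 4,
                   snp_rate = 0.001, max_breakpoints = 0)
  tc0 <- two_clade_collection(spec, divergence_between = 0)
  expect_identical(tc0$reference[[1]], tc0$reference_b[[1]])
  tc <- two_clade_collection(spec, divergence_between = 0.3)
  k <- 31
  kmers <- function(s) unique(canonical_kmer(
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))))
  ka <- kmers(tc$reference[[1]])
  kb <- kmers(tc$reference_b[[1]])
  expect_lt(length(intersect(kb, ka)) / length(kb), 0.01)
  expect_identical(tc, two_clade_collection(spec, divergence_between = 0.3))
})

test_that("impossible specifications are rejected", {
  expect_error(sim_spec(snp_rate = 1.5), "rates")
  expect_error(sim_spec(ref_len = 100, indel_mean = 200), "indel_mean")
  expect_error(two_clade_collection(sim_spec(), 2), "divergence")
})
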