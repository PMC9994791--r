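test_that("a reference-only archive round-trips, upper-cased", {
  set.seed(40)
  ref <- c(chr1 = tolower(rnd_dna(5000)), chr2 = rnd_dna(3000))
  path <- tempfile()
  pgarc_create(path, ref, params = pgarc_params(k = 17, segment_size = 1000,
                                                block_size = 5),
               reference_name = "ref")
  got <- get_sample(path, "ref")
  expect_genome_equal(got, ref)
})

test_that("unspecified parameters default to k=31, s=60000, b=50", {
  set.seed(41)
  path <- tempfile()
  pgarc_create(path, c(ctg = rnd_dna(2000)), reference_name = "ref")
  pr <- archive_open(path)$params
  expect_identical(pr$k, 31L)
  expect_identical(pr$segment_size, 60000L)
  expect_identical(pr$block_size, 50L)
  expect_false(pr$adaptive)
})

test_that("identical inputs produce byte-identical archives", {
  sim <- fx_small_sim()
  a1 <- tempfile(); a2 <- tempfile()
  for (a in c(a1, a2))
    pgarc_create(a, sim$reference, sim$samples, params = fx_small_params(),
                 reference_name = "ref")
  expect_identical(readBin(a1, "raw", file.size(a1)),
                   readBin(a2, "raw", file.size(a2)))
})

test_that("duplicate sample names and unreadable FASTA are rejected", {
  set.seed(42)
  ref <- c(ctg = rnd_dna(2000))
  path <- tempfile()
  ar <- create_archive(path, ref, fx_small_params(), "ref")
  expect_error(add_genome(ar, c(c1 = "ACGT"), "ref"), "duplicate sample.*ref")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("the header round-trips through seal and reopen", {
  set.seed(43)
  ref <- c(ctg = rnd_dna(20000))
  p <- pgarc_params(k = 17, segment_size = 1500, block_size = 7)
  path <- tempfile()
  ar <- create_archive(path, ref, p, "ref")
  archive_seal(ar)
  re <- archive_open(path)
  expect_identical(re$params, p)
  expect_identical(re$splitters, ar$splitters)
  expect_identical(list_samples(re), "ref")
  expect_error(archive_open(tempfile()), "not found")
})

test_that("all frame offsets stay within the file", {
  path <- fx_small_archive()
  ar <- archive_open(path)
  sz <- file.size(path)
  for (g in ar$groups) {
    expect_lte(g$ref_frame[1] + g$ref_frame[2], sz)
    expect_gte(g$ref_frame[1], 8)
    for (blk in g$blocks) expect_lte(blk$off + blk$size, sz)
    if (!is.null(g$tail_frame))
      expect_lte(g$tail_frame[1] + g$tail_frame[2], sz)
  }
  expect_lte(ar$immutable_end, sz)
})

test_that("groups with empty open blocks write no tail frames", {
  set.seed(44)
  ref <- c(ctg = rnd_dna(20000))
  path <- tempfile()
  # block_size 1 seals every description immediately: no tails anywhere
  pgarc_create(path, ref, list(S = ref), reference_name = "ref",
               params = pgarc_params(k = 17, segment_size = 1500,
                                     block_size = 1))
  ar <- archive_open(path)
  expect_true(all(vapply(ar$groups, function(g) is.null(g$tail_frame), NA)))
})

test_that("batch create and create+append yield identical collections", {
  sim <- fx_small_sim()
  p <- fx_small_params()
  a_all <- tempfile(); a_inc <- tempfile()
  pgarc_create(a_all, sim$reference, sim$samples, params = p,
               reference_name = "ref")
  pgarc_create(a_inc, sim$reference, sim$samples[1:2], params = p,
               reference_name = "ref")
  pre <- archive_open(a_inc)
  sealed_end <- pre$immutable_end
  pre_bytes <- readBin(a_inc, "raw", sealed_end)
  pgarc_append(a_inc, sim$samples[3:4])
  # sealed frames of the pre-append archive are byte-unchanged
  expect_identical(readBin(a_inc, "raw", sealed_end), pre_bytes)
  expect_identical(get_collection(a_all), get_collection(a_inc))
})

test_that("resealing without new genomes leaves the content unchanged", {
  path <- fx_small_archive()
  tmp <- tempfile()
  file.copy(path, tmp)
  before <- get_collection(tmp)
  archive_seal(archive_open_append(tmp))
  expect_identical(get_collection(tmp), before)
})

test_that("appending works across multiple seal generations", {
  sim <- fx_small_sim()
  p <- fx_small_params()
  path <- tempfile()
  pgarc_create(path, sim$reference, params = p, reference_name = "ref")
  for (nm in names(sim$samples)) {
    smp <- list(sim$samples[[nm]])
    names(smp) <- nm
    pgarc_append(path, smp)
  }
  col <- get_collection(path)
  expect_identical(length(col), 5L)
  for (nm in names(sim$samples))
    expect_genome_equal(col[[nm]], sim$samples[[nm]])
})

test_that("read-only archives refuse modification", {
  path <- fx_small_archive()
  ar <- archive_open(path)
  expect_error(add_genome(ar, c(c1 = "ACGT"), "new"), "read-only")
  expect_error(archive_seal(ar), "read-only")
})
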