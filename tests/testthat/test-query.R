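test_that("range queries equal slices of the full contig", {
  set.seed(50)
  path <- fx_small_archive()
  ar <- archive_open(path)
  col <- get_collection(ar)
  for (smp in names(col)) {
    for (ctg in names(col[[smp]])) {
      full <- col[[smp]][[ctg]]
      expect_identical(get_contig(ar, smp, ctg), full)
      n <- nchar(full)
      for (r in 1:10) {
        a <- sample(n, 1)
        b <- min(n, a + sample(0:2000, 1))
        expect_identical(get_contig(ar, smp, ctg, a, b), substr(full, a, b))
      }
    }
  }
})

test_that("zero-length and out-of-range queries behave as documented", {
  path <- fx_small_archive()
  ar <- archive_open(path)
  lc <- list_contigs(ar)
  ctg <- lc$contig[lc$sample == "ref"][1]
  n <- nchar(get_contig(ar, "ref", ctg))
  expect_identical(get_contig(ar, "ref", ctg, 11, 10), "")
  expect_error(get_contig(ar, "ref", ctg, 0, 10), "out of bounds")
  expect_error(get_contig(ar, "ref", ctg, 1, n + 1), "out of bounds")
})

test_that("unknown names fail with nearby suggestions", {
  path <- fx_small_archive()
  ar <- archive_open(path)
  expect_error(get_sample(ar, "rev"), "unknown sample.*ref")
  expect_error(get_sample(ar, "zzzzzz"), "unknown sample")
  ctg <- list_contigs(ar, "S01")$contig[1]
  typo <- paste0(substr(ctg, 1, nchar(ctg) - 1), "X")
  expect_error(get_contig(ar, "S01", typo), "unknown contig.*did you mean")
})

test_that("listings cover all samples and contigs", {
  path <- fx_small_archive()
  sim <- fx_small_sim()
  ar <- archive_open(path)
  expect_identical(list_samples(ar), c("ref", names(sim$samples)))
  lc <- list_contigs(ar)
  expect_identical(nrow(lc),
                   1L + sum(vapply(sim$samples, length, 0L)))
  expect_identical(list_contigs(ar, "S02")$contig,
                   names(sim$samples$S02))
})

test_that("info reports consistent statistics", {
  path <- fx_small_archive()
  inf <- archive_info(path)
  expect_identical(inf$n_samples, 5L)
  expect_identical(sum(inf$groups_by_kind), inf$n_groups)
  expect_lte(inf$groups_by_kind[["bucket"]], 16L)
  expect_gt(inf$n_splitters, 0L)
  expect_identical(inf$file_size, file.size(path))
})

test_that("frames touched depend on the query, not the collection size", {
  set.seed(51)
  spec_small <- sim_spec(seed = 77, ref_len = 30000, n_samples = 3,
                         snp_rate = 0.001, max_breakpoints = 0)
  spec_big <- sim_spec(seed = 77, ref_len = 30000, n_samples = 8,
                       snp_rate = 0.001, max_breakpoints = 0)
  p <- pgarc_params(k = 17, segment_size = 2000, block_size = 50)
  touch <- function(spec) {
    sim <- simulate_collection(spec)
    path <- tempfile()
    pgarc_create(path, sim$reference, sim$samples, params = p,
                 reference_name = "ref")
    ar <- archive_open(path)
    ctg <- list_contigs(ar, "S02")$contig[1]
    reset_io_stats(ar)
    get_contig(ar, "S02", ctg, 5000, 7000)
    io_stats(ar)$frames
  }
  t_small <- touch(spec_small)
  t_big <- touch(spec_big)
  expect_identical(t_small, t_big)
  # a range inside one interior segment touches one group: ref + block frames
  expect_lte(t_small, 4)
})

test_that("per-sample extraction touches fewer frames than the collection", {
  path <- fx_small_archive()
  ar <- archive_open(path)
  reset_io_stats(ar)
  invisible(get_sample(ar, "S01"))
  one <- io_stats(ar)$frames
  reset_io_stats(ar)
  invisible(get_collection(ar))
  all <- io_stats(ar)$frames
  expect_lt(one, all)
})
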