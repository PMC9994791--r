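p_seg <- pgarc_params(k = 17, segment_size = 2000, block_size = 5)

test_that("contigs without splitter occurrences are single spt-0 segments", {
  set.seed(30)
  contig <- rnd_dna(500)
  segs <- split_contig(contig, character(0), p_seg)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$type, "spt-0")
  expect_identical(segs$start, 1L)
  expect_identical(segs$end, 500L)
  # shorter than k behaves the same
  segs2 <- split_contig("ACGT", c("ACGTACGTACGTACGTA"), p_seg)
  expect_identical(segs2$type, "spt-0")
})

test_that("one interior splitter yields two spt-1 segments sharing k bases", {
  set.seed(31)
  contig <- rnd_dna(1000)
  kmer <- canonical_kmer(substr(contig, 401, 417))
  segs <- split_contig(contig, kmer, p_seg)
  expect_identical(segs$type, c("spt-1", "spt-1"))
  expect_identical(segs$end[1] - segs$start[2] + 1L, 17L)   # k-base overlap
  expect_identical(segs$overlap, c(0L, 17L))
  expect_identical(substr(contig, segs$start[2], segs$end[1]), # shared bases
                   substr(contig, 401, 417))
})

test_that("segments reconstruct the contig when overlap prefixes are dropped", {
  set.seed(32)
  for (i in 1:15) {
    contig <- rnd_dna(sample(100:4000, 1))
    # random splitter set drawn from the contig's own k-mers
    npos <- sample(0:6, 1)
    spl <- unique(canonical_kmer(vapply(seq_len(npos), function(j) {
      a <- sample(nchar(contig) - 17, 1)
      substr(contig, a, a + 16)
    }, "")))
    segs <- split_contig(contig, spl, p_seg)
    pieces <- substring(contig, segs$start, segs$end)
    rebuilt <- paste(substring(pieces, segs$overlap + 1), collapse = "")
    expect_identical(rebuilt, contig)
    # classification is consistent with splitter presence
    expect_identical(segs$type,
                     ifelse(is.na(segs$left) & is.na(segs$right), "spt-0",
                     ifelse(is.na(segs$left) | is.na(segs$right), "spt-1",
                            "spt-2")))
  }
})

test_that("a reference re-segmented with its own splitters alternates types", {
  set.seed(33)
  ref <- c(ctg = rnd_dna(20000))
  cand <- find_candidate_kmers(ref, p_seg$k)
  spl <- determine_splitters(ref, cand, p_seg)
  segs <- split_contig(ref[[1]], spl, p_seg)
  expect_gt(nrow(segs), 5L)
  expect_identical(segs$type[1], "spt-1")
  expect_identical(segs$type[nrow(segs)], "spt-1")
  expect_true(all(segs$type[2:(nrow(segs) - 1)] == "spt-2"))
  # interior segments span successive splitters spaced >= segment_size;
  # only the one ending at the last-candidate splitter may be shorter
  inner <- segs[2:(nrow(segs) - 1), ]
  lens <- inner$end - inner$start + 1
  expect_true(all(head(lens, -1) >= p_seg$segment_size))
})

test_that("normalization brings the smaller splitter forward, idempotently", {
  set.seed(34)
  for (i in 1:20) {
    seg <- rnd_dna(200)
    left <- canonical_kmer(substr(seg, 1, 17))
    right <- canonical_kmer(substr(seg, 184, 200))
    n1 <- normalize_segment(seg, left, right)
    expect_false(pgarc:::cpp_lex_lt(n1$right, n1$left))
    # idempotence
    n2 <- normalize_segment(n1$seq, n1$left, n1$right)
    expect_identical(n2$seq, n1$seq)
    expect_false(n2$is_rc)
    # a segment and its reverse complement normalize to the same sequence
    nrc <- normalize_segment(reverse_complement(seg), right, left)
    expect_identical(nrc$seq, n1$seq)
    expect_identical(nrc$is_rc, !n1$is_rc)
  }
})

test_that("spt-1 normalization brings the splitter to the front", {
  set.seed(35)
  seg <- rnd_dna(100)
  s <- canonical_kmer(substr(seg, 84, 100))
  n <- normalize_segment(seg, left = NULL, right = s)
  expect_true(n$is_rc)
  expect_identical(n$seq, reverse_complement(seg))
  expect_identical(n$left, s)
})

test_that("equal-canonical-splitter ties pick the smaller orientation", {
  set.seed(36)
  kmer <- "ACGTTTTGGGCCCAATT"
  filler <- rnd_dna(100)
  seg <- paste0(kmer, filler, reverse_complement(kmer))
  ck <- canonical_kmer(kmer)
  n <- normalize_segment(seg, ck, ck)
  expect_identical(n$seq, min(seg, reverse_complement(seg)))
  n2 <- normalize_segment(n$seq, n$left, n$right)
  expect_identical(n2$seq, n$seq)
})

test_that("spt-0 buckets are deterministic, in range, and strand-free", {
  set.seed(37)
  seqs <- rnd_dna_many(10000, 1000)
  b1 <- spt0_bucket(seqs)
  expect_true(all(b1 >= 0 & b1 <= 15))
  expect_identical(b1, spt0_bucket(seqs))
  expect_identical(spt0_bucket(reverse_complement(seqs[1:50])), b1[1:50])
  # 10,000 random 1 kb sequences populate all 16 buckets
  expect_identical(sort(unique(b1)), 0:15)
})

test_that("a segment and its reverse complement land in the same group", {
  set.seed(38)
  ref <- c(ctg = rnd_dna(20000))
  # a reference-derived contig, lightly mutated, so segments carry splitters
  contig <- substr(ref[[1]], 3000, 9000)
  for (j in 1:5) {
    q <- sample(nchar(contig), 1)
    substr(contig, q, q) <- sample(c("A", "C", "G", "T"), 1)
  }
  p <- pgarc_params(k = 17, segment_size = 1000, block_size = 5)
  a1 <- tempfile(); a2 <- tempfile()
  pgarc_create(a1, ref, list(S = c(c1 = contig)), params = p,
               reference_name = "ref")
  pgarc_create(a2, ref, list(S = c(c1 = reverse_complement(contig))),
               params = p, reference_name = "ref")
  ar1 <- archive_open(a1); ar2 <- archive_open(a2)
  key_of <- function(ar, gid) {
    g <- ar$groups[[gid]]
    paste(g$kind, g$a, g$b)
  }
  r1 <- ar1$samples[[2]]$contigs[[1]]$recs
  r2 <- ar2$samples[[2]]$contigs[[1]]$recs
  # same group keys in reverse order, complementary orientation flags
  expect_identical(vapply(r1[, "gid"], key_of, "", ar = ar1),
                   rev(vapply(r2[, "gid"], key_of, "", ar = ar2)))
  expect_identical(unname(r1[, "rc"]), 1 - rev(unname(r2[, "rc"])))
  expect_identical(get_contig(a2, "S", "c1"), reverse_complement(contig))
})

test_that("adding the reference itself never triggers missing-splitter splits", {
  set.seed(39)
  ref <- c(c1 = rnd_dna(15000), c2 = rnd_dna(8000))
  p <- pgarc_params(k = 17, segment_size = 1000, block_size = 5)
  path <- tempfile()
  ar <- create_archive(path, ref, p, "ref")
  # no case-b splits: one record per split segment
  for (ci in 1:2) {
    recs <- ar$samples[[1]]$contigs[[ci]]$recs
    segs <- split_contig(ref[[ci]], ar$splitters, p)
    expect_identical(nrow(recs), nrow(segs))
  }
})
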