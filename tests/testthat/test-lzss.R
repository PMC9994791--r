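p_lzss <- pgarc_params()

test_that("parsing a sequence against itself yields one whole match", {
  set.seed(20)
  r <- rnd_dna(500)
  tok <- lzss_parse(r, r, p_lzss)
  df <- lzss_tokens(tok, p_lzss)
  expect_identical(nrow(df), 1L)
  expect_identical(df$type, "match")
  expect_identical(df$offset, 0)
  expect_identical(df$length, 500)
  expect_identical(lzss_decode(tok, r, p_lzss), r)
})

test_that("sequences sharing no anchor parse to literals only", {
  set.seed(21)
  s <- rnd_dna(100)
  tok <- lzss_parse(s, strrep("A", 100), p_lzss)
  df <- lzss_tokens(tok, p_lzss)
  expect_true(all(df$type == "literal"))
  expect_gte(length(tok), 100)            # literals cost >= 1 byte each
  expect_identical(lzss_decode(tok, strrep("A", 100), p_lzss), s)
})

test_that("a single substitution splits the parse into match/literal/match", {
  set.seed(22)
  r <- rnd_dna(400)
  pos <- 180
  s <- r
  old <- substr(s, pos, pos)
  substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  tok <- lzss_parse(s, r, p_lzss)
  df <- lzss_tokens(tok, p_lzss)
  expect_identical(df$type, c("match", "literal", "match"))
  expect_identical(df$offset[1], 0)
  expect_identical(df$length[2], 1)
  expect_identical(df$offset[3], pos)     # resumes right after the mismatch
  expect_identical(lzss_decode(tok, r, p_lzss), s)
})

test_that("empty inputs and corrupt streams behave as specified", {
  r <- rnd_dna(50)
  tok <- lzss_parse("", r, p_lzss)
  expect_identical(length(tok), 1L)       # terminator only
  expect_identical(lzss_decode(tok, r, p_lzss), "")
  # match window outside the reference: match at offset 0 length 120 vs 50-base ref
  bad <- c(as.raw(2), pgarc:::cpp_leb128_encode(c(0, 100)), as.raw(0))
  expect_error(lzss_decode(bad, r, p_lzss), "corrupt stream")
  expect_error(lzss_decode(as.raw(c(7, 0)), r, p_lzss), "unknown token flag")
  expect_error(lzss_decode(raw(0), r, p_lzss), "corrupt stream")
})

test_that("decode . parse is the identity on randomized pairs", {
  set.seed(23)
  for (i in 1:800) {
    r <- rnd_dna(sample(0:800, 1))
    s <- if (runif(1) < 0.4) rnd_dna(sample(0:800, 1)) else {
      x <- r
      nmut <- sample(0:5, 1)
      for (j in seq_len(min(nmut, nchar(x)))) {
        q <- sample(nchar(x), 1)
        substr(x, q, q) <- sample(c("A", "C", "G", "T"), 1)
      }
      x
    }
    tok <- lzss_parse(s, r, p_lzss)
    expect_identical(lzss_decode(tok, r, p_lzss), s)
    expect_identical(lzss_cost(s, r, p_lzss), as.numeric(length(tok)))
  }
})

test_that("greedy cost never exceeds the literal-only cost", {
  set.seed(24)
  for (i in 1:100) {
    r <- rnd_dna(sample(50:500, 1))
    s <- if (runif(1) < 0.5) r else rnd_dna(sample(50:500, 1))
    expect_lte(lzss_cost(s, r, p_lzss), lzss_cost(s, "", p_lzss))
  }
})

test_that("a matching reference is cheaper than an unrelated one", {
  set.seed(25)
  for (i in 1:30) {
    s <- rnd_dna(sample(200:600, 1))
    expect_lt(lzss_cost(s, s, p_lzss),
              lzss_cost(s, rnd_dna(nchar(s)), p_lzss))
  }
})

test_that("parses are deterministic byte for byte", {
  set.seed(26)
  r <- rnd_dna(300)
  s <- rnd_dna(300)
  expect_identical(lzss_parse(s, r, p_lzss), lzss_parse(s, r, p_lzss))
})

test_that("division point matches exhaustive minimization", {
  set.seed(27)
  exhaustive <- function(s, ra, rb) {
    n <- nchar(s)
    tot <- vapply(0:n, function(i)
      lzss_cost(substr(s, 1, i), ra, p_lzss) +
      lzss_cost(substr(s, i + 1, n), rb, p_lzss), 0)
    which.min(tot) - 1L   # which.min takes the smallest index on ties
  }
  for (i in 1:60) {
    ra <- rnd_dna(sample(30:180, 1))
    rb <- rnd_dna(sample(30:180, 1))
    s <- switch(sample(3, 1),
      paste0(ra, rb),
      { x <- paste0(ra, rb)
        for (j in 1:3) {
          q <- sample(nchar(x), 1)
          substr(x, q, q) <- sample(c("A", "C", "G", "T"), 1)
        }
        x },
      rnd_dna(sample(2:180, 1)))
    expect_identical(find_division_point(s, ra, rb, p_lzss),
                     exhaustive(s, ra, rb))
  }
})

test_that("division point lands on structural boundaries", {
  set.seed(28)
  ra <- rnd_dna(150)
  rb <- rnd_dna(150)
  # concatenation splits at the junction
  expect_identical(find_division_point(paste0(ra, rb), ra, rb, p_lzss), 150L)
  # a segment alien to refA but equal to refB splits at 0
  expect_identical(find_division_point(rb, rnd_dna(150), rb, p_lzss), 0L)
})
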