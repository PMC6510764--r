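test_that("scoring scheme validation", {
  expect_error(scoring_scheme(match = -1, mismatch = 0), "exceed")
  expect_error(scoring_scheme(gap = 1), "negative")
  expect_error(scoring_scheme(gap_open = -5, gap_extend = 1), "gap_extend")
  s <- scoring_scheme(2, -3, gap_open = -5, gap_extend = -2)
  expect_true(s$affine)
})

test_that("global alignment handles trivial and empty inputs", {
  s <- scoring_scheme(1, -1, -1)
  expect_equal(nw_align("A", "A", s)$score, 1)
  e <- nw_align("", "ACG", s)
  expect_equal(e$score, -3)
  expect_equal(e$aligned_query, "---")
  expect_equal(e$aligned_reference, "ACG")
  b <- nw_align("", "", s)
  expect_equal(b$score, 0)
})

test_that("GATTACA vs GCATGCU equals the exhaustive optimum", {
  s <- scoring_scheme(1, -1, -1)
  aln <- nw_align("GATTACA", "GCATGCU", s)
  expect_equal(aln$score, oracle_scores("GATTACA", "GCATGCU", s)$global)
  # ungapping the aligned strings recovers the inputs
  expect_equal(gsub("-", "", aln$aligned_query), "GATTACA")
  expect_equal(gsub("-", "", aln$aligned_reference), "GCATGCU")
  expect_equal(nchar(aln$aligned_query), nchar(aln$aligned_reference))
})

test_that("local alignment basics", {
  s <- scoring_scheme(1, -1, -1)
  z <- sw_align("AAA", "GGG", s)
  expect_equal(z$score, 0)
  expect_equal(z$aligned_query, "")
  f <- sw_align("ACGT", "ACGT", s)
  expect_equal(f$score, 4)
  g <- sw_align("TTACGTT", "GGACGGG", s)
  expect_equal(g$score, 3)
  expect_equal(g$aligned_query, "ACG")
  expect_equal(c(g$q_start, g$q_end), c(2, 5))
})

test_that("alignment scores match the enumeration oracle on random pairs", {
  s <- scoring_scheme(1, -1, -2)
  set.seed(91)
  for (i in 1:30) {
    a <- paste(sample(c("A", "C", "G"), sample(0:5, 1), replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G"), sample(0:5, 1), replace = TRUE), collapse = "")
    orc <- oracle_scores(a, b, s)
    expect_equal(nw_align(a, b, s)$score, orc$global,
                 info = paste(a, b, "global"))
    expect_equal(sw_align(a, b, s)$score, orc$local,
                 info = paste(a, b, "local"))
  }
})

test_that("scores agree with an independent library implementation", {
  s <- scoring_scheme(1, -1, -2)
  mat <- matrix(-1, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  diag(mat) <- 1
  set.seed(17)
  for (i in 1:10) {
    a <- random_dna(sample(3:12, 1), 500 + i)
    b <- random_dna(sample(3:12, 1), 600 + i)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    expect_equal(nw_align(a, b, s)$score, Biostrings::score(ref))
    refl <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 0, gapExtension = 2)
    expect_equal(sw_align(a, b, s)$score, Biostrings::score(refl))
  }
})

test_that("affine gap costs agree with an independent library implementation", {
  s <- scoring_scheme(2, -3, gap_open = -4, gap_extend = -1)
  mat <- matrix(-3, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  diag(mat) <- 2
  set.seed(23)
  for (i in 1:10) {
    a <- random_dna(sample(4:14, 1), 700 + i)
    b <- random_dna(sample(4:14, 1), 800 + i)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 4, gapExtension = 1)
    expect_equal(nw_align(a, b, s)$score, Biostrings::score(ref))
  }
})

test_that("alignment results are internally consistent", {
  s <- scoring_scheme(1, -1, -2)
  sa <- scoring_scheme(2, -1, gap_open = -3, gap_extend = -1)
  set.seed(41)
  for (i in 1:10) {
    a <- random_dna(sample(1:10, 1), 900 + i)
    b <- random_dna(sample(1:10, 1), 950 + i)
    for (sch in list(s, sa)) {
      g <- nw_align(a, b, sch)
      expect_equal(score_alignment(g, sch), g$score)
      l <- sw_align(a, b, sch)
      expect_equal(score_alignment(l, sch), l$score)
      expect_equal(gsub("-", "", l$aligned_query),
                   substr(a, l$q_start + 1, l$q_end))
    }
    # symmetry under swapping inputs (symmetric scheme)
    expect_equal(nw_align(a, b, s)$score, nw_align(b, a, s)$score)
    expect_equal(sw_align(a, b, s)$score, sw_align(b, a, s)$score)
    expect_gte(sw_align(a, b, s)$score, 0)
  }
})

test_that("CIGAR strings describe the alignment operations", {
  s <- scoring_scheme(1, -1, -1)
  aln <- nw_align("ACGT", "ACT", s)
  cg <- alignment_cigar(aln)
  expect_match(cg, "^([0-9]+[MID])+$")
  # total M+I consumes the query, M+D the reference
  ops <- regmatches(cg, gregexpr("[0-9]+[MID]", cg))[[1]]
  n <- as.integer(sub("[MID]", "", ops)); o <- sub("[0-9]+", "", ops)
  expect_equal(sum(n[o != "D"]), 4L)
  expect_equal(sum(n[o != "I"]), 3L)
})

test_that("banded alignment reduces to global at full band", {
  s <- scoring_scheme(1, -1, -2)
  set.seed(53)
  for (i in 1:20) {
    a <- random_dna(sample(2:12, 1), 1000 + i)
    b <- random_dna(sample(2:12, 1), 1100 + i)
    full <- banded_align(a, b, band = max(nchar(a), nchar(b)), scheme = s,
                         offset = 0L)
    expect_equal(full$score, nw_align(a, b, s)$score)
    # banded score never exceeds the unbanded score
    bd <- abs(nchar(b) - nchar(a))
    narrow <- banded_align(a, b, band = bd + 1L, scheme = s, offset = 0L)
    expect_lte(narrow$score, nw_align(a, b, s)$score + 1e-12)
  }
})

test_that("band 0 on an exact-match record gives the identity alignment", {
  s <- scoring_scheme(1, -1, -2)
  a <- random_dna(10, 1300)
  aln <- banded_align(a, a, band = 0L, scheme = s, offset = 0L)
  expect_equal(aln$score, 10)
  expect_equal(aln$aligned_query, a)
  rec <- data.frame(x0 = 5L, y0 = 0L)
  expect_error(banded_align("ACGT", "ACGT", record = rec, band = 1L, scheme = s),
               "corner")
})
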