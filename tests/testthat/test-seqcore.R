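test_that("reverse complement maps ambiguity codes and is an involution", {
  expect_equal(unname(reverse_complement("ACGT")), "ACGT")
  expect_equal(unname(reverse_complement("AAAC")), "GTTT")
  expect_equal(unname(reverse_complement("ARN")), "NYT")
  expect_error(reverse_complement("ACXG"), "position 3")
  set.seed(11)
  for (i in 1:100) {
    s <- random_dna(50)
    expect_equal(unname(reverse_complement(reverse_complement(s))), s)
  }
})

test_that("global alignment matches the affine-gap DP oracle", {
  a <- global_align("ACGT", "ACGT")
  expect_equal(a$identity, 1)
  expect_false(grepl("-", a$gapped_a, fixed = TRUE))

  a <- global_align("ACGTACGT", "ACGAACGT")
  expect_equal(a$identity, 7 / 8)

  set.seed(21)
  for (i in 1:30) {
    x <- random_dna(sample(5:12, 1))
    y <- random_dna(sample(5:12, 1))
    aln <- global_align(x, y)
    expect_equal(aln$score, oracle_affine_global_score(x, y),
                 tolerance = 1e-9, info = paste(x, y))
    # score is self-consistent with the gapped strings
    expect_equal(aln$score,
                 sinescout:::.score_from_gapped(aln$gapped_a, aln$gapped_b,
                                                aln$scoring),
                 tolerance = 1e-9)
    # stripping gaps recovers the inputs
    expect_equal(gsub("-", "", aln$gapped_a, fixed = TRUE), x)
    expect_equal(gsub("-", "", aln$gapped_b, fixed = TRUE), y)
  }
  expect_error(global_align("", "ACGT"))
})

test_that("percent identity excludes terminal overhangs and is symmetric", {
  # terminal gap columns are not counted
  a <- global_align("AAAA", "AA")
  expect_equal(a$n_columns_counted, 2L)
  expect_equal(percent_identity(a), 1)

  # one internal 1-bp gap in a 10-column core counts as a mismatch
  a <- global_align("ACGTTACGTA", "ACGTACGTA")
  expect_equal(a$n_columns_counted, 10L)
  expect_equal(percent_identity(a), 0.9)

  s <- random_dna(20)
  expect_equal(percent_identity(global_align(s, s)), 1)

  set.seed(31)
  for (i in 1:20) {
    # substitution-only relatives: the optimum is gap-free, so identity
    # is strictly symmetric; scores are symmetric for any pair
    x <- random_dna(30)
    y <- mutate_copy(x, divergence = 0.2)$copy
    expect_equal(percent_identity(global_align(x, y)),
                 percent_identity(global_align(y, x)))
    z <- random_dna(25)
    expect_equal(global_align(x, z)$score, global_align(z, x)$score)
  }
})

test_that("GC fraction counts unambiguous bases only", {
  expect_equal(gc_fraction("GGCC"), 1)
  expect_equal(gc_fraction("ATAT"), 0)
  expect_equal(gc_fraction("ACGTN"), 0.5)   # N excluded
  expect_error(gc_fraction("NNNN"), "undefined")
  set.seed(41)
  s <- random_dna(10000, gc = 0.4)
  chars <- strsplit(s, "")[[1]]
  expect_equal(gc_fraction(s), sum(chars %in% c("G", "C")) / length(chars))
  # GC + AT partition unambiguous sequence
  at <- sum(chars %in% c("A", "T")) / length(chars)
  expect_equal(gc_fraction(s) + at, 1)
})

test_that("six-frame ORF finder agrees with a regex-style enumeration", {
  # a clean 20-codon ORF on the forward strand
  s <- paste0("CC", "ATG", strrep("GCT", 20), "TAA", "GG")
  orfs <- six_frame_orfs(s, min_aa = 10)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start, 3L)
  expect_equal(orfs$end, 3L + 63L + 3L - 1L)
  expect_equal(orfs$protein, paste0("M", strrep("A", 20)))

  # no start codon anywhere
  expect_equal(nrow(six_frame_orfs(strrep("CCT", 50), min_aa = 10)), 0L)

  set.seed(51)
  for (i in 1:5) {
    s <- random_dna(3000)
    got <- six_frame_orfs(s, min_aa = 15)
    want <- oracle_orfs(s, min_aa = 15)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(unname(as.matrix(got[, c("start", "end")])),
                   unname(want))
    }
  }
})

test_that("FASTA round-trips through read and write", {
  seqs <- c(one = random_dna(150), two = random_dna(90))
  f <- tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(back, seqs)
  expect_error(dna("ACGT!"), "position 5")
})

test_that("clustal and aligned-FASTA readers return consistent alignments", {
  rows <- c(s1 = "ACGT-ACGT", s2 = "ACGTTACGT")
  fa <- tempfile(fileext = ".fa")
  write_fasta(rows, fa)
  m1 <- read_alignment(fa, "fasta")
  expect_s3_class(m1, "sine_msa")
  expect_equal(m1$width, 9L)
  cl <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (dummy)", "",
               "s1   ACGT-ACGT", "s2   ACGTTACGT"), cl)
  m2 <- read_alignment(cl, "clustal")
  expect_equal(m2$rows, m1$rows)
})
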