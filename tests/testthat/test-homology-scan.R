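make_planted_genome <- function(seed, qlen = 300, glen = 10000, at = 1000) {
  set.seed(seed)
  q <- random_dna(qlen, gc = 0.4)
  bg <- random_dna(glen, gc = 0.36)
  g <- paste0(substr(bg, 1, at), q, substr(bg, at + 1, glen))
  list(query = c(q1 = q), genome = c(chr = g),
       start = at + 1, end = at + qlen)
}

test_that("an exact planted copy is found once with perfect identity", {
  p <- make_planted_genome(101)
  hits <- scan_genome(p$query, p$genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, p$start)
  expect_equal(hits$end, p$end)
  expect_equal(hits$strand, "+")
  expect_equal(hits$identity, 1)
  expect_error(scan_genome(c(q = "ACGTACGT"), p$genome, word_size = 11),
               "shorter than word_size")
})

test_that("a diverged planted copy is recovered over >=90% of its extent", {
  p <- make_planted_genome(102)
  set.seed(103)
  mut <- mutate_copy(unname(p$query), divergence = 0.15)
  g <- paste0(substr(p$genome, 1, p$start - 1), mut$copy,
              substr(p$genome, p$end + 1, nchar(p$genome)))
  hits <- scan_genome(p$query, c(chr = g), min_identity = 0.7)
  expect_equal(nrow(hits), 1L)
  planted <- c(p$start, p$start + nchar(mut$copy) - 1)
  ov <- min(hits$end, planted[2]) - max(hits$start, planted[1]) + 1
  expect_gte(ov / (planted[2] - planted[1] + 1), 0.9)
  # identity consistent with a direct alignment of query vs planted region
  direct <- overlap_align(unname(p$query), mut$copy)
  expect_equal(hits$identity, direct$identity, tolerance = 0.05)
})

test_that("reverse-complement copies are reported with start > end", {
  p <- make_planted_genome(104)
  grc <- paste0(substr(p$genome, 1, p$start - 1),
                unname(reverse_complement(p$query)),
                substr(p$genome, p$end + 1, nchar(p$genome)))
  hits <- scan_genome(p$query, c(chr = grc))
  expect_equal(nrow(hits), 1L)
  expect_gt(hits$start, hits$end)
  expect_equal(hits$strand, "-")
  expect_equal(min(hits$start, hits$end), p$start)
  expect_equal(max(hits$start, hits$end), p$end)
})

test_that("scanning is strand-symmetric and identities are recomputable", {
  set.seed(105)
  bg <- generate_background(30000, seed = 106)
  fs <- family_spec(n_copies = 6, truncation_prob = 0,
                    divergence = 0.05, tsd_edit_prob = 0, seed = 107)
  sim <- plant_family(bg, fs, seed = 108)
  hits <- scan_genome(fs$consensus, sim$genome)
  expect_equal(nrow(hits), 6L)
  # identity invariant: recompute on the extracted region
  for (i in seq_len(nrow(hits))) {
    ex <- extract_with_flanks(
      sim$genome, genomic_location(hits$contig[i], hits$start[i], hits$end[i]),
      flank = 0)
    expect_equal(overlap_align(unname(fs$consensus), ex$element)$identity,
                 hits$identity[i], tolerance = 1e-9)
  }
  # mirror-image hit set on the reverse-complemented genome
  grc <- reverse_complement(sim$genome)
  names(grc) <- names(sim$genome)
  hits_rc <- scan_genome(fs$consensus, grc)
  expect_equal(nrow(hits_rc), nrow(hits))
  L <- nchar(sim$genome)
  mirrored_lo <- sort(L - pmax(hits$start, hits$end) + 1)
  expect_equal(sort(pmin(hits_rc$start, hits_rc$end)), mirrored_lo)
  expect_equal(sum(hits_rc$strand == "-"), sum(hits$strand == "+"))
  expect_equal(sum(hits_rc$strand == "+"), sum(hits$strand == "-"))
})

test_that("hit merging joins fragments and respects the gap bound", {
  h <- data.frame(query_id = "q", contig = "c",
                  start = c(100L, 301L), end = c(300L, 500L),
                  strand = "+", identity = c(0.9, 0.8),
                  aligned_length = c(201L, 200L), score = c(50, 40),
                  stringsAsFactors = FALSE)
  m <- merge_hits(h, max_gap = 10)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100L, 500L))
  expect_equal(m$identity, (0.9 * 201 + 0.8 * 200) / 401, tolerance = 1e-9)

  h2 <- h; h2$start[2] <- 5301L; h2$end[2] <- 5500L
  expect_equal(nrow(merge_hits(h2, max_gap = 100)), 2L)
})

test_that("extraction honors orientation and truncates at contig edges", {
  g <- c(chr = paste0(strrep("A", 90), "CCCCCCCCCC", strrep("G", 100),
                      "TTTTTTTTTT", strrep("A", 90)))
  # plus strand 101-200 with 10 bp flanks
  ex <- extract_with_flanks(g, genomic_location("chr", 101, 200), flank = 10)
  expect_equal(ex$left_flank, "CCCCCCCCCC")
  expect_equal(ex$element, strrep("G", 100))
  expect_equal(ex$right_flank, "TTTTTTTTTT")
  # minus strand: element reverse-complemented, flanks swapped + rc'd
  ex2 <- extract_with_flanks(g, genomic_location("chr", 200, 101), flank = 10)
  expect_equal(ex2$element, strrep("C", 100))
  expect_equal(ex2$left_flank, "AAAAAAAAAA")
  expect_equal(ex2$right_flank, "GGGGGGGGGG")
  # edge truncation, never padding
  ex3 <- extract_with_flanks(g, genomic_location("chr", 3, 20), flank = 10)
  expect_equal(nchar(ex3$left_flank), 2L)
  expect_error(extract_with_flanks(g, genomic_location("chr", 1, 999)),
               "outside contig")
})

test_that("tail-boundary refinement lands on the last complete unit", {
  set.seed(109)
  left <- random_dna(200, gc = 0.36)
  right <- random_dna(200, gc = 0.36)
  core <- random_dna(150, gc = 0.4)
  g <- c(chr = paste0(left, core, strrep("TGA", 8), right))
  elem_start <- 201L
  elem_end <- 200L + 150L + 24L
  # a hit that stopped 6 bp short inside the tail
  loc <- refine_tail_boundary(g, genomic_location("chr", elem_start,
                                                  elem_end - 6L),
                              unit = "TGA")
  expect_equal(loc$end, elem_end)
  # and one that overran 4 bp into the flank
  loc2 <- refine_tail_boundary(g, genomic_location("chr", elem_start,
                                                   elem_end + 4L),
                               unit = "TGA")
  # exact unless the flank happens to continue the repeat
  expect_lte(abs(loc2$end - elem_end), 3L)
})
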