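test_that("find_tsd recovers published perfect and near-perfect TSDs", {
  set.seed(201)
  # perfect 16-bp duplication flanking a truncated copy
  tsd <- "AGAGCTGAATCAGCTG"
  left <- paste0(random_dna(60), tsd)
  right <- paste0(tsd, random_dna(60))
  hit <- find_tsd(left, right)
  expect_equal(hit$left_seq, tsd)
  expect_equal(hit$right_seq, tsd)
  expect_equal(hit$length, 16L)
  expect_equal(hit$edits, 0L)
  expect_equal(hit$left_end_offset, 0L)
  expect_equal(hit$right_start_offset, 0L)

  # one-base insertion on the right copy: atcctcta(g)cagtc
  l2 <- paste0(random_dna(60), "ATCCTCTACAGTC")
  r2 <- paste0("ATCCTCTAGCAGTC", random_dna(60))
  hit2 <- find_tsd(l2, r2, max_edits = 1)
  expect_equal(hit2$length, 14L)
  expect_equal(hit2$edits, 1L)
  expect_equal(hit2$right_seq, "ATCCTCTAGCAGTC")
})

test_that("find_tsd agrees with exhaustive enumeration and is rare on noise", {
  set.seed(202)
  n_none <- 0
  for (i in 1:50) {
    l <- random_dna(50); r <- random_dna(50)
    got <- find_tsd(l, r, max_edits = 0)
    want <- oracle_tsd(l, r, max_edits = 0)
    if (is.null(want)) {
      n_none <- n_none + 1
      expect_null(got)
    } else {
      expect_equal(got$left_seq, want$left_seq)
      expect_equal(got$right_seq, want$right_seq)
      expect_equal(got$edits, want$edits)
    }
    # and with one edit allowed
    got1 <- find_tsd(l, r, max_edits = 1)
    want1 <- oracle_tsd(l, r, max_edits = 1)
    if (is.null(want1)) expect_null(got1)
    else expect_equal(got1$left_seq, want1$left_seq)
  }
  expect_gte(n_none, 45)  # chance duplications are rare on unrelated flanks
})

test_that("find_tsd is stable under distant padding and monotone in edits", {
  set.seed(203)
  tsd <- "CATTGACCAT"
  left <- paste0(random_dna(40), tsd)
  right <- paste0(tsd, random_dna(40))
  base <- find_tsd(left, right)
  padded <- find_tsd(paste0(random_dna(100), left),
                     paste0(right, random_dna(100)))
  expect_equal(base$left_seq, padded$left_seq)
  expect_equal(base$length, padded$length)
  for (i in 1:20) {
    l <- random_dna(60); r <- random_dna(60)
    len0 <- (function(x) if (is.null(x)) 0L else x$length)(
      find_tsd(l, r, max_edits = 0))
    len1 <- (function(x) if (is.null(x)) 0L else x$length)(
      find_tsd(l, r, max_edits = 1))
    expect_gte(len1, len0)
  }
})

test_that("type-2 promoter scan finds ordered boxes and mirrors the oracle", {
  set.seed(204)
  # exact box instances: A at 5, B at 45 (gap 28, inside 20-80)
  boxa <- "TGGCATAGCTTG"   # instance of TRGCNNARYNNG
  boxb <- "GTTCGAATC"      # instance of GTTCRANNC
  head <- paste0(random_dna(4), boxa, random_dna(28), boxb, random_dna(30))
  p <- scan_type2_promoter(head)
  expect_equal(p$promoter_type, "type2_AB")
  expect_true(p$spacing_ok)
  expect_equal(p$boxes$start[p$boxes$box == "A"], 5L)
  expect_equal(p$boxes$start[p$boxes$box == "B"], 45L)

  # reversed box order must not be called
  head_rev <- paste0(random_dna(4), boxb, random_dna(28), boxa,
                     random_dna(30))
  expect_equal(scan_type2_promoter(head_rev,
                                   max_mismatch = 0)$promoter_type, "none")

  # zero-mismatch scan equals the sliding-window oracle on random heads
  for (i in 1:20) {
    h <- random_dna(80)
    got <- scan_type2_promoter(h, max_mismatch = 0)
    a_hits <- oracle_iupac_hits("TRGCNNARYNNG", h, 0)
    b_hits <- oracle_iupac_hits("GTTCRANNC", h, 0)
    ordered <- length(a_hits) > 0 && length(b_hits) > 0 &&
      any(outer(a_hits + 11, b_hits, "<"))
    expect_equal(got$promoter_type != "none", ordered, info = h)
  }
})

test_that("type-1 promoter scan requires all three ordered boxes", {
  set.seed(205)
  motifs <- list(A = "GCTAAGCAGGGTC", IE = "CCTGGT", C = "GGATGGGAGACCGCC")
  head <- paste0(random_dna(6), motifs$A, random_dna(8), motifs$IE,
                 random_dna(10), motifs$C, random_dna(15))
  p <- scan_type1_promoter(head, motifs)
  expect_equal(p$promoter_type, "type1_AIEC")
  expect_true(p$spacing_ok)

  head_noc <- paste0(random_dna(6), motifs$A, random_dna(8), motifs$IE,
                     random_dna(30))
  expect_equal(scan_type1_promoter(head_noc, motifs,
                                   max_mismatch = 0)$promoter_type, "none")

  # one mismatch per box is tolerated within the allowance
  mm <- function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[3] <- setdiff(c("A", "C", "G", "T"), ch[3])[1]
    paste(ch, collapse = "")
  }
  head_mm <- paste0(random_dna(6), mm(motifs$A), random_dna(8),
                    mm(motifs$IE), random_dna(10), mm(motifs$C),
                    random_dna(15))
  expect_equal(scan_type1_promoter(head_mm, motifs,
                                   max_mismatch = 1)$promoter_type,
               "type1_AIEC")
})

test_that("head classification assigns the best reference class", {
  set.seed(206)
  trna <- c(`tRNA-Glu_sim` = random_dna(72))
  rrna <- c(`5S_rRNA_sim` = random_dna(120))
  refs <- c(trna, rrna)

  got <- classify_head(unname(trna), refs)
  expect_equal(got$head_class, "tRNA")
  expect_equal(got$head_identity, 1)
  expect_equal(got$best_reference_id, "tRNA-Glu_sim")

  # 20% diverged 5S head still classifies as 5S with identity near 0.8
  mut <- mutate_copy(unname(rrna), divergence = 0.2)
  got2 <- classify_head(mut$copy, refs)
  expect_equal(got2$head_class, "5S")
  expect_equal(got2$head_identity, 1 - mut$realized_divergence,
               tolerance = 0.06)

  # random heads fall below the default threshold
  n_unknown <- 0
  for (i in 1:20) {
    g <- classify_head(random_dna(70), refs)
    if (g$head_class == "unknown") n_unknown <- n_unknown + 1
  }
  expect_gte(n_unknown, 19)
  expect_error(classify_head(random_dna(70), character(0)), "empty")
})

test_that("tandem tail finder scores copies and purity correctly", {
  set.seed(207)
  elem <- paste0(random_dna(150, gc = 0.5), "TGATGATGATGA")
  t <- find_tail_repeat(elem)
  expect_equal(t$unit, "TGA")
  expect_equal(t$copies, 4)
  expect_equal(t$purity, 1)
  expect_equal(t$distance_from_3prime, 0L)

  # one impure copy: 11 of 12 positions match the unit
  elem2 <- paste0(random_dna(150, gc = 0.5), "TGATGGTGATGA")
  t2 <- find_tail_repeat(elem2, min_purity = 0.8)
  expect_equal(t2$unit, "TGA")
  expect_equal(t2$copies, 4)
  expect_equal(t2$purity, 11 / 12, tolerance = 1e-9)

  # non-repetitive 3' end
  expect_null(find_tail_repeat(
    paste0(strrep("TGA", 10), "ACGGTCATTGCCAGATCGATCGTTACGGATCA"),
    tail_window = 30))
})

test_that("3'-proximal motif search is leftmost-exact and oracle-consistent", {
  set.seed(208)
  elem <- paste0(random_dna(100, gc = 0.6), "ATAAAAA", "CCGG",
                 random_dna(9, gc = 1))
  m <- find_motif_near_3prime(elem, "ATAAAAA", window = 20)
  expect_equal(m$position, 101L)
  expect_equal(m$matched_string, "ATAAAAA")
  expect_null(find_motif_near_3prime(strrep("CG", 60), "ATAAAAA",
                                     window = 40))
  for (i in 1:50) {
    e <- random_dna(80)
    got <- find_motif_near_3prime(e, "ATAAAAA", window = 40)
    region <- substr(e, 41, 80)
    want <- regexpr("ATAAAAA", region, fixed = TRUE)
    if (want[1] == -1) expect_null(got)
    else expect_equal(got$position, 40L + want[1])
  }
})

test_that("truncation is called from uncovered consensus 5' length", {
  set.seed(209)
  cons <- random_dna(400, gc = 0.4)
  full <- classify_truncation(cons, cons)
  expect_equal(full$truncation, "full_length")
  expect_equal(full$missing_5prime_bp, 0L)

  tr <- classify_truncation(substr(cons, 201, 400), cons)
  expect_equal(tr$truncation, "five_prime_truncated")
  expect_equal(tr$missing_5prime_bp, 200L, tolerance = 5)

  scattered <- cons
  for (p in c(50, 120, 200, 280, 360)) {
    ch <- strsplit(scattered, "")[[1]]
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    scattered <- paste(ch, collapse = "")
  }
  expect_equal(classify_truncation(scattered, cons)$truncation,
               "full_length")
})

test_that("composite annotation reflects the planted structure", {
  set.seed(210)
  refs <- c(`tRNA_sim` = sinescout:::.SIM_TRNA_HEAD,
            `5S_sim` = random_dna(120))
  fs <- family_spec(n_copies = 4, truncation_prob = 0, divergence = 0.05,
                    indel_rate = 0, tsd_edit_prob = 0, seed = 211)
  bg <- generate_background(20000, seed = 212)
  sim <- plant_family(bg, fs, seed = 213)
  k <- which(sim$truth$strand == "+")[1]
  loc <- genomic_location(sim$truth$contig[k], sim$truth$start[k], sim$truth$end[k])
  ex <- extract_with_flanks(sim$genome, loc, 200)
  ann <- annotate_element(ex$element, ex$left_flank, ex$right_flank,
                          consensus = unname(fs$consensus),
                          references = refs, location = loc)
  expect_equal(ann$truncation, "full_length")
  expect_equal(ann$head_class, "tRNA")
  expect_equal(ann$promoter$promoter_type, "type2_AB")
  expect_equal(ann$tail$unit, "TGA")
  expect_false(is.null(ann$tsd))
  expect_equal(ann$tsd$left_seq, toupper(sim$truth$tsd_seq[k]))

  # a deeply 5'-truncated copy: truncation called, promoter not scanned
  fs2 <- family_spec(n_copies = 4, truncation_prob = 1, divergence = 0.05,
                     indel_rate = 0, tsd_edit_prob = 0, seed = 214)
  sim2 <- plant_family(bg, fs2, seed = 215)
  k2 <- which.max(sim2$truth$missing_5prime_bp)
  loc2 <- genomic_location(sim2$truth$contig[k2], sim2$truth$start[k2],
                           sim2$truth$end[k2])
  ex2 <- extract_with_flanks(sim2$genome, loc2, 200)
  ann2 <- annotate_element(ex2$element, ex2$left_flank, ex2$right_flank,
                           consensus = unname(fs2$consensus),
                           references = refs, location = loc2)
  expect_equal(ann2$truncation, "five_prime_truncated")
  expect_equal(ann2$promoter$promoter_type, "none")
})
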