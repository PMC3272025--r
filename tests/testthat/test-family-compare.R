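test_that("best local match pinpoints a shared planted segment", {
  set.seed(401)
  shared <- random_dna(100, gc = 0.5)
  a <- paste0(random_dna(150), shared, random_dna(100))
  b <- paste0(random_dna(80), shared, random_dna(170))
  m <- best_local_match(a, b, min_length = 50)
  expect_equal(m$identity, 1)
  expect_equal(m$length, 100L)
  expect_equal(c(m$a_start, m$a_end), c(151L, 250L))
  expect_equal(c(m$b_start, m$b_end), c(81L, 180L))
  # identity is recomputable from the reported coordinates
  re <- global_align(substr(a, m$a_start, m$a_end),
                     substr(b, m$b_start, m$b_end))
  expect_equal(re$identity, m$identity, tolerance = 1e-9)
})

test_that("unrelated sequences yield no long local segment", {
  set.seed(402)
  for (i in 1:20) {
    expect_null(best_local_match(random_dna(500, gc = 0.36),
                                 random_dna(500, gc = 0.36),
                                 min_length = 50))
  }
})

test_that("a diverged shared region is recovered near its true identity", {
  set.seed(403)
  shared <- random_dna(132, gc = 0.45)
  mut <- mutate_copy(shared, divergence = 0.06)   # ~94% identity
  a <- paste0(random_dna(100), shared, random_dna(100))
  b <- paste0(random_dna(60), mut$copy, random_dna(140))
  m <- best_local_match(a, b, min_length = 60)
  expect_equal(m$length, 132, tolerance = 8)
  expect_equal(m$identity, 1 - mut$realized_divergence, tolerance = 0.03)
})

test_that("chimera detection separates head and body/tail sources", {
  set.seed(404)
  rrna <- c(`5S_sim` = random_dna(120, gc = 0.5))
  famX <- c(famX = random_dna(350, gc = 0.4))
  famY <- c(famY = random_dna(300, gc = 0.4))
  head_refs <- c(rrna, `tRNA_sim` = random_dna(72))

  # synthetic chimera: 5S head + famX body/tail
  chim <- c(chimera = paste0(substr(rrna, 1, 100),
                             substr(famX, 101, 350)))
  rep <- detect_chimera(chim, head_refs, c(famX, famY))
  expect_true(rep$is_chimera)
  expect_equal(rep$head_source, "5S")
  expect_equal(rep$body_tail_source, "famX")

  # a family compared against itself is never split into two sources
  rep2 <- detect_chimera(famX, head_refs, c(famX, famY))
  expect_false(rep2$is_chimera)

  # random sequence matches nothing
  rep3 <- detect_chimera(c(rnd = random_dna(350)), head_refs,
                         c(famX, famY))
  expect_false(rep3$is_chimera)
})

test_that("SINE-LINE partnership is read from the shared 3' tail", {
  set.seed(405)
  line_tail <- random_dna(43, gc = 0.4)
  line <- c(lineA = paste0(random_dna(1500), line_tail))
  mut <- mutate_copy(line_tail, divergence = 0.18)   # ~82% identity
  sine <- c(sineA = paste0(random_dna(300), mut$copy))
  other <- c(lineB = random_dna(1200))

  res <- match_line_partner(sine, c(line, other), tail_window = 60,
                            min_identity = 0.7, min_length = 30)
  expect_true(res$passes[res$line_id == "lineA"])
  expect_equal(res$length[res$line_id == "lineA"], 43, tolerance = 6)
  expect_false(isTRUE(res$passes[res$line_id == "lineB"]))

  # identical tails give identity 1; swapping roles preserves the verdict
  sine2 <- c(sineB = paste0(random_dna(300), line_tail))
  r2 <- match_line_partner(sine2, line, tail_window = 60)
  expect_equal(r2$identity, 1)
  r3 <- match_line_partner(c(x = unname(line)), c(y = unname(sine2)),
                           tail_window = 60)
  expect_equal(r3$passes, r2$passes)
})

test_that("RT protein identity is computed from the longest ORF", {
  set.seed(406)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  prot <- paste(c("M", sample(aas, 149, replace = TRUE)), collapse = "")
  back_translate <- function(p) {
    paste(vapply(strsplit(p, "")[[1]], function(a)
      names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1],
      character(1)), collapse = "")
  }
  cds <- paste0(back_translate(prot), "TAA")
  line <- paste0(random_dna(90), cds, random_dna(90))
  expect_equal(rt_protein_identity(line, prot), 1)

  # 30% substituted reference -> ~70% identity
  ch <- strsplit(prot, "")[[1]]
  at <- sample(2:150, 45)
  for (p in at) ch[p] <- sample(setdiff(aas, ch[p]), 1)
  expect_equal(rt_protein_identity(line, paste(ch, collapse = "")),
               1 - 45 / 150, tolerance = 0.03)

  # frameshift destroys the ORF
  broken <- paste0(substr(cds, 1, 200), substr(cds, 202, nchar(cds)))
  expect_error(rt_protein_identity(paste0(random_dna(90), broken), prot),
               "no ORF")
})
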