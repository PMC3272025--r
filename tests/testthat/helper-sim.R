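# shared machinery for truth-based recovery scoring on simulated genomes

# match scan hits to planted truth rows by interval overlap; returns one
# row per truth copy with boundary errors (element orientation) and the
# outcome of TSD annotation against the planted TSD string
score_recovery <- function(genome, hits, truth, flank = 200) {
  rows <- lapply(seq_len(nrow(truth)), function(k) {
    tlo <- min(truth$start[k], truth$end[k])
    thi <- max(truth$start[k], truth$end[k])
    cand <- which(pmin(hits$start, hits$end) <= thi &
                  pmax(hits$start, hits$end) >= tlo)
    if (length(cand) == 0) {
      return(data.frame(copy_id = truth$copy_id[k], found = FALSE,
                        err5 = NA_integer_, err3 = NA_integer_,
                        tsd_exact = NA, stringsAsFactors = FALSE))
    }
    h <- hits[cand[1], ]
    hlo <- min(h$start, h$end); hhi <- max(h$start, h$end)
    if (truth$strand[k] == "+") {
      err5 <- hlo - tlo; err3 <- hhi - thi
    } else {
      err5 <- thi - hhi; err3 <- tlo - hlo
    }
    ex <- extract_with_flanks(genome,
                              genomic_location(h$contig, h$start, h$end),
                              flank)
    tsd <- find_tsd(ex$left_flank, ex$right_flank)
    expected <- if (truth$strand[k] == "+") toupper(truth$tsd_seq[k])
                else unname(reverse_complement(truth$tsd_seq[k]))
    data.frame(copy_id = truth$copy_id[k], found = TRUE,
               err5 = err5, err3 = err3,
               tsd_exact = !is.null(tsd) && tsd$edits == 0 &&
                 tsd$left_seq == expected,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# an alignment of two clean clades (~2% divergence within, ~20% between),
# substitutions only so rows stay aligned
make_clade_msa <- function(seed, n_per = 6, len = 400) {
  set.seed(seed)
  anc1 <- random_dna(len, gc = 0.4)
  anc2 <- mutate_copy(anc1, divergence = 0.2)$copy
  rows <- c(
    vapply(1:n_per, function(i) mutate_copy(anc1, 0.02)$copy, character(1)),
    vapply(1:n_per, function(i) mutate_copy(anc2, 0.02)$copy, character(1)))
  new_msa(c(paste0("one_", 1:n_per), paste0("two_", 1:n_per)), rows)
}

# scan + tail-boundary refinement, as the pipeline applies it
scan_and_refine <- function(query, genome, unit = "TGA", ...) {
  hits <- scan_genome(query, genome, ...)
  if (nrow(hits) == 0) return(hits)
  for (i in seq_len(nrow(hits))) {
    loc <- refine_tail_boundary(
      genome, genomic_location(hits$contig[i], hits$start[i], hits$end[i]),
      unit = unit)
    hits$start[i] <- loc$start
    hits$end[i] <- loc$end
  }
  hits
}
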