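## homology scan: k-mer seeded, chained, gapped-extended search of a query
## against genome contigs -- a local, reproducible stand-in for web blastn.

#' Genomic location (1-based, strand by coordinate order)
#'
#' `start > end` encodes the minus strand: the element's 5' end sits at
#' `start` on the reverse-complement strand (the convention used for
#' reverse-orientation entries in copy coordinate tables).
#'
#' @param contig Contig/accession id.
#' @param start,end 1-based inclusive endpoints (positive integers).
#' @return A list of class `genomic_location`.
#' @export
genomic_location <- function(contig, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < 1L)
    stop("genomic_location: start and end must be positive integers")
  structure(list(contig = as.character(contig), start = start, end = end),
            class = "genomic_location")
}

#' @export
print.genomic_location <- function(x, ...) {
  cat(sprintf("<%s:%d-%d (%s)>\n", x$contig, x$start, x$end, loc_strand(x)))
  invisible(x)
}

#' Strand of a genomic location ("+" or "-")
#' @param loc A `genomic_location`.
#' @export
loc_strand <- function(loc) if (loc$start > loc$end) "-" else "+"

.loc_lo <- function(loc) min(loc$start, loc$end)
.loc_hi <- function(loc) max(loc$start, loc$end)

#' Length in bp of a genomic location
#'
#' `|end - start| + 1`, matching printed Length columns of copy tables
#' (e.g. 1082-759 spans 324 bp).
#'
#' @param loc A `genomic_location`, or a start coordinate if `end` given.
#' @param end Optional end coordinate when `loc` is numeric.
#' @return Integer length in bp.
#' @export
location_length <- function(loc, end = NULL) {
  if (is.null(end)) {
    stopifnot(inherits(loc, "genomic_location"))
    return(abs(loc$end - loc$start) + 1L)
  }
  loc <- as.integer(loc); end <- as.integer(end)
  if (loc < 1L || end < 1L) stop("coordinates must be positive")
  abs(end - loc) + 1L
}

## 1-based inclusive <-> BED 0-based half-open conversion is centralized here
.loc_to_bed <- function(loc) {
  c(start0 = .loc_lo(loc) - 1L, end0 = .loc_hi(loc))
}

#' Export hits to BED6
#'
#' @param hits A hit data.frame from [scan_genome()].
#' @param path Output path.
#' @export
hits_to_bed <- function(hits, path) {
  lo <- pmin(hits$start, hits$end) - 1L
  hi <- pmax(hits$start, hits$end)
  bed <- data.frame(hits$contig, lo, hi,
                    paste0(hits$query_id, "_hit", seq_len(nrow(hits))),
                    round(1000 * hits$identity), hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# seed positions of all query k-mers in one contig (forward orientation).
# returns data.frame(qpos, gpos); only unambiguous k-mers are seeded.
.seed_hits <- function(query, contig_seq, word_size) {
  q <- unname(query)
  nk <- nchar(q) - word_size + 1L
  starts <- seq_len(nk)
  kmers <- substring(q, starts, starts + word_size - 1L)
  keep <- !grepl("[^ACGT]", kmers)
  if (!any(keep)) return(data.frame(qpos = integer(), gpos = integer()))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[keep]))
  m <- Biostrings::matchPDict(pd, Biostrings::DNAString(unname(contig_seq)))
  qpos <- rep(starts[keep], S4Vectors::elementNROWS(m))
  gpos <- unlist(lapply(m, Biostrings::start), use.names = FALSE)
  if (length(qpos) == 0L) return(data.frame(qpos = integer(), gpos = integer()))
  data.frame(qpos = qpos, gpos = as.integer(gpos))
}

# cluster seeds into co-linear chains: split on diagonal drift > drift and
# on genomic jumps > chain_gap, then emit candidate windows.
.seed_windows <- function(seeds, qlen, clen, word_size,
                          drift = 50L, chain_gap = 250L, pad = 40L) {
  if (nrow(seeds) == 0L) return(NULL)
  seeds$diag <- seeds$gpos - seeds$qpos
  seeds <- seeds[order(seeds$diag, seeds$gpos), ]
  band <- cumsum(c(1L, diff(seeds$diag) > drift))
  wins <- list()
  for (b in split(seeds, band)) {
    b <- b[order(b$gpos), ]
    chain <- cumsum(c(1L, diff(b$gpos) > chain_gap))
    for (ch in split(b, chain)) {
      lo <- max(1L, min(ch$gpos) - (min(ch$qpos) - 1L) - pad)
      hi <- min(clen, max(ch$gpos) + word_size - 1L +
                  (qlen - (max(ch$qpos) + word_size - 1L)) + pad)
      wins[[length(wins) + 1L]] <- c(lo, hi)
    }
  }
  w <- do.call(rbind, wins)
  w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE]
  # merge overlapping windows so one locus is aligned once
  merged <- list(w[1L, ])
  if (nrow(w) > 1L) for (i in 2L:nrow(w)) {
    last <- merged[[length(merged)]]
    if (w[i, 1L] <= last[2L] + 1L) {
      merged[[length(merged)]] <- c(last[1L], max(last[2L], w[i, 2L]))
    } else {
      merged[[length(merged) + 1L]] <- w[i, ]
    }
  }
  merged
}

# snap unaligned query termini back onto the genome by exact-match
# extension (stops at the first mismatch or contig edge). Corrects
# boundary clipping caused by point mutations near copy ends.
.snap_ends <- function(contig_seq, qchars, g_lo, g_hi, q_lo, q_hi,
                       max_overhang = 12L) {
  clen <- nchar(contig_seq)
  left_over <- q_lo - 1L
  if (left_over > 0L && left_over <= max_overhang) {
    while (q_lo > 1L && g_lo > 1L &&
           substr(contig_seq, g_lo - 1L, g_lo - 1L) == qchars[q_lo - 1L]) {
      q_lo <- q_lo - 1L; g_lo <- g_lo - 1L
    }
  }
  right_over <- length(qchars) - q_hi
  if (right_over > 0L && right_over <= max_overhang) {
    while (q_hi < length(qchars) && g_hi < clen &&
           substr(contig_seq, g_hi + 1L, g_hi + 1L) == qchars[q_hi + 1L]) {
      q_hi <- q_hi + 1L; g_hi <- g_hi + 1L
    }
  }
  c(g_lo, g_hi)
}

#' Scan genome contigs for copies of a query sequence
#'
#' Exact k-mer seeds are chained along diagonals, each chain is extended by
#' ends-free gapped alignment of the query against the candidate window,
#' and hit identity is recomputed on the final extracted region so it always
#' equals [percent_identity()] of region vs query. Both strands are
#' searched; minus-strand hits are reported with `start > end`.
#'
#' @param query Query sequence (named character scalar; the name becomes
#'   `query_id`).
#' @param genome Named character vector of contig sequences.
#' @param word_size Seed k-mer size, 8-16 (default 11).
#' @param min_identity Minimum identity fraction (default 0.70).
#' @param min_length Minimum aligned length in bp (default 80; SINEs are
#'   roughly 80-500 bp).
#' @param scoring An [align_scoring()].
#' @return data.frame with columns query_id, contig, start, end, strand,
#'   identity, aligned_length, score, sorted by contig then coordinate.
#' @export
scan_genome <- function(query, genome, word_size = 11L, min_identity = 0.70,
                        min_length = 80L, scoring = align_scoring()) {
  if (word_size < 8L || word_size > 16L) stop("word_size must be in [8, 16]")
  query <- dna(query)
  if (is.null(names(query))) names(query) <- "query"
  if (nchar(query) < word_size) stop("query shorter than word_size")
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
  qlen <- nchar(query)
  rows <- list()
  for (cname in names(genome)) {
    cseq <- dna(genome[[cname]])
    clen <- nchar(cseq)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else reverse_complement(query)
      qchars <- .seq_chars(q)
      seeds <- .seed_hits(q, cseq, word_size)
      wins <- .seed_windows(seeds, qlen, clen, word_size)
      if (is.null(wins)) next
      # queue of candidate windows; after a hit the residual window
      # segments are re-queued so tandem neighbors sharing one seed
      # window are each reported
      queue <- wins
      while (length(queue) > 0L) {
        w <- queue[[1L]]; queue <- queue[-1L]
        if (w[2L] - w[1L] + 1L < min_length) next
        region <- substr(cseq, w[1L], w[2L])
        aln <- tryCatch(overlap_align(q, region, scoring),
                        error = function(e) NULL)
        if (is.null(aln) || aln$n_columns_counted == 0L) next
        g_lo <- w[1L] + aln$b_start - 1L
        g_hi <- w[1L] + aln$b_end - 1L
        snapped <- .snap_ends(cseq, qchars, g_lo, g_hi, aln$a_start, aln$a_end)
        g_lo <- snapped[1L]; g_hi <- snapped[2L]
        final <- tryCatch(overlap_align(q, substr(cseq, g_lo, g_hi), scoring),
                          error = function(e) NULL)
        if (is.null(final) || final$n_columns_counted == 0L) next
        g_lo2 <- g_lo + final$b_start - 1L
        g_hi2 <- g_lo + final$b_end - 1L
        alen <- g_hi2 - g_lo2 + 1L
        if (final$identity < min_identity || alen < min_length) next
        if (strand == "+") {
          s <- g_lo2; e <- g_hi2
        } else {
          s <- g_hi2; e <- g_lo2
        }
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = names(query), contig = cname, start = s, end = e,
          strand = strand, identity = final$identity,
          aligned_length = alen, score = final$score,
          stringsAsFactors = FALSE)
        if (g_lo2 - 1L >= w[1L])
          queue[[length(queue) + 1L]] <- c(w[1L], g_lo2 - 1L)
        if (w[2L] >= g_hi2 + 1L)
          queue[[length(queue) + 1L]] <- c(g_hi2 + 1L, w[2L])
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(query_id = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      identity = numeric(), aligned_length = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  hits <- do.call(rbind, rows)
  hits <- hits[!duplicated(hits[, c("contig", "start", "end", "strand")]), ]
  hits <- hits[order(hits$contig, pmin(hits$start, hits$end),
                     pmax(hits$start, hits$end)), ]
  rownames(hits) <- NULL
  hits
}

#' Merge fragmented hits into loci
#'
#' Hits on the same contig and strand whose genomic gap is at most
#' `max_gap` bp are merged into one locus spanning both; identities are
#' length-weighted, scores summed.
#'
#' @param hits A hit data.frame from [scan_genome()].
#' @param max_gap Maximum genomic gap in bp (default 50).
#' @return A merged hit data.frame.
#' @export
merge_hits <- function(hits, max_gap = 50L) {
  if (nrow(hits) < 2L) return(hits)
  out <- list()
  for (grp in split(hits, paste(hits$contig, hits$strand, hits$query_id))) {
    grp <- grp[order(pmin(grp$start, grp$end)), ]
    cur <- grp[1L, ]
    for (i in seq_len(nrow(grp))[-1L]) {
      nxt <- grp[i, ]
      gap <- min(nxt$start, nxt$end) - max(cur$start, cur$end) - 1L
      if (gap <= max_gap) {
        lo <- min(cur$start, cur$end, nxt$start, nxt$end)
        hi <- max(cur$start, cur$end, nxt$start, nxt$end)
        wid <- cur$aligned_length + nxt$aligned_length
        cur$identity <- (cur$identity * cur$aligned_length +
                         nxt$identity * nxt$aligned_length) / wid
        cur$aligned_length <- hi - lo + 1L
        cur$score <- cur$score + nxt$score
        if (cur$strand == "+") { cur$start <- lo; cur$end <- hi }
        else { cur$start <- hi; cur$end <- lo }
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- nxt
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, pmin(res$start, res$end)), ]
  rownames(res) <- NULL
  res
}

#' Extract an element and its flanks in reading orientation
#'
#' The element is returned in its own 5'->3' orientation
#' (reverse-complemented for minus-strand locations); flanks are the
#' adjacent genomic sequence in the same orientation, truncated (never
#' padded) at contig edges.
#'
#' @param genome Named character vector of contigs.
#' @param loc A `genomic_location`.
#' @param flank Flank length in bp (default 200, the window used for
#'   hallmark analysis).
#' @return list(left_flank, element, right_flank) of character scalars.
#' @export
extract_with_flanks <- function(genome, loc, flank = 200L) {
  stopifnot(inherits(loc, "genomic_location"))
  if (!loc$contig %in% names(genome))
    stop(sprintf("contig '%s' not in genome", loc$contig))
  cseq <- genome[[loc$contig]]
  clen <- nchar(cseq)
  lo <- .loc_lo(loc); hi <- .loc_hi(loc)
  if (hi > clen) stop("location outside contig bounds")
  elem <- substr(cseq, lo, hi)
  up <- substr(cseq, max(1L, lo - flank), lo - 1L)       # genomic upstream
  dn <- substr(cseq, hi + 1L, min(clen, hi + flank))     # genomic downstream
  if (loc_strand(loc) == "+") {
    list(left_flank = up, element = elem, right_flank = dn)
  } else {
    list(left_flank = reverse_complement(dn),
         element = reverse_complement(elem),
         right_flank = reverse_complement(up))
  }
}

#' Refine a hit's 3' boundary through its tandem-repeat tail
#'
#' Tandem tails vary in copy number between element copies, so an
#' alignment-defined hit boundary routinely stops inside the tail or
#' absorbs a few AT-rich target-site bases beyond it. This re-derives the
#' 3' boundary from the repeat itself: the last tandem run (>= 2 exact
#' copies) of `unit` near the hit's 3' terminus is located and the
#' boundary is set to the end of its whole-unit continuation in the
#' genome, trimming or extending as needed (at most `max_adjust` bp). The
#' unit is best supplied from the family consensus (its phase anchors the
#' boundary exactly); when NULL it is detected from the hit's own
#' terminus. Hits without a recognizable terminal array are returned
#' unchanged.
#'
#' @param genome Named character vector of contigs.
#' @param loc A `genomic_location` for the hit.
#' @param unit Tandem unit in element orientation (e.g. "TGA"), or NULL to
#'   detect it.
#' @param max_unit Maximum unit length when detecting (default 6).
#' @param probe Terminal window searched for the array, in bp (default 36).
#' @param max_adjust Maximum boundary shift in bp (default 18).
#' @return A possibly adjusted `genomic_location`.
#' @export
refine_tail_boundary <- function(genome, loc, unit = NULL, max_unit = 6L,
                                 probe = 36L, max_adjust = 18L) {
  ex <- extract_with_flanks(genome, loc, flank = 0L)
  elem <- ex$element
  L <- nchar(elem)
  units <- unit
  if (is.null(units)) {
    rep_hit <- find_tail_repeat(elem, max_unit = max_unit,
                                tail_window = min(probe, L),
                                min_copies = 2, min_purity = 0.9,
                                end_slack = max_adjust)
    if (is.null(rep_hit)) return(loc)
    # phase unknown when detected: try all rotations, keep the rightmost
    u0 <- rep_hit$unit
    units <- vapply(seq_len(nchar(u0)), function(r)
      paste0(substr(u0, r, nchar(u0)), substr(u0, 1L, r - 1L)), character(1))
  }
  win_start <- max(1L, L - probe - max_adjust + 1L)
  region <- substr(elem, win_start, L)
  best_end <- NA_integer_; best_unit <- NULL
  for (un in units) {
    u <- nchar(un)
    pos <- gregexpr(strrep(un, 2L), region, fixed = TRUE)[[1L]]
    if (pos[1L] == -1L) next
    last <- max(pos)
    end_r <- last + 2L * u - 1L
    # run may continue inside the region
    while (end_r + u <= nchar(region) &&
           substr(region, end_r + 1L, end_r + u) == un)
      end_r <- end_r + u
    end_e <- win_start + end_r - 1L
    if (is.na(best_end) || end_e > best_end) {
      best_end <- end_e; best_unit <- un
    }
  }
  if (is.na(best_end)) return(loc)
  u <- nchar(best_unit)
  cseq <- genome[[loc$contig]]
  clen <- nchar(cseq)
  if (loc_strand(loc) == "+") {
    hi <- .loc_lo(loc) + best_end - 1L
    while (hi + u <= clen && substr(cseq, hi + 1L, hi + u) == best_unit)
      hi <- hi + u
    if (abs(hi - .loc_hi(loc)) > max_adjust) return(loc)
    genomic_location(loc$contig, .loc_lo(loc), hi)
  } else {
    lo <- .loc_hi(loc) - best_end + 1L   # element 3' maps to genomic lo side
    unit_rc <- unname(reverse_complement(best_unit))
    while (lo - u >= 1L && substr(cseq, lo - u, lo - 1L) == unit_rc)
      lo <- lo - u
    if (abs(lo - .loc_lo(loc)) > max_adjust) return(loc)
    genomic_location(loc$contig, .loc_hi(loc), lo)
  }
}
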