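## structure_annot: SINE hallmark annotation -- target site duplications,
## internal Pol III promoter boxes, RNA-derived head classification,
## tandem-repeat tails, 5' truncation status.

#' Annotation configuration
#'
#' All hallmark-scan parameters in one place. Defaults follow the observed
#' biology of tRNA- and 5S-derived SINEs: TSDs of 5-19 bp with at most one
#' edit searched in 30-bp windows abutting the element boundaries; type-2
#' promoter box A/B consensus motifs with 20-80 bp spacing; a 90-bp head
#' region (tRNA heads run 70-74 bp); tandem tails of unit <= 6 bp within
#' 60 bp of the 3' terminus.
#'
#' @param tsd_min_len,tsd_max_len,tsd_max_edits,tsd_window,tsd_max_offset
#'   TSD search bounds: length range, edit allowance (mismatches+indels),
#'   flank window size, and maximum distance of each copy from the element
#'   boundary, all in bp.
#' @param box_a,box_b Type-2 (tRNA-type) promoter IUPAC motifs.
#' @param box_ab_spacing Length-2 integer vector, allowed bp between box A
#'   end and box B start.
#' @param box_max_mismatch Mismatch allowance per box.
#' @param type1_boxes Named list of IUPAC motifs A, IE, C for the type-1
#'   (5S-type) promoter.
#' @param type1_spacings List of two length-2 vectors: allowed gaps A->IE
#'   and IE->C.
#' @param head_length Head region length in bp.
#' @param head_min_identity Minimum identity for head classification.
#' @param tail_max_unit,tail_window,tail_min_copies,tail_min_purity Tandem
#'   tail parameters.
#' @param purine_motif,purine_window 3'-proximal purine-rich motif and its
#'   search window.
#' @param truncation_head_fraction Fraction of the consensus 5' end that
#'   must be uncovered to call a copy 5'-truncated.
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(tsd_min_len = 5L, tsd_max_len = 19L,
                              tsd_max_edits = 1L, tsd_window = 30L,
                              tsd_max_offset = 5L,
                              box_a = "TRGCNNARYNNG", box_b = "GTTCRANNC",
                              box_ab_spacing = c(20L, 80L),
                              box_max_mismatch = 2L,
                              type1_boxes = list(A = "GCTAAGCAGGGTC",
                                                 IE = "CCTGGT",
                                                 C = "GGATGGGAGACCGCC"),
                              type1_spacings = list(c(0L, 20L), c(0L, 25L)),
                              head_length = 90L, head_min_identity = 0.5,
                              tail_max_unit = 6L, tail_window = 60L,
                              tail_min_copies = 3, tail_min_purity = 0.8,
                              purine_motif = "ATAAAAA", purine_window = 60L,
                              truncation_head_fraction = 0.25) {
  structure(as.list(environment()), class = "annotation_config")
}

## ---- target site duplications --------------------------------------------

#' Find the target site duplication flanking an element
#'
#' Searches the final `window` bp of the left flank and the first `window`
#' bp of the right flank for the best-scoring pair of substrings: longest
#' first, then fewest edits (Levenshtein), then the pair closest to the
#' element boundaries. Because a genuine target site duplication abuts the
#' insertion, the left copy must end within `max_offset` bp of the element
#' 5' boundary and the right copy start within `max_offset` bp of the 3'
#' boundary; this adjacency constraint is what keeps chance substring
#' pairs deeper in the flanks from outranking the true duplication.
#' Absence is a legal outcome (some genuine copies carry no recognizable
#' TSD).
#'
#' @param left_flank,right_flank Flanking sequences in element orientation.
#' @param min_len,max_len TSD length bounds (min >= 4).
#' @param max_edits Maximum mismatches+indels between the two copies.
#' @param window Search window size in bp (default 30).
#' @param max_offset Maximum distance of each copy from its element
#'   boundary in bp (default 5).
#' @return A list of class `tsd_hit` (left_seq, right_seq, length, edits,
#'   left_end_offset, right_start_offset) or NULL.
#' @export
find_tsd <- function(left_flank, right_flank, min_len = 5L, max_len = 19L,
                     max_edits = 1L, window = 30L, max_offset = 5L) {
  stopifnot(min_len >= 4L)
  lf <- dna(left_flank); rf <- dna(right_flank)
  if (nchar(lf) < min_len || nchar(rf) < min_len) return(NULL)
  lw <- substr(lf, max(1L, nchar(lf) - window + 1L), nchar(lf))
  rw <- substr(rf, 1L, min(window, nchar(rf)))
  nl <- nchar(lw); nr <- nchar(rw)
  cand_l <- list(); cand_r <- list()
  for (len in min_len:max_len) {
    if (len <= nl) {
      st <- seq_len(nl - len + 1L)
      cand_l[[length(cand_l) + 1L]] <- data.frame(
        seq = substring(lw, st, st + len - 1L), start = st, len = len,
        stringsAsFactors = FALSE)
    }
    if (len <= nr) {
      st <- seq_len(nr - len + 1L)
      cand_r[[length(cand_r) + 1L]] <- data.frame(
        seq = substring(rw, st, st + len - 1L), start = st, len = len,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand_l) == 0L || length(cand_r) == 0L) return(NULL)
  L <- do.call(rbind, cand_l); R <- do.call(rbind, cand_r)
  # adjacency constraint: copies must lie within max_offset of boundaries
  L <- L[nl - (L$start + L$len - 1L) <= max_offset, , drop = FALSE]
  R <- R[R$start - 1L <= max_offset, , drop = FALSE]
  if (nrow(L) == 0L || nrow(R) == 0L) return(NULL)
  d <- adist(L$seq, R$seq)
  ok <- which(d <= max_edits, arr.ind = TRUE)
  if (nrow(ok) == 0L) return(NULL)
  li <- ok[, 1L]; ri <- ok[, 2L]
  pair_len <- pmax(L$len[li], R$len[ri])
  edits <- d[ok]
  # offsets from the element boundaries (0 = immediately adjacent)
  l_off <- nl - (L$start[li] + L$len[li] - 1L)
  r_off <- R$start[ri] - 1L
  # rank by edit-corrected length so a perfect duplication is never
  # outranked by itself plus one flank base and one spent edit
  ord <- order(-(pair_len - edits), edits, l_off + r_off,
               L$start[li], R$start[ri])
  best <- ord[1L]
  structure(list(left_seq = L$seq[li[best]], right_seq = R$seq[ri[best]],
                 length = pair_len[best], edits = edits[best],
                 left_end_offset = l_off[best],
                 right_start_offset = r_off[best]),
            class = "tsd_hit")
}

#' @export
print.tsd_hit <- function(x, ...) {
  cat(sprintf("<tsd_hit %d bp, %d edit(s): %s | %s (offsets %d/%d)>\n",
              x$length, x$edits, x$left_seq, x$right_seq,
              x$left_end_offset, x$right_start_offset))
  invisible(x)
}

## ---- IUPAC motif matching -------------------------------------------------

# mismatch counts of an IUPAC pattern at every start position of a subject;
# a subject base matches when it belongs to the pattern letter's base set.
.iupac_mismatch_profile <- function(pattern, subject) {
  p <- .seq_chars(pattern); s <- .seq_chars(subject)
  m <- length(p); n <- length(s)
  if (n < m) return(integer(0))
  ok <- matrix(FALSE, nrow = m, ncol = n)
  for (j in seq_len(m)) ok[j, ] <- s %in% .IUPAC_SET[[p[j]]]
  starts <- seq_len(n - m + 1L)
  vapply(starts, function(i) sum(!ok[cbind(seq_len(m), i:(i + m - 1L))]),
         integer(1))
}

#' Match an IUPAC pattern against a sequence
#'
#' @param pattern IUPAC motif.
#' @param subject Subject sequence.
#' @param max_mismatch Mismatch allowance.
#' @return data.frame(start, end, mismatches), sorted by mismatches then
#'   position. Zero rows when nothing matches.
#' @export
match_iupac <- function(pattern, subject, max_mismatch = 0L) {
  prof <- .iupac_mismatch_profile(pattern, subject)
  hit <- which(prof <= max_mismatch)
  out <- data.frame(start = hit, end = hit + nchar(pattern) - 1L,
                    mismatches = prof[hit])
  out[order(out$mismatches, out$start), , drop = FALSE]
}

.best_ordered_boxes <- function(head, motifs, spacings, max_mismatch) {
  cands <- lapply(motifs, function(m) match_iupac(m, head, max_mismatch))
  if (any(vapply(cands, nrow, integer(1)) == 0L)) return(NULL)
  # enumerate ordered combinations; small candidate sets keep this cheap
  best <- NULL
  pick <- function(level, prev_end, acc_mm, acc) {
    if (level > length(cands)) {
      spacing_ok <- TRUE
      for (k in seq_along(spacings)) {
        gap <- acc[[k + 1L]]$start - acc[[k]]$end - 1L
        if (gap < spacings[[k]][1L] || gap > spacings[[k]][2L])
          spacing_ok <- FALSE
      }
      key <- c(acc_mm, !spacing_ok, acc[[1L]]$start)
      if (is.null(best) ||
          isTRUE(key[1L] < best$key[1L]) ||
          (key[1L] == best$key[1L] && key[2L] < best$key[2L]) ||
          (key[1L] == best$key[1L] && key[2L] == best$key[2L] &&
           key[3L] < best$key[3L])) {
        best <<- list(boxes = acc, spacing_ok = spacing_ok, key = key)
      }
      return(invisible())
    }
    cc <- cands[[level]]
    for (i in seq_len(nrow(cc))) {
      if (cc$start[i] <= prev_end) next
      pick(level + 1L, cc$end[i], acc_mm + cc$mismatches[i],
           c(acc, list(cc[i, ])))
    }
  }
  pick(1L, 0L, 0L, list())
  best
}

.promoter_result <- function(type, boxes = NULL, spacing_ok = NA) {
  structure(list(promoter_type = type, boxes = boxes, spacing_ok = spacing_ok),
            class = "promoter_annotation")
}

#' @export
print.promoter_annotation <- function(x, ...) {
  cat(sprintf("<promoter %s%s>\n", x$promoter_type,
              if (!is.na(x$spacing_ok))
                sprintf(", spacing_ok=%s", x$spacing_ok) else ""))
  if (!is.null(x$boxes)) print(x$boxes)
  invisible(x)
}

#' Scan a head region for a type-2 (tRNA-type) Pol III promoter
#'
#' Finds the best box A and box B instances (fewest IUPAC mismatches, then
#' leftmost) with A preceding B. `spacing_ok` reports whether the inter-box
#' gap falls inside the allowed range; reversed box order or a box beyond
#' the mismatch allowance yields `promoter_type = "none"`.
#'
#' @param head Head-region sequence (>= 40 bp).
#' @param motif_A,motif_B IUPAC motifs (defaults: box A `TRGCNNARYNNG`,
#'   box B `GTTCRANNC`).
#' @param spacing Allowed bp between box A end and box B start.
#' @param max_mismatch Per-box mismatch allowance.
#' @return A `promoter_annotation`.
#' @export
scan_type2_promoter <- function(head, motif_A = "TRGCNNARYNNG",
                                motif_B = "GTTCRANNC",
                                spacing = c(20L, 80L), max_mismatch = 2L) {
  head <- dna(head)
  if (nchar(head) < 40L) stop("head region shorter than 40 bp")
  best <- .best_ordered_boxes(head, list(A = motif_A, B = motif_B),
                              list(spacing), max_mismatch)
  if (is.null(best)) return(.promoter_result("none"))
  boxes <- do.call(rbind, best$boxes)
  boxes <- data.frame(box = c("A", "B"), boxes, stringsAsFactors = FALSE)
  .promoter_result("type2_AB", boxes, best$spacing_ok)
}

#' Scan a head region for a type-1 (5S-type) Pol III promoter
#'
#' Three ordered boxes A < IE < C, otherwise as [scan_type2_promoter()].
#' Default motifs are loose approximations of the strongly conserved
#' eukaryotic 5S rRNA internal control region (+50/+67/+80 layout) and
#' should be overridden with family-specific patterns where known.
#'
#' @param head Head-region sequence (>= 40 bp).
#' @param motifs Named list with IUPAC motifs A, IE, C.
#' @param spacings List of two length-2 vectors: allowed gaps A->IE, IE->C.
#' @param max_mismatch Per-box mismatch allowance.
#' @return A `promoter_annotation`.
#' @export
scan_type1_promoter <- function(head,
                                motifs = list(A = "GCTAAGCAGGGTC",
                                              IE = "CCTGGT",
                                              C = "GGATGGGAGACCGCC"),
                                spacings = list(c(0L, 20L), c(0L, 25L)),
                                max_mismatch = 2L) {
  head <- dna(head)
  if (nchar(head) < 40L) stop("head region shorter than 40 bp")
  best <- .best_ordered_boxes(head, motifs, spacings, max_mismatch)
  if (is.null(best)) return(.promoter_result("none"))
  boxes <- do.call(rbind, best$boxes)
  boxes <- data.frame(box = c("A", "IE", "C"), boxes, stringsAsFactors = FALSE)
  .promoter_result("type1_AIEC", boxes, best$spacing_ok)
}

## ---- head classification --------------------------------------------------

#' Classify an element head against a reference RNA library
#'
#' The head is aligned (ends-free global) to every reference and scored by
#' coverage-corrected identity: matches divided by the length of the
#' shorter sequence. (Plain aligned-core identity would let a short
#' high-identity sliver from an unrelated reference win; dividing by the
#' shorter length demands both identity and coverage.) The class of the
#' best reference is returned when its score reaches `min_identity`, else
#' "unknown". Reference classes default to "5S" for ids containing "5S"
#' and "tRNA" otherwise; pass `ref_classes` to override.
#'
#' @param head Head-region sequence (>= 40 bp).
#' @param references Named character vector of reference RNAs (tRNA
#'   library, 5S rRNA).
#' @param min_identity Classification threshold (default 0.50).
#' @param ref_classes Optional named character vector id -> class.
#' @param scoring An [align_scoring()].
#' @return list(head_class, head_identity, best_reference_id).
#' @export
classify_head <- function(head, references, min_identity = 0.5,
                          ref_classes = NULL, scoring = align_scoring()) {
  if (length(references) == 0L) stop("empty reference library")
  head <- dna(head)
  if (nchar(head) < 40L) stop("head region shorter than 40 bp")
  if (is.null(names(references)))
    names(references) <- paste0("ref", seq_along(references))
  ids <- names(references)
  idents <- vapply(ids, function(id) {
    aln <- overlap_align(head, references[[id]], scoring)
    aln$n_match / min(nchar(head), nchar(references[[id]]))
  }, numeric(1))
  best <- ids[which.max(idents)]
  best_id <- max(idents)
  cls <- if (!is.null(ref_classes)) unname(ref_classes[best])
         else if (grepl("5S", best, ignore.case = TRUE)) "5S" else "tRNA"
  if (best_id < min_identity)
    return(list(head_class = "unknown", head_identity = best_id,
                best_reference_id = NA_character_))
  list(head_class = cls, head_identity = best_id, best_reference_id = best)
}

## ---- 3' tail --------------------------------------------------------------

#' Find the tandem-repeat tail of an element
#'
#' Searches the final `tail_window` bases for the best tandem repeat:
#' maximal copies x purity (ties broken toward higher purity, then smaller
#' units, then arrays ending closer to the 3' terminus). Trailing partial
#' units add fractional copies. Typical SINE tails are (TGA)n or poly(A).
#'
#' A tail is terminal by definition, so candidate arrays must end within
#' `end_slack` bp of the 3' terminus; `tail_window` bounds how far back an
#' array may start.
#'
#' @param element Element sequence in reading orientation.
#' @param max_unit Maximum unit length, 1-6.
#' @param tail_window Search window at the 3' end in bp.
#' @param min_copies Minimum (possibly fractional) copy count.
#' @param min_purity Minimum fraction of bases matching a perfect repeat.
#' @param end_slack Maximum distance of the array end from the 3' terminus
#'   (default 5).
#' @return A list of class `tail_repeat` (unit, copies, purity, start, end,
#'   distance_from_3prime; element coordinates) or NULL.
#' @export
find_tail_repeat <- function(element, max_unit = 6L, tail_window = 60L,
                             min_copies = 3, min_purity = 0.8,
                             end_slack = 5L) {
  stopifnot(max_unit >= 1L, max_unit <= 6L)
  elem <- dna(element)
  L <- nchar(elem)
  tail_window <- min(tail_window, L)
  region <- substr(elem, L - tail_window + 1L, L)
  rchars <- .seq_chars(region)
  n <- length(rchars)
  best <- NULL
  for (u in seq_len(min(max_unit, n %/% 2L))) {
    for (s in seq_len(n - 2L * u + 1L)) {
      unit <- rchars[s:(s + u - 1L)]
      max_m <- (n - s + 1L) %/% u
      if (max_m < 2L) next
      matches_per <- vapply(seq_len(max_m), function(m) {
        idx <- s + (m - 1L) * u + seq_len(u) - 1L
        sum(rchars[idx] == unit)
      }, integer(1))
      cum <- cumsum(matches_per)
      m_seq <- seq_len(max_m)
      purity <- cum / (m_seq * u)
      elig <- which(purity >= min_purity & m_seq >= 2L)
      if (length(elig) == 0L) next
      m <- elig[which.max(cum[elig])]
      copies <- m
      matches <- cum[m]
      end_pos <- s + m * u - 1L
      # fractional trailing extension: exact unit-prefix match only
      extra <- 0L
      while (end_pos + extra + 1L <= n &&
             rchars[end_pos + extra + 1L] == unit[(extra %% u) + 1L] &&
             extra + 1L < u) {
        extra <- extra + 1L
      }
      copies_f <- copies + extra / u
      purity_f <- (matches + extra) / (m * u + extra)
      if (copies_f < min_copies) next
      if (n - (end_pos + extra) > end_slack) next
      score <- copies_f * purity_f
      end_f <- end_pos + extra
      key <- c(-score, -purity_f, u, n - end_f, s)
      if (is.null(best) || .lex_less(key, best$key)) {
        best <- list(unit = paste(unit, collapse = ""), copies = copies_f,
                     purity = purity_f,
                     start = L - tail_window + s,
                     end = L - tail_window + end_f,
                     distance_from_3prime = n - end_f, key = key)
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$key <- NULL
  structure(best, class = "tail_repeat")
}

.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.tail_repeat <- function(x, ...) {
  cat(sprintf("<tail_repeat (%s)x%.2f purity=%.3f at %d-%d, %d bp from 3'>\n",
              x$unit, x$copies, x$purity, x$start, x$end,
              x$distance_from_3prime))
  invisible(x)
}

#' Find a motif near the 3' terminus
#'
#' Leftmost exact IUPAC match within the final `window` bases (e.g. the
#' conserved purine-rich ATAAAAA signal of tailless SINE families).
#'
#' @param element Element sequence.
#' @param motif IUPAC motif (default "ATAAAAA").
#' @param window Search window at the 3' end in bp.
#' @return list(position, matched_string) in element coordinates, or NULL.
#' @export
find_motif_near_3prime <- function(element, motif = "ATAAAAA", window = 60L) {
  elem <- dna(element)
  L <- nchar(elem)
  if (window > L) stop("window larger than element")
  region <- substr(elem, L - window + 1L, L)
  m <- match_iupac(motif, region, max_mismatch = 0L)
  if (nrow(m) == 0L) return(NULL)
  pos <- L - window + m$start[1L]
  list(position = pos, matched_string = substr(elem, pos, pos + nchar(motif) - 1L))
}

## ---- truncation -----------------------------------------------------------

#' Classify 5' truncation of a copy against its family consensus
#'
#' The copy is aligned to the consensus with free terminal gaps; the copy
#' is called 5'-truncated when at least `head_fraction` of the consensus 5'
#' end is left uncovered. Reports the uncovered 5' length in bp.
#'
#' @param copy Copy sequence.
#' @param consensus Family consensus sequence.
#' @param head_fraction Uncovered-fraction threshold (default 0.25).
#' @param scoring An [align_scoring()].
#' @return list(truncation, missing_5prime_bp).
#' @export
classify_truncation <- function(copy, consensus, head_fraction = 0.25,
                                scoring = align_scoring()) {
  consensus <- dna(consensus)
  if (nchar(consensus) == 0L) stop("empty consensus")
  aln <- overlap_align(copy, consensus, scoring)
  missing <- aln$b_start - 1L
  status <- if (missing >= head_fraction * nchar(consensus))
    "five_prime_truncated" else "full_length"
  list(truncation = status, missing_5prime_bp = missing)
}

## ---- composite annotation -------------------------------------------------

#' Annotate one candidate copy with all SINE hallmarks
#'
#' Composes [find_tsd()], the promoter scans, [classify_head()],
#' [find_tail_repeat()], [find_motif_near_3prime()] and
#' [classify_truncation()] into a single structural record. The type-2
#' (tRNA) promoter is scanned first; the type-1 (5S) layout is reported
#' when type 2 is absent. Promoter and head calls are skipped for copies
#' whose 5' end is missing (truncated copies have no head to scan).
#'
#' @param element Element sequence in reading orientation.
#' @param left_flank,right_flank Flanks in the same orientation.
#' @param consensus Optional family consensus (enables truncation calls).
#' @param references Optional reference RNA library for head
#'   classification.
#' @param config An [annotation_config()].
#' @param copy_id Copy identifier.
#' @param location Optional `genomic_location`.
#' @return A list of class `sine_annotation`.
#' @export
annotate_element <- function(element, left_flank, right_flank,
                             consensus = NULL, references = NULL,
                             config = annotation_config(),
                             copy_id = "copy", location = NULL) {
  element <- dna(element)
  if (nchar(element) == 0L) stop("empty element")
  tsd <- if (nchar(left_flank) >= config$tsd_min_len &&
             nchar(right_flank) >= config$tsd_min_len)
    find_tsd(left_flank, right_flank, config$tsd_min_len, config$tsd_max_len,
             config$tsd_max_edits, config$tsd_window,
             config$tsd_max_offset) else NULL
  trunc <- if (!is.null(consensus))
    classify_truncation(element, consensus, config$truncation_head_fraction)
  else list(truncation = "full_length", missing_5prime_bp = 0L)

  head_len <- min(config$head_length, nchar(element))
  headseq <- substr(element, 1L, head_len)
  promoter <- .promoter_result("none")
  head_class <- "unknown"; head_identity <- NA_real_; head_ref <- NA_character_
  if (trunc$truncation == "full_length" && head_len >= 40L) {
    promoter <- scan_type2_promoter(headseq, config$box_a, config$box_b,
                                    config$box_ab_spacing,
                                    config$box_max_mismatch)
    if (promoter$promoter_type == "none") {
      p1 <- scan_type1_promoter(headseq, config$type1_boxes,
                                config$type1_spacings,
                                config$box_max_mismatch)
      if (p1$promoter_type != "none") promoter <- p1
    }
    if (!is.null(references)) {
      hc <- classify_head(headseq, references, config$head_min_identity)
      head_class <- hc$head_class
      head_identity <- hc$head_identity
      head_ref <- hc$best_reference_id
    }
  }
  tail <- find_tail_repeat(element, config$tail_max_unit,
                           min(config$tail_window, nchar(element)),
                           config$tail_min_copies, config$tail_min_purity)
  purine <- if (nchar(element) >= config$purine_window)
    find_motif_near_3prime(element, config$purine_motif,
                           config$purine_window) else NULL
  structure(list(copy_id = copy_id, location = location, tsd = tsd,
                 promoter = promoter, head_class = head_class,
                 head_identity = head_identity, head_reference = head_ref,
                 tail = tail, purine_motif = purine,
                 truncation = trunc$truncation,
                 missing_5prime_bp = trunc$missing_5prime_bp),
            class = "sine_annotation")
}

#' @export
print.sine_annotation <- function(x, ...) {
  cat(sprintf("<sine_annotation %s: %s, promoter=%s, head=%s, tail=%s, tsd=%s>\n",
              x$copy_id, x$truncation, x$promoter$promoter_type,
              x$head_class,
              if (is.null(x$tail)) "none"
              else sprintf("(%s)x%.1f", x$tail$unit, x$tail$copies),
              if (is.null(x$tsd)) "none" else x$tsd$left_seq))
  invisible(x)
}

#' Flatten annotations into a table
#'
#' @param annotations A list of `sine_annotation` records.
#' @return One row per copy: id, contig, start, end, strand, tsd_seq,
#'   tsd_len, tsd_edits, promoter_type, head_class, head_identity,
#'   tail_unit, tail_copies, truncation, missing_5prime_bp.
#' @export
annotations_to_df <- function(annotations) {
  rows <- lapply(annotations, function(a) {
    loc <- a$location
    data.frame(
      copy_id = a$copy_id,
      contig = if (is.null(loc)) NA_character_ else loc$contig,
      start = if (is.null(loc)) NA_integer_ else loc$start,
      end = if (is.null(loc)) NA_integer_ else loc$end,
      strand = if (is.null(loc)) NA_character_ else loc_strand(loc),
      tsd_seq = if (is.null(a$tsd)) NA_character_ else a$tsd$left_seq,
      tsd_len = if (is.null(a$tsd)) NA_integer_ else a$tsd$length,
      tsd_edits = if (is.null(a$tsd)) NA_integer_ else a$tsd$edits,
      promoter_type = a$promoter$promoter_type,
      head_class = a$head_class,
      head_identity = a$head_identity,
      tail_unit = if (is.null(a$tail)) NA_character_ else a$tail$unit,
      tail_copies = if (is.null(a$tail)) NA_real_ else a$tail$copies,
      truncation = a$truncation,
      missing_5prime_bp = a$missing_5prime_bp,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write annotations as GFF3
#'
#' One `dispersed_repeat` feature per copy with child features for TSD
#' copies, promoter boxes, and the tandem tail. Coordinates are 1-based
#' inclusive genome coordinates taken from each record's location.
#'
#' @param annotations A list of `sine_annotation` records (locations
#'   required).
#' @param path Output path.
#' @export
write_annotations_gff3 <- function(annotations, path) {
  lines <- c("##gff-version 3")
  for (a in annotations) {
    loc <- a$location
    if (is.null(loc)) stop(sprintf("copy %s has no location", a$copy_id))
    lo <- min(loc$start, loc$end); hi <- max(loc$start, loc$end)
    strand <- loc_strand(loc)
    id <- a$copy_id
    lines <- c(lines, paste(loc$contig, "sinescout", "dispersed_repeat",
                            lo, hi, ".", strand, ".",
                            sprintf("ID=%s;truncation=%s;head_class=%s",
                                    id, a$truncation, a$head_class),
                            sep = "\t"))
    kid <- function(type, s, e, extra = "") {
      paste(loc$contig, "sinescout", type, s, e, ".", strand, ".",
            sprintf("Parent=%s%s", id, extra), sep = "\t")
    }
    if (!is.null(a$tsd)) {
      ll <- nchar(a$tsd$left_seq); rl <- nchar(a$tsd$right_seq)
      if (strand == "+") {
        lines <- c(lines,
          kid("target_site_duplication",
              lo - a$tsd$left_end_offset - ll, lo - a$tsd$left_end_offset - 1L),
          kid("target_site_duplication",
              hi + a$tsd$right_start_offset + 1L,
              hi + a$tsd$right_start_offset + rl))
      } else {
        lines <- c(lines,
          kid("target_site_duplication",
              hi + a$tsd$left_end_offset + 1L, hi + a$tsd$left_end_offset + ll),
          kid("target_site_duplication",
              lo - a$tsd$right_start_offset - rl,
              lo - a$tsd$right_start_offset - 1L))
      }
    }
    if (!is.null(a$promoter$boxes)) {
      for (i in seq_len(nrow(a$promoter$boxes))) {
        b <- a$promoter$boxes[i, ]
        if (strand == "+") {
          lines <- c(lines, kid("promoter_element", lo + b$start - 1L,
                                lo + b$end - 1L,
                                sprintf(";box=%s", b$box)))
        } else {
          lines <- c(lines, kid("promoter_element", hi - b$end + 1L,
                                hi - b$start + 1L,
                                sprintf(";box=%s", b$box)))
        }
      }
    }
    if (!is.null(a$tail)) {
      if (strand == "+") {
        lines <- c(lines, kid("tandem_repeat", lo + a$tail$start - 1L,
                              lo + a$tail$end - 1L,
                              sprintf(";unit=%s", a$tail$unit)))
      } else {
        lines <- c(lines, kid("tandem_repeat", hi - a$tail$end + 1L,
                              hi - a$tail$start + 1L,
                              sprintf(";unit=%s", a$tail$unit)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
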