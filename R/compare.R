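## family_compare: segment-level comparison between SINE families and
## LINEs -- shared domains, chimeric architectures (e.g. a 5S-derived head
## on a tRNA-SINE body/tail), SINE-LINE 3'-tail partnership, and RT
## protein identity.

#' Default scoring for local segment matching
#'
#' Stringent parameters (match +1, mismatch -2, gap open -5, gap extend
#' -2, the classic nucleotide-BLAST regime) so that a local search returns
#' compact high-identity segments instead of long gap-chained noise.
#'
#' @return An [align_scoring()] list.
#' @export
local_scoring <- function() {
  align_scoring(match = 1, mismatch = -2, gap_open = -5, gap_extend = -2)
}

#' Best local match between two sequences
#'
#' Highest-scoring Smith-Waterman segment; NULL when the best segment is
#' shorter than `min_length` alignment columns.
#'
#' @param a,b DNA sequences.
#' @param min_length Minimum segment length in alignment columns.
#' @param scoring An [align_scoring()] (default [local_scoring()]).
#' @return A list of class `segment_match`: a_start, a_end, b_start,
#'   b_end, length (columns), identity, score; or NULL.
#' @export
best_local_match <- function(a, b, min_length = 30L,
                             scoring = local_scoring()) {
  a <- dna(a); b <- dna(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  aln <- local_align(a, b, scoring)
  if (aln$n_columns_counted < min_length) return(NULL)
  structure(list(a_start = aln$a_start, a_end = aln$a_end,
                 b_start = aln$b_start, b_end = aln$b_end,
                 length = aln$n_columns_counted, identity = aln$identity,
                 score = aln$score),
            class = "segment_match")
}

#' @export
print.segment_match <- function(x, ...) {
  cat(sprintf("<segment_match a:%d-%d b:%d-%d len=%d identity=%.3f>\n",
              x$a_start, x$a_end, x$b_start, x$b_end, x$length, x$identity))
  invisible(x)
}

#' Detect a chimeric (mosaic) family architecture
#'
#' The head region (first `head_length` bp) of a family consensus is
#' classified against the reference RNA library; the remainder (body +
#' tail) is matched against the other families' consensi by local
#' alignment. The family is called chimeric when head and body/tail
#' best-match *different* sources and both matches clear the thresholds --
#' the signature of template switching between a structural RNA and an
#' existing SINE during reverse transcription.
#'
#' @param family_consensus Named character scalar (name = family id).
#' @param head_refs Reference RNA library (named character vector).
#' @param other_family_consensi Named character vector of other families'
#'   consensi; an entry with the same name as `family_consensus` is
#'   excluded from comparison.
#' @param min_identity,min_length Thresholds for both segments (defaults
#'   0.7 identity over >= 40 bp).
#' @param head_length Head region size in bp (default 90).
#' @param scoring An [align_scoring()].
#' @return A list of class `chimera_report`.
#' @export
detect_chimera <- function(family_consensus, head_refs,
                           other_family_consensi,
                           min_identity = 0.7, min_length = 40L,
                           head_length = 90L, scoring = local_scoring()) {
  if (length(head_refs) == 0L) stop("empty head reference library")
  if (length(other_family_consensi) == 0L) stop("no other family consensi")
  fam_id <- if (!is.null(names(family_consensus))) names(family_consensus)[1L]
            else "family"
  cons <- dna(family_consensus)
  others <- other_family_consensi[setdiff(names(other_family_consensi), fam_id)]
  # drop sequence-identical entries too (same family under another name)
  others <- others[toupper(others) != toupper(unname(cons))]
  if (length(others) == 0L)
    return(structure(list(family_id = fam_id, head_source = NA_character_,
                          head_match = NULL, body_tail_source = NA_character_,
                          body_tail_match = NULL, is_chimera = FALSE),
                     class = "chimera_report"))
  head_len <- min(head_length, nchar(cons))
  headseq <- substr(cons, 1L, head_len)
  hc <- classify_head(headseq, head_refs, min_identity = 0, scoring = scoring)
  head_match <- best_local_match(headseq, head_refs[[hc$best_reference_id]],
                                 min_length = min(min_length, head_len),
                                 scoring = scoring)
  head_ok <- !is.null(head_match) && head_match$identity >= min_identity &&
    hc$head_identity >= min_identity
  body <- substr(cons, head_len + 1L, nchar(cons))
  body_matches <- lapply(names(others), function(id)
    best_local_match(body, others[[id]], min_length = min_length,
                     scoring = scoring))
  names(body_matches) <- names(others)
  body_matches <- Filter(Negate(is.null), body_matches)
  body_source <- NA_character_; body_match <- NULL; body_ok <- FALSE
  if (length(body_matches) > 0L) {
    idents <- vapply(body_matches, `[[`, numeric(1), "identity")
    body_source <- names(body_matches)[which.max(idents)]
    body_match <- body_matches[[body_source]]
    body_ok <- body_match$identity >= min_identity
  }
  head_source <- if (head_ok) hc$head_class else NA_character_
  is_chimera <- head_ok && body_ok && !is.na(head_source) &&
    !identical(head_source, body_source)
  structure(list(family_id = fam_id, head_source = head_source,
                 head_reference = hc$best_reference_id,
                 head_match = head_match,
                 body_tail_source = if (body_ok) body_source else NA_character_,
                 body_tail_match = body_match, is_chimera = is_chimera),
            class = "chimera_report")
}

#' @export
print.chimera_report <- function(x, ...) {
  cat(sprintf("<chimera_report %s: head=%s body/tail=%s chimera=%s>\n",
              x$family_id, x$head_source, x$body_tail_source, x$is_chimera))
  invisible(x)
}

#' Match a SINE 3' tail against candidate partner LINEs
#'
#' A SINE is mobilized by the LINE whose reverse transcriptase recognizes
#' its 3' tail, so SINE and partner LINE share their 3' terminal sequence.
#' The comparison is restricted to the final `tail_window` bases of both
#' sequences; each candidate passes when its best local segment reaches
#' `min_identity` over `min_length` columns.
#'
#' @param sine_consensus SINE consensus (named).
#' @param line_candidates Named character vector of LINE sequences.
#' @param tail_window 3' window in bp (default 60).
#' @param min_identity,min_length Pass thresholds (defaults 0.7, 30).
#' @param scoring An [align_scoring()].
#' @return data.frame(sine_id, line_id, identity, length, passes), sorted
#'   by identity (descending). Candidates with no qualifying segment get
#'   identity NA and passes FALSE.
#' @export
match_line_partner <- function(sine_consensus, line_candidates,
                               tail_window = 60L, min_identity = 0.7,
                               min_length = 30L, scoring = local_scoring()) {
  sine <- dna(sine_consensus)
  if (tail_window > nchar(sine)) stop("tail_window longer than SINE")
  sine_id <- if (!is.null(names(sine_consensus))) names(sine_consensus)[1L]
             else "sine"
  stail <- substr(sine, nchar(sine) - tail_window + 1L, nchar(sine))
  if (is.null(names(line_candidates)))
    names(line_candidates) <- paste0("line", seq_along(line_candidates))
  rows <- lapply(names(line_candidates), function(id) {
    lseq <- dna(line_candidates[[id]])
    if (tail_window > nchar(lseq)) stop("tail_window longer than LINE ", id)
    ltail <- substr(lseq, nchar(lseq) - tail_window + 1L, nchar(lseq))
    m <- best_local_match(stail, ltail, min_length = min_length,
                          scoring = scoring)
    if (is.null(m))
      data.frame(sine_id = sine_id, line_id = id, identity = NA_real_,
                 length = NA_integer_, passes = FALSE,
                 stringsAsFactors = FALSE)
    else
      data.frame(sine_id = sine_id, line_id = id, identity = m$identity,
                 length = m$length,
                 passes = m$identity >= min_identity && m$length >= min_length,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-ifelse(is.na(out$identity), -1, out$identity)), , drop = FALSE]
}

#' Reverse-transcriptase protein identity between a LINE and a reference
#'
#' The longest open reading frame of the LINE (>= `min_aa` aa, six-frame)
#' is conceptually translated and aligned to the reference protein with
#' identity scoring and free terminal gaps; plain percent amino-acid
#' identity is returned.
#'
#' @param line_seq LINE nucleotide sequence.
#' @param ref_protein Reference RT protein (single-letter amino acids).
#' @param min_aa Minimum ORF length in aa (default 100).
#' @return Identity fraction in \[0, 1\].
#' @export
rt_protein_identity <- function(line_seq, ref_protein, min_aa = 100L) {
  orfs <- six_frame_orfs(line_seq, min_aa = max(10L, min_aa))
  orfs <- orfs[nchar(orfs$protein) >= min_aa, , drop = FALSE]
  if (nrow(orfs) == 0L)
    stop(sprintf("no ORF of >= %d aa found", min_aa))
  prot <- orfs$protein[which.max(nchar(orfs$protein))]
  .protein_identity(prot, ref_protein)
}

# ends-free protein alignment under identity scoring (+1/-1, affine gaps)
.protein_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  letters26 <- c(LETTERS, "*")
  m <- matrix(-1, length(letters26), length(letters26),
              dimnames = list(letters26, letters26))
  diag(m) <- 1
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    type = "overlap", substitutionMatrix = m,
    gapOpening = 2, gapExtension = 0.5)
  ga <- .seq_chars(as.character(Biostrings::pattern(aln)))
  gb <- .seq_chars(as.character(Biostrings::subject(aln)))
  n_match <- sum(ga == gb & ga != "-")
  n_match / length(ga)
}

#' Human-readable comparison report for a family pair
#'
#' @param a,b Named consensus sequences.
#' @param min_length Minimum local segment length.
#' @param scoring An [align_scoring()].
#' @return A character vector of report lines (also printed invisibly
#'   usable with [writeLines()]).
#' @export
family_pair_report <- function(a, b, min_length = 30L,
                               scoring = local_scoring()) {
  ida <- if (is.null(names(a))) "A" else names(a)[1L]
  idb <- if (is.null(names(b))) "B" else names(b)[1L]
  m <- best_local_match(a, b, min_length, scoring)
  lines <- c(sprintf("family pair: %s (%d bp) vs %s (%d bp)",
                     ida, nchar(a), idb, nchar(b)))
  if (is.null(m)) {
    c(lines, sprintf("  no shared segment of >= %d columns", min_length))
  } else {
    c(lines, sprintf("  shared segment: %s:%d-%d / %s:%d-%d",
                     ida, m$a_start, m$a_end, idb, m$b_start, m$b_end),
      sprintf("  length %d columns, identity %.1f%%",
              m$length, 100 * m$identity))
  }
}
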