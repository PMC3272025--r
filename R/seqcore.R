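#' @import Biostrings
#' @importFrom stats median setNames
#' @importFrom utils adist write.table read.delim
NULL

# IUPAC DNA alphabet accepted throughout; sequences are stored as plain
# uppercase character strings with the id carried in names().
.IUPAC_DNA <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                "V", "H", "D", "B", "N")

.IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A",
                 M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
                 V = "B", H = "D", D = "H", B = "V", N = "N")

# base sets encoded by each IUPAC letter (used for motif matching)
.IUPAC_SET <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"), D = c("A", "G", "T"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T"))

#' Validate and normalize a DNA sequence
#'
#' Uppercases the input and rejects any character outside the IUPAC DNA
#' alphabet (ACGT plus ambiguity codes and N), naming the offending position.
#'
#' @param x A character scalar (the residues). May carry an id in `names()`.
#' @param id Optional id; overrides `names(x)`.
#' @return The validated uppercase sequence, id preserved in `names()`.
#' @export
dna <- function(x, id = NULL) {
  if (!is.character(x) || length(x) != 1L)
    stop("sequence must be a length-1 character vector")
  if (is.null(id)) id <- names(x)
  s <- toupper(x)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .IUPAC_DNA)
  if (length(bad) > 0L)
    stop(sprintf("non-IUPAC character '%s' at position %d", chars[bad[1L]], bad[1L]))
  if (!is.null(id)) names(s) <- id
  s
}

.seq_chars <- function(s) strsplit(toupper(unname(s)), "", fixed = TRUE)[[1L]]

#' Reverse complement
#'
#' Watson-Crick complement, reversed; ambiguity codes are mapped to their
#' complements. An involution: `reverse_complement(reverse_complement(s))`
#' equals `s`.
#'
#' @param seq A DNA sequence (character scalar, IUPAC alphabet).
#' @return The reverse complement, names preserved.
#' @export
reverse_complement <- function(seq) {
  s <- dna(seq)
  chars <- .seq_chars(s)
  out <- paste(rev(.IUPAC_COMP[chars]), collapse = "")
  names(out) <- names(s)
  out
}

## ---- scoring and alignment ------------------------------------------------

#' Alignment scoring parameters
#'
#' Defaults: match +1, mismatch -1, gap open -2, gap extend -0.5. A gap of
#' length L costs `gap_open + L * gap_extend`. `N` (and any ambiguity code)
#' never matches anything, including itself.
#'
#' @param match,mismatch,gap_open,gap_extend Scoring parameters; gap
#'   penalties are negative numbers.
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -1, gap_open = -2,
                          gap_extend = -0.5) {
  stopifnot(gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

.sub_matrix <- function(scoring) {
  n <- length(.IUPAC_DNA)
  m <- matrix(scoring$mismatch, n, n, dimnames = list(.IUPAC_DNA, .IUPAC_DNA))
  for (b in c("A", "C", "G", "T")) m[b, b] <- scoring$match
  m
}

# identity bookkeeping from two equal-length gapped strings.
# counted columns exclude terminal overhangs (leading/trailing runs where
# either row is gapped); internal gap columns count as mismatches.
.identity_from_gapped <- function(ga, gb) {
  a <- .seq_chars(ga); b <- .seq_chars(gb)
  if (length(a) != length(b)) stop("gapped rows differ in length")
  gap <- a == "-" | b == "-"
  core <- which(!gap)
  if (length(core) == 0L) stop("alignment has zero counted columns")
  lo <- core[1L]; hi <- core[length(core)]
  idx <- lo:hi
  n_match <- sum(a[idx] == b[idx] & a[idx] %in% c("A", "C", "G", "T"))
  list(n_match = n_match, n_columns_counted = length(idx),
       identity = n_match / length(idx))
}

.pw_result <- function(ga, gb, score, a_range, b_range, type, scoring) {
  # a local/overlap alignment can be empty (nothing scores positive);
  # record it as zero columns rather than failing
  stats <- if (nchar(ga) == 0L)
    list(n_match = 0L, n_columns_counted = 0L, identity = 0)
  else .identity_from_gapped(ga, gb)
  structure(list(gapped_a = ga, gapped_b = gb, score = score,
                 n_match = stats$n_match,
                 n_columns_counted = stats$n_columns_counted,
                 identity = stats$identity,
                 a_start = a_range[1L], a_end = a_range[2L],
                 b_start = b_range[1L], b_end = b_range[2L],
                 type = type, scoring = scoring),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment type=%s score=%.2f identity=%.4f over %d columns>\n",
              x$type, x$score, x$identity, x$n_columns_counted))
  if (nchar(x$gapped_a) <= 80) {
    cat(" a: ", x$gapped_a, "\n b: ", x$gapped_b, "\n", sep = "")
  }
  invisible(x)
}

.align_engine <- function(a, b, scoring, type) {
  a <- dna(a); b <- dna(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("cannot align an empty sequence")
  # ends-free global alignment (free terminal gaps in both sequences)
  # is the same optimization as Smith-Waterman: skip both prefixes and
  # suffixes free, maximize the contiguous aligned core
  engine_type <- if (type == "overlap") "local" else type
  aln <- Biostrings::pairwiseAlignment(
    pattern = unname(a), subject = unname(b), type = engine_type,
    substitutionMatrix = .sub_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  if (type == "global") {
    ga <- as.character(Biostrings::alignedPattern(aln))
    gb <- as.character(Biostrings::alignedSubject(aln))
    a_range <- c(1L, nchar(a)); b_range <- c(1L, nchar(b))
  } else {
    ga <- as.character(Biostrings::pattern(aln))
    gb <- as.character(Biostrings::subject(aln))
    a_range <- c(Biostrings::start(Biostrings::pattern(aln)),
                 Biostrings::end(Biostrings::pattern(aln)))
    b_range <- c(Biostrings::start(Biostrings::subject(aln)),
                 Biostrings::end(Biostrings::subject(aln)))
  }
  .pw_result(ga, gb, Biostrings::score(aln), a_range, b_range, type, scoring)
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment of two sequences under affine gap scoring.
#' Terminal gaps are penalized; the identity statistic excludes terminal
#' overhang columns and counts internal gap columns as mismatches.
#'
#' @param a,b DNA sequences (character scalars).
#' @param scoring An [align_scoring()] list.
#' @return A `pairwise_alignment`: gapped strings, score, match count,
#'   counted columns, and identity fraction.
#' @seealso [overlap_align()] for free terminal gaps, [local_align()] for
#'   Smith-Waterman.
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  .align_engine(a, b, scoring, "global")
}

#' Ends-free (overlap) pairwise alignment
#'
#' Global alignment with unpenalized terminal gaps on both sequences: the
#' reported gapped strings cover only the aligned core. Used for comparing
#' a copy with a consensus when 5' truncation is possible.
#'
#' @inheritParams global_align
#' @return A `pairwise_alignment` with `a_start`/`a_end`, `b_start`/`b_end`
#'   giving the aligned region in each input.
#' @export
overlap_align <- function(a, b, scoring = align_scoring()) {
  .align_engine(a, b, scoring, "overlap")
}

#' Local pairwise alignment (Smith-Waterman)
#'
#' @inheritParams global_align
#' @return A `pairwise_alignment` covering the best-scoring local segment.
#' @export
local_align <- function(a, b, scoring = align_scoring()) {
  .align_engine(a, b, scoring, "local")
}

#' Percent identity of a pairwise alignment
#'
#' Matches divided by counted columns. Counted columns exclude terminal gap
#' overhangs and include internal gap columns as mismatches. Symmetric in
#' the two sequences and 1.0 for a self-alignment.
#'
#' @param aln A `pairwise_alignment`.
#' @return Identity fraction in \[0, 1\].
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (aln$n_columns_counted == 0L)
    stop("alignment has zero counted columns")
  aln$identity
}

# recompute an alignment score from its gapped strings (self-consistency
# check used by tests): matches/mismatches plus open+extend per gap run.
.score_from_gapped <- function(ga, gb, scoring) {
  a <- .seq_chars(ga); b <- .seq_chars(gb)
  gap <- a == "-" | b == "-"
  subs <- sum(ifelse(a[!gap] == b[!gap] & a[!gap] %in% c("A", "C", "G", "T"),
                     scoring$match, scoring$mismatch))
  runs <- rle(gap)
  gap_lens <- runs$lengths[runs$values]
  subs + sum(scoring$gap_open + gap_lens * scoring$gap_extend)
}

## ---- composition ----------------------------------------------------------

#' GC fraction of a sequence
#'
#' (#G + #C) / (#A + #C + #G + #T). Ambiguity codes and N are excluded from
#' numerator and denominator; a sequence with no unambiguous base is an
#' error (the fraction is undefined).
#'
#' @param seq A DNA sequence.
#' @return Fraction in \[0, 1\].
#' @export
gc_fraction <- function(seq) {
  chars <- .seq_chars(dna(seq))
  n_acgt <- sum(chars %in% c("A", "C", "G", "T"))
  if (n_acgt == 0L) stop("GC fraction undefined: no unambiguous bases")
  sum(chars %in% c("G", "C")) / n_acgt
}

## ---- ORFs -----------------------------------------------------------------

#' Six-frame open reading frames
#'
#' All maximal ATG-to-stop ORFs of at least `min_aa` codons on both strands
#' under the standard genetic code. For each stop-bounded segment the ORF
#' starts at the first (leftmost) ATG. Coordinates are 1-based on the
#' forward strand; frames are +1/+2/+3 and -1/-2/-3.
#'
#' @param seq A DNA sequence.
#' @param min_aa Minimum protein length in amino acids (>= 10), stop
#'   excluded.
#' @return A data.frame with columns frame, start, end, protein. Zero rows
#'   when no ORF qualifies.
#' @export
six_frame_orfs <- function(seq, min_aa = 10L) {
  stopifnot(min_aa >= 10L)
  s <- dna(seq)
  L <- nchar(s)
  out <- list()
  for (strand in c(1L, -1L)) {
    ss <- if (strand == 1L) s else reverse_complement(s)
    for (f in 0:2) {
      n_codons <- (nchar(ss) - f) %/% 3L
      if (n_codons < 1L) next
      codseq <- substr(ss, f + 1L, f + 3L * n_codons)
      aa <- .seq_chars(as.character(
        Biostrings::translate(Biostrings::DNAString(codseq),
                              no.init.codon = TRUE,
                              if.fuzzy.codon = "X")))
      stops <- which(aa == "*")
      seg_start <- 1L
      for (st in stops) {
        seg <- seg_start:st
        atg <- seg[which(aa[seg] == "M")]
        # leftmost ATG before this stop (excluding the stop itself)
        atg <- atg[atg < st]
        if (length(atg) > 0L) {
          i0 <- atg[1L]
          prot <- paste(aa[i0:(st - 1L)], collapse = "")
          if (nchar(prot) >= min_aa) {
            s1 <- f + 3L * (i0 - 1L) + 1L      # in ss coordinates
            e1 <- f + 3L * st                   # includes stop codon
            if (strand == 1L) {
              out[[length(out) + 1L]] <-
                data.frame(frame = f + 1L, start = s1, end = e1,
                           protein = prot, stringsAsFactors = FALSE)
            } else {
              out[[length(out) + 1L]] <-
                data.frame(frame = -(f + 1L), start = L - e1 + 1L,
                           end = L - s1 + 1L, protein = prot,
                           stringsAsFactors = FALSE)
            }
          }
        }
        seg_start <- st + 1L
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$frame), , drop = FALSE]
}

## ---- FASTA / alignment I/O ------------------------------------------------

#' Read a (multi-record) FASTA file
#'
#' Accepts any line width; residues are validated against the IUPAC DNA
#' alphabet and uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- vapply(seq_along(seqs), function(i) dna(seqs[[i]]), character(1))
  names(out) <- ids
  out
}

#' Write sequences to FASTA (70-column wrap)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

#' Read an externally produced multiple alignment
#'
#' Supports aligned FASTA and Clustal format. Rows are returned gapped
#' ('-') and equal length.
#'
#' @param path Path to the alignment file.
#' @param format "fasta" or "clustal".
#' @return A `sine_msa` object (see [star_msa()]).
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    rows <- toupper(as.character(set))
    ids <- sub("\\s.*$", "", names(rows))
  } else {
    lines <- readLines(path)
    if (length(lines) == 0L || !grepl("^CLUSTAL", lines[1L], ignore.case = TRUE))
      stop("not a Clustal-format file (missing CLUSTAL header)")
    body <- lines[-1L]
    body <- body[nzchar(trimws(body))]
    body <- body[!grepl("^\\s", body)]     # drop conservation lines
    toks <- strsplit(trimws(body), "\\s+")
    ids0 <- vapply(toks, `[[`, character(1), 1L)
    frag <- vapply(toks, `[[`, character(1), 2L)
    ids <- unique(ids0)
    rows <- vapply(ids, function(id)
      paste(frag[ids0 == id], collapse = ""), character(1))
    rows <- toupper(rows)
  }
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows differ in length")
  new_msa(ids, unname(rows))
}
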