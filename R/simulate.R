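## synthetic_data: genomes with planted SINE copies and full ground truth,
## so every pipeline stage is testable without external sequence data.

# a deterministic 76-bp tRNA-like head template carrying exact instances of
# the type-2 promoter box motifs (box A at 9, box B at 53); used when a
# family consensus is auto-generated.
.SIM_TRNA_HEAD <- paste0(
  "GCGGAAGT",            # acceptor-stem-like 5'
  "TGGCATAGCTTG",        # box A instance (TRGCNNARYNNG)
  "CAGACTTCAGGTTCTCCGTATGGACGTG",
  "ACCT",
  "GTTCGAATC",           # box B instance (GTTCRANNC)
  "CCGTAGCCGCCACCA")     # 3' acceptor-like end

#' Specification of a simulated SINE family
#'
#' Defaults mirror the copy architecture observed for small insect
#' tRNA-derived SINE families: a 386-bp consensus (a ~75-bp tRNA-like head
#' with planted promoter boxes, random body, (TGA) tail), TSDs of 5-19 bp
#' drawn from the insertion site, per-copy divergence uniform in
#' 0.03-0.23, 5' truncation of half the copies removing enough of the 5'
#' end to leave 75-356 bp, and insertion on either strand.
#'
#' @param name Family name.
#' @param consensus Optional consensus sequence; auto-generated when NULL.
#' @param length Total consensus length when auto-generating.
#' @param head_template Head sequence for auto-generation (default: a
#'   76-bp tRNA-like template with exact promoter box instances).
#' @param tail_unit Tandem tail unit (default "TGA").
#' @param tail_copies_range Min/max tail copies per planted copy.
#' @param divergence Per-copy substitution divergence; a single value or a
#'   range sampled uniformly per copy. Must satisfy
#'   `max(divergence) + indel_rate < 0.5`.
#' @param indel_rate Per-site indel probability (events of 1-3 bp).
#' @param truncation_prob Probability that a copy is 5'-truncated.
#' @param truncation_range Range of *retained* element length (bp) for
#'   truncated copies.
#' @param tsd_len_range TSD length range (within 4-25).
#' @param tsd_edit_prob Probability that the inserted TSD copy carries one
#'   edit.
#' @param n_copies Number of copies to plant.
#' @param gc Background GC used for auto-generated body sequence.
#' @param seed Seed for auto-generating the consensus body.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(name = "simSE1", consensus = NULL, length = 386L,
                        head_template = .SIM_TRNA_HEAD, tail_unit = "TGA",
                        tail_copies_range = c(3L, 10L),
                        divergence = c(0.03, 0.23), indel_rate = 0.005,
                        truncation_prob = 0.5,
                        truncation_range = c(75L, 356L),
                        tsd_len_range = c(5L, 19L), tsd_edit_prob = 0.1,
                        n_copies = 30L, gc = 0.361, seed = 20120203L) {
  stopifnot(all(divergence >= 0), max(divergence) <= 0.5,
            max(divergence) + indel_rate < 0.5,
            tsd_len_range[1L] >= 4L, tsd_len_range[2L] <= 25L,
            n_copies >= 0L)
  if (is.null(consensus)) {
    tail6 <- strrep(tail_unit, 6L)
    body_len <- length - nchar(head_template) - nchar(tail6)
    if (body_len < 20L) stop("consensus length too small for head + tail")
    body <- generate_background(body_len, gc = gc, seed = seed)
    consensus <- paste0(head_template, unname(body), tail6)
  }
  consensus <- dna(consensus)
  names(consensus) <- name
  structure(list(name = name, consensus = consensus,
                 head_length = nchar(head_template),
                 tail_unit = toupper(tail_unit),
                 tail_copies_range = as.integer(tail_copies_range),
                 divergence = divergence, indel_rate = indel_rate,
                 truncation_prob = truncation_prob,
                 truncation_range = as.integer(truncation_range),
                 tsd_len_range = as.integer(tsd_len_range),
                 tsd_edit_prob = tsd_edit_prob,
                 n_copies = as.integer(n_copies)),
            class = "family_spec")
}

#' Generate a random background genome
#'
#' i.i.d. bases with P(G) = P(C) = gc/2 and P(A) = P(T) = (1-gc)/2;
#' reproducible for a fixed seed.
#'
#' @param length Sequence length (>= 1).
#' @param gc GC fraction in (0, 1); 0.361 matches a typical
#'   moderately-AT-rich insect genome.
#' @param seed Integer seed; NULL uses the current RNG state.
#' @return A named character scalar (id "background").
#' @export
generate_background <- function(length, gc = 0.361, seed = NULL) {
  stopifnot(length >= 1L, gc > 0, gc < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- paste(sample(names(probs), length, replace = TRUE, prob = probs),
             collapse = "")
  names(s) <- "background"
  s
}

#' Mutate a copy of a consensus
#'
#' Per-site substitution with probability `divergence` (uniform over the
#' other three bases) and per-site indel events with probability
#' `indel_rate` (insertions or deletions of 1-3 bp, equiprobable).
#' Realized divergence is reported as events per consensus base.
#'
#' @param consensus Template sequence.
#' @param divergence Per-site substitution probability.
#' @param indel_rate Per-site indel event probability
#'   (`divergence + indel_rate < 0.5`).
#' @param seed Optional seed; NULL continues the current RNG stream.
#' @return list(copy, realized_divergence, n_substitutions, n_indels).
#' @export
mutate_copy <- function(consensus, divergence, indel_rate = 0, seed = NULL) {
  stopifnot(divergence + indel_rate < 0.5)
  if (!is.null(seed)) set.seed(as.integer(seed))
  chars <- .seq_chars(dna(consensus))
  L <- length(chars)
  orig_len <- L
  bases <- c("A", "C", "G", "T")
  sub_at <- which(stats::runif(L) < divergence)
  for (i in sub_at) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  }
  n_indels <- 0L
  if (indel_rate > 0) {
    indel_at <- which(stats::runif(L) < indel_rate)
    n_indels <- length(indel_at)
    # apply right-to-left so earlier positions stay valid
    for (i in rev(indel_at)) {
      size <- sample(1:3, 1L)
      if (stats::runif(1) < 0.5) {            # deletion
        hi <- min(L, i + size - 1L)
        chars <- chars[-(i:hi)]
      } else {                                 # insertion after i
        ins <- sample(bases, size, replace = TRUE)
        chars <- append(chars, ins, after = i)
      }
      L <- length(chars)
    }
  }
  list(copy = paste(chars, collapse = ""),
       realized_divergence = (length(sub_at) + n_indels) / orig_len,
       n_substitutions = length(sub_at), n_indels = n_indels)
}

# apply a single random substitution to a string
.edit_one <- function(s) {
  chars <- .seq_chars(s)
  i <- sample(length(chars), 1L)
  chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Plant a SINE family into a background genome
#'
#' For each copy: the consensus core is mutated, optionally 5'-truncated,
#' and given a tandem tail; a TSD is read from the insertion site
#' (target-site model) and duplicated on both sides of the copy; the copy
#' is inserted at a uniformly random position on a uniformly random
#' strand. Copies never overlap and keep >= 100 bp of background between
#' insertion sites. All truth coordinates refer to the final genome, and
#' the truth TSD is verbatim present flanking each copy (modulo the
#' optional single edit on the inserted side).
#'
#' @param genome A background genome (named character scalar).
#' @param spec A [family_spec()].
#' @param seed Integer seed driving all randomness of the planting.
#' @return list(genome, truth) where truth is a data.frame with one row
#'   per planted copy: copy_id, family, contig, start, end (start > end on
#'   the minus strand), strand, tsd_seq, tsd_len, tsd_edited, truncated,
#'   missing_5prime_bp, realized_divergence, tail_copies, element_length.
#' @export
plant_family <- function(genome, spec, seed = 1L) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(as.integer(seed))
  contig <- if (is.null(names(genome))) "contig1" else names(genome)[1L]
  bg <- unname(dna(genome))
  L <- nchar(bg)
  n <- spec$n_copies
  if (n == 0L)
    return(list(genome = setNames(bg, contig),
                truth = .empty_truth()))
  max_tsd <- spec$tsd_len_range[2L]
  spacing <- 100L
  usable <- L - max_tsd - 1L
  if (usable - (n - 1L) * spacing < n)
    stop("genome too short for non-overlapping placement")
  # sorted sites with >= `spacing` bp of background between them
  raw <- sort(sample.int(usable - (n - 1L) * spacing, n))
  sites <- raw + (seq_len(n) - 1L) * spacing

  # strip the consensus tail; per-copy tails are appended fresh
  cons <- unname(spec$consensus)
  core <- cons
  tail6 <- strrep(spec$tail_unit, 6L)
  if (endsWith(core, tail6))
    core <- substr(core, 1L, nchar(core) - nchar(tail6))

  inserts <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    div <- if (length(spec$divergence) > 1L)
      stats::runif(1L, spec$divergence[1L], spec$divergence[2L])
    else spec$divergence
    mut <- mutate_copy(core, div, spec$indel_rate)
    copy <- mut$copy
    truncated <- stats::runif(1L) < spec$truncation_prob
    missing <- 0L
    if (truncated) {
      keep <- sample(spec$truncation_range[1L]:min(spec$truncation_range[2L],
                                                   nchar(copy)), 1L)
      missing <- nchar(copy) - keep
      copy <- substr(copy, missing + 1L, nchar(copy))
    }
    tail_copies <- sample(spec$tail_copies_range[1L]:spec$tail_copies_range[2L], 1L)
    element <- paste0(copy, strrep(spec$tail_unit, tail_copies))
    strand <- sample(c("+", "-"), 1L)
    oriented <- if (strand == "+") element
                else unname(reverse_complement(element))
    tsd_len <- sample(spec$tsd_len_range[1L]:spec$tsd_len_range[2L], 1L)
    tsd <- substr(bg, sites[i] + 1L, sites[i] + tsd_len)
    tsd_edited <- stats::runif(1L) < spec$tsd_edit_prob
    tsd_left <- if (tsd_edited) .edit_one(tsd) else tsd
    inserts[i] <- paste0(tsd_left, oriented)
    truth[[i]] <- data.frame(
      copy_id = sprintf("%s.%d", spec$name, i), family = spec$name,
      contig = contig, start = NA_integer_, end = NA_integer_,
      strand = strand, tsd_seq = tsd, tsd_len = tsd_len,
      tsd_edited = tsd_edited, truncated = truncated,
      missing_5prime_bp = missing,
      realized_divergence = mut$realized_divergence,
      tail_copies = tail_copies,
      element_length = nchar(element), stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)

  # assemble and compute final coordinates
  pieces <- character(2L * n + 1L)
  prev <- 0L
  offset <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- substr(bg, prev + 1L, sites[i])
    pieces[2L * i] <- inserts[i]
    elem_start <- sites[i] + offset + truth$tsd_len[i] + 1L
    elem_end <- elem_start + truth$element_length[i] - 1L
    if (truth$strand[i] == "+") {
      truth$start[i] <- elem_start; truth$end[i] <- elem_end
    } else {
      truth$start[i] <- elem_end; truth$end[i] <- elem_start
    }
    offset <- offset + nchar(inserts[i])
    prev <- sites[i]
  }
  pieces[2L * n + 1L] <- substr(bg, prev + 1L, L)
  new_genome <- paste(pieces, collapse = "")
  names(new_genome) <- contig
  list(genome = new_genome, truth = truth)
}

.empty_truth <- function() {
  data.frame(copy_id = character(), family = character(),
             contig = character(), start = integer(), end = integer(),
             strand = character(), tsd_seq = character(),
             tsd_len = integer(), tsd_edited = logical(),
             truncated = logical(), missing_5prime_bp = integer(),
             realized_divergence = numeric(), tail_copies = integer(),
             element_length = integer(), stringsAsFactors = FALSE)
}

#' Write a simulation to disk
#'
#' Genome FASTA, truth table TSV, truth BED, and the generating parameters
#' as JSON (seed included) for full provenance.
#'
#' @param sim A list from [plant_family()].
#' @param spec The [family_spec()] used.
#' @param seed The planting seed used.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, spec, seed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  if (nrow(tr) > 0L) {
    bed <- data.frame(tr$contig, pmin(tr$start, tr$end) - 1L,
                      pmax(tr$start, tr$end), tr$copy_id, 0L, tr$strand)
    write.table(bed, file.path(dir, "truth.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  pars <- spec[setdiff(names(spec), "consensus")]
  pars$consensus <- unname(spec$consensus)
  pars$seed <- seed
  jsonlite::write_json(pars, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
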