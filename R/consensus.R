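## consensus: family consensus construction from member copies and the
## per-copy identity profile (min/median/max) reported per family.

#' Construct a multiple alignment object
#'
#' @param ids Row ids.
#' @param rows Equal-length gapped strings ('-' gaps).
#' @return A list of class `sine_msa` (ids, rows, width, n).
#' @export
new_msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows), length(rows) >= 2L)
  widths <- unique(nchar(rows))
  if (length(widths) != 1L) stop("MSA rows differ in length")
  structure(list(ids = as.character(ids), rows = unname(rows),
                 width = widths, n = length(rows)), class = "sine_msa")
}

#' @export
print.sine_msa <- function(x, ...) {
  cat(sprintf("<sine_msa %d sequences x %d columns>\n", x$n, x$width))
  invisible(x)
}

#' @export
as.matrix.sine_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$rows, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Ungap MSA rows (recovers the input sequences)
#' @param msa A `sine_msa`.
#' @return Named character vector of ungapped sequences.
#' @export
ungap_msa <- function(msa) {
  out <- gsub("-", "", msa$rows, fixed = TRUE)
  names(out) <- msa$ids
  out
}

#' Star multiple alignment around a seed copy
#'
#' Every copy is globally aligned to the seed (default: the longest copy;
#' ties broken by input order) and the pairwise alignments are projected
#' onto common coordinates by merging the insertion columns each copy
#' induces between seed positions. Deterministic for a fixed input order;
#' ungapping any row recovers the input copy.
#'
#' @param copies Named character vector of >= 2 copies.
#' @param seed_id Optional id of the seed copy.
#' @param scoring An [align_scoring()].
#' @return A `sine_msa` whose rows follow the input order.
#' @export
star_msa <- function(copies, seed_id = NULL, scoring = align_scoring()) {
  if (length(copies) < 2L) stop("star_msa needs at least 2 copies")
  if (is.null(names(copies)) || any(!nzchar(names(copies))))
    names(copies) <- paste0("copy", seq_along(copies))
  copies <- vapply(names(copies), function(i) dna(copies[[i]]), character(1))
  if (is.null(seed_id)) seed_id <- names(copies)[which.max(nchar(copies))]
  if (!seed_id %in% names(copies)) stop("seed_id not among copies")
  seed <- copies[[seed_id]]
  L <- nchar(seed)

  # per copy: chars aligned to each seed position (or '-') and insertion
  # strings between seed positions (slot j = insertion after seed pos j,
  # slot 0 = before the first seed position)
  proj <- list()
  for (id in names(copies)) {
    if (id == seed_id) {
      proj[[id]] <- list(at = .seq_chars(seed), ins = rep("", L + 1L))
      next
    }
    aln <- global_align(copies[[id]], seed, scoring)
    a <- .seq_chars(aln$gapped_a)   # copy row
    b <- .seq_chars(aln$gapped_b)   # seed row
    at <- character(L); ins <- rep("", L + 1L)
    spos <- 0L
    for (k in seq_along(b)) {
      if (b[k] == "-") {
        ins[spos + 1L] <- paste0(ins[spos + 1L], a[k])
      } else {
        spos <- spos + 1L
        at[spos] <- a[k]
      }
    }
    proj[[id]] <- list(at = at, ins = ins)
  }
  max_ins <- Reduce(pmax, lapply(proj, function(p) nchar(p$ins)))
  rows <- vapply(names(copies), function(id) {
    p <- proj[[id]]
    parts <- character(2L * L + 1L)
    for (j in 0:L) {
      block <- p$ins[j + 1L]
      pad <- max_ins[j + 1L] - nchar(block)
      parts[2L * j + 1L] <- paste0(block, strrep("-", pad))
      if (j < L) parts[2L * j + 2L] <- p$at[j + 1L]
    }
    paste(parts, collapse = "")
  }, character(1))
  new_msa(names(copies), rows)
}

#' Majority-rule consensus of a multiple alignment
#'
#' Per column: the most frequent base, provided its frequency among
#' non-gap characters reaches `min_fraction`, else 'N' (ties broken
#' alphabetically). Columns whose gap frequency exceeds `gap_rule` are
#' dropped, so insertions carried by a minority of copies do not enter the
#' consensus.
#'
#' @param msa A `sine_msa`.
#' @param min_fraction Majority threshold among non-gap characters
#'   (default 0.5).
#' @param gap_rule Columns with gap frequency > `gap_rule` are dropped
#'   (default 0.5).
#' @return The consensus sequence (character scalar, named "consensus").
#' @export
majority_consensus <- function(msa, min_fraction = 0.5, gap_rule = 0.5) {
  m <- as.matrix(msa)
  out <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gap_frac <- mean(col == "-")
    if (gap_frac > gap_rule) next
    bases <- col[col != "-"]
    tab <- sort(table(bases), decreasing = TRUE)
    # deterministic tie-break: alphabetical among top counts
    top <- names(tab)[tab == tab[1L]]
    base <- sort(top)[1L]
    out <- c(out, if (tab[1L] / length(bases) >= min_fraction) base else "N")
  }
  cons <- paste(out, collapse = "")
  names(cons) <- "consensus"
  cons
}

#' Identity profile of family copies against a consensus
#'
#' Each copy is aligned to the consensus with free terminal gaps (so
#' truncated copies are scored over their aligned core) and the identity
#' distribution is summarized as min / exact median / max. The median is
#' the middle order statistic (mean of the two central values for even n),
#' and is invariant to copy input order.
#'
#' @param copies Named character vector of copies.
#' @param consensus Consensus sequence.
#' @param scoring An [align_scoring()].
#' @return A list of class `consensus_profile`: consensus, per_copy
#'   (named identities), min, median, max, n.
#' @export
identity_profile <- function(copies, consensus, scoring = align_scoring()) {
  if (length(copies) == 0L) stop("empty copy list")
  consensus <- dna(consensus)
  if (nchar(consensus) == 0L) stop("empty consensus")
  if (is.null(names(copies)))
    names(copies) <- paste0("copy", seq_along(copies))
  ids <- vapply(names(copies), function(id)
    overlap_align(copies[[id]], consensus, scoring)$identity, numeric(1))
  structure(list(consensus = consensus, per_copy = ids,
                 min = min(ids), median = median(ids), max = max(ids),
                 n = length(ids)),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("<consensus_profile n=%d identity min/median/max = %.3f/%.3f/%.3f>\n",
              x$n, x$min, x$median, x$max))
  invisible(x)
}

#' Write a consensus profile report
#'
#' A per-copy TSV (copy_id, identity) and a JSON summary
#' (min/median/max/n).
#'
#' @param profile A `consensus_profile`.
#' @param tsv_path,json_path Output paths (NULL to skip either).
#' @export
write_profile_report <- function(profile, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    write.table(data.frame(copy_id = names(profile$per_copy),
                           identity = unname(profile$per_copy)),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(n = profile$n, min = profile$min,
                              median = profile$median, max = profile$max),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(profile)
}

#' Write an MSA as aligned FASTA
#'
#' @param msa A `sine_msa`.
#' @param path Output path.
#' @export
write_alignment <- function(msa, path) {
  write_fasta(setNames(msa$rows, msa$ids), path)
}
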