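## genome_stats: flanking GC content, copy-number extrapolation from a
## sampled genome fraction, and genomic-context labeling against a GFF3
## annotation.

#' GC content of element flanks
#'
#' GC fraction of the `window` bases upstream and downstream of an element
#' in its own orientation (for minus-strand elements the 5' flank is the
#' element's 5' in reading orientation). Windows are clipped at contig
#' edges and flagged; a side with no available sequence gets NA.
#'
#' @param genome Named character vector of contigs.
#' @param loc A `genomic_location`.
#' @param window Flank window in bp (default 2000, the standard window for
#'   insertion-site GC profiles).
#' @return list(gc_5prime, gc_3prime, window, truncated_5, truncated_3).
#' @export
flank_gc <- function(genome, loc, window = 2000L) {
  ex <- extract_with_flanks(genome, loc, flank = window)
  n5 <- nchar(ex$left_flank); n3 <- nchar(ex$right_flank)
  list(gc_5prime = if (n5 > 0L) gc_fraction(ex$left_flank) else NA_real_,
       gc_3prime = if (n3 > 0L) gc_fraction(ex$right_flank) else NA_real_,
       window = window,
       truncated_5 = n5 < window,
       truncated_3 = n3 < window)
}

# round-half-up to `digits` significant figures
.signif_half_up <- function(x, digits = 2L) {
  if (x == 0) return(0)
  mag <- floor(log10(abs(x)))
  scale <- 10^(mag - digits + 1)
  floor(abs(x) / scale + 0.5) * scale * sign(x)
}

# round-half-up to `digits` decimal places
.round_half_up <- function(x, digits = 1L) {
  scale <- 10^digits
  floor(abs(x) * scale + 0.5) / scale * sign(x)
}

#' Extrapolate genome-wide copy number from a sampled fraction
#'
#' Linear scaling of an observed copy count from the sampled megabases to
#' the full genome size, with the raw estimate rounded to `sig_digits`
#' significant figures (round-half-up), the convention used when such
#' estimates are quoted. Also reports the sampled fraction as a percentage
#' (1 decimal).
#'
#' @param observed_count Copies observed in the sampled sequence.
#' @param sampled_mb Sampled sequence in Mb (default 1.963, a typical
#'   BAC-clone sample).
#' @param genome_mb Genome size in Mb (default 400).
#' @param sig_digits Significant figures for the rounded estimate
#'   (default 2).
#' @return A list of class `copy_number_estimate`: observed_count,
#'   sampled_mb, genome_mb, raw_estimate, rounded_estimate,
#'   sampled_fraction_pct.
#' @export
estimate_copy_number <- function(observed_count, sampled_mb = 1.963,
                                 genome_mb = 400, sig_digits = 2L) {
  if (sampled_mb <= 0) stop("sampled_mb must be positive")
  if (genome_mb < sampled_mb) stop("genome_mb must be >= sampled_mb")
  if (observed_count < 0) stop("observed_count must be >= 0")
  raw <- observed_count * genome_mb / sampled_mb
  structure(list(observed_count = as.integer(observed_count),
                 sampled_mb = sampled_mb, genome_mb = genome_mb,
                 raw_estimate = raw,
                 rounded_estimate = .signif_half_up(raw, sig_digits),
                 sampled_fraction_pct =
                   .round_half_up(100 * sampled_mb / genome_mb, 1L)),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf(
    "<copy_number_estimate: %d copies in %.3f Mb (%.1f%% of %g Mb) -> ~%s genome-wide>\n",
    x$observed_count, x$sampled_mb, x$sampled_fraction_pct, x$genome_mb,
    format(x$rounded_estimate, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Read a GFF3 annotation
#'
#' Thin wrapper over rtracklayer's GFF3 importer returning a GRanges; a
#' parse failure is reported with the file name.
#'
#' @param path Path to a GFF3 file.
#' @return A GRanges of features.
#' @export
read_gff3 <- function(path) {
  tryCatch(rtracklayer::import(path, format = "gff3"),
           error = function(e)
             stop(sprintf("malformed GFF3 '%s': %s", path,
                          conditionMessage(e))))
}

.TE_TYPES <- c("transposable_element", "repeat_region", "dispersed_repeat",
               "mobile_genetic_element", "transposable_element_gene")

#' Label the genomic context of an insertion
#'
#' Precedence: exonic (overlaps any exon) > intronic (fully inside a gene
#' but no exon overlap) > near_TE (within `te_distance` of a transposable
#' element feature) > intergenic. Also reports the nearest feature.
#'
#' @param loc A `genomic_location`.
#' @param annotation A GRanges from [read_gff3()] or a GFF3 path.
#' @param te_distance Distance threshold for near_TE in bp (default 1000).
#' @return list(context, nearest_feature_type, nearest_feature_id,
#'   nearest_distance).
#' @export
genomic_context <- function(loc, annotation, te_distance = 1000L) {
  stopifnot(inherits(loc, "genomic_location"))
  if (is.character(annotation)) annotation <- read_gff3(annotation)
  gr <- GenomicRanges::GRanges(
    seqnames = loc$contig,
    ranges = IRanges::IRanges(start = .loc_lo(loc), end = .loc_hi(loc)))
  type <- as.character(annotation$type)
  feat_id <- if (!is.null(annotation$ID)) as.character(annotation$ID)
             else as.character(seq_along(annotation))
  exons <- annotation[type == "exon"]
  genes <- annotation[type == "gene"]
  tes <- annotation[type %in% .TE_TYPES]
  context <- "intergenic"
  if (length(exons) > 0L &&
      length(GenomicRanges::findOverlaps(gr, exons)) > 0L) {
    context <- "exonic"
  } else if (length(genes) > 0L &&
             any(IRanges::overlapsAny(gr, genes, type = "within"))) {
    context <- "intronic"
  } else if (length(tes) > 0L) {
    d <- GenomicRanges::distanceToNearest(gr, tes)
    if (length(d) > 0L &&
        S4Vectors::mcols(d)$distance <= te_distance) context <- "near_TE"
  }
  nearest <- list(type = NA_character_, id = NA_character_,
                  distance = NA_integer_)
  if (length(annotation) > 0L) {
    dn <- GenomicRanges::distanceToNearest(gr, annotation)
    if (length(dn) > 0L) {
      i <- S4Vectors::subjectHits(dn)[1L]
      nearest <- list(type = type[i], id = feat_id[i],
                      distance = S4Vectors::mcols(dn)$distance[1L])
    }
  }
  list(context = context, nearest_feature_type = nearest$type,
       nearest_feature_id = nearest$id, nearest_distance = nearest$distance)
}

#' Label the genomic context of many copies at once
#'
#' @param locs A list of `genomic_location`s.
#' @param annotation A GRanges or GFF3 path.
#' @param te_distance Distance threshold for near_TE in bp.
#' @return data.frame(contig, start, end, context, nearest_feature_type,
#'   nearest_feature_id); labels partition the copies (each copy gets
#'   exactly one).
#' @export
genomic_context_table <- function(locs, annotation, te_distance = 1000L) {
  if (is.character(annotation)) annotation <- read_gff3(annotation)
  rows <- lapply(locs, function(loc) {
    ctx <- genomic_context(loc, annotation, te_distance)
    data.frame(contig = loc$contig, start = loc$start, end = loc$end,
               context = ctx$context,
               nearest_feature_type = ctx$nearest_feature_type,
               nearest_feature_id = ctx$nearest_feature_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
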