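## pipeline: end-to-end orchestration (scan -> extract -> annotate ->
## consensus -> profile -> stats) and validation of published copy tables.

#' Pipeline configuration
#'
#' All stage parameters in one serializable list. `flank` is the window
#' extracted around each hit for hallmark analysis; `gc_window` the larger
#' window for insertion-site GC profiles.
#'
#' @param word_size,min_identity,min_length Scan parameters (see
#'   [scan_genome()]).
#' @param merge_gap Maximum gap when merging fragmented hits.
#' @param flank Hallmark-analysis flank in bp (default 200).
#' @param gc_window GC-profile flank in bp (default 2000).
#' @param annotation An [annotation_config()].
#' @param consensus_min_fraction,consensus_gap_rule Majority-consensus
#'   rules.
#' @param refine_tails Extend hit 3' ends through tandem tails (default
#'   TRUE).
#' @param iterate Re-scan once with the derived consensus as query
#'   (default FALSE).
#' @param sampled_mb,genome_mb Copy-number extrapolation defaults.
#' @param scoring An [align_scoring()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(word_size = 11L, min_identity = 0.70,
                            min_length = 80L, merge_gap = 50L,
                            flank = 200L, gc_window = 2000L,
                            annotation = annotation_config(),
                            consensus_min_fraction = 0.5,
                            consensus_gap_rule = 0.5,
                            refine_tails = TRUE, iterate = FALSE,
                            sampled_mb = 1.963, genome_mb = 400,
                            scoring = align_scoring()) {
  structure(as.list(environment()), class = "pipeline_config")
}

.hit_locations <- function(hits) {
  lapply(seq_len(nrow(hits)), function(i)
    genomic_location(hits$contig[i], hits$start[i], hits$end[i]))
}

#' Characterize a SINE family in a genome
#'
#' Runs the full workflow: scan the genome with the query (both strands),
#' merge fragmented hits, refine 3' boundaries through tandem tails,
#' extract each element with flanks and annotate its hallmarks, build a
#' star alignment and majority consensus from the recovered copies,
#' profile per-copy identity against that consensus, and compute
#' flanking-GC statistics. With `config$iterate`, the genome is re-scanned
#' once using the derived consensus as the query before annotation (the
#' usual trick for pulling in copies diverged from the original seed
#' query).
#'
#' @param genome Named character vector of contigs, or a FASTA path.
#' @param query Named character scalar (family seed/consensus), or a FASTA
#'   path with one record.
#' @param references Optional reference RNA library (named vector or FASTA
#'   path) for head classification.
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for TSV/GFF3/JSON reports.
#' @return A list of class `sine_family_report`: hits, annotations (list),
#'   annotation_table (data.frame), msa, consensus, profile, stats.
#' @export
run_characterize <- function(genome, query, references = NULL,
                             config = pipeline_config(), output_dir = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (is.character(query) && length(query) == 1L && file.exists(query))
    query <- read_fasta(query)
  if (!is.null(references) && is.character(references) &&
      length(references) == 1L && file.exists(references))
    references <- read_fasta(references)

  hits <- scan_genome(query, genome, config$word_size, config$min_identity,
                      config$min_length, config$scoring)
  hits <- merge_hits(hits, config$merge_gap)
  if (config$iterate && nrow(hits) >= 2L) {
    elems <- .extract_elements(genome, hits)
    msa0 <- star_msa(elems, scoring = config$scoring)
    cons0 <- majority_consensus(msa0, config$consensus_min_fraction,
                                config$consensus_gap_rule)
    if (!grepl("^N*$", cons0)) {
      hits2 <- scan_genome(setNames(unname(cons0), "derived_consensus"),
                           genome, config$word_size, config$min_identity,
                           config$min_length, config$scoring)
      hits2 <- merge_hits(hits2, config$merge_gap)
      if (nrow(hits2) >= nrow(hits)) hits <- hits2
    }
  }
  if (config$refine_tails && nrow(hits) > 0L) {
    # the query's own terminal tandem unit (if any) anchors the phase
    qt <- tryCatch(
      find_tail_repeat(query, max_unit = config$annotation$tail_max_unit,
                       tail_window = min(config$annotation$tail_window,
                                         nchar(query)),
                       min_copies = 2, min_purity = 0.95),
      error = function(e) NULL)
    q_unit <- if (!is.null(qt) && qt$distance_from_3prime == 0L) qt$unit
              else NULL
    for (i in seq_len(nrow(hits))) {
      loc <- refine_tail_boundary(
        genome, genomic_location(hits$contig[i], hits$start[i], hits$end[i]),
        unit = q_unit, max_unit = config$annotation$tail_max_unit)
      hits$start[i] <- loc$start; hits$end[i] <- loc$end
    }
  }
  if (nrow(hits) == 0L) {
    return(structure(list(hits = hits, annotations = list(),
                          annotation_table = NULL, msa = NULL,
                          consensus = NULL, profile = NULL, stats = NULL),
                     class = "sine_family_report"))
  }
  elems <- .extract_elements(genome, hits)
  msa <- NULL; consensus <- NULL; profile <- NULL
  if (length(elems) >= 2L) {
    msa <- star_msa(elems, scoring = config$scoring)
    consensus <- majority_consensus(msa, config$consensus_min_fraction,
                                    config$consensus_gap_rule)
    profile <- identity_profile(elems, consensus, config$scoring)
  }
  annotations <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    loc <- genomic_location(hits$contig[i], hits$start[i], hits$end[i])
    ex <- extract_with_flanks(genome, loc, config$flank)
    annotations[[i]] <- annotate_element(
      ex$element, ex$left_flank, ex$right_flank,
      consensus = if (is.null(consensus)) NULL else unname(consensus),
      references = references, config = config$annotation,
      copy_id = sprintf("%s_copy%d", hits$query_id[i], i), location = loc)
  }
  ann_df <- annotations_to_df(annotations)
  gc <- do.call(rbind, lapply(.hit_locations(hits), function(loc) {
    g <- flank_gc(genome, loc, config$gc_window)
    data.frame(gc_5prime = g$gc_5prime, gc_3prime = g$gc_3prime)
  }))
  stats <- list(n_copies = nrow(hits),
                n_full_length = sum(ann_df$truncation == "full_length"),
                n_truncated = sum(ann_df$truncation == "five_prime_truncated"),
                mean_gc_5prime = mean(gc$gc_5prime, na.rm = TRUE),
                mean_gc_3prime = mean(gc$gc_3prime, na.rm = TRUE))
  report <- structure(list(hits = hits, annotations = annotations,
                           annotation_table = cbind(ann_df, gc),
                           msa = msa, consensus = consensus,
                           profile = profile, stats = stats),
                      class = "sine_family_report")
  if (!is.null(output_dir)) .write_report(report, output_dir)
  report
}

.extract_elements <- function(genome, hits) {
  elems <- vapply(seq_len(nrow(hits)), function(i) {
    ex <- extract_with_flanks(
      genome, genomic_location(hits$contig[i], hits$start[i], hits$end[i]),
      flank = 0L)
    ex$element
  }, character(1))
  names(elems) <- sprintf("%s_copy%d", hits$query_id, seq_len(nrow(hits)))
  elems
}

.write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$hits, file.path(dir, "hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hits_to_bed(report$hits, file.path(dir, "hits.bed"))
  write.table(report$annotation_table, file.path(dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_annotations_gff3(report$annotations, file.path(dir, "annotations.gff3"))
  if (!is.null(report$msa))
    write_alignment(report$msa, file.path(dir, "family_alignment.fa"))
  if (!is.null(report$consensus))
    write_fasta(report$consensus, file.path(dir, "consensus.fa"))
  if (!is.null(report$profile))
    write_profile_report(report$profile,
                         tsv_path = file.path(dir, "identity_profile.tsv"),
                         json_path = file.path(dir, "identity_summary.json"))
  jsonlite::write_json(report$stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.sine_family_report <- function(x, ...) {
  cat(sprintf("<sine_family_report: %d copies", nrow(x$hits)))
  if (!is.null(x$profile))
    cat(sprintf(", identity min/median/max %.2f/%.2f/%.2f",
                x$profile$min, x$profile$median, x$profile$max))
  cat(">\n")
  invisible(x)
}

## ---- copy tables ----------------------------------------------------------

#' Packaged SINE copy coordinate tables
#'
#' Transcriptions of the published full-length (HaSE1/HaSE2) and
#' 5'-truncated (HaSE1) copy tables for the cotton bollworm BAC survey,
#' with columns name, accession, start, end, length (plus identity_pct or
#' tsd, and flanking GC percentages). Coordinates are 1-based inclusive
#' with start > end encoding the minus strand.
#'
#' @param which "full_length" (HaSE1.1-HaSE1.22 and HaSE2.1-HaSE2.7) or
#'   "truncated" (HaSE1.23-HaSE1.43).
#' @return A data.frame.
#' @export
hase_copy_table <- function(which = c("full_length", "truncated")) {
  which <- match.arg(which)
  f <- if (which == "full_length") "hase_table1.tsv" else "hase_table2.tsv"
  path <- system.file("extdata", f, package = "sinescout", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Validate a copy coordinate table
#'
#' Recomputes each row's length from its coordinates and flags rows whose
#' printed length disagrees; flags coordinate-duplicate rows; summarizes
#' copy counts by family and by accession class (BAC-resident FP-prefixed
#' accessions vs other).
#'
#' @param table A data.frame with columns name, accession, start, end,
#'   length, or a path to such a TSV.
#' @return A list of class `copy_table_validation`: table (with
#'   length_expected and length_ok columns), n_length_mismatch,
#'   duplicates (data.frame), counts (family x accession-class).
#' @export
validate_copy_table <- function(table) {
  if (is.character(table)) table <- read.delim(table, stringsAsFactors = FALSE)
  req <- c("name", "accession", "start", "end", "length")
  if (!all(req %in% names(table)))
    stop("copy table must have columns: ", paste(req, collapse = ", "))
  tab <- table
  tab$length_expected <- abs(tab$end - tab$start) + 1L
  tab$length_ok <- tab$length_expected == tab$length
  key <- paste(tab$accession, pmin(tab$start, tab$end),
               pmax(tab$start, tab$end))
  dup_keys <- unique(key[duplicated(key)])
  duplicates <- tab[key %in% dup_keys, c("name", "accession", "start", "end")]
  fam <- sub("\\..*$", "", tab$name)
  acc_class <- ifelse(grepl("^FP", tab$accession), "BAC", "other")
  counts <- as.data.frame(table(family = fam, accession_class = acc_class))
  counts <- counts[counts$Freq > 0L, ]
  rownames(counts) <- NULL
  structure(list(table = tab,
                 n_length_mismatch = sum(!tab$length_ok),
                 duplicates = duplicates, counts = counts),
            class = "copy_table_validation")
}

#' @export
print.copy_table_validation <- function(x, ...) {
  cat(sprintf("<copy_table_validation: %d rows, %d length mismatch(es), %d duplicate row(s)>\n",
              nrow(x$table), x$n_length_mismatch, nrow(x$duplicates)))
  print(x$counts)
  invisible(x)
}
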