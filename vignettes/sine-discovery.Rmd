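---
title: "Discovering and characterizing SINE families with sinescout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and characterizing SINE families with sinescout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinescout)
```

## The problem

Short interspersed nuclear elements (SINEs) are nonautonomous
retrotransposons of roughly 80–500 bp. A typical family has a three-part
architecture: a 5′ *head* derived from a structural RNA (usually a tRNA,
sometimes 5S rRNA) carrying an internal RNA polymerase III promoter; an
RNA-unrelated *body*; and a 3′ *tail* recognized by the reverse
transcriptase of an autonomous partner LINE. Because integration proceeds
by target-primed reverse transcription, each insertion is flanked by a
short direct repeat of the target site (the target site duplication,
TSD), and incomplete reverse transcription leaves many copies truncated
at their 5′ end.

`sinescout` turns the manual workflow used to characterize such families
— BLAST a seed sequence, extract hits with flanks, eyeball TSDs and
promoter boxes, build a consensus, compare families, extrapolate copy
numbers — into a reproducible pipeline, and pairs it with a simulator
that plants SINE copies with full ground truth so that every stage can be
validated quantitatively.

## The pipeline

`run_characterize()` chains the stages; each is also exported on its own.

1. **Scan** (`scan_genome`): exact k-mer seeds (default word size 11) are
   chained along diagonals; each chained locus is extended by ends-free
   gapped alignment of the query against the candidate window, on both
   strands. Minus-strand hits are reported with `start > end`, the
   convention used in published copy tables. Defaults: minimum identity
   0.70, minimum aligned length 80 bp (the lower bound of the SINE size
   range).
2. **Boundary refinement** (`refine_tail_boundary`): tandem tails vary in
   copy number between copies, so an alignment-defined 3′ boundary
   routinely stops inside the tail or absorbs a few AT-rich target-site
   bases. The boundary is re-derived from the repeat itself: the last run
   of at least two exact units near the hit terminus is located and the
   boundary set to the end of its whole-unit continuation in the genome.
   Supplying the unit from the family consensus anchors the phase.
3. **Hallmark annotation** (`annotate_element`): TSD search, promoter
   scans, head classification, tail detection, truncation call (details
   below).
4. **Consensus and profile** (`star_msa`, `majority_consensus`,
   `identity_profile`): a star alignment around the longest copy,
   a majority-rule consensus, and the per-copy identity distribution
   (min / exact median / max) that is conventionally reported per family.
5. **Statistics** (`flank_gc`, `estimate_copy_number`,
   `genomic_context`): insertion-site GC over 2 kb windows, genome-wide
   copy-number extrapolation from a sampled fraction, and
   exonic/intronic/near-TE/intergenic labeling against a GFF3 annotation.

## Alignment conventions

All pairwise alignment is affine-gap (match +1, mismatch −1, gap open −2,
gap extend −0.5 by default; a gap of length L costs
`gap_open + L·gap_extend`). Three entry points share the engine:

* `global_align` — Needleman–Wunsch, terminal gaps penalized;
* `overlap_align` — free terminal gaps on both sequences. This is
  mathematically the same optimization as Smith–Waterman (skipped
  prefixes and suffixes are free, the contiguous core is maximized), and
  is implemented that way;
* `local_align` — Smith–Waterman proper.

**Identity** is matches divided by counted columns, where counted columns
exclude terminal overhangs and include internal gap columns as
mismatches. The published identity percentages this package aims to
reproduce were produced by unstated alignment settings, so exact
reproduction of any single printed identity is not guaranteed; the
convention here is fixed, documented, and self-consistent. `N` and
ambiguity codes never match anything, including themselves.

Segment-level comparison (`best_local_match`, `detect_chimera`,
`match_line_partner`) defaults to a stringent local regime
(+1/−2, gaps −5/−2, the classic nucleotide-BLAST parameters). Under the
lenient global defaults, a Smith–Waterman search of two unrelated 500-mers
happily chains short chance matches through cheap gaps into "segments"
of 50+ columns at ~55% identity; the stringent regime returns compact
high-identity segments, which is what a shared-domain or shared-tail call
needs.

## TSD detection

`find_tsd` searches the final 30 bp of the left flank and the first 30 bp
of the right flank for the best pair of substrings of 5–19 bp within one
edit (Levenshtein) of each other. Pairs are ranked by edit-corrected
length (`length − edits`), then fewest edits, then proximity to the
element boundaries, then coordinate. Two constraints reflect the biology
and keep the search honest on AT-rich genomes:

* **Adjacency**: a genuine TSD abuts the insertion, so the left copy must
  end, and the right copy start, within 5 bp of the element boundary
  (`max_offset`). At 36% GC, two unconstrained 30-bp windows contain on
  the order of one chance 5–6-mer pair, which would regularly outrank a
  short true TSD under longest-first ranking.
* **Edit-corrected ranking**: with plain longest-first ranking, a perfect
  duplication of length L is always beaten by itself plus one flank base
  and one spent edit (length L+1, one edit). Ranking by `length − edits`
  makes the perfect pair win that tie while still preferring a genuinely
  longer imperfect duplication — e.g. a 14-bp pair with one internal
  insertion beats its own 8-bp exact sub-pair.

Absence of a TSD is a legal outcome; some genuine copies have none.

## Promoter boxes and head classification

The type-2 (tRNA-type) promoter is scanned with IUPAC consensus motifs
box A `TRGCNNARYNNG` and box B `GTTCRANNC`, up to 2 mismatches each, box
A before box B, with the 20–80 bp inter-box spacing reported as a flag
rather than a gate. The type-1 (5S-type) layout is scanned the same way
with three ordered boxes A/IE/C; the default patterns are loose
approximations distilled from the strongly conserved eukaryotic 5S rRNA
internal control region layout (+50/+67/+80) and should be overridden
with family-specific patterns where known — the families that motivated
this package had their boxes labeled by hand. All motifs and allowances
are configuration, not constants.

Head classification aligns the first 90 bp of the element (tRNA-derived
heads run 70–76 bp) to a user-supplied reference RNA library and scores
each reference by *coverage-corrected identity*: matches divided by the
length of the shorter sequence. Plain aligned-core identity would let a
12-bp perfect sliver from an unrelated reference win; dividing by the
shorter length demands both identity and coverage. The default
classification threshold is 0.50, under which random 70-mers classify as
`unknown` essentially always. Covariance-model tRNA scoring is out of
scope; classification is by identity and promoter motifs only.

## Tails and truncation

`find_tail_repeat` enumerates candidate tandem arrays (unit 1–6 bp)
within the final 60 bp and maximizes copies × purity, with ties broken
toward higher purity, then smaller units, then arrays ending closer to
the 3′ terminus. A tail is terminal by definition, so candidate arrays
must end within 5 bp of the 3′ end (`end_slack`) — without this, a chance
homopolymer run deeper in the window can outscore a genuine (TGA)n tail.
Trailing partial units count as fractional copies.

`classify_truncation` aligns a copy to the family consensus with free
terminal gaps and calls `five_prime_truncated` when at least 25% of the
consensus 5′ end is uncovered, reporting the uncovered length. Promoter
and head calls are skipped for truncated copies, which have no head to
scan.

## Copy-number extrapolation

`estimate_copy_number` scales an observed count linearly from the sampled
megabases to the genome size and rounds to two significant figures
(round-half-up), the precision at which such estimates are conventionally
quoted. The packaged copy tables ship with the package
(`hase_copy_table()`); `validate_copy_table` recomputes every row's
length from its coordinates, flags coordinate duplicates, and summarizes
counts by accession class. Faithful transcription preserved two quirks
worth knowing about: one full-length row's printed length disagrees with
its own coordinates by 6 bp, and two truncated rows share identical
coordinates; the validator reports both rather than silently fixing them.

## Phylogeny mechanics

`p_distance_matrix` computes pairwise p-distances over mutually ungapped
columns; `neighbor_joining` wraps the Saitou–Nei algorithm (exact on
additive matrices; negative branch lengths clamped to zero with a
warning); `bootstrap_support` resamples alignment columns with
replacement under a single seeded generator and reports percent support
for each internal bipartition of the full-data tree. p-distance is the
only distance model offered — the published trees this mirrors do not
state their model, and model selection is out of scope, as are
ML/parsimony/Bayesian inference. `write_newick` can blank supports below
50, the usual display convention.

## The simulator and what passing tests mean

`plant_family` plants copies of a family consensus into an i.i.d.
background genome (default GC 36.1%, matching the AT-rich insect genome
that motivated the defaults). Per copy: substitutions at a per-copy rate
drawn uniformly from 3–23% (the spread observed in real family tables),
indels at 0.5% per site (1–3 bp), 5′ truncation with probability 0.5
leaving 75–356 bp (the published range for truncated copies), a fresh
(TGA)×3–10 tail, and a TSD of 5–19 bp *read from the insertion site*
(target-site model) and duplicated on both sides, on a uniformly random
strand. Copies never overlap and keep 100 bp of background spacing,
which keeps truth-based scoring unambiguous; nested insertions, which do
occur in real genomes, are deliberately not generated.

The background is i.i.d., so the simulator does not reproduce isochores,
satellite DNA, pre-existing repeat landscapes, or gene structure.
Passing recovery tests therefore demonstrates correctness of the
machinery under clean insertion biology — they do not certify performance
on a real repeat-dense genome, where seeding and boundary refinement
would face homologous competing repeats.

Recovery on these conditions, measured by the test suite at fixed seeds
(40 copies in 150 kb, divergence ≤ 10% for the scored full-length
copies): ≥ 95% of full-length copies found with both boundaries within
5 bp, and the planted TSD string recovered exactly for ≥ 90% of them.
The residual TSD failures have three understood causes, each rare: the
target site happens to continue the tail's repeat phase (boundary
overruns by one unit); a 1–3 bp 5′ snap overrun when the copy's first
base is mutated and the preceding target-site base matches the
consensus; and, for the shortest TSDs, a chance pair within one edit
elsewhere in the search windows.

## Numerical and degenerate-input choices

* Deterministic tie-breaks everywhere: alignment traceback follows the
  engine's fixed preference; TSD and tail ranking are total orders;
  consensus base ties resolve alphabetically; NJ joins the
  lowest-index pair on ties.
* Consensus columns with majority gaps are dropped; positions without a
  majority base become `N` (never two-base ambiguity codes — simpler for
  downstream matching).
* Zero-width local alignments (nothing scores positive) are reported as
  zero-column results internally; `percent_identity` refuses them.
* An all-N or empty flank, a location outside its contig, an asymmetric
  distance matrix, and a pair of rows with no comparable columns are all
  hard errors naming the offending object.
* Problem sizes in the test suite (150 kb genomes, 40 planted copies,
  100 bootstrap replicates) were chosen so the full suite exercises every
  stage at meaningful sample sizes while staying fast enough to run on
  every change.

## Known limitations

* The star alignment projects pairwise alignments onto the seed copy; for
  families with heavy indel load it is cruder than a progressive MSA, and
  an externally computed alignment can be supplied instead
  (`read_alignment`).
* Identity conventions differ between tools; printed identities from
  other software will not reproduce exactly.
* E-value statistics are not computed; the scanner's thresholds are
  identity- and length-based.
* Horizontal-transfer inference, subfamily splitting by diagnostic
  nucleotides, and LTR/DNA-transposon structures are out of scope.
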