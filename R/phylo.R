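## phylo: distance-based phylogeny of family members -- p-distances from an
## MSA, neighbor joining, bootstrap support, Newick output.

#' Pairwise p-distance matrix from a multiple alignment
#'
#' p-distance = proportion of differing sites among columns where both
#' rows are non-gap. A pair with zero comparable columns is an error
#' naming the pair.
#'
#' @param msa A `sine_msa` with >= 3 rows.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = row
#'   ids.
#' @export
p_distance_matrix <- function(msa) {
  stopifnot(inherits(msa, "sine_msa"))
  if (msa$n < 3L) stop("p_distance_matrix needs >= 3 rows")
  m <- as.matrix(msa)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok))
      stop(sprintf("no comparable columns between '%s' and '%s'",
                   msa$ids[i], msa$ids[j]))
    d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (exact on additive matrices); negative
#' branch lengths are clamped to zero with a warning, the standard
#' treatment. The input must be symmetric with a zero diagonal.
#'
#' @param dm A symmetric numeric matrix with dimnames (>= 3 labels).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  if (!is.matrix(dm)) stop("dm must be a matrix")
  if (nrow(dm) < 3L) stop("neighbor joining needs >= 3 labels")
  if (is.null(rownames(dm))) stop("dm must carry labels in dimnames")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  tree <- ape::nj(dm)
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to zero")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' Alignment columns are resampled with replacement `n_reps` times; a NJ
#' tree is built per replicate and the support of each internal
#' bipartition of the full-data tree is the percentage of replicates
#' containing it. A single seeded generator drives all replicates, so
#' results are reproducible and invariant to leaf input order.
#'
#' @param msa A `sine_msa`.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed.
#' @return The full-data `phylo` tree with `node.label` holding percent
#'   support for internal nodes (root label NA).
#' @export
bootstrap_support <- function(msa, n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  full <- neighbor_joining(p_distance_matrix(msa))
  m <- as.matrix(msa)
  set.seed(as.integer(seed))
  rep_trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    mb <- m[, cols, drop = FALSE]
    rows <- apply(mb, 1L, paste, collapse = "")
    rep_trees[[r]] <- tryCatch(
      suppressWarnings(
        neighbor_joining(p_distance_matrix(new_msa(msa$ids, rows)))),
      error = function(e) NULL)
  }
  rep_trees <- Filter(Negate(is.null), rep_trees)
  class(rep_trees) <- "multiPhylo"
  counts <- ape::prop.clades(full, rep_trees, rooted = FALSE)
  support <- 100 * counts / length(rep_trees)
  full$node.label <- support
  full
}

#' Write a tree as Newick
#'
#' Branch lengths always; bootstrap supports as internal node labels when
#' present. Supports below `min_support` can be blanked (the usual display
#' convention hides values under 50%).
#'
#' @param tree An `ape::phylo`, optionally with numeric `node.label`
#'   supports.
#' @param file Output path, or NULL to return the string.
#' @param include_support Emit node labels (default TRUE).
#' @param min_support If non-NULL, blank supports below this value.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, include_support = TRUE,
                         min_support = NULL) {
  stopifnot(inherits(tree, "phylo"))
  t2 <- tree
  if (!include_support) {
    t2$node.label <- NULL
  } else if (!is.null(t2$node.label) && !is.null(min_support)) {
    lab <- t2$node.label
    num <- suppressWarnings(as.numeric(lab))
    lab[!is.na(num) & num < min_support] <- ""
    t2$node.label <- lab
  }
  s <- ape::write.tree(t2)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}
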