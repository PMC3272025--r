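# Independent oracles used to cross-check the package's operators.
# These are deliberately naive re-derivations (plain DP, nested loops,
# regexes) that share no code with the implementation.

# Gotoh affine-gap global alignment, score only. A gap of length L costs
# gap_open + L * gap_extend; only identical A/C/G/T letters match.
oracle_affine_global_score <- function(a, b, match = 1, mismatch = -1,
                                       gap_open = -2, gap_extend = -0.5) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes A)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes B)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- gap_open + i * gap_extend
  for (j in seq_len(m)) Y[1L, j + 1L] <- gap_open + j * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j] && A[i] %in% c("A", "C", "G", "T")) match
           else mismatch
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap_open + gap_extend,
                               X[i, j + 1L] + gap_extend,
                               Y[i, j + 1L] + gap_open + gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap_open + gap_extend,
                               Y[i + 1L, j] + gap_extend,
                               X[i + 1L, j] + gap_open + gap_extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# exhaustive TSD search by nested loops over all substring pairs under the
# same window/offset/length constraints and ranking as find_tsd
oracle_tsd <- function(left_flank, right_flank, min_len = 5, max_len = 19,
                       max_edits = 1, window = 30, max_offset = 5) {
  lf <- toupper(left_flank); rf <- toupper(right_flank)
  lw <- substr(lf, max(1, nchar(lf) - window + 1), nchar(lf))
  rw <- substr(rf, 1, min(window, nchar(rf)))
  best <- NULL
  for (ll in min_len:max_len) {
    for (ls in seq_len(max(0, nchar(lw) - ll + 1))) {
      l_off <- nchar(lw) - (ls + ll - 1)
      if (l_off > max_offset) next
      lsub <- substr(lw, ls, ls + ll - 1)
      for (rl in min_len:max_len) {
        for (rs in seq_len(max(0, nchar(rw) - rl + 1))) {
          r_off <- rs - 1
          if (r_off > max_offset) next
          rsub <- substr(rw, rs, rs + rl - 1)
          ed <- utils::adist(lsub, rsub)[1, 1]
          if (ed > max_edits) next
          len <- max(ll, rl)
          key <- c(-(len - ed), ed, l_off + r_off, ls, rs)
          if (is.null(best) || .key_less(key, best$key)) {
            best <- list(left_seq = lsub, right_seq = rsub, length = len,
                         edits = ed, key = key)
          }
        }
      }
    }
  }
  best
}

.key_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# regex-based six-frame ORF enumeration (leftmost ATG per stop, both
# strands, coordinates on the forward strand)
oracle_orfs <- function(seq, min_aa) {
  seq <- toupper(seq)
  L <- nchar(seq)
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  out <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") seq else rc(seq)
    for (f in 0:2) {
      ncod <- (nchar(ss) - f) %/% 3
      if (ncod < 1) next
      codons <- substring(ss, f + 1 + 3 * (0:(ncod - 1)),
                          f + 3 * (1:ncod))
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_atg <- codons == "ATG"
      seg_start <- 1
      for (st in which(is_stop)) {
        atgs <- which(is_atg[seg_start:(st - 1)])
        if (st > seg_start && length(atgs) > 0) {
          i0 <- seg_start + atgs[1] - 1
          n_aa <- st - i0
          if (n_aa >= min_aa) {
            s1 <- f + 3 * (i0 - 1) + 1
            e1 <- f + 3 * st
            if (strand == "+") {
              out[[length(out) + 1]] <- c(s1, e1)
            } else {
              out[[length(out) + 1]] <- c(L - e1 + 1, L - s1 + 1)
            }
          }
        }
        seg_start <- st + 1
      }
    }
  }
  if (length(out) == 0) return(matrix(numeric(0), ncol = 2))
  mat <- do.call(rbind, out)
  mat[order(mat[, 1], mat[, 2]), , drop = FALSE]
}

# sliding-window IUPAC motif matcher
oracle_iupac_hits <- function(pattern, subject, max_mismatch = 0) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
               S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
               V = c("A", "C", "G"), H = c("A", "C", "T"),
               D = c("A", "G", "T"), B = c("C", "G", "T"),
               N = c("A", "C", "G", "T"))
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  hits <- integer(0)
  if (length(s) < length(p)) return(hits)
  for (i in 1:(length(s) - length(p) + 1)) {
    mm <- 0
    for (j in seq_along(p)) {
      if (!s[i + j - 1] %in% sets[[p[j]]]) mm <- mm + 1
    }
    if (mm <= max_mismatch) hits <- c(hits, i)
  }
  hits
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
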