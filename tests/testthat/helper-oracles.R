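# Independent brute-force oracles used to freeze expected values.

# Exhaustive free-end-gap global alignment DP (match +1 / mismatch -1 /
# gap -2), returning the number of identical unambiguous positions on an
# optimal-score alignment. Pure R, independent of the package's engine.
oracle_identity <- function(a, b) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)      # best score
  M <- matrix(0, n + 1, m + 1)      # matches along a best path
  for (i in 1:(n + 1)) {
    for (j in 1:(m + 1)) {
      if (i == 1 && j == 1) next
      best <- -Inf; bm <- 0
      gp_i <- if (j == 1 || j == m + 1) 0 else -2   # free end gaps
      gp_j <- if (i == 1 || i == n + 1) 0 else -2
      if (i > 1 && j > 1) {
        hit <- A[i - 1] == B[j - 1] && A[i - 1] %in% c("A", "C", "G", "T")
        sc <- S[i - 1, j - 1] + if (hit) 1 else -1
        if (sc > best) { best <- sc; bm <- M[i - 1, j - 1] + as.integer(hit) }
      }
      if (i > 1) {
        sc <- S[i - 1, j] + gp_i
        if (sc > best) { best <- sc; bm <- M[i - 1, j] }
      }
      if (j > 1) {
        sc <- S[i, j - 1] + gp_j
        if (sc > best) { best <- sc; bm <- M[i, j - 1] }
      }
      S[i, j] <- best; M[i, j] <- bm
    }
  }
  M[n + 1, m + 1] / min(n, m)
}

# Replay of the greedy clustering rule from precomputed all-pairs
# identities (canonical order: length descending, id ascending).
oracle_greedy <- function(ids, seqs, threshold, identity_fun) {
  ord <- order(-nchar(seqs), ids, method = "radix")
  ids <- ids[ord]; seqs <- seqs[ord]
  reps <- integer(0)
  assign <- integer(length(ids))
  for (k in seq_along(ids)) {
    hit <- 0L
    for (r in seq_along(reps)) {
      if (identity_fun(seqs[k], seqs[reps[r]]) >= threshold) { hit <- r; break }
    }
    if (hit == 0L) { reps <- c(reps, k); hit <- length(reps) }
    assign[k] <- hit
  }
  split(ids, assign)
}

# Naive double-loop p-distance recount.
oracle_pdist <- function(rows, valid = c("A", "C", "G", "T")) {
  mat <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comp <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!sum(comp)) { d[i, j] <- 1; next }
    mm <- sum(!(mat[i, comp] == mat[j, comp] & mat[i, comp] %in% valid))
    d[i, j] <- mm / sum(comp)
  }
  d
}

# Brute-force discriminative-window scan: mean pairwise p-distance
# recomputed per window from scratch.
oracle_window <- function(rows, width) {
  mat <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(mat); n <- nrow(mat)
  nwin <- L - width + 1
  sc <- numeric(nwin)
  for (s in seq_len(nwin)) {
    tot <- 0; np <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- mat[i, s:(s + width - 1)]; b <- mat[j, s:(s + width - 1)]
      comp <- a != "-" & b != "-"
      tot <- tot + if (!sum(comp)) 1 else {
        sum(!(a[comp] == b[comp] & a[comp] %in% c("A", "C", "G", "T"))) / sum(comp)
      }
      np <- np + 1
    }
    sc[s] <- tot / np
  }
  list(start_col = which.max(sc) - 1L, score = max(sc), profile = sc)
}

# Brute-force six-frame longest stop-free stretch (in codons).
oracle_longest_orf_codons <- function(seq) {
  seq <- toupper(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  best <- 0L
  for (s in c(seq, rc)) {
    for (off in 0:2) {
      sub <- substr(s, off + 1, nchar(s))
      nc <- nchar(sub) %/% 3
      if (nc == 0) next
      codons <- substring(sub, 3 * (0:(nc - 1)) + 1, 3 * (1:nc))
      isstop <- codons %in% c("TAA", "TAG", "TGA")
      r <- rle(!isstop)
      if (any(r$values)) best <- max(best, max(r$lengths[r$values]))
    }
  }
  best
}

# Direct subset tally for the OMZ overlap table.
oracle_omz_tally <- function(sets) {
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  lab <- vapply(sets, function(s) {
    paste(intersect(c("AS", "ETNP", "ETSP"), s), collapse = "+")
  }, character(1))
  table(factor(lab, levels = c("AS", "ETNP", "ETSP", "AS+ETNP", "AS+ETSP",
                               "ETNP+ETSP", "AS+ETNP+ETSP")))
}
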