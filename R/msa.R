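# Multiple alignment (progressive, profile-profile), ORF finding,
# back-translation and p-distances.

#' Construct a multiple-alignment object
#'
#' @param ids Character vector of row ids.
#' @param seqs Character vector of equal-length aligned strings (gap `-`).
#' @param alphabet `"nt"` or `"aa"`.
#' @return An object of class `"msa"`.
#' @export
msa <- function(ids, seqs, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  seqs <- toupper(as.character(seqs))
  ids <- as.character(ids)
  stopifnot(length(ids) == length(seqs))
  if (length(seqs) && length(unique(nchar(seqs))) != 1L) {
    stop("alignment rows must have equal length")
  }
  structure(list(ids = ids, seqs = stats::setNames(seqs, ids),
                 alphabet = alphabet),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d x %d (%s)\n", length(x$ids),
              if (length(x$seqs)) nchar(x$seqs[[1]]) else 0L, x$alphabet))
  invisible(x)
}

#' Remove gaps from an aligned string
#' @param x Character vector of aligned strings.
#' @return The ungapped strings.
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

.msa_matrix <- function(m) {
  if (inherits(m, "msa")) m <- m$seqs
  out <- do.call(rbind, strsplit(m, ""))
  rownames(out) <- names(m)
  out
}

# k-mer set distance used for the guide tree
.kmer_dist <- function(seqs, k) {
  sets <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(sets)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mn <- min(length(sets[[i]]), length(sets[[j]]))
      d[i, j] <- d[j, i] <-
        if (mn == 0) 1 else 1 - length(intersect(sets[[i]], sets[[j]])) / mn
    }
  }
  d
}

.align_alphabet <- function(alphabet) {
  if (alphabet == "nt") {
    letters <- c(.nt_letters, "-")
    S <- matrix(-3, 16, 16, dimnames = list(letters, letters))
    for (b in c("A", "C", "G", "T")) S[b, b] <- 2
    S["-", ] <- 0; S[, "-"] <- 0
    list(letters = letters, S = S, gap_open = 5, gap_ext = 2)
  } else {
    # BLOSUM62 shifted by +1 so that the expected column score between
    # distant homologs (>= ~20% identity) stays positive; without the
    # shift, free-end-gap profile alignment prefers sliding highly
    # divergent profiles past each other over aligning them.
    B <- .aa_score_matrix() + 1
    letters <- c(rownames(B), "-")
    n <- length(letters)
    S <- matrix(0, n, n, dimnames = list(letters, letters))
    S[rownames(B), colnames(B)] <- B
    S["-", ] <- 0; S[, "-"] <- 0
    list(letters = letters, S = S, gap_open = 10, gap_ext = 1)
  }
}

.profile_freq <- function(mat, letters) {
  f <- apply(mat, 2, function(col) {
    tabulate(factor(col, levels = letters), nbins = length(letters))
  })
  f <- matrix(f, nrow = length(letters))
  sweep(f, 2, pmax(colSums(f), 1), "/")
}

.merge_profiles <- function(m1, m2, alph) {
  F1 <- .profile_freq(m1, alph$letters)
  F2 <- .profile_freq(m2, alph$letters)
  cs <- crossprod(F1, alph$S %*% F2)
  res <- .profile_dp(cs, alph$gap_open, alph$gap_ext)
  L <- length(res$p1)
  out1 <- matrix("-", nrow(m1), L)
  out2 <- matrix("-", nrow(m2), L)
  out1[, res$p1 > 0] <- m1[, res$p1[res$p1 > 0], drop = FALSE]
  out2[, res$p2 > 0] <- m2[, res$p2[res$p2 > 0], drop = FALSE]
  out <- rbind(out1, out2)
  rownames(out) <- c(rownames(m1), rownames(m2))
  out
}

#' Progressive multiple alignment
#'
#' A classical progressive aligner: a guide tree is built by UPGMA on
#' k-mer set distances, then profiles are merged up the tree by
#' profile-profile global alignment with affine gaps and free end gaps.
#' Scoring: BLOSUM62, gap open -10 / extend -1 for amino acids; match +2 /
#' mismatch -3, gap open -5 / extend -2 for nucleotides. Inputs are sorted
#' by id before tree building, so the result does not depend on input
#' order.
#'
#' @param seqs Named character vector of (ungapped) sequences.
#' @param alphabet `"nt"` or `"aa"`.
#' @return An [msa] object whose rows, once ungapped, reproduce the inputs.
#' @export
progressive_align <- function(seqs, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("seqs must carry unique names")
  }
  seqs <- toupper(seqs[order(names(seqs), method = "radix")])
  n <- length(seqs)
  if (n == 0L) stop("no sequences to align")
  if (n == 1L) return(msa(names(seqs), seqs, alphabet))
  alph <- .align_alphabet(alphabet)
  leaf <- lapply(seqs, function(s) {
    m <- matrix(strsplit(s, "")[[1]], nrow = 1)
    m
  })
  for (i in seq_len(n)) rownames(leaf[[i]]) <- names(seqs)[i]
  if (n == 2L) {
    merged <- .merge_profiles(leaf[[1]], leaf[[2]], alph)
  } else {
    k <- if (alphabet == "aa") 3L else 6L
    d <- .kmer_dist(unname(seqs), k)
    dimnames(d) <- list(names(seqs), names(seqs))
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    nodes <- vector("list", nrow(hc$merge))
    for (r in seq_len(nrow(hc$merge))) {
      a <- hc$merge[r, 1]; b <- hc$merge[r, 2]
      pa <- if (a < 0) leaf[[-a]] else nodes[[a]]
      pb <- if (b < 0) leaf[[-b]] else nodes[[b]]
      nodes[[r]] <- .merge_profiles(pa, pb, alph)
    }
    merged <- nodes[[nrow(hc$merge)]]
  }
  merged <- merged[order(rownames(merged), method = "radix"), , drop = FALSE]
  msa(rownames(merged), apply(merged, 1, paste, collapse = ""), alphabet)
}

.GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

.translate_nt <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3
  if (n < 3) return("")
  s <- Biostrings::DNAString(substr(nt, 1, n))
  as.character(suppressWarnings(Biostrings::translate(s, if.fuzzy.codon = "X")))
}

.revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Find the longest open reading frame across six frames
#'
#' An ORF here is a maximal stop-free stretch of codons in one of the six
#' reading frames (standard genetic code); a start codon is not required,
#' since most compiled sequences are gene fragments. Ties are broken by
#' frame order (+1, +2, +3, -1, -2, -3), then leftmost.
#'
#' @param record A single-row `seq_records` data frame, or a named length-1
#'   character vector, or a plain string (id taken from names where
#'   available).
#' @param min_codons Minimum acceptable stretch; below this in every frame
#'   an error "no plausible ORF" is raised.
#' @return A list of class `"orf_call"`: `parent_id`, `frame`, `nt_start`,
#'   `nt_end` (0-based half-open, forward-strand coordinates), `protein`,
#'   and `cds` (the in-frame nucleotide stretch, reverse-complemented for
#'   negative frames so that `translate(cds) == protein`).
#' @export
find_orf <- function(record, min_codons = 20L) {
  if (inherits(record, "data.frame")) {
    id <- record$id[1]; seq <- record$seq[1]
  } else {
    id <- if (!is.null(names(record))) names(record)[1] else NA_character_
    seq <- as.character(record)[1]
  }
  seq <- toupper(seq)
  L <- nchar(seq)
  best <- NULL
  frames <- list(c(1, 0), c(1, 1), c(1, 2), c(-1, 0), c(-1, 1), c(-1, 2))
  for (f in frames) {
    strand <- f[1]; off <- f[2]
    s <- if (strand == 1) seq else .revcomp(seq)
    sub <- substr(s, off + 1, nchar(s))
    prot <- .translate_nt(sub)
    if (!nzchar(prot)) next
    runs <- .stop_free_runs(prot)
    for (r in runs) {
      len <- r[2] - r[1] + 1
      if (is.null(best) || len > best$len) {
        best <- list(len = len, strand = strand, off = off,
                     p1 = r[1], p2 = r[2], src = s)
      }
    }
  }
  if (is.null(best) || best$len < min_codons) stop("no plausible ORF")
  a <- best$off + 3 * (best$p1 - 1)        # 0-based on the working strand
  b <- best$off + 3 * best$p2
  cds <- substr(best$src, a + 1, b)
  if (best$strand == 1) {
    nt_start <- a; nt_end <- b; frame <- best$off + 1L
  } else {
    nt_start <- L - b; nt_end <- L - a; frame <- -(best$off + 1L)
  }
  structure(list(parent_id = id, frame = frame,
                 nt_start = nt_start, nt_end = nt_end,
                 protein = .translate_nt(cds), cds = cds),
            class = "orf_call")
}

# maximal runs of non-stop residues, as (first, last) 1-based positions
.stop_free_runs <- function(prot) {
  ch <- strsplit(prot, "")[[1]]
  ok <- ch != "*"
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  Map(c, starts[r$values], ends[r$values])
}

#' @export
print.orf_call <- function(x, ...) {
  cat(sprintf("<orf> %s frame %+d, nt [%d,%d), %d aa\n",
              x$parent_id, x$frame, x$nt_start, x$nt_end, nchar(x$protein)))
  invisible(x)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino-acid column expands into a 3-nt codon block; protein gaps
#' become `---`. Every protein row must match the translation of its ORF's
#' coding sequence.
#'
#' @param protein_msa An [msa] with `alphabet = "aa"`.
#' @param orfs Named list of `orf_call` objects (names = row ids), or an
#'   unnamed list in which case `parent_id` fields are used.
#' @return An [msa] with `alphabet = "nt"` of 3x the protein width.
#' @export
backtranslate <- function(protein_msa, orfs) {
  stopifnot(inherits(protein_msa, "msa"), protein_msa$alphabet == "aa")
  if (is.null(names(orfs))) {
    names(orfs) <- vapply(orfs, `[[`, character(1), "parent_id")
  }
  rows <- vapply(protein_msa$ids, function(id) {
    orf <- orfs[[id]]
    if (is.null(orf)) stop("no ORF provided for row ", id)
    aln <- strsplit(protein_msa$seqs[[id]], "")[[1]]
    prot <- paste(aln[aln != "-"], collapse = "")
    if (!identical(prot, orf$protein)) {
      stop("translation mismatch for row ", id)
    }
    codons <- substring(orf$cds, seq(1, nchar(orf$cds), 3),
                        seq(3, nchar(orf$cds), 3))
    out <- rep("---", length(aln))
    out[aln != "-"] <- codons
    paste(out, collapse = "")
  }, character(1))
  msa(protein_msa$ids, rows, "nt")
}

#' Pairwise p-distance matrix of an alignment
#'
#' `d(i, j)` is the fraction of mismatching positions among comparable
#' columns (both rows non-gap). `N`, IUPAC ambiguity codes and `X` count as
#' mismatches against anything, including themselves. Pairs with zero
#' comparable columns receive distance 1 with a warning.
#'
#' @param m An [msa] object or character vector of equal-length aligned
#'   strings.
#' @param alphabet Used when `m` is a plain character vector.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(m, alphabet = c("nt", "aa")) {
  if (inherits(m, "msa")) {
    alphabet <- m$alphabet
  } else {
    alphabet <- match.arg(alphabet)
  }
  mat <- .msa_matrix(m)
  if (nrow(mat) < 2) stop("p_distance_matrix needs at least 2 rows")
  valid <- if (alphabet == "nt") c("A", "C", "G", "T")
           else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  ng <- mat != "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ng[i, ] & ng[j, ]
      nc <- sum(comp)
      if (nc == 0) {
        warning(sprintf("rows %s and %s share no comparable columns",
                        rownames(mat)[i], rownames(mat)[j]))
        d[i, j] <- d[j, i] <- 1
      } else {
        match <- mat[i, comp] == mat[j, comp] & mat[i, comp] %in% valid
        d[i, j] <- d[j, i] <- 1 - sum(match) / nc
      }
    }
  }
  d
}
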