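# Greedy identity clustering (CD-HIT-style), rank abundance and
# majority-rule consensus calling.

.nt_letters <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                 "V", "H", "D", "B", "N")

# +1 for an exact A/C/G/T match, -1 otherwise; N and ambiguity codes never
# score as matches.
.nt_score_matrix <- function() {
  m <- matrix(-1, length(.nt_letters), length(.nt_letters),
              dimnames = list(.nt_letters, .nt_letters))
  for (b in c("A", "C", "G", "T")) m[b, b] <- 1
  m
}

.aa_score_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Global alignment with free end gaps of one query against many subjects;
# returns the fraction of identical unambiguous positions over the shorter
# input length for each pair.
.identity_many <- function(query, refs, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(query) || any(!nzchar(refs))) stop("empty sequence")
  if (alphabet == "nt") {
    sm <- .nt_score_matrix()
    go <- 0; ge <- 2
    valid <- c("A", "C", "G", "T")
    pat <- Biostrings::DNAStringSet(refs)
    subj <- Biostrings::DNAString(query)
  } else {
    sm <- .aa_score_matrix()
    go <- 10; ge <- 1
    valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    pat <- Biostrings::AAStringSet(refs)
    subj <- Biostrings::AAString(query)
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = pat, subject = subj, type = "overlap",
    substitutionMatrix = sm, gapOpening = go, gapExtension = ge
  )
  ap <- as.character(Biostrings::alignedPattern(pa))
  as <- as.character(Biostrings::alignedSubject(pa))
  nmatch <- mapply(function(a, b) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    sum(ca == cb & ca %in% valid)
  }, ap, as, USE.NAMES = FALSE)
  nmatch / pmin(nchar(refs), nchar(query))
}

#' Pairwise sequence identity
#'
#' Identity between two sequences under the CD-HIT convention: the two
#' sequences are globally aligned (free end gaps; nt scoring match +1,
#' mismatch -1, gap -2; amino acids BLOSUM62 with gap open -10 / extend -1)
#' and identity is the number of identical unambiguous positions divided by
#' the length of the shorter input. `N` and IUPAC ambiguity codes never
#' count as matches.
#'
#' @param a,b Nucleotide (or amino-acid) strings.
#' @param alphabet `"nt"` or `"aa"`.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  as.numeric(.identity_many(a, b, alphabet))
}

#' Greedy identity clustering into OTUs
#'
#' Records are processed longest first (ties broken by id, ascending); each
#' record joins the first existing OTU whose representative it matches at
#' `>= threshold` identity (see [pairwise_identity()]), otherwise it founds
#' a new OTU with itself as representative. This mirrors CD-HIT's greedy
#' incremental scheme with exact dynamic-programming alignments in place of
#' its k-mer screening heuristics.
#'
#' @param records A `seq_records` data frame (deduplicated).
#' @param threshold Identity threshold (fraction).
#' @return List of OTU objects (class `"otu"`), in founding order. Each has
#'   `otu_id`, `members` (ids, representative first), `representative`,
#'   `n`, `is_individual` (n <= 2) and `consensus` (filled later).
#' @export
greedy_cluster <- function(records, threshold = 0.87) {
  if (nrow(records) == 0L) return(list())
  ord <- order(-nchar(records$seq), records$id, method = "radix")
  ids <- records$id[ord]
  seqs <- records$seq[ord]
  rep_seq <- character(0)
  members <- list()
  for (k in seq_along(ids)) {
    hit <- 0L
    if (length(rep_seq)) {
      idn <- .identity_many(seqs[k], rep_seq, "nt")
      w <- which(idn >= threshold)
      if (length(w)) hit <- w[1L]
    }
    if (hit > 0L) {
      members[[hit]] <- c(members[[hit]], ids[k])
    } else {
      rep_seq <- c(rep_seq, seqs[k])
      members[[length(rep_seq)]] <- ids[k]
    }
  }
  lapply(seq_along(members), function(i) {
    m <- members[[i]]
    structure(list(
      otu_id = sprintf("OTU%04d", i),
      members = m,
      representative = m[[1L]],
      n = length(m),
      is_individual = length(m) <= 2L,
      consensus = NULL
    ), class = "otu")
  })
}

#' @export
print.otu <- function(x, ...) {
  cat(sprintf("<%s> %d member(s), representative %s%s\n", x$otu_id, x$n,
              x$representative,
              if (x$is_individual) " [individual]" else ""))
  invisible(x)
}

#' Rank-abundance summary of an OTU set
#'
#' @param x List of OTU objects, or a numeric vector of cluster sizes
#'   (optionally named by cluster id).
#' @return A list of class `"rank_abundance"` with the size table sorted
#'   descending, totals, and derived shares: fraction of sequences in OTUs
#'   with more than two members, in individual OTUs (one or two members),
#'   and in the largest OTU; plus the fraction of clusters that are
#'   individuals.
#' @export
rank_abundance <- function(x) {
  if (is.list(x) && length(x) && inherits(x[[1]], "otu")) {
    sizes <- vapply(x, `[[`, integer(1), "n")
    names(sizes) <- vapply(x, `[[`, character(1), "otu_id")
  } else {
    sizes <- as.numeric(x)
    if (is.null(names(sizes)) && length(sizes)) {
      names(sizes) <- sprintf("OTU%04d", seq_along(sizes))
    }
  }
  ord <- order(-sizes, method = "radix")
  sizes <- sizes[ord]
  n_seq <- sum(sizes)
  big <- sizes > 2
  structure(list(
    table = data.frame(otu_id = names(sizes), members = as.integer(sizes),
                       rank = seq_along(sizes), stringsAsFactors = FALSE),
    n_otus = length(sizes),
    n_sequences = as.integer(n_seq),
    frac_seqs_gt2 = if (n_seq > 0) sum(sizes[big]) / n_seq else NA_real_,
    frac_seqs_individual = if (n_seq > 0) sum(sizes[!big]) / n_seq else NA_real_,
    frac_seqs_largest = if (n_seq > 0) max(sizes) / n_seq else NA_real_,
    frac_otus_individual = if (length(sizes)) mean(!big) else NA_real_
  ), class = "rank_abundance")
}

#' @export
print.rank_abundance <- function(x, ...) {
  cat(sprintf("Rank abundance: %d clusters, %d sequences\n",
              x$n_otus, x$n_sequences))
  cat(sprintf("  largest cluster share : %.1f%%\n", 100 * x$frac_seqs_largest))
  cat(sprintf("  sequences in >2-member clusters: %.1f%%\n",
              100 * x$frac_seqs_gt2))
  cat(sprintf("  sequences in individual clusters: %.1f%%\n",
              100 * x$frac_seqs_individual))
  invisible(x)
}

.expand_iupac <- function(ch) {
  map <- Biostrings::IUPAC_CODE_MAP
  unlist(strsplit(map[ch], ""), use.names = FALSE)
}

.merge_iupac <- function(bases) {
  bases <- sort(unique(.expand_iupac(bases)))
  map <- Biostrings::IUPAC_CODE_MAP
  key <- vapply(strsplit(map, ""), function(x) paste(sort(x), collapse = ""),
                character(1))
  names(map)[match(paste(bases, collapse = ""), key)]
}

#' Majority-rule consensus of aligned sequences
#'
#' Per column: the most frequent non-gap character wins; ties are resolved
#' to the minimal IUPAC ambiguity code covering the tied bases; columns in
#' which the gap character is the strict majority are dropped. Terminal
#' gaps are treated as missing data, not gap characters: in a fragment
#' alignment a leading or trailing gap means the fragment simply does not
#' extend there, so each column is called over the rows whose footprint
#' covers it, and only internal gaps count towards gap-majority dropping.
#' The result carries no gaps.
#'
#' @param aligned Character vector of equal-length aligned nucleotide
#'   strings (gap `-`), or an `msa` object.
#' @return Consensus nucleotide string.
#' @export
consensus_sequence <- function(aligned) {
  if (inherits(aligned, "msa")) aligned <- aligned$seqs
  if (length(unique(nchar(aligned))) != 1L) {
    stop("consensus requires aligned (equal-length) sequences")
  }
  m <- do.call(rbind, strsplit(toupper(aligned), ""))
  # mask terminal gaps as missing data
  for (i in seq_len(nrow(m))) {
    ng <- which(m[i, ] != "-")
    if (!length(ng)) { m[i, ] <- NA_character_; next }
    if (ng[1] > 1L) m[i, seq_len(ng[1] - 1L)] <- NA_character_
    L <- ncol(m)
    if (ng[length(ng)] < L) m[i, (ng[length(ng)] + 1L):L] <- NA_character_
  }
  out <- apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    n <- length(col)
    if (n == 0L) return("")
    gaps <- sum(col == "-")
    if (gaps > n / 2) return("")
    col <- col[col != "-"]
    tab <- sort(table(col), decreasing = TRUE)
    top <- names(tab)[tab == tab[1]]
    if (length(top) == 1L) top else .merge_iupac(top)
  })
  paste(out, collapse = "")
}
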