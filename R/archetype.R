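# 5'/3' region assignment, discriminative-window discovery and archetype
# clustering -- the probe-finding core.

#' Reference coordinate anchors for the 5' and 3' analysis regions
#'
#' Coordinates are 1-based inclusive nucleotide positions on a full-length
#' reference gene (default length 1,920 nt, the Pseudomonas fluorescens
#' nosZ reference). The default discriminative-window anchors sit at
#' ~792-861 nt (5') and ~1,322-1,391 nt (3'); each spans exactly
#' `window_len` bases. The two amplicon groups share only a ~42 bp overlap,
#' which is why the regions are analysed separately.
#'
#' @param reference_id Id of the reference sequence row.
#' @param reference_len Reference length in nt.
#' @param five_prime_range,three_prime_range Integer length-2 vectors
#'   (start, end), 1-based inclusive.
#' @param window_len Window width in nt; both ranges must span exactly this
#'   many bases.
#' @return A list of class `"reference_anchors"`.
#' @export
reference_anchors <- function(reference_id,
                              reference_len = 1920L,
                              five_prime_range = c(792L, 861L),
                              three_prime_range = c(1322L, 1391L),
                              window_len = 70L) {
  stopifnot(
    diff(five_prime_range) + 1L == window_len,
    diff(three_prime_range) + 1L == window_len,
    five_prime_range[1] >= 1L, three_prime_range[2] <= reference_len,
    five_prime_range[2] < three_prime_range[1]
  )
  structure(list(reference_id = reference_id,
                 reference_len = as.integer(reference_len),
                 five_prime_range = as.integer(five_prime_range),
                 three_prime_range = as.integer(three_prime_range),
                 window_len = as.integer(window_len)),
            class = "reference_anchors")
}

# protein-residue (codon) range covering a nucleotide range
.codon_range <- function(nt_range) {
  c(ceiling(nt_range[1] / 3), ceiling(nt_range[2] / 3))
}

# alignment columns occupied by reference residues p1..p2
.anchor_cols <- function(ref_row, p_range) {
  ch <- strsplit(ref_row, "")[[1]]
  pos <- which(ch != "-")
  if (p_range[2] > length(pos)) stop("anchor range beyond reference row")
  pos[p_range[1]:p_range[2]]
}

.footprint <- function(aln_row) {
  ng <- which(strsplit(aln_row, "")[[1]] != "-")
  if (!length(ng)) c(NA_integer_, NA_integer_) else range(ng)
}

#' Assign aligned sequences to the 5' and/or 3' analysis region
#'
#' A row joins the 5' group iff its footprint (first to last non-gap
#' alignment column) covers every alignment column of the 5' anchor;
#' likewise for 3'. Full-length rows appear in both groups; rows covering
#' neither anchor are reported as excluded.
#'
#' @param master_msa Protein [msa] containing the reference row.
#' @param anchors A [reference_anchors] object.
#' @return List with `five_prime`, `three_prime` and `excluded` id vectors.
#' @export
assign_region <- function(master_msa, anchors) {
  stopifnot(inherits(master_msa, "msa"))
  if (!anchors$reference_id %in% master_msa$ids) {
    stop("reference row ", anchors$reference_id, " absent from alignment")
  }
  ref_row <- master_msa$seqs[[anchors$reference_id]]
  c5 <- .anchor_cols(ref_row, .codon_range(anchors$five_prime_range))
  c3 <- .anchor_cols(ref_row, .codon_range(anchors$three_prime_range))
  ids <- setdiff(master_msa$ids, anchors$reference_id)
  in5 <- logical(length(ids)); in3 <- logical(length(ids))
  for (k in seq_along(ids)) {
    fp <- .footprint(master_msa$seqs[[ids[k]]])
    if (anyNA(fp)) next
    in5[k] <- fp[1] <= min(c5) && fp[2] >= max(c5)
    in3[k] <- fp[1] <= min(c3) && fp[2] >= max(c3)
  }
  excluded <- ids[!in5 & !in3]
  if (length(excluded)) {
    message("assign_region: ", length(excluded),
            " sequence(s) cover neither anchor: ",
            paste(excluded, collapse = ", "))
  }
  list(five_prime = ids[in5], three_prime = ids[in3], excluded = excluded)
}

#' Build a region-restricted codon alignment
#'
#' Back-translates the master protein alignment and restricts it to the
#' longest stretch of columns covered by every member of the region group
#' (their common footprint), keeping the reference row for coordinates.
#'
#' @param master_msa Protein [msa] including the reference row.
#' @param orfs Named list of `orf_call` objects for every row.
#' @param anchors A [reference_anchors] object.
#' @param region `"five_prime"` or `"three_prime"`.
#' @param member_ids Ids assigned to this region (see [assign_region()]).
#' @return A list of class `"region_alignment"`: `region`, `msa`
#'   (nucleotide, members + reference), `member_ids`, `reference_id` and
#'   `column_map` (alignment column -> reference nt coordinate, 0 where the
#'   reference is gapped).
#' @export
region_alignment <- function(master_msa, orfs, anchors,
                             region = c("five_prime", "three_prime"),
                             member_ids) {
  region <- match.arg(region)
  stopifnot(length(member_ids) >= 1)
  fps <- vapply(member_ids, function(id) .footprint(master_msa$seqs[[id]]),
                integer(2))
  c1 <- max(fps[1, ]); c2 <- min(fps[2, ])
  if (c2 < c1) stop("region members share no common aligned columns")
  nt_all <- backtranslate(master_msa, orfs)
  keep <- c(member_ids, anchors$reference_id)
  lo <- 3L * (c1 - 1L) + 1L
  hi <- 3L * c2
  rows <- substr(nt_all$seqs[keep], lo, hi)
  m <- msa(keep, rows, "nt")
  ref_full <- strsplit(nt_all$seqs[[anchors$reference_id]], "")[[1]]
  ref_ch <- ref_full[lo:hi]
  ref_orf <- orfs[[anchors$reference_id]]
  offset <- if (!is.null(ref_orf)) ref_orf$nt_start else 0L
  offset <- offset + sum(ref_full[seq_len(lo - 1L)] != "-")
  cmap <- integer(length(ref_ch))
  cmap[ref_ch != "-"] <- offset + seq_len(sum(ref_ch != "-"))
  structure(list(region = region, msa = m, member_ids = member_ids,
                 reference_id = anchors$reference_id, column_map = cmap),
            class = "region_alignment")
}

#' Find the most discriminative fixed-width window
#'
#' Scans every window of `width` alignment columns and returns the one with
#' the greatest mean pairwise p-distance among member rows (the reference
#' row is excluded from scoring). Ties are broken leftmost. Pairs with no
#' comparable columns inside a window contribute distance 1.
#'
#' @param ra A [region_alignment()] object.
#' @param width Window width in columns (default 70).
#' @return A list of class `"window_score"`: `start_col` (0-based), `width`
#'   and `mean_pairwise_distance`, plus the full `profile` of scores.
#' @export
find_discriminative_window <- function(ra, width = 70L) {
  stopifnot(inherits(ra, "region_alignment"))
  mat <- .msa_matrix(ra$msa)[ra$member_ids, , drop = FALSE]
  n <- nrow(mat); L <- ncol(mat)
  if (n < 2) stop("window scan needs at least 2 member rows")
  if (L < width) {
    warning(sprintf("alignment (%d columns) shorter than window (%d); using full alignment",
                    L, width))
    width <- L
  }
  valid <- c("A", "C", "G", "T")
  ng <- mat != "-"
  nwin <- L - width + 1L
  score <- numeric(nwin)
  npairs <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ng[i, ] & ng[j, ]
      mism <- comp & !(mat[i, ] == mat[j, ] & mat[i, ] %in% valid)
      cc <- cumsum(comp); cm <- cumsum(mism)
      wc <- cc[width:L] - c(0, cc)[1:nwin]
      wm <- cm[width:L] - c(0, cm)[1:nwin]
      score <- score + ifelse(wc == 0, 1, wm / pmax(wc, 1))
      npairs <- npairs + 1L
    }
  }
  score <- score / npairs
  s <- which.max(score)
  structure(list(start_col = s - 1L, width = as.integer(width),
                 mean_pairwise_distance = score[s], profile = score),
            class = "window_score")
}

#' Extract each member's slice of the discriminative window
#'
#' Members whose slice is more than 50% gap characters are excluded with a
#' warning (gap-dominated slices would cluster spuriously).
#'
#' @param ra A [region_alignment()] object.
#' @param window A `window_score` from [find_discriminative_window()].
#' @return Named character vector of window slices (length = window width).
#' @export
extract_70mers <- function(ra, window) {
  stopifnot(inherits(ra, "region_alignment"))
  lo <- window$start_col + 1L
  hi <- window$start_col + window$width
  sl <- substr(ra$msa$seqs[ra$member_ids], lo, hi)
  gapfrac <- vapply(strsplit(sl, ""), function(x) mean(x == "-"), numeric(1))
  drop <- gapfrac > 0.5
  if (any(drop)) {
    warning("excluding gap-dominated window slice(s): ",
            paste(ra$member_ids[drop], collapse = ", "))
  }
  sl[!drop]
}

# column-wise identity on a fixed alignment slice: matching characters
# (including gap-gap) / width; no realignment
.slice_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

#' Cluster window slices into archetypes
#'
#' Greedy clustering of equal-length window slices: slices are processed in
#' id order; each joins the first archetype whose representative (founder)
#' slice matches at `>= threshold` column-wise identity (gap-gap columns
#' count as matches, gap-base as mismatches; no realignment), else founds a
#' new archetype.
#'
#' @param seventymers Named character vector of equal-length slices.
#' @param threshold Identity threshold (fraction).
#' @param region Region tag stored on each archetype.
#' @return List of `"archetype"` objects in founding order, each with
#'   `archetype_id`, `region`, `representative` (the founder's slice),
#'   `representative_id`, `member_ids`, and annotation slots (`clade`,
#'   `sources`, `omz_regions`, `taxonomy`, `n_seqs`) filled by
#'   [annotate_archetypes()].
#' @export
cluster_archetypes <- function(seventymers, threshold = 0.87,
                               region = c("five_prime", "three_prime")) {
  region <- match.arg(region)
  if (length(seventymers) == 0L) return(list())
  if (length(unique(nchar(seventymers))) != 1L) {
    stop("window slices must all have the same length")
  }
  ids <- sort(names(seventymers), method = "radix")
  reps <- character(0)
  members <- list()
  for (id in ids) {
    s <- seventymers[[id]]
    hit <- 0L
    if (length(reps)) {
      idn <- vapply(reps, .slice_identity, numeric(1), a = s)
      w <- which(idn >= threshold)
      if (length(w)) hit <- w[1L]
    }
    if (hit > 0L) {
      members[[hit]] <- c(members[[hit]], id)
    } else {
      reps <- c(reps, s)
      members[[length(reps)]] <- id
    }
  }
  tag <- if (region == "five_prime") "A5" else "A3"
  lapply(seq_along(reps), function(i) {
    structure(list(
      archetype_id = sprintf("%s-%04d", tag, i),
      region = region,
      representative = unname(reps[i]),
      representative_id = members[[i]][1L],
      member_ids = members[[i]],
      clade = "unknown",
      sources = character(0),
      omz_regions = character(0),
      taxonomy = NA_character_,
      n_seqs = length(members[[i]])
    ), class = "archetype")
  })
}

#' @export
print.archetype <- function(x, ...) {
  cat(sprintf("<%s> %s, %d row(s), %d seq(s), clade %s\n", x$archetype_id,
              x$region, length(x$member_ids), x$n_seqs, x$clade))
  invisible(x)
}

#' Neighbor-joining tree of archetype representatives
#'
#' Classical neighbor joining on p-distances among the representative
#' window slices; negative branch lengths are clamped to zero. Intended
#' for visualisation and ordering, not for formal phylogenetic inference.
#'
#' @param archetypes List of at least 3 archetypes (equal-width
#'   representatives).
#' @return A Newick string with archetype ids as tip labels.
#' @export
nj_tree <- function(archetypes) {
  if (length(archetypes) < 3) stop("neighbor joining needs >= 3 archetypes")
  reps <- vapply(archetypes, `[[`, character(1), "representative")
  names(reps) <- vapply(archetypes, `[[`, character(1), "archetype_id")
  d <- p_distance_matrix(reps, "nt")
  phy <- ape::nj(d)
  phy$edge.length <- pmax(phy$edge.length, 0)
  ape::write.tree(phy)
}
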