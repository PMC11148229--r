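# Clade classification against a reference panel, and the biogeography
# summary tables.

#' Build a clade reference panel
#'
#' A small curated set of reference sequences of known clade (I or II) used
#' for nearest-reference classification. The default minimum identity for a
#' call reflects the random-match baseline of the alphabet: 0.60 for amino
#' acids, 0.50 for nucleotides.
#'
#' @param ids,seqs,clades Parallel vectors; `clades` in `{"I","II"}`, both
#'   clades must be represented.
#' @param alphabet `"nt"` or `"aa"`.
#' @param min_identity Minimum identity to the best hit for a clade call;
#'   below it the archetype is `"unknown"`.
#' @return A list of class `"clade_panel"`.
#' @export
clade_panel <- function(ids, seqs, clades, alphabet = c("nt", "aa"),
                        min_identity = NULL) {
  alphabet <- match.arg(alphabet)
  stopifnot(length(ids) == length(seqs), length(ids) == length(clades))
  if (anyDuplicated(ids)) stop("panel ids must be unique")
  if (!all(clades %in% c("I", "II"))) stop("panel clades must be 'I' or 'II'")
  if (!all(c("I", "II") %in% clades)) {
    stop("panel must contain at least one entry per clade")
  }
  if (is.null(min_identity)) {
    min_identity <- if (alphabet == "aa") 0.60 else 0.50
  }
  structure(list(ids = as.character(ids), seqs = toupper(as.character(seqs)),
                 clades = as.character(clades), alphabet = alphabet,
                 min_identity = min_identity),
            class = "clade_panel")
}

#' Classify an archetype (or sequence) into clade I, II or unknown
#'
#' The query is compared with every panel entry by pairwise identity
#' (free-end-gap global alignment, identity over the shorter sequence); the
#' clade of the best hit is returned when its identity reaches the panel's
#' `min_identity`. Equal best identity in both clades, or a best hit below
#' the threshold, yields `"unknown"`. When the panel is protein and the
#' query nucleotide, the query is translated in the three forward frames
#' and the best-scoring frame is used.
#'
#' @param x An `"archetype"` object or a nucleotide/protein string.
#' @param panel A [clade_panel()].
#' @return `"I"`, `"II"` or `"unknown"`.
#' @export
classify_clade <- function(x, panel) {
  stopifnot(inherits(panel, "clade_panel"))
  query <- if (inherits(x, "archetype")) ungap(x$representative) else ungap(toupper(x))
  queries <- query
  if (panel$alphabet == "aa" && !grepl("[^ACGTNU-]", query)) {
    # nucleotide query against a protein panel: try the 3 forward frames
    queries <- vapply(0:2, function(off) {
      p <- .translate_nt(substr(query, off + 1, nchar(query)))
      gsub("\\*", "X", p)
    }, character(1))
    queries <- queries[nzchar(queries)]
    if (!length(queries)) return("unknown")
  }
  best <- -Inf
  idn <- rep(-Inf, length(panel$ids))
  for (q in queries) {
    idn <- pmax(idn, .identity_many(q, panel$seqs, panel$alphabet))
  }
  best <- max(idn)
  if (best < panel$min_identity) return("unknown")
  hit_clades <- unique(panel$clades[idn == best])
  if (length(hit_clades) != 1L) "unknown" else hit_clades
}

#' Annotate archetypes with clade, sources, OMZ regions and taxonomy
#'
#' Joins archetype membership back to the per-row annotations (one row per
#' alignment member: its underlying sequence count, source labels, OMZ
#' regions of origin and taxonomy) and classifies each archetype's
#' representative against the panel.
#'
#' @param archetypes List of `"archetype"` objects.
#' @param row_info Data frame with columns `id`, `n_seqs`, `sources`
#'   (list-column or `;`-separated string), `omz_regions` (idem),
#'   `taxonomy`.
#' @param panel Optional [clade_panel()]; without it clades stay
#'   `"unknown"`.
#' @return The annotated archetype list.
#' @export
annotate_archetypes <- function(archetypes, row_info, panel = NULL) {
  split_col <- function(x) {
    if (is.list(x)) return(x)
    strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE)
  }
  srcs <- split_col(row_info$sources)
  omzs <- split_col(row_info$omz_regions)
  idx <- stats::setNames(seq_len(nrow(row_info)), row_info$id)
  lapply(archetypes, function(a) {
    rows <- idx[a$member_ids]
    if (anyNA(rows)) stop("row_info missing member(s) of ", a$archetype_id)
    a$n_seqs <- sum(row_info$n_seqs[rows])
    a$sources <- sort(unique(unlist(srcs[rows])))
    a$omz_regions <- sort(unique(unlist(omzs[rows])))
    a$taxonomy <- row_info$taxonomy[idx[[a$representative_id]]]
    if (!is.null(panel)) a$clade <- classify_clade(a, panel)
    a
  })
}

#' Environmental-source spectrum per clade
#'
#' For each clade, the percentage of archetypes containing at least one
#' member from each environmental source (presence/absence per archetype,
#' so rows can sum to more than 100% when archetypes carry several
#' sources). Unknown-clade archetypes are excluded and counted.
#'
#' @param archetypes Annotated archetypes (see [annotate_archetypes()]).
#' @return List of class `"source_by_clade"`: `percent` (source x clade
#'   matrix), `n_per_clade`, `n_unknown`.
#' @export
source_by_clade <- function(archetypes) {
  clades <- vapply(archetypes, `[[`, character(1), "clade")
  keep <- clades %in% c("I", "II")
  out <- matrix(0, length(env_sources()), 2,
                dimnames = list(env_sources(), c("I", "II")))
  n_per <- c(I = sum(clades == "I"), II = sum(clades == "II"))
  for (cl in c("I", "II")) {
    sub <- archetypes[clades == cl]
    if (!length(sub)) next
    for (s in env_sources()) {
      cnt <- sum(vapply(sub, function(a) s %in% a$sources, logical(1)))
      out[s, cl] <- 100 * cnt / length(sub)
    }
  }
  structure(list(percent = out, n_per_clade = n_per,
                 n_unknown = sum(!keep)),
            class = "source_by_clade")
}

.omz_labels <- c("AS", "ETNP", "ETSP", "AS+ETNP", "AS+ETSP", "ETNP+ETSP",
                 "AS+ETNP+ETSP")

#' Regional-overlap table of OMZ-containing archetypes
#'
#' Restricts to archetypes containing at least one marine-OMZ member,
#' tabulates the seven nonempty subsets of \{AS, ETNP, ETSP\} as
#' percentages, and aggregates to how many archetypes span exactly one,
#' two or all three OMZ regions.
#'
#' @param archetypes Annotated archetypes (their `omz_regions` sets over
#'   `{"AS","ETNP","ETSP"}`).
#' @return List of class `"omz_overlap"`: `n`, `counts` and `percent`
#'   (named by subset), `bands` (percent spanning 1, 2 or 3 regions).
#' @export
omz_overlap_table <- function(archetypes) {
  sets <- lapply(archetypes, function(a) {
    sort(intersect(a$omz_regions, c("AS", "ETNP", "ETSP")))
  })
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  n <- length(sets)
  counts <- stats::setNames(integer(7), .omz_labels)
  for (s in sets) {
    lab <- paste(intersect(c("AS", "ETNP", "ETSP"), s), collapse = "+")
    counts[lab] <- counts[lab] + 1L
  }
  pct <- if (n > 0) 100 * counts / n else counts * NA_real_
  sizes <- c(1, 1, 1, 2, 2, 2, 3)
  bands <- vapply(1:3, function(k) sum(pct[sizes == k]), numeric(1))
  names(bands) <- c("one_region", "two_regions", "three_regions")
  structure(list(n = n, counts = counts, percent = pct, bands = bands),
            class = "omz_overlap")
}

#' @export
print.omz_overlap <- function(x, ...) {
  cat(sprintf("OMZ regional overlap (n = %d archetypes)\n", x$n))
  print(round(x$percent, 1))
  cat("bands:", paste(sprintf("%s %.1f%%", names(x$bands), x$bands),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Weighted complete-denitrifier percentage
#'
#' `100 * (w1 * n_clade1 + w2 * n_clade2) / n_total`, rounded to the
#' nearest integer percent, under the assumption that a fraction `w1` of
#' clade I and `w2` of clade II organisms carry the complete
#' denitrification pathway.
#'
#' @param n_clade1,n_clade2 Sequence counts assigned to clade I / II.
#' @param n_total Total sequence count (>= n_clade1 + n_clade2).
#' @param w1,w2 Complete-denitrifier weights (defaults 0.83 and 0.50).
#' @return Rounded integer percent, with the unrounded value in attribute
#'   `"raw"`.
#' @export
denitrifier_fraction <- function(n_clade1, n_clade2, n_total,
                                 w1 = 0.83, w2 = 0.50) {
  stopifnot(n_total > 0, n_clade1 + n_clade2 <= n_total,
            w1 >= 0, w1 <= 1, w2 >= 0, w2 <= 1)
  raw <- 100 * (w1 * n_clade1 + w2 * n_clade2) / n_total
  structure(round(raw), raw = raw)
}

#' Environmental-source spectrum per taxon
#'
#' Strata are phyla, except Pseudomonadota which is split into classes
#' (`"Pseudomonadota;<class>"`). Percentages are of archetypes in the
#' stratum containing each source; archetypes without taxonomy are counted
#' in an `"unassigned"` row (percentages left NA there).
#'
#' @param archetypes Annotated archetypes carrying `taxonomy` paths
#'   (`phylum[/class[/...]]`).
#' @return List of class `"taxon_by_source"`: `percent` (stratum x source),
#'   `n_per_stratum`, `n_unassigned`.
#' @export
taxon_by_source <- function(archetypes) {
  tax <- vapply(archetypes, `[[`, character(1), "taxonomy")
  stratum <- vapply(tax, function(t) {
    if (is.na(t) || !nzchar(t)) return(NA_character_)
    parts <- strsplit(t, "/", fixed = TRUE)[[1]]
    if (parts[1] == "Pseudomonadota") {
      paste0("Pseudomonadota;",
             if (length(parts) >= 2) parts[2] else "unclassified")
    } else {
      parts[1]
    }
  }, character(1), USE.NAMES = FALSE)
  assigned <- !is.na(stratum)
  strata <- sort(unique(stratum[assigned]))
  out <- matrix(0, length(strata), length(env_sources()),
                dimnames = list(strata, env_sources()))
  n_per <- stats::setNames(integer(length(strata)), strata)
  for (st in strata) {
    sub <- archetypes[assigned & stratum == st]
    n_per[st] <- length(sub)
    for (s in env_sources()) {
      cnt <- sum(vapply(sub, function(a) s %in% a$sources, logical(1)))
      out[st, s] <- 100 * cnt / length(sub)
    }
  }
  structure(list(percent = out, n_per_stratum = n_per,
                 n_unassigned = sum(!assigned)),
            class = "taxon_by_source")
}
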