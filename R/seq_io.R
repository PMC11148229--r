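#' Build a sequence-record table
#'
#' Internal constructor validating the canonical record data frame used
#' throughout the pipeline.
#'
#' @param id,seq Character vectors (same length); `id` unique and nonempty.
#' @param source Environmental source labels (see [env_sources()]) or
#'   `"unlabeled"`.
#' @param region_of_origin,taxonomy,known_clade Optional per-record metadata
#'   (NA where absent).
#' @return A `data.frame` of class `"seq_records"`.
#' @keywords internal
new_seq_records <- function(id, seq,
                            source = rep("unlabeled", length(id)),
                            region_of_origin = rep(NA_character_, length(id)),
                            taxonomy = rep(NA_character_, length(id)),
                            known_clade = rep(NA_character_, length(id))) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (any(!nzchar(id)) || anyNA(id)) stop("record ids must be nonempty")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(seq))) stop("empty sequence(s): ",
                              paste(id[!nzchar(seq)], collapse = ", "))
  ok <- source %in% c(env_sources(), .unlabeled)
  if (any(!ok)) {
    stop("unknown source label(s): ", paste(unique(source[!ok]), collapse = ", "),
         "; allowed: ", paste(c(env_sources(), .unlabeled), collapse = ", "))
  }
  df <- data.frame(
    id = id, seq = seq, source = source,
    region_of_origin = region_of_origin, taxonomy = taxonomy,
    known_clade = known_clade, stringsAsFactors = FALSE
  )
  class(df) <- c("seq_records", "data.frame")
  df
}

#' Read a sequence compilation from FASTA (+ optional TSV metadata)
#'
#' Sequences are uppercased on read. Metadata rows are joined by `id`;
#' records absent from the metadata are labeled `"unlabeled"`. The metadata
#' TSV must have a header with columns `id` and `source` and may carry
#' `region`, `taxonomy` and `clade`; unrecognised extra columns are ignored
#' with a warning.
#'
#' @param fasta_path Path to a (possibly multi-line) FASTA file.
#' @param metadata_path Optional path to a tab-separated metadata file.
#' @return A `seq_records` data frame in file order.
#' @export
read_sequences <- function(fasta_path, metadata_path = NULL) {
  ss <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rec <- new_seq_records(ids, as.character(ss))
  if (length(ids) == 0L) return(rec)
  if (!is.null(metadata_path)) {
    md <- utils::read.delim(metadata_path, header = TRUE,
                            stringsAsFactors = FALSE, colClasses = "character")
    known <- c("id", "source", "region", "taxonomy", "clade")
    extra <- setdiff(names(md), known)
    if (length(extra)) {
      warning("ignoring unrecognised metadata column(s): ",
              paste(extra, collapse = ", "))
    }
    if (!all(c("id", "source") %in% names(md))) {
      stop("metadata must contain 'id' and 'source' columns")
    }
    bad <- setdiff(md$source, c(env_sources(), .unlabeled))
    if (length(bad)) {
      stop("unknown source label(s) in metadata: ",
           paste(bad, collapse = ", "),
           "; allowed: ", paste(c(env_sources(), .unlabeled), collapse = ", "))
    }
    m <- match(rec$id, md$id)
    hit <- !is.na(m)
    rec$source[hit] <- md$source[m[hit]]
    if ("region" %in% names(md)) rec$region_of_origin[hit] <- .na_if_empty(md$region[m[hit]])
    if ("taxonomy" %in% names(md)) rec$taxonomy[hit] <- .na_if_empty(md$taxonomy[m[hit]])
    if ("clade" %in% names(md)) rec$known_clade[hit] <- .na_if_empty(md$clade[m[hit]])
  }
  rec
}

.na_if_empty <- function(x) {
  x[!nzchar(x) | is.na(x)] <- NA_character_
  x
}

#' Write records to FASTA (and optionally their metadata to TSV)
#'
#' @param records A `seq_records` data frame.
#' @param fasta_path Output FASTA path (wrapped at 80 columns).
#' @param metadata_path Optional output TSV path.
#' @return `records`, invisibly.
#' @export
write_sequences <- function(records, fasta_path, metadata_path = NULL) {
  ss <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(ss, fasta_path, width = 80L)
  if (!is.null(metadata_path)) {
    md <- data.frame(
      id = records$id, source = records$source,
      region = ifelse(is.na(records$region_of_origin), "", records$region_of_origin),
      taxonomy = ifelse(is.na(records$taxonomy), "", records$taxonomy),
      clade = ifelse(is.na(records$known_clade), "", records$known_clade),
      stringsAsFactors = FALSE
    )
    utils::write.table(md, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(records)
}

#' Filter records by length
#'
#' Keeps records whose length satisfies
#' `min_len <= nchar(seq) <= max_len` (both bounds inclusive), preserving
#' input order.
#'
#' @param records A `seq_records` data frame.
#' @param params A [pipeline_params()] object.
#' @return The filtered `seq_records`.
#' @export
filter_by_length <- function(records, params = pipeline_params()) {
  len <- nchar(records$seq)
  keep <- len >= params$min_len & len <= params$max_len
  records[keep, , drop = FALSE]
}

#' Remove exact duplicate sequences
#'
#' Among records with byte-identical (uppercased) nucleotide strings, only
#' the first in input order is kept, retaining its id.
#'
#' @param records A `seq_records` data frame.
#' @return The deduplicated `seq_records`, in input order of the survivors.
#' @export
deduplicate_exact <- function(records) {
  records[!duplicated(records$seq), , drop = FALSE]
}

#' Retain OTUs containing marine or other aquatic sequences
#'
#' An OTU is kept when at least one member's source label is in
#' `priority_sources` (default: every label except `terrestrial` and
#' `animal`).
#'
#' @param otus List of OTU objects from [greedy_cluster()].
#' @param records The `seq_records` the OTUs were built from.
#' @param priority_sources Character vector of source labels that qualify.
#' @return The retained subset of `otus` (founding order preserved).
#' @export
filter_aquatic <- function(otus, records, priority_sources = aquatic_sources()) {
  src <- stats::setNames(records$source, records$id)
  keep <- vapply(otus, function(o) any(src[o$members] %in% priority_sources),
                 logical(1))
  otus[keep]
}
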