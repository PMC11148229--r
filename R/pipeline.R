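# End-to-end orchestration: compilation filters -> OTU clustering ->
# consensus/translation -> master alignment -> region split -> window /
# archetype discovery -> classification -> biogeography summaries.

.md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

#' Run the full archetype pipeline
#'
#' Executes: length filter, exact deduplication, greedy OTU clustering,
#' aquatic-source OTU filter, consensus calling (clusters of at least
#' `min_consensus_cluster` members) with smaller clusters carried as
#' individual sequences, ORF finding and translation, progressive protein
#' alignment with the reference, 5'/3' region assignment, per-region
#' back-translated alignment, discriminative-window discovery, archetype
#' clustering, clade classification and the biogeography summaries.
#'
#' @param x A `"sim_compilation"` from [simulate_compilation()], or a
#'   `seq_records` data frame (then `reference` and normally `panel` must
#'   be supplied).
#' @param params A [pipeline_params()].
#' @param reference `list(id, seq)`: full-length reference gene (taken from
#'   the simulation when `x` is one).
#' @param panel Optional [clade_panel()] (idem).
#' @param anchors Optional [reference_anchors()]; defaults to the standard
#'   anchors on the reference.
#' @param out_dir Optional output directory; when given, every stage
#'   artifact (TSV/FASTA/Newick/JSON) plus a run log is written there.
#' @return A list of class `"pipeline_result"` with `manifest`, `otus`,
#'   `rank_abundance`, per-region `regions` (alignment, window, archetypes,
#'   summaries) and `summary` (see [pipeline_report()]).
#' @export
run_pipeline <- function(x, params = pipeline_params(), reference = NULL,
                         panel = NULL, anchors = NULL, out_dir = NULL) {
  t0 <- Sys.time()
  if (inherits(x, "sim_compilation")) {
    records <- x$records
    if (is.null(reference)) reference <- x$reference
    if (is.null(panel)) panel <- x$panel
  } else {
    records <- x
  }
  if (is.null(reference)) stop("a full-length reference gene is required")
  if (is.null(anchors)) {
    anchors <- reference_anchors(reference$id,
                                 reference_len = nchar(reference$seq),
                                 window_len = params$window_len)
  }
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  manifest <- list(params = unclass(params),
                   input_checksum = .md5_of(paste(records$id, records$seq)),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"))

  n_input <- nrow(records)
  records <- filter_by_length(records, params)
  note("length filter: %d of %d records kept", nrow(records), n_input)
  n_len <- nrow(records)
  records <- deduplicate_exact(records)
  note("deduplication: %d unique sequences", nrow(records))
  n_uni <- nrow(records)
  manifest$counts <- list(input = n_input, length_filtered = n_len,
                          unique = n_uni)
  if (n_uni == 0L) {
    note("no sequences left; stopping early")
    manifest$counts$otus <- 0L
    res <- structure(list(manifest = manifest, otus = list(),
                          rank_abundance = NULL, regions = list(),
                          summary = NULL, log = log),
                     class = "pipeline_result")
    if (!is.null(out_dir)) .write_outputs(res, out_dir)
    return(res)
  }

  otus <- greedy_cluster(records, params$otu_identity)
  note("OTU clustering at %.2f identity: %d OTUs", params$otu_identity,
       length(otus))
  aq <- filter_aquatic(otus, records)
  note("aquatic filter: %d of %d OTUs retained", length(aq), length(otus))
  ra_curve <- rank_abundance(aq)
  manifest$counts$otus <- length(otus)
  manifest$counts$aquatic_otus <- length(aq)
  manifest$counts$aquatic_seqs <- ra_curve$n_sequences

  # pipeline rows: consensus per large OTU, members of small OTUs as
  # individual sequences
  rec_idx <- stats::setNames(seq_len(nrow(records)), records$id)
  rows <- list()
  for (o in aq) {
    mem <- records[rec_idx[o$members], , drop = FALSE]
    omz <- sort(unique(mem$region_of_origin[mem$source == "marine_omz" &
                                            !is.na(mem$region_of_origin)]))
    if (o$n >= params$min_consensus_cluster) {
      aln <- progressive_align(stats::setNames(mem$seq, mem$id), "nt")
      cons <- consensus_sequence(aln)
      rows[[o$otu_id]] <- list(
        id = o$otu_id, seq = cons, n_seqs = o$n,
        sources = sort(unique(mem$source)), omz_regions = omz,
        taxonomy = mem$taxonomy[mem$id == o$representative][1]
      )
    } else {
      for (i in seq_len(nrow(mem))) {
        m_omz <- if (mem$source[i] == "marine_omz" &&
                     !is.na(mem$region_of_origin[i])) {
          mem$region_of_origin[i]
        } else character(0)
        rows[[mem$id[i]]] <- list(
          id = mem$id[i], seq = mem$seq[i], n_seqs = 1L,
          sources = mem$source[i], omz_regions = m_omz,
          taxonomy = mem$taxonomy[i]
        )
      }
    }
  }
  note("alignment rows: %d (%d consensus + %d individual)", length(rows),
       sum(vapply(rows, function(r) grepl("^OTU", r$id), logical(1))),
       sum(!vapply(rows, function(r) grepl("^OTU", r$id), logical(1))))

  # ORFs and translation
  orfs <- list()
  kept <- character(0)
  for (r in rows) {
    orf <- tryCatch(find_orf(stats::setNames(r$seq, r$id),
                             min_codons = params$min_orf_codons),
                    error = function(e) NULL)
    if (is.null(orf)) {
      note("row %s: no plausible ORF; excluded", r$id)
    } else {
      orfs[[r$id]] <- orf
      kept <- c(kept, r$id)
    }
  }
  orfs[[reference$id]] <- find_orf(stats::setNames(toupper(reference$seq),
                                                   reference$id),
                                   min_codons = params$min_orf_codons)
  manifest$counts$orf_rows <- length(kept)

  prot <- vapply(orfs, `[[`, character(1), "protein")
  names(prot) <- names(orfs)
  master <- progressive_align(prot, "aa")
  groups <- assign_region(master, anchors)
  note("region split: %d five-prime, %d three-prime, %d excluded",
       length(groups$five_prime), length(groups$three_prime),
       length(groups$excluded))
  manifest$counts$five_prime_rows <- length(groups$five_prime)
  manifest$counts$three_prime_rows <- length(groups$three_prime)
  manifest$counts$region_excluded <- length(groups$excluded)

  row_info <- data.frame(
    id = vapply(rows, `[[`, character(1), "id"),
    n_seqs = vapply(rows, `[[`, integer(1), "n_seqs"),
    taxonomy = vapply(rows, function(r) {
      if (is.na(r$taxonomy) || !nzchar(r$taxonomy)) NA_character_ else r$taxonomy
    }, character(1)),
    stringsAsFactors = FALSE
  )
  row_info$sources <- lapply(rows, `[[`, "sources")
  row_info$omz_regions <- lapply(rows, `[[`, "omz_regions")

  regions <- list()
  for (rg in c("five_prime", "three_prime")) {
    ids <- groups[[rg]]
    if (length(ids) < 2L) {
      note("region %s: fewer than 2 members; skipped", rg)
      next
    }
    raln <- region_alignment(master, orfs, anchors, rg, ids)
    win <- find_discriminative_window(raln, params$window_len)
    mers <- extract_70mers(raln, win)
    arch <- cluster_archetypes(mers, params$archetype_identity, rg)
    arch <- annotate_archetypes(arch, row_info, panel)
    clades <- vapply(arch, `[[`, character(1), "clade")
    nseq <- vapply(arch, `[[`, numeric(1), "n_seqs")
    denitr <- denitrifier_fraction(sum(nseq[clades == "I"]),
                                   sum(nseq[clades == "II"]), sum(nseq),
                                   params$clade1_complete_frac,
                                   params$clade2_complete_frac)
    regions[[rg]] <- list(
      alignment = raln, window = win, archetypes = arch,
      source_by_clade = source_by_clade(arch),
      omz_overlap = omz_overlap_table(arch),
      taxon_by_source = taxon_by_source(arch),
      denitrifier_fraction = denitr,
      tree = if (length(arch) >= 3) nj_tree(arch) else NULL
    )
    note("region %s: window at column %d (ref ~%d-%d nt), %d archetypes, %.0f%% weighted complete denitrifiers",
         rg, win$start_col,
         raln$column_map[win$start_col + 1L],
         raln$column_map[min(win$start_col + win$width, length(raln$column_map))],
         length(arch), as.numeric(denitr))
    manifest$counts[[paste0("archetypes_", rg)]] <- length(arch)
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  res <- structure(list(manifest = manifest, otus = otus, aquatic_otus = aq,
                        rank_abundance = ra_curve, records = records,
                        row_info = row_info, master_msa = master,
                        groups = groups, regions = regions, log = log),
                   class = "pipeline_result")
  res$summary <- pipeline_report(res)
  if (!is.null(out_dir)) .write_outputs(res, out_dir)
  res
}

#' Summarise a pipeline run
#'
#' Collects the headline numbers of a run -- rank-abundance shares, per
#' region the archetype counts, clade proportions, OMZ overlap bands and
#' weighted complete-denitrifier percentage -- into one plain list suitable
#' for JSON serialisation. Percentages are reported to one decimal.
#'
#' @param res A `"pipeline_result"`.
#' @return A named list.
#' @export
pipeline_report <- function(res) {
  stopifnot(inherits(res, "pipeline_result"))
  out <- list(counts = res$manifest$counts)
  if (!is.null(res$rank_abundance)) {
    ra <- res$rank_abundance
    out$rank_abundance <- list(
      n_otus = ra$n_otus, n_sequences = ra$n_sequences,
      pct_seqs_largest = round(100 * ra$frac_seqs_largest, 1),
      pct_seqs_gt2 = round(100 * ra$frac_seqs_gt2, 1),
      pct_seqs_individual = round(100 * ra$frac_seqs_individual, 1),
      pct_otus_individual = round(100 * ra$frac_otus_individual, 1)
    )
  }
  for (rg in names(res$regions)) {
    r <- res$regions[[rg]]
    clades <- vapply(r$archetypes, `[[`, character(1), "clade")
    n <- length(clades)
    out[[rg]] <- list(
      n_archetypes = n,
      window_start_col = r$window$start_col,
      window_mean_distance = round(r$window$mean_pairwise_distance, 4),
      pct_clade_I = round(100 * sum(clades == "I") / max(n, 1), 1),
      pct_clade_II = round(100 * sum(clades == "II") / max(n, 1), 1),
      n_unknown_clade = sum(clades == "unknown"),
      omz_overlap_bands = round(r$omz_overlap$bands, 1),
      omz_n = r$omz_overlap$n,
      denitrifier_pct = as.numeric(r$denitrifier_fraction)
    )
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Archetype pipeline run\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

.write_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  writeLines(res$log, fp("run_log.txt"))
  jsonlite::write_json(res$manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  if (!is.null(res$summary)) {
    jsonlite::write_json(res$summary, fp("summary.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  if (length(res$otus)) {
    memb <- do.call(rbind, lapply(res$otus, function(o) {
      data.frame(otu_id = o$otu_id, member_id = o$members,
                 is_representative = o$members == o$representative,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(memb, fp("otu_membership.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$rank_abundance)) {
    utils::write.table(res$rank_abundance$table, fp("rank_abundance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (rg in names(res$regions)) {
    r <- res$regions[[rg]]
    arch_tab <- do.call(rbind, lapply(r$archetypes, function(a) {
      data.frame(archetype_id = a$archetype_id, region = a$region,
                 member_id = a$member_ids, clade = a$clade,
                 n_seqs = a$n_seqs,
                 sources = paste(a$sources, collapse = ";"),
                 omz_regions = paste(a$omz_regions, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(arch_tab, fp(sprintf("archetypes_%s.tsv", rg)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    reps <- vapply(r$archetypes, `[[`, character(1), "representative")
    names(reps) <- vapply(r$archetypes, `[[`, character(1), "archetype_id")
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(reps),
      fp(sprintf("archetype_reps_%s.fasta", rg)), width = 80L)
    w <- r$window
    cm <- r$alignment$column_map
    utils::write.table(
      data.frame(region = rg, start_col = w$start_col, width = w$width,
                 ref_start = cm[w$start_col + 1L],
                 ref_end = cm[min(w$start_col + w$width, length(cm))],
                 mean_pairwise_distance = w$mean_pairwise_distance),
      fp(sprintf("window_%s.tsv", rg)), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (!is.null(r$tree)) {
      writeLines(r$tree, fp(sprintf("tree_%s.nwk", rg)))
    }
  }
  invisible(out_dir)
}

#' Read a plain key=value run configuration
#'
#' Lines of the form `key = value` (comments with `#`). Recognised keys
#' mirror [pipeline_params()] and [simulation_config()] argument names,
#' plus `simulate` (logical), `fasta`, `metadata`, `reference_fasta`,
#' `panel_fasta`, `panel_clades` (comma-separated, parallel to the panel
#' FASTA).
#'
#' @param path Path to the configuration file.
#' @return Named list of strings.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  stats::setNames(lapply(kv, function(x) trimws(paste(x[-1], collapse = "="))),
                  trimws(vapply(kv, `[`, character(1), 1)))
}

#' Run the pipeline from a configuration file
#'
#' @param config_path Path to a key=value configuration (see
#'   [read_run_config()]).
#' @param out_dir Output directory.
#' @return The `"pipeline_result"`, invisibly.
#' @export
run_pipeline_file <- function(config_path, out_dir) {
  cfg <- read_run_config(config_path)
  num <- function(k, d) if (!is.null(cfg[[k]])) as.numeric(cfg[[k]]) else d
  p <- pipeline_params(
    min_len = num("min_len", 500), max_len = num("max_len", 3500),
    otu_identity = num("otu_identity", 0.87),
    archetype_identity = num("archetype_identity", 0.87),
    window_len = num("window_len", 70),
    min_consensus_cluster = num("min_consensus_cluster", 3),
    clade1_complete_frac = num("clade1_complete_frac", 0.83),
    clade2_complete_frac = num("clade2_complete_frac", 0.50),
    rng_seed = num("rng_seed", 1)
  )
  if (isTRUE(tolower(cfg$simulate %||% "false") == "true")) {
    sc <- simulation_config(
      n_clades = num("n_clades", 2),
      families_per_clade = num("families_per_clade", 4),
      seqs_per_family = if (!is.null(cfg$seqs_per_family)) {
        as.integer(cfg$seqs_per_family)
      } else list(dist = "geometric", mean = 6),
      intra_family_div = num("intra_family_div", 0.08),
      inter_family_div = num("inter_family_div", 0.22),
      inter_clade_div = num("inter_clade_div", 0.40),
      dup_rate = num("dup_rate", 0.05),
      source_concentration = num("source_concentration", 0.3),
      rng_seed = num("rng_seed", 1)
    )
    x <- simulate_compilation(sc)
    write_sequences(x$records, file.path(dirname(config_path), "simulated.fasta"))
    res <- run_pipeline(x, params = p, out_dir = out_dir)
  } else {
    if (is.null(cfg$fasta) || is.null(cfg$reference_fasta)) {
      stop("config must set 'fasta' and 'reference_fasta' (or simulate = true)")
    }
    rec <- read_sequences(cfg$fasta, cfg$metadata)
    ref_ss <- Biostrings::readBStringSet(cfg$reference_fasta)
    reference <- list(id = sub("\\s.*$", "", names(ref_ss)[1]),
                      seq = as.character(ref_ss[[1]]))
    panel <- NULL
    if (!is.null(cfg$panel_fasta)) {
      pp <- Biostrings::readBStringSet(cfg$panel_fasta)
      panel <- clade_panel(sub("\\s.*$", "", names(pp)),
                           as.character(pp),
                           strsplit(cfg$panel_clades, ",")[[1]],
                           alphabet = "nt")
    }
    res <- run_pipeline(rec, params = p, reference = reference,
                        panel = panel, out_dir = out_dir)
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
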