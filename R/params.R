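#' Environmental source labels
#'
#' The controlled vocabulary of environmental sources a sequence record may
#' carry. Records without a label use the sentinel `"unlabeled"`, which is
#' not itself a source.
#'
#' @return Character vector of the ten recognised source labels.
#' @export
env_sources <- function() {
  c(
    "marine_sediment", "marine_water_column", "marine_omz",
    "hydrothermal_vent", "terrestrial", "animal", "salt_marsh",
    "freshwater_estuary", "wastewater", "aquatic_other"
  )
}

#' Marine and other aquatic source labels
#'
#' The default "priority" set used to retain OTUs: every recognised source
#' except `terrestrial` and `animal`.
#'
#' @return Character vector of eight source labels.
#' @export
aquatic_sources <- function() {
  setdiff(env_sources(), c("terrestrial", "animal"))
}

.unlabeled <- "unlabeled"

#' Pipeline parameters
#'
#' Bundles the tunable parameters of the compilation-to-archetype pipeline.
#' Defaults follow the standard functional-gene archetype workflow: length
#' window 500--3,500 bp for compiled CDS records, 87% identity for both OTU
#' and archetype clustering (the level found to discriminate functional genes
#' at roughly species resolution), a 70 bp discriminative window, consensus
#' calling for clusters of at least 3 members, and complete-denitrifier
#' weights of 0.83 (clade I) and 0.50 (clade II).
#'
#' @param min_len,max_len Inclusive length bounds in bases for compiled
#'   sequences.
#' @param otu_identity Identity threshold (fraction) for OTU clustering.
#' @param archetype_identity Identity threshold (fraction) for archetype
#'   clustering over the discriminative window.
#' @param window_len Width in alignment columns (nt) of the discriminative
#'   window.
#' @param min_consensus_cluster Minimum OTU size for consensus calling;
#'   smaller OTUs are carried forward as individual sequences.
#' @param clade1_complete_frac,clade2_complete_frac Assumed fraction of
#'   clade I / clade II organisms that are complete denitrifiers.
#' @param min_orf_codons Minimum stop-free stretch (codons) accepted as an
#'   open reading frame.
#' @param rng_seed Integer seed for any randomised step.
#' @return A list of class `"pipeline_params"`.
#' @export
pipeline_params <- function(min_len = 500L,
                            max_len = 3500L,
                            otu_identity = 0.87,
                            archetype_identity = 0.87,
                            window_len = 70L,
                            min_consensus_cluster = 3L,
                            clade1_complete_frac = 0.83,
                            clade2_complete_frac = 0.50,
                            min_orf_codons = 20L,
                            rng_seed = 1L) {
  p <- list(
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    otu_identity = otu_identity, archetype_identity = archetype_identity,
    window_len = as.integer(window_len),
    min_consensus_cluster = as.integer(min_consensus_cluster),
    clade1_complete_frac = clade1_complete_frac,
    clade2_complete_frac = clade2_complete_frac,
    min_orf_codons = as.integer(min_orf_codons),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    p$min_len <= p$max_len,
    p$otu_identity > 0, p$otu_identity <= 1,
    p$archetype_identity > 0, p$archetype_identity <= 1,
    p$window_len >= 1L,
    p$clade1_complete_frac >= 0, p$clade1_complete_frac <= 1,
    p$clade2_complete_frac >= 0, p$clade2_complete_frac <= 1
  )
  class(p) <- "pipeline_params"
  p
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("Pipeline parameters:\n")
  cat(sprintf("  length window        : %d-%d bp\n", x$min_len, x$max_len))
  cat(sprintf("  OTU identity         : %.2f\n", x$otu_identity))
  cat(sprintf("  archetype identity   : %.2f\n", x$archetype_identity))
  cat(sprintf("  discriminative window: %d nt\n", x$window_len))
  cat(sprintf("  consensus min size   : %d\n", x$min_consensus_cluster))
  cat(sprintf("  complete-denitrifier weights: clade I %.2f, clade II %.2f\n",
              x$clade1_complete_frac, x$clade2_complete_frac))
  invisible(x)
}
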