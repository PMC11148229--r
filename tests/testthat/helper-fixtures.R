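# Fixture builders shared across test files.

.codons64 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                               c("A", "C", "G", "T")), 1, paste, collapse = "")
.sense_codons <- setdiff(.codons64, c("TAA", "TAG", "TGA"))

# random stop-free (frame +1) gene of `n_codons` codons
random_gene <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(.sense_codons, n_codons, replace = TRUE), collapse = "")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly k positions of `seq` (guaranteed different base)
mutate_k <- function(seq, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    character(1))
  paste(ch, collapse = "")
}

make_records <- function(seqs, sources = NULL, ids = NULL, ...) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(seqs))
  if (is.null(sources)) sources <- rep("unlabeled", length(seqs))
  archetypeR:::new_seq_records(ids, seqs, source = sources, ...)
}

# bare annotated archetype for the biogeography summaries
make_arch <- function(id, clade = "unknown", sources = character(0),
                      omz = character(0), taxonomy = NA_character_,
                      n_seqs = 1L, region = "five_prime",
                      representative = strrep("A", 70)) {
  structure(list(archetype_id = id, region = region,
                 representative = representative, representative_id = id,
                 member_ids = id, clade = clade, sources = sources,
                 omz_regions = omz, taxonomy = taxonomy, n_seqs = n_seqs),
            class = "archetype")
}
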