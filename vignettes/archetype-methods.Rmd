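---
title: "Methods: archetype analysis of functional-gene compilations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: archetype analysis of functional-gene compilations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`archetypeR` implements a complete desk-scale pipeline for profiling the
diversity and environmental distribution of a functional gene family from
a heterogeneous sequence compilation. It was written around *nosZ*
(nitrous oxide reductase), but nothing in the machinery is *nosZ*-specific
beyond the default reference coordinates. This vignette records the
methods, the tunable parameters, and the design decisions taken where the
procedure was genuinely open.

## The analysis model

The input is a set of nucleotide sequences — whole-gene CDS records and
PCR-amplicon or metagenome fragments — with an environmental source label
per sequence (ten controlled labels from `marine_sediment` to
`aquatic_other`, plus an `unlabeled` sentinel). The pipeline proceeds:

1. **Length filter** (default 500–3,500 bp, both bounds inclusive — the
   conventional reading of a stated range) and **exact deduplication**
   (first instance wins). Deduplication is byte-exact after uppercasing;
   reverse complements and near-duplicates are deliberately *not*
   collapsed, since the gene orientation of CDS records is meaningful and
   near-duplicate collapsing is what OTU clustering is for.
2. **Greedy OTU clustering** at 87% identity. Records are processed
   longest-first (ties by id) and each joins the first OTU whose
   representative it matches at or above the threshold — the CD-HIT
   scheme, but with exact free-end-gap dynamic programming (match +1,
   mismatch −1, gap −2) instead of word filters; identity is identical
   unambiguous positions over the shorter sequence, and `N`/IUPAC codes
   never count as matches. 87% is the threshold classically used to bin
   functional genes at roughly species-level resolution. The canonical
   processing order makes the partition independent of input file order.
3. **Aquatic filter**: OTUs with no member from a marine or other aquatic
   source (i.e. everything except `terrestrial` and `animal`; the set is
   overridable) are dropped from further analysis.
4. **Consensus and individuals**: OTUs with ≥ 3 members are aligned
   (nucleotide) and collapsed to a majority-rule consensus; 1–2-member
   OTUs are carried forward as individual sequences. A 3-member cluster
   therefore gets a consensus — the smallest size at which a majority
   vote is meaningful.
5. **Translation**: each row is translated via its longest stop-free
   stretch across all six frames (standard code, ≥ 20 codons). A start
   codon is not required because most rows are internal gene fragments.
6. **Master protein alignment** of all rows plus the full-length
   reference, then **region assignment**: the reference anchor windows
   (default 792–861 nt and 1,322–1,391 nt on a 1,920 nt gene) are mapped
   to alignment columns through the reference row; a row joins the 5′
   (3′) group iff its footprint — first to last non-gap column — covers
   every 5′ (3′) anchor column. Full-length rows join both; rows covering
   neither are excluded and logged. The two amplicon populations overlap
   by only ~42 bp, which is why the regions are analysed separately.
7. **Discriminative window ("probe finding")**: the region alignment is
   back-translated to codons and every 70-column window is scored by the
   mean pairwise p-distance over member rows (the reference anchors
   coordinates but is never scored). The maximising window is selected,
   ties leftmost. Members are sliced at that window and greedily
   clustered at 87% column-wise identity into **archetypes**.
8. **Classification and summaries**: each archetype representative is
   classified clade I/II/unknown by best identity against a reference
   panel; the biogeography tables (source-by-clade, OMZ overlap,
   taxon-by-source, rank abundance, weighted complete-denitrifier
   percentage) are tabulated per region.

### Distances and identities

Three related but distinct quantities are used, each where the procedure
calls for it:

* **Alignment identity** (OTU clustering, classification): matches over
  the shorter input after free-end-gap global alignment.
* **p-distance** (window scoring, trees): mismatches over comparable
  (both non-gap) columns; ambiguity codes count as mismatches; a pair
  with *zero* comparable columns inside a window is assigned distance 1
  with a warning — such pairs carry no signal and treating them as
  maximally distant keeps degenerate windows from looking informative.
* **Slice identity** (archetype clustering): matching characters over the
  fixed window width, without realignment; gap–gap columns count as
  matches so co-deleted members can cluster, gap–base as mismatches, and
  members whose slice is more than 50% gaps are excluded outright
  (gap-dominated slices would otherwise cluster on shared absence).

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_len`, `max_len` | 500, 3500 | bp | compilation window for credible gene records |
| `otu_identity` | 0.87 | fraction | species-level binning for functional genes |
| `archetype_identity` | 0.87 | fraction | same resolution on the 70-mer |
| `window_len` | 70 | nt columns | long enough to discriminate, short enough to admit fragments |
| `min_consensus_cluster` | 3 | sequences | smallest meaningful majority |
| `clade1_complete_frac`, `clade2_complete_frac` | 0.83, 0.50 | fraction | genome-survey estimates of complete denitrifiers per clade |
| `min_orf_codons` | 20 | codons | floor below which a stop-free stretch is noise |
| panel `min_identity` | 0.60 (aa) / 0.50 (nt) | fraction | random-match baselines differ (~6% aa vs 25% nt) |

Aligner scoring: BLOSUM62, gap open −10 / extend −1 for proteins; match
+2 / mismatch −3, gap open −5 / extend −2 for nucleotides. End gaps are
free (semi-global): rows are mostly fragments, and end gaps are missing
data, not evolutionary events.

## Numerical and design choices

* **Profile scoring shift.** Profile–profile columns are scored as
  frequency-weighted sums over a BLOSUM62 matrix shifted by +1. At the
  protein divergences this pipeline must absorb (down to ~20–25%
  identity between clades), the expected unshifted column score is
  slightly negative, and a free-end-gap DP then prefers sliding two
  profiles past each other to aligning them. The +1 shift keeps the
  expected score for genuine homologs positive while unrelated segments
  (e.g. a 5′-only against a 3′-only fragment) still score negative and
  stay unforced. Guide trees are UPGMA on k-mer set distances (k = 3 for
  proteins, 6 for nucleotides), with inputs sorted by id first so the
  result is independent of input order.
* **Terminal gaps are missing data in consensus calling.** Within a
  column, the majority vote is taken over the rows whose footprint covers
  that column, and only *internal* gaps count towards the
  gap-strict-majority rule that drops a column. A fragment that simply
  does not extend into a region must not vote to delete it: an OTU
  holding, say, eleven 3′ fragments, six 5′ fragments and three
  full-length members would otherwise lose its entire 5′ region from the
  consensus, and with it the family's representation in the 5′ analysis.
  Ties among bases become the minimal covering IUPAC code.
* **Anchor widths.** The anchor ranges are taken at exactly
  `window_len` = 70 nt (792–861, 1322–1391); published descriptions of
  these coordinates are approximate and a fixed width keeps the
  anchor-coverage semantics exact.
* **Window ties leftmost; window wider than the alignment** falls back to
  the whole alignment with a warning rather than failing.
* **Neighbor joining** (on representative 70-mer p-distances, negative
  branch lengths clamped to 0) stands in for likelihood tree inference;
  the tree is for visualisation and ordering, and no topological claims
  are tested.
* **Classification** uses best-hit identity with ties across clades →
  `unknown`; the call is invariant to panel entry order. When a protein
  panel meets a nucleotide query, the query is translated in the three
  forward frames and the best frame is used.
* **Command line**: the pipeline stages are exported R functions, so the
  shipped CLI (`inst/scripts/archetyper.R`) exposes just `simulate` and
  `all` over a key=value config; per-stage experimentation is more
  natural in R than through per-stage subcommands.

## The synthetic generator

`simulate_compilation()` emulates the structure of a real compilation
with known ground truth: a random stop-free root gene (1,920 nt) is
mutated per-site at `inter_clade_div` (default 0.40) to make clade
ancestors, at `inter_family_div` (0.22) to make phylotype-family
founders, and at `intra_family_div` (0.08) to make members — so
within-family < between-family < between-clade divergence by
construction. Members become full-length, 5′-only (699 nt) or 3′-only
(745 nt) records; the amplicon spans are placed so each covers its anchor
window and the two overlap by exactly 42 bp (reference 519–1217 and
1176–1920), mirroring the real amplicon geometry. Family sizes default to
a geometric distribution (long-tailed, rank-abundance-like); exact
duplicates are injected at `dup_rate`; each family draws a source
distribution from a symmetric Dirichlet whose concentration sets habitat
specificity, and marine-OMZ members draw a region of origin (AS / ETNP /
ETSP) with per-family bias. Substitutions are uniform to a different
base, with nonsense codons resolved by setting their third base to C —
a crude stand-in for purifying selection that keeps every lineage
translatable in frame +1.

What it does **not** emulate: indels within amplicons (an optional
per-codon deletion rate exists purely to stress the aligner; with it the
ground-truth coordinate map is no longer exact), transition/transversion
bias, codon-level selection, chimeras, sequencing error profiles, or
taxonomy inferred from sequence (taxonomy is a per-family label). Tests
passing on this generator therefore demonstrate the pipeline's logic —
clustering, region assignment, window discovery, classification,
bookkeeping — not robustness to alignment-hostile real data; for real
compilations the aligner is pluggable (a precomputed alignment can be
substituted where an external MSA tool is preferred).

Because mutations are substitution-only, the true multiple alignment is
the identity map on reference coordinates, and every downstream oracle in
the test suite (window scans, distance recounts, greedy replays) is
exact.

## Test problem sizes

The unit suites run on strings of tens to hundreds of bases with
brute-force oracles (exhaustive DP alignment, six-frame ORF enumeration,
naive distance recounts, direct subset tallies). The end-to-end benchmark
simulates 2 clades × 4 families × 20 members (~166 records with
duplicates) and requires every simulated family to surface as exactly one
archetype per region with every clade call matching ground truth; smaller
2×2 configurations exercise determinism and artifact writing. These sizes
were chosen as the smallest at which each recovery property is
non-trivial.

## Known limitations

* Greedy clustering is order-dependent by design (canonicalised, but a
  different canonical order would give a different — equally valid —
  partition near the threshold).
* The consensus of a cluster whose members split over two regions joins
  them through the ~42 bp overlap; if an OTU contained *only*
  non-overlapping 5′ and 3′ fragments (no full-length, no overlap
  coverage), its consensus would concatenate the regions at the overlap
  boundary. Such OTUs do not arise from the generator's geometry but
  could from pathological real inputs.
* p-distance is uncorrected; no model-based distance (hooks exist: any
  symmetric matrix can be fed to the NJ step).
* The weighted complete-denitrifier percentage inherits the cultivation
  bias of its clade weights; it is reported as a rounded integer percent
  by construction.
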