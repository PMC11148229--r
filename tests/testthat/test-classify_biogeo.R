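test_that("clade classification calls the best reference and respects the threshold", {
  set.seed(71)
  ref1 <- random_dna(300)
  ref2 <- mutate_k(ref1, 180)   # well separated
  panel <- clade_panel(c("p1", "p2"), c(ref1, ref2), c("I", "II"), "nt")
  expect_equal(classify_clade(substr(ref1, 50, 119), panel), "I")
  expect_equal(classify_clade(substr(ref2, 50, 119), panel), "II")
  # a random unrelated query stays unknown under the identity floor
  expect_equal(classify_clade(random_dna(70), panel), "unknown")
  # equal best identity in both clades -> unknown, and panel order is
  # irrelevant
  panel_tie <- clade_panel(c("a", "b"), c(ref1, ref1), c("I", "II"), "nt")
  expect_equal(classify_clade(substr(ref1, 1, 70), panel_tie), "unknown")
  panel_rev <- clade_panel(c("p2", "p1"), c(ref2, ref1), c("II", "I"), "nt")
  expect_equal(classify_clade(substr(ref1, 50, 119), panel_rev), "I")
  expect_error(clade_panel("x", ref1, "I", "nt"), "per clade")
})

test_that("source-by-clade percentages use presence/absence per archetype", {
  arch <- list(
    make_arch("a1", "I", sources = "marine_sediment"),
    make_arch("a2", "I", sources = c("marine_sediment", "terrestrial")),
    make_arch("a3", "II", sources = "marine_water_column"),
    make_arch("a4", "unknown", sources = "animal")
  )
  sb <- source_by_clade(arch)
  expect_equal(unname(sb$percent["marine_sediment", "I"]), 100)
  expect_equal(unname(sb$percent["terrestrial", "I"]), 50)
  expect_equal(unname(sb$percent["marine_water_column", "II"]), 100)
  expect_equal(unname(sb$n_per_clade), c(2L, 2L - 1L))
  expect_equal(sb$n_unknown, 1L)
  # multi-source archetypes can push a clade's row sum above 100
  expect_gt(sum(sb$percent[, "I"]), 100 - 1e-9)
})

test_that("OMZ overlap table reproduces the published 5' and 3' breakdowns", {
  # 5' region, n = 25: 7 AS, 1 ETNP, 11 ETSP, 6 AS+ETNP
  arch5 <- c(
    lapply(1:7, function(i) make_arch(paste0("a", i), omz = "AS")),
    lapply(8, function(i) make_arch(paste0("a", i), omz = "ETNP")),
    lapply(9:19, function(i) make_arch(paste0("a", i), omz = "ETSP")),
    lapply(20:25, function(i) make_arch(paste0("a", i), omz = c("AS", "ETNP")))
  )
  t5 <- omz_overlap_table(arch5)
  expect_equal(t5$n, 25L)
  expect_equal(unname(t5$percent[c("AS", "ETNP", "ETSP", "AS+ETNP")]),
               c(28, 4, 44, 24))
  expect_equal(unname(t5$bands), c(76, 24, 0))

  # 3' region, n = 49: 13/12/4/17/0/1/2
  mk <- function(n, omz) lapply(seq_len(n), function(i) {
    make_arch(paste0(paste(omz, collapse = ""), i), omz = omz)
  })
  arch3 <- c(mk(13, "AS"), mk(12, "ETNP"), mk(4, "ETSP"),
             mk(17, c("AS", "ETNP")), mk(1, c("ETNP", "ETSP")),
             mk(2, c("AS", "ETNP", "ETSP")))
  t3 <- omz_overlap_table(arch3)
  expect_equal(t3$n, 49L)
  expect_equal(round(unname(t3$bands), 1), c(59.2, 36.7, 4.1))
  expect_equal(round(unname(t3$percent), 1),
               c(26.5, 24.5, 8.2, 34.7, 0, 2.0, 4.1))
})

test_that("OMZ overlap equals a direct subset tally on random sets and sums to 100", {
  set.seed(72)
  for (k in 1:5) {
    sets <- replicate(30, sample(c("AS", "ETNP", "ETSP"),
                                 sample(0:3, 1)), simplify = FALSE)
    arch <- Map(function(i, s) make_arch(paste0("r", i), omz = s),
                seq_along(sets), sets)
    tab <- omz_overlap_table(arch)
    want <- oracle_omz_tally(sets)
    expect_equal(unname(tab$counts), as.integer(want))
    expect_equal(sum(tab$counts), tab$n)
    if (tab$n > 0) {
      expect_equal(sum(tab$percent), 100, tolerance = 0.1)
      expect_equal(sum(tab$bands), 100, tolerance = 0.1)
    }
  }
})

test_that("weighted complete-denitrifier percentage matches the worked examples", {
  expect_equal(as.numeric(denitrifier_fraction(681, 182, 866)), 76)
  expect_equal(as.numeric(denitrifier_fraction(2758, 431, 3190)), 79)
  expect_equal(as.numeric(denitrifier_fraction(10, 0, 10)), 83)
  # linear in the weights; equals w1 when everything is clade I
  expect_equal(attr(denitrifier_fraction(100, 0, 100, w1 = 0.4), "raw"), 40)
  a <- attr(denitrifier_fraction(50, 50, 100, w1 = 0.8, w2 = 0.2), "raw")
  b <- attr(denitrifier_fraction(50, 50, 100, w1 = 0.4, w2 = 0.1), "raw")
  expect_equal(a, 2 * b)
  expect_error(denitrifier_fraction(1, 1, 0))
  expect_error(denitrifier_fraction(5, 6, 10))
})

test_that("taxon-by-source strata split Pseudomonadota into classes and report unassigned", {
  arch <- list(
    make_arch("x1", taxonomy = "Pseudomonadota/Alphaproteobacteria",
              sources = "marine_sediment"),
    make_arch("x2", taxonomy = "Pseudomonadota/Alphaproteobacteria",
              sources = "marine_sediment"),
    make_arch("x3", taxonomy = "Pseudomonadota/Gammaproteobacteria",
              sources = "terrestrial"),
    make_arch("x4", taxonomy = "Bacteroidota",
              sources = c("marine_water_column", "freshwater_estuary")),
    make_arch("x5", taxonomy = NA_character_, sources = "animal")
  )
  tb <- taxon_by_source(arch)
  expect_setequal(rownames(tb$percent),
                  c("Pseudomonadota;Alphaproteobacteria",
                    "Pseudomonadota;Gammaproteobacteria", "Bacteroidota"))
  expect_equal(unname(tb$percent["Pseudomonadota;Alphaproteobacteria",
                                 "marine_sediment"]), 100)
  expect_equal(unname(tb$percent["Bacteroidota", "marine_water_column"]), 100)
  expect_equal(unname(tb$percent["Bacteroidota", "freshwater_estuary"]), 100)
  expect_equal(tb$n_unassigned, 1L)
  expect_equal(unname(tb$n_per_stratum),
               c(1L, 2L, 1L)[order(c("Bacteroidota",
                                     "Pseudomonadota;Alphaproteobacteria",
                                     "Pseudomonadota;Gammaproteobacteria"))])
})
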