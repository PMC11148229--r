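test_that("six-frame ORF finding returns the longest stop-free stretch", {
  set.seed(21)
  body <- random_gene(25)
  seq <- paste0(body, "ATGAAA", body)
  orf <- find_orf(c(x = seq))
  expect_true(grepl("MK", orf$protein))
  expect_false(grepl("\\*", orf$protein))
  expect_equal(orf$frame, 1L)
  # strand symmetry: the reverse complement yields the same protein
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  orf_rc <- find_orf(c(xrc = rc))
  expect_equal(orf_rc$protein, orf$protein)
  expect_lt(orf_rc$frame, 0)
})

test_that("of two ORFs the longer one wins, and coordinates are consistent", {
  # stop cassettes bound the planted ORFs; in frame +1 the cassette
  # "TTAATTAATTAA" only stops at its final codon, so the longest stretch
  # is the 45-codon ORF plus the three leading cassette codons (48), as
  # the brute-force six-frame oracle confirms
  set.seed(22)
  stopper <- "TTAATTAATTAA"
  orf30 <- random_gene(30)
  orf45 <- random_gene(45)
  seq <- paste0(stopper, orf30, stopper, orf45, stopper)
  orf <- find_orf(c(y = seq))
  expect_equal(nchar(orf$protein), oracle_longest_orf_codons(seq))
  expect_equal(nchar(orf$protein), 48L)
  expect_equal(orf$frame, 1L)
  # the stretch embeds the planted 45-codon ORF, not the 30-codon one
  expect_true(grepl(archetypeR:::.translate_nt(orf45), orf$protein, fixed = TRUE))
  expect_false(grepl(archetypeR:::.translate_nt(orf30), orf$protein, fixed = TRUE))
  expect_equal(orf$nt_end - orf$nt_start, 3L * nchar(orf$protein))
  expect_equal(substr(seq, orf$nt_start + 1, orf$nt_end), orf$cds)
  expect_equal(archetypeR:::.translate_nt(orf$cds), orf$protein)
})

test_that("ORF length equals the brute-force six-frame scan on random sequences", {
  set.seed(23)
  for (k in 1:10) {
    s <- random_dna(sample(150:400, 1))
    want <- oracle_longest_orf_codons(s)
    if (want < 20) {
      expect_error(find_orf(c(z = s)), "no plausible ORF")
    } else {
      expect_equal(nchar(find_orf(c(z = s))$protein), want)
    }
  }
  expect_error(find_orf(c(w = strrep("TTAATTAATTAA", 15))), "no plausible ORF")
})

test_that("progressive alignment handles the pairwise base cases", {
  m <- progressive_align(c(a = "ACGTA", b = "ACGTA"), "nt")
  expect_equal(unname(m$seqs), c("ACGTA", "ACGTA"))
  m2 <- progressive_align(c(a = "ACGT", b = "ACG"), "nt")
  expect_equal(unname(m2$seqs[["a"]]), "ACGT")
  expect_equal(nchar(m2$seqs[["b"]]), 4L)
  expect_equal(sum(strsplit(m2$seqs[["b"]], "")[[1]] == "-"), 1L)
  # the 3 aligned positions match (one terminal gap)
  ca <- strsplit(m2$seqs[["a"]], "")[[1]]; cb <- strsplit(m2$seqs[["b"]], "")[[1]]
  expect_equal(sum(ca == cb & cb != "-"), 3L)
})

test_that("progressive alignment rows ungap to their inputs and ignore input order", {
  set.seed(31)
  base <- random_gene(60)
  seqs <- c(a = base,
            b = mutate_k(base, 15),
            c = mutate_k(base, 30),
            d = substr(base, 31, 150),
            e = mutate_k(base, 5))
  m <- progressive_align(seqs, "nt")
  expect_equal(ungap(unname(m$seqs[names(seqs)])), unname(seqs[names(seqs)]))
  m2 <- progressive_align(seqs[c(3, 1, 5, 2, 4)], "nt")
  expect_equal(m$seqs, m2$seqs)
  # protein alphabet path
  prots <- vapply(seqs[1:3], archetypeR:::.translate_nt, character(1))
  pm <- progressive_align(prots, "aa")
  expect_equal(ungap(unname(pm$seqs)), unname(prots[sort(names(prots))]))
})

test_that("back-translation expands residues to codons and gaps to triplets", {
  m <- msa(c("r1", "r2"), c("MK", "M-"), "aa")
  orfs <- list(r1 = list(parent_id = "r1", protein = "MK", cds = "ATGAAA"),
               r2 = list(parent_id = "r2", protein = "M", cds = "ATG"))
  nt <- backtranslate(m, orfs)
  expect_equal(unname(nt$seqs), c("ATGAAA", "ATG---"))
  m3 <- msa("r3", "M-K", "aa")
  orfs3 <- list(r3 = list(parent_id = "r3", protein = "MK", cds = "ATGAAA"))
  expect_equal(unname(backtranslate(m3, orfs3)$seqs), "ATG---AAA")
  # translate(ungap(backtranslate(x))) round-trips to the protein row
  expect_equal(archetypeR:::.translate_nt(ungap(backtranslate(m3, orfs3)$seqs[["r3"]])),
               "MK")
  bad <- list(r3 = list(parent_id = "r3", protein = "MM", cds = "ATGATG"))
  expect_error(backtranslate(m3, bad), "r3")
})

test_that("p-distances match a naive recount and satisfy metric basics", {
  expect_equal(unname(p_distance_matrix(c(x = "ACGT", y = "ACGT"))["x", "y"]), 0)
  d <- p_distance_matrix(c(a = "AC-GT", b = "ACCGA"))
  expect_equal(unname(d["a", "b"]), 0.25)   # 1 mismatch / 4 comparable
  set.seed(41)
  rows <- replicate(10, paste(sample(c("A", "C", "G", "T", "-"), 100, TRUE,
                                     prob = c(rep(0.22, 4), 0.12)), collapse = ""))
  names(rows) <- sprintf("r%02d", 1:10)
  got <- p_distance_matrix(rows)
  want <- oracle_pdist(unname(rows))
  expect_equal(unname(got), want, tolerance = 1e-12)
  expect_true(all(diag(got) == 0))
  expect_true(all(got >= 0 & got <= 1))
  expect_equal(got, t(got))
  # zero comparable columns -> distance 1 with a warning
  expect_warning(d2 <- p_distance_matrix(c(u = "AA--", v = "--TT")), "comparable")
  expect_equal(unname(d2["u", "v"]), 1)
})
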