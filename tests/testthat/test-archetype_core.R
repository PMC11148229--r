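# Helper: build a protein master alignment with a gap-free reference row
# of `n_res` residues plus member rows padded with terminal gaps.
make_master <- function(n_res, members, ref_id = "REF") {
  set.seed(99)
  ref <- paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                      n_res, TRUE), collapse = "")
  rows <- c(stats::setNames(ref, ref_id),
            vapply(members, function(fp) {
              paste0(strrep("-", fp[1] - 1),
                     substr(ref, fp[1], fp[2]),
                     strrep("-", n_res - fp[2]))
            }, character(1)))
  msa(names(rows), rows, "aa")
}

test_that("region assignment follows anchor-column coverage of the footprint", {
  anch <- reference_anchors("REF", reference_len = 300,
                            five_prime_range = c(91, 100),
                            three_prime_range = c(201, 210),
                            window_len = 10)
  # protein columns: 5' anchor = residues 31..34, 3' anchor = 67..70
  m <- make_master(100, list(full = c(1, 100),
                             left = c(10, 50),
                             right = c(40, 100),
                             mid_half = c(33, 60)))
  suppressMessages(gr <- assign_region(m, anch))
  expect_true(all(c("full", "left", "right") %in%
                  c(gr$five_prime, gr$three_prime)))
  expect_setequal(gr$five_prime, c("full", "left"))
  expect_setequal(gr$three_prime, c("full", "right"))
  # fragment covering only half the 5' anchor is excluded
  expect_equal(gr$excluded, "mid_half")
  expect_error(assign_region(m, reference_anchors("MISSING", 300,
                                                  c(91, 100), c(201, 210), 10)),
               "absent")
})

test_that("discriminative window equals the brute-force scan and prefers leftmost ties", {
  # all-identical members: score 0, leftmost window
  ra <- structure(list(region = "five_prime",
                       msa = msa(c("REF", "m1", "m2"),
                                 rep(strrep("ACGT", 30), 3), "nt"),
                       member_ids = c("m1", "m2"), reference_id = "REF",
                       column_map = seq_len(120)),
                  class = "region_alignment")
  w <- find_discriminative_window(ra, 70)
  expect_equal(w$start_col, 0L)
  expect_equal(w$mean_pairwise_distance, 0)
  expect_equal(w$width, 70L)

  # 200-column alignment variable only in columns 50..119 (1-based)
  set.seed(61)
  base <- random_dna(200)
  vary <- function(s) {
    ch <- strsplit(s, "")[[1]]
    idx <- 50:119
    ch[idx] <- vapply(ch[idx], function(b) sample(c("A", "C", "G", "T"), 1),
                      character(1))
    paste(ch, collapse = "")
  }
  rows <- c(base, replicate(4, vary(base)))
  names(rows) <- c("m0", sprintf("m%d", 1:4))
  ra2 <- structure(list(region = "five_prime",
                        msa = msa(c("REF", names(rows)), c(base, rows), "nt"),
                        member_ids = names(rows), reference_id = "REF",
                        column_map = seq_len(200)),
                   class = "region_alignment")
  w2 <- find_discriminative_window(ra2, 70)
  want <- oracle_window(unname(rows), 70)
  expect_equal(w2$start_col, want$start_col)
  expect_equal(w2$start_col, 49L)   # window [50, 119] in 1-based columns
  expect_equal(w2$mean_pairwise_distance, want$score, tolerance = 1e-12)
  expect_equal(w2$profile, want$profile, tolerance = 1e-12)

  # row permutation leaves the score profile unchanged
  ra3 <- ra2; ra3$member_ids <- rev(ra2$member_ids)
  expect_equal(find_discriminative_window(ra3, 70)$profile, w2$profile)
})

test_that("window scan matches the oracle on random gapped alignments", {
  set.seed(62)
  for (k in 1:5) {
    rows <- replicate(4, paste(sample(c("A", "C", "G", "T", "-"), 120, TRUE,
                                      prob = c(rep(0.23, 4), 0.08)),
                               collapse = ""))
    names(rows) <- sprintf("r%d", 1:4)
    ra <- structure(list(region = "five_prime",
                         msa = msa(c("REF", names(rows)),
                                   c(paste(rep("A", 120), collapse = ""), rows),
                                   "nt"),
                         member_ids = names(rows), reference_id = "REF",
                         column_map = seq_len(120)),
                    class = "region_alignment")
    w <- find_discriminative_window(ra, 30)
    want <- oracle_window(unname(rows), 30)
    expect_equal(w$start_col, want$start_col)
    expect_equal(w$mean_pairwise_distance, want$score, tolerance = 1e-12)
  }
})

test_that("window slices are literal alignment columns, gap-dominated members excluded", {
  rows <- c(m1 = strrep("ACGTACG", 10),         # 70 columns, gap-free
            m2 = paste0(strrep("-", 40), strrep("A", 30)))
  ra <- structure(list(region = "five_prime",
                       msa = msa(c("REF", names(rows)),
                                 c(strrep("G", 70), rows), "nt"),
                       member_ids = names(rows), reference_id = "REF",
                       column_map = seq_len(70)),
                  class = "region_alignment")
  w <- structure(list(start_col = 0L, width = 70L, mean_pairwise_distance = 0.5),
                 class = "window_score")
  expect_warning(mers <- extract_70mers(ra, w), "m2")
  expect_equal(names(mers), "m1")
  expect_equal(unname(nchar(mers)), 70L)
  expect_equal(unname(mers), rows[["m1"]])
})

test_that("archetype clustering replays the greedy rule on aligned slices", {
  expect_length(cluster_archetypes(c(a = strrep("A", 70), b = strrep("A", 70))),
                1L)
  set.seed(63)
  A <- random_dna(70)
  B <- mutate_k(A, 7)    # identity 0.90 to A
  C <- mutate_k(A, 14)   # identity 0.80 to A (and <=0.87 to B)
  stopifnot(mean(strsplit(B, "")[[1]] == strsplit(C, "")[[1]]) < 0.87)
  arch <- cluster_archetypes(c(a = A, b = B, c = C), 0.87)
  expect_equal(lapply(arch, `[[`, "member_ids"), list(c("a", "b"), "c"))
  expect_equal(arch[[1]]$representative, A)

  # 10 mutants of a founder at <= 8 of 70 positions all join it
  mut <- vapply(1:10, function(i) mutate_k(A, sample(0:8, 1)), character(1))
  names(mut) <- sprintf("z%02d", 1:10)
  arch2 <- cluster_archetypes(c(c(a0 = A), mut), 0.87)
  expect_length(arch2, 1L)
  expect_equal(arch2[[1]]$n_seqs, 11L)
  expect_error(cluster_archetypes(c(a = "ACGT", b = "ACG")), "same length")
})

test_that("archetype partition is exhaustive and count is monotone in the threshold", {
  set.seed(64)
  mers <- vapply(1:20, function(i) random_dna(70), character(1))
  base <- random_dna(70)
  mers <- c(mers, vapply(1:10, function(i) mutate_k(base, sample(1:20, 1)),
                         character(1)))
  names(mers) <- sprintf("s%02d", seq_along(mers))
  counts <- vapply(c(0.5, 0.7, 0.87, 0.95, 1.0), function(th) {
    arch <- cluster_archetypes(mers, th)
    members <- unlist(lapply(arch, `[[`, "member_ids"))
    expect_setequal(members, names(mers))
    expect_equal(anyDuplicated(members), 0L)
    length(arch)
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("neighbor joining recovers a known split and emits valid Newick", {
  set.seed(65)
  anc <- random_dna(70)
  left <- mutate_k(anc, 20)
  right <- mutate_k(anc, 20)
  tips <- list(A = mutate_k(left, 3), B = mutate_k(left, 3),
               C = mutate_k(right, 3), D = mutate_k(right, 3))
  arch <- Map(function(id, s) make_arch(id, representative = s),
              names(tips), tips)
  nwk <- nj_tree(unname(arch))
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, names(tips))
  expect_true(all(phy$edge.length >= 0))
  expected <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(phy), ape::unroot(expected))), 0)
  expect_error(nj_tree(unname(arch)[1:2]), ">= 3")
})
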