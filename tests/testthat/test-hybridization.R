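test_that("a perfect complement gives the full-length hand-summed duplex", {
  p <- energy_params()
  h <- hybridize("GGGGGGGG", "CCCCCCCC", params = p)
  expect_equal(nrow(h), 1)
  expect_equal(h$n_pairs, 8L)
  expect_equal(h$dG_hybrid, 7 * p$stack["GC", "GC"], tolerance = 1e-12)
  expect_equal(h$dG_hybrid,
               duplex_energy("GGGGGGGG", "CCCCCCCC", h$pairs[[1]], p),
               tolerance = 1e-12)
})

test_that("unpairable inputs give an empty hybrid list, not an error", {
  h <- hybridize(strrep("A", 10), strrep("A", 20))
  expect_equal(nrow(h), 0)
  expect_error(hybridize("GGGG", "CCCC", window = c(3, 2)), "window")
})

test_that("duplex DP equals brute-force enumeration of monotone pairings", {
  p <- energy_params()
  fixtures <- list(
    c(7, 9, 201), c(7, 9, 202), c(6, 12, 203), c(8, 10, 204), c(7, 9, 205)
  )
  for (fx in fixtures) {
    s <- random_rna(fx[1], seed = fx[3])
    m <- random_rna(fx[2], seed = fx[3] + 5000)
    or <- oracle_best_duplex(s, m, p, max_loop = 15)
    h <- hybridize(s, m, params = p, max_loop = 15, n_suboptimal = 0)
    if (or$energy < 0) {
      expect_equal(h$dG_hybrid[1], or$energy, tolerance = 1e-9)
    } else {
      expect_equal(nrow(h), 0)
    }
  }
})

test_that("suboptimals are ordered and non-redundant; MFE is the minimum", {
  p <- energy_params()
  # two separated complementary patches on the mRNA
  s <- "GGGGGGGG"
  m <- paste0("CCCCCCCC", strrep("A", 20), "CCCCCCC")
  h <- hybridize(s, m, params = p, n_suboptimal = 5)
  expect_gte(nrow(h), 2)
  expect_true(all(diff(h$dG_hybrid) >= -1e-12))
  expect_true(all(h$dG_hybrid >= h$dG_hybrid[1]))
  # reported mRNA intervals overlap pairwise by < 50%
  if (nrow(h) > 1) {
    for (a in 1:(nrow(h) - 1)) for (b in (a + 1):nrow(h)) {
      ov <- max(0, min(h$mrna_end[a], h$mrna_end[b]) -
                   max(h$mrna_start[a], h$mrna_start[b]) + 1)
      shorter <- min(h$mrna_end[a] - h$mrna_start[a],
                     h$mrna_end[b] - h$mrna_start[b]) + 1
      expect_lt(ov / shorter, 0.5)
    }
  }
})

test_that("unpairable mRNA flanks do not shift the predicted duplex energy", {
  p <- energy_params()
  s <- "GGAGGAGG"
  core <- "CCUCCUCC"
  h0 <- hybridize(s, core, params = p)
  h1 <- hybridize(s, paste0(strrep("A", 11), core, strrep("A", 7)), params = p)
  expect_equal(h1$dG_hybrid[1], h0$dG_hybrid[1], tolerance = 1e-12)
  expect_equal(h1$mrna_start[1], h0$mrna_start[1] + 11L)
  expect_equal(h1$n_pairs[1], h0$n_pairs[1])
})

test_that("swapping the strands mirrors the duplex at equal energy", {
  p <- energy_params()
  a <- "GGCGCG"
  b <- "CGCGCC"
  ha <- hybridize(a, b, params = p, n_suboptimal = 0)
  hb <- hybridize(b, a, params = p, n_suboptimal = 0)
  expect_equal(ha$dG_hybrid[1], hb$dG_hybrid[1], tolerance = 1e-9)
  expect_equal(ha$pairs[[1]][, 1], rev(hb$pairs[[1]][, 2]))
  expect_equal(ha$pairs[[1]][, 2], rev(hb$pairs[[1]][, 1]))
})

test_that("the seed-overlap filter discards hybrids off the seed region", {
  p <- energy_params()
  s <- paste0("GGGGGGGG", strrep("A", 20), "GAGAGAGA")
  m <- "CCCCCCCC"  # complements only positions 1-8, far from the seed
  h <- hybridize(s, m, params = p, seed_region = c(29, 36),
                 min_overlap_with_seed = 1)
  expect_equal(nrow(h), 0)
  h2 <- hybridize(s, m, params = p, seed_region = c(1, 8),
                  min_overlap_with_seed = 1)
  expect_gte(nrow(h2), 1)
})

test_that("start-codon-relative duplex coordinates follow the anchor", {
  p <- energy_params()
  m <- rna_sequence(paste0(strrep("A", 12), "CCCCCCCC", "AUGAAA"),
                    start_codon_offset = 20)
  h <- hybridize("GGGGGGGG", m, params = p)
  expect_equal(h$mrna_start[1], 13L)
  expect_equal(h$mrna_start_rel[1], -8L)   # 13 is 8 upstream of the AUG
  expect_equal(h$mrna_end_rel[1], -1L)
})

test_that("compensatory mutations are recognized; one-sided swaps are not", {
  p <- energy_params()
  srna_wt <- "AAGGGGGGGGAA"
  mrna_wt <- paste0(strrep("A", 6), "CCCCCCCC", strrep("A", 6))
  site <- c(7, 14)
  # no mutation: all four combinations identical
  same <- evaluate_mutant_pairing(srna_wt, srna_wt, mrna_wt, mrna_wt, site, p)
  expect_equal(length(unique(round(same$table$dG_hybrid, 9))), 1)
  # swap four central positions on both strands (G<->C, so no wobble rescue
  # of the mismatched combinations), restoring complementarity in mut:mut
  srna_mut <- "AAGGCCCCGGAA"
  mrna_mut <- paste0(strrep("A", 6), "CCGGGGCC", strrep("A", 6))
  res <- evaluate_mutant_pairing(srna_wt, srna_mut, mrna_wt, mrna_mut, site, p)
  expect_true(res$compensatory)
  g <- function(s, m) res$table$dG_hybrid[res$table$srna == s &
                                            res$table$mrna == m]
  # the mismatched combinations lose at least the three broken GC stacks
  expect_gte(g("wt", "mut") - g("wt", "wt"), 3 * abs(p$stack["GC", "GC"]) - 1)
  one_sided <- evaluate_mutant_pairing(srna_wt, srna_mut, mrna_wt, mrna_wt,
                                       site, p)
  expect_false(one_sided$compensatory)
  expect_error(
    evaluate_mutant_pairing(srna_wt, "AAGG", mrna_wt, mrna_wt, site, p),
    "unsupported")
})
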