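test_that("partition function: unpairable chain, capacity, 3' extension", {
  expect_equal(partition_function("AAAA")$Z, 1)
  expect_equal(partition_function("AAAA")$ensemble_free_energy, 0)
  expect_error(partition_function(strrep("A", 30), max_len = 20), "capacity")
  z1 <- partition_function("GGGAAACCCC")$Z
  z2 <- partition_function("GGGAAACCCCAAA")$Z  # A-run unpairable: no U present
  expect_equal(z1, z2, tolerance = 1e-12)
  expect_gt(z1, 1)
})

test_that("partition function matches exhaustive enumeration on short RNAs", {
  p <- energy_params()
  for (sd in 1:5) {
    seq_str <- random_rna(15, seed = 500 + sd)
    or <- oracle_partition(strsplit(seq_str, "")[[1]], p)
    expect_equal(partition_function(seq_str, p)$Z, or$Z,
                 tolerance = 1e-6)
  }
})

test_that("exact pair probabilities match enumeration up to 18 nt", {
  p <- energy_params()
  for (spec in list(c(12, 11), c(15, 21), c(18, 31), c(16, 41))) {
    seq_str <- random_rna(spec[1], seed = spec[2])
    or <- oracle_partition(strsplit(seq_str, "")[[1]], p)
    P <- pair_probabilities(seq_str, p)
    expect_equal(P, or$pair_prob, tolerance = 1e-6)
  }
})

test_that("sampling is seed-deterministic and respects trivial cases", {
  p <- energy_params()
  e1 <- sample_structures("GGGAAAUCCC", p, n = 5, seed = 7)
  e2 <- sample_structures("GGGAAAUCCC", p, n = 5, seed = 7)
  expect_identical(lapply(e1$structures, function(s) s$pairs),
                   lapply(e2$structures, function(s) s$pairs))
  e3 <- sample_structures("GGGAAAUCCC", p, n = 5, seed = 8)
  expect_false(identical(c(e1$seed, lapply(e1$structures, function(s) s$pairs)),
                         c(e3$seed, lapply(e3$structures, function(s) s$pairs))))
  ea <- sample_structures("AAAA", p, n = 10, seed = 1)
  expect_true(all(vapply(ea$structures, function(s) nrow(s$pairs) == 0,
                         logical(1))))
  expect_error(sample_structures("AAAA", p, n = 0, seed = 1), "positive")
  expect_error(sample_structures("AAAA", p, n = 5), "seed")
})

test_that("sampled structure frequencies converge to Boltzmann probabilities", {
  p <- energy_params()
  seq_str <- random_rna(12, seed = 77)
  chars <- strsplit(seq_str, "")[[1]]
  or <- oracle_partition(chars, p)
  n <- 10000
  ens <- sample_structures(seq_str, p, n = n, seed = 13)
  key <- function(pairs) {
    if (nrow(pairs) == 0) "open"
    else paste(pairs[, 1], pairs[, 2], collapse = ";")
  }
  emp <- table(vapply(ens$structures, function(s) key(s$pairs), character(1)))
  for (k in seq_along(or$structures)) {
    prob <- or$weights[k] / or$Z
    if (prob < 0.01) next
    obs <- emp[key(or$structures[[k]])]
    obs <- if (is.na(obs)) 0 else as.numeric(obs)
    se <- sqrt(prob * (1 - prob) / n)
    expect_lt(abs(obs / n - prob), 3 * se + 1e-3)
  }
})

test_that("single-strandedness profiles: exact, empirical, and agreement", {
  p <- energy_params()
  expect_equal(ss_profile(sample_structures("AAAA", p, n = 5, seed = 1)),
               rep(1, 4))
  forced <- manual_ensemble("GGGGAAAACCCC",
                            list(parse_dotbracket("((((....))))", "GGGGAAAACCCC")))
  expect_equal(ss_profile(forced), c(rep(0, 4), rep(1, 4), rep(0, 4)))
  seq_str <- random_rna(15, seed = 99)
  exact <- ss_profile(pair_probabilities(seq_str, p))
  emp <- ss_profile(sample_structures(seq_str, p, n = 10000, seed = 3))
  expect_lt(max(abs(exact - emp)), 0.03)
})

test_that("empirical pair probabilities approach exact ones as n grows", {
  p <- energy_params()
  seq_str <- random_rna(15, seed = 321)
  exact <- pair_probabilities(seq_str, p)
  err <- vapply(c(100, 1000, 10000), function(n) {
    max(abs(sample_structures(seq_str, p, n = n, seed = 5)$pair_prob - exact))
  }, numeric(1))
  expect_lt(err[3], err[1] + 0.02)  # monotone in expectation, with slack
  expect_lt(err[3], 0.03)
})

test_that("centroid follows the majority rule and stays within sampled pairs", {
  s <- "GGGGAAAACCCC"
  hp <- parse_dotbracket("((((....))))", s)
  open <- secondary_structure(NULL, s)
  ens <- manual_ensemble(s, list(open, open, hp))
  expect_equal(nrow(centroid_structure(ens)$pairs), 0)  # majority open
  ens2 <- manual_ensemble(s, list(hp, hp, open))
  expect_equal(centroid_structure(ens2)$pairs, hp$pairs)
  # centroid pairs are a subset of the union of sampled pairs
  p <- energy_params()
  ens3 <- sample_structures(random_rna(25, seed = 8), p, n = 200, seed = 9)
  cen <- centroid_structure(ens3, params = p)
  seen <- unique(do.call(rbind, lapply(ens3$structures, function(x) x$pairs)))
  if (nrow(cen$pairs) > 0) {
    keys <- paste(cen$pairs[, 1], cen$pairs[, 2])
    expect_true(all(keys %in% paste(seen[, 1], seen[, 2])))
  }
  expect_equal(centroid_structure(ens3, params = p)$pairs,
               centroid_structure(ens3, params = p)$pairs)
})

test_that("clustering recovers separated populations and degenerate cases", {
  s <- paste0("GGGGAAAACCCC", "AA", "GGGGAAAACCCC")
  hp1 <- parse_dotbracket("((((....))))..............", s)
  hp2 <- parse_dotbracket("..............((((....))))", s)
  ens <- manual_ensemble(s, c(rep(list(hp1), 6), rep(list(hp2), 4)))
  cl <- cluster_ensemble(ens, max_clusters = 4)
  expect_length(cl, 2)
  expect_equal(sort(cl[[1]]$members), 1:6)   # largest first
  expect_equal(sort(cl[[2]]$members), 7:10)
  expect_equal(cl[[1]]$centroid$pairs, hp1$pairs)
  expect_equal(cl[[2]]$centroid$pairs, hp2$pairs)
  same <- manual_ensemble(s, rep(list(hp1), 8))
  expect_length(cluster_ensemble(same, max_clusters = 3), 1)
  expect_error(cluster_ensemble(ens, max_clusters = 50), "max_clusters")
})

test_that("a dominant structure yields a dominant cluster", {
  p <- energy_params()
  # strong single hairpin: the MFE structure dominates the ensemble
  s <- "AAGGGGGCAAAAGCCCCCAA"
  ens <- sample_structures(s, p, n = 60, seed = 11)
  cl <- cluster_ensemble(ens, max_clusters = 4, params = p)
  expect_gt(length(cl[[1]]$members), 30)
})

test_that("ensemble dump/load and pair-probability TSV round trip", {
  p <- energy_params()
  ens <- sample_structures("GGGGAAAACCCC", p, n = 20, seed = 2)
  f <- withr::local_tempfile(fileext = ".dbn")
  write_ensemble(ens, f)
  back <- read_ensemble(f)
  expect_equal(back$n, ens$n)
  expect_equal(back$ensemble_energies, ens$ensemble_energies, tolerance = 1e-4)
  expect_equal(back$pair_prob, ens$pair_prob)
  g <- withr::local_tempfile(fileext = ".tsv")
  write_pair_prob(ens$pair_prob, g)
  m <- as.matrix(read.delim(g, header = FALSE))
  expect_equal(unname(m), unname(ens$pair_prob), tolerance = 1e-6)
})
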