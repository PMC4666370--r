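test_that("stack table is complete and strand-exchange symmetric", {
  p <- energy_params()
  expect_true(all(is.finite(p$stack)))
  rev_idx <- c(2, 1, 4, 3, 6, 5)  # AU<->UA, GC<->CG, GU<->UG
  for (o in 1:6) for (i in 1:6)
    expect_equal(p$stack[o, i], p$stack[rev_idx[i], rev_idx[o]])
})

test_that("parameter plain-text round trip preserves every table", {
  p <- energy_params(duplex_init = 1.25)
  f <- withr::local_tempfile(fileext = ".txt")
  write_energy_params(p, f)
  q <- read_energy_params(f)
  expect_equal(q$stack, p$stack, tolerance = 1e-9)
  expect_equal(q$hairpin, p$hairpin, tolerance = 1e-9)
  expect_equal(q$bulge, p$bulge, tolerance = 1e-9)
  expect_equal(q$internal, p$internal, tolerance = 1e-9)
  expect_equal(q$duplex_init, 1.25)
  expect_equal(q$max_loop, p$max_loop)
})

test_that("sequence validation converts T, rejects bad residues, checks anchor", {
  expect_message(s <- rna_sequence("ACGT"), "T converted to U")
  expect_equal(s$seq, "ACGU")
  expect_error(rna_sequence("ACGX"), "invalid residue")
  expect_error(rna_sequence(""), "nzchar")
  expect_error(rna_sequence("ACGU", start_codon_offset = 7), "outside")
  m <- rna_sequence("CCCCCAUGGC", start_codon_offset = 5)
  expect_equal(codon_relative(m, c(4, 5, 6, 8)), c(-2L, -1L, 1L, 3L))
  expect_true(all(codon_relative(m, 1:10) != 0))
})

test_that("FASTA round trip preserves ids and residues", {
  skip_if_not_installed("Biostrings")
  f <- withr::local_tempfile(fileext = ".fa")
  a <- rna_sequence("GGGAAAUCCC", id = "hp")
  b <- rna_sequence("ACACAC", id = "lin")
  write_rna_fasta(list(a, b), f)
  back <- read_rna_fasta(f)
  expect_equal(names(back), c("hp", "lin"))
  expect_equal(back$hp$seq, a$seq)
  expect_equal(back$lin$seq, b$seq)
})

test_that("dot-bracket parsing matches brackets and flags structural errors", {
  expect_equal(nrow(parse_dotbracket("..........", "AAAAAAAAAA")$pairs), 0)
  st <- parse_dotbracket("(((....)))", "GGGAAAUCCC")
  expect_equal(unname(st$pairs), cbind(1:3, 10:8))
  expect_error(parse_dotbracket("(()", "AAA"), "unbalanced")
  expect_error(parse_dotbracket("())", "AAA"), "unbalanced")
  expect_error(parse_dotbracket("(....)", "AAAAAC"), "disallowed pair")
  expect_error(parse_dotbracket("((..))", "GGAACC"), "hairpin loop")
  expect_error(secondary_structure(rbind(c(1, 7), c(3, 9)), "GGGAAACCCC"),
               "crossing")
  expect_error(secondary_structure(rbind(c(1, 7), c(1, 9)), "GAAAAACCCC"),
               "more than one pair")
})

test_that("CT round trip reproduces sequence and pairing", {
  s <- rna_sequence("GGGAAAUCCC", id = "hp")
  st <- parse_dotbracket("(((....)))", s)
  f <- withr::local_tempfile(fileext = ".ct")
  write_ct(st, s, f, energy = -1.5)
  back <- read_ct(f)
  expect_equal(back$seq$seq, s$seq)
  expect_equal(back$structure$pairs, st$pairs)
})

test_that("structure energy: open chain, hand-summed hairpin, additivity", {
  p <- energy_params()
  s <- rna_sequence("GGGAAAUCCC")
  expect_identical(structure_energy(s, secondary_structure(NULL, s), p), 0)
  st <- parse_dotbracket("(((....)))", s)
  # hand sum from the shipped table: two GC-on-GC stacks + 4-nt hairpin loop,
  # no terminal penalty for GC closing pairs
  hand <- 2 * p$stack["GC", "GC"] + p$hairpin[4]
  expect_equal(structure_energy(s, st, p), hand, tolerance = 1e-12)
  # additivity over independent exterior substructures
  two <- rna_sequence(strrep("GGGAAAUCCC", 2))
  st2 <- parse_dotbracket(strrep("(((....)))", 2), two)
  expect_equal(structure_energy(two, st2, p), 2 * hand, tolerance = 1e-12)
})

test_that("structure energy is a set function and locally decomposable", {
  p <- energy_params()
  s <- rna_sequence(paste0("GGGAAAUCCC", "A", "GGGAAAUCCC", "A"))
  st <- parse_dotbracket("(((....))).(((....))).", s)
  shuffled <- secondary_structure(st$pairs[c(4, 1, 6, 2, 5, 3), ], s)
  expect_equal(structure_energy(s, st, p), structure_energy(s, shuffled, p))
  # removing one helix leaves the other helix's contribution unchanged
  one <- parse_dotbracket("(((....)))............", s)
  other <- parse_dotbracket("...........(((....))).", s)
  expect_equal(structure_energy(s, st, p),
               structure_energy(s, one, p) + structure_energy(s, other, p))
})

test_that("structure energy agrees with the term-enumeration oracle", {
  p <- energy_params()
  checked <- 0
  for (sd in 1:8) {
    seq_str <- random_rna(28, seed = 1000 + sd)
    s <- rna_sequence(seq_str)
    ens <- sample_structures(s, p, n = 25, seed = sd)
    for (st in ens$structures) {
      expect_equal(structure_energy(s, st, p),
                   oracle_structure_energy(s$residues, st$pairs, p),
                   tolerance = 1e-9)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 200)
})

test_that("duplex energy: init-only, hand-summed perfect duplex, 1x1 loop", {
  p <- energy_params(duplex_init = 2.0)
  none <- duplex_energy("GGGG", "CCCC", matrix(integer(0), ncol = 2), p)
  expect_equal(none, 2.0)
  # fully complementary 8-mer: 7 stacks + init + terminal penalties
  s <- "GGGGGGGG"; m <- "CCCCCCCC"
  pairs <- cbind(1:8, 8:1)
  hand <- 2.0 + 7 * p$stack["GC", "GC"]  # GC ends: no terminal AU penalty
  expect_equal(duplex_energy(s, m, pairs, p), hand, tolerance = 1e-12)
  # knock out the middle pair on both strands -> 1x1 interior loop
  loop_pairs <- pairs[-4, ]
  hand_loop <- 2.0 + 5 * p$stack["GC", "GC"] + p$internal[2]
  expect_equal(duplex_energy(s, m, loop_pairs, p), hand_loop, tolerance = 1e-12)
  expect_error(duplex_energy(s, m, cbind(c(1, 2), c(2, 5)), p), "antiparallel")
  expect_error(duplex_energy("AAAA", "GGGG", cbind(1, 4), p), "disallowed")
})
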