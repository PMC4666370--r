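test_that("local alteration removes exactly the footprint-touching pairs", {
  s <- paste0("GGGGAAAACCCC", "AA", "GGGGAAAACCCC")
  st <- parse_dotbracket("((((....))))..((((....))))", s)
  # footprint away from all pairs: identical structure
  expect_equal(locally_alter(st, 13:14)$pairs, st$pairs)
  # footprint covering the first hairpin entirely: it vanishes, second stays
  alt <- locally_alter(st, 1:12)
  expect_equal(nrow(alt$pairs), 4)
  expect_true(all(alt$pairs[, 1] >= 15))
  # half-covered helix: only covered pairs removed, isolated pairs survive
  half <- locally_alter(st, 1:2)
  expect_equal(nrow(half$pairs), 6)
  expect_false(any(half$pairs[, 1] %in% 1:2))
  expect_error(locally_alter(st, 99), "outside")
})

test_that("disruption energy: unpairable chain, hand-summed hairpin, off-site", {
  p <- energy_params()
  ens0 <- sample_structures(strrep("A", 12), p, n = 20, seed = 1)
  d0 <- disruption_energy(ens0, 3:6, p)
  expect_equal(d0$dG_disruption, 0)
  expect_equal(d0$n_altered, 0L)
  # single-structure ensemble whose hairpin is fully removed: the disruption
  # equals the hand-summed hairpin stability (before - 0)
  s <- "GGGGAAAACCCC"
  hp <- parse_dotbracket("((((....))))", s)
  ens1 <- manual_ensemble(s, list(hp), p)
  d1 <- disruption_energy(ens1, 1:12, p)
  hand <- 3 * p$stack["GC", "GC"] + p$hairpin[4]
  expect_equal(d1$dG_before, hand, tolerance = 1e-12)
  expect_equal(d1$dG_after, 0)
  expect_equal(d1$dG_disruption, hand, tolerance = 1e-12)
  # footprint outside all sampled pairs: before == after
  d2 <- disruption_energy(ens1, 5:8, p)  # loop interior nucleotides only
  expect_equal(d2$dG_before, d2$dG_after)
  expect_error(disruption_energy(structure(list(n = 0), class = "structure_ensemble"),
                                 1, p))
})

test_that("total energy follows the formula with a strict favorability rule", {
  r1 <- total_energy(-20, 0, 0)
  expect_equal(r1$dG_total, -15.9)
  expect_true(r1$favorable)
  r2 <- total_energy(-10, -4, -2)
  expect_equal(r2$dG_total, 0.1, tolerance = 1e-12)
  expect_false(r2$favorable)
  r3 <- total_energy(-4.1, 0, 0)
  expect_equal(r3$dG_total, 0)
  expect_false(r3$favorable)  # boundary: dG_total == 0 is not favorable
})

test_that("every emitted record satisfies the total-energy identity", {
  sc <- make_sequence_scenario(seed = 5)
  pred <- predict_sites(sc$srna, sc$mrna, seed = 11, n = 150)
  sites <- tidy(pred)
  expect_gt(nrow(sites), 0)
  expect_lt(max(abs(sites$dG_total -
                      (sites$dG_initiation + sites$dG_hybrid -
                         (sites$dG_T_disruption + sites$dG_S_disruption)))),
            1e-9)
  expect_equal(sites$favorable, sites$dG_total < 0)
  # dG_hybrid of each site equals duplex_energy recomputed from its pairs
  for (k in seq_len(nrow(sites)))
    expect_equal(sites$dG_hybrid[k],
                 duplex_energy(sc$srna, sc$mrna, sites$pairs[[k]]),
                 tolerance = 1e-9)
})

test_that("prediction is deterministic given the master seed", {
  sc <- make_sequence_scenario(seed = 6)
  p1 <- predict_sites(sc$srna, sc$mrna, seed = 21, n = 100)
  p2 <- predict_sites(sc$srna, sc$mrna, seed = 21, n = 100)
  expect_identical(tidy(p1), tidy(p2))
  expect_identical(glance(p1), glance(p2))
  p3 <- predict_sites(sc$srna, sc$mrna, seed = 22, n = 100)
  expect_false(identical(p1$seed_srna, p3$seed_srna))
})

test_that("occluding the planted site raises dG_total for the same duplex", {
  open <- make_sequence_scenario(seed = 9)
  shut <- make_sequence_scenario(seed = 9, site_context = "hairpin_occluded")
  po <- predict_sites(open$srna, open$mrna, seed = 33, n = 400)
  ps <- predict_sites(shut$srna, shut$mrna, seed = 33, n = 400)
  to <- tidy(po); ts <- tidy(ps)
  ko <- which(to$mrna_start == open$site_start)[1]
  ks <- which(ts$mrna_start == shut$site_start)[1]
  expect_false(is.na(ko))
  expect_false(is.na(ks))
  expect_equal(to$dG_hybrid[ko], ts$dG_hybrid[ks], tolerance = 1e-9)
  # occlusion adds (at least) the stem stability minus the loop penalty; the
  # verdict itself need not flip when the occluder is the site's own
  # complement, but the total must be strictly worse
  expect_gt(ts$dG_total[ks], to$dG_total[ko] + 10)
  expect_true(to$favorable[ko])
})

test_that("altered-structure energies are re-evaluated from scratch", {
  p <- energy_params()
  sc <- make_sequence_scenario(seed = 2)
  ens <- sample_structures(sc$mrna, p, n = 50, seed = 17)
  foot <- sc$site_start:sc$site_end
  dis <- disruption_energy(ens, foot, p)
  after <- vapply(ens$structures, function(st) {
    structure_energy(ens$seq, locally_alter(st, foot), p)
  }, numeric(1))
  expect_equal(dis$dG_after, mean(after), tolerance = 1e-12)
})

test_that("the JSON site report round-trips the energy terms", {
  sc <- make_sequence_scenario(seed = 3)
  pred <- predict_sites(sc$srna, sc$mrna, seed = 8, n = 100)
  f <- withr::local_tempfile(fileext = ".json")
  write_sites_json(pred, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$seed, 8)
  expect_equal(nrow(back$sites), nrow(tidy(pred)))
  expect_equal(back$sites$dG_total, tidy(pred)$dG_total, tolerance = 1e-9)
})
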