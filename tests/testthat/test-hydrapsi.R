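test_that("rolling background is a clipped windowed mean with zero guards", {
  expect_equal(rolling_background(rep(7, 30))[10:20], rep(7, 11))
  expect_true(all(is.na(rolling_background(rep(0, 30)))))
  # hand mean of the 10-wide window around a protected position
  v <- c(10, 10, 10, 10, 10, 0, 10, 10, 10, 10)
  expect_equal(rolling_background(v, 10)[6], 9.0)
  # leave-one-out mean excludes the queried position
  expect_equal(rolling_background(v, 10, exclude_self = TRUE)[6], 10.0)
  # end windows shrink but stay defined at >= window/2 positions ...
  expect_false(is.na(rolling_background(rep(5, 30), 10)[1]))
  # ... and fall undefined below window/2 (molecule shorter than half-window)
  expect_true(all(is.na(rolling_background(rep(5, 4), 10))))
  expect_error(rolling_background(rep(5, 30), 1), "window")
})

test_that("even-window centering does not matter on constant backgrounds", {
  v <- rep(4, 40)
  for (w in c(8L, 9L, 10L, 11L))
    expect_equal(rolling_background(v, w)[10:30], rep(4, 21))
})

test_that("NormUcount is the background-normalised 5'-end count", {
  counts <- c(rep(7, 12), 0, 49)
  bg <- c(rep(7, 12), 5, 10)
  expect_equal(norm_ucount(counts, bg, 1L), 1.0)
  expect_equal(norm_ucount(counts, bg, 13L), 0.0)
  expect_equal(norm_ucount(counts, bg, 14L), 4.9)
  expect_error(norm_ucount(counts, bg, 99L), "range")
})

test_that("U profiles keep molecule coordinates and drop other residues", {
  ref <- rna_reference("m", "GGUAGUCCUG")
  p <- end_count_profile("m", rep(3L, 10), integer(10), "r1", "HydraPsi")
  up <- u_profile(u_protection_track(p, window = 4), ref)
  expect_equal(up$position, c(3L, 6L, 9L))      # no re-indexing
  allg <- rna_reference("g", strrep("G", 10))
  pg <- end_count_profile("g", rep(3L, 10), integer(10), "r1", "HydraPsi")
  expect_equal(nrow(u_profile(u_protection_track(pg, window = 4), allg)), 0L)
})

test_that("psiscore is 1 - NormUcount, unclipped below", {
  up <- data.frame(position = c(5L, 9L, 12L), normu = c(1.0, 0.0, 4.9))
  expect_equal(psiscore(up, 5L), 0.0)
  expect_equal(psiscore(up, 9L), 1.0)
  expect_equal(psiscore(up, 12L), -3.9)  # hyper-reactive residue
  expect_error(psiscore(up, 6L), "not in U profile")
})

test_that("scoremean is the RMS-style local score on the U profile", {
  up <- data.frame(position = seq(2L, 40L, by = 3L), normu = 1.0)
  mid <- 7L
  expect_equal(scoremean(up, up$position[mid]), 0)
  up2 <- up; up2$normu[mid] <- 0
  expect_equal(scoremean(up2, up$position[mid]), 1)
  up3 <- up; up3$normu[mid] <- 0.4
  expect_equal(scoremean(up3, up$position[mid]), 0.6)
  expect_true(is.na(scoremean(up, up$position[2])))  # < 3 U neighbours left
})

test_that("PsiScore recovers the truth grid on a U-homogeneous substrate", {
  pu <- make_polyU(120L)
  grid <- c(0, 0.3, 0.6, 0.9)
  means <- vapply(grid, function(f)
    mean(mc_psiscore(pu, 60L, f, depth = 2000, nsim = 50L, seed = 50L)),
    numeric(1))
  expect_true(all(abs(means - grid) < 0.04))
  expect_true(all(diff(means) >= 0))
})

test_that("null simulations stay centred near zero PsiScore", {
  pu <- make_polyU(120L)
  s <- mc_psiscore(pu, 60L, 0, depth = 1000, nsim = 200L, seed = 70L)
  expect_gt(mean(s), -0.03)
  expect_lt(mean(s), 0.03)
})

test_that("PsiScore is invariant under uniform count scaling", {
  pu <- make_polyU(60L)
  truth <- truth_profile("polyU", 30L, 0.5, "Psi", pu)
  p <- simulate_hydrapsi(pu, truth, protocol_params("HydraPsi", depth = 500),
                         n_replicates = 1L, seed = 31L)[[1]]
  p2 <- end_count_profile(p$molecule, p$counts5 * 9L, p$counts3, "r1",
                          "HydraPsi")
  s1 <- psiscore(u_profile(u_protection_track(p), pu), 30L)
  s2 <- psiscore(u_profile(u_protection_track(p2), pu), 30L)
  expect_equal(s1, s2)
})

test_that("the 5'-end attribution offset round-trips simulator and scorer", {
  pu <- make_polyU(80L)
  truth <- truth_profile("polyU", 40L, 0.8, "Psi", pu)
  p0 <- simulate_hydrapsi(pu, truth, protocol_params("HydraPsi", depth = 1000,
                                                     end_offset = 0L),
                          n_replicates = 1L, seed = 17L)[[1]]
  p1 <- simulate_hydrapsi(pu, truth, protocol_params("HydraPsi", depth = 1000,
                                                     end_offset = 1L),
                          n_replicates = 1L, seed = 17L)[[1]]
  s0 <- psiscore(u_profile(u_protection_track(p0, end_offset = 0L), pu), 40L)
  s1 <- psiscore(u_profile(u_protection_track(p1, end_offset = 1L), pu), 40L)
  expect_equal(s0, s1)
})

test_that("catalog Psi scoring yields records per site and replicate", {
  pu <- make_polyU(150L)
  pos <- c(40L, 70L, 100L, 130L)
  refs <- list(polyU = pu)
  catalog <- site_catalog(data.frame(molecule = "polyU", position = pos,
                                     residue = "U", mod_type = "Psi"), refs)
  truth <- truth_profile("polyU", pos, c(0.9, 0.3, 0, 0.6), "Psi", pu)
  sims <- simulate_hydrapsi(pu, truth, protocol_params("HydraPsi",
                                                       depth = 2000),
                            n_replicates = 3L, seed = 23L)
  tab <- score_catalog_psi(sims, catalog, refs)
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$score <= 1))
  expect_true(all(c("score", "scoremean") %in% names(tab)))
  # two replicates are the accepted minimum for downstream pairing
  tab2 <- score_catalog_psi(sims[1:2], catalog, refs)
  expect_equal(nrow(tab2), 8L)
})
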