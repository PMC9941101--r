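test_that("simulation is deterministic and replicate streams are stable", {
  ref <- make_ref(L = 80L)
  truth <- truth_profile(ref$name, 40L, 0.5, "Nm", ref)
  a <- simulate_rms(ref, truth, protocol_params("RMS", depth = 500),
                    n_replicates = 3L, seed = 11L)
  b <- simulate_rms(ref, truth, protocol_params("RMS", depth = 500),
                    n_replicates = 3L, seed = 11L)
  expect_identical(lapply(a, `[[`, "counts5"), lapply(b, `[[`, "counts5"))
  # adding replicates never perturbs earlier ones
  c4 <- simulate_rms(ref, truth, protocol_params("RMS", depth = 500),
                     n_replicates = 4L, seed = 11L)
  expect_identical(c4[[2]]$counts3, a[[2]]$counts3)
  # different replicates use different streams
  expect_false(identical(a[[1]]$counts3, a[[2]]$counts3))
})

test_that("a fully methylated site gives exactly zero cleavage at its bond", {
  ref <- make_ref(L = 60L)
  i <- 30L
  truth <- truth_profile(ref$name, i, 1, "Nm", ref)
  sims <- simulate_rms(ref, truth, protocol_params("RMS", depth = 2000),
                       n_replicates = 5L, seed = 3L)
  for (p in sims) {
    expect_identical(p$counts3[i], 0L)
    expect_identical(p$counts5[i + 1L], 0L)
  }
})

test_that("Monte-Carlo cleavage ratio matches the closed-form intensity", {
  # brute-force oracle: at f = 0.5 the event rate at the modified bond is
  # half the flanking rate, so the mean-count ratio converges to 0.5
  ref <- make_ref(L = 41L)
  i <- 20L
  truth <- truth_profile(ref$name, i, 0.5, "Nm", ref)
  params <- protocol_params("RMS", depth = 1000)
  nrep <- 200L
  sims <- simulate_rms(ref, truth, params, n_replicates = nrep, seed = 5L)
  at_bond <- vapply(sims, function(p) p$counts3[i], integer(1))
  flank_idx <- c((i - 6L):(i - 1L), (i + 1L):(i + 6L))
  flanks <- vapply(sims, function(p) mean(p$counts3[flank_idx]), numeric(1))
  ratio <- mean(at_bond) / mean(flanks)
  se <- sd(at_bond / flanks) / sqrt(nrep)
  expect_lt(abs(ratio - 0.5), 3 * se + 1e-3)
})

test_that("expected cleavage is monotone non-increasing in the truth fraction", {
  ref <- make_ref(L = 41L)
  i <- 20L
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    truth <- truth_profile(ref$name, i, f, "Nm", ref)
    sims <- simulate_rms(ref, truth, protocol_params("RMS", depth = 1000),
                         n_replicates = 100L, seed = 7L)
    mean(vapply(sims, function(p) p$counts3[i], integer(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
})

test_that("hydrazine cleavage is U-specific with Psi protection", {
  ref <- make_ref(L = 100L, seed = 42L)
  is_u <- strsplit(ref$sequence, "")[[1]] == "U"
  u_pos <- which(is_u)
  truth0 <- truth_profile(ref$name, integer(0), numeric(0), "Psi", ref)
  params <- protocol_params("HydraPsi", depth = 1000, bg_rate = 0.01)
  sims <- simulate_hydrapsi(ref, truth0, params, n_replicates = 50L, seed = 2L)
  m5 <- rowMeans(vapply(sims, `[[`, numeric(100), "counts5"))
  expect_gt(mean(m5[u_pos]), 900)      # lambda = 1000 at unprotected U
  expect_lt(mean(m5[!is_u]), 30)       # lambda = 10 at non-U
  expect_true(all(vapply(sims, function(p) all(p$counts3 == 0L), logical(1))))
  # full protection: zero counts at the modified U
  truth1 <- truth_profile(ref$name, u_pos[3], 1, "Psi", ref)
  sims1 <- simulate_hydrapsi(ref, truth1, params, n_replicates = 5L, seed = 2L)
  expect_true(all(vapply(sims1, function(p) p$counts5[u_pos[3]] == 0L,
                         logical(1))))
})

test_that("parameter domain is validated", {
  expect_error(protocol_params("HydraPsi", residual = 1.5), "residual")
  expect_error(protocol_params("RMS", depth = 0), "depth")
  expect_error(protocol_params("RMS", frag_min = 50, frag_max = 40),
               "frag_min")
  ref <- make_ref(L = 50L)
  expect_error(truth_profile(ref$name, 999L, 0.5, "Nm", ref), "outside")
  expect_error(truth_profile(ref$name, 10L, 1.2, "Nm", ref), "\\[0,1\\]")
})

test_that("profiles round-trip losslessly through TSV", {
  ref <- make_ref(L = 50L)
  truth <- truth_profile(ref$name, 25L, 0.4, "Nm", ref)
  p <- simulate_rms(ref, truth, protocol_params("RMS", depth = 100),
                    n_replicates = 1L, seed = 9L)[[1]]
  tmp <- tempfile(fileext = ".tsv")
  write_profile(p, tmp)
  q <- read_profile(tmp)
  expect_equal(q, p)
  # malformed inputs fail
  writeLines(c("# molecule: m", "# protocol: RMS", "# replicate_id: r",
               "position\tcount5\tcount3", "1\t-3\t0"), tmp)
  expect_error(read_profile(tmp), "negative")
  writeLines(c("# molecule: m", "# protocol: RMS",
               "position\tcount5\tcount3"), tmp)
  expect_error(read_profile(tmp), "empty")
})

test_that("fragment mode conserves paired read ends within the size window", {
  ref <- make_ref(L = 150L)
  truth <- truth_profile(ref$name, 75L, 0.5, "Nm", ref)
  params <- protocol_params("RMS", depth = 50, fragment_mode = TRUE)
  sims <- simulate_rms(ref, truth, params, n_replicates = 3L, seed = 13L)
  for (p in sims) {
    expect_identical(sum(p$counts5), sum(p$counts3))
    tr <- build_cleavage_track(p)
    expect_identical(sum(tr$c), 2L * sum(p$counts5))
    # fragment spans stay within the molecule given the size window
    expect_gte(min(rep(seq_along(p$counts5), p$counts5)), 2L)
    expect_lte(max(rep(seq_along(p$counts3), p$counts3)),
               length(p$counts3) - 1L)
  }
})

test_that("BEDGraph export uses 0-based half-open intervals", {
  p <- end_count_profile("m", c(0L, 3L, 0L, 1L), c(0L, 0L, 0L, 0L), "r1",
                         "RMS")
  tmp <- tempfile(fileext = ".bedgraph")
  write_bedgraph(p, tmp, "counts5")
  lines <- readLines(tmp)
  expect_equal(lines[2], "m\t1\t2\t3")
  expect_equal(lines[3], "m\t3\t4\t1")
})
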