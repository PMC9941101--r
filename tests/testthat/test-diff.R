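test_that("closed-form paired t agrees with the independent oracle", {
  # textbook example on three differences
  ref <- c(0.60, 0.62, 0.58); alt <- c(0.70, 0.74, 0.69)
  ours <- paired_t(ref, alt)
  oracle <- t.test(alt, ref, paired = TRUE)
  expect_equal(ours$t, unname(oracle$statistic))
  expect_equal(ours$p, oracle$p.value)
  expect_equal(ours$df, unname(oracle$parameter))
  # randomised cases
  set.seed(99)
  for (k in 1:20) {
    n <- sample(2:6, 1)
    x <- runif(n); y <- x + rnorm(n, 0, 0.1)
    ours <- paired_t(x, y)
    oracle <- t.test(y, x, paired = TRUE)
    expect_equal(ours$t, unname(oracle$statistic))
    expect_equal(ours$p, oracle$p.value)
  }
})

test_that("degenerate difference vectors follow the stated conventions", {
  same <- paired_t(c(0.3, 0.3, 0.3), c(0.3, 0.3, 0.3))
  expect_equal(same$p, 1)
  expect_false(same$degenerate)
  shift <- paired_t(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))
  expect_equal(shift$p, 0)
  expect_true(shift$degenerate)
  expect_equal(shift$mean_diff, 0.1)
  expect_error(paired_t(1:3, 1:2), "equal length")
  expect_error(paired_t(1, 2), "n >= 2")
})

test_that("stars are monotone in p and follow the cutpoints", {
  p <- c(0.0005, 0.001, 0.005, 0.01, 0.03, 0.05, 0.07, 0.5)
  s <- stars_for_p(p)
  expect_equal(s, c("***", "***", "**", "**", "*", "*", "ns", "ns"))
  rank <- match(s, c("***", "**", "*", "ns"))
  expect_true(all(diff(rank) >= 0))
})

sim_scores <- function(f_wt, f_ko, position = 20L, depth = 2000,
                       n_rep = 3L, seed = 1L, ref = make_ref(L = 41L)) {
  truth_wt <- truth_profile(ref$name, position, f_wt, "Nm", ref)
  truth_ko <- truth_profile(ref$name, position, f_ko, "Nm", ref)
  catalog <- site_catalog(data.frame(molecule = ref$name, position = position,
                                     residue = ref_residue(ref, position),
                                     mod_type = "Nm"),
                          setNames(list(ref), ref$name))
  params <- protocol_params("RMS", depth = depth)
  combine_score_tables(list(
    WT = score_catalog_rms(simulate_rms(ref, truth_wt, params, n_rep,
                                        seed = seed), catalog),
    KO = score_catalog_rms(simulate_rms(ref, truth_ko, params, n_rep,
                                        seed = seed + 1000L), catalog)))
}

test_that("a planted stoichiometry shift is called affected and upward", {
  scores <- sim_scores(0.02, 0.31, seed = 5L)
  d <- diff_table(scores, "WT", "KO")
  expect_equal(nrow(d), 1L)
  expect_true(d$affected)
  expect_true(d$heatmap_eligible)
  expect_equal(d$direction, "up")
  expect_lt(abs(d$delta - 0.29), 0.08)
})

test_that("swapping conditions negates delta and keeps p", {
  scores <- sim_scores(0.2, 0.6, seed = 9L)
  d1 <- diff_table(scores, "WT", "KO")
  d2 <- diff_table(scores, "KO", "WT")
  expect_equal(d2$delta, -d1$delta)
  expect_equal(d2$p_raw, d1$p_raw)
  expect_equal(d1$direction, "up")
  expect_equal(d2$direction, "down")
})

test_that("sites without two complete pairs are skipped with a warning", {
  scores <- sim_scores(0.2, 0.6, seed = 9L)
  scores$score[scores$condition == "KO" & scores$replicate != "rep1"] <- NA
  expect_warning(d <- diff_table(scores, "WT", "KO"), "skipped")
  expect_null(d)
  # exactly two pairs run at df = 1, flagged low power
  scores2 <- sim_scores(0.2, 0.6, seed = 9L)
  scores2 <- scores2[scores2$replicate != "rep3", ]
  d2 <- diff_table(scores2, "WT", "KO")
  expect_equal(d2$df, 1L)
  expect_true(d2$low_power)
})

test_that("type-I error of the site test matches the nominal level", {
  # null: same truth in both conditions; >= 1000 site-simulations
  ref <- make_ref(L = 41L, seed = 12L)
  i <- 20L
  truth <- truth_profile(ref$name, i, 0.4, "Nm", ref)
  params <- protocol_params("RMS", depth = 2000)
  nsim <- 1000L
  score_one <- function(seed) {
    p <- simulate_rms(ref, truth, params, n_replicates = 1L, seed = seed)[[1]]
    methscore(build_cleavage_track(p), i)
  }
  pvals <- vapply(seq_len(nsim), function(s) {
    wt <- vapply(1:3, function(r) score_one(10000L + s * 10L + r), numeric(1))
    ko <- vapply(1:3, function(r) score_one(50000L + s * 10L + r), numeric(1))
    paired_t(wt, ko)$p
  }, numeric(1))
  rate <- mean(pvals <= 0.05)
  ci_half <- 2.576 * sqrt(0.05 * 0.95 / nsim)   # 99% binomial CI
  expect_lt(abs(rate - 0.05), ci_half)
})

test_that("a 0.3 truth shift at n = 3 is detected with high power", {
  ref <- make_ref(L = 41L, seed = 12L)
  hits <- vapply(seq_len(200L), function(s) {
    scores <- sim_scores(0.3, 0.6, depth = 2000, seed = 7000L + 7L * s,
                         ref = ref)
    diff_table(scores, "WT", "KO")$p_raw <= 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("heatmap matrices keep only 10%-shifted sites in given column order", {
  d1 <- data.frame(molecule = "18S", position = c(10L, 20L), mod_type = "Nm",
                   delta = c(0.29, 0.02),
                   heatmap_eligible = c(TRUE, FALSE))
  d2 <- data.frame(molecule = "18S", position = c(10L, 20L), mod_type = "Nm",
                   delta = c(0.12, 0.01),
                   heatmap_eligible = c(TRUE, FALSE))
  hm <- heatmap_matrix(list(cmpA = d1, cmpB = d2))
  expect_equal(nrow(hm), 1L)
  expect_equal(names(hm), c("molecule", "position", "mod_type",
                            "cmpA", "cmpB"))
  expect_equal(hm$cmpA, 0.29)
  # no eligible site: empty but valid
  d3 <- transform(d1, heatmap_eligible = FALSE)
  expect_equal(nrow(heatmap_matrix(list(only = d3))), 0L)
})
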