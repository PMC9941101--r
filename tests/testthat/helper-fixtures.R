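# In-code fixtures shared across the suite.

# Random reference of length L (fixed seed -> reproducible site layouts).
make_ref <- function(name = "M", L = 120L, seed = 99L) {
  set.seed(seed)
  rna_reference(name, paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                            collapse = ""))
}

# Uridine-homogeneous substrate: under U-specific cleavage every position
# carries background-level signal, so the rolling background is well defined
# and PsiScore calibration can be read directly.
make_polyU <- function(L = 200L, name = "polyU") {
  rna_reference(name, paste(rep("U", L), collapse = ""))
}

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  for (nm in names(records)) {
    writeLines(paste0(">", nm), con)
    writeLines(records[[nm]], con)
  }
  close(con)
  path
}

extdata <- function(...) system.file("extdata", ..., package = "riboscore",
                                     mustWork = TRUE)

load_fixture_refs <- function() read_reference(extdata("synthetic_rrna.fa"))

# Mean MethScore at one site over nsim independent simulations.
mc_methscore <- function(ref, position, f, depth = 2000, nsim = 50L,
                         seed = 1L, flank = 6L) {
  truth <- truth_profile(ref$name, position, f, "Nm", ref)
  params <- protocol_params("RMS", depth = depth)
  vapply(seq_len(nsim), function(s) {
    p <- simulate_rms(ref, truth, params, n_replicates = 1L,
                      seed = seed + s)[[1]]
    methscore(build_cleavage_track(p), position, flank = flank)
  }, numeric(1))
}

# Mean PsiScore at one U over nsim simulations (poly-U substrate,
# leave-one-out background as used for calibration).
mc_psiscore <- function(ref, position, f, depth = 2000, nsim = 50L,
                        seed = 1L, exclude_self = TRUE) {
  truth <- truth_profile(ref$name, position, f, "Psi", ref)
  params <- protocol_params("HydraPsi", depth = depth)
  vapply(seq_len(nsim), function(s) {
    p <- simulate_hydrapsi(ref, truth, params, n_replicates = 1L,
                           seed = seed + s)[[1]]
    up <- u_profile(u_protection_track(p, exclude_self = exclude_self), ref)
    psiscore(up, position)
  }, numeric(1))
}
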