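# Synthetic cleavage-library simulator.
#
# Both chemistries are modelled as independent Poisson cleavage events per
# bond (RMS, alkaline hydrolysis with 2'-O-Me protection of the bond 3' of
# the methylated ribose) or per residue (HydraPsi, hydrazine/aniline cleavage
# of uridines with Psi protection). A molecule-by-molecule simulation is not
# needed for the local-ratio scorers downstream; the optional fragment mode
# exists solely to exercise 5'/3' end-count conservation and the 20-40 nt
# size-selection window.

#' Ground-truth modification profile
#'
#' Per-position modification fractions, the quantity that MethScore /
#' PsiScore estimate ("fraction of molecules" modified at a site).
#'
#' @param molecule reference name.
#' @param positions integer vector of 1-based modified positions.
#' @param fractions modification fractions in `[0,1]`, recycled to
#'   `length(positions)`.
#' @param mod_type `"Nm"` or `"Psi"`.
#' @param ref the matching [rna_reference]; positions are validated against
#'   it and `Psi` truths must sit on U residues.
#' @return object of class `truth_profile`.
#' @export
truth_profile <- function(molecule, positions, fractions, mod_type, ref) {
  stopifnot(inherits(ref, "rna_reference"), ref$name == molecule)
  mod_type <- match.arg(mod_type, c("Nm", "Psi"))
  positions <- as.integer(positions)
  fractions <- rep_len(as.numeric(fractions), length(positions))
  if (anyDuplicated(positions)) stop("duplicate truth positions")
  if (length(positions) &&
      (min(positions) < 1L || max(positions) > ref$length))
    stop("truth positions outside reference '", molecule, "'")
  if (any(fractions < 0 | fractions > 1))
    stop("modification fractions must lie in [0,1]")
  if (mod_type == "Psi" && length(positions)) {
    res <- ref_residue(ref, positions)
    if (any(res != "U"))
      stop("Psi truth on non-U residue at position(s) ",
           paste(positions[res != "U"], collapse = ", "))
  }
  structure(list(molecule = molecule, positions = positions,
                 fractions = fractions, mod_type = mod_type),
            class = "truth_profile")
}

#' Truth profile from a site catalog
#'
#' Convenience constructor: takes the catalog sites of one molecule and one
#' modality and attaches a fraction to each.
#'
#' @param catalog a `site_catalog`.
#' @param molecule molecule name.
#' @param mod_type `"Nm"` or `"Psi"`.
#' @param fractions numeric vector aligned with the selected sites (recycled).
#' @param ref the matching [rna_reference].
#' @return a [truth_profile()].
#' @export
truth_from_catalog <- function(catalog, molecule, mod_type, fractions, ref) {
  sel <- catalog$molecule == molecule & catalog$mod_type == mod_type
  truth_profile(molecule, catalog$position[sel], fractions, mod_type, ref)
}

#' Protocol parameters for the cleavage simulator
#'
#' @param protocol `"RMS"` (alkaline hydrolysis, 2'-O-Me read-out) or
#'   `"HydraPsi"` (hydrazine/aniline, pseudouridine read-out).
#' @param depth expected cleavage events per bond/residue pool (dimensionless
#'   multiplier; the scorers see `depth * base_rate` as the per-bond Poisson
#'   mean at unprotected sites).
#' @param base_rate per-bond (RMS) or per-U (HydraPsi) cleavage propensity.
#' @param residual relative cleavage propensity retained at a fully modified
#'   site; 0 means full protection.
#' @param bg_rate HydraPsi only: relative cleavage propensity at non-U
#'   residues (hydrazine is U-specific).
#' @param frag_min,frag_max RMS fragment-mode size-selection window in nt.
#' @param end_offset HydraPsi only: integer offset between the cleaved U and
#'   the position at which its 5' end is counted; shared with the scorer.
#' @param fragment_mode RMS only: simulate paired fragment ends (two cleavage
#'   events 20-40 nt apart) instead of independent per-bond events.
#' @return object of class `protocol_params`.
#' @export
protocol_params <- function(protocol = c("RMS", "HydraPsi"),
                            depth = 2000, base_rate = 1,
                            residual = 0, bg_rate = 0.01,
                            frag_min = 20L, frag_max = 40L,
                            end_offset = 0L, fragment_mode = FALSE) {
  protocol <- match.arg(protocol)
  if (depth <= 0) stop("depth must be > 0")
  if (base_rate <= 0) stop("base_rate must be > 0")
  if (residual < 0 || residual > 1)
    stop("residual must lie in [0,1] (got ", residual, ")")
  if (bg_rate < 0) stop("bg_rate must be >= 0")
  frag_min <- as.integer(frag_min); frag_max <- as.integer(frag_max)
  if (frag_min > frag_max) stop("frag_min must be <= frag_max")
  structure(list(protocol = protocol, depth = depth, base_rate = base_rate,
                 residual = residual, bg_rate = bg_rate,
                 frag_min = frag_min, frag_max = frag_max,
                 end_offset = as.integer(end_offset),
                 fragment_mode = isTRUE(fragment_mode)),
            class = "protocol_params")
}

#' End-count profile for one replicate
#'
#' @param molecule reference name.
#' @param counts5,counts3 non-negative integer vectors over positions
#'   `1..L` of 5'-end and 3'-end read counts.
#' @param replicate_id replicate label.
#' @param protocol `"RMS"` or `"HydraPsi"`.
#' @param seed the RNG seed the profile was generated under (or `NA`).
#' @return object of class `end_count_profile`.
#' @export
end_count_profile <- function(molecule, counts5, counts3, replicate_id,
                              protocol = c("RMS", "HydraPsi"),
                              seed = NA_integer_) {
  protocol <- match.arg(protocol)
  counts5 <- as.integer(counts5); counts3 <- as.integer(counts3)
  if (length(counts5) == 0L) stop("empty profile (L = 0)")
  if (length(counts5) != length(counts3))
    stop("counts5 and counts3 lengths differ")
  if (anyNA(counts5) || anyNA(counts3) ||
      any(counts5 < 0L) || any(counts3 < 0L))
    stop("end counts must be non-negative integers")
  structure(list(molecule = molecule, counts5 = counts5, counts3 = counts3,
                 replicate_id = as.character(replicate_id),
                 protocol = protocol, seed = as.integer(seed)),
            class = "end_count_profile")
}

#' @export
print.end_count_profile <- function(x, ...) {
  cat(sprintf("<end_count_profile> %s %s %s: L=%d, sum5=%d, sum3=%d\n",
              x$protocol, x$molecule, x$replicate_id, length(x$counts5),
              sum(x$counts5), sum(x$counts3)))
  invisible(x)
}

# Deterministic per-replicate stream seed. Replicate r always gets the same
# stream for a given master seed, so adding replicates never perturbs earlier
# ones. Kept below 2^31 - 1.
derive_stream_seed <- function(master, replicate) {
  (abs(as.integer(master)) %% 2003654321L + as.integer(replicate) * 7954979L) %%
    2147483647L
}

truth_fraction_vector <- function(truth, L) {
  f <- numeric(L)
  f[truth$positions] <- truth$fractions
  f
}

#' Simulate RiboMeth-seq end-count profiles
#'
#' Phosphodiester bond `j` (3' of nucleotide `j`, `j = 1..L-1`) receives
#' expected cleavage intensity
#' `lambda_j = depth * base_rate * (1 - f_j * (1 - residual))`,
#' where `f_j` is the 2'-O-Me fraction of nucleotide `j`. Realised counts are
#' Poisson; each cleavage event increments `counts3[j]` and `counts5[j+1]`.
#' Replicates differ only by their derived RNG stream, so output is
#' deterministic given `(seed, replicate index)`.
#'
#' In fragment mode, fragments are pairs of cleavage events `frag_min` to
#' `frag_max` nt apart (uniform acceptance within the size window); each
#' fragment contributes one 5' and one 3' end, so
#' `sum(counts5) == sum(counts3)`.
#'
#' @param ref an [rna_reference].
#' @param truth a [truth_profile()] with `mod_type == "Nm"`.
#' @param params [protocol_params()] with `protocol == "RMS"`.
#' @param n_replicates number of biological replicates to draw.
#' @param seed master RNG seed.
#' @return list of [end_count_profile()] objects, names `rep1..repN`.
#' @export
simulate_rms <- function(ref, truth, params = protocol_params("RMS"),
                         n_replicates = 3L, seed = 1L) {
  stopifnot(inherits(ref, "rna_reference"), inherits(truth, "truth_profile"),
            inherits(params, "protocol_params"))
  if (truth$mod_type != "Nm") stop("simulate_rms needs an Nm truth profile")
  if (params$protocol != "RMS") stop("params$protocol must be 'RMS'")
  if (truth$molecule != ref$name) stop("truth/reference molecule mismatch")
  L <- ref$length
  if (L < 2L) stop("reference too short to cleave")
  f <- truth_fraction_vector(truth, L)
  lambda <- params$depth * params$base_rate *
    (1 - f[seq_len(L - 1L)] * (1 - params$residual))
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- derive_stream_seed(seed, r)
    set.seed(s)
    counts5 <- integer(L); counts3 <- integer(L)
    if (params$fragment_mode) {
      ends <- draw_fragments(lambda, params$frag_min, params$frag_max)
      counts5 <- tabulate(ends$left + 1L, nbins = L)
      counts3 <- tabulate(ends$right, nbins = L)
    } else {
      ev <- stats::rpois(L - 1L, lambda)
      counts3[seq_len(L - 1L)] <- ev
      counts5[seq_len(L - 1L) + 1L] <- ev
    }
    out[[r]] <- end_count_profile(ref$name, counts5, counts3,
                                  paste0("rep", r), "RMS", seed = s)
  }
  names(out) <- vapply(out, `[[`, character(1), "replicate_id")
  out
}

# Fragment mode: a fragment spans nucleotides (a+1)..b where a and b are its
# bounding cleaved bonds, b - a in [frag_min, frag_max]. Bonds are chosen
# proportionally to their cleavage intensity; the right bond by rejection.
draw_fragments <- function(lambda, frag_min, frag_max) {
  nb <- length(lambda)
  n_frag <- stats::rpois(1L, sum(lambda) / 2)
  left <- integer(0); right <- integer(0)
  wmax <- max(lambda)
  got <- 0L; guard <- 0L
  while (got < n_frag && guard < 200L) {
    guard <- guard + 1L
    need <- n_frag - got
    a <- sample.int(nb, size = need * 2L, replace = TRUE, prob = lambda)
    len <- sample(seq.int(frag_min, frag_max), size = need * 2L, replace = TRUE)
    b <- a + len
    ok <- b <= nb
    if (any(ok)) {
      acc <- stats::runif(sum(ok)) < lambda[b[ok]] / wmax
      a <- a[ok][acc]; b <- b[ok][acc]
      take <- seq_len(min(length(a), need))
      left <- c(left, a[take]); right <- c(right, b[take])
      got <- length(left)
    }
  }
  list(left = left, right = right)
}

#' Simulate HydraPsiSeq end-count profiles
#'
#' Residue `i` receives cleavage intensity
#' `lambda_i = depth * base_rate * (1 - f_i * (1 - residual))` if it is a U,
#' else `depth * base_rate * bg_rate` (hydrazine is U-specific). Each event
#' increments `counts5[i + end_offset]`; `counts3` stays zero (only 5' ends
#' are used by the protection scorer).
#'
#' @inheritParams simulate_rms
#' @param truth a [truth_profile()] with `mod_type == "Psi"`.
#' @param params [protocol_params()] with `protocol == "HydraPsi"`.
#' @return list of [end_count_profile()] objects.
#' @export
simulate_hydrapsi <- function(ref, truth,
                              params = protocol_params("HydraPsi"),
                              n_replicates = 3L, seed = 1L) {
  stopifnot(inherits(ref, "rna_reference"), inherits(truth, "truth_profile"),
            inherits(params, "protocol_params"))
  if (truth$mod_type != "Psi") stop("simulate_hydrapsi needs a Psi truth profile")
  if (params$protocol != "HydraPsi") stop("params$protocol must be 'HydraPsi'")
  if (truth$molecule != ref$name) stop("truth/reference molecule mismatch")
  L <- ref$length
  is_u <- strsplit(ref$sequence, "")[[1]] == "U"
  f <- truth_fraction_vector(truth, L)
  d <- params$depth * params$base_rate
  lambda <- ifelse(is_u, d * (1 - f * (1 - params$residual)), d * params$bg_rate)
  off <- params$end_offset
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- derive_stream_seed(seed, r)
    set.seed(s)
    ev <- stats::rpois(L, lambda)
    counts5 <- integer(L)
    idx <- seq_len(L) + off
    keep <- idx >= 1L & idx <= L
    counts5[idx[keep]] <- ev[keep]
    out[[r]] <- end_count_profile(ref$name, counts5, integer(L),
                                  paste0("rep", r), "HydraPsi", seed = s)
  }
  names(out) <- vapply(out, `[[`, character(1), "replicate_id")
  out
}
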