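# RiboMeth-seq MethScore: local drop in cleavage evidence at the bond 3' of
# a 2'-O-methylated ribose, relative to six flanking bonds per side.

#' Build a per-bond cleavage track from an RMS profile
#'
#' Combines both read-end channels: a cleavage at bond `j` (3' of nucleotide
#' `j`) leaves a 3' end at `j` and a 5' end at `j + 1`, so
#' `c[j] = counts3[j] + counts5[j+1]`, robust to one-sided end losses.
#'
#' @param profile an [end_count_profile()] with `protocol == "RMS"`.
#' @return object of class `cleavage_track` with fields `molecule`, `c`
#'   (length `L - 1`) and `source_replicate`.
#' @export
build_cleavage_track <- function(profile) {
  stopifnot(inherits(profile, "end_count_profile"))
  if (profile$protocol != "RMS")
    stop("cleavage tracks are defined for RMS profiles, got ",
         profile$protocol)
  L <- length(profile$counts5)
  j <- seq_len(L - 1L)
  structure(list(molecule = profile$molecule,
                 c = profile$counts3[j] + profile$counts5[j + 1L],
                 source_replicate = profile$replicate_id),
            class = "cleavage_track")
}

#' MethScore at one position
#'
#' 2'-O-Me at nucleotide `i` protects the phosphodiester bond between `i` and
#' `i + 1`, so the inquired bond for a site at `i` is bond index `i`. The
#' score compares the cleavage evidence there with the means of the `flank`
#' bonds on either side:
#' `score = clip(1 - 2 * c[i] / (Lbar + Rbar), 0, 1)`.
#' It estimates the fraction of molecules methylated at the site.
#'
#' The score is *undefined* (returned as `NA`, never 0) when fewer than 3
#' bonds are available on either side or when the flanking background is
#' zero; this prevents fake "unmethylated" calls at molecule ends.
#'
#' @param track a [build_cleavage_track()] result.
#' @param position 1-based nucleotide position of the site.
#' @param flank number of flanking bonds per side (default 6).
#' @param details if `TRUE`, return a list with `score` and
#'   `local_coverage` (mean flanking count) instead of a bare number.
#' @return numeric score in `[0,1]`, or `NA` when undefined.
#' @export
methscore <- function(track, position, flank = 6L, details = FALSE) {
  stopifnot(inherits(track, "cleavage_track"), flank >= 1L)
  nb <- length(track$c)
  i <- as.integer(position)
  if (i < 1L || i > nb)
    stop("position ", position, " maps to no bond on ", track$molecule,
         " (bonds 1..", nb, ")")
  lidx <- seq.int(max(1L, i - flank), i - 1L)
  ridx <- seq.int(i + 1L, min(nb, i + flank))
  lidx <- lidx[lidx >= 1L & lidx < i]
  ridx <- ridx[ridx > i & ridx <= nb]
  if (length(lidx) < 3L || length(ridx) < 3L) {
    score <- NA_real_; cov <- NA_real_
  } else {
    lbar <- mean(track$c[lidx]); rbar <- mean(track$c[ridx])
    cov <- (lbar + rbar) / 2
    score <- if (lbar + rbar == 0) NA_real_ else
      min(max(1 - 2 * track$c[i] / (lbar + rbar), 0), 1)
  }
  if (details) list(score = score, local_coverage = cov) else score
}

#' Score a catalog of 2'-O-Me sites across replicates
#'
#' @param profiles list of RMS [end_count_profile()] objects (replicates),
#'   possibly spanning several molecules.
#' @param catalog a `site_catalog`; only its `Nm` sites are scored.
#' @param flank flanking bonds per side, passed to [methscore()].
#' @return a `score table`: data frame with columns `molecule`, `position`,
#'   `residue`, `mod_type`, `replicate`, `score`, `local_coverage`. Undefined
#'   scores propagate as `NA` with a warning.
#' @export
score_catalog_rms <- function(profiles, catalog, flank = 6L) {
  stopifnot(length(profiles) >= 1L)
  nm <- catalog[catalog$mod_type == "Nm", , drop = FALSE]
  mols <- unique(nm$molecule)
  have <- unique(vapply(profiles, `[[`, character(1), "molecule"))
  missing_mol <- setdiff(mols, have)
  if (length(missing_mol))
    stop("no profiles for catalog molecule(s): ",
         paste(missing_mol, collapse = ", "))
  rows <- list()
  for (p in profiles) {
    if (p$protocol != "RMS") stop("non-RMS profile in score_catalog_rms")
    track <- build_cleavage_track(p)
    sites <- nm[nm$molecule == p$molecule, , drop = FALSE]
    if (nrow(sites) == 0L) next
    res <- lapply(sites$position, methscore, track = track, flank = flank,
                  details = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      molecule = sites$molecule, position = sites$position,
      residue = sites$residue, mod_type = sites$mod_type,
      replicate = p$replicate_id,
      score = vapply(res, `[[`, numeric(1), "score"),
      local_coverage = vapply(res, `[[`, numeric(1), "local_coverage"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyNA(out$score)) {
    und <- unique(paste0(out$molecule, ":", out$position)[is.na(out$score)])
    warning("MethScore undefined (insufficient window or zero background) ",
            "at: ", paste(und, collapse = ", "))
  }
  out
}
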