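# HydraPsiSeq protection scoring: rolling-window background normalisation of
# 5'-end counts -> NormUcount -> U-only profile -> PsiScore (primary) and
# scoremean (auxiliary RMS-style local score on the U profile).

#' Rolling local background of a 5'-end count vector
#'
#' Mean of `counts5` over a `window`-wide rolling window. For even windows
#' the centering is center-right: positions `i - window/2` to
#' `i + window/2 - 1`. Windows are clipped (shrunk) at molecule ends; the
#' background is `NA` where the clipped window holds fewer than `window / 2`
#' positions or where its mean is zero.
#'
#' @param counts5 numeric vector of 5'-end counts over positions `1..L`.
#' @param window window width in nt (default 10).
#' @param exclude_self if `TRUE`, compute the leave-one-out mean (the queried
#'   position is dropped from its own window). The default plain mean
#'   includes it; the two differ at strongly protected sites.
#' @return numeric vector of backgrounds, `NA` where undefined.
#' @export
rolling_background <- function(counts5, window = 10L, exclude_self = FALSE) {
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2")
  L <- length(counts5)
  half <- window %/% 2L
  lo_off <- -half
  hi_off <- if (window %% 2L == 0L) half - 1L else half
  bg <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    lo <- max(1L, i + lo_off); hi <- min(L, i + hi_off)
    idx <- seq.int(lo, hi)
    if (exclude_self) idx <- idx[idx != i]
    if (length(idx) < window / 2) next
    m <- mean(counts5[idx])
    if (m > 0) bg[i] <- m
  }
  bg
}

#' NormUcount: background-normalised 5'-end count at a position
#'
#' The protection "Uscore" value: `counts5[position] / background[position]`.
#'
#' @param counts5 5'-end count vector.
#' @param background matching [rolling_background()] vector.
#' @param position 1-based position (vectorised).
#' @return numeric; `NA` where the background is undefined.
#' @export
norm_ucount <- function(counts5, background, position) {
  stopifnot(length(counts5) == length(background))
  if (any(position < 1L | position > length(counts5)))
    stop("position out of range")
  counts5[position] / background[position]
}

#' Build a U-protection track from a HydraPsi profile
#'
#' @param profile an [end_count_profile()] with `protocol == "HydraPsi"`.
#' @param window rolling-background window (nt).
#' @param exclude_self leave-one-out background, see [rolling_background()].
#' @param end_offset integer offset between a cleaved U and the position its
#'   5' end was counted at; must match the value used upstream (simulator or
#'   aligner attribution). Counts are shifted back before scoring.
#' @return object of class `u_protection_track` with `normu` and
#'   `background` vectors over all positions (consumed only at U residues).
#' @export
u_protection_track <- function(profile, window = 10L, exclude_self = FALSE,
                               end_offset = 0L) {
  stopifnot(inherits(profile, "end_count_profile"))
  if (profile$protocol != "HydraPsi")
    stop("U-protection tracks are defined for HydraPsi profiles, got ",
         profile$protocol)
  counts5 <- profile$counts5
  off <- as.integer(end_offset)
  if (off != 0L) {
    L <- length(counts5)
    shifted <- numeric(L)
    src <- seq_len(L) + off           # count for residue i was stored at i+off
    keep <- src >= 1L & src <= L
    shifted[keep] <- counts5[src[keep]]
    counts5 <- shifted
  }
  bg <- rolling_background(counts5, window = window,
                           exclude_self = exclude_self)
  structure(list(molecule = profile$molecule,
                 normu = counts5 / bg, background = bg,
                 replicate_id = profile$replicate_id,
                 window = window, exclude_self = exclude_self,
                 end_offset = off),
            class = "u_protection_track")
}

#' U-only cleavage profile
#'
#' Restricts a protection track to uridine residues ("omitting values for
#' other nucleotides"); positions keep their full-molecule coordinates.
#'
#' @param track a [u_protection_track()].
#' @param ref the matching [rna_reference].
#' @return data frame with columns `position` and `normu`, one row per U.
#' @export
u_profile <- function(track, ref) {
  stopifnot(inherits(track, "u_protection_track"),
            inherits(ref, "rna_reference"))
  if (track$molecule != ref$name)
    stop("track/reference molecule mismatch")
  is_u <- strsplit(ref$sequence, "")[[1]] == "U"
  data.frame(position = which(is_u), normu = track$normu[is_u])
}

#' PsiScore at one U position
#'
#' `psiscore = 1 - NormUcount`. Not clipped below: negative values mean the
#' residue is cleaved above its local background, i.e. not protected and
#' hence not pseudouridylated. Always `<= 1`.
#'
#' @param uprof a [u_profile()] data frame.
#' @param position 1-based position of a U residue present in `uprof`.
#' @return numeric score `<= 1`, `NA` when NormUcount is undefined.
#' @export
psiscore <- function(uprof, position) {
  k <- match(as.integer(position), uprof$position)
  if (anyNA(k)) stop("position(s) not in U profile: ",
                     paste(position[is.na(k)], collapse = ", "))
  1 - uprof$normu[k]
}

#' Auxiliary RMS-style local score on the U profile
#'
#' `scoremean = 1 - 2 * u_i / (Lbar + Rbar)` over the nearest `flank_u`
#' U-neighbours per side (at least 3 with defined values required on each
#' side). Clipped at 1 from above only; a diagnostic complement to the
#' primary [psiscore()].
#'
#' @param uprof a [u_profile()] data frame.
#' @param position 1-based position of a U residue in `uprof`.
#' @param flank_u number of U-neighbours per side.
#' @return numeric score `<= 1`, `NA` when undefined.
#' @export
scoremean <- function(uprof, position, flank_u = 6L) {
  k <- match(as.integer(position), uprof$position)
  if (is.na(k)) stop("position ", position, " not in U profile")
  if (is.na(uprof$normu[k])) return(NA_real_)
  lv <- uprof$normu[seq_len(k - 1L)]
  rv <- if (k < nrow(uprof)) uprof$normu[seq.int(k + 1L, nrow(uprof))] else numeric(0)
  lv <- rev(lv[!is.na(lv)]); rv <- rv[!is.na(rv)]
  lv <- lv[seq_len(min(flank_u, length(lv)))]
  rv <- rv[seq_len(min(flank_u, length(rv)))]
  if (length(lv) < 3L || length(rv) < 3L) return(NA_real_)
  lbar <- mean(lv); rbar <- mean(rv)
  if (lbar + rbar == 0) return(NA_real_)
  min(1 - 2 * uprof$normu[k] / (lbar + rbar), 1)
}

#' Score a catalog of pseudouridine sites across replicates
#'
#' @param profiles list of HydraPsi [end_count_profile()] objects
#'   (replicates); at least 2 replicates expected for downstream testing.
#' @param catalog a `site_catalog`; only its `Psi` sites are scored.
#' @param refs named list of [rna_reference] objects.
#' @param window rolling-background window (nt).
#' @param exclude_self leave-one-out background.
#' @param end_offset 5'-end attribution offset shared with the simulator.
#' @param flank_u U-neighbours per side for the auxiliary scoremean.
#' @return data frame with columns `molecule`, `position`, `residue`,
#'   `mod_type`, `replicate`, `score` (PsiScore) and `scoremean`.
#' @export
score_catalog_psi <- function(profiles, catalog, refs, window = 10L,
                              exclude_self = FALSE, end_offset = 0L,
                              flank_u = 6L) {
  stopifnot(length(profiles) >= 1L)
  ps <- catalog[catalog$mod_type == "Psi", , drop = FALSE]
  have <- unique(vapply(profiles, `[[`, character(1), "molecule"))
  missing_mol <- setdiff(unique(ps$molecule), have)
  if (length(missing_mol))
    stop("no profiles for catalog molecule(s): ",
         paste(missing_mol, collapse = ", "))
  rows <- list()
  for (p in profiles) {
    if (p$protocol != "HydraPsi")
      stop("non-HydraPsi profile in score_catalog_psi")
    ref <- refs[[p$molecule]]
    if (is.null(ref)) stop("no reference for molecule ", p$molecule)
    track <- u_protection_track(p, window = window,
                                exclude_self = exclude_self,
                                end_offset = end_offset)
    uprof <- u_profile(track, ref)
    sites <- ps[ps$molecule == p$molecule, , drop = FALSE]
    if (nrow(sites) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      molecule = sites$molecule, position = sites$position,
      residue = sites$residue, mod_type = sites$mod_type,
      replicate = p$replicate_id,
      score = psiscore(uprof, sites$position),
      scoremean = vapply(sites$position, scoremean, numeric(1),
                         uprof = uprof, flank_u = flank_u),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyNA(out$score)) {
    und <- unique(paste0(out$molecule, ":", out$position)[is.na(out$score)])
    warning("PsiScore undefined (no local background) at: ",
            paste(und, collapse = ", "))
  }
  out
}
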