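#!/usr/bin/env Rscript
# Regenerates the synthetic fixtures under inst/extdata/. Run from the
# repository root. Deterministic (fixed seed); outputs are committed, this
# script documents their provenance.
#
# The references are random sequences of realistic mature-rRNA lengths with
# the well-known modified residues forced at their published positions; they
# are NOT the real rRNA sequences (synthetic_* filenames flag this).

set.seed(20230220)

out <- "inst/extdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lens <- c(`18S` = 1869L, `28S` = 5070L, `5.8S` = 157L)

rand_seq <- function(n) sample(c("A", "C", "G", "U"), n, replace = TRUE,
                               prob = c(0.26, 0.24, 0.28, 0.22))

seqs <- lapply(lens, rand_seq)

# molecule, position, residue, guides, legacy (NA = none)
nm_named <- rbind(
  data.frame(molecule = "18S",
             position = c(174L, 354L, 436L, 576L, 867L, 951L, 995L, 1000L,
                          1034L, 1272L, 1440L, 1639L),
             residue  = c("C", "U", "G", "A", "G", "C", "G", "C",
                          "A", "C", "C", "G"),
             guides   = c("SNORD45C", "SNORD90", "SNORD100", "SNORD93",
                          "SNORD98", "SNORD114-3", "SNORD53", "SNORD44",
                          "SNORD59A", "SNORD66", "SNORD125", "SNORD81"),
             legacy   = NA_integer_),
  data.frame(molecule = "28S",
             position = c(1323L, 1881L, 2075L, 2401L, 2787L, 2861L, 2876L,
                          3867L, 3904L, 4042L, 4456L),
             residue  = c("A", "C", "C", "A", "A", "C", "G", "A", "U",
                          "G", "C"),
             guides   = c("SNORD126", "SNORD48", "SNORD114-14", "SNORD68",
                          "SNORD99", "SNORD50A;SNORD50B", "SNORD50A;SNORD50B",
                          "SNORD92", "SNORD52", "SNORD102",
                          "SNORD49A;SNORD49B"),
             legacy   = c(1310L, 1868L, NA, 2388L, 2774L, 2848L, 2863L,
                          3846L, NA, 4020L, 4426L)),
  data.frame(molecule = "5.8S", position = c(14L, 75L),
             residue = c("U", "G"), guides = "Unknown", legacy = NA_integer_))

psi_named <- rbind(
  data.frame(molecule = "18S", position = c(296L, 681L, 897L, 1046L),
             guides = c("Unknown", "Unknown", "SNORA44", "Unknown"),
             legacy = NA_integer_),
  data.frame(molecule = "28S",
             position = c(1536L, 1582L, 1779L, 2839L, 2843L, 3734L, 3822L,
                          3884L, 4312L, 4420L, 4579L, 4636L, 4673L, 4973L,
                          5001L),
             guides   = c("Unknown", "SNORA7A;SNORA7B", "SNORA47", "Unknown",
                          "Unknown", "SNORA31", "SNORA54", "Unknown",
                          "SNORA2A;SNORA2B;SNORA34", "SNORA63", "Unknown",
                          "SNORA81", "SNORA30;SNORA37", "SNORA43",
                          "SNORA22;SNORA33"),
             legacy   = c(NA, 1569L, 1766L, 2826L, 2830L, 3713L, 3801L, NA,
                          4282L, 4390L, 4549L, 4606L, 4643L, 4938L, 4966L)),
  data.frame(molecule = "5.8S", position = c(55L, 69L), guides = "Unknown",
             legacy = NA_integer_))
psi_named$residue <- "U"

# stated per-molecule site counts
target_nm  <- c(`18S` = 41L, `28S` = 67L, `5.8S` = 2L)
target_psi <- c(`18S` = 44L, `28S` = 61L, `5.8S` = 2L)

pick_filler <- function(mol, n, taken, min_pos = 25L) {
  L <- lens[[mol]]
  avail <- setdiff(seq.int(min_pos, L - 25L), unlist(lapply(taken, function(p)
    (p - 2L):(p + 2L))))
  sort(sample(avail, n))
}

taken <- split(c(nm_named$position, psi_named$position),
               c(nm_named$molecule, psi_named$molecule))

nm_fill <- list(); psi_fill <- list()
for (mol in names(lens)) {
  n_nm <- target_nm[[mol]] - sum(nm_named$molecule == mol)
  n_psi <- target_psi[[mol]] - sum(psi_named$molecule == mol)
  pos_nm <- if (n_nm > 0) pick_filler(mol, n_nm, taken[[mol]]) else integer(0)
  taken[[mol]] <- c(taken[[mol]], pos_nm)
  pos_psi <- if (n_psi > 0) pick_filler(mol, n_psi, taken[[mol]]) else integer(0)
  taken[[mol]] <- c(taken[[mol]], pos_psi)
  nm_fill[[mol]] <- pos_nm
  psi_fill[[mol]] <- pos_psi
}

# force residues: named sites, then U at every Psi position
for (k in seq_len(nrow(nm_named)))
  seqs[[nm_named$molecule[k]]][nm_named$position[k]] <- nm_named$residue[k]
for (k in seq_len(nrow(psi_named)))
  seqs[[psi_named$molecule[k]]][psi_named$position[k]] <- "U"
for (mol in names(psi_fill))
  seqs[[mol]][psi_fill[[mol]]] <- "U"

fa <- file.path(out, "synthetic_rrna.fa")
con <- file(fa, "w")
for (mol in names(seqs)) {
  writeLines(paste0(">", mol, " synthetic mature rRNA (random sequence, ",
                    "published modified residues forced)"), con)
  s <- paste(seqs[[mol]], collapse = "")
  starts <- seq(1, nchar(s), by = 70)
  writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
}
close(con)

catalog_df <- function(named, fill, mod_type) {
  fill_df <- do.call(rbind, lapply(names(fill), function(mol) {
    if (!length(fill[[mol]])) return(NULL)
    data.frame(molecule = mol, position = fill[[mol]],
               residue = seqs[[mol]][fill[[mol]]],
               guides = "Unknown", legacy = NA_integer_)
  }))
  df <- rbind(named[c("molecule", "position", "residue", "guides", "legacy")],
              fill_df)
  df$mod_type <- mod_type
  df <- df[order(df$molecule, df$position), ]
  data.frame(molecule = df$molecule, position = df$position,
             residue = df$residue, mod_type = df$mod_type,
             guides = df$guides,
             legacy_position = ifelse(is.na(df$legacy), "",
                                      as.character(df$legacy)))
}

nm_cat <- catalog_df(nm_named, nm_fill, "Nm")
psi_cat <- catalog_df(psi_named, psi_fill, "Psi")
stopifnot(table(nm_cat$molecule)[names(target_nm)] == target_nm,
          table(psi_cat$molecule)[names(target_psi)] == target_psi)
write.table(nm_cat, file.path(out, "synthetic_sites_nm.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(psi_cat, file.path(out, "synthetic_sites_psi.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# Demo ground truths: near-saturated baseline, with the dynamic HEK293T
# WT -> KO stoichiometries at their published positions.
nm_dyn <- data.frame(
  molecule = c("18S", "18S", "18S", "18S", "18S", "18S", "18S",
               "28S", "28S", "28S", "28S", "28S"),
  position = c(354L, 576L, 867L, 951L, 1000L, 1272L, 1639L,
               2075L, 2401L, 2861L, 2876L, 4042L),
  wt = c(0.02, 0.57, 0.76, 0.34, 0.29, 0.39, 0.62,
         0.21, 0.76, 0.64, 0.37, 0.46),
  ko = c(0.31, 0.64, 0.82, 0.01, 0.14, 0.60, 0.49,
         0.04, 0.87, 0.79, 0.54, 0.63))
psi_dyn <- data.frame(
  molecule = "28S",
  position = c(1582L, 1779L, 2839L, 3734L, 3822L, 4312L, 4420L, 4579L,
               4673L, 5001L),
  wt = c(0.68, 0.75, 0.17, 0.86, 0.72, 0.85, 0.56, 0.41, 0.65, 0.59),
  ko = c(0.77, 0.92, 0.29, 0.92, 0.85, 0.91, 0.72, 0.32, 0.79, 0.77))

set.seed(7)
base_nm <- round(runif(nrow(nm_cat), 0.85, 0.98), 3)
base_psi <- round(runif(nrow(psi_cat), 0.85, 0.98), 3)
truth_of <- function(cat, base, dyn, col) {
  f <- base
  idx <- match(paste(dyn$molecule, dyn$position),
               paste(cat$molecule, cat$position))
  f[idx] <- dyn[[col]]
  data.frame(molecule = cat$molecule, position = cat$position, fraction = f)
}
write.table(truth_of(nm_cat, base_nm, nm_dyn, "wt"),
            file.path(out, "demo_truth_nm_wt.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(truth_of(nm_cat, base_nm, nm_dyn, "ko"),
            file.path(out, "demo_truth_nm_ko.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(truth_of(psi_cat, base_psi, psi_dyn, "wt"),
            file.path(out, "demo_truth_psi_wt.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(truth_of(psi_cat, base_psi, psi_dyn, "ko"),
            file.path(out, "demo_truth_psi_ko.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# Synthetic guide DE table (the shape of a DESeq2 export + qPCR summary).
de <- rbind(
  data.frame(snorna = c("SNORD90", "SNORD66", "SNORD50A", "SNORD68",
                        "SNORD102", "SNORD114-14", "SNORD93", "SNORD98",
                        "SNORA47", "SNORA33", "SNORA22", "SNORA37",
                        "SNORA30", "SNORA63", "SNORA7A", "SNORA54",
                        "SNORA31", "SNORA2A"),
             log2fc = c(1.20, 0.90, 0.80, 0.70, 0.60, -1.50, 0.30, 0.25,
                        1.10, 0.90, 0.10, 0.80, 0.05, 0.40, 0.30, 0.70,
                        0.35, 0.45),
             padj = c(0.001, 0.004, 0.010, 0.030, 0.200, 0.002, 0.400,
                      0.350, 0.0005, 0.010, 0.800, 0.020, 0.900, 0.040,
                      0.300, 0.015, 0.250, 0.120),
             source = "smallRNAseq"),
  data.frame(snorna = c("SNORD90", "SNORD66", "SNORD114-14"),
             log2fc = c(1.05, 0.85, -1.20), padj = c(0.010, 0.020, 0.010),
             source = "qPCR"))
write.table(de, file.path(out, "synthetic_guide_de.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("fixtures written to", out, "\n")
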