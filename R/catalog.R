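# Reference sequences and modification-site catalogs.
#
# Coordinates are 1-based, inclusive, on mature molecules throughout the
# package; only the BEDGraph writer converts to 0-based half-open. The
# internal alphabet is {A,C,G,U,N}: DNA-style FASTA is accepted and T is
# canonicalised to U on read.

#' Construct an RNA reference
#'
#' A named RNA molecule with 1-based coordinates, the substrate against which
#' modification sites are validated and on which cleavage profiles live.
#'
#' @param name molecule identifier, e.g. `"18S"`, `"28S"`, `"5.8S"`.
#' @param sequence character scalar over `{A,C,G,U/T,N}` (case-insensitive);
#'   `T` is stored as `U`.
#' @return an object of class `rna_reference` with fields `name`, `sequence`
#'   (canonical `ACGUN` string) and `length`.
#' @export
rna_reference <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- chartr("tu", "TU", toupper(sequence))
  seq <- gsub("T", "U", seq, fixed = TRUE)
  if (nchar(seq) == 0L)
    stop("reference '", name, "' has an empty sequence")
  bad <- gsub("[ACGUN]", "", seq)
  if (nchar(bad) > 0L)
    stop("reference '", name, "' contains illegal characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = " "))
  structure(list(name = name, sequence = seq, length = nchar(seq)),
            class = "rna_reference")
}

#' @export
print.rna_reference <- function(x, ...) {
  cat(sprintf("<rna_reference> %s (%d nt)\n", x$name, x$length))
  invisible(x)
}

#' Residue at a position of a reference
#'
#' @param ref an [rna_reference].
#' @param position 1-based position (vectorised).
#' @return character vector of residues in `{A,C,G,U,N}`.
#' @export
ref_residue <- function(ref, position) {
  stopifnot(inherits(ref, "rna_reference"))
  if (any(position < 1L | position > ref$length))
    stop("position out of range for reference '", ref$name, "' (length ",
         ref$length, ")")
  vapply(position, function(p) substr(ref$sequence, p, p), character(1))
}

#' Read reference sequences from a FASTA file
#'
#' Names are the first whitespace-delimited token of each header. U/T are
#' normalised internally; duplicate names, empty files and illegal characters
#' are hard errors naming the offending record.
#'
#' @param path path to a FASTA file (RNA or DNA alphabet).
#' @return a named list of [rna_reference] objects.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nm <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate record name(s) in ", path, ": ", paste(dup, collapse = ", "))
  refs <- Map(rna_reference, nm, as.character(set))
  names(refs) <- nm
  refs
}

#' Write references to FASTA
#'
#' @param refs named list of [rna_reference] objects.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_reference <- function(refs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ref in refs) {
    writeLines(paste0(">", ref$name), con)
    starts <- seq(1L, ref$length, by = width)
    writeLines(substring(ref$sequence, starts,
                         pmin(starts + width - 1L, ref$length)), con)
  }
  invisible(path)
}

catalog_columns <- c("molecule", "position", "residue", "mod_type",
                     "guides", "legacy_position")

new_site_catalog <- function(df) {
  df <- df[order(df$molecule, df$position), , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$molecule, df$position, df$mod_type)
  if (anyDuplicated(key))
    stop("duplicate catalog entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  mods <- unique(df$mod_type)
  modality <- if (length(mods) == 1L) mods else "mixed"
  structure(df, class = c("site_catalog", "data.frame"), modality = modality)
}

#' Build a modification-site catalog from a data frame
#'
#' Validates every site against the reference sequences: positions must be in
#' range, the annotated residue must match the reference (after U/T
#' normalisation) and pseudouridine (`Psi`) sites must sit on a U. Guides are
#' stored as a `;`-separated string; `"Unknown"` and the empty string both
#' mean "no annotated guide" (orphan site).
#'
#' @param df data frame with columns `molecule`, `position`, `residue`,
#'   `mod_type` (`Nm` or `Psi`), and optionally `guides` and
#'   `legacy_position` (old residue numbering, stored as data, never derived
#'   by an offset).
#' @param refs named list of [rna_reference] objects covering every molecule
#'   in `df`.
#' @return a `site_catalog` (data frame sorted by molecule, position, with a
#'   `modality` attribute in `{Nm, Psi, mixed}`).
#' @export
site_catalog <- function(df, refs) {
  stopifnot(is.data.frame(df))
  need <- c("molecule", "position", "residue", "mod_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$guides)) df$guides <- ""
  if (is.null(df$legacy_position)) df$legacy_position <- NA_integer_
  df$molecule <- as.character(df$molecule)
  df$position <- as.integer(df$position)
  df$residue <- gsub("T", "U", toupper(as.character(df$residue)))
  df$mod_type <- as.character(df$mod_type)
  df$guides <- normalize_guides(df$guides)
  df$legacy_position <- suppressWarnings(as.integer(df$legacy_position))
  if (!all(df$mod_type %in% c("Nm", "Psi")))
    stop("mod_type must be 'Nm' or 'Psi'")
  for (k in seq_len(nrow(df))) {
    mol <- df$molecule[k]
    ref <- refs[[mol]]
    if (is.null(ref))
      stop("catalog molecule '", mol, "' not found among references")
    pos <- df$position[k]
    if (is.na(pos) || pos < 1L || pos > ref$length)
      stop("site ", mol, ":", pos, " out of range (reference length ",
           ref$length, ")")
    got <- ref_residue(ref, pos)
    if (got != df$residue[k])
      stop("residue mismatch at ", mol, ":", pos, " - catalog says ",
           df$residue[k], ", reference holds ", got)
    if (df$mod_type[k] == "Psi" && df$residue[k] != "U")
      stop("Psi site on non-U residue at ", mol, ":", pos)
  }
  new_site_catalog(df[catalog_columns])
}

normalize_guides <- function(g) {
  g <- trimws(as.character(g))
  g[is.na(g) | toupper(g) == "UNKNOWN"] <- ""
  g
}

#' Guides of catalog sites as a list
#'
#' @param catalog a `site_catalog`.
#' @return list of character vectors, one per site (empty for orphan sites).
#' @export
guide_list <- function(catalog) {
  lapply(strsplit(catalog$guides, ";", fixed = TRUE),
         function(x) x[nzchar(trimws(x))])
}

#' Read a modification-site catalog from TSV
#'
#' Expected header: `molecule  position  residue  mod_type  guides
#' legacy_position` (tab-separated; `legacy_position` may be blank). The
#' catalog is validated against `refs`, see [site_catalog()].
#'
#' @param path TSV file.
#' @param refs named list of [rna_reference] objects.
#' @return a `site_catalog`.
#' @export
read_site_catalog <- function(path, refs) {
  if (!file.exists(path)) stop("site catalog not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", comment.char = "#",
                          stringsAsFactors = FALSE)
  site_catalog(df, refs)
}

#' Write a site catalog to TSV
#'
#' Emits the same dialect that [read_site_catalog()] consumes (round-trip up
#' to column order and whitespace).
#'
#' @param catalog a `site_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)[catalog_columns]
  df$legacy_position <- ifelse(is.na(df$legacy_position), "",
                               as.character(df$legacy_position))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up a site by its legacy (old-nomenclature) position
#'
#' Legacy numbering is stored per site and only looked up, never computed:
#' the old/new offset varies along a molecule (e.g. 28S Am2401 was Am2388
#' but Gm4042 was Gm4020).
#'
#' @param catalog a `site_catalog`.
#' @param molecule molecule name.
#' @param legacy_position old-nomenclature 1-based position.
#' @return the matching catalog row (one-row data frame).
#' @export
legacy_lookup <- function(catalog, molecule, legacy_position) {
  hit <- which(catalog$molecule == molecule &
               !is.na(catalog$legacy_position) &
               catalog$legacy_position == as.integer(legacy_position))
  if (length(hit) == 0L)
    stop("no site with legacy position ", legacy_position, " on ", molecule)
  if (length(hit) > 1L)
    stop("ambiguous legacy position ", legacy_position, " on ", molecule)
  as.data.frame(catalog)[hit, , drop = FALSE]
}

#' Subset a catalog by modification type
#'
#' @param catalog a `site_catalog`.
#' @param mod_type `"Nm"` or `"Psi"`.
#' @return a `site_catalog` with the matching sites.
#' @export
catalog_subset <- function(catalog, mod_type) {
  new_site_catalog(as.data.frame(catalog)[catalog$mod_type == mod_type, ,
                                          drop = FALSE])
}
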