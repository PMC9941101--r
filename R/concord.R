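# snoRNA guide concordance: does the expression change of a site's guide
# snoRNA(s) parallel the site's modification change?

#' Read a guide snoRNA differential-expression table
#'
#' Consumed as an external results export (e.g. a DESeq2 table or qPCR
#' summary); never computed here. Expected TSV columns: `snorna`, `log2fc`,
#' `padj`, `source` (`smallRNAseq` or `qPCR`; defaults to `smallRNAseq` if
#' absent).
#'
#' @param path TSV path.
#' @return data frame with those four columns.
#' @export
read_guide_de <- function(path) {
  if (!file.exists(path)) stop("guide DE table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  guide_de_table(df)
}

#' Validate a guide DE table
#'
#' @param df data frame with columns `snorna`, `log2fc`, `padj` and
#'   optionally `source`.
#' @return the validated data frame.
#' @export
guide_de_table <- function(df) {
  miss <- setdiff(c("snorna", "log2fc", "padj"), names(df))
  if (length(miss)) stop("guide DE table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$source)) df$source <- "smallRNAseq"
  key <- paste(df$snorna, df$source)
  if (anyDuplicated(key))
    stop("duplicate snoRNA id(s) within a source: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  ok <- is.na(df$padj) | (df$padj >= 0 & df$padj <= 1)
  if (!all(ok)) stop("padj outside [0,1]")
  df[c("snorna", "log2fc", "padj", "source")]
}

# Direction call for one guide across evidence sources. Default ("any")
# mode: any significant source contributes its sign; sources that
# significantly disagree cancel to "none". Strict mode additionally requires
# all sources with data to agree in sign.
guide_direction <- function(de, id, fc_threshold, sig_threshold, strict) {
  rows <- de[de$snorna == id, , drop = FALSE]
  if (nrow(rows) == 0L) return(list(direction = "none", significant = FALSE))
  sig <- !is.na(rows$padj) & rows$padj <= sig_threshold &
    abs(rows$log2fc) > fc_threshold
  if (!any(sig)) return(list(direction = "none", significant = FALSE))
  signs <- unique(sign(rows$log2fc[sig]))
  if (length(signs) > 1L) return(list(direction = "none", significant = FALSE))
  if (strict) {
    all_signs <- unique(sign(rows$log2fc[rows$log2fc != 0]))
    if (length(all_signs) > 1L)
      return(list(direction = "none", significant = FALSE))
  }
  list(direction = if (signs > 0) "up" else "down", significant = TRUE)
}

#' Classify site/guide direction concordance
#'
#' For each differential site, joins its annotated guide snoRNAs with the DE
#' table and assigns exactly one verdict:
#' \describe{
#'   \item{site_unchanged}{the site's modification direction is `none`.}
#'   \item{no_guide}{the site has no annotated guide (orphan).}
#'   \item{concordant}{at least one guide changes significantly in the
#'     site's direction and none significantly opposes it.}
#'   \item{partial}{significant guides disagree with each other.}
#'   \item{discordant}{no significant guide change supports the site's
#'     direction (all significant guides oppose it, or none is significant).}
#' }
#' Guides missing from the DE table degrade to direction `none`.
#'
#' @param diff a [diff_table()] result.
#' @param de a guide DE table ([read_guide_de()] / [guide_de_table()]).
#' @param catalog the `site_catalog` carrying guide annotations.
#' @param fc_threshold minimum `|log2fc|` (exclusive) for a guide to count
#'   as changed; 0 by default (direction is read, not magnitude).
#' @param sig_threshold adjusted-p cutoff for guide significance.
#' @param strict require all evidence sources for a guide to agree in sign.
#' @return data frame with one row per site: site key, `site_direction`,
#'   `guides`, per-guide call summary `guide_calls`
#'   (`id:direction[:sig]` joined by `;`), and `verdict`.
#' @export
classify_concordance <- function(diff, de, catalog, fc_threshold = 0,
                                 sig_threshold = 0.05, strict = FALSE) {
  de <- guide_de_table(de)
  gl <- guide_list(catalog)
  ckey <- paste(catalog$molecule, catalog$position, catalog$mod_type)
  rows <- list()
  for (k in seq_len(nrow(diff))) {
    key <- paste(diff$molecule[k], diff$position[k], diff$mod_type[k])
    guides <- gl[[match(key, ckey)]]
    if (is.null(guides)) guides <- character(0)
    site_dir <- diff$direction[k]
    calls <- lapply(guides, guide_direction, de = de,
                    fc_threshold = fc_threshold,
                    sig_threshold = sig_threshold, strict = strict)
    dirs <- vapply(calls, `[[`, character(1), "direction")
    sig <- vapply(calls, `[[`, logical(1), "significant")
    sig_dirs <- unique(dirs[sig])
    verdict <- if (length(guides) == 0L) "no_guide"
      else if (site_dir == "none") "site_unchanged"
      else if (length(sig_dirs) > 1L) "partial"
      else if (length(sig_dirs) == 1L && sig_dirs == site_dir) "concordant"
      else "discordant"
    rows[[k]] <- data.frame(
      molecule = diff$molecule[k], position = diff$position[k],
      mod_type = diff$mod_type[k], site_direction = site_dir,
      delta = diff$delta[k],
      guides = paste(guides, collapse = ";"),
      guide_calls = paste(sprintf("%s:%s%s", guides, dirs,
                                  ifelse(sig, ":sig", "")), collapse = ";"),
      verdict = verdict, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally concordance verdicts
#'
#' @param calls a [classify_concordance()] result.
#' @return data frame with one row per verdict (fixed order) and a `count`
#'   column; counts sum to `nrow(calls)`.
#' @export
concordance_summary <- function(calls) {
  levels <- c("concordant", "discordant", "partial", "no_guide",
              "site_unchanged")
  n <- if (is.null(calls) || nrow(calls) == 0L) integer(length(levels)) else
    vapply(levels, function(v) sum(calls$verdict == v), integer(1))
  data.frame(verdict = levels, count = as.integer(n))
}
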