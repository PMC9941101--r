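# File-backed interchange: end-count profiles, score tables, BEDGraph export.
# All tables are plain TSV with '#'-prefixed header comments so every stage
# of the pipeline can be re-loaded individually.

#' Write an end-count profile to TSV
#'
#' Dialect: `#`-prefixed metadata lines (`molecule`, `protocol`,
#' `replicate_id`, `seed`) followed by a header `position  count5  count3`.
#' Lossless round trip with [read_profile()].
#'
#' @param profile an [end_count_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "end_count_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# molecule: ", profile$molecule),
               paste0("# protocol: ", profile$protocol),
               paste0("# replicate_id: ", profile$replicate_id),
               paste0("# seed: ", profile$seed),
               "position\tcount5\tcount3"), con)
  utils::write.table(data.frame(position = seq_along(profile$counts5),
                                count5 = profile$counts5,
                                count3 = profile$counts3),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

profile_meta <- function(lines, key) {
  pat <- paste0("^#\\s*", key, ":\\s*")
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  trimws(sub(pat, "", hit[1]))
}

#' Read an end-count profile from TSV
#'
#' @param path a file written by [write_profile()].
#' @return an [end_count_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile not found: ", path)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  molecule <- profile_meta(meta, "molecule")
  protocol <- profile_meta(meta, "protocol")
  replicate_id <- profile_meta(meta, "replicate_id")
  seed <- suppressWarnings(as.integer(profile_meta(meta, "seed")))
  if (is.na(molecule) || is.na(protocol))
    stop("profile ", path, " lacks molecule/protocol metadata")
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("empty profile (L = 0): ", path)
  df <- utils::read.delim(text = body, sep = "\t", header = TRUE)
  if (!identical(names(df), c("position", "count5", "count3")))
    stop("malformed profile header in ", path)
  if (anyNA(df$count5) || anyNA(df$count3))
    stop("malformed counts in ", path)
  if (any(df$count5 < 0) || any(df$count3 < 0))
    stop("negative counts in ", path)
  if (!identical(as.integer(df$position), seq_len(nrow(df))))
    stop("positions in ", path, " are not contiguous 1..L")
  end_count_profile(molecule, df$count5, df$count3, replicate_id,
                    protocol, seed = seed)
}

#' Export one end-count channel as BEDGraph
#'
#' Note the coordinate change: this writer alone converts the package's
#' 1-based inclusive positions to BEDGraph's 0-based half-open intervals.
#' Zero-count positions are omitted, as usual for sparse tracks.
#'
#' @param profile an [end_count_profile()].
#' @param path output path.
#' @param channel `"counts5"` or `"counts3"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, channel = c("counts5", "counts3")) {
  channel <- match.arg(channel)
  v <- profile[[channel]]
  keep <- which(v > 0L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s_%s_%s\"",
                     profile$molecule, profile$replicate_id, channel), con)
  if (length(keep))
    writeLines(sprintf("%s\t%d\t%d\t%d", profile$molecule, keep - 1L, keep,
                       v[keep]), con)
  invisible(path)
}

#' Write a score table to TSV
#'
#' @param scores a score table data frame (see [score_catalog_rms()] /
#'   [score_catalog_psi()]).
#' @param path output path.
#' @param metadata named character vector written as `# key: value` comments
#'   (used to record the formula variant, background mode, end offset, seed).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(metadata))
    writeLines(paste0("# ", names(metadata), ": ", unname(metadata)), con)
  utils::write.table(scores, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_score_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
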