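# Differential modification between conditions: paired t-test per site on
# replicate-level scores, with the affected (> 0.05) and heatmap (>= 0.1)
# delta thresholds and raw-p significance stars.

#' Paired Student's t-test from the closed form
#'
#' Computed directly on the within-pair differences `d = alt - ref`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`, two-sided p from the t
#' distribution. Degenerate cases follow fixed conventions: all differences
#' exactly zero gives `p = 1`; zero variance with a nonzero mean difference
#' is reported as the 0-limit (`p = 0`) with `degenerate = TRUE`.
#'
#' @param scores_ref,scores_alt equal-length numeric vectors, paired by
#'   index (replicate label).
#' @return list with `t`, `p`, `df`, `mean_diff` and `degenerate` flag.
#' @export
paired_t <- function(scores_ref, scores_alt) {
  if (length(scores_ref) != length(scores_alt))
    stop("paired vectors must have equal length")
  n <- length(scores_ref)
  if (n < 2L) stop("paired t-test needs n >= 2")
  d <- scores_alt - scores_ref
  if (anyNA(d)) stop("paired t-test on incomplete pairs")
  m <- mean(d); s <- stats::sd(d)
  # guard against floating-point dust in exactly-constant differences
  if (s <= 1e-10 * max(1, abs(m))) {
    if (abs(m) <= 1e-10)
      return(list(t = 0, p = 1, df = n - 1L, mean_diff = 0,
                  degenerate = FALSE))
    return(list(t = sign(m) * Inf, p = 0, df = n - 1L, mean_diff = m,
                degenerate = TRUE))
  }
  tstat <- m / (s / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1L),
       df = n - 1L, mean_diff = m, degenerate = FALSE)
}

#' Significance stars for raw p-values
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, else `ns`.
#'
#' @param p numeric vector of p-values.
#' @return character vector of stars.
#' @export
stars_for_p <- function(p) {
  ifelse(is.na(p), "ns",
  ifelse(p <= 0.001, "***",
  ifelse(p <= 0.01, "**",
  ifelse(p <= 0.05, "*", "ns"))))
}

#' Combine per-condition score tables into one long table
#'
#' @param tables named list of score tables (names are condition labels; the
#'   first is conventionally the reference condition).
#' @return one data frame with a `condition` column.
#' @export
combine_score_tables <- function(tables) {
  stopifnot(length(tables) >= 1L, !is.null(names(tables)),
            all(nzchar(names(tables))))
  do.call(rbind, lapply(names(tables), function(cn) {
    df <- tables[[cn]]
    df$condition <- cn
    df
  }))
}

#' Per-site differential modification table
#'
#' For every site with at least 2 complete replicate pairs: condition means
#' over defined replicates, `delta = mean_alt - mean_ref`, a paired t-test
#' on the replicate-label-aligned pairs, raw-p stars, and the two delta
#' thresholds: `affected` (strictly `|delta| > affected_threshold`) and
#' `heatmap_eligible` (`|delta| >= heatmap_threshold`). `direction` is the
#' sign of `delta` when affected, else `"none"`. A Benjamini-Hochberg column
#' `p_bh` is emitted for reference but never drives the calls. Sites with
#' exactly 2 pairs run at df = 1 and are flagged `low_power`.
#'
#' @param scores long score table with columns `molecule`, `position`,
#'   `mod_type`, `replicate`, `score`, `condition` (see
#'   [combine_score_tables()]).
#' @param ref_condition,alt_condition condition labels to contrast.
#' @param affected_threshold minimum `|delta|` (exclusive) for `affected`.
#' @param heatmap_threshold minimum `|delta|` (inclusive) for heatmap
#'   eligibility.
#' @return data frame with one row per testable site.
#' @export
diff_table <- function(scores, ref_condition, alt_condition,
                       affected_threshold = 0.05, heatmap_threshold = 0.1) {
  need <- c("molecule", "position", "mod_type", "replicate", "score",
            "condition")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("score table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (cn in c(ref_condition, alt_condition))
    if (!cn %in% scores$condition)
      stop("condition '", cn, "' absent from score table")
  key <- unique(scores[c("molecule", "position", "mod_type")])
  key <- key[order(key$molecule, key$position, key$mod_type), , drop = FALSE]
  rows <- list(); skipped <- character(0)
  for (k in seq_len(nrow(key))) {
    sel <- scores$molecule == key$molecule[k] &
      scores$position == key$position[k] &
      scores$mod_type == key$mod_type[k]
    sref <- scores[sel & scores$condition == ref_condition, ]
    salt <- scores[sel & scores$condition == alt_condition, ]
    xr <- stats::setNames(sref$score, sref$replicate)
    xa <- stats::setNames(salt$score, salt$replicate)
    common <- intersect(names(xr)[!is.na(xr)], names(xa)[!is.na(xa)])
    if (length(common) < 2L) {
      skipped <- c(skipped, paste0(key$molecule[k], ":", key$position[k]))
      next
    }
    tt <- paired_t(xr[common], xa[common])
    mean_ref <- mean(xr, na.rm = TRUE)
    mean_alt <- mean(xa, na.rm = TRUE)
    delta <- mean_alt - mean_ref
    affected <- abs(delta) > affected_threshold
    rows[[length(rows) + 1L]] <- data.frame(
      molecule = key$molecule[k], position = key$position[k],
      mod_type = key$mod_type[k],
      mean_ref = mean_ref, mean_alt = mean_alt, delta = delta,
      t = tt$t, p_raw = tt$p, df = tt$df,
      degenerate = tt$degenerate,
      low_power = length(common) == 2L,
      affected = affected,
      heatmap_eligible = abs(delta) >= heatmap_threshold,
      direction = if (!affected) "none" else if (delta > 0) "up" else "down",
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("site(s) skipped (< 2 complete replicate pairs): ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_bh <- stats::p.adjust(out$p_raw, method = "BH")
  out$stars <- stars_for_p(out$p_raw)
  rownames(out) <- NULL
  out
}

#' Delta matrix for heatmap export
#'
#' Rows are sites that are heatmap-eligible (|delta| >= 0.1 by default) in at
#' least one comparison; values are the deltas; column order follows the
#' order of `diffs`.
#'
#' @param diffs named list of [diff_table()] results (names label the
#'   comparisons).
#' @return data frame with `molecule`, `position`, `mod_type` and one delta
#'   column per comparison (possibly zero rows).
#' @export
heatmap_matrix <- function(diffs) {
  stopifnot(length(diffs) >= 1L, !is.null(names(diffs)))
  keys <- unique(do.call(rbind, lapply(diffs, function(d)
    d[d$heatmap_eligible, c("molecule", "position", "mod_type"),
      drop = FALSE])))
  keys <- keys[order(keys$molecule, keys$position), , drop = FALSE]
  rownames(keys) <- NULL
  for (cmp in names(diffs)) {
    d <- diffs[[cmp]]
    idx <- match(paste(keys$molecule, keys$position, keys$mod_type),
                 paste(d$molecule, d$position, d$mod_type))
    keys[[cmp]] <- d$delta[idx]
  }
  keys
}

#' Write a differential table (or heatmap matrix) to TSV
#'
#' @param diff data frame from [diff_table()] or [heatmap_matrix()].
#' @param path output path.
#' @param metadata optional named character vector of `# key: value` header
#'   comments.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(diff, path, metadata = NULL) {
  write_score_table(diff, path, metadata = metadata)
}
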