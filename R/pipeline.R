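# Pipeline orchestration: simulate -> score -> diff -> concord from a single
# YAML config, with plain-TSV handoff between stages so every intermediate
# can be inspected and re-loaded on its own.

#' Read a pipeline run configuration
#'
#' YAML with fields: `reference` (FASTA path), `catalog_nm` / `catalog_psi`
#' (site-catalog TSVs), `guide_de` (optional DE table TSV), `conditions`
#' (named list; each condition holds `truth_nm` / `truth_psi` TSV paths with
#' columns `molecule position fraction`), `replicates`, `seed`, `params`
#' (optional per-protocol overrides: `depth`, `base_rate`, `residual`,
#' `bg_rate`, `end_offset`), and `thresholds` (optional: `flank`, `window`,
#' `affected`, `heatmap`, `exclude_self`). Relative paths are resolved
#' against the config file's directory.
#'
#' @param path YAML file.
#' @return config list with absolute paths.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), normalizePath(p), file.path(base, p))
  }
  cfg$reference <- resolve(cfg$reference)
  cfg$catalog_nm <- resolve(cfg$catalog_nm)
  cfg$catalog_psi <- resolve(cfg$catalog_psi)
  cfg$guide_de <- resolve(cfg$guide_de)
  for (cn in names(cfg$conditions)) {
    cfg$conditions[[cn]]$truth_nm <- resolve(cfg$conditions[[cn]]$truth_nm)
    cfg$conditions[[cn]]$truth_psi <- resolve(cfg$conditions[[cn]]$truth_psi)
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  for (p in c(cfg$reference, cfg$catalog_nm, cfg$catalog_psi, cfg$guide_de,
              unlist(lapply(cfg$conditions, function(x)
                c(x$truth_nm, x$truth_psi)))))
    if (!is.null(p) && !file.exists(p)) stop("config file missing: ", p)
  if (length(cfg$conditions) < 2L)
    stop("config needs at least two conditions (reference first)")
  cfg$replicates <- if (is.null(cfg$replicates)) 3L else as.integer(cfg$replicates)
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  th <- cfg$thresholds
  cfg$thresholds <- list(
    flank = if (is.null(th$flank)) 6L else as.integer(th$flank),
    window = if (is.null(th$window)) 10L else as.integer(th$window),
    affected = if (is.null(th$affected)) 0.05 else th$affected,
    heatmap = if (is.null(th$heatmap)) 0.1 else th$heatmap,
    exclude_self = isTRUE(th$exclude_self))
  if (cfg$thresholds$affected <= 0 || cfg$thresholds$heatmap <= 0)
    stop("thresholds must be positive")
  cfg
}

read_truth_tsv <- function(path, mod_type, refs) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  lapply(split(df, df$molecule), function(x)
    truth_profile(x$molecule[1], x$position, x$fraction, mod_type,
                  refs[[x$molecule[1]]]))
}

build_params <- function(cfg, protocol) {
  ov <- cfg$params[[protocol]]
  args <- list(protocol = if (protocol == "rms") "RMS" else "HydraPsi")
  for (k in c("depth", "base_rate", "residual", "bg_rate", "end_offset"))
    if (!is.null(ov[[k]])) args[[k]] <- ov[[k]]
  do.call(protocol_params, args)
}

# Condition c, molecule m, replicate r must each get an independent stream;
# fold them into one master per (condition, molecule) block.
condition_seed <- function(seed, ci, mi, protocol_id) {
  (abs(as.integer(seed)) %% 104729L) * 10007L + ci * 101L + mi * 13L +
    protocol_id
}

#' Run the full simulate / score / diff / concord pipeline
#'
#' Deterministic given the config's master seed. Writes per-condition score
#' tables, differential tables for every non-reference condition against the
#' first (reference) condition, heatmap delta matrices, a concordance report
#' (when a guide DE table is configured) and a run log carrying the package
#' version, seed and a parameter digest.
#'
#' @param config a config list from [read_run_config()] (or a path to the
#'   YAML file).
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  refs <- read_reference(cfg$reference)
  th <- cfg$thresholds
  conds <- names(cfg$conditions)
  score_tabs <- list(Nm = list(), Psi = list())
  meta_common <- c(package = as.character(utils::packageVersion("riboscore")),
                   seed = as.character(cfg$seed),
                   methscore_form = "symmetric-flank-mean",
                   background_mode = if (th$exclude_self) "leave-one-out"
                                     else "plain-rolling-mean")
  for (ci in seq_along(conds)) {
    cn <- conds[ci]
    cond <- cfg$conditions[[cn]]
    if (!is.null(cond$truth_nm)) {
      catalog <- read_site_catalog(cfg$catalog_nm, refs)
      params <- build_params(cfg, "rms")
      truths <- read_truth_tsv(cond$truth_nm, "Nm", refs)
      profiles <- list()
      for (mi in seq_along(truths)) {
        tr <- truths[[mi]]
        profiles <- c(profiles, simulate_rms(
          refs[[tr$molecule]], tr, params, n_replicates = cfg$replicates,
          seed = condition_seed(cfg$seed, ci, mi, 1L)))
      }
      tab <- suppressWarnings(
        score_catalog_rms(profiles, catalog, flank = th$flank))
      score_tabs$Nm[[cn]] <- tab
      write_score_table(tab, file.path(outdir,
                                       paste0("scores_nm_", cn, ".tsv")),
                        metadata = c(meta_common, condition = cn))
    }
    if (!is.null(cond$truth_psi)) {
      catalog <- read_site_catalog(cfg$catalog_psi, refs)
      params <- build_params(cfg, "hydrapsi")
      truths <- read_truth_tsv(cond$truth_psi, "Psi", refs)
      profiles <- list()
      for (mi in seq_along(truths)) {
        tr <- truths[[mi]]
        profiles <- c(profiles, simulate_hydrapsi(
          refs[[tr$molecule]], tr, params, n_replicates = cfg$replicates,
          seed = condition_seed(cfg$seed, ci, mi, 2L)))
      }
      tab <- suppressWarnings(
        score_catalog_psi(profiles, catalog, refs, window = th$window,
                          exclude_self = th$exclude_self,
                          end_offset = params$end_offset))
      score_tabs$Psi[[cn]] <- tab
      write_score_table(tab, file.path(outdir,
                                       paste0("scores_psi_", cn, ".tsv")),
                        metadata = c(meta_common, condition = cn))
    }
  }
  ref_cond <- conds[1]
  diffs <- list()
  for (mod in c("Nm", "Psi")) {
    tabs <- score_tabs[[mod]]
    if (length(tabs) < 2L) next
    long <- combine_score_tables(tabs)
    for (cn in setdiff(names(tabs), ref_cond)) {
      cmp <- paste0(cn, "_vs_", ref_cond)
      d <- suppressWarnings(
        diff_table(long, ref_cond, cn, affected_threshold = th$affected,
                   heatmap_threshold = th$heatmap))
      diffs[[paste(mod, cmp, sep = "_")]] <- d
      write_diff_table(d, file.path(outdir,
                                    paste0("diff_", tolower(mod), "_",
                                           cmp, ".tsv")),
                       metadata = c(meta_common, comparison = cmp))
    }
    hm <- heatmap_matrix(diffs[grep(paste0("^", mod, "_"), names(diffs))])
    write_diff_table(hm, file.path(outdir,
                                   paste0("heatmap_", tolower(mod), ".tsv")),
                     metadata = meta_common)
  }
  if (!is.null(cfg$guide_de) && length(diffs)) {
    de <- read_guide_de(cfg$guide_de)
    cat_all <- rbind(
      if (!is.null(cfg$catalog_nm))
        as.data.frame(read_site_catalog(cfg$catalog_nm, refs)),
      if (!is.null(cfg$catalog_psi))
        as.data.frame(read_site_catalog(cfg$catalog_psi, refs)))
    catalog <- new_site_catalog(cat_all)
    calls <- do.call(rbind, lapply(names(diffs), function(nm) {
      cc <- classify_concordance(diffs[[nm]], de, catalog)
      cc$comparison <- nm
      cc
    }))
    write_score_table(calls, file.path(outdir, "concordance.tsv"),
                      metadata = meta_common)
    write_score_table(concordance_summary(calls),
                      file.path(outdir, "concordance_summary.tsv"),
                      metadata = meta_common)
  }
  cfg_path <- file.path(outdir, "effective_config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  writeLines(c(paste0("riboscore ", utils::packageVersion("riboscore")),
               paste0("seed: ", cfg$seed),
               paste0("config_digest: ", unname(tools::md5sum(cfg_path))),
               paste0("methscore_form: symmetric-flank-mean"),
               paste0("background_mode: ",
                      if (th$exclude_self) "leave-one-out"
                      else "plain-rolling-mean"),
               paste0("finished: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' Path to the packaged demo configuration
#'
#' A complete small run over the packaged synthetic references, catalogs,
#' ground-truth stoichiometries (wild type vs knockout) and guide DE table.
#'
#' @return path to the YAML config inside the installed package.
#' @export
demo_config <- function() {
  system.file("extdata", "demo_config.yaml", package = "riboscore",
              mustWork = TRUE)
}

#' Run the packaged end-to-end demo
#'
#' @param outdir output directory.
#' @param seed master seed override (`NULL` keeps the config's seed).
#' @return `outdir`, invisibly.
#' @export
run_demo <- function(outdir, seed = NULL) {
  cfg <- read_run_config(demo_config())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  run_pipeline(cfg, outdir)
}
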