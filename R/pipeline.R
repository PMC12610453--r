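# End-to-end orchestration: simulate or ingest -> DE per contrast ->
# power/MDES -> target convergence/enrichment -> concordance, under one
# config with a fixed seed and a hashed artifact manifest.

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate a study-shaped panel) or `"files"`
#'   (read Ct table, metadata and layout from disk).
#' @param out_dir output directory for all artifacts.
#' @param seed integer seed driving every source of randomness.
#' @param sim named list of [sim_config()] overrides (synthetic mode).
#' @param ct_path,meta_path,layout_path input files (files mode).
#' @param interactions_path validated-interaction snapshot; in synthetic
#'   mode a synthetic snapshot is generated when NULL. In files mode NULL
#'   skips the targets stage with a warning.
#' @param term_map_path gene-to-term mapping for over-representation;
#'   same conventions as `interactions_path`.
#' @param external_de_path external DE table for concordance; same
#'   conventions.
#' @param lfc_threshold,fdr_threshold significance thresholds (1, 0.05).
#' @param base_alpha familywise level for the power stage (0.05).
#' @param power_levels required power levels (c(0.80, 0.90)).
#' @param pi0_method `"fixed"` or `"smoother"`.
#' @param top_k ranking depth for convergence/enrichment displays (20).
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), out_dir, seed = 1L,
                       sim = list(), ct_path = NULL, meta_path = NULL,
                       layout_path = NULL, interactions_path = NULL,
                       term_map_path = NULL, external_de_path = NULL,
                       lfc_threshold = 1, fdr_threshold = 0.05,
                       base_alpha = 0.05, power_levels = c(0.80, 0.90),
                       pi0_method = "fixed", top_k = 20,
                       log_level = c("info", "quiet")) {
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  stopifnot(lfc_threshold > 0, fdr_threshold > 0)
  if (mode == "files") {
    for (p in c(ct_path, meta_path, layout_path))
      if (!is.null(p) && !file.exists(p)) stop("input not found: ", p)
    if (is.null(ct_path) || is.null(meta_path))
      stop("files mode needs ct_path and meta_path")
  }
  structure(list(
    mode = mode, out_dir = out_dir, seed = as.integer(seed), sim = sim,
    ct_path = ct_path, meta_path = meta_path, layout_path = layout_path,
    interactions_path = interactions_path,
    term_map_path = term_map_path, external_de_path = external_de_path,
    lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold,
    base_alpha = base_alpha, power_levels = power_levels,
    pi0_method = pi0_method, top_k = top_k, log_level = log_level),
    class = "run_config")
}

#' Read a run configuration from a JSON file
#' @param path JSON file whose keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

pipe_log <- function(cfg, ...) {
  if (cfg$log_level != "quiet")
    message(sprintf("[mirpanel %s] ", format(Sys.time(), "%H:%M:%S")), ...)
}

run_stage <- function(cfg, stage, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  pipe_log(cfg, "stage ", stage, " done in ",
           sprintf("%.2fs", as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full pipeline
#'
#' Executes both study contrasts (cancer vs healthy; POLE-mutant vs
#' wild-type strictly within cancer samples), then the power/MDES stage,
#' per-direction target convergence and over-representation, and
#' cross-platform concordance when an external table is available. All
#' artifacts are written as TSV under `config$out_dir` together with a
#' manifest listing each file and its MD5 hash; an identical config and
#' seed reproduces identical hashes.
#'
#' @param config a [run_config()].
#' @return data.frame manifest (artifact, path, md5), invisibly written
#'   to `manifest.tsv` as well.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  set.seed(cfg$seed)

  dat <- run_stage(cfg, "input", {
    if (cfg$mode == "synthetic") {
      sim_args <- cfg$sim
      sim_args$seed <- cfg$seed
      sim <- do.call(sim_config, sim_args)
      simulate_panel(sim)
    } else {
      layout <- if (!is.null(cfg$layout_path))
        read_panel_layout(cfg$layout_path) else default_panel_layout()
      list(ct = read_ct_table(cfg$ct_path, layout),
           meta = read_sample_metadata(cfg$meta_path))
    }
  })
  extra <- setdiff(c(dat$ct$sample_ids, dat$meta$sample_id),
                   intersect(dat$ct$sample_ids, dat$meta$sample_id))
  if (length(extra))
    stop("Ct table and metadata sample ids disagree: ",
         paste(extra, collapse = ", "))

  dct <- run_stage(cfg, "normalize", normalize_delta_ct(dat$ct))

  contrasts <- list(study_contrast(dat$meta, "cancer_vs_healthy"))
  n_mut <- sum(dat$meta$pole_status == "mutant")
  n_wt <- sum(dat$meta$pole_status == "wildtype")
  if (n_mut >= 2 && n_wt >= 2) {
    contrasts <- c(contrasts, list(study_contrast(dat$meta, "pole")))
  } else {
    warning("POLE contrast skipped: fewer than 2 samples per POLE group")
  }

  de_tables <- run_stage(cfg, "diffexpr", lapply(contrasts, function(ctr)
    run_contrast(dct, ctr, cfg$lfc_threshold, cfg$fdr_threshold)))
  names(de_tables) <- paste0("de_", vapply(contrasts, `[[`, "", "name"))

  pw <- run_stage(cfg, "power", mdes_report(
    dct, de_tables, contrasts, base_alpha = cfg$base_alpha,
    power_levels = cfg$power_levels, pi0_method = cfg$pi0_method))

  out <- de_tables
  out$mdes <- pw$mdes
  out$power_curves <- pw$curves

  # targets stage: snapshot from disk, or synthesized in synthetic mode
  de_ch <- de_tables[[1L]]
  up <- de_ch$mirna[de_ch$significant & de_ch$log2_fold_reg > 0]
  down <- de_ch$mirna[de_ch$significant & de_ch$log2_fold_reg < 0]
  interactions <- NULL
  if (!is.null(cfg$interactions_path)) {
    if (file.exists(cfg$interactions_path)) {
      interactions <- run_stage(cfg, "targets-load",
                                load_interactions(cfg$interactions_path))
    } else {
      warning("interaction snapshot not found (", cfg$interactions_path,
              "); targets stage skipped")
    }
  } else if (cfg$mode == "synthetic") {
    pool <- sprintf("GENE%03d", 1:60)
    interactions <- interaction_table(simulate_interactions(
      dct$target_assay_ids, pool, seed = cfg$seed + 1L))
  }
  if (!is.null(interactions)) {
    run_stage(cfg, "targets", {
      out$convergence_up <- convergence_counts(interactions, up, "up",
                                               cfg$top_k)
      out$convergence_down <- convergence_counts(interactions, down,
                                                 "down", cfg$top_k)
      universe <- target_universe(interactions, c(up, down))
      term_map <- if (!is.null(cfg$term_map_path) &&
                      file.exists(cfg$term_map_path)) {
        read_delim_auto(cfg$term_map_path)
      } else if (cfg$mode == "synthetic" && length(universe)) {
        simulate_term_map(universe, seed = cfg$seed + 2L)
      }
      if (!is.null(term_map) && length(universe)) {
        for (dir in c("up", "down")) {
          set <- intersect(target_universe(interactions,
                                           if (dir == "up") up else down),
                           universe)
          out[[paste0("enrichment_", dir)]] <-
            hypergeom_enrich(set, term_map, universe)
        }
      }
      NULL
    })
  }

  ext <- NULL
  if (!is.null(cfg$external_de_path)) {
    if (file.exists(cfg$external_de_path)) {
      ext <- read_external_de(cfg$external_de_path)
    } else {
      warning("external DE table not found (", cfg$external_de_path,
              "); concordance stage skipped")
    }
  } else if (cfg$mode == "synthetic") {
    ext <- external_de(simulate_external_de(de_ch, seed = cfg$seed + 3L))
  }
  if (!is.null(ext)) {
    run_stage(cfg, "concordance", {
      cr <- concordance_report(de_ch, ext, cfg$lfc_threshold,
                               cfg$fdr_threshold)
      out$concordance_pairs <- cr$pairs
      out$concordance_summary <- cr$summary
      NULL
    })
  }

  paths <- run_stage(cfg, "write", write_results(out, cfg$out_dir))
  manifest <- data.frame(
    artifact = names(paths), path = unname(paths),
    md5 = unname(tools::md5sum(unname(paths))), seed = cfg$seed,
    stringsAsFactors = FALSE)
  write_delim_auto(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  pipe_log(cfg, "wrote ", nrow(manifest), " artifacts to ", cfg$out_dir)
  manifest
}
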