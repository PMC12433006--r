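#' Read and validate a pipeline configuration
#'
#' The configuration is a single declarative JSON file with nested blocks
#' `simulate`, `predict`, `design`, `validate` plus top-level `seed`,
#' `outdir` and `log_level`. Unknown keys are rejected. Relative paths are
#' resolved against the config file's directory.
#'
#' @param path Path to a JSON configuration file, or an equivalent named
#'   list.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) {
    base <- dirname(path)
    out <- jsonlite::read_json(path, simplifyVector = TRUE)
    attr(out, "base_dir") <- base
    out
  } else path
  allowed <- c("seed", "outdir", "log_level", "simulate", "predict",
               "design", "validate")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  .check_block(cfg$simulate, c(names(formals(simulation_config))), "simulate")
  .check_block(cfg$predict, c("manifest", "islands", "params"), "predict")
  .check_block(cfg$predict$params, names(formals(prediction_config)),
               "predict.params")
  .check_block(cfg$design, c("reference", "strand", "max_regions", "params"),
               "design")
  .check_block(cfg$design$params, names(formals(design_constraints)),
               "design.params")
  .check_block(cfg$validate, c("ct_table", "manifest", "censor_value"),
               "validate")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$outdir)) cfg$outdir <- "nanomsp_out"
  base <- attr(cfg, "base_dir")
  if (!is.null(base) && nzchar(base) && base != ".") {
    fix <- function(p) if (!is.null(p) && !grepl("^(/|~)", p))
      file.path(base, p) else p
    cfg$predict$manifest <- fix(cfg$predict$manifest)
    cfg$predict$islands <- fix(cfg$predict$islands)
    cfg$design$reference <- fix(cfg$design$reference)
    cfg$validate$ct_table <- fix(cfg$validate$ct_table)
    cfg$validate$manifest <- fix(cfg$validate$manifest)
    if (!grepl("^(/|~)", cfg$outdir)) cfg$outdir <- file.path(base, cfg$outdir)
  }
  structure(cfg, class = "pipeline_config")
}

.check_block <- function(block, allowed, what) {
  if (is.null(block)) return(invisible())
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    .stopf("unknown key(s) in config block '%s': %s", what,
           paste(unknown, collapse = ", "))
  invisible()
}

.stage_fail <- function(stage, e) {
  stop(structure(class = c("nanomsp_stage_error", "error", "condition"),
                 list(message = sprintf("stage %s: %s", stage,
                                        conditionMessage(e)),
                      call = NULL, stage = stage)))
}

#' Run the full discovery pipeline
#'
#' Executes, in order: `simulate` (optional; generates every downstream
#' input), `predict` (region calling), `design` (primer and probe design
#' for the selected regions) and `validate` (marker statistics from the CT
#' table). Artifacts are written to the configured output directory:
#' `regions.bed`, `predict_report.json`, `primers.tsv`, `probes.tsv`,
#' `markers.tsv`, the exact configuration used (`config.json`) and a
#' machine-readable `run_manifest.json` with package version, seed and
#' per-stage counts. Runs are idempotent given identical configuration and
#' seed. A failing stage aborts with an error naming the stage.
#'
#' @param config Path to a JSON config file or a configuration list (see
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with `artifacts` (paths), `report` (per-stage
#'   counts), `regions`, `pairs`, `markers`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  artifacts <- list(config = file.path(outdir, "config.json"))
  jsonlite::write_json(unclass(cfg), artifacts$config, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  manifest_path <- cfg$predict$manifest
  islands_path <- cfg$predict$islands
  reference_path <- cfg$design$reference
  ct_path <- cfg$validate$ct_table
  ct_manifest_path <- cfg$validate$manifest

  if (!is.null(cfg$simulate)) {
    sim <- tryCatch({
      sim_cfg <- do.call(simulation_config, cfg$simulate)
      simulate_msp_dataset(file.path(outdir, "simulated"), sim_cfg,
                           seed = cfg$seed)
    }, error = function(e) .stage_fail("simulate", e))
    if (is.null(manifest_path)) manifest_path <- sim$paths$manifest
    if (is.null(islands_path)) islands_path <- sim$paths$islands
    if (is.null(reference_path)) reference_path <- sim$paths$reference
    if (is.null(ct_path)) ct_path <- sim$paths$ct_table
    if (is.null(ct_manifest_path)) ct_manifest_path <- sim$paths$manifest
    counts$simulate <- list(n_islands = nrow(sim$reference$islands),
                            n_dm_islands = sum(sim$reference$islands$dm),
                            n_samples = nrow(sim$bedmethyl$manifest))
  }

  pred <- tryCatch({
    if (is.null(manifest_path)) .stopf("no manifest configured")
    manifest <- read_sample_manifest(manifest_path)
    islands <- if (!is.null(islands_path)) read_bed_intervals(islands_path)
    pcfg <- do.call(prediction_config,
                    as.list(cfg$predict$params %||% list()))
    predict_msp_regions(manifest, pcfg, islands = islands)
  }, error = function(e) .stage_fail("predict", e))
  artifacts$regions <- file.path(outdir, "regions.bed")
  write_regions_bed(pred$regions, artifacts$regions)
  artifacts$predict_report <- file.path(outdir, "predict_report.json")
  jsonlite::write_json(pred$report, artifacts$predict_report,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  counts$predict <- pred$report

  des <- tryCatch({
    if (is.null(reference_path)) .stopf("no reference configured")
    if (!file.exists(reference_path))
      .stopf("reference FASTA not found: %s", reference_path)
    dcfg <- do.call(design_constraints, as.list(cfg$design$params %||% list()))
    max_regions <- cfg$design$max_regions %||% 10L
    strand <- cfg$design$strand %||% "OT"
    regions <- utils::head(pred$regions[order(-pred$regions$score), ,
                                        drop = FALSE], max_regions)
    pair_rows <- list(); probe_rows <- list()
    for (i in seq_len(nrow(regions))) {
      pairs <- design_primer_pairs(regions[i, ], reference_path, dcfg, strand)
      if (!nrow(pairs)) next
      top <- pairs[1, ]
      top$region_id <- sprintf("region_%d", i)
      pair_rows[[length(pair_rows) + 1L]] <- top
      probes <- design_probe(top, attr(pairs, "template"), dcfg)
      if (nrow(probes)) {
        pr <- probes[1, ]
        pr$region_id <- sprintf("region_%d", i)
        probe_rows[[length(probe_rows) + 1L]] <- pr
      }
    }
    list(pairs = if (length(pair_rows)) do.call(rbind, pair_rows)
                 else .empty_pairs(),
         probes = if (length(probe_rows)) do.call(rbind, probe_rows)
                  else NULL)
  }, error = function(e) .stage_fail("design", e))
  artifacts$primers <- file.path(outdir, "primers.tsv")
  write.table(des$pairs, artifacts$primers, sep = "\t", quote = FALSE,
              row.names = FALSE)
  artifacts$probes <- file.path(outdir, "probes.tsv")
  if (!is.null(des$probes))
    write.table(des$probes, artifacts$probes, sep = "\t", quote = FALSE,
                row.names = FALSE)
  else file.create(artifacts$probes)
  counts$design <- list(n_regions_attempted = min(nrow(pred$regions),
                                                  cfg$design$max_regions %||% 10L),
                        n_pairs = nrow(des$pairs),
                        n_probes = if (is.null(des$probes)) 0L
                                   else nrow(des$probes))

  markers <- tryCatch({
    if (is.null(ct_path)) .stopf("no CT table configured")
    ct <- read_ct_table(ct_path)
    man <- read_sample_manifest(ct_manifest_path %||% manifest_path)
    delta <- compute_delta_ct(ct, man,
                              censor_value = cfg$validate$censor_value %||% 43)
    summarize_markers(delta)
  }, error = function(e) .stage_fail("validate", e))
  artifacts$markers <- file.path(outdir, "markers.tsv")
  write.table(markers, artifacts$markers, sep = "\t", quote = FALSE,
              row.names = FALSE)
  counts$validate <- list(n_markers = nrow(markers),
                          n_significant_adj05 = sum(markers$p_adj < 0.05))

  artifacts$run_manifest <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(
    list(package = "nanomsp",
         version = as.character(packageVersion("nanomsp")),
         seed = cfg$seed, stages = counts),
    artifacts$run_manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(artifacts = artifacts, report = counts,
                 regions = pred$regions, pairs = des$pairs,
                 markers = markers))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
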