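#' Run configuration
#'
#' Validated bundle of every tunable of an end-to-end run, with the
#' screen's working values as defaults: threshold multiplier `k = 12`,
#' bead-count floor `min_events = 32`, expression significance
#' `alpha = 0.05`, abundance boundary `ratio_cut = 2` (twofold), homology
#' boundary `evalue_cut = 1`. Round-trips losslessly through YAML.
#'
#' @param input_dir directory holding the standard input files (as written
#'   by [write_dataset()]).
#' @param output_dir directory for run outputs.
#' @param k,min_events,alpha,ratio_cut,evalue_cut,coupling_floor analysis
#'   parameters.
#' @param seed integer seed recorded in the run manifest (and used by
#'   [pipeline_simulate()]).
#' @param structure_dir optional directory of predicted models named
#'   `<gpcr_id>.pdb`; when absent the antigen stage is skipped.
#' @return list of class `sba_run_config`.
#' @export
sba_run_config <- function(input_dir = "data", output_dir = "results",
                           k = 12, min_events = 32, alpha = 0.05,
                           ratio_cut = 2.0, evalue_cut = 1.0,
                           coupling_floor = 1000, seed = 1L,
                           structure_dir = NULL) {
  cfg <- list(input_dir = input_dir, output_dir = output_dir, k = k,
              min_events = min_events, alpha = alpha, ratio_cut = ratio_cut,
              evalue_cut = evalue_cut, coupling_floor = coupling_floor,
              seed = as.integer(seed), structure_dir = structure_dir)
  if (cfg$k <= 0) sba_stop("k must be positive", "sba_config_error")
  for (nm in c("alpha", "ratio_cut", "evalue_cut"))
    if (cfg[[nm]] <= 0) sba_stop(paste0(nm, " must be positive"),
                                 "sba_config_error")
  class(cfg) <- "sba_run_config"
  cfg
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(sba_run_config, y)
}

#' @rdname read_run_config
#' @param config an [sba_run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null,
                                           logical(1))], path)
  invisible(config)
}

#' Simulate a dataset from a run configuration
#'
#' Wraps [generate_dataset()] with the config's seed and writes the
#' standard input files (including the ground-truth ledger) to
#' `input_dir`.
#'
#' @param config an [sba_run_config()].
#' @param sim_config optional [sba_sim_config()]; by default one is built
#'   from the run config's seed.
#' @return the `sba_dataset`, invisibly; the truth-ledger path is printed.
#' @export
pipeline_simulate <- function(config, sim_config = NULL) {
  sim_config <- sim_config %||% sba_sim_config(seed = config$seed)
  ds <- generate_dataset(sim_config, dir = config$input_dir)
  message("truth ledger: ", file.path(config$input_dir, "truth.json"))
  invisible(ds)
}

#' Run the full analysis pipeline
#'
#' Executes QC (bead counts, coupling), expression assessment, the
#' selectivity fit and threshold sweep, cross-reactivity deconvolution,
#' paired-antibody agreement and (when structures are available) the
#' antigen stage, writing every standard table plus a JSON run manifest
#' (package version, config hash, seed) and a plain-text log that records
#' every masked well, excluded bead and skipped pair.
#'
#' @param config an [sba_run_config()].
#' @return list of class `sba_run` with all stage results, invisibly.
#' @export
pipeline_run <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$output_dir, "run.log")
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  ds <- read_dataset(config$input_dir)
  vio <- validate_panel(ds$antibodies, ds$samples, ds$library)
  if (nrow(vio)) {
    writeLines(c(log_lines, vio$message), paste0(logf, ".partial"))
    sba_stop(paste0("panel validation failed: ",
                    paste(vio$message, collapse = "; ")),
             "sba_validation_error")
  }
  note("panel validation: clean")

  flt <- filter_bead_counts(ds$assay, config$min_events)
  masked <- which(flt$mask, arr.ind = TRUE)
  for (i in seq_len(nrow(masked)))
    note("masked well: sample ", rownames(flt$mask)[masked[i, 1]],
         " bead ", colnames(flt$mask)[masked[i, 2]],
         " (", ds$assay$bead_count[masked[i, 1], masked[i, 2]], " events)")

  ctrl_ids <- ds$antibodies$antibody_id[is_control_bead(ds$antibodies)]
  failed_beads <- coupling_qc(ds$coupling, config$coupling_floor, ctrl_ids)
  for (b in failed_beads) note("excluded bead (coupling QC): ", b)

  capture_beads <- c(
    FLAG = as.character(ds$antibodies$bead_id[ds$antibodies$target_id == "anti-FLAG"][1]),
    HA = as.character(ds$antibodies$bead_id[ds$antibodies$target_id == "anti-HA"][1]))
  expr <- assess_expression(flt$mfi, ds$samples, ds$library, capture_beads,
                            alpha = config$alpha)
  expr_sum <- expression_summary(expr, ds$library)

  fit <- withCallingHandlers(
    sba_selectivity(ds$assay, ds$antibodies, ds$samples, k = config$k,
                    min_events = config$min_events, coupling = ds$coupling,
                    coupling_floor = config$coupling_floor),
    warning = function(w) { note("warning: ", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  sweep <- threshold_sweep(fit, k_grid = 0:20)
  cls_sum <- summarize_classifications(fit$annotations)
  xreact <- crossreact_table(fit, ds$library, expr,
                             ratio_cut = config$ratio_cut,
                             evalue_cut = config$evalue_cut)
  pairs <- withCallingHandlers(
    pair_correlations(fit),
    warning = function(w) { note("skipped pair: ", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  psum <- pair_summary(pairs, fit$annotations)

  antigen <- NULL
  if (!is.null(config$structure_dir) && dir.exists(config$structure_dir)) {
    antigen <- tryCatch(
      antigen_stage(fit, ds$antibodies, config$structure_dir),
      error = function(e) { note("antigen stage failed: ", conditionMessage(e))
                            NULL })
  } else if (!is.null(config$structure_dir)) {
    warning("structure directory missing; antigen stage skipped")
    note("antigen stage skipped: structure directory missing")
  }

  p <- function(f) file.path(config$output_dir, f)
  write_tsv(expr, p("expression.tsv"))
  write_tsv(expr_sum, p("expression_summary.tsv"))
  write_tsv(fit$profiles, p("profiles.tsv"))
  write_tsv(fit$annotations, p("annotations.tsv"))
  write_tsv(cls_sum$table, p("classification_summary.tsv"))
  write_tsv(sweep, p("threshold_sweep.tsv"))
  write_tsv(as.data.frame(xreact), p("crossreact_events.tsv"))
  write_tsv(as.data.frame(pairs), p("pairs.tsv"))
  rz_long <- do.call(rbind, lapply(names(fit$rz), function(ab)
    data.frame(antibody_id = ab, sample_id = names(fit$rz[[ab]]),
               rz = round(unname(fit$rz[[ab]]), 4), stringsAsFactors = FALSE)))
  write_tsv(rz_long, p("rz_long.tsv"))
  jsonlite::write_json(psum, p("pair_summary.json"), auto_unbox = TRUE,
                       digits = NA)

  cfg_path <- p("config.yaml")
  write_run_config(config, cfg_path)
  manifest <- list(package = "sbaselect",
                   version = as.character(utils::packageVersion("sbaselect")),
                   config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   n_antibodies = nrow(fit$annotations),
                   n_excluded = length(fit$excluded))
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE)
  writeLines(log_lines, logf)

  invisible(structure(list(expression = expr, expression_summary = expr_sum,
                           fit = fit, sweep = sweep,
                           classification_summary = cls_sum,
                           crossreact = xreact, pairs = pairs,
                           pair_summary = psum, antigen = antigen,
                           config = config, manifest = manifest),
                      class = "sba_run"))
}

antigen_stage <- function(fit, antibodies, structure_dir) {
  ab <- antibodies[!is_control_bead(antibodies), , drop = FALSE]
  rows <- list()
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(ab))) {
    path <- file.path(structure_dir, paste0(ab$target_id[i], ".pdb"))
    if (!file.exists(path)) next
    key <- ab$target_id[i]
    res <- if (!is.null(cache[[key]])) cache[[key]]
           else cache[[key]] <- residue_annotations(read_structure_model(path))
    rows[[length(rows) + 1L]] <-
      antigen_profile(res, ab$antigen_start[i], ab$antigen_end[i],
                      antibody_id = ab$antibody_id[i])
  }
  if (!length(rows)) return(NULL)
  profiles <- do.call(rbind, rows)
  cls <- fit$annotations$category[match(profiles$antibody_id,
                                        fit$annotations$antibody_id)]
  keep <- !is.na(cls)
  list(profiles = profiles,
       stats = compare_groups(profiles[keep, , drop = FALSE], cls[keep]))
}

#' Static report export
#'
#' Re-reads the tables of a finished run and writes presentation-ready
#' files: beeswarm-ready long-format robust-Z scores (already emitted by
#' the run, validated here), a per-antibody x construct maximum-R.Z
#' heatmap matrix, pair-correlation panel data, and a Markdown summary.
#' No server; files only.
#'
#' @param run an `sba_run` object (or `NULL` to re-read from files).
#' @param output_dir the run's output directory.
#' @return invisible list of the written file paths.
#' @export
pipeline_report <- function(run = NULL, output_dir = run$config$output_dir) {
  p <- function(f) file.path(output_dir, f)
  ann <- if (!is.null(run)) run$fit$annotations else read_tsv(p("annotations.tsv"))
  rz_long <- if (!is.null(run)) read_tsv(p("rz_long.tsv")) else read_tsv(p("rz_long.tsv"))
  samples <- if (!is.null(run)) run$fit$samples else NULL
  ## heatmap: antibodies x constructs, max robust Z (0 where never scored)
  constructs <- if (!is.null(samples))
    setdiff(unique(samples$construct), MOCK_TOKEN)
  else unique(sub("_b\\d+_t\\d+$", "", grep("_b\\d+_t\\d+$",
                                            unique(rz_long$sample_id),
                                            value = TRUE)))
  abs_ids <- unique(ann$antibody_id)
  H <- matrix(0, length(abs_ids), length(constructs),
              dimnames = list(abs_ids, constructs))
  con_of <- if (!is.null(samples)) setNames(samples$construct, samples$sample_id)
            else setNames(sub("_b\\d+_t\\d+$", "", rz_long$sample_id),
                          rz_long$sample_id)
  for (i in seq_len(nrow(rz_long))) {
    g <- con_of[[rz_long$sample_id[i]]]
    if (is.null(g) || is.na(g) || !(g %in% constructs)) next
    v <- rz_long$rz[i]
    if (is.finite(v) && v > H[rz_long$antibody_id[i], g])
      H[rz_long$antibody_id[i], g] <- v
  }
  hm <- data.frame(antibody_id = rownames(H), H, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(hm, p("heatmap_max_rz.tsv"))
  pairs_path <- p("pairs.tsv")
  summary_md <- c("# SBA selectivity run report",
                  "",
                  sprintf("- antibodies scored: %d", length(abs_ids)),
                  sprintf("- constructs: %d", length(constructs)),
                  sprintf("- category counts: %s",
                          paste(names(table(ann$category)),
                                table(ann$category), sep = "=",
                                collapse = ", ")),
                  "",
                  "Files: heatmap_max_rz.tsv (antibody x construct max R.Z),",
                  "rz_long.tsv (beeswarm-ready scores), pairs.tsv",
                  "(pair-correlation panel).")
  writeLines(summary_md, p("report.md"))
  invisible(list(heatmap = p("heatmap_max_rz.tsv"), report = p("report.md"),
                 pairs = pairs_path))
}
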