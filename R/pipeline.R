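#' Preprocess every subject/timepoint of a cohort
#'
#' @param cohort a [generate_cohort()] result (or any list with `subjects`
#'   and `ts` laid out the same way).
#' @param config a [preproc_config()].
#' @return named list (per subject) of lists with `tp1`/`tp2`
#'   [functional_matrix()] entries.
#' @export
preprocess_cohort <- function(cohort, config = preproc_config()) {
  out <- lapply(cohort$subjects$subject, function(s)
    list(tp1 = run_preproc(cohort$ts[[s]]$tp1, config),
         tp2 = run_preproc(cohort$ts[[s]]$tp2, config)))
  names(out) <- cohort$subjects$subject
  out
}

#' Full analysis of a cohort in memory
#'
#' Convenience wrapper chaining the pipeline stages: preprocessing to
#' Fisher-z matrices, consensus backbone over both groups pooled, backbone
#' masking, network metric table, edge-wise ANOVA scan with FDR, and the
#' network-level ANOVAs.
#'
#' @param cohort a [generate_cohort()] result.
#' @param preproc a [preproc_config()].
#' @param threshold consensus backbone threshold (default 0.5).
#' @param q FDR level for the edge-wise scan (default 0.05).
#' @param networks named list of [network_definition()]s (or NULL to skip
#'   network metrics).
#' @param scan_masked logical; run the edge-wise scan on backbone-masked
#'   matrices instead of the full functional matrices (default FALSE).
#' @return list with `fmats`, `backbone`, `mixed`, `metric_table`, `scan`,
#'   `network_anovas`.
#' @export
analyze_cohort <- function(cohort, preproc = preproc_config(),
                           threshold = 0.5, q = 0.05, networks = NULL,
                           scan_masked = FALSE) {
  fmats <- preprocess_cohort(cohort, preproc)
  backbone <- consensus_binary(cohort$structural, threshold)
  mixed <- lapply(fmats, function(x)
    list(tp1 = apply_mask(x$tp1, backbone), tp2 = apply_mask(x$tp2, backbone)))
  scan <- edgewise_scan(fmats, cohort$subjects, q = q,
                        mask = if (scan_masked) backbone)
  metric_table <- NULL
  network_anovas <- NULL
  if (!is.null(networks)) {
    metric_table <- compute_metric_table(fmats, mixed, cohort$subjects,
                                         networks)
    network_anovas <- list()
    for (net in names(networks))
      for (metric in c("strength", "e_glob", "e_loc"))
        network_anovas[[paste(net, metric, sep = ".")]] <-
          network_metric_anova(metric_table, metric, net)
  }
  list(fmats = fmats, backbone = backbone, mixed = mixed,
       metric_table = metric_table, scan = scan,
       network_anovas = network_anovas)
}

#' Pipeline configuration
#'
#' @param out output directory.
#' @param seed master seed.
#' @param cohort list of arguments for [cohort_spec()] (seed is filled in).
#' @param effect list with `edges` (two-column matrix/data.frame, or
#'   `"default"`) and `delta_z`; `NULL` for a null cohort.
#' @param preproc list of arguments for [preproc_config()].
#' @param consensus_threshold backbone threshold (default 0.5).
#' @param q FDR level (default 0.05).
#' @param networks `"default"`, a path to a networks JSON file, or `NULL`.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(out, seed = 1L, cohort = list(),
                            effect = list(edges = "default", delta_z = -0.4),
                            preproc = list(), consensus_threshold = 0.5,
                            q = 0.05, networks = "default") {
  if (consensus_threshold <= 0 || consensus_threshold > 1)
    stop2("consensus_threshold must be in (0, 1]")
  if (q <= 0 || q >= 1) stop2("q must be in (0, 1)")
  if (is.character(networks) && networks != "default" &&
      !file.exists(networks))
    stop2("network-definition file not found: %s", networks)
  structure(list(out = out, seed = as.integer(seed), cohort = cohort,
                 effect = effect, preproc = preproc,
                 consensus_threshold = consensus_threshold, q = q,
                 networks = networks),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file with the fields above.
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj)
}

#' Run the full pipeline: simulate, preprocess, mask, measure, test
#'
#' Generates the configured synthetic cohort, writes its files, runs the
#' analysis stages, and writes functional matrices, the backbone, the
#' network metric table, the per-edge statistics, the significant
#' subnetwork edge list, and a JSON report. Re-running with the same config
#' and seed reproduces identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage progress (default TRUE).
#' @return the run manifest (list), invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  t0 <- Sys.time()
  log <- function(...) if (verbose) message(sprintf(...))
  stage_times <- list()
  tic <- function() Sys.time()
  toc <- function(start, name) {
    stage_times[[name]] <<- as.numeric(difftime(Sys.time(), start,
                                                units = "secs"))
  }

  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  spec <- do.call(cohort_spec, modifyList(config$cohort,
                                          list(seed = config$seed)))
  effect <- if (is.null(config$effect)) {
    effect_spec(edges = matrix(character(0), 0, 2))
  } else {
    edges <- config$effect$edges
    if (is.character(edges) && identical(edges[1], "default"))
      edges <- default_effect_edges()
    effect_spec(edges = as.matrix(edges),
                delta_z = config$effect$delta_z %||% -0.4)
  }
  networks <- if (is.null(config$networks)) NULL
    else if (identical(config$networks, "default"))
      default_networks(spec$parcellation$label)
    else read_networks_json(config$networks, spec$parcellation$label)

  s <- tic()
  log("stage simulate: %d+%d subjects, %d ROIs, %d volumes, seed %d",
      spec$n_group1, spec$n_group2, spec$n_rois, spec$n_volumes, spec$seed)
  cohort <- generate_cohort(spec, effect)
  cohort_dir <- file.path(config$out, "cohort")
  write_cohort(cohort, cohort_dir, networks = networks)
  toc(s, "simulate")

  s <- tic()
  pconf <- do.call(preproc_config, config$preproc)
  log("stage connectivity: steps = %s", paste(pconf$steps, collapse = " -> "))
  res <- analyze_cohort(cohort, preproc = pconf,
                        threshold = config$consensus_threshold, q = config$q,
                        networks = networks)
  toc(s, "analysis")

  s <- tic()
  func_dir <- file.path(config$out, "functional")
  dir.create(func_dir, showWarnings = FALSE)
  for (sub in cohort$subjects$subject)
    for (tp in c("tp1", "tp2"))
      write_matrix_tsv(res$fmats[[sub]][[tp]]$z,
                       file.path(func_dir, sprintf("%s_%s_z.tsv", sub, tp)))
  write_matrix_tsv(res$backbone$mask, file.path(config$out, "backbone.tsv"))
  if (!is.null(res$metric_table))
    write.table(res$metric_table, file.path(config$out, "metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$scan$table, file.path(config$out, "edge_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- res$scan$table[res$scan$table$fdr_sig, c("node1", "node2")]
  write.table(sig, file.path(config$out, "subnetwork_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    component_summary = res$scan$component_summary,
    q = config$q,
    consensus_threshold = config$consensus_threshold,
    n_edges_tested = nrow(res$scan$table),
    network_anovas = lapply(res$network_anovas, function(a)
      list(metric = a$metric, network = a$network,
           F_group = a$anova$F_group, p_group = a$anova$p_group,
           F_time = a$anova$F_time, p_time = a$anova$p_time,
           F_inter = a$anova$F_inter, p_inter = a$anova$p_inter,
           df = a$anova$df, posthoc = a$posthoc)))
  jsonlite::write_json(report, file.path(config$out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  toc(s, "write")

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  cfg_file <- file.path(config$out, "config.json")
  writeLines(cfg_json, cfg_file)
  outputs <- list.files(config$out, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("restconn")),
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    stage_seconds = stage_times,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = sub(paste0(config$out, "/"), "", outputs, fixed = TRUE))
  jsonlite::write_json(manifest, file.path(config$out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log("pipeline complete: %d flagged edge(s), %d output file(s), %.1f s",
      res$scan$component_summary$n_edges, length(outputs),
      manifest$total_seconds)
  invisible(manifest)
}

#' Validate a cohort directory
#'
#' Checks the files written by [write_cohort()]: square symmetric matrices,
#' consistent ROI labels across files (label-order mismatches are realigned
#' with a warning), timepoint completeness per subject, and binary
#' structural matrices. Issues are returned, not thrown.
#'
#' @param dir cohort directory.
#' @return data.frame with columns `level` (`"error"`/`"warning"`),
#'   `file`, `message`; zero rows when everything checks out.
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  note <- function(level, file, msg)
    issues[[length(issues) + 1L]] <<- data.frame(level = level, file = file,
                                                 message = msg,
                                                 stringsAsFactors = FALSE)
  manifest_file <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_file)) {
    note("error", "manifest.json", "manifest missing")
    return(do.call(rbind, issues))
  }
  man <- jsonlite::read_json(manifest_file, simplifyVector = TRUE)
  subs <- man$subjects$subject
  ref_labels <- NULL
  for (s in subs) {
    for (tp in c("tp1", "tp2")) {
      f <- file.path(dir, sprintf("%s_%s_timeseries.tsv", s, tp))
      if (!file.exists(f)) {
        note("error", basename(f), sprintf("subject %s missing %s", s, tp))
        next
      }
      ts <- read_timeseries_tsv(f, man$tr_seconds %||% 2)
      if (is.null(ref_labels)) ref_labels <- ts$roi_labels
      if (!identical(ts$roi_labels, ref_labels)) {
        if (setequal(ts$roi_labels, ref_labels))
          note("warning", basename(f),
               "ROI label order differs; realign before analysis")
        else
          note("error", basename(f), "ROI label set differs")
      }
    }
    f <- file.path(dir, sprintf("%s_structural.tsv", s))
    if (!file.exists(f)) {
      note("error", basename(f), sprintf("subject %s missing structural", s))
      next
    }
    m <- read_matrix_tsv(f)
    asym <- max(abs(m - t(m)))
    if (asym > 1e-8)
      note("error", basename(f),
           sprintf("asymmetric structural matrix (max asymmetry %.3g)", asym))
    if (!all(m %in% c(0, 1)))
      note("warning", basename(f),
           "structural matrix not binary; will be binarized at > 0")
    if (!is.null(ref_labels) && !identical(rownames(m), ref_labels)) {
      if (setequal(rownames(m), ref_labels))
        note("warning", basename(f), "ROI label order differs")
      else
        note("error", basename(f), "ROI label set differs")
    }
  }
  if (!length(issues))
    return(data.frame(level = character(0), file = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
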