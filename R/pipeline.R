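#' Assemble a pipeline configuration
#'
#' Bundles every stage's parameters with their package defaults: the
#' cohort generator settings ([cohort_config()]), the analysis band set,
#' filter order, Welch estimator settings, the fixed connectivity
#' threshold `tau`, the pattern `min_edges` rule, and the statistics
#' levels.  `seed` overrides the cohort seed so one integer reproduces the
#' whole run.
#'
#' @param cohort A [cohort_config()] (default: the package's desk-scale
#'   cohort).
#' @param bands Data frame of analysis bands (default [default_bands()]).
#' @param filter_order Butterworth order per pass (default 4).
#' @param segment_s,overlap Welch estimator settings (defaults 4 s, 0.5).
#' @param tau Fixed connectivity threshold for maps, patterns and graph
#'   metrics (default 0.5).
#' @param min_edges Pattern presence rule (default 1).
#' @param trim_s Edge-transient trim in seconds (default 2).
#' @param alpha,n_comparisons Statistics levels (defaults 0.05 and 3).
#' @param exclude_flagged Drop QC-flagged recordings before analysis
#'   (default TRUE).
#' @param write_signals Also write every raw recording as text (default
#'   FALSE; a full cohort is large).
#' @param seed Global seed (default: the cohort's seed).
#' @param out_dir Default output directory for [run_pipeline()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), bands = default_bands(),
                            filter_order = 4, segment_s = 4, overlap = 0.5,
                            tau = 0.5, min_edges = 1L, trim_s = 2,
                            alpha = 0.05, n_comparisons = 3L,
                            exclude_flagged = TRUE, write_signals = FALSE,
                            seed = NULL, out_dir = NULL) {
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  cfg <- list(cohort = cohort, bands = bands, filter_order = filter_order,
              segment_s = segment_s, overlap = overlap, tau = tau,
              min_edges = as.integer(min_edges), trim_s = trim_s,
              alpha = alpha, n_comparisons = as.integer(n_comparisons),
              exclude_flagged = exclude_flagged,
              write_signals = write_signals, seed = cohort$seed,
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Any field omitted from the file keeps its package default.  The
#' `cohort` section maps onto [cohort_config()] arguments; `bands` may be
#' either the string `"default"` or a list of `{name, lo, hi}` entries;
#' `couplings` under `cohort` is a list of [coupling_spec()] argument
#' sets.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  couplings <- cohort_args$couplings
  cohort_args$couplings <- NULL
  if (!is.null(couplings))
    cohort_args$coupling_specs <- lapply(couplings, function(cs)
      do.call(coupling_spec, cs))
  cohort <- do.call(cohort_config, cohort_args)
  bands <- if (is.null(y$bands) || identical(y$bands, "default"))
    default_bands()
  else do.call(rbind, lapply(y$bands, function(b)
    as_band(list(name = b$name, lo = b$lo, hi = b$hi))))
  args <- y[setdiff(names(y), c("cohort", "bands"))]
  do.call(pipeline_config, c(list(cohort = cohort, bands = bands), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulate-to-statistics pipeline
#'
#' Executes every stage in order for each subject -- simulation, DC
#' removal, artifact flagging, band filtering, edge trimming, signed
#' coherence estimation, graph metrics, pattern classification -- then the
#' group statistics, writing every tabular artifact plus a parameter log
#' and a checksum manifest into `out_dir`.  Re-running with the same
#' configuration reproduces byte-identical tables.
#'
#' @param config A [pipeline_config()] or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `out_dir`, the result tables and the
#'   `manifest` data frame (file, md5).
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(out_dir)) stop("out_dir must be given")
  check_bands_nyquist(config$bands, config$cohort$sampling_rate)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "connectivity"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "results"), showWarnings = FALSE)
  if (config$write_signals)
    dir.create(file.path(out_dir, "signals"), showWarnings = FALSE)

  layout <- make_sensor_layout(config$cohort$n_channels, config$cohort$seed)
  meta <- cohort_metadata(config$cohort)
  write_layout_json(layout, file.path(out_dir, "layout.json"))
  write_cohort_meta_tsv(meta, file.path(out_dir, "cohort.tsv"))

  metrics <- list(); patterns <- list(); power <- list()
  excluded <- character()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$subject_id[i]
    rec <- tryCatch(
      simulate_subject(layout, meta[i, ], config$cohort,
                       seed = subject_seed(config$cohort$seed, i, 2L)),
      error = function(e) stop("stage simulate failed for ", sid, ": ",
                               conditionMessage(e)))
    rec <- flag_artifact(remove_dc(rec))
    if (config$write_signals)
      write_recording_txt(rec, file.path(out_dir, "signals",
                                         paste0(sid, ".tsv")))
    if (config$exclude_flagged && length(rec$qc_flags)) {
      excluded <- c(excluded, sid)
      next
    }
    for (b in seq_len(nrow(config$bands))) {
      band <- config$bands[b, ]
      filt <- tryCatch({
        fr <- bandpass(rec, band, order = config$filter_order)
        trim_edges(fr, trim_s = config$trim_s)
      }, error = function(e) stop("stage filter failed for ", sid, " (",
                                  band$name, "): ", conditionMessage(e)))
      cm <- tryCatch(
        pairwise_connectivity(filt, segment_s = config$segment_s,
                              overlap = config$overlap),
        error = function(e) stop("stage connectivity failed for ", sid,
                                 " (", band$name, "): ",
                                 conditionMessage(e)))
      write_connectivity_tsv(cm, file.path(out_dir, "connectivity",
                                           paste0(sid, "_", band$name,
                                                  ".tsv")))
      metrics[[length(metrics) + 1L]] <- network_metrics(cm, config$tau)
      net <- apply_threshold(cm, config$tau)
      patterns[[length(patterns) + 1L]] <-
        classify_pattern(net, layout, config$min_edges)
      power[[length(power) + 1L]] <- data.frame(
        subject_id = sid, band = band$name, power = band_power(filt),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(metrics))
    stop("no subjects survived QC; nothing to analyse")
  metrics <- do.call(rbind, metrics)
  metrics <- cbind(metrics,
                   group = meta$group[match(metrics$subject_id,
                                            meta$subject_id)],
                   subgroup = meta$subgroup[match(metrics$subject_id,
                                                  meta$subject_id)])
  patterns <- do.call(rbind, patterns); rownames(patterns) <- NULL
  power <- do.call(rbind, power)

  write.table(metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(patterns, file.path(out_dir, "patterns.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(power, file.path(out_dir, "power.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  results <- run_group_analysis(metrics, patterns, meta, power = power,
                                alpha = config$alpha,
                                n_comparisons = config$n_comparisons)
  for (nm in names(results)) {
    if (is.null(results[[nm]])) next
    write.table(results[[nm]],
                file.path(out_dir, "results", paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  log_lines <- c(
    "megnet pipeline run",
    paste0("seed: ", config$seed),
    paste0("subjects: ", nrow(meta), " (excluded by QC: ",
           if (length(excluded)) paste(excluded, collapse = ", ")
           else "none", ")"),
    paste0("channels: ", config$cohort$n_channels,
           "; sampling_rate: ", config$cohort$sampling_rate,
           " Hz; duration: ", config$cohort$duration_s, " s"),
    paste0("bands: ", paste(sprintf("%s(%g-%g)", config$bands$name,
                                    config$bands$lo, config$bands$hi),
                            collapse = ", ")),
    paste0("filter_order: ", config$filter_order, "; segment_s: ",
           config$segment_s, "; overlap: ", config$overlap),
    paste0("tau: ", config$tau, "; min_edges: ", config$min_edges,
           "; trim_s: ", config$trim_s),
    paste0("alpha: ", config$alpha, "; bonferroni divisor: ",
           config$n_comparisons)
  )
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  invisible(list(out_dir = out_dir, metrics = metrics, patterns = patterns,
                 power = power, results = results, manifest = manifest,
                 excluded = excluded))
}
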