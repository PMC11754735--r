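#' Pipeline configuration
#'
#' Collects every stage's parameters plus input/output paths into one
#' validated list. Input coverage can come from a simulation scenario
#' (`scenario`) or from files (`track_sets`, a list of per-study lists with
#' `fwd`/`rev` bedGraph or bigWig paths per replicate, plus `annotation`).
#' Unknown keys are rejected.
#'
#' @param scenario Optional [sim_scenario()]: simulate inputs in-process.
#' @param track_sets Optional list of replicate sets; each set a list of
#'   replicates, each replicate `list(fwd = path, rev = path)`.
#' @param annotation GTF path (file mode).
#' @param out_dir Output directory; `NULL` keeps results in memory only.
#' @param selection A [selection_params()].
#' @param call A [broad_call_params()], or `NULL` to use
#'   [suggest_call_params()] in scenario mode and the documented defaults in
#'   file mode.
#' @param classify A [class_params()].
#' @param extension_bp,anchor Signal extension settings.
#' @param window_bp PAS/TSS ratio window width.
#' @param body_extension_bp Body extension for activity grouping.
#' @param n_groups Number of activity groups.
#' @param strand_mode `"both"` or `"+"`/`"-"` to restrict window calling.
#' @param compute_metrics Also compute PAS/TSS ratios and activity groups
#'   from the pooled average track.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = NULL, track_sets = NULL,
                            annotation = NULL, out_dir = NULL,
                            selection = selection_params(),
                            call = NULL,
                            classify = class_params(),
                            extension_bp = 150L, anchor = "five_prime",
                            window_bp = 200L, body_extension_bp = 5000L,
                            n_groups = 5L, strand_mode = "both",
                            compute_metrics = TRUE) {
  if (is.null(scenario) && (is.null(track_sets) || is.null(annotation)))
    stop("provide either 'scenario' or both 'track_sets' and 'annotation'")
  stopifnot(is.null(scenario) || is(scenario, "sim_scenario"),
            is(selection, "selection_params"),
            is.null(call) || is(call, "broad_call_params"),
            is(classify, "class_params"),
            strand_mode %in% c("both", "+", "-"))
  if (is.null(call))
    call <- if (!is.null(scenario)) suggest_call_params(scenario, extension_bp)
            else broad_call_params()
  structure(list(scenario = scenario, track_sets = track_sets,
                 annotation = annotation, out_dir = out_dir,
                 selection = selection, call = call, classify = classify,
                 extension_bp = as.integer(extension_bp), anchor = anchor,
                 window_bp = as.integer(window_bp),
                 body_extension_bp = as.integer(body_extension_bp),
                 n_groups = as.integer(n_groups),
                 strand_mode = strand_mode,
                 compute_metrics = isTRUE(compute_metrics)),
            class = "pipeline_config")
}

params_echo <- function(config) {
  list(selection = unclass(config$selection),
       call = unclass(config$call),
       classify = unclass(config$classify),
       extension_bp = config$extension_bp, anchor = config$anchor,
       window_bp = config$window_bp,
       body_extension_bp = config$body_extension_bp,
       n_groups = config$n_groups, strand_mode = config$strand_mode,
       scenario = if (!is.null(config$scenario)) unclass(config$scenario),
       version = as.character(packageVersion("termwin")))
}

#' Run the full termination-window pipeline
#'
#' Composition of all stages: gene loading and preselection, per-strand
#' window calling (per-study averaging, extension, broad calling,
#' cross-study consensus), three-way classification, per-category window
#' statistics, and (optionally) PAS/TSS ratios and activity groups on the
#' pooled average track. In scenario mode the planted truth is evaluated
#' with [evaluate_recovery()]. Deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a result list: `genes_selected`, `windows`,
#'   `classified`, `stats`, `metrics`, `recovery` (scenario mode),
#'   `summary` (the machine-readable summary also written to
#'   `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(is(config, "pipeline_config"))
  sim <- NULL
  if (!is.null(config$scenario)) {
    sim <- simulate_tracks(config$scenario)
    genes <- sim$genes
    sets_by_strand <- lapply(c(`+` = "+", `-` = "-"), function(st)
      lapply(sim$tracks, function(set) lapply(set, `[[`, st)))
    checksums <- NULL
  } else {
    genes <- load_annotation(config$annotation)
    sets_by_strand <- lapply(c(`+` = "+", `-` = "-"), function(st) {
      key <- if (st == "+") "fwd" else "rev"
      lapply(config$track_sets, function(set)
        lapply(set, function(rep) read_track(rep[[key]], strand = st)))
    })
    paths <- unlist(config$track_sets, use.names = FALSE)
    checksums <- vapply(c(config$annotation, paths), function(p)
      unname(tools::md5sum(p)), character(1))
  }
  selected <- select_genes(genes, config$selection)
  strands <- if (config$strand_mode == "both") c("+", "-")
             else config$strand_mode
  windows <- do.call(c, lapply(strands, function(st)
    call_termination_windows(sets_by_strand[[st]], params = config$call,
                             extension_bp = config$extension_bp,
                             anchor = config$anchor,
                             labels = names(sets_by_strand[[st]]))))
  classified <- classify_windows(windows, selected, config$classify)
  stats <- window_stats(classified)
  metrics <- NULL
  if (config$compute_metrics) {
    pooled <- lapply(c(`+` = "+", `-` = "-"), function(st)
      mean_tracks(unlist(sets_by_strand[[st]], recursive = FALSE)))
    ratios <- do.call(rbind, lapply(strands, function(st)
      pas_tss_ratio(pooled[[st]],
                    selected[as.character(strand(selected)) == st],
                    window_bp = config$window_bp)))
    groups <- lapply(strands, function(st) {
      g <- selected[as.character(strand(selected)) == st]
      if (length(g) < config$n_groups) return(NULL)
      activity_groups(pooled[[st]], g,
                      body_extension_bp = config$body_extension_bp,
                      n_groups = config$n_groups)
    })
    names(groups) <- strands
    metrics <- list(pas_tss = ratios, activity = groups)
  }
  recovery <- if (!is.null(sim))
    evaluate_recovery(classified, sim$truth)
  summary <- list(n_genes = length(genes), n_selected = length(selected),
                  n_windows = length(windows),
                  categories = setNames(as.list(stats$n), stats$category),
                  median_length_bp = setNames(as.list(stats$median_length_bp),
                                              stats$category),
                  recovery = if (!is.null(recovery))
                    recovery[c("sensitivity", "sensitivity_by_category",
                               "precision", "category_accuracy")],
                  parameters = params_echo(config),
                  input_checksums = as.list(checksums))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_genes(selected, file.path(od, "selected_genes.bed"),
                file.path(od, "selected_genes.tsv"))
    write_classified(classified, file.path(od, "windows.bed"),
                     file.path(od, "windows.tsv"))
    write.table(stats, file.path(od, "window_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(metrics))
      write.table(metrics$pas_tss, file.path(od, "pas_tss_ratio.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  invisible(list(genes_selected = selected, windows = windows,
                 classified = classified, stats = stats, metrics = metrics,
                 recovery = recovery, summary = summary, sim = sim))
}
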