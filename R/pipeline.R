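.DEFAULT_THRESHOLDS <- list(
  expressing_fraction = 0.20,   # output >= this fraction of pop. output
  response_fraction = 0.2,      # normalized trace must exceed this
  fusion_jump = 50,             # AU, frame-to-frame step defining fusion
  fusion_flat = 10,             # AU, max forward increase of non-fusing
  min_track_frames = 10,        # mating-mode track length floor
  late_delay = 15)              # min, late-class median-delay bound

#' Pipeline configuration
#'
#' Bundles the I/O column dialect, the QC thresholds and the analysis
#' thresholds (all at the study defaults) into one list. Values can be
#' overridden by arguments or by a YAML file with the same keys
#' (`io: columns:`, `qc:`, `thresholds:`).
#'
#' @param file optional path to a YAML config file.
#' @param ... named overrides of entries in `thresholds`.
#' @param qc a [QCConfig-class] (default [QCConfig()]).
#' @param dialect optional column-name mapping for [readTraceTable()].
#' @return List with `dialect`, `qc`, `thresholds`.
#' @export
pipelineConfig <- function(file = NULL, ..., qc = QCConfig(),
                           dialect = NULL) {
  thresholds <- .DEFAULT_THRESHOLDS
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    if (!is.null(y$io$columns)) dialect <- unlist(y$io$columns)
    if (!is.null(y$qc)) qc <- do.call(QCConfig, y$qc)
    for (k in names(y$thresholds)) thresholds[[k]] <- y$thresholds[[k]]
  }
  dots <- list(...)
  for (k in names(dots)) thresholds[[k]] <- dots[[k]]
  missing <- names(.DEFAULT_THRESHOLDS)[
    !vapply(names(.DEFAULT_THRESHOLDS),
            function(k) !is.null(thresholds[[k]]) &&
              is.finite(thresholds[[k]]), logical(1))]
  if (length(missing) > 0)
    stop("config missing threshold(s): ", paste(missing, collapse = ", "))
  list(dialect = dialect, qc = qc, thresholds = thresholds)
}

#' Exogenous-stimulation analysis pipeline
#'
#' Runs QC, trace correction, per-cell timing for the two reporter
#' channels, paired delays with the sign test, the CPV series, and (when a
#' reference strain is supplied) the diagonal-offset series and promoter
#' classification. Deterministic given its inputs. When `out_dir` is
#' given, stage outputs are written as CSV/JSON files.
#'
#' @param table a [TraceTable-class] (or a CSV path, read through the
#'   config dialect).
#' @param config list from [pipelineConfig()].
#' @param test_channel,ref_channel reporter channels (defaults "RFP" test
#'   vs "YFP" reference, the usual dual-reporter layout).
#' @param reference_table optional [TraceTable-class] of the reference
#'   strain (same promoter on both channels) for the offset test and
#'   classification.
#' @param out_dir optional output directory.
#' @return List: `qc_report`, `timing` (both channels), `delays`
#'   (a `"DelaySet"`), `sign_test_p`, `cpv` (a [CPVSeries-class]),
#'   `offsets` (or NULL), `classification` (or NULL), `log` (per-stage
#'   cell counts).
#' @export
runStimulationPipeline <- function(table, config = pipelineConfig(),
                                   test_channel = "RFP",
                                   ref_channel = "YFP",
                                   reference_table = NULL,
                                   out_dir = NULL) {
  if (is.character(table))
    table <- readTraceTable(table, dialect = config$dialect)
  thr <- config$thresholds
  qc <- applyQC(table, config$qc)
  tab <- qc$table
  log <- c(input_cells = qc$report@n_input,
           qc_kept = sum(qc$report@per_cell$pass))
  ct_ref <- correctTraces(tab, ref_channel)
  ct_test <- correctTraces(tab, test_channel)
  timing_ref <- computeTiming(ct_ref, threshold = thr$expressing_fraction,
                              frac = thr$response_fraction)
  timing_test <- computeTiming(ct_test, threshold = thr$expressing_fraction,
                               frac = thr$response_fraction)
  timing <- rbind(timing_ref, timing_test)
  delays <- pairedDelay(timing_test, timing_ref)
  p_sign <- if (!delays$empty) signTest(delays$deltas$delta) else NA_real_
  log <- c(log, dual_expressing = delays$n_dual)
  cpv_series <- cpvSeries(list(list(r = ct_test, y = ct_ref)))
  offsets <- NULL; classification <- NULL
  if (!is.null(reference_table)) {
    rq <- applyQC(reference_table, config$qc)
    rr <- correctTraces(rq$table, ref_channel)
    rt <- correctTraces(rq$table, test_channel)
    offsets <- offsetTestSeries(ct_ref, ct_test, rr, rt)
    classification <- classifyPromoter(delays, offsets,
                                       late_delay = thr$late_delay)
  }
  res <- list(qc_report = qc$report, timing = timing, delays = delays,
              sign_test_p = p_sign, cpv = cpv_series, offsets = offsets,
              classification = classification, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeResults(timing, file.path(out_dir, "timing.csv"))
    if (!delays$empty)
      writeResults(delays$deltas, file.path(out_dir, "delays.csv"))
    writeResults(cpv_series@per_replicate, file.path(out_dir, "cpv.csv"))
    if (!is.null(offsets))
      writeResults(offsets, file.path(out_dir, "offsets.csv"))
    if (!is.null(classification) &&
        requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(classification,
                           file.path(out_dir, "classification.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Mating analysis pipeline
#'
#' Runs track-length QC, fusion detection on the tdiRFP channel, mating
#' timing for the reporter channels, fusion alignment, response times
#' relative to fusion and their ECDFs.
#'
#' @inheritParams runStimulationPipeline
#' @param channels reporter channels to analyze (default early "YFP" and
#'   late "RFP").
#' @return List: `fusion` (per-cell records), `timing`, `aligned` (per
#'   channel), `rt_rel_fusion` (per channel), `ecdf` (per channel),
#'   `log`.
#' @export
runMatingPipeline <- function(table, config = pipelineConfig(),
                              channels = c("YFP", "RFP"),
                              out_dir = NULL) {
  if (is.character(table))
    table <- readTraceTable(table, dialect = config$dialect)
  thr <- config$thresholds
  fusion <- detectFusion(table, jump = thr$fusion_jump,
                         flat = thr$fusion_flat,
                         min_track_frames = thr$min_track_frames)
  log <- c(cells = nrow(fusion),
           fusing = sum(fusion$status == "fusing"),
           non_fusing = sum(fusion$status == "non_fusing"),
           indeterminate = sum(fusion$status == "indeterminate"),
           excluded = sum(fusion$status == "excluded"))
  if (log[["fusing"]] == 0)
    warning("no fusing cells detected; fusion-aligned outputs empty")
  timing <- list(); aligned <- list(); rel <- list(); ecdfs <- list()
  for (ch in channels) {
    timing[[ch]] <- matingTiming(table, ch,
                                 threshold = thr$expressing_fraction,
                                 frac = thr$response_fraction)
    if (log[["fusing"]] > 0) {
      aligned[[ch]] <- alignToFusion(table, ch, fusion)
      rel[[ch]] <- responseTimeRelFusion(timing[[ch]], fusion)
      if (nrow(rel[[ch]]$values) > 0)
        ecdfs[[ch]] <- responseEcdf(rel[[ch]]$values$rt_rel_fusion)
    }
  }
  res <- list(fusion = fusion, timing = timing, aligned = aligned,
              rt_rel_fusion = rel, ecdf = ecdfs, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeResults(fusion, file.path(out_dir, "fusion.csv"))
    writeResults(do.call(rbind, timing),
                 file.path(out_dir, "mating_timing.csv"))
    for (ch in names(aligned))
      writeResults(aligned[[ch]]$aligned,
                   file.path(out_dir, paste0("aligned_", ch, ".csv")))
    for (ch in names(rel))
      if (nrow(rel[[ch]]$values) > 0)
        writeResults(rel[[ch]]$values,
                     file.path(out_dir, paste0("rt_rel_fusion_", ch,
                                               ".csv")))
  }
  res
}
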