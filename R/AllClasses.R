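#' @import methods
NULL

.TRACE_COLUMNS <- c("cell_id", "replicate_id", "frame_time", "channel",
                    "nuclear_mean", "cytoplasmic_mean",
                    "nuclear_area", "cell_area")

#' TraceTable: long-format single-cell fluorescence traces
#'
#' The universal input of the pipeline: one row per cell, frame and channel,
#' carrying the mean nuclear and cytoplasmic fluorescence of that channel
#' plus nuclear and whole-cell areas. Frame times are minutes relative to
#' stimulation (negative values are pre-stimulus; in mating experiments the
#' movie starts at 0 and no stimulation time exists).
#'
#' Invariants enforced by the validity method: frame times are strictly
#' increasing within each (cell, channel) and identical across the channels
#' of a cell; intensities and areas are non-negative (cytoplasmic means may
#' be NA for channels measured only in the nucleus, e.g. CFP or tdiRFP);
#' each (cell, frame, channel) combination appears at most once.
#'
#' @slot traces data.frame with columns cell_id, replicate_id, frame_time,
#'   channel, nuclear_mean, cytoplasmic_mean, nuclear_area, cell_area,
#'   sorted by (cell_id, channel, frame_time).
#' @export
setClass("TraceTable", representation(traces = "data.frame"))

.validTraceTable <- function(object) {
  df <- object@traces
  missing <- setdiff(.TRACE_COLUMNS, names(df))
  if (length(missing) > 0)
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  if (nrow(df) == 0)
    return("trace table is empty")
  num_cols <- c("frame_time", "nuclear_mean", "cytoplasmic_mean",
                "nuclear_area", "cell_area")
  for (cl in num_cols)
    if (!is.numeric(df[[cl]]))
      return(sprintf("column '%s' must be numeric", cl))
  for (cl in c("nuclear_mean", "nuclear_area", "cell_area"))
    if (any(df[[cl]] < 0, na.rm = TRUE))
      return(sprintf("negative values in '%s'", cl))
  key <- paste(df$cell_id, df$frame_time, df$channel, sep = "\r")
  if (anyDuplicated(key))
    return("duplicated (cell_id, frame_time, channel) row(s)")
  cc <- paste(df$cell_id, df$channel, sep = "\r")
  ord <- order(cc, df$frame_time)
  t_sorted <- df$frame_time[ord]
  same_cc <- cc[ord][-1] == cc[ord][-length(ord)]
  if (length(t_sorted) > 1 && any(same_cc & diff(t_sorted) <= 0))
    return("frame times not strictly increasing within a (cell, channel)")
  # identical grids across channels of a cell
  grids <- tapply(df$frame_time, cc,
                  function(x) paste(sort(x), collapse = ","))
  cell_of <- sub("\r.*$", "", names(grids))
  n_grid <- tapply(grids, cell_of, function(g) length(unique(g)))
  if (any(n_grid > 1))
    return(sprintf("cell '%s' has different frame grids across channels",
                   names(n_grid)[which(n_grid > 1)[1]]))
  TRUE
}
setValidity("TraceTable", .validTraceTable)

#' Construct a TraceTable from a data.frame
#'
#' Rows are sorted by (cell_id, channel, frame_time); absent optional columns
#' (replicate_id, cytoplasmic_mean, areas) are filled with defaults.
#'
#' @param df data.frame with at least cell_id, frame_time, channel and
#'   nuclear_mean columns.
#' @return A validated [TraceTable-class] object.
#' @export
TraceTable <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("cell_id", "frame_time", "channel", "nuclear_mean")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (is.null(df$replicate_id)) df$replicate_id <- "R1"
  if (is.null(df$cytoplasmic_mean)) df$cytoplasmic_mean <- NA_real_
  if (is.null(df$nuclear_area)) df$nuclear_area <- NA_real_
  if (is.null(df$cell_area)) df$cell_area <- NA_real_
  df <- df[.TRACE_COLUMNS]
  df$cell_id <- as.character(df$cell_id)
  df$replicate_id <- as.character(df$replicate_id)
  df$channel <- as.character(df$channel)
  df <- df[order(df$cell_id, df$channel, df$frame_time), , drop = FALSE]
  rownames(df) <- NULL
  new("TraceTable", traces = df)
}

#' @describeIn TraceTable show method
#' @param object a TraceTable
#' @export
setMethod("show", "TraceTable", function(object) {
  df <- object@traces
  cat(sprintf("TraceTable: %d cells, %d channels (%s), %d frames\n",
              length(unique(df$cell_id)),
              length(unique(df$channel)),
              paste(sort(unique(df$channel)), collapse = ", "),
              length(unique(df$frame_time))))
  cat(sprintf("  time range: [%g, %g] min; %d rows\n",
              min(df$frame_time), max(df$frame_time), nrow(df)))
})

#' Quality-control configuration
#'
#' Thresholds for the per-cell trace quality control. A threshold set to
#' `NA` disables the corresponding rule. Variability is measured as the
#' coefficient of variation (sd/mean) over the track, chosen for scale
#' invariance.
#'
#' @slot require_full_track logical; keep only cells tracked over the whole
#'   movie span.
#' @slot max_cv_nuclear_area,max_cv_cell_area,max_cv_nuclear_cfp numeric
#'   CV ceilings (default 0.2).
#' @slot max_rfp_yfp_ratio numeric ceiling on mean nuclear RFP over mean
#'   nuclear YFP (default 3).
#' @slot min_track_frames integer; minimum track length in frames, used in
#'   mating mode where full-movie tracking is not required.
#' @export
setClass("QCConfig", representation(
  require_full_track = "logical",
  max_cv_nuclear_area = "numeric",
  max_cv_cell_area = "numeric",
  max_cv_nuclear_cfp = "numeric",
  max_rfp_yfp_ratio = "numeric",
  min_track_frames = "numeric"))

setValidity("QCConfig", function(object) {
  thr <- c(object@max_cv_nuclear_area, object@max_cv_cell_area,
           object@max_cv_nuclear_cfp, object@max_rfp_yfp_ratio,
           object@min_track_frames)
  if (any(!is.na(thr) & thr <= 0)) return("all thresholds must be > 0")
  TRUE
})

#' Construct a QCConfig
#'
#' @param require_full_track logical (default TRUE).
#' @param max_cv_nuclear_area,max_cv_cell_area,max_cv_nuclear_cfp CV ceilings
#'   (default 0.2; NA disables).
#' @param max_rfp_yfp_ratio ratio ceiling (default 3; NA disables).
#' @param min_track_frames minimum frames per track (default NA: disabled).
#' @return A [QCConfig-class] object.
#' @export
QCConfig <- function(require_full_track = TRUE,
                     max_cv_nuclear_area = 0.2,
                     max_cv_cell_area = 0.2,
                     max_cv_nuclear_cfp = 0.2,
                     max_rfp_yfp_ratio = 3,
                     min_track_frames = NA_real_) {
  new("QCConfig",
      require_full_track = require_full_track,
      max_cv_nuclear_area = as.numeric(max_cv_nuclear_area),
      max_cv_cell_area = as.numeric(max_cv_cell_area),
      max_cv_nuclear_cfp = as.numeric(max_cv_nuclear_cfp),
      max_rfp_yfp_ratio = as.numeric(max_rfp_yfp_ratio),
      min_track_frames = as.numeric(min_track_frames))
}

#' Quality-control report
#'
#' @slot per_cell data.frame with cell_id, pass, reasons (comma-joined
#'   labels of the failed rules, "" when passing).
#' @slot counts named integer vector of discards per rule plus "kept".
#' @slot n_input number of cells before filtering.
#' @export
setClass("QCReport", representation(
  per_cell = "data.frame", counts = "integer", n_input = "integer"))

setValidity("QCReport", function(object) {
  if (nrow(object@per_cell) != object@n_input)
    return("per-cell rows must equal input cell count")
  kept <- sum(object@per_cell$pass)
  if (kept + sum(!object@per_cell$pass) != object@n_input)
    return("kept + discarded must equal input cell count")
  TRUE
})

#' @describeIn QCReport show method
#' @param object a QCReport
#' @export
setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %d / %d cells kept\n",
              sum(object@per_cell$pass), object@n_input))
  bad <- object@counts[object@counts > 0 & names(object@counts) != "kept"]
  for (nm in names(bad))
    cat(sprintf("  %s: %d discarded\n", nm, bad[[nm]]))
})

#' Corrected single-channel traces for a set of cells
#'
#' Holds, as cells-by-frames matrices, the raw nuclear enrichment
#' (nuclear minus cytoplasmic mean), the 3-point moving-average smoothed
#' trace, and the basal-corrected trace (smoothed minus the per-cell basal,
#' the mean of the smoothed values at the last three frames at or before
#' stimulation). All cells must share one frame grid.
#'
#' @slot cell_ids character vector (row names of the matrices).
#' @slot channel single channel name.
#' @slot times numeric frame times in minutes (column order).
#' @slot raw,smoothed,corrected numeric matrices, cells x frames.
#' @slot basal numeric per-cell basal level (AU).
#' @export
setClass("CorrectedTraces", representation(
  cell_ids = "character", channel = "character", times = "numeric",
  raw = "matrix", smoothed = "matrix", corrected = "matrix",
  basal = "numeric"))

setValidity("CorrectedTraces", function(object) {
  n <- length(object@cell_ids); m <- length(object@times)
  for (nm in c("raw", "smoothed", "corrected")) {
    mat <- slot(object, nm)
    if (!all(dim(mat) == c(n, m)))
      return(sprintf("'%s' must be %d x %d", nm, n, m))
  }
  if (length(object@basal) != n) return("basal must have one value per cell")
  if (max(abs(object@corrected - (object@smoothed - object@basal))) > 1e-9)
    return("corrected must equal smoothed - basal elementwise")
  TRUE
})

#' @describeIn CorrectedTraces show method
#' @param object a CorrectedTraces
#' @export
setMethod("show", "CorrectedTraces", function(object) {
  cat(sprintf("CorrectedTraces [%s]: %d cells x %d frames (%g..%g min)\n",
              object@channel, length(object@cell_ids),
              length(object@times), min(object@times), max(object@times)))
})

#' Accessors for trace containers
#'
#' @param x a TraceTable or CorrectedTraces object.
#' @return `cellIds`: character vector of cell identifiers;
#'   `channelNames`: channels present; `frameTimes`: the frame grid;
#'   `traceData`: the underlying long-format data.frame;
#'   `correctedMatrix`/`smoothedMatrix`: cells-by-frames matrices.
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname trace-accessors
#' @export
setMethod("cellIds", "TraceTable", function(x) unique(x@traces$cell_id))
#' @rdname trace-accessors
#' @export
setMethod("cellIds", "CorrectedTraces", function(x) x@cell_ids)

#' @rdname trace-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname trace-accessors
#' @export
setMethod("channelNames", "TraceTable",
          function(x) sort(unique(x@traces$channel)))

#' @rdname trace-accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname trace-accessors
#' @export
setMethod("frameTimes", "TraceTable",
          function(x) sort(unique(x@traces$frame_time)))
#' @rdname trace-accessors
#' @export
setMethod("frameTimes", "CorrectedTraces", function(x) x@times)

#' @rdname trace-accessors
#' @export
setGeneric("traceData", function(x) standardGeneric("traceData"))
#' @rdname trace-accessors
#' @export
setMethod("traceData", "TraceTable", function(x) x@traces)

#' @rdname trace-accessors
#' @export
setGeneric("correctedMatrix", function(x) standardGeneric("correctedMatrix"))
#' @rdname trace-accessors
#' @export
setMethod("correctedMatrix", "CorrectedTraces", function(x) {
  m <- x@corrected; rownames(m) <- x@cell_ids; colnames(m) <- x@times; m
})

#' @rdname trace-accessors
#' @export
setGeneric("smoothedMatrix", function(x) standardGeneric("smoothedMatrix"))
#' @rdname trace-accessors
#' @export
setMethod("smoothedMatrix", "CorrectedTraces", function(x) {
  m <- x@smoothed; rownames(m) <- x@cell_ids; colnames(m) <- x@times; m
})

#' Subset a TraceTable by cell
#'
#' @param x a TraceTable.
#' @param i character vector of cell ids (or logical/integer over
#'   `cellIds(x)`).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "TraceTable", function(x, i, j, ..., drop = FALSE) {
  ids <- cellIds(x)
  keep <- if (is.character(i)) i else ids[i]
  df <- x@traces[x@traces$cell_id %in% keep, , drop = FALSE]
  if (nrow(df) == 0) stop("no cells left after subsetting")
  rownames(df) <- NULL
  new("TraceTable", traces = df)
})

#' Time-resolved correlative promoter variability
#'
#' Per-replicate CPV(t) with across-replicate mean and standard deviation,
#' as plotted for dual-reporter pairs.
#'
#' @slot times numeric frame times.
#' @slot per_replicate data.frame: time, replicate, cpv, n_cells.
#' @slot summary data.frame: time, mean_cpv, sd_cpv.
#' @export
setClass("CPVSeries", representation(
  times = "numeric", per_replicate = "data.frame", summary = "data.frame"))

#' @describeIn CPVSeries show method
#' @param object a CPVSeries
#' @export
setMethod("show", "CPVSeries", function(object) {
  cat(sprintf("CPVSeries: %d time points, %d replicate(s)\n",
              length(object@times),
              length(unique(object@per_replicate$replicate))))
  s <- object@summary
  pre <- s$mean_cpv[s$time <= 0]
  if (length(pre) > 0)
    cat(sprintf("  mean CPV at last pre-stimulus frame: %.3f\n",
                pre[length(pre)]))
})

#' @rdname CPVSeries-class
#' @param x a CPVSeries
#' @return `cpvSummary`: data.frame with time, mean_cpv, sd_cpv.
#' @export
setGeneric("cpvSummary", function(x) standardGeneric("cpvSummary"))
#' @rdname CPVSeries-class
#' @export
setMethod("cpvSummary", "CPVSeries", function(x) x@summary)
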