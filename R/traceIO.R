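#' Read a trace table from CSV
#'
#' Reads a long-format per-cell per-frame trace CSV (one row per cell,
#' frame and channel) into a validated [TraceTable-class]. Column names can
#' be remapped through `dialect` so that tables exported under different
#' header conventions load without editing the file.
#'
#' @param source path to a CSV file (or a connection) with a header row.
#' @param dialect optional named character vector mapping canonical column
#'   names (`cell_id`, `replicate_id`, `frame_time`, `channel`,
#'   `nuclear_mean`, `cytoplasmic_mean`, `nuclear_area`, `cell_area`) to the
#'   names used in the file, e.g. `c(cell_id = "track", frame_time = "t")`.
#' @return A [TraceTable-class], rows sorted by (cell_id, channel,
#'   frame_time).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(cell_id = "c1", frame_time = c(-2, 0, 5),
#'                      channel = "RFP", nuclear_mean = c(1, 1, 4),
#'                      cytoplasmic_mean = 1), f, row.names = FALSE)
#' readTraceTable(f)
#' @export
readTraceTable <- function(source, dialect = NULL) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!is.null(dialect)) {
    stopifnot(!is.null(names(dialect)))
    for (canon in names(dialect)) {
      from <- dialect[[canon]]
      if (!from %in% names(df))
        stop(sprintf("dialect maps '%s' to missing column '%s'",
                     canon, from))
      names(df)[names(df) == from] <- canon
    }
  }
  need <- c("cell_id", "frame_time", "channel", "nuclear_mean")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  num_cols <- intersect(c("frame_time", "nuclear_mean", "cytoplasmic_mean",
                          "nuclear_area", "cell_area"), names(df))
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "" & v != "NA")
      if (length(bad) > 0)
        stop(sprintf("non-numeric value in column '%s' at data row %d",
                     cl, bad[1]))
      df[[cl]] <- conv
    }
  }
  TraceTable(df)
}

.cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(if (stats::sd(x) == 0) 0 else Inf)
  stats::sd(x) / m
}

#' Apply trace quality control
#'
#' Filters cells following the study's trace quality control: only cells
#' tracked from the beginning to the end of the movie are kept, and among
#' those, only cells with low variability (coefficient of variation over the
#' track) in nuclear area, cell area and nuclear CFP fluorescence, and with
#' a mean nuclear RFP-to-YFP ratio below a ceiling. Every discard is
#' recorded with its rule label.
#'
#' @param table a [TraceTable-class].
#' @param cfg a [QCConfig-class]; rules with `NA` thresholds are skipped.
#' @param movie_span numeric length-2 `[t_min, t_max]` in minutes; defaults
#'   to the range of frame times in `table`. Full-track coverage and CVs are
#'   evaluated on the global frame grid restricted to this span.
#' @return A list with `table` (the filtered [TraceTable-class]) and
#'   `report` (a [QCReport-class]).
#' @export
applyQC <- function(table, cfg = QCConfig(), movie_span = NULL) {
  stopifnot(is(table, "TraceTable"), is(cfg, "QCConfig"))
  df <- table@traces
  if (nrow(df) == 0) stop("empty trace table")
  if (!is.na(cfg@max_cv_nuclear_cfp) && !"CFP" %in% df$channel)
    stop("QC config requires channel 'CFP' which is absent from the table")
  if (!is.na(cfg@max_rfp_yfp_ratio) &&
      !all(c("RFP", "YFP") %in% df$channel))
    stop("QC config requires channels 'RFP' and 'YFP' for the ratio rule")
  if (is.null(movie_span)) movie_span <- range(df$frame_time)
  grid <- sort(unique(df$frame_time))
  grid <- grid[grid >= movie_span[1] & grid <= movie_span[2]]
  ids <- unique(df$cell_id)
  per_cell <- lapply(ids, function(id) {
    sub <- df[df$cell_id == id, , drop = FALSE]
    ch1 <- sub[sub$channel == sub$channel[1], , drop = FALSE]
    reasons <- character(0)
    if (isTRUE(cfg@require_full_track) &&
        !all(grid %in% ch1$frame_time))
      reasons <- c(reasons, "incomplete_track")
    if (!is.na(cfg@min_track_frames) &&
        nrow(ch1) < cfg@min_track_frames)
      reasons <- c(reasons, "short_track")
    if (!is.na(cfg@max_cv_nuclear_area)) {
      v <- .cv(ch1$nuclear_area)
      if (!is.na(v) && v > cfg@max_cv_nuclear_area)
        reasons <- c(reasons, "cv_nuclear_area")
    }
    if (!is.na(cfg@max_cv_cell_area)) {
      v <- .cv(ch1$cell_area)
      if (!is.na(v) && v > cfg@max_cv_cell_area)
        reasons <- c(reasons, "cv_cell_area")
    }
    if (!is.na(cfg@max_cv_nuclear_cfp)) {
      v <- .cv(sub$nuclear_mean[sub$channel == "CFP"])
      if (!is.na(v) && v > cfg@max_cv_nuclear_cfp)
        reasons <- c(reasons, "cv_nuclear_cfp")
    }
    if (!is.na(cfg@max_rfp_yfp_ratio)) {
      r <- mean(sub$nuclear_mean[sub$channel == "RFP"], na.rm = TRUE)
      y <- mean(sub$nuclear_mean[sub$channel == "YFP"], na.rm = TRUE)
      if (is.finite(r) && is.finite(y) && y > 0 &&
          r / y > cfg@max_rfp_yfp_ratio)
        reasons <- c(reasons, "rfp_yfp_ratio")
    }
    data.frame(cell_id = id, pass = length(reasons) == 0,
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  per_cell <- do.call(rbind, per_cell)
  rule_names <- c("incomplete_track", "short_track", "cv_nuclear_area",
                  "cv_cell_area", "cv_nuclear_cfp", "rfp_yfp_ratio")
  counts <- vapply(rule_names, function(r)
    sum(grepl(r, per_cell$reasons, fixed = TRUE)), integer(1))
  counts <- c(counts, kept = sum(per_cell$pass))
  report <- new("QCReport", per_cell = per_cell,
                counts = counts, n_input = length(ids))
  kept_ids <- per_cell$cell_id[per_cell$pass]
  if (length(kept_ids) == 0)
    stop("no cells pass quality control")
  out <- df[df$cell_id %in% kept_ids, , drop = FALSE]
  rownames(out) <- NULL
  list(table = new("TraceTable", traces = out), report = report)
}

#' Write a tabular result to CSV
#'
#' Writes with a stable column order and no row names so outputs round-trip
#' bit-identically through [utils::read.csv()].
#'
#' @param result a non-empty data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(result, path) {
  if (!is.data.frame(result))
    stop("result must be a data.frame")
  if (nrow(result) == 0)
    stop("refusing to write an empty result table")
  utils::write.csv(result, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
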