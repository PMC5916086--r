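#' Nuclear enrichment of a reporter channel
#'
#' The per-frame difference between the average nuclear and cytoplasmic
#' fluorescence of a channel — the raw readout of a relocation-based
#' expression reporter. May be negative.
#'
#' @param table a [TraceTable-class].
#' @param channel channel name; must carry both nuclear and cytoplasmic
#'   means.
#' @return Long data.frame: cell_id, frame_time, enrichment.
#' @export
nuclearEnrichment <- function(table, channel) {
  stopifnot(is(table, "TraceTable"))
  df <- table@traces[table@traces$channel == channel, , drop = FALSE]
  if (nrow(df) == 0)
    stop(sprintf("channel '%s' not present", channel))
  if (all(is.na(df$cytoplasmic_mean)))
    stop(sprintf("channel '%s' has no cytoplasmic means", channel))
  data.frame(cell_id = df$cell_id, frame_time = df$frame_time,
             enrichment = df$nuclear_mean - df$cytoplasmic_mean,
             stringsAsFactors = FALSE)
}

# centered 3-point moving average with shrunken windows at both ends
.movavg3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  y <- (x[c(1, 1:(n - 1))] + x + x[c(2:n, n)]) / 3
  y[1] <- (x[1] + x[2]) / 2
  y[n] <- (x[n - 1] + x[n]) / 2
  y
}

#' Preprocess a single raw enrichment series
#'
#' Smooths with a centered 3-point moving average (shrunken 2-point windows
#' at the series ends), computes the basal level as the mean of the smoothed
#' values at the last three frames at or before stimulation (t <= 0), and
#' subtracts it. In mating experiments no stimulation time exists, so
#' `basal = "start"` takes the first three frames of the track instead.
#'
#' @param values numeric raw enrichment series.
#' @param times numeric frame times (minutes), same length.
#' @param basal `"prestim"` (default) or `"start"`.
#' @return List with `times`, `raw`, `smoothed`, `basal` (scalar) and
#'   `corrected` (= smoothed - basal).
#' @export
preprocessTrace <- function(values, times, basal = c("prestim", "start")) {
  basal <- match.arg(basal)
  stopifnot(length(values) == length(times))
  sm <- .movavg3(values)
  if (basal == "prestim") {
    pre <- which(times <= 0)
    if (length(pre) < 3)
      stop("insufficient baseline: need >= 3 frames with t <= 0")
    if (sum(times > 0) < 2)
      stop("need >= 2 post-stimulus frames")
    b <- mean(sm[pre[(length(pre) - 2):length(pre)]])
  } else {
    if (length(values) < 3)
      stop("insufficient baseline: need >= 3 frames")
    b <- mean(sm[1:3])
  }
  list(times = times, raw = values, smoothed = sm, basal = b,
       corrected = sm - b)
}

#' Build corrected traces for all cells of a channel
#'
#' Applies [nuclearEnrichment()] and [preprocessTrace()] to every cell;
#' all cells must share a single frame grid.
#'
#' @param table a [TraceTable-class].
#' @param channel reporter channel name.
#' @param basal passed to [preprocessTrace()].
#' @return A [CorrectedTraces-class].
#' @export
correctTraces <- function(table, channel, basal = "prestim") {
  enr <- nuclearEnrichment(table, channel)
  ids <- unique(enr$cell_id)
  times <- sort(unique(enr$frame_time))
  wide <- matrix(NA_real_, nrow = length(ids), ncol = length(times),
                 dimnames = list(ids, NULL))
  idx <- cbind(match(enr$cell_id, ids), match(enr$frame_time, times))
  wide[idx] <- enr$enrichment
  if (anyNA(wide))
    stop("mixed frame grids: not all cells cover the common grid")
  pp <- apply(wide, 1, preprocessTrace, times = times, basal = basal,
              simplify = FALSE)
  new("CorrectedTraces",
      cell_ids = ids, channel = channel, times = times,
      raw = wide,
      smoothed = do.call(rbind, lapply(pp, `[[`, "smoothed")),
      corrected = do.call(rbind, lapply(pp, `[[`, "corrected")),
      basal = vapply(pp, `[[`, numeric(1), "basal"))
}

#' Expression output
#'
#' The maximal corrected nuclear enrichment of a cell after stimulation
#' (frames with t > `after`). Not clamped at zero: a non-responder can have
#' a negative output.
#'
#' @param x a [CorrectedTraces-class].
#' @param after search start time, exclusive (default 0, the stimulation).
#' @return Named numeric vector, one value per cell.
#' @export
expressionOutput <- function(x, after = 0) {
  stopifnot(is(x, "CorrectedTraces"))
  sel <- x@times > after
  if (!any(sel)) stop("no frames after the search start")
  out <- apply(x@corrected[, sel, drop = FALSE], 1, max)
  names(out) <- x@cell_ids
  out
}

#' Population-averaged expression output
#'
#' Computed on the mean trace of all cells: the pointwise mean corrected
#' trace is formed first, then its maximum over post-stimulation frames is
#' taken. By Jensen's inequality this is at most the mean of the individual
#' outputs when cells peak at different frames.
#'
#' @inheritParams expressionOutput
#' @return Scalar population output (AU).
#' @export
populationOutput <- function(x, after = 0) {
  stopifnot(is(x, "CorrectedTraces"))
  sel <- x@times > after
  if (!any(sel)) stop("no frames after the search start")
  max(colMeans(x@corrected[, sel, drop = FALSE]))
}

#' Flag expressing cells
#'
#' A cell qualifies as expressing when its expression output reaches at
#' least 20% (by default) of the population-averaged expression output.
#' The boundary is inclusive (>=).
#'
#' @param outputs per-cell expression outputs (from [expressionOutput()]).
#' @param pop_output population-averaged output (from
#'   [populationOutput()]); must be positive.
#' @param threshold fraction of the population output (default 0.2).
#' @return Named logical vector.
#' @export
classifyExpressing <- function(outputs, pop_output, threshold = 0.2) {
  if (!is.finite(pop_output) || pop_output <= 0)
    stop("population non-responsive: population output is not positive")
  outputs >= threshold * pop_output
}

#' Response time of one cell
#'
#' The corrected trace is normalized by the cell's expression output and
#' the response time is the first frame time after stimulation at which the
#' normalized trace strictly exceeds `frac` (default 0.2). The frame at
#' t = `after` itself is excluded ("after stimulation"). Frame-quantized by
#' design: no sub-frame interpolation is attempted.
#'
#' @param corrected numeric corrected trace of one cell.
#' @param times frame times.
#' @param output the cell's expression output; must be positive (the caller
#'   must restrict to expressing cells).
#' @param after search start time, exclusive (default 0).
#' @param frac normalized threshold (default 0.2, strict >).
#' @return Response time in minutes, or `NA` if the threshold is never
#'   exceeded after stimulation.
#' @export
responseTime <- function(corrected, times, output, after = 0, frac = 0.2) {
  if (!is.finite(output) || output <= 0)
    stop("response time requested for a cell with non-positive output; ",
         "restrict to expressing cells first")
  post <- times > after
  hit <- post & (corrected / output > frac)
  if (!any(hit)) return(NA_real_)
  min(times[hit])
}

#' Per-cell expression timing
#'
#' Runs [expressionOutput()], [populationOutput()], [classifyExpressing()]
#' and [responseTime()] for every cell of a channel.
#'
#' @param x a [CorrectedTraces-class].
#' @param threshold expressing threshold as a fraction of the population
#'   output (default 0.2).
#' @param frac response-time crossing fraction (default 0.2).
#' @param after search start time, exclusive (default 0).
#' @return data.frame: cell_id, channel, expression_output, expressing,
#'   response_time (NA for non-expressing cells or cells never crossing).
#' @export
computeTiming <- function(x, threshold = 0.2, frac = 0.2, after = 0) {
  stopifnot(is(x, "CorrectedTraces"))
  out <- expressionOutput(x, after = after)
  pop <- populationOutput(x, after = after)
  expressing <- classifyExpressing(out, pop, threshold = threshold)
  rt <- rep(NA_real_, length(out))
  for (i in which(expressing & out > 0))
    rt[i] <- responseTime(x@corrected[i, ], x@times, out[i],
                          after = after, frac = frac)
  data.frame(cell_id = x@cell_ids, channel = x@channel,
             expression_output = unname(out),
             expressing = unname(expressing), response_time = rt,
             stringsAsFactors = FALSE)
}

#' Paired response-time delays between two reporters
#'
#' For every cell expressing both channels (with a defined response time in
#' each), the delay is `response_time(test) - response_time(reference)`, so
#' a promoter that lags the reference yields positive delays.
#'
#' @param test,reference timing data.frames from [computeTiming()] for the
#'   test and reference channel of the same cells.
#' @return An object of class `"DelaySet"`: list with `deltas` (data.frame
#'   cell_id, delta), `n_dual`, `median`, `mean`, `fraction_positive` (ties
#'   excluded from numerator and denominator) and `empty`.
#' @export
pairedDelay <- function(test, reference) {
  m <- merge(test[!is.na(test$response_time),
                  c("cell_id", "response_time")],
             reference[!is.na(reference$response_time),
                       c("cell_id", "response_time")],
             by = "cell_id", suffixes = c("_test", "_ref"))
  delta <- m$response_time_test - m$response_time_ref
  res <- list(deltas = data.frame(cell_id = m$cell_id, delta = delta,
                                  stringsAsFactors = FALSE),
              n_dual = nrow(m),
              median = if (nrow(m) > 0) stats::median(delta) else NA_real_,
              mean = if (nrow(m) > 0) mean(delta) else NA_real_,
              fraction_positive = if (any(delta != 0))
                sum(delta > 0) / sum(delta != 0) else NA_real_,
              empty = nrow(m) == 0)
  class(res) <- "DelaySet"
  res
}

#' @export
print.DelaySet <- function(x, ...) {
  if (x$empty) {
    cat("DelaySet: no dual-expressing cells\n")
  } else {
    cat(sprintf(
      "DelaySet: %d dual-expressing cells; median %.1f min, mean %.1f min, %.0f%% positive\n",
      x$n_dual, x$median, x$mean, 100 * x$fraction_positive))
  }
  invisible(x)
}

#' Exact two-sided sign test
#'
#' Tests whether a delay distribution is centered around zero: the signs of
#' the nonzero delays are compared to a symmetric binomial, and the p-value
#' is twice the smaller tail probability, capped at 1.
#'
#' @param deltas numeric vector of paired delays; zeros are dropped.
#' @return p-value in (0, 1].
#' @export
signTest <- function(deltas) {
  deltas <- deltas[!is.na(deltas)]
  nz <- deltas[deltas != 0]
  if (length(nz) == 0) {
    warning("all delays are zero; sign test uninformative")
    return(1)
  }
  n <- length(nz)
  k <- sum(nz > 0)
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' MAPK activity readout of a kinase relocation sensor
#'
#' The sensor exits the nucleus upon phosphorylation, so kinase activity is
#' read as the ratio of cytoplasmic to nuclear fluorescence per frame.
#'
#' @param table a [TraceTable-class].
#' @param channel sensor channel (default "YFP").
#' @return Long data.frame: cell_id, frame_time, activity.
#' @export
kinaseActivity <- function(table, channel = "YFP") {
  stopifnot(is(table, "TraceTable"))
  df <- table@traces[table@traces$channel == channel, , drop = FALSE]
  if (nrow(df) == 0)
    stop(sprintf("channel '%s' not present", channel))
  if (all(is.na(df$cytoplasmic_mean)))
    stop(sprintf("channel '%s' has no cytoplasmic means", channel))
  bad <- which(df$nuclear_mean == 0)
  if (length(bad) > 0)
    stop(sprintf("zero nuclear mean for cell '%s' at frame t = %g",
                 df$cell_id[bad[1]], df$frame_time[bad[1]]))
  data.frame(cell_id = df$cell_id, frame_time = df$frame_time,
             activity = df$cytoplasmic_mean / df$nuclear_mean,
             stringsAsFactors = FALSE)
}
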