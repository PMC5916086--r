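#' Detect cell-fusion events from the tdiRFP channel
#'
#' In mating mixtures the partner constitutively expresses tdiRFP, so
#' fusion transfers a sudden fluorescence step into the tracked cell. A
#' cell is fusing when any frame-to-frame increase of its average nuclear
#' tdiRFP exceeds `jump` (default 50 AU), with the fusion time at the first
#' such frame; non-fusing when its maximal forward increase over the whole
#' track stays at or below `flat` (default 10 AU). Cells between the two
#' thresholds are indeterminate and excluded from both groups; tracks
#' shorter than `min_track_frames` (default 10) are excluded outright.
#'
#' @param table a [TraceTable-class] containing the fusion-marker channel.
#' @param jump frame-to-frame increase defining fusion (AU, strict >).
#' @param flat maximal forward increase compatible with non-fusing (AU,
#'   inclusive <=).
#' @param min_track_frames minimum track length in frames.
#' @param channel fusion-marker channel name (default "tdiRFP").
#' @return data.frame: cell_id, status ("fusing", "non_fusing",
#'   "indeterminate" or "excluded"), fusion_time (NA unless fusing),
#'   track_length, reason.
#' @export
detectFusion <- function(table, jump = 50, flat = 10,
                         min_track_frames = 10, channel = "tdiRFP") {
  stopifnot(is(table, "TraceTable"))
  df <- table@traces[table@traces$channel == channel, , drop = FALSE]
  if (nrow(df) == 0)
    stop(sprintf("channel '%s' not present", channel))
  ids <- unique(df$cell_id)
  rows <- lapply(ids, function(id) {
    sub <- df[df$cell_id == id, , drop = FALSE]
    f <- sub$nuclear_mean
    t <- sub$frame_time
    n <- length(f)
    if (n < min_track_frames)
      return(data.frame(cell_id = id, status = "excluded",
                        fusion_time = NA_real_, track_length = n,
                        reason = "short_track", stringsAsFactors = FALSE))
    steps <- diff(f)
    if (any(steps > jump)) {
      status <- "fusing"
      ft <- t[which(steps > jump)[1] + 1]
      reason <- ""
    } else {
      fwd <- max(f - cummin(f))      # max over i<j of F_j - F_i
      if (fwd <= flat) {
        status <- "non_fusing"; ft <- NA_real_; reason <- ""
      } else {
        status <- "indeterminate"; ft <- NA_real_
        reason <- "increase_between_thresholds"
      }
    }
    data.frame(cell_id = id, status = status, fusion_time = ft,
               track_length = n, reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# per-cell corrected traces for ragged mating tracks (basal = track start)
.matingCorrected <- function(table, channel) {
  enr <- nuclearEnrichment(table, channel)
  split_enr <- split(enr, enr$cell_id)
  lapply(split_enr, function(sub) {
    sub <- sub[order(sub$frame_time), , drop = FALSE]
    preprocessTrace(sub$enrichment, sub$frame_time, basal = "start")
  })
}

#' Expression timing on mating tracks
#'
#' Mating movies have no global stimulation time and tracks start and end
#' at different frames, so the basal level of each cell is taken from the
#' first three frames of its own track and the response-time search starts
#' after that basal window. The population-averaged output is the maximum
#' of the pointwise mean corrected trace over cells present at each frame.
#'
#' @param table a [TraceTable-class].
#' @param channel reporter channel.
#' @param threshold expressing threshold as a fraction of the population
#'   output (default 0.2).
#' @param frac response-time crossing fraction (default 0.2).
#' @return data.frame as in [computeTiming()].
#' @export
matingTiming <- function(table, channel, threshold = 0.2, frac = 0.2) {
  pp <- .matingCorrected(table, channel)
  ids <- names(pp)
  # pointwise population mean over cells present at each frame
  all_t <- sort(unique(unlist(lapply(pp, `[[`, "times"))))
  sums <- numeric(length(all_t)); cnt <- integer(length(all_t))
  for (p in pp) {
    j <- match(p$times, all_t)
    sums[j] <- sums[j] + p$corrected
    cnt[j] <- cnt[j] + 1L
  }
  pop <- max(sums[cnt > 0] / cnt[cnt > 0])
  if (!is.finite(pop) || pop <= 0)
    stop("population non-responsive: population output is not positive")
  rows <- lapply(ids, function(id) {
    p <- pp[[id]]
    after <- p$times[3]                 # end of the basal window
    sel <- p$times > after
    out <- if (any(sel)) max(p$corrected[sel]) else NA_real_
    expressing <- !is.na(out) && out >= threshold * pop
    rt <- NA_real_
    if (expressing && out > 0)
      rt <- responseTime(p$corrected, p$times, out,
                         after = after, frac = frac)
    data.frame(cell_id = id, channel = channel,
               expression_output = out, expressing = expressing,
               response_time = rt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Align corrected traces to the fusion time
#'
#' Shifts every fusing cell's time axis so that its detected fusion frame
#' sits at relative time 0, and computes the population median and
#' 25th-75th percentile bands per relative-time bin over the cells present
#' in that bin.
#'
#' @param table a [TraceTable-class].
#' @param channel reporter channel to align.
#' @param fusion data.frame from [detectFusion()]; only fusing cells are
#'   used.
#' @return List with `aligned` (long data.frame: cell_id, rel_time,
#'   corrected) and `bands` (rel_time, median, q25, q75, n_cells).
#' @export
alignToFusion <- function(table, channel, fusion) {
  fusing <- fusion[fusion$status == "fusing", , drop = FALSE]
  if (nrow(fusing) == 0) stop("no fusing cells")
  pp <- .matingCorrected(table, channel)
  pp <- pp[names(pp) %in% fusing$cell_id]
  ft <- stats::setNames(fusing$fusion_time, fusing$cell_id)
  aligned <- do.call(rbind, lapply(names(pp), function(id)
    data.frame(cell_id = id,
               rel_time = pp[[id]]$times - ft[[id]],
               corrected = pp[[id]]$corrected,
               stringsAsFactors = FALSE)))
  qs <- function(v, p) unname(stats::quantile(v, p, type = 7))
  agg <- split(aligned$corrected, aligned$rel_time)
  bands <- data.frame(
    rel_time = as.numeric(names(agg)),
    median = vapply(agg, stats::median, numeric(1)),
    q25 = vapply(agg, qs, numeric(1), p = 0.25),
    q75 = vapply(agg, qs, numeric(1), p = 0.75),
    n_cells = vapply(agg, length, numeric(1)), row.names = NULL)
  bands <- bands[order(bands$rel_time), , drop = FALSE]
  list(aligned = aligned, bands = bands)
}

#' Response time relative to fusion
#'
#' For fusing cells expressing the channel, the difference between the
#' response time and the fusion time (minutes; negative means the promoter
#' responded before fusion).
#'
#' @param timing data.frame from [matingTiming()] (or [computeTiming()]).
#' @param fusion data.frame from [detectFusion()].
#' @return List with `values` (data.frame: cell_id, rt_rel_fusion),
#'   `n_fusing`, `n_expressing` and `n_omitted` (fusing cells without a
#'   response time).
#' @export
responseTimeRelFusion <- function(timing, fusion) {
  fusing <- fusion[fusion$status == "fusing", , drop = FALSE]
  if (nrow(fusing) == 0) stop("no fusing cells")
  m <- merge(fusing[, c("cell_id", "fusion_time")], timing, by = "cell_id")
  has_rt <- !is.na(m$response_time)
  list(values = data.frame(
         cell_id = m$cell_id[has_rt],
         rt_rel_fusion = m$response_time[has_rt] - m$fusion_time[has_rt],
         stringsAsFactors = FALSE),
       n_fusing = nrow(fusing),
       n_expressing = sum(has_rt),
       n_omitted = sum(!has_rt))
}

#' Empirical cumulative distribution of response times
#'
#' Right-continuous ECDF reaching 1, as used for cumulative-probability
#' plots of response times relative to fusion.
#'
#' @param values numeric vector (length >= 1).
#' @return List with `support` (sorted unique values), `prob` (cumulative
#'   probability at each support point) and `fun` (the step function, from
#'   [stats::ecdf()]).
#' @export
responseEcdf <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("need >= 1 value")
  f <- stats::ecdf(values)
  support <- sort(unique(values))
  list(support = support, prob = f(support), fun = f)
}
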