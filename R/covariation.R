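#' Normalize cell traces by the population mean trace
#'
#' Every cell's corrected trace is divided by the maximum over time of the
#' population mean corrected trace — one scalar per channel — as used for
#' population-average correlation and instant-correlation scatter plots.
#'
#' @param x a [CorrectedTraces-class].
#' @return cells-by-frames matrix of normalized values.
#' @export
normalizeByMeanTrace <- function(x) {
  stopifnot(is(x, "CorrectedTraces"))
  norm <- max(colMeans(x@corrected))
  if (!is.finite(norm) || norm <= 0)
    stop("non-positive normalizer: population mean trace never rises")
  m <- x@corrected / norm
  rownames(m) <- x@cell_ids
  colnames(m) <- x@times
  m
}

#' Min-max normalization by the population-averaged trace
#'
#' Values are mapped through (x - m) / (M - m) where m and M are the lowest
#' and highest values over time of the population-averaged trace of the
#' channel for one replicate. Individual cells may fall outside 0..1.
#' By default the smoothed (not basal-subtracted) traces are used, so
#' pre-stimulus cell-to-cell heterogeneity in basal expression is retained —
#' this is the input of the correlative promoter variability.
#'
#' @param x a [CorrectedTraces-class].
#' @param use `"smoothed"` (default) or `"corrected"`.
#' @return cells-by-frames matrix of normalized values.
#' @export
minmaxNormalize <- function(x, use = c("smoothed", "corrected")) {
  use <- match.arg(use)
  stopifnot(is(x, "CorrectedTraces"))
  mat <- slot(x, use)
  mu <- colMeans(mat)
  m <- min(mu); M <- max(mu)
  if (M - m <= 0)
    stop("degenerate normalization: population-averaged trace is constant")
  out <- (mat - m) / (M - m)
  rownames(out) <- x@cell_ids
  colnames(out) <- x@times
  out
}

#' Population correlation trajectory of two reporters
#'
#' One point per frame: the population means of the min-max-normalized
#' traces of the reference (x) and test (y) channel. For two reporters with
#' identical dynamics the trajectory runs along the x = y diagonal from
#' near (0,0) to near (1,1); a delayed test promoter bows the curve below
#' the diagonal.
#'
#' @param ref,test [CorrectedTraces-class] objects on the same frame grid
#'   (reference on x, test on y).
#' @param use trace matrix to normalize, see [minmaxNormalize()].
#' @return data.frame: time, x, y, ordered by ascending time.
#' @export
correlationTrajectory <- function(ref, test, use = "smoothed") {
  if (!isTRUE(all.equal(ref@times, test@times)))
    stop("frame grids of the two channels differ")
  data.frame(time = ref@times,
             x = colMeans(minmaxNormalize(ref, use)),
             y = colMeans(minmaxNormalize(test, use)),
             row.names = NULL)
}

.offsetTier <- function(p) {
  if (p < 1e-6) "p<1e-6" else if (p < 1e-3) "1e-3>p>1e-6" else "none"
}

#' Diagonal-offset test at one time point
#'
#' Each cell's offset from the x = y line is the perpendicular distance
#' d = (y - x) / sqrt(2) of its normalized reporter pair. The offsets of
#' the test strain are compared with those of the reference strain by a
#' Welch (unequal-variance) two-sample t-test, and the p-value is mapped to
#' the significance tiers used when plotting correlation trajectories.
#'
#' @param test_x,test_y normalized values of the two channels in the test
#'   strain (one value per cell).
#' @param ref_x,ref_y same for the reference strain.
#' @return List with `p` and `tier` (one of "none", "1e-3>p>1e-6",
#'   "p<1e-6").
#' @export
diagonalOffsetTest <- function(test_x, test_y, ref_x, ref_y) {
  stopifnot(length(test_x) == length(test_y),
            length(ref_x) == length(ref_y))
  if (length(test_x) < 2 || length(ref_x) < 2)
    stop("need >= 2 cells per strain")
  d_test <- (test_y - test_x) / sqrt(2)
  d_ref <- (ref_y - ref_x) / sqrt(2)
  if (stats::var(d_test) == 0 && stats::var(d_ref) == 0) {
    warning("zero variance in both groups; p set to 1")
    return(list(p = 1, tier = "none"))
  }
  p <- stats::t.test(d_test, d_ref, var.equal = FALSE)$p.value
  list(p = p, tier = .offsetTier(p))
}

#' Diagonal-offset test over all frames
#'
#' Applies [diagonalOffsetTest()] at every frame of the experiment. No
#' multiple-testing correction is applied across time points; raw per-time
#' tiers are reported.
#'
#' @param test_ref,test_test [CorrectedTraces-class] of the reference (x)
#'   and test (y) channel in the test strain.
#' @param ref_ref,ref_test same pair in the reference strain.
#' @param use trace matrix to normalize, see [minmaxNormalize()].
#' @return data.frame: time, p, tier.
#' @export
offsetTestSeries <- function(test_ref, test_test, ref_ref, ref_test,
                             use = "smoothed") {
  if (!isTRUE(all.equal(test_ref@times, ref_ref@times)))
    stop("frame grids of the two strains differ")
  tx <- minmaxNormalize(test_ref, use); ty <- minmaxNormalize(test_test, use)
  rx <- minmaxNormalize(ref_ref, use); ry <- minmaxNormalize(ref_test, use)
  res <- lapply(seq_along(test_ref@times), function(j)
    diagonalOffsetTest(tx[, j], ty[, j], rx[, j], ry[, j]))
  data.frame(time = test_ref@times,
             p = vapply(res, `[[`, numeric(1), "p"),
             tier = vapply(res, `[[`, character(1), "tier"),
             stringsAsFactors = FALSE)
}

#' Correlative promoter variability
#'
#' The ratio of intrinsic to total noise of a dual-reporter pair, following
#' the classic dual-reporter decomposition: with r_i and y_i the normalized
#' nuclear accumulations of the two reporters in cell i,
#' eta^2_int = <(r - y)^2> / (2 <r><y>) and
#' eta^2_tot = (<r^2> + <y^2> - 2 <r><y>) / (2 <r><y>), and
#' CPV = eta^2_int / eta^2_tot = <(r - y)^2> / (<r^2> + <y^2> - 2 <r><y>).
#' The common denominator cancels, so CPV is invariant under any affine
#' transform applied to both channels. CPV is 0 for perfectly co-regulated
#' reporters and tends to 1 for independent ones.
#'
#' @param r,y numeric vectors of normalized values, same cells in the same
#'   order.
#' @return Scalar CPV (>= 0), or `NA` with a warning when the total-noise
#'   denominator is zero.
#' @export
cpv <- function(r, y) {
  stopifnot(length(r) == length(y))
  if (length(r) < 2) stop("need >= 2 cells")
  num <- mean((r - y)^2)
  den <- mean(r^2) + mean(y^2) - 2 * mean(r) * mean(y)
  if (den == 0) {
    warning("zero total-noise denominator; CPV undefined")
    return(NA_real_)
  }
  num / den
}

#' CPV over time with replicate aggregation
#'
#' Each replicate is min-max normalized within itself (per channel), CPV is
#' computed at every frame, and the across-replicate mean and standard
#' deviation are reported per time point.
#'
#' @param replicates list of replicates, each a list with elements `r` and
#'   `y`, the [CorrectedTraces-class] of the two channels for the same
#'   cells. All replicates must share one frame grid.
#' @param use trace matrix to normalize, see [minmaxNormalize()].
#' @return A [CPVSeries-class].
#' @export
cpvSeries <- function(replicates, use = "smoothed") {
  stopifnot(length(replicates) >= 1)
  times <- replicates[[1]]$r@times
  rows <- list()
  for (k in seq_along(replicates)) {
    rep_k <- replicates[[k]]
    if (!isTRUE(all.equal(rep_k$r@times, times)) ||
        !isTRUE(all.equal(rep_k$y@times, times)))
      stop("replicates have different frame grids")
    if (!identical(rep_k$r@cell_ids, rep_k$y@cell_ids))
      stop("the two channels of a replicate must cover the same cells")
    rn <- minmaxNormalize(rep_k$r, use)
    yn <- minmaxNormalize(rep_k$y, use)
    rows[[k]] <- data.frame(
      time = times, replicate = k,
      cpv = vapply(seq_along(times),
                   function(j) cpv(rn[, j], yn[, j]), numeric(1)),
      n_cells = length(rep_k$r@cell_ids))
  }
  per_rep <- do.call(rbind, rows)
  mu <- tapply(per_rep$cpv, per_rep$time, mean)
  sdv <- tapply(per_rep$cpv, per_rep$time,
                function(v) if (length(v) > 1) stats::sd(v) else 0)
  ord <- order(as.numeric(names(mu)))
  new("CPVSeries", times = times, per_replicate = per_rep,
      summary = data.frame(time = as.numeric(names(mu))[ord],
                           mean_cpv = as.numeric(mu)[ord],
                           sd_cpv = as.numeric(sdv)[ord]))
}
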