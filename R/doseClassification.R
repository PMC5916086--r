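#' Hill dose-response fit
#'
#' Least-squares fit of E(c) = base + amplitude * c^n / (ec50^n + c^n) to
#' per-dose mean expression outputs, with multi-start over Hill coefficients
#' {0.5, 1, 2, 4} and EC50 starting values at the quartiles of the positive
#' doses. The fit distinguishes graded induction (n near 1) from the
#' switch-like behavior of late mating promoters (n near 3). The 0-dose
#' control enters as c = 0, where E = base.
#'
#' @param doses numeric pheromone concentrations in nM, including a 0
#'   control; at least 4 distinct positive doses required.
#' @param outputs mean expression output per dose (AU), finite.
#' @param weights optional per-dose weights (e.g. 1/sd^2); unweighted by
#'   default.
#' @return List with `base`, `amplitude`, `ec50`, `hill_n`, `residual`
#'   (sum of squared residuals), `converged` and `fitted` (per-dose fitted
#'   values).
#' @export
hillFit <- function(doses, outputs, weights = NULL) {
  stopifnot(length(doses) == length(outputs))
  if (!all(is.finite(outputs))) stop("outputs must be finite")
  pos <- sort(unique(doses[doses > 0]))
  if (length(pos) < 4)
    stop("need >= 4 distinct positive doses plus a 0-dose control")
  if (!any(doses == 0)) stop("a 0-dose control is required")
  if (is.null(weights)) weights <- rep(1, length(doses))
  hill <- function(c, base, amplitude, ec50, n)
    base + amplitude * ifelse(c > 0, c^n / (ec50^n + c^n), 0)
  rng <- diff(range(outputs))
  if (rng == 0) {
    # constant outputs: amplitude ~ 0, the Hill coefficient unidentifiable
    return(list(base = outputs[1], amplitude = 0, ec50 = stats::median(pos),
                hill_n = NA_real_, residual = 0, converged = FALSE,
                fitted = outputs))
  }
  starts <- expand.grid(
    n = c(0.5, 1, 2, 4),
    ec50 = stats::quantile(pos, c(0.25, 0.5, 0.75), names = FALSE))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        outputs ~ hill(doses, base, amplitude, ec50, n),
        start = list(base = min(outputs), amplitude = rng,
                     ec50 = starts$ec50[i], n = starts$n[i]),
        weights = weights,
        lower = c(base = -Inf, amplitude = 0,
                  ec50 = min(pos) / 100, n = 0.05),
        upper = c(base = Inf, amplitude = Inf,
                  ec50 = max(pos) * 100, n = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(weights * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$residual) {
      p <- as.list(stats::coef(fit))
      best <- list(base = p$base, amplitude = p$amplitude, ec50 = p$ec50,
                   hill_n = p$n, residual = rss, converged = TRUE,
                   fitted = stats::fitted(fit))
    }
  }
  if (is.null(best))
    stop("Hill fit failed to converge from every start; ",
         "check that outputs rise with dose")
  best
}

#' Promoter timing classification
#'
#' Assigns a promoter to the early / intermediate / late timing class from
#' its paired delays relative to the reference promoter and from the
#' diagonal-offset significance series of its correlation trajectory.
#' A promoter is late when its median delay is at least `late_delay` (the
#' study's 15 min) and its offsets deviate significantly from the reference
#' at a majority of post-stimulus time points; early when the median delay
#' is within `early_delay` of zero and significant offsets are sporadic;
#' intermediate otherwise. The 15-min bound comes from the study; the
#' remaining cut-offs operationalize its qualitative rule and are
#' configurable.
#'
#' @param delay_set a `"DelaySet"` from [pairedDelay()].
#' @param offset_series data.frame from [offsetTestSeries()]; only rows
#'   with time > 0 are used.
#' @param late_delay minutes (default 15); median delay at or above this is
#'   required for the late class.
#' @param early_delay minutes (default 5); |median delay| below this is
#'   required for the early class.
#' @param sig_level per-time significance level (default 1e-3).
#' @param late_frac,early_frac fraction of significant post-stimulus time
#'   points required for late (>= 0.5) / tolerated for early (< 0.25).
#' @return List with `class` ("early", "intermediate", "late" or
#'   "unclassifiable"), and `evidence` (median_delta, sign_test_p,
#'   fraction_significant_offsets).
#' @export
classifyPromoter <- function(delay_set, offset_series,
                             late_delay = 15, early_delay = 5,
                             sig_level = 1e-3,
                             late_frac = 0.5, early_frac = 0.25) {
  if (isTRUE(delay_set$empty))
    return(list(class = "unclassifiable",
                evidence = list(median_delta = NA_real_,
                                sign_test_p = NA_real_,
                                fraction_significant_offsets = NA_real_)))
  post <- offset_series[offset_series$time > 0, , drop = FALSE]
  if (nrow(post) == 0) stop("offset series has no post-stimulus frames")
  frac_sig <- mean(post$p < sig_level)
  med <- delay_set$median
  p_sign <- signTest(delay_set$deltas$delta)
  klass <- if (med >= late_delay && frac_sig >= late_frac) "late"
  else if (abs(med) < early_delay && frac_sig < early_frac) "early"
  else "intermediate"
  list(class = klass,
       evidence = list(median_delta = med, sign_test_p = p_sign,
                       fraction_significant_offsets = frac_sig))
}
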