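#' Synthetic trace-generator parameters
#'
#' Builds the parameter bundle of the synthetic single-cell trace
#' generator. The generator emulates the statistical structure the
#' analysis assumes: a per-cell expression capacity E (lognormal, shared
#' by all reporters of a cell — the extrinsic noise), reporter-specific
#' lognormal amplitude jitter (intrinsic noise), heterogeneous onset times
#' (early reporters follow a Gamma law; late reporters fire a
#' commitment delay after the early onset of the same cell), optional
#' pheromone-dose gating of the amplitude through a Hill function,
#' optional cell-cycle basal pulses, and additive Gaussian measurement
#' noise on each compartment.
#'
#' The noiseless corrected signal of a responding cell is a linear ramp
#' `A * E * I * H(dose) * clip((t - t0)/t_ramp, 0, 1)` with
#' `t0 = tau - 0.2 * t_ramp`, so the 20% crossing of the ramp is exactly
#' the true onset `tau` — the generator's ground truth is defined in the
#' same observable the response-time estimator measures.
#'
#' @param n_cells number of cells.
#' @param times_pre,times_post frame grids in minutes (defaults
#'   `seq(-6, 0, 2)` and `seq(5, 100, 5)`; stimulation at t = 0).
#' @param responder_fraction fraction of cells that respond at all.
#' @param sigma_E sd of log expression capacity (lognormal, log-mean 0).
#' @param sigma_I sd of log reporter-specific amplitude jitter.
#' @param measurement_sd additive Gaussian noise sd per compartment (AU).
#' @param cytoplasm_baseline baseline fluorescence of both compartments.
#' @param reporters named list (names are channels); each element a list
#'   with `role` ("early" or "late"), `amplitude` (AU) and `basal`
#'   (constant basal enrichment in AU, scaled by E and I like the signal).
#' @param t_ramp signal rise time, 0 to 100% (minutes).
#' @param onset_shape,onset_scale Gamma law of the early onset (minutes).
#' @param delta_mean,delta_sd Normal law of the late commitment delay
#'   (minutes); shared per cell across late reporters.
#' @param late_jitter_sd per-late-reporter onset jitter sd (minutes).
#' @param share_onset if FALSE, every reporter draws its own independent
#'   onset (removes the shared-onset extrinsic component).
#' @param dose NULL, or list(conc, hill_n, ec50): amplitudes are scaled by
#'   `conc^n / (ec50^n + conc^n)`.
#' @param cellcycle NULL, or list(channels, amplitude, period): adds a
#'   sinusoidal basal pulse with random phase to the named channels.
#' @param min_onset earliest allowed onset (minutes, default 1).
#' @param seed RNG seed.
#' @return A validated parameter list of class `"SimParams"`.
#' @export
simParams <- function(n_cells = 500,
                      times_pre = seq(-6, 0, by = 2),
                      times_post = seq(5, 100, by = 5),
                      responder_fraction = 0.91,
                      sigma_E = 0.3, sigma_I = 0.1,
                      measurement_sd = 1, cytoplasm_baseline = 100,
                      reporters = list(
                        YFP = list(role = "early", amplitude = 20, basal = 2),
                        RFP = list(role = "late", amplitude = 10, basal = 2)),
                      t_ramp = 15,
                      onset_shape = 4, onset_scale = 4.3,
                      delta_mean = 23, delta_sd = 20, late_jitter_sd = 0,
                      share_onset = TRUE,
                      dose = NULL, cellcycle = NULL,
                      min_onset = 1, seed = 1) {
  p <- list(n_cells = n_cells, times_pre = times_pre,
            times_post = times_post,
            responder_fraction = responder_fraction,
            sigma_E = sigma_E, sigma_I = sigma_I,
            measurement_sd = measurement_sd,
            cytoplasm_baseline = cytoplasm_baseline,
            reporters = reporters, t_ramp = t_ramp,
            onset_shape = onset_shape, onset_scale = onset_scale,
            delta_mean = delta_mean, delta_sd = delta_sd,
            late_jitter_sd = late_jitter_sd, share_onset = share_onset,
            dose = dose, cellcycle = cellcycle,
            min_onset = min_onset, seed = seed)
  stopifnot(p$n_cells >= 1,
            p$responder_fraction >= 0, p$responder_fraction <= 1,
            p$sigma_E >= 0, p$sigma_I >= 0, p$measurement_sd >= 0,
            p$t_ramp > 0, p$late_jitter_sd >= 0)
  if (p$min_onset >= max(p$times_post))
    stop("frame grid too short for the earliest allowed onset")
  class(p) <- "SimParams"
  p
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

.doseScale <- function(dose) {
  if (is.null(dose)) return(1)
  if (dose$conc <= 0) return(0)
  dose$conc^dose$hill_n / (dose$ec50^dose$hill_n + dose$conc^dose$hill_n)
}

#' Simulate a stimulated cell population
#'
#' Draws a population under the generator model of [simParams()] and emits
#' a [TraceTable-class] (channels: the configured reporters plus a
#' constant-plus-noise CFP nuclear marker and per-frame areas) together
#' with the per-cell ground truth for parameter-recovery tests.
#'
#' @param params a `"SimParams"` list from [simParams()] or [simPreset()].
#' @return List with `traces` (a [TraceTable-class]) and `truth`
#'   (data.frame: cell_id, responder, E, commitment, and per reporter
#'   `tau_<channel>` and `amp_<channel>`; `tau` is the true 20%-crossing
#'   time, NA for non-responders).
#' @export
simulatePopulation <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(params$seed)
  times <- c(params$times_pre, params$times_post)
  n <- params$n_cells
  ids <- sprintf("cell_%04d", seq_len(n))
  responder <- stats::runif(n) < params$responder_fraction
  E <- exp(stats::rnorm(n, 0, params$sigma_E))
  # onsets are truncated so the sub-threshold foot of the ramp
  # (tau - 0.2 * t_ramp) never precedes the stimulation
  min_onset <- max(params$min_onset, 0.2 * params$t_ramp)
  tau_shared <- pmax(min_onset,
                     stats::rgamma(n, shape = params$onset_shape,
                                   scale = params$onset_scale))
  delta_shared <- stats::rnorm(n, params$delta_mean, params$delta_sd)
  H <- .doseScale(params$dose)
  truth <- data.frame(cell_id = ids, responder = responder, E = E,
                      commitment = NA_real_, stringsAsFactors = FALSE)
  all_rows <- list()
  for (ch in names(params$reporters)) {
    rep_cfg <- params$reporters[[ch]]
    I <- exp(stats::rnorm(n, 0, params$sigma_I))
    if (rep_cfg$role == "early") {
      tau <- if (params$share_onset) tau_shared else
        pmax(min_onset,
             stats::rgamma(n, shape = params$onset_shape,
                           scale = params$onset_scale))
    } else {
      jit <- if (params$late_jitter_sd > 0)
        stats::rnorm(n, 0, params$late_jitter_sd) else 0
      tau <- pmax(min_onset, tau_shared + delta_shared + jit)
      truth$commitment <- tau - tau_shared
    }
    amp <- rep_cfg$amplitude * E * I * H
    amp[!responder] <- 0
    basal <- rep_cfg$basal * E * I
    t0 <- tau - 0.2 * params$t_ramp
    ramp <- .clip01(outer(-t0, times, `+`) / params$t_ramp)   # (t - t0)/T
    signal <- amp * ramp
    if (!is.null(params$cellcycle) &&
        ch %in% params$cellcycle$channels) {
      phase <- stats::runif(n, 0, params$cellcycle$period)
      pulse <- params$cellcycle$amplitude *
        (1 + sin(2 * pi * outer(phase, times, `+`) /
                   params$cellcycle$period)) / 2
      signal <- signal + pulse
    }
    nm <- length(times)
    noise_nuc <- matrix(stats::rnorm(n * nm, 0, params$measurement_sd),
                        n, nm)
    noise_cyt <- matrix(stats::rnorm(n * nm, 0, params$measurement_sd),
                        n, nm)
    nuc_mat <- params$cytoplasm_baseline + basal + signal + noise_nuc
    cyt_mat <- params$cytoplasm_baseline + noise_cyt
    all_rows[[ch]] <- data.frame(
      cell_id = rep(ids, each = nm), replicate_id = "R1",
      frame_time = rep(times, n), channel = ch,
      nuclear_mean = pmax(0, as.vector(t(nuc_mat))),
      cytoplasmic_mean = pmax(0, as.vector(t(cyt_mat))),
      nuclear_area = 25 * (1 + stats::rnorm(n * nm, 0, 0.02)),
      cell_area = 400 * (1 + stats::rnorm(n * nm, 0, 0.02)),
      stringsAsFactors = FALSE)
    truth[[paste0("tau_", ch)]] <- ifelse(responder, tau, NA_real_)
    truth[[paste0("amp_", ch)]] <- amp
  }
  nm <- length(times)
  all_rows[["CFP"]] <- data.frame(
    cell_id = rep(ids, each = nm), replicate_id = "R1",
    frame_time = rep(times, n), channel = "CFP",
    nuclear_mean = pmax(0, 150 + stats::rnorm(n * nm, 0, 1)),
    cytoplasmic_mean = NA_real_,
    nuclear_area = 25 * (1 + stats::rnorm(n * nm, 0, 0.02)),
    cell_area = 400 * (1 + stats::rnorm(n * nm, 0, 0.02)),
    stringsAsFactors = FALSE)
  list(traces = TraceTable(do.call(rbind, all_rows)), truth = truth)
}

#' Simulate a mating mixture
#'
#' Fusing cells receive a fusion time drawn uniformly over mid-movie
#' frames, a tdiRFP trace that steps up by `step` at fusion on top of a
#' noisy baseline, an early-reporter onset preceding fusion by
#' Normal(`early_offset`) minutes and a late-reporter onset preceding it
#' by Normal(`late_offset`) minutes (late onsets are tighter — late genes
#' fire close to fusion). Non-fusing cells never step, and express only
#' the early reporter, with probability `p_express_nonfusing`. Tracks
#' start and end at random frames but always keep at least
#' `min_track_frames` frames and, for fusing cells, cover the fusion
#' frame.
#'
#' @param params a `"SimParams"`-like list from
#'   `simPreset("mating_mix")`; relevant fields: `n_cells`, `times`
#'   (default `seq(0, 150, 5)`), `fusing_fraction`, `fusion_window`,
#'   `tdirfp_baseline`, `step`, `drift_sd`, `early_offset` and
#'   `late_offset` (length-2 mean/sd), `p_express_nonfusing`,
#'   `min_track_frames`, plus the reporter/noise fields of [simParams()].
#' @return List with `traces` (a [TraceTable-class] including a tdiRFP
#'   channel) and `truth` (cell_id, fusing, fusion_time, E, per-reporter
#'   tau).
#' @export
simulateMating <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  m <- params$mating
  if (is.null(m)) stop("mating model not enabled in params")
  set.seed(params$seed)
  times <- m$times
  dt <- times[2] - times[1]
  n <- params$n_cells
  ids <- sprintf("cell_%04d", seq_len(n))
  fusing <- stats::runif(n) < m$fusing_fraction
  grid_win <- times[times >= m$fusion_window[1] &
                      times <= m$fusion_window[2]]
  T_f <- ifelse(fusing, sample(grid_win, n, replace = TRUE), NA_real_)
  E <- exp(stats::rnorm(n, 0, params$sigma_E))
  truth <- data.frame(cell_id = ids, fusing = fusing, fusion_time = T_f,
                      E = E, tau_YFP = NA_real_, tau_RFP = NA_real_,
                      stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    if (fusing[i]) {
      start <- dt * sample(0:3, 1)
      start <- max(0, min(start, T_f[i] - (m$min_track_frames - 2) * dt))
      end <- min(max(times), T_f[i] + dt * sample(2:8, 1))
      tau_e <- max(start + 3 * dt,
                   T_f[i] - stats::rnorm(1, m$early_offset[1],
                                         m$early_offset[2]))
      tau_l <- max(start + 3 * dt,
                   T_f[i] - stats::rnorm(1, m$late_offset[1],
                                         m$late_offset[2]))
    } else {
      len <- dt * (m$min_track_frames - 1 + sample(0:20, 1))
      start <- dt * sample(0:6, 1)
      end <- start + len
      if (end > max(times)) { start <- start - (end - max(times))
                              end <- max(times) }
      start <- max(0, start)
      tau_e <- if (stats::runif(1) < m$p_express_nonfusing)
        max(start + 3 * dt, stats::runif(1, 30, 120)) else NA_real_
      tau_l <- NA_real_
    }
    tt <- times[times >= start & times <= end]
    nt <- length(tt)
    truth$tau_YFP[i] <- tau_e; truth$tau_RFP[i] <- tau_l
    for (ch in c("YFP", "RFP")) {
      rep_cfg <- params$reporters[[ch]]
      tau <- if (ch == "YFP") tau_e else tau_l
      I <- exp(stats::rnorm(1, 0, params$sigma_I))
      amp <- rep_cfg$amplitude * E[i] * I
      sig <- if (is.na(tau)) rep(0, nt) else
        amp * .clip01((tt - (tau - 0.2 * params$t_ramp)) / params$t_ramp)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = ids[i], replicate_id = "R1", frame_time = tt,
        channel = ch,
        nuclear_mean = pmax(0, params$cytoplasm_baseline +
                              rep_cfg$basal * E[i] * I + sig +
                              stats::rnorm(nt, 0, params$measurement_sd)),
        cytoplasmic_mean = pmax(0, params$cytoplasm_baseline +
                                  stats::rnorm(nt, 0,
                                               params$measurement_sd)),
        nuclear_area = 25 * (1 + stats::rnorm(nt, 0, 0.02)),
        cell_area = 400 * (1 + stats::rnorm(nt, 0, 0.02)),
        stringsAsFactors = FALSE)
    }
    td <- m$tdirfp_baseline + stats::rnorm(nt, 0, m$drift_sd)
    if (fusing[i]) td <- td + m$step * (tt >= T_f[i])
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = ids[i], replicate_id = "R1", frame_time = tt,
      channel = "tdiRFP", nuclear_mean = pmax(0, td),
      cytoplasmic_mean = NA_real_,
      nuclear_area = 25 * (1 + stats::rnorm(nt, 0, 0.02)),
      cell_area = 400 * (1 + stats::rnorm(nt, 0, 0.02)),
      stringsAsFactors = FALSE)
  }
  list(traces = TraceTable(do.call(rbind, rows)), truth = truth)
}

#' Documented generator presets
#'
#' Named parameter bundles reproducing the study conditions the pipeline
#' is validated against:
#' \describe{
#'   \item{fig1f}{dual reporter, early YFP (amplitude 20 AU) vs late RFP
#'     (10 AU): 91% responders, early onset Gamma(shape 4, scale 4.3) min,
#'     commitment delay Normal(23, 20) min, sigma_E 0.3, sigma_I 0.1,
#'     measurement sd 1 AU, ramp 15 min.}
#'   \item{early_pair}{two early reporters sharing onset and capacity,
#'     basal enrichment 5 AU each — the co-regulated pair whose
#'     pre-stimulus CPV stays below 50%.}
#'   \item{late_pair}{early reference plus late test reporter (the fig1f
#'     kinetics), used for the late-class rule.}
#'   \item{intrinsic_only}{sigma_E 0, sigma_I 0.3, independent onsets:
#'     CPV near 1 at all times.}
#'   \item{dose_series_early}{graded dose response, hill_n 1, ec50 30 nM,
#'     doses {0, 10, 30, 100, 300, 1000} nM, 200 cells per dose.}
#'   \item{dose_series_late}{switch-like dose response, hill_n 3,
#'     ec50 300 nM, same doses.}
#'   \item{mating_mix}{mating pad: 60% fusing cells, fusion uniform over
#'     40-110 min, tdiRFP baseline 50 + step 100 AU, drift sd 3 AU; early
#'     onset fusion - Normal(60, 25) min, late onset fusion -
#'     Normal(30, 8) min; non-fusing cells express the early reporter
#'     with probability 0.7.}
#' }
#'
#' @param name preset name.
#' @param n_cells optional override of the cell count (per dose for the
#'   dose presets).
#' @param seed RNG seed.
#' @return A `"SimParams"` list.
#' @export
simPreset <- function(name, n_cells = NULL, seed = 1) {
  presets <- c("fig1f", "early_pair", "late_pair", "intrinsic_only",
               "dose_series_early", "dose_series_late", "mating_mix")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  p <- switch(name,
    fig1f = simParams(n_cells = 500, seed = seed),
    late_pair = simParams(n_cells = 500, seed = seed),
    early_pair = simParams(
      n_cells = 300, responder_fraction = 0.95, seed = seed,
      reporters = list(
        YFP = list(role = "early", amplitude = 20, basal = 5),
        RFP = list(role = "early", amplitude = 20, basal = 5))),
    intrinsic_only = simParams(
      n_cells = 300, responder_fraction = 1,
      sigma_E = 0, sigma_I = 0.3, share_onset = FALSE, seed = seed,
      reporters = list(
        YFP = list(role = "early", amplitude = 20, basal = 5),
        RFP = list(role = "early", amplitude = 20, basal = 5))),
    dose_series_early = simParams(
      n_cells = 200, responder_fraction = 1, seed = seed,
      reporters = list(
        YFP = list(role = "early", amplitude = 20, basal = 2)),
      dose = list(conc = 1000, hill_n = 1, ec50 = 30)),
    dose_series_late = simParams(
      n_cells = 200, responder_fraction = 1, seed = seed,
      reporters = list(
        RFP = list(role = "late", amplitude = 20, basal = 2)),
      dose = list(conc = 1000, hill_n = 3, ec50 = 300)),
    mating_mix = {
      pm <- simParams(n_cells = 60, responder_fraction = 1, seed = seed,
                      reporters = list(
                        YFP = list(role = "early", amplitude = 20,
                                   basal = 2),
                        RFP = list(role = "late", amplitude = 10,
                                   basal = 2)))
      pm$mating <- list(times = seq(0, 150, by = 5),
                        fusing_fraction = 0.6,
                        fusion_window = c(40, 110),
                        tdirfp_baseline = 50, step = 100, drift_sd = 3,
                        early_offset = c(60, 25), late_offset = c(30, 8),
                        p_express_nonfusing = 0.7, min_track_frames = 10)
      pm
    })
  if (!is.null(n_cells)) p$n_cells <- n_cells
  p$preset <- name
  p
}

#' Dose-response curve from a dose-series preset
#'
#' Simulates one population per dose (seeds derived from the base seed),
#' runs the trace-correction and expression-output stages, and returns the
#' mean expression output per dose over all cells — the input of
#' [hillFit()].
#'
#' @param params a dose-series `"SimParams"` (see [simPreset()]); the
#'   reporter channel is taken from the params.
#' @param doses doses in nM (default `c(0, 10, 30, 100, 300, 1000)`).
#' @return data.frame: dose_nM, mean_output, sd, n_cells.
#' @export
simulateDoseResponse <- function(params,
                                 doses = c(0, 10, 30, 100, 300, 1000)) {
  stopifnot(inherits(params, "SimParams"), !is.null(params$dose))
  ch <- names(params$reporters)[1]
  rows <- lapply(seq_along(doses), function(k) {
    pk <- params
    pk$dose$conc <- doses[k]
    pk$seed <- params$seed + k - 1
    sim <- simulatePopulation(pk)
    ct <- correctTraces(sim$traces, ch)
    out <- expressionOutput(ct)
    data.frame(dose_nM = doses[k], mean_output = mean(out),
               sd = stats::sd(out), n_cells = length(out))
  })
  do.call(rbind, rows)
}
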