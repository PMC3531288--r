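#' Specification for the synthetic fluorescence trace generator
#'
#' Defaults emulate the statistical structure of the real recordings the
#' trace analysis was designed for: 1.2 s sampling; mean cell-to-cell lag
#' 1.8 s with per-pair lags varying by up to a factor of two; pulses with
#' a fast rise (3 s) and a slower decay (to 10\% in 12 s), so the full
#' pulse width is on the order of 10 to 15 s; and a propagation range of
#' 4.7 cells beyond the stimulated cell.
#'
#' @param n_cells number of cells (default 15).
#' @param layout \code{"chain"} or \code{"dual"}.
#' @param stimulated stimulated cell indices (defaults: middle cell for
#'   \code{"chain"}; two cells separated by 7 around the middle for
#'   \code{"dual"}).
#' @param mean_lag,lag_dispersion,rise_time,decay_time,amplitude,noise_sd
#'   see [TraceGeneratorSpec-class].
#' @param sample_interval,propagation_range,seed see
#'   [TraceGeneratorSpec-class].
#' @return a [TraceGeneratorSpec-class].
#' @export
traceGeneratorSpec <- function(n_cells = 15, layout = c("chain", "dual"),
                               stimulated = NULL, mean_lag = 1.8,
                               lag_dispersion = 2, rise_time = 3,
                               decay_time = 12, amplitude = 1,
                               noise_sd = 0.05, sample_interval = 1.2,
                               propagation_range = 4.7, seed = 1L) {
  layout <- match.arg(layout)
  if (is.null(stimulated)) {
    mid <- ceiling(n_cells / 2)
    stimulated <- if (layout == "chain") mid else
      c(max(1, mid - 4), min(n_cells, mid + 3))
  }
  new("TraceGeneratorSpec", n_cells = n_cells, layout = layout,
      stimulated = stimulated, mean_lag = mean_lag,
      lag_dispersion = lag_dispersion, rise_time = rise_time,
      decay_time = decay_time, amplitude = amplitude, noise_sd = noise_sd,
      sample_interval = sample_interval,
      propagation_range = propagation_range, seed = seed)
}

setMethod("show", "TraceGeneratorSpec", function(object) {
  cat(sprintf(
    paste0("TraceGeneratorSpec: %d cells (%s), stimulated [%s], ",
           "lag %g s (x%g), noise sd %g, seed %d\n"),
    as.integer(object@n_cells), object@layout,
    paste(object@stimulated, collapse = ", "), object@mean_lag,
    object@lag_dispersion, object@noise_sd, as.integer(object@seed)))
})

# Pulse shape on the normalized-intensity scale: 0 before onset, linear
# rise to 1 over rise_time, then exponential decay reaching 10% of the
# peak decay_time seconds after the peak.
.pulse_shape <- function(t, onset, rise_time, decay_time) {
  tau <- decay_time / log(10)
  s <- numeric(length(t))
  rising <- t >= onset & t < onset + rise_time
  falling <- t >= onset + rise_time
  s[rising] <- (t[rising] - onset) / rise_time
  s[falling] <- exp(-(t[falling] - onset - rise_time) / tau)
  s
}

# Run fn with a private, seeded RNG stream; the caller's RNG state is
# untouched.
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

#' Generate a synthetic fluorescence trace set with ground truth
#'
#' Responding cells receive a pulse (baseline 1 plus the rise/decay shape
#' scaled by \code{amplitude} on the normalized scale) whose onset is
#' shifted by cumulative per-pair lags \code{mean_lag * U}, U uniform on
#' \code{[1/lag_dispersion, lag_dispersion]}; cells farther than
#' \code{round(propagation_range)} cells from a stimulated cell do not
#' respond.  Additive Gaussian noise with sd \code{noise_sd} is applied on
#' the normalized-intensity scale.  All randomness is drawn from one
#' generator seeded with \code{spec@seed}; fixed seed means bit-identical
#' output.
#'
#' @param spec a [TraceGeneratorSpec-class].
#' @param duration recording duration in seconds (default: long enough for
#'   the farthest pulse to decay).
#' @param style \code{"normalized"} (default): intensities on the
#'   normalized scale, baseline 1 plus pulse plus noise, ready for
#'   [callResponse()].  \code{"raw"}: additionally scaled by
#'   \code{resting_intensity}, offset by \code{background_level}, with a
#'   background series emitted, so that [normalizeTraces()] recovers the
#'   normalized pulses.
#' @param resting_intensity raw intensity corresponding to normalized 1
#'   (default 100; \code{style = "raw"} only).
#' @param background_level raw background intensity (default 50;
#'   \code{style = "raw"} only).
#' @return list with \code{traces} (a [FluorescenceTraceSet-class])
#'   and \code{truth}: per-cell \code{responder} flags, true
#'   \code{response_time}s (seconds; max-rate definition on the noiseless
#'   sampled trace), true \code{onset}s and per-pair \code{lags}.
#' @export
generateTraces <- function(spec, duration = NULL,
                           style = c("normalized", "raw"),
                           resting_intensity = 100,
                           background_level = 50) {
  style <- match.arg(style)
  stopifnot(is(spec, "TraceGeneratorSpec"))
  n <- as.integer(spec@n_cells)
  stim <- as.integer(spec@stimulated)
  reach <- round(spec@propagation_range)
  .with_seed(spec@seed, function() {
    # per-pair lags between adjacent cells, one draw per gap
    u <- stats::runif(n - 1L, 1 / spec@lag_dispersion, spec@lag_dispersion)
    pair_lags <- spec@mean_lag * u
    # onset per cell: nearest-origin cumulative lag; t0 leaves pre-stimulus
    # baseline samples
    t0 <- 4 * spec@sample_interval
    onset <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      d <- abs(i - stim)
      o <- stim[which.min(d)]
      if (min(d) <= reach) {
        gaps <- if (i >= o) seq.int(o, length.out = i - o) else
          seq.int(i, length.out = o - i)
        onset[i] <- t0 + if (length(gaps)) sum(pair_lags[gaps]) else 0
      }
    }
    if (is.null(duration)) {
      duration <- max(onset, na.rm = TRUE) + spec@rise_time +
        2 * spec@decay_time + 6 * spec@sample_interval
    }
    times <- seq(0, duration, by = spec@sample_interval)
    clean <- matrix(1, n, length(times),
                    dimnames = list(as.character(seq_len(n)), NULL))
    for (i in which(!is.na(onset))) {
      clean[i, ] <- 1 + spec@amplitude *
        .pulse_shape(times, onset[i], spec@rise_time, spec@decay_time)
    }
    noisy <- clean +
      matrix(stats::rnorm(length(clean), 0, spec@noise_sd), nrow(clean))
    if (style == "raw") {
      noisy <- background_level + resting_intensity * noisy
      background <- background_level +
        stats::rnorm(length(times), 0, spec@noise_sd * resting_intensity)
    } else {
      background <- numeric(length(times))
    }
    true_rt <- vapply(seq_len(n), function(i) {
      if (is.na(onset[i])) return(NA_real_)
      responseTime(clean[i, ], times)
    }, numeric(1))
    names(true_rt) <- rownames(clean)
    fts <- fluorescenceTraceSet(noisy, spec@sample_interval, background,
                                times = times)
    list(
      traces = fts,
      truth = list(
        responder = stats::setNames(!is.na(onset), rownames(clean)),
        response_time = true_rt,
        onset = stats::setNames(onset, rownames(clean)),
        lags = pair_lags
      )
    )
  })
}

#' Convert a simulation into an experiment-style trace set
#'
#' Bridges model output to experiment-style data: concentration
#' trajectories are converted to seconds with a [Calibration-class],
#' resampled at the imaging interval by linear interpolation, mapped
#' affinely to a normalized-intensity scale (resting level 1; the global
#' concentration maximum maps to intensity 2, matching typical normalized
#' peak heights), then scaled to raw units with additive Gaussian noise.
#' Ground truth comes from the wave metrics of the unnoised trajectories.
#'
#' @param sim a [CalciumSimulation-class].
#' @param calibration a [Calibration-class].
#' @param noise_sd noise standard deviation as a fraction of the resting
#'   intensity (default 0).
#' @param sample_interval imaging interval in seconds (default 1.2; must
#'   not be finer than the recorded resolution).
#' @param baseline_samples number of pre-stimulus baseline samples
#'   prepended to the recording (default 4), mimicking the baseline
#'   images gathered before the probe touches the cell; without them the
#'   stimulated cell's rise would fall outside the recording.
#' @param seed seed for the noise stream.
#' @param resting_intensity,background_level raw intensity scale.
#' @return list with \code{traces} and \code{truth} (responder set =
#'   activated cells; response times in seconds on the emitted time axis,
#'   from [responseTimes()]).
#' @export
tracesFromSimulation <- function(sim, calibration, noise_sd = 0,
                                 sample_interval = 1.2,
                                 baseline_samples = 4, seed = 1L,
                                 resting_intensity = 100,
                                 background_level = 50) {
  stopifnot(is(sim, "CalciumSimulation"), is(calibration, "Calibration"))
  tc <- timeConversion(calibration)
  t_s <- simTimes(sim) * tc
  res <- diff(t_s[1:2])
  if (sample_interval < res - 1e-12) {
    stop(sprintf(
      "sample_interval (%g s) finer than recorded resolution (%g s)",
      sample_interval, res))
  }
  conc <- concentrations(sim)
  offset <- baseline_samples * sample_interval
  times <- seq(0, max(t_s) + offset, by = sample_interval)
  shape <- conc / max(conc)
  # every cell rests at the baseline until the stimulus at t = offset,
  # when the stimulated cells jump to their initial concentration
  clean <- t(vapply(seq_len(nrow(shape)), function(i) {
    y <- stats::approx(t_s + offset, shape[i, ], xout = times,
                       yleft = 0)$y
    1 + y
  }, numeric(length(times))))
  rownames(clean) <- rownames(conc)
  rt_dimless <- responseTimes(sim)
  truth <- list(
    responder = !is.na(S4Vectors::metadata(sim)$lock_step),
    response_time = rt_dimless * tc + offset
  )
  .with_seed(seed, function() {
    noise_scale <- noise_sd * resting_intensity
    raw <- background_level + resting_intensity * clean +
      matrix(stats::rnorm(length(clean), 0, noise_scale), nrow(clean))
    background <- background_level +
      stats::rnorm(length(times), 0, noise_scale)
    fts <- fluorescenceTraceSet(raw, sample_interval, background,
                                times = times)
    list(traces = fts, truth = truth)
  })
}
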