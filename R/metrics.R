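#' Response time of a single trace
#'
#' The response time is the time at which the signal attains its maximum
#' positive rate of change, the same definition used for experimental
#' fluorescence traces.  Rates are forward first differences of consecutive
#' samples, timestamped at the end of their interval; ties are broken
#' toward the earliest time.  Returns \code{NA} when the trace never rises
#' (maximum first difference <= 0).
#'
#' @param trace numeric vector of >= 3 samples.
#' @param times sample times (default: 0-based unit steps).
#' @param method \code{"max_rate"} (default) or \code{"threshold"}
#'   (first upward crossing of \code{threshold}).
#' @param threshold concentration threshold for \code{method="threshold"}.
#' @return the response time, or \code{NA_real_}.
#' @export
responseTime <- function(trace, times = seq_along(trace) - 1,
                         method = c("max_rate", "threshold"),
                         threshold = 0.3) {
  method <- match.arg(method)
  if (length(trace) < 3L) stop("trace must have at least 3 samples")
  stopifnot(length(times) == length(trace))
  if (method == "max_rate") {
    d <- diff(trace)
    if (max(d) <= 0) return(NA_real_)
    times[which.max(d) + 1L]
  } else {
    up <- which(trace[-1L] > threshold & trace[-length(trace)] <= threshold)
    if (!length(up)) return(NA_real_)
    times[up[1L] + 1L]
  }
}

#' Per-cell response times of a simulation
#'
#' Applies [responseTime()] to every recorded concentration trajectory.
#' Cells whose rate regime never left the low-concentration intake state
#' (i.e. that never activated) are reported as \code{NA} even if diffusion
#' briefly raised their concentration.
#'
#' @param sim a [CalciumSimulation-class].
#' @param method,threshold passed to [responseTime()].
#' @return named numeric vector of response times (dimensionless).
#' @export
responseTimes <- function(sim, method = c("max_rate", "threshold"),
                          threshold = NULL) {
  stopifnot(is(sim, "CalciumSimulation"))
  method <- match.arg(method)
  if (is.null(threshold)) {
    threshold <- S4Vectors::metadata(sim)$parameters@uc1
  }
  conc <- concentrations(sim)
  reg <- regimes(sim)
  tt <- simTimes(sim)
  rt <- apply(conc, 1L, responseTime, times = tt, method = method,
              threshold = threshold)
  never <- apply(reg, 1L, function(r) all(r == 1L))
  rt[never] <- NA_real_
  rt
}

#' Cell-to-cell propagation times along a path
#'
#' Differences of consecutive response times along a simple path of cell
#' labels, and their mean.  At least two responding cells are required.
#'
#' @param response_times named numeric vector (e.g. from
#'   [responseTimes()]).
#' @param path character vector of cell labels in path order.
#' @return list with \code{pairs} (data.frame \code{from}, \code{to},
#'   \code{dt}) and \code{mean}.
#' @export
cellToCellTime <- function(response_times, path) {
  stopifnot(all(path %in% names(response_times)))
  rt <- response_times[path]
  ok <- !is.na(rt)
  if (sum(ok) < 2L) stop("insufficient data: fewer than 2 responding cells")
  rt <- rt[ok]
  lab <- names(rt)
  d <- diff(rt)
  list(pairs = data.frame(from = lab[-length(lab)], to = lab[-1L], dt = d),
       mean = mean(d))
}

#' Spatial extent of a calcium pulse
#'
#' The maximum, over recorded times, of the number of contiguous cells
#' whose concentration exceeds \code{threshold}.  With
#' \code{scope = "pulse"} (default) the count is restricted to one
#' propagation direction (the stimulated cell and everything on one side
#' of it), measuring the width of a single travelling pulse; a middle-cell
#' stimulus launches two mirror-image pulses that share the stimulated
#' cell early on, so the whole-chain count (\code{scope = "chain"})
#' briefly spans both.
#'
#' @param sim a single-chain [CalciumSimulation-class].
#' @param threshold concentration threshold (default: \code{uc1}).
#' @param scope \code{"pulse"} or \code{"chain"}.
#' @return extent in cells (integer).
#' @export
spatialExtent <- function(sim, threshold = NULL,
                          scope = c("pulse", "chain")) {
  stopifnot(is(sim, "CalciumSimulation"))
  scope <- match.arg(scope)
  md <- S4Vectors::metadata(sim)
  if (md$network@architecture != "chain") {
    stop("spatialExtent is defined for single-chain results")
  }
  if (is.null(threshold)) threshold <- md$parameters@uc1
  conc <- concentrations(sim)
  ord <- order(md$network@cells$col)
  conc <- conc[ord, , drop = FALSE]
  if (scope == "pulse") {
    stim <- md$stimulus@cells[1L]
    i <- match(stim, rownames(conc))
    conc <- conc[seq.int(i, nrow(conc)), , drop = FALSE]
  }
  runs <- apply(conc > threshold, 2L, function(above) {
    r <- rle(above)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  })
  as.integer(max(runs))
}

#' Detect wave crossing in a dual-stimulation chain run
#'
#' Two counter-propagating calcium pulses annihilate when they meet because
#' activated cells are permanently refractory; a wave "crossing" would show
#' up as a second distinct activation episode in cells beyond a stimulated
#' cell, on the far side from the other stimulus.  A second episode is a
#' second local maximum of the positive rate of change occurring after the
#' cell's first pulse has peaked and exceeding \code{noise_floor_frac}
#' (default 10\%) of the first-pulse peak rate.  The small hump in the tail
#' of each pulse -- a known artifact of the discrete diffusion model -- stays
#' below this floor and must not count as crossing.
#'
#' @param sim a dual-stimulus chain [CalciumSimulation-class] from
#'   [runChainDual()].
#' @param noise_floor_frac second-episode detection floor as a fraction of
#'   the first-pulse peak rate.
#' @return list with \code{crossing} (logical) and \code{evidence}
#'   (data.frame of candidate cells and times; empty when no crossing).
#' @export
detectCrossing <- function(sim, noise_floor_frac = 0.1) {
  stopifnot(is(sim, "CalciumSimulation"))
  md <- S4Vectors::metadata(sim)
  stim <- md$stimulus@cells
  if (md$network@architecture != "chain" || length(stim) != 2L) {
    stop("detectCrossing requires a dual-stimulus chain run")
  }
  cols <- md$network@cells$col
  names(cols) <- md$network@cells$label
  lo <- min(cols[stim]); hi <- max(cols[stim])
  outside <- names(cols)[cols < lo | cols > hi]
  conc <- concentrations(sim)
  tt <- simTimes(sim)
  ev <- list()
  for (lbl in outside) {
    x <- conc[lbl, ]
    d <- diff(x)
    if (max(d) <= 0) next
    p1 <- which.max(d)                    # first-pulse steepest rise
    peak1 <- p1 - 1L + which.max(x[p1:length(x)])   # first-pulse peak
    if (peak1 >= length(d)) next
    later <- d[(peak1 + 1L):length(d)]
    # local maxima of the positive rate after the first peak
    idx <- which(later > 0 &
                 later >= c(later[-1L], -Inf) &
                 later > c(-Inf, later[-length(later)]))
    big <- idx[later[idx] > noise_floor_frac * d[p1]]
    if (length(big)) {
      ev[[lbl]] <- data.frame(
        cell = lbl,
        time = tt[peak1 + big + 1L],
        rate = later[big],
        first_peak_rate = d[p1]
      )
    }
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(cell = character(0), time = numeric(0), rate = numeric(0),
               first_peak_rate = numeric(0))
  rownames(evidence) <- NULL
  list(crossing = nrow(evidence) > 0L, evidence = evidence)
}

#' Calibrate dimensionless model units to physical units
#'
#' Matching the simulated cell-to-cell propagation time (dimensionless) to
#' the measured one (seconds) gives the conversion factor
#' \code{time_conversion = experimental / simulated} seconds per
#' dimensionless unit.
#'
#' @param simulated_cell_time simulated mean cell-to-cell time
#'   (dimensionless).
#' @param experimental_cell_time measured mean cell-to-cell time in seconds
#'   (default 1.8).
#' @param cell_spacing mean intercellular spacing in micrometres
#'   (default 31.2).
#' @param dt dimensionless integration step (default 0.01).
#' @return a [Calibration-class].
#' @examples
#' cal <- calibrate(0.87)
#' effectiveStep(cal)   # ~0.0207 s
#' waveSpeed(cal)       # ~17.3 um/s
#' @export
calibrate <- function(simulated_cell_time, experimental_cell_time = 1.8,
                      cell_spacing = 31.2, dt = 0.01) {
  v <- c(simulated_cell_time, experimental_cell_time, cell_spacing, dt)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all calibration inputs must be positive")
  }
  new("Calibration",
      cell_spacing = cell_spacing,
      experimental_cell_time = experimental_cell_time,
      simulated_cell_time = simulated_cell_time,
      time_conversion = experimental_cell_time / simulated_cell_time,
      dt = dt)
}

#' @describeIn calibrate seconds per dimensionless time unit
#' @param cal a [Calibration-class]
#' @export
timeConversion <- function(cal) cal@time_conversion

#' @describeIn calibrate physical duration of one integration step, seconds
#' @export
effectiveStep <- function(cal) cal@dt * cal@time_conversion

#' @describeIn calibrate wave speed in micrometres per second
#' @export
waveSpeed <- function(cal) cal@cell_spacing / cal@experimental_cell_time

#' @describeIn calibrate physical diffusion coefficient in m^2/s implied by
#'   a dimensionless edge coefficient (\code{d_edge} per unit dimensionless
#'   time over one cell spacing)
#' @param d_edge dimensionless edge diffusion coefficient
#' @export
physicalDiffusion <- function(cal, d_edge = 0.6) {
  d_edge * (cal@cell_spacing * 1e-6)^2 / cal@time_conversion
}

setMethod("show", "Calibration", function(object) {
  cat(sprintf(
    paste0("Calibration: %g s per dimensionless unit ",
           "(%g s experimental vs %g simulated per cell); ",
           "step %g = %.4g s; speed %.3g um/s\n"),
    object@time_conversion, object@experimental_cell_time,
    object@simulated_cell_time, object@dt, effectiveStep(object),
    waveSpeed(object)))
})

#' Wave report: descriptors of a simulated calcium wave
#'
#' Collects per-cell response times, cell-to-cell propagation times along a
#' path, the pulse spatial extent and (when a calibration is supplied) the
#' same quantities in physical units.
#'
#' @param sim a chain [CalciumSimulation-class].
#' @param path labels of the path for cell-to-cell times (default: from the
#'   stimulated cell to 9 cells down-chain).
#' @param calibration optional [Calibration-class].
#' @return list with elements \code{response_times},
#'   \code{cell_to_cell}, \code{mean_cell_time}, \code{spatial_extent},
#'   and, when calibrated, \code{response_times_s},
#'   \code{mean_cell_time_s}, \code{speed_um_per_s}.
#' @export
waveReport <- function(sim, path = NULL, calibration = NULL) {
  stopifnot(is(sim, "CalciumSimulation"))
  md <- S4Vectors::metadata(sim)
  rt <- responseTimes(sim)
  if (is.null(path)) {
    cl <- md$network@cells
    stim <- md$stimulus@cells[1L]
    cols <- stats::setNames(cl$col, cl$label)
    # default path: ten cells down the stimulated cell's own row
    onrow <- cl$row == cl$row[match(stim, cl$label)]
    cols <- cols[onrow]
    from <- cols[stim]
    path <- names(sort(cols[cols >= from & cols <= from + 9]))
  }
  ctc <- cellToCellTime(rt, path)
  rep <- list(
    response_times = rt,
    cell_to_cell = ctc$pairs,
    mean_cell_time = ctc$mean,
    spatial_extent = if (md$network@architecture == "chain")
      spatialExtent(sim) else NA_integer_,
    path = path
  )
  if (!is.null(calibration)) {
    stopifnot(is(calibration, "Calibration"))
    tc <- timeConversion(calibration)
    rep$response_times_s <- rt * tc
    rep$mean_cell_time_s <- ctc$mean * tc
    rep$speed_um_per_s <- waveSpeed(calibration)
    rep$calibration <- calibration
  }
  rep
}

#' Write a wave report to JSON plus a pairwise CSV
#'
#' @param report a list from [waveReport()].
#' @param json_path JSON output path (per-cell metrics).
#' @param csv_path CSV output path (pairwise propagation times);
#'   \code{NULL} to skip.
#' @return \code{json_path}, invisibly.
#' @export
writeWaveReport <- function(report, json_path, csv_path = NULL) {
  doc <- list(
    response_times = as.list(report$response_times),
    mean_cell_time = report$mean_cell_time,
    spatial_extent = report$spatial_extent,
    path = report$path
  )
  if (!is.null(report$mean_cell_time_s)) {
    doc$mean_cell_time_s <- report$mean_cell_time_s
    doc$speed_um_per_s <- report$speed_um_per_s
    doc$response_times_s <- as.list(report$response_times_s)
  }
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_path)) {
    utils::write.csv(report$cell_to_cell, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
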