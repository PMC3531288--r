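#' Construct a fluorescence trace set
#'
#' @param intensity numeric matrix, cells x samples (rownames are cell
#'   labels).
#' @param sample_interval sampling interval in seconds (default 1.2).
#' @param background background intensity series (same length as the
#'   columns; default all zero).
#' @param times optional explicit sample times (must be uniformly spaced);
#'   overrides \code{sample_interval}.
#' @param normalized is the set already normalized?
#' @return a [FluorescenceTraceSet-class].
#' @export
fluorescenceTraceSet <- function(intensity, sample_interval = 1.2,
                                 background = NULL, times = NULL,
                                 normalized = FALSE) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity))) {
    rownames(intensity) <- as.character(seq_len(nrow(intensity)))
  }
  nt <- ncol(intensity)
  if (is.null(times)) {
    times <- (seq_len(nt) - 1) * sample_interval
  } else {
    stopifnot(length(times) == nt)
    if (nt > 1L) {
      dtv <- diff(times)
      if (max(dtv) - min(dtv) > 1e-9 * max(abs(dtv))) {
        stop("sample times must be uniformly spaced")
      }
      sample_interval <- mean(dtv)
    }
  }
  if (is.null(background)) background <- numeric(nt)
  stopifnot(length(background) == nt)
  if (normalized) {
    first <- intensity[, 1L]
    if (any(abs(first - 1) > 1e-6)) {
      stop("normalized trace sets must start at intensity 1")
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = S4Vectors::DataFrame(label = rownames(intensity)),
    colData = S4Vectors::DataFrame(time = times)
  )
  S4Vectors::metadata(se) <- list(
    background = background, sample_interval = sample_interval,
    normalized = normalized, unusable = character(0)
  )
  new("FluorescenceTraceSet", se)
}

#' @describeIn fluorescenceTraceSet intensity matrix accessor
#' @param x a \code{FluorescenceTraceSet}
#' @export
setMethod("intensities", "FluorescenceTraceSet", function(x) {
  SummarizedExperiment::assay(x, "intensity")
})

#' @describeIn fluorescenceTraceSet sample times in seconds
#' @export
setMethod("sampleTimes", "FluorescenceTraceSet", function(x) {
  SummarizedExperiment::colData(x)$time
})

#' @describeIn fluorescenceTraceSet normalized flag accessor
#' @export
setMethod("isNormalized", "FluorescenceTraceSet", function(x) {
  isTRUE(S4Vectors::metadata(x)$normalized)
})

setMethod("show", "FluorescenceTraceSet", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf(
    "FluorescenceTraceSet: %d cells x %d samples @ %g s%s%s\n",
    nrow(object), ncol(object), md$sample_interval,
    ifelse(md$normalized, " (normalized)", ""),
    ifelse(length(md$unusable),
           sprintf("; unusable: %s", paste(md$unusable, collapse = ", ")),
           "")))
})

#' Background-correct and normalize fluorescence traces
#'
#' Each trace is corrected for the background series and divided by its
#' first background-corrected sample, so every usable normalized trace
#' starts at 1.  Traces whose initial corrected intensity is not strictly
#' positive cannot be normalized; they are set to \code{NA} and their
#' labels recorded in the set's \code{unusable} metadata.
#'
#' @param fts a raw [FluorescenceTraceSet-class].
#' @return a normalized [FluorescenceTraceSet-class].
#' @export
normalizeTraces <- function(fts) {
  stopifnot(is(fts, "FluorescenceTraceSet"))
  if (isNormalized(fts)) stop("trace set is already normalized")
  md <- S4Vectors::metadata(fts)
  raw <- intensities(fts)
  corrected <- sweep(raw, 2L, md$background, "-")
  first <- corrected[, 1L]
  unusable <- rownames(raw)[!is.finite(first) | first <= 0]
  norm <- corrected / first
  norm[unusable, ] <- NA_real_
  out <- fluorescenceTraceSet(
    norm,
    sample_interval = md$sample_interval,
    background = numeric(ncol(raw)),
    times = sampleTimes(fts),
    normalized = FALSE
  )
  # set the flag after construction: unusable rows are NA, not 1
  md_out <- S4Vectors::metadata(out)
  md_out$normalized <- TRUE
  md_out$unusable <- unusable
  S4Vectors::metadata(out) <- md_out
  out
}

#' Running average of the rate of change
#'
#' Moving mean of consecutive forward first differences over \code{window}
#' intervals, used to improve the signal-to-noise ratio of weak responses.
#' Each smoothed rate is timestamped at the trailing (last) sample of its
#' window.
#'
#' @param trace numeric sample vector.
#' @param sample_interval sampling interval (seconds) used for the
#'   timestamps.
#' @param window number of intervals averaged (default 4).
#' @param times optional explicit sample times.
#' @return data.frame with columns \code{time} and \code{rate}.
#' @export
runningAverageRate <- function(trace, sample_interval = 1.2, window = 4,
                               times = NULL) {
  n <- length(trace)
  if (!(length(window) == 1L && window >= 1 && window == floor(window))) {
    stop("window must be an integer >= 1")
  }
  if (n <= window) stop("trace too short for the requested window")
  if (is.null(times)) times <- (seq_len(n) - 1) * sample_interval
  d <- diff(trace) / diff(times)
  sm <- stats::filter(d, rep(1 / window, window), sides = 1)
  keep <- window:length(d)
  data.frame(time = times[keep + 1L], rate = as.numeric(sm[keep]))
}

#' Call whether (and when) a cell responded
#'
#' A cell is considered to have responded when its trace shows the
#' characteristic pulse shape: an initial fast rise followed by a slower
#' decline.  Operationally: the peak prominence over the pre-rise baseline
#' must exceed \code{noise_mult} times the baseline noise, and the
#' half-prominence rise time must be shorter than the half-prominence
#' decay time.  The response time is the time of the maximum positive rate
#' of change of the raw samples (uncertainty: half the sampling interval),
#' or, for weak signals, of the maximum of the \code{window}-interval
#' running average of the rate (uncertainty: one sampling interval).
#'
#' @param trace numeric vector of >= 8 samples (normalized intensity).
#' @param sample_interval sampling interval in seconds (default 1.2).
#' @param weak_signal use the running-average rate (default \code{FALSE}).
#' @param noise_mult prominence threshold as a multiple of baseline noise
#'   (default 3).
#' @param window running-average window in intervals (default 4).
#' @return list with \code{responded}, \code{response_time} (seconds or
#'   \code{NA}), \code{method} (\code{"raw_rate"} or
#'   \code{"running_average"}) and \code{uncertainty} (seconds).
#' @export
callResponse <- function(trace, sample_interval = 1.2, weak_signal = FALSE,
                         noise_mult = 3, window = 4) {
  n <- length(trace)
  if (n < 8L) stop("trace must have at least 8 samples")
  if (anyNA(trace)) {
    return(list(responded = FALSE, response_time = NA_real_,
                method = ifelse(weak_signal, "running_average", "raw_rate"),
                uncertainty = ifelse(weak_signal, sample_interval,
                                     sample_interval / 2)))
  }
  times <- (seq_len(n) - 1) * sample_interval
  # For weak signals all structural decisions (peak location, prominence,
  # rise/decay shape) are made on a centred running mean of the trace, so
  # a single noise spike cannot masquerade as the peak; noise is estimated
  # robustly from the first differences (the few pulse-rise differences do
  # not move the MAD).
  w_probe <- if (weak_signal) max(2L, ceiling(window / 2)) else 1L
  probe <- if (w_probe > 1L) {
    as.numeric(stats::filter(trace, rep(1 / w_probe, w_probe), sides = 2))
  } else {
    trace
  }
  probe[is.na(probe)] <- trace[is.na(probe)]
  p <- which.max(probe)
  # pre-rise baseline: the lower quartile of the smoothed pre-peak samples
  # is robust to the rise itself sitting inside the leading window (cells
  # stimulated early have no quiet leading segment)
  baseline <- stats::quantile(probe[seq_len(max(p, 4L))], 0.25,
                              names = FALSE, type = 7)
  noise <- stats::mad(diff(trace)) / sqrt(2)
  prominence <- probe[p] - baseline
  # quarter-prominence crossing level: the rise/decline asymmetry of a
  # fast-rise slow-decay pulse is strongest low on the flanks, and the
  # light smoothing inflates both sides by about the same amount there
  lev <- baseline + prominence / 4
  # rise and return are measured on the raw samples with a two-sample
  # debounce: a single noisy sample on the wrong side of the level does
  # not open or close the pulse
  below <- trace <= lev
  pre <- which(below[seq_len(p)] & c(TRUE, below[seq_len(p)][-p]))
  rise <- if (length(pre)) times[p] - times[max(pre)] else times[p] - times[1L]
  post <- below[seq.int(p, n)]
  ret <- which(post & c(post[-1L], TRUE))
  fall <- if (length(ret)) times[p - 1L + min(ret)] - times[p] else Inf
  shape_ok <- prominence > noise_mult * noise && fall > rise && rise >= 0
  method <- ifelse(weak_signal, "running_average", "raw_rate")
  uncertainty <- ifelse(weak_signal, sample_interval, sample_interval / 2)
  if (!shape_ok) {
    return(list(responded = FALSE, response_time = NA_real_,
                method = method, uncertainty = uncertainty))
  }
  if (weak_signal) {
    ra <- runningAverageRate(trace, sample_interval, window)
    # the response is the steepest smoothed rise of the rise phase: only
    # rates timestamped up to one window past the peak are candidates
    cand <- ra$time <= times[p] + window * sample_interval / 2
    if (!any(cand) || max(ra$rate[cand]) <= 0) {
      return(list(responded = FALSE, response_time = NA_real_,
                  method = method, uncertainty = uncertainty))
    }
    rt <- ra$time[cand][which.max(ra$rate[cand])]
  } else {
    rt <- responseTime(trace, times)
    if (is.na(rt)) {
      return(list(responded = FALSE, response_time = NA_real_,
                  method = method, uncertainty = uncertainty))
    }
  }
  list(responded = TRUE, response_time = rt, method = method,
       uncertainty = uncertainty)
}

#' Propagation statistics from response calls along a chain
#'
#' Per-pair response-time differences between adjacent responding cells,
#' their mean and standard deviation, directional means when two stimulated
#' cells exist (upward: away from the first origin; downward: away from the
#' second), and the distance of propagation (number of responders beyond
#' each stimulated cell).  Pairs spanning a non-responder are excluded and
#' counted.
#'
#' @param calls list of [callResponse()] results, ordered along the chain.
#' @param labels cell labels in chain order (default: names of
#'   \code{calls} or indices).
#' @param origin label(s) of the stimulated cell(s), 1 or 2 of them.
#' @param contiguous restrict to the contiguous run(s) of responders
#'   containing the origin(s) (default \code{FALSE}).  A propagating wave
#'   activates a contiguous stretch of cells, so isolated distant
#'   responder calls are usually spurious.
#' @return list with \code{pairs} (data.frame), \code{mean_lag},
#'   \code{median_lag} (robust to occasional spurious responder calls),
#'   \code{sd_lag}, \code{directional} (named means, dual layouts),
#'   \code{distance} (responders beyond each origin) and
#'   \code{n_excluded_pairs}.
#' @export
propagationStats <- function(calls, labels = NULL, origin,
                             contiguous = FALSE) {
  if (is.null(labels)) {
    labels <- names(calls) %||% as.character(seq_along(calls))
  }
  stopifnot(length(labels) == length(calls),
            length(origin) %in% 1:2, all(origin %in% labels))
  responded <- vapply(calls, function(x) isTRUE(x$responded), logical(1))
  rt <- vapply(calls, function(x) x$response_time %||% NA_real_, numeric(1))
  if (contiguous) {
    keep <- logical(length(responded))
    for (o in match(origin, labels)) {
      i <- o
      while (i >= 1L && responded[i]) { keep[i] <- TRUE; i <- i - 1L }
      i <- o + 1L
      while (i <= length(responded) && responded[i]) {
        keep[i] <- TRUE; i <- i + 1L
      }
    }
    responded <- responded & keep
  }
  if (sum(responded) < 2L) {
    stop("insufficient data: fewer than 2 responders")
  }
  idx <- seq_along(labels)
  oi <- match(origin, labels)
  # signed direction: positive when moving away from the nearest origin
  nearest <- vapply(idx, function(i) oi[which.min(abs(i - oi))], numeric(1))
  pairs <- list(); excluded <- 0L; meeting <- 0L
  for (i in idx[-length(idx)]) {
    j <- i + 1L
    if (!responded[i] || !responded[j]) {
      if (xor(responded[i], responded[j])) excluded <- excluded + 1L
      next
    }
    if (length(oi) == 2L && nearest[i] != nearest[j]) {
      # the pair straddles the region where the two waves meet; its lag
      # belongs to neither direction
      meeting <- meeting + 1L
      next
    }
    away_j <- abs(j - nearest[j]) >= abs(i - nearest[i])
    lag <- if (away_j) rt[j] - rt[i] else rt[i] - rt[j]
    dir <- if (nearest[i] == oi[1L]) "upward" else "downward"
    pairs[[length(pairs) + 1L]] <- data.frame(
      from = labels[i], to = labels[j], lag = lag, direction = dir
    )
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(from = character(0), to = character(0), lag = numeric(0),
               direction = character(0))
  directional <- if (length(oi) == 2L && nrow(pairs)) {
    tapply(pairs$lag, pairs$direction, mean)
  } else NULL
  distance <- vapply(oi, function(o) {
    left <- sum(responded[idx < o])
    right <- sum(responded[idx > o])
    max(left, right)
  }, numeric(1))
  names(distance) <- origin
  list(pairs = pairs,
       mean_lag = mean(pairs$lag),
       median_lag = stats::median(pairs$lag),
       sd_lag = stats::sd(pairs$lag),
       directional = directional,
       distance = distance,
       n_excluded_pairs = excluded,
       n_meeting_pairs = meeting)
}

#' Read / write fluorescence traces as CSV
#'
#' Wide format: a \code{time} column plus one column per cell label, with
#' \code{background} as a reserved column name.  Long format: columns
#' \code{time}, \code{cell_label}, \code{intensity}.  The reader detects
#' the layout from the header.
#'
#' @param path CSV path.
#' @return \code{readTracesCSV}: a [FluorescenceTraceSet-class].
#' @export
readTracesCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("time", "cell_label", "intensity") %in% colnames(df))) {
    labs <- unique(df$cell_label)
    times <- sort(unique(df$time))
    m <- matrix(NA_real_, length(labs), length(times),
                dimnames = list(labs, NULL))
    m[cbind(match(df$cell_label, labs), match(df$time, times))] <-
      df$intensity
    bg <- if ("background" %in% labs) m["background", ] else NULL
    m <- m[setdiff(labs, "background"), , drop = FALSE]
    fluorescenceTraceSet(m, background = bg, times = times)
  } else if ("time" %in% colnames(df)) {
    times <- df$time
    labs <- setdiff(colnames(df), "time")
    bg <- if ("background" %in% labs) df$background else NULL
    labs <- setdiff(labs, "background")
    m <- t(as.matrix(df[, labs, drop = FALSE]))
    rownames(m) <- labs
    fluorescenceTraceSet(m, background = bg, times = times)
  } else {
    stop("unrecognized trace CSV layout (no 'time' column)")
  }
}

#' @rdname readTracesCSV
#' @param fts a [FluorescenceTraceSet-class].
#' @param layout \code{"wide"} (default) or \code{"long"}.
#' @export
writeTracesCSV <- function(fts, path, layout = c("wide", "long")) {
  stopifnot(is(fts, "FluorescenceTraceSet"))
  layout <- match.arg(layout)
  m <- intensities(fts)
  tt <- sampleTimes(fts)
  bg <- S4Vectors::metadata(fts)$background
  if (layout == "wide") {
    df <- data.frame(time = tt, check.names = FALSE)
    for (lbl in rownames(m)) df[[lbl]] <- m[lbl, ]
    df$background <- bg
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    df <- data.frame(
      time = rep(tt, each = nrow(m) + 1L),
      cell_label = rep(c(rownames(m), "background"), times = length(tt)),
      intensity = as.vector(rbind(m, bg))
    )
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
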