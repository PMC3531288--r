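#' Rate regime labels
#'
#' @keywords internal
.REGIMES <- c("intake_low", "release", "refractory")

#' Cell rate state
#'
#' The per-cell state of the rate-switching machine: the current regime and
#' whether the permanent refractory lock has engaged.  Below the lock the
#' machine is memoryless in the concentration; once the concentration has
#' strictly exceeded \code{uc2} the cell retains the refractory rate
#' \code{k3} indefinitely.
#'
#' @param regime one of \code{"intake_low"}, \code{"release"},
#'   \code{"refractory"}.
#' @param locked has the permanent refractory lock engaged?
#' @return a list with elements \code{regime} and \code{locked}.
#' @export
cellRateState <- function(regime = "intake_low", locked = FALSE) {
  regime <- match.arg(regime, .REGIMES)
  if (locked && regime != "refractory") {
    stop("a locked cell is always in the refractory regime")
  }
  list(regime = regime, locked = locked)
}

#' Concentration-dependent rate constant with permanent refractory lock
#'
#' Returns the rate constant for a cell at concentration \code{c} and the
#' updated rate state.  Unlocked cells switch memorylessly:
#' \code{c < uc1} gives \code{k1} (intake), \code{uc1 <= c <= uc2} gives
#' \code{k2} (release; threshold equality is assigned to the release
#' regime), and \code{c > uc2} engages the permanent lock and gives
#' \code{k3}.  A locked cell returns \code{k3} regardless of \code{c}.
#'
#' @param c cytosolic calcium concentration (>= 0).
#' @param state a [cellRateState()] list.
#' @param p a [ReactionParameters-class].
#' @return list with elements \code{k} (rate constant) and \code{state}
#'   (updated rate state).
#' @examples
#' p <- reactionParameters()
#' rateConstant(0.1, cellRateState(), p)$k    # 0.03
#' rateConstant(1.0, cellRateState(), p)$k    # -0.025
#' @export
rateConstant <- function(c, state = cellRateState(),
                         p = reactionParameters()) {
  if (!is.finite(c) || c < 0) stop("concentration must be >= 0")
  if (isTRUE(state$locked)) {
    return(list(k = p@k3, state = cellRateState("refractory", TRUE)))
  }
  if (c < p@uc1) {
    list(k = p@k1, state = cellRateState("intake_low", FALSE))
  } else if (c <= p@uc2) {
    list(k = p@k2, state = cellRateState("release", FALSE))
  } else {
    list(k = p@k3, state = cellRateState("refractory", TRUE))
  }
}

#' Reaction rate of intracellular calcium
#'
#' The single-variable reaction function \eqn{f(C) = -k\,C}: positive rate
#' constants (intake regimes) give a negative rate of change, the negative
#' release constant \code{k2} gives a positive one.
#'
#' @param c concentration (>= 0).
#' @param k rate constant value.
#' @return the rate of concentration change \eqn{-k c}.
#' @examples
#' reactionRate(0.1, 0.03)    # -0.003
#' reactionRate(1.0, -0.025)  # +0.025
#' @export
reactionRate <- function(c, k) {
  if (any(!is.finite(c)) || any(c < 0)) stop("concentration must be >= 0")
  -k * c
}

# Vectorised regime/rate lookup from pre-step concentrations.
# Returns list(k, regime, locked): `locked` already includes locks engaged
# by the current concentrations (strictly above uc2).
.rates_vec <- function(C, locked, p) {
  locked <- locked | (C > p@uc2)
  k <- ifelse(locked, p@k3,
              ifelse(C < p@uc1, p@k1, p@k2))
  regime <- ifelse(locked, 3L, ifelse(C < p@uc1, 1L, 2L))
  list(k = k, regime = regime, locked = locked)
}

# Symmetric per-step coupling weight matrix and its row sums.
# calibrated / per_time: w = coefficient * dt;  per_step: w = coefficient.
.step_weights <- function(net, settings) {
  labels <- net@cells$label
  n <- length(labels)
  cp <- as.data.frame(net@couplings)
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  if (nrow(cp)) {
    ia <- match(cp$a, labels); ib <- match(cp$b, labels)
    scale <- if (settings@convention == "per_step") 1 else settings@dt
    w <- cp$coefficient * scale
    W[cbind(ia, ib)] <- W[cbind(ia, ib)] + w
    W[cbind(ib, ia)] <- W[cbind(ib, ia)] + w
  }
  list(W = W, deg = rowSums(W))
}

# Per-step scale of the reaction increment.
.reaction_scale <- function(settings) {
  if (settings@convention == "per_time") settings@dt else 1
}

#' One synchronous explicit update step
#'
#' Advances every cell by one step of the explicit scheme
#' \deqn{C_i \leftarrow C_i + \sum_j w_{ij}(C_j - C_i) - k(C_i)\,C_i\,s}
#' where \eqn{w_{ij}} is the coupling's effective per-step weight and
#' \eqn{s} the reaction scale, both fixed by the settings' scaling
#' convention.  Rate states are evaluated from the pre-step concentration
#' vector (fully synchronous update) and the result is clamped at zero from
#' below.
#'
#' @param concentration named numeric vector over the network's cells.
#' @param locked named logical vector (permanent refractory locks).
#' @param net a [CellNetwork-class].
#' @param p a [ReactionParameters-class].
#' @param s a [SimulationSettings-class].
#' @param reaction set \code{FALSE} to switch the reaction term off
#'   (diffusion-only dynamics, used to verify conservation).
#' @return list with elements \code{concentration}, \code{locked},
#'   \code{regime} (integer codes 1/2/3) and \code{clamped} (number of
#'   cells clamped at zero this step).
#' @export
stepConcentrations <- function(concentration, locked, net,
                               p = reactionParameters(),
                               s = simulationSettings(),
                               reaction = TRUE) {
  labels <- net@cells$label
  stopifnot(length(concentration) == length(labels))
  if (!is.null(names(concentration))) {
    concentration <- concentration[labels]
  }
  if (!is.null(names(locked))) locked <- locked[labels]
  wt <- .step_weights(net, s)
  st <- .step_core(concentration, locked, wt$W, wt$deg, p, s, reaction)
  if (any(!is.finite(st$concentration))) {
    stop("integration instability: non-finite concentration")
  }
  names(st$concentration) <- labels
  names(st$locked) <- labels
  names(st$regime) <- labels
  st
}

# Hot loop body shared by stepConcentrations() and simulateNetwork().
.step_core <- function(C, locked, W, deg, p, s, reaction) {
  if (reaction) {
    r <- .rates_vec(C, locked, p)
    f <- -r$k * C * .reaction_scale(s)
    locked <- r$locked
    regime <- r$regime
  } else {
    f <- 0
    regime <- ifelse(locked, 3L, ifelse(C < p@uc1, 1L, 2L))
  }
  C_new <- C + as.vector(W %*% C) - deg * C + f
  clamped <- sum(C_new < 0)
  if (clamped) C_new[C_new < 0] <- 0
  list(concentration = C_new, locked = locked, regime = regime,
       clamped = clamped)
}

#' Simulate calcium dynamics on a cell network
#'
#' Initializes every cell to concentration zero except the stimulated cells
#' (set to their stimulus concentration at t = 0), then iterates the
#' synchronous explicit update for \code{n_steps} steps, recording every
#' \code{record_every} steps.  The run is deterministic: identical inputs
#' give bit-identical output.
#'
#' With \code{early_stop = TRUE} the loop terminates early once no further
#' activation is possible: either every cell has locked, or the global
#' maximum concentration has fallen below \code{uc1} (below the lower
#' threshold all dynamics are contracting, so the maximum can never rise
#' again).  This does not change which cells activate and is used by the
#' sweep protocols.
#'
#' @param net a [CellNetwork-class].
#' @param p a [ReactionParameters-class].
#' @param s a [SimulationSettings-class].
#' @param stimulus a [StimulationProtocol-class]; defaults to the middle
#'   cell of the network at \code{p@c0}.
#' @param reaction set \code{FALSE} for diffusion-only dynamics.
#' @param early_stop stop once the activation pattern is final.
#' @return a [CalciumSimulation-class].
#' @examples
#' net <- buildChain(5, 0.6)
#' sim <- simulateNetwork(net, stimulus = stimulationProtocol("3"),
#'                        s = simulationSettings(n_steps = 100))
#' concentrations(sim)[, 1:3]
#' @export
simulateNetwork <- function(net, p = reactionParameters(),
                            s = simulationSettings(), stimulus = NULL,
                            reaction = TRUE, early_stop = FALSE) {
  stopifnot(is(net, "CellNetwork"), is(p, "ReactionParameters"),
            is(s, "SimulationSettings"))
  labels <- net@cells$label
  n <- length(labels)
  if (is.null(stimulus)) {
    stimulus <- stimulationProtocol(labels[ceiling(n / 2)], p@c0)
  }
  stopifnot(is(stimulus, "StimulationProtocol"))
  if (!all(stimulus@cells %in% labels)) {
    stop("stimulated cells must belong to the network: ",
         paste(setdiff(stimulus@cells, labels), collapse = ", "))
  }
  C <- stats::setNames(numeric(n), labels)
  C[stimulus@cells] <- rep_len(stimulus@concentration,
                               length(stimulus@cells))
  locked <- stats::setNames(logical(n), labels)
  lock_step <- stats::setNames(rep(NA_integer_, n), labels)
  wt <- .step_weights(net, s)
  n_steps <- as.integer(s@n_steps)
  stride <- as.integer(s@record_every)
  rec_steps <- seq.int(0L, n_steps, by = stride)
  conc_rec <- matrix(NA_real_, n, length(rec_steps),
                     dimnames = list(labels, NULL))
  reg_rec <- matrix(NA_integer_, n, length(rec_steps),
                    dimnames = list(labels, NULL))
  r0 <- .rates_vec(C, locked, p)
  conc_rec[, 1L] <- C
  reg_rec[, 1L] <- r0$regime
  ri <- 1L
  clamp_total <- 0L
  steps_run <- 0L
  stopped <- "horizon"
  for (step in seq_len(n_steps)) {
    st <- .step_core(C, locked, wt$W, wt$deg, p, s, reaction)
    if (any(!is.finite(st$concentration))) {
      stop(sprintf("integration instability at step %d (non-finite %s)",
                   step, "concentration"))
    }
    newly <- st$locked & !locked
    if (any(newly)) lock_step[newly] <- step
    C <- st$concentration
    locked <- st$locked
    clamp_total <- clamp_total + st$clamped
    steps_run <- step
    if (step %% stride == 0L) {
      ri <- ri + 1L
      conc_rec[, ri] <- C
      reg_rec[, ri] <- st$regime
    }
    if (early_stop && reaction) {
      if (all(locked)) { stopped <- "all_locked"; break }
      if (max(C) < p@uc1) { stopped <- "quiescent"; break }
    }
  }
  keep <- which(rec_steps <= steps_run)
  if (ri < length(keep)) keep <- keep[seq_len(ri)]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(concentration = conc_rec[, keep, drop = FALSE],
                  regime = reg_rec[, keep, drop = FALSE]),
    rowData = net@cells,
    colData = S4Vectors::DataFrame(time = rec_steps[keep] * s@dt,
                                   step = rec_steps[keep])
  )
  S4Vectors::metadata(se) <- list(
    network = net, parameters = p, settings = s, stimulus = stimulus,
    lock_step = lock_step, steps_run = steps_run, stopped = stopped,
    clamp_events = clamp_total, reaction = reaction
  )
  new("CalciumSimulation", se)
}

#' @describeIn simulateNetwork concentration matrix (cells x recorded times)
#' @param x a \code{CalciumSimulation}
#' @export
setMethod("concentrations", "CalciumSimulation", function(x) {
  SummarizedExperiment::assay(x, "concentration")
})

#' @describeIn simulateNetwork regime code matrix (1 = intake_low,
#'   2 = release, 3 = refractory)
#' @export
setMethod("regimes", "CalciumSimulation", function(x) {
  SummarizedExperiment::assay(x, "regime")
})

#' @describeIn simulateNetwork recorded dimensionless time points
#' @export
setMethod("simTimes", "CalciumSimulation", function(x) {
  SummarizedExperiment::colData(x)$time
})

#' @describeIn simulateNetwork per-cell step index at which the refractory
#'   lock engaged (NA when the cell never activated)
#' @export
setMethod("activationSteps", "CalciumSimulation", function(x) {
  S4Vectors::metadata(x)$lock_step
})

#' @describeIn simulateNetwork per-cell dimensionless activation time
#' @export
setMethod("activationTimes", "CalciumSimulation", function(x) {
  S4Vectors::metadata(x)$lock_step * S4Vectors::metadata(x)$settings@dt
})

setMethod("show", "CalciumSimulation", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf(
    "CalciumSimulation: %d cells x %d recorded times (dt=%g, %s)\n",
    nrow(object), ncol(object), md$settings@dt, md$settings@convention))
  cat(sprintf("  stimulus: [%s]; activated %d/%d cells; stopped: %s\n",
              paste(md$stimulus@cells, collapse = ", "),
              sum(!is.na(md$lock_step)), nrow(object), md$stopped))
})

#' Write simulated trajectories to CSV with a JSON parameter sidecar
#'
#' The CSV is tidy with columns \code{time}, \code{cell_label},
#' \code{concentration}, \code{regime}.  The sidecar records the full
#' parameter provenance: reaction parameters, settings (including the
#' scaling convention), stimulus and network architecture.
#'
#' @param sim a [CalciumSimulation-class].
#' @param path CSV output path.
#' @param sidecar JSON sidecar path (default \code{paste0(path, ".json")};
#'   \code{NULL} to skip).
#' @return \code{path}, invisibly.
#' @export
writeSimulationCSV <- function(sim, path, sidecar = paste0(path, ".json")) {
  stopifnot(is(sim, "CalciumSimulation"))
  md <- S4Vectors::metadata(sim)
  conc <- concentrations(sim)
  reg <- regimes(sim)
  tt <- simTimes(sim)
  df <- data.frame(
    time = rep(tt, each = nrow(conc)),
    cell_label = rep(rownames(conc), times = length(tt)),
    concentration = as.vector(conc),
    regime = .REGIMES[as.vector(reg)]
  )
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(sidecar)) {
    p <- md$parameters; s <- md$settings
    doc <- list(
      parameters = list(uc1 = p@uc1, uc2 = p@uc2, k1 = p@k1, k2 = p@k2,
                        k3 = p@k3, c0 = p@c0),
      settings = list(dt = s@dt, n_steps = s@n_steps,
                      record_every = s@record_every,
                      convention = s@convention),
      stimulus = list(cells = md$stimulus@cells,
                      concentration = md$stimulus@concentration),
      network = list(architecture = md$network@architecture,
                     n_cells = nrow(md$network@cells)),
      steps_run = md$steps_run, stopped = md$stopped,
      clamp_events = md$clamp_events,
      package = as.character(utils::packageVersion("CICRwave"))
    )
    jsonlite::write_json(doc, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
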