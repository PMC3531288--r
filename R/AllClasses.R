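#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Cell network with weighted gap-junction couplings
#'
#' A \code{CellNetwork} represents a patterned multicellular structure as a
#' set of square cells on an integer lattice plus a set of symmetric pairwise
#' couplings.  Cells that share a side are coupled through an \emph{edge}
#' contact (coefficient \eqn{\bar{D}}); cells that share only a corner are
#' coupled through a \emph{vertex} contact (coefficient \eqn{\bar{D}_v}),
#' the situation that arises in the cluster of cells at a branch junction.
#'
#' @slot cells \code{DataFrame} with columns \code{label} (unique character
#'   identifier), \code{col}, \code{row} (integer lattice coordinates; one
#'   unit is one cell width).
#' @slot couplings \code{DataFrame} with columns \code{a}, \code{b} (cell
#'   labels), \code{kind} (\code{"edge"} or \code{"vertex"}) and
#'   \code{coefficient} (dimensionless diffusion coefficient, >= 0).
#' @slot architecture one of \code{"chain"}, \code{"t_structure"},
#'   \code{"custom"}.
#'
#' @seealso [buildChain()], [buildTStructure()], [validateNetwork()]
#' @export
setClass("CellNetwork",
  representation(
    cells = "DataFrame",
    couplings = "DataFrame",
    architecture = "character"
  )
)

# Validity enforces the structural frame only; content invariants (unique
# labels and positions, kind/geometry agreement, connectivity) are checked
# by validateNetwork(), which reports violations instead of raising, so
# that invalid networks can be represented and diagnosed.
setValidity("CellNetwork", function(object) {
  msg <- character(0)
  need <- c("label", "col", "row")
  if (!all(need %in% colnames(object@cells))) {
    return(paste("cells must have columns", paste(need, collapse = ", ")))
  }
  need2 <- c("a", "b", "kind", "coefficient")
  if (!all(need2 %in% colnames(object@couplings))) {
    return(paste("couplings must have columns",
                 paste(need2, collapse = ", ")))
  }
  if (nrow(object@couplings) > 0 &&
      !all(object@couplings$kind %in% c("edge", "vertex"))) {
    msg <- c(msg, "coupling kind must be 'edge' or 'vertex'")
  }
  if (!(length(object@architecture) == 1L &&
        object@architecture %in% c("chain", "t_structure", "custom"))) {
    msg <- c(msg, "architecture must be 'chain', 't_structure' or 'custom'")
  }
  if (length(msg)) msg else TRUE
})

#' Reaction parameters of the threshold-switched CICR model
#'
#' Intracellular calcium dynamics is modelled by \eqn{f(C) = -k(C)\,C} where
#' the rate constant \eqn{k} switches among three values depending on the
#' cytosolic concentration \eqn{C}: below \code{uc1} the endoplasmic
#' reticulum absorbs calcium (\code{k1 > 0}, so \eqn{f < 0}); between
#' \code{uc1} and \code{uc2} calcium-induced calcium release dominates
#' (\code{k2 < 0}, \eqn{f > 0}); once \eqn{C} exceeds \code{uc2} the cell
#' switches permanently to the refractory intake rate \code{k3 > 0}.
#'
#' @slot uc1 lower concentration threshold (dimensionless; default 0.3).
#' @slot uc2 upper concentration threshold (default 3.0).
#' @slot k1 intake rate constant for \eqn{C < uc1} (default 0.03).
#' @slot k2 release rate constant for \eqn{uc1 \le C \le uc2}
#'   (negative; default -0.025).
#' @slot k3 refractory intake rate constant for \eqn{C > uc2}
#'   (default 0.0045).
#' @slot c0 default stimulus concentration assigned to a stimulated cell
#'   (default 2.0).
#' @export
setClass("ReactionParameters",
  representation(uc1 = "numeric", uc2 = "numeric", k1 = "numeric",
                 k2 = "numeric", k3 = "numeric", c0 = "numeric")
)

setValidity("ReactionParameters", function(object) {
  msg <- character(0)
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!all(vapply(list(object@uc1, object@uc2, object@k1, object@k2,
                       object@k3, object@c0), one, logical(1)))) {
    return("all parameters must be finite scalars")
  }
  if (!(object@uc1 > 0 && object@uc1 < object@uc2)) {
    msg <- c(msg, "thresholds must satisfy 0 < uc1 < uc2")
  }
  if (object@k1 <= 0) msg <- c(msg, "k1 must be > 0")
  if (object@k2 >= 0) msg <- c(msg, "k2 must be < 0")
  if (object@k3 <= 0) msg <- c(msg, "k3 must be > 0")
  if (object@c0 <= 0) msg <- c(msg, "c0 must be > 0")
  if (length(msg)) msg else TRUE
})

#' Integrator settings
#'
#' @slot dt dimensionless integration time step (default 0.01).
#' @slot n_steps number of explicit update steps (default 15000, i.e.
#'   dimensionless time 150).
#' @slot record_every recording stride in steps (default 1).
#' @slot convention scaling convention for the per-step update; one of
#'   \code{"calibrated"} (default; diffusion weight = coefficient * dt,
#'   reaction rates applied per step), \code{"per_step"} (both per step) or
#'   \code{"per_time"} (both multiplied by dt).  See the package vignette
#'   for why \code{"calibrated"} is the shipped default.
#' @export
setClass("SimulationSettings",
  representation(dt = "numeric", n_steps = "numeric",
                 record_every = "numeric", convention = "character")
)

setValidity("SimulationSettings", function(object) {
  msg <- character(0)
  if (!(length(object@dt) == 1L && is.finite(object@dt) && object@dt > 0)) {
    msg <- c(msg, "dt must be a positive scalar")
  }
  if (!(length(object@n_steps) == 1L && object@n_steps >= 1 &&
        object@n_steps == floor(object@n_steps))) {
    msg <- c(msg, "n_steps must be an integer >= 1")
  }
  if (!(length(object@record_every) == 1L && object@record_every >= 1 &&
        object@record_every == floor(object@record_every))) {
    msg <- c(msg, "record_every must be an integer >= 1")
  }
  if (!(length(object@convention) == 1L &&
        object@convention %in% c("calibrated", "per_step", "per_time"))) {
    msg <- c(msg, "convention must be 'calibrated', 'per_step' or 'per_time'")
  }
  if (length(msg)) msg else TRUE
})

#' Stimulation protocol
#'
#' Mechano-stimulation is modelled purely as an initial concentration
#' assignment: each stimulated cell starts at its stimulus concentration,
#' all other cells start at zero.  All stimuli are simultaneous (t = 0).
#'
#' @slot cells labels of the stimulated cells.
#' @slot concentration initial concentration per stimulated cell (recycled).
#' @slot simultaneous logical; always \code{TRUE} in this model.
#' @export
setClass("StimulationProtocol",
  representation(cells = "character", concentration = "numeric",
                 simultaneous = "logical")
)

setValidity("StimulationProtocol", function(object) {
  msg <- character(0)
  if (length(object@cells) < 1L) msg <- c(msg, "at least one stimulated cell")
  if (any(!is.finite(object@concentration)) ||
      any(object@concentration <= 0)) {
    msg <- c(msg, "stimulus concentrations must be positive")
  }
  if (!(length(object@concentration) %in% c(1L, length(object@cells)))) {
    msg <- c(msg, "concentration must have length 1 or length(cells)")
  }
  if (!isTRUE(all(object@simultaneous))) {
    msg <- c(msg, "only simultaneous stimulation is supported")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated calcium trajectories on a cell network
#'
#' Extends \code{SummarizedExperiment}: rows are cells, columns are recorded
#' time points.  Assay \code{"concentration"} holds the dimensionless
#' cytosolic calcium concentration, assay \code{"regime"} the rate regime
#' (1 = intake below \code{uc1}, 2 = release, 3 = refractory).  Metadata
#' carries the network, parameters, settings, protocol, per-cell lock step
#' and clamping diagnostics.
#'
#' @seealso [simulateNetwork()], [concentrations()], [regimes()],
#'   [simTimes()], [activationTimes()]
#' @export
setClass("CalciumSimulation", contains = "SummarizedExperiment")

#' Propagation outcome of a stimulation experiment
#'
#' @slot activated labels of cells whose rate regime reached the refractory
#'   state within the horizon.
#' @slot reached_side_branch did the wave activate the mid-branch sentinel
#'   cell (\code{NA} for networks without a side branch)?
#' @slot reached_full_structure were all cells except the degree-one
#'   terminal cells activated?
#' @slot blocking_location label of the closest non-activated cell to the
#'   stimulus when the wave is blocked (\code{NA_character_} otherwise).
#' @slot inconclusive \code{TRUE} when any cell activated in the last 5\% of
#'   the requested horizon, i.e. the front may still have been advancing.
#' @export
setClass("PropagationOutcome",
  representation(activated = "character", reached_side_branch = "logical",
                 reached_full_structure = "logical",
                 blocking_location = "character", inconclusive = "logical")
)

setValidity("PropagationOutcome", function(object) {
  if (isTRUE(object@reached_full_structure) &&
      isFALSE(object@reached_side_branch)) {
    return("reached_full_structure implies reached_side_branch")
  }
  TRUE
})

#' Dimensionless-to-physical calibration
#'
#' Matches the simulated cell-to-cell propagation time to the experimentally
#' measured one, yielding a conversion factor from dimensionless time to
#' seconds and derived physical quantities.
#'
#' @slot cell_spacing mean cell-to-cell distance in micrometres.
#' @slot experimental_cell_time measured mean cell-to-cell propagation time
#'   in seconds.
#' @slot simulated_cell_time simulated mean cell-to-cell propagation time,
#'   dimensionless.
#' @slot time_conversion seconds per dimensionless time unit
#'   (= experimental_cell_time / simulated_cell_time).
#' @slot dt dimensionless integration step the calibration refers to.
#' @export
setClass("Calibration",
  representation(cell_spacing = "numeric", experimental_cell_time = "numeric",
                 simulated_cell_time = "numeric", time_conversion = "numeric",
                 dt = "numeric")
)

setValidity("Calibration", function(object) {
  v <- c(object@cell_spacing, object@experimental_cell_time,
         object@simulated_cell_time, object@time_conversion, object@dt)
  if (any(!is.finite(v)) || any(v <= 0)) {
    return("all calibration fields must be positive and finite")
  }
  expected <- object@experimental_cell_time / object@simulated_cell_time
  if (abs(object@time_conversion - expected) >
      1e-12 * max(1, abs(expected))) {
    return("time_conversion must equal experimental/simulated cell time")
  }
  TRUE
})

#' Fluorescence trace set
#'
#' Extends \code{SummarizedExperiment}: rows are cells, columns are uniformly
#' spaced sample times.  Assay \code{"intensity"} holds whole-cell integrated
#' fluorescence (arbitrary units, or normalized units after
#' [normalizeTraces()]).  Metadata carries the background intensity series,
#' the sampling interval, the \code{normalized} flag and any trace labels
#' flagged unusable during normalization.
#'
#' @seealso [fluorescenceTraceSet()], [normalizeTraces()], [callResponse()]
#' @export
setClass("FluorescenceTraceSet", contains = "SummarizedExperiment")

#' Specification for the synthetic fluorescence trace generator
#'
#' @slot n_cells number of cells in the (chain) layout.
#' @slot layout \code{"chain"} (single stimulus) or \code{"dual"}.
#' @slot stimulated integer indices of stimulated cells.
#' @slot mean_lag mean cell-to-cell response lag in seconds (default 1.8).
#' @slot lag_dispersion multiplicative dispersion bound d: each per-pair lag
#'   is \code{mean_lag * U} with U uniform on [1/d, d] (default 2).
#' @slot rise_time pulse rise duration in seconds (default 3).
#' @slot decay_time time for the pulse to decay to 10\% of its amplitude,
#'   seconds (default 12; rise_time < decay_time).
#' @slot amplitude pulse amplitude on the normalized-intensity scale, i.e.
#'   peak normalized intensity is 1 + amplitude (default 1).
#' @slot noise_sd additive Gaussian noise standard deviation on the raw
#'   intensity scale, as a fraction of the resting intensity (default 0.05).
#' @slot sample_interval sampling interval in seconds (default 1.2).
#' @slot propagation_range number of cells a pulse travels beyond the
#'   stimulated cell in each direction (default 4.7; rounded).
#' @slot seed integer seed; fixed seed implies bit-reproducible output.
#' @export
setClass("TraceGeneratorSpec",
  representation(n_cells = "numeric", layout = "character",
                 stimulated = "numeric", mean_lag = "numeric",
                 lag_dispersion = "numeric", rise_time = "numeric",
                 decay_time = "numeric", amplitude = "numeric",
                 noise_sd = "numeric", sample_interval = "numeric",
                 propagation_range = "numeric", seed = "numeric")
)

setValidity("TraceGeneratorSpec", function(object) {
  msg <- character(0)
  pos <- function(x) length(x) == 1L && is.finite(x) && x > 0
  if (!pos(object@n_cells) || object@n_cells < 2) {
    msg <- c(msg, "n_cells must be >= 2")
  }
  if (!(object@layout %in% c("chain", "dual"))) {
    msg <- c(msg, "layout must be 'chain' or 'dual'")
  }
  nstim <- if (object@layout == "dual") 2L else 1L
  if (length(object@stimulated) != nstim ||
      any(object@stimulated < 1 | object@stimulated > object@n_cells)) {
    msg <- c(msg, sprintf("stimulated must index %d cell(s) in range", nstim))
  }
  if (!pos(object@mean_lag)) msg <- c(msg, "mean_lag must be positive")
  if (!(pos(object@lag_dispersion) && object@lag_dispersion >= 1)) {
    msg <- c(msg, "lag_dispersion must be >= 1")
  }
  if (!pos(object@rise_time) || !pos(object@decay_time) ||
      object@rise_time >= object@decay_time) {
    msg <- c(msg, "need 0 < rise_time < decay_time")
  }
  if (!pos(object@amplitude)) msg <- c(msg, "amplitude must be positive")
  if (!(length(object@noise_sd) == 1L && is.finite(object@noise_sd) &&
        object@noise_sd >= 0)) {
    msg <- c(msg, "noise_sd must be >= 0")
  }
  if (!pos(object@sample_interval)) {
    msg <- c(msg, "sample_interval must be positive")
  }
  if (!pos(object@propagation_range)) {
    msg <- c(msg, "propagation_range must be positive")
  }
  if (!(length(object@seed) == 1L && is.finite(object@seed) &&
        object@seed == floor(object@seed))) {
    msg <- c(msg, "seed must be an integer")
  }
  if (length(msg)) msg else TRUE
})
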