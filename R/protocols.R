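#' In-silico stimulation protocols
#'
#' The four simulated experiments: a 61-cell chain with a single stimulus in
#' the middle cell; the same chain with two simultaneous stimuli; and the
#' branched "T" structure with a single stimulus (backbone cell 28) or dual
#' stimuli (backbone cells 28 and 34) flanking the junction.
#'
#' @param p a [ReactionParameters-class].
#' @param s a [SimulationSettings-class].
#' @param d_edge edge diffusion coefficient (default 0.6).
#' @param early_stop passed to [simulateNetwork()].
#' @return \code{runChainSingle}, \code{runChainDual}: a
#'   [CalciumSimulation-class].  \code{runTSingle}, \code{runTDual}: a list
#'   with elements \code{result} ([CalciumSimulation-class]) and
#'   \code{outcome} ([PropagationOutcome-class]).
#' @name protocols
NULL

#' @describeIn protocols 61-cell chain, single stimulus at the middle cell
#'   (cell 31) with concentration \code{p@c0}.
#' @export
runChainSingle <- function(p = reactionParameters(),
                           s = simulationSettings(), d_edge = 0.6,
                           early_stop = FALSE) {
  net <- buildChain(61, d_edge)
  simulateNetwork(net, p, s, stimulationProtocol("31", p@c0),
                  early_stop = early_stop)
}

#' @describeIn protocols 61-cell chain, two simultaneous stimuli placed
#'   centrally with \code{separation - 1} cells between them (default
#'   separation 7: cells 28 and 35, six cells between, relabelled
#'   1 ... 8 in the metadata \code{dual_labels} map).
#' @param separation index distance between the two stimulated cells
#'   (>= 1).
#' @export
runChainDual <- function(p = reactionParameters(),
                         s = simulationSettings(), d_edge = 0.6,
                         separation = 7, early_stop = FALSE) {
  if (!(length(separation) == 1L && separation >= 1 &&
        separation == floor(separation))) {
    stop("separation must be an integer >= 1")
  }
  n <- 61L
  first <- floor((n - separation) / 2) + 1L
  second <- first + as.integer(separation)
  if (second > n) stop("separation too large for the 61-cell chain")
  net <- buildChain(n, d_edge)
  sim <- simulateNetwork(net, p, s,
                         stimulationProtocol(as.character(c(first, second)),
                                             p@c0),
                         early_stop = early_stop)
  seg <- seq.int(first, second)
  md <- S4Vectors::metadata(sim)
  md$dual_labels <- stats::setNames(as.character(seq_along(seg)),
                                    as.character(seg))
  S4Vectors::metadata(sim) <- md
  sim
}

#' @describeIn protocols "T" structure, single stimulus at backbone cell 28.
#' @param dv vertex diffusion coefficient.
#' @param vertex_pairs passed to [buildTStructure()].
#' @export
runTSingle <- function(p = reactionParameters(), s = simulationSettings(),
                       d_edge = 0.6, dv = 0.1,
                       vertex_pairs = c("junction", "all"),
                       early_stop = FALSE) {
  net <- buildTStructure(d_edge, dv, match.arg(vertex_pairs))
  sim <- simulateNetwork(net, p, s, stimulationProtocol("28", p@c0),
                         early_stop = early_stop)
  list(result = sim, outcome = classifyPropagation(sim))
}

#' @describeIn protocols "T" structure, simultaneous stimuli at backbone
#'   cells 28 and 34.
#' @export
runTDual <- function(p = reactionParameters(), s = simulationSettings(),
                     d_edge = 0.6, dv = 0.1,
                     vertex_pairs = c("junction", "all"),
                     early_stop = FALSE) {
  net <- buildTStructure(d_edge, dv, match.arg(vertex_pairs))
  sim <- simulateNetwork(net, p, s,
                         stimulationProtocol(c("28", "34"), p@c0),
                         early_stop = early_stop)
  list(result = sim, outcome = classifyPropagation(sim))
}

#' Classify the propagation outcome of a simulation
#'
#' Operationalizes "propagates throughout the structure" versus "blocked at
#' the junction": a cell counts as activated when its rate regime reached
#' the refractory state within the horizon; side-branch propagation means
#' the mid-branch sentinel cell (default \code{"15s"}, far from both the
#' junction and the branch tip) activated; full-structure propagation means
#' every cell except the degree-one terminal cells activated.  When the
#' wave is blocked, \code{blocking_location} names the closest
#' non-activated cell (graph distance) to the stimulus.  A run is flagged
#' inconclusive when any cell activated within the final 5\% of the
#' requested horizon, because the front may still have been advancing.
#'
#' @param sim a [CalciumSimulation-class].
#' @param sentinel label of the side-branch sentinel cell.
#' @param final_fraction fraction of the horizon treated as "too late to be
#'   sure" (default 0.05).
#' @return a [PropagationOutcome-class].
#' @export
classifyPropagation <- function(sim, sentinel = "15s",
                                final_fraction = 0.05) {
  stopifnot(is(sim, "CalciumSimulation"))
  md <- S4Vectors::metadata(sim)
  net <- md$network
  lock_step <- md$lock_step
  labels <- names(lock_step)
  activated <- labels[!is.na(lock_step)]
  cp <- as.data.frame(net@couplings)
  deg <- table(factor(c(cp$a, cp$b), levels = labels))
  terminals <- labels[deg == 1L]
  reached_full <- all(setdiff(labels, terminals) %in% activated)
  reached_branch <- if (sentinel %in% labels) {
    sentinel %in% activated
  } else {
    NA
  }
  blocking <- NA_character_
  if (!reached_full) {
    dist <- .graph_distances(net, md$stimulus@cells)
    non_act <- setdiff(labels, activated)
    non_act <- non_act[is.finite(dist[non_act])]
    if (length(non_act)) {
      blocking <- non_act[which.min(dist[non_act])]
    }
  }
  horizon <- md$settings@n_steps
  late <- !is.na(lock_step) & lock_step > (1 - final_fraction) * horizon
  # a run cut short because every cell locked, or because activity died out,
  # is final by construction
  inconclusive <- any(late) && md$stopped == "horizon"
  new("PropagationOutcome",
      activated = activated,
      reached_side_branch = as.logical(reached_branch),
      reached_full_structure = reached_full,
      blocking_location = blocking,
      inconclusive = inconclusive)
}

setMethod("show", "PropagationOutcome", function(object) {
  cat(sprintf(
    "PropagationOutcome: %d activated; side branch: %s; full: %s%s%s\n",
    length(object@activated),
    ifelse(is.na(object@reached_side_branch), "n/a",
           object@reached_side_branch),
    object@reached_full_structure,
    ifelse(is.na(object@blocking_location), "",
           sprintf("; blocked near %s", object@blocking_location)),
    ifelse(object@inconclusive, "; INCONCLUSIVE", "")))
})

#' Sweep the vertex diffusion coefficient of the "T" structure
#'
#' Runs the single- or dual-stimulation "T" protocol for each value of the
#' vertex coefficient grid and classifies side-branch propagation.  Also
#' reports the largest grid value with side-branch propagation and the
#' smallest without, and checks (reports, does not assume) that propagating
#' values form a contiguous prefix of the grid.
#'
#' @param p a [ReactionParameters-class].
#' @param s a [SimulationSettings-class]; trajectories are not needed, so a
#'   coarse \code{record_every} is used automatically.
#' @param d_edge edge diffusion coefficient.
#' @param dv_grid sorted non-empty grid of vertex coefficients.
#' @param mode \code{"single"} or \code{"dual"}.
#' @param vertex_pairs passed to [buildTStructure()].
#' @return data.frame with columns \code{dv}, \code{mode},
#'   \code{reached_side_branch}, \code{reached_full_structure},
#'   \code{n_activated}, \code{blocking_location}, \code{inconclusive};
#'   attributes \code{largest_propagating}, \code{smallest_blocked} and
#'   \code{contiguous}.
#' @export
sweepDv <- function(p = reactionParameters(), s = simulationSettings(),
                    d_edge = 0.6, dv_grid = seq(0, 0.3, by = 0.01),
                    mode = c("single", "dual"),
                    vertex_pairs = c("junction", "all")) {
  mode <- match.arg(mode)
  vertex_pairs <- match.arg(vertex_pairs)
  if (!length(dv_grid)) stop("dv_grid must be non-empty")
  if (is.unsorted(dv_grid)) stop("dv_grid must be sorted increasingly")
  run <- if (mode == "single") runTSingle else runTDual
  s_sweep <- simulationSettings(dt = s@dt, n_steps = s@n_steps,
                                record_every = max(s@record_every, 50),
                                convention = s@convention)
  rows <- lapply(dv_grid, function(dv) {
    out <- run(p, s_sweep, d_edge, dv, vertex_pairs,
               early_stop = TRUE)$outcome
    data.frame(
      dv = dv, mode = mode,
      reached_side_branch = out@reached_side_branch,
      reached_full_structure = out@reached_full_structure,
      n_activated = length(out@activated),
      blocking_location = out@blocking_location,
      inconclusive = out@inconclusive
    )
  })
  res <- do.call(rbind, rows)
  prop <- res$dv[isTRUE_vec(res$reached_side_branch)]
  blocked <- res$dv[!isTRUE_vec(res$reached_side_branch)]
  attr(res, "largest_propagating") <- if (length(prop)) max(prop) else NA_real_
  attr(res, "smallest_blocked") <- if (length(blocked)) min(blocked) else NA_real_
  contiguous <- !length(prop) || !length(blocked) || max(prop) < min(blocked)
  attr(res, "contiguous") <- contiguous
  if (!contiguous) {
    warning("side-branch propagation is not a contiguous prefix of the grid")
  }
  res
}

isTRUE_vec <- function(x) !is.na(x) & x
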