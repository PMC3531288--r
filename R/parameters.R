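#' Reaction parameters
#'
#' Constructor with the calibrated defaults of the model: thresholds
#' \code{uc1 = 0.3}, \code{uc2 = 3.0}; rates \code{k1 = 0.03} (intake below
#' \code{uc1}), \code{k2 = -0.025} (release between the thresholds),
#' \code{k3 = 0.0045} (permanent refractory intake); stimulus concentration
#' \code{c0 = 2.0}.
#'
#' @param uc1,uc2 concentration thresholds, \code{0 < uc1 < uc2}.
#' @param k1,k2,k3 rate constants (\code{k1 > 0}, \code{k2 < 0},
#'   \code{k3 > 0}).
#' @param c0 default stimulus concentration (> 0).
#' @return a [ReactionParameters-class].
#' @export
reactionParameters <- function(uc1 = 0.3, uc2 = 3.0, k1 = 0.03, k2 = -0.025,
                               k3 = 0.0045, c0 = 2.0) {
  new("ReactionParameters", uc1 = uc1, uc2 = uc2, k1 = k1, k2 = k2, k3 = k3,
      c0 = c0)
}

#' Integrator settings
#'
#' @param dt dimensionless time step (default 0.01).
#' @param n_steps number of update steps (default 15000).
#' @param record_every recording stride (default 1).
#' @param convention scaling convention; see [SimulationSettings-class].
#' @return a [SimulationSettings-class].
#' @export
simulationSettings <- function(dt = 0.01, n_steps = 15000, record_every = 1,
                               convention = c("calibrated", "per_step",
                                              "per_time")) {
  convention <- match.arg(convention)
  new("SimulationSettings", dt = dt, n_steps = n_steps,
      record_every = record_every, convention = convention)
}

#' Stimulation protocol
#'
#' @param cells labels of stimulated cells.
#' @param concentration initial concentration(s), recycled over cells.
#' @return a [StimulationProtocol-class].
#' @export
stimulationProtocol <- function(cells, concentration = 2.0) {
  new("StimulationProtocol", cells = as.character(cells),
      concentration = concentration, simultaneous = TRUE)
}

setMethod("show", "ReactionParameters", function(object) {
  cat(sprintf(
    "ReactionParameters: uc1=%g uc2=%g k1=%g k2=%g k3=%g c0=%g\n",
    object@uc1, object@uc2, object@k1, object@k2, object@k3, object@c0))
})

setMethod("show", "SimulationSettings", function(object) {
  cat(sprintf(
    "SimulationSettings: dt=%g n_steps=%d record_every=%d convention=%s\n",
    object@dt, as.integer(object@n_steps),
    as.integer(object@record_every), object@convention))
})

setMethod("show", "StimulationProtocol", function(object) {
  cat(sprintf("StimulationProtocol: cells [%s] at C0 = %s\n",
              paste(object@cells, collapse = ", "),
              paste(object@concentration, collapse = ", ")))
})

#' Read / write a parameter configuration file
#'
#' YAML configuration with blocks \code{parameters} (the reaction
#' parameters), \code{settings} (integrator settings) and optional
#' \code{d_edge}.  A template with the model defaults ships at
#' \code{system.file("extdata", "default_parameters.yaml",
#' package = "CICRwave")}.
#'
#' @param path file path.
#' @return \code{readParametersYAML}: list with elements \code{parameters}
#'   ([ReactionParameters-class]), \code{settings}
#'   ([SimulationSettings-class]) and \code{d_edge} (numeric).
#' @export
readParametersYAML <- function(path) {
  doc <- yaml::read_yaml(path)
  p <- doc$parameters %||% list()
  s <- doc$settings %||% list()
  list(
    parameters = do.call(reactionParameters, p),
    settings = do.call(simulationSettings, s),
    d_edge = doc$d_edge %||% 0.6
  )
}

#' @rdname readParametersYAML
#' @param parameters a [ReactionParameters-class].
#' @param settings a [SimulationSettings-class].
#' @param d_edge edge diffusion coefficient.
#' @export
writeParametersYAML <- function(path, parameters = reactionParameters(),
                                settings = simulationSettings(),
                                d_edge = 0.6) {
  doc <- list(
    parameters = list(uc1 = parameters@uc1, uc2 = parameters@uc2,
                      k1 = parameters@k1, k2 = parameters@k2,
                      k3 = parameters@k3, c0 = parameters@c0),
    settings = list(dt = settings@dt, n_steps = settings@n_steps,
                    record_every = settings@record_every,
                    convention = settings@convention),
    d_edge = d_edge
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
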