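# Shared simulation fixtures, computed once per test run.
.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# The calibrated single-stimulus chain run (full horizon, full recording).
fx_chain_single <- function() {
  fx("chain_single", function() {
    runChainSingle(reactionParameters(), simulationSettings())
  })
}

# The calibrated dual-stimulus chain run.
fx_chain_dual <- function() {
  fx("chain_dual", function() {
    runChainDual(reactionParameters(), simulationSettings())
  })
}
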