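p_tab <- reactionParameters()

test_that("single chain stimulation propagates symmetrically outward", {
  sim <- fx_chain_single()
  at <- activationTimes(sim)
  expect_false(any(is.na(at)))           # the whole chain activates
  # neighbours of the stimulated cell activate first, then theirs, in order
  right <- at[as.character(31:55)]
  expect_true(all(diff(right) > 0))
  expect_equal(unname(at[as.character(30:26)]),
               unname(at[as.character(32:36)]))
})

test_that("zero coupling confines activation to the stimulated cell", {
  s <- simulationSettings(n_steps = 2000)
  sim <- runChainSingle(p_tab, s, d_edge = 0)
  act <- names(which(!is.na(activationSteps(sim))))
  expect_equal(act, "31")
  other <- setdiff(rownames(concentrations(sim)), "31")
  expect_true(all(concentrations(sim)[other, ] == 0))
})

test_that("dual stimulation places stimuli centrally and validates input", {
  sim <- fx_chain_dual()
  md <- S4Vectors::metadata(sim)
  expect_equal(md$stimulus@cells, c("28", "35"))
  expect_equal(unname(md$dual_labels[c("28", "35")]), c("1", "8"))
  expect_error(runChainDual(p_tab, separation = 61), "too large")
  expect_error(runChainDual(p_tab, separation = 0), "integer >= 1")
})

test_that("mirrored cells of the dual run behave identically", {
  sim <- fx_chain_dual()
  conc <- concentrations(sim)
  pairs <- list(c("28", "35"), c("29", "34"), c("30", "33"), c("31", "32"))
  for (pr in pairs) {
    expect_lt(max(abs(conc[pr[1], ] - conc[pr[2], ])), 1e-8)
  }
})

test_that("cells activate exactly once: the waves merge and annihilate", {
  sim <- fx_chain_dual()
  conc <- concentrations(sim)
  uc1 <- 0.3
  between <- as.character(29:34)
  outside <- as.character(c(10, 20, 27, 36, 45))
  for (lbl in c(between, outside)) {
    x <- conc[lbl, ]
    upcross <- sum(x[-1] > uc1 & x[-length(x)] <= uc1)
    expect_equal(upcross, 1L)
  }
})

test_that("T single stimulation propagates at low dv and blocks at high dv", {
  s <- simulationSettings()
  lo <- runTSingle(p_tab, s, dv = 0.1, early_stop = TRUE)
  expect_true(lo$outcome@reached_side_branch)
  expect_true(lo$outcome@reached_full_structure)
  expect_false(lo$outcome@inconclusive)

  hi <- runTSingle(p_tab, s, dv = 0.45, early_stop = TRUE)
  expect_false(hi$outcome@reached_side_branch)
  expect_true(hi$outcome@blocking_location %in%
                c("30", "31", "32", "1'", "2'", "1s"))
  # the wave dies at the junction: the far backbone side stays quiet
  far <- activationSteps(hi$result)[as.character(40:61)]
  expect_true(all(is.na(far)))
})

test_that("dual T stimulation crosses the junction where single cannot", {
  s <- simulationSettings()
  dv <- 0.45
  single <- runTSingle(p_tab, s, dv = dv, early_stop = TRUE)
  dual <- runTDual(p_tab, s, dv = dv, early_stop = TRUE)
  expect_false(single$outcome@reached_side_branch)
  expect_true(dual$outcome@reached_side_branch)
})

test_that("dual-stimulated T trajectories respect the reflection symmetry", {
  s <- simulationSettings(n_steps = 6000)
  dual <- runTDual(p_tab, s, dv = 0.2)
  conc <- concentrations(dual$result)
  for (pr in list(c("30", "32"), c("1'", "2'"), c("29", "33"),
                  c("28", "34"))) {
    expect_lt(max(abs(conc[pr[1], ] - conc[pr[2], ])), 1e-10)
  }
})

test_that("classifyPropagation flags short horizons and empty activation", {
  short <- runChainSingle(p_tab, simulationSettings(n_steps = 2000))
  out <- classifyPropagation(short)
  expect_true(out@inconclusive)
  expect_false(out@reached_full_structure)

  none <- runChainSingle(reactionParameters(c0 = 0.2),
                         simulationSettings(n_steps = 1000),
                         early_stop = TRUE)
  expect_length(classifyPropagation(none)@activated, 0L)
})

test_that("sweepDv reports transitions, contiguity and dual dominance", {
  s <- simulationSettings()
  grid <- c(0.10, 0.30, 0.36, 0.40, 0.48)
  single <- sweepDv(p_tab, s, dv_grid = grid, mode = "single")
  dual <- sweepDv(p_tab, s, dv_grid = grid, mode = "dual")
  expect_equal(nrow(single), length(grid))
  expect_true(attr(single, "contiguous"))
  expect_true(attr(dual, "contiguous"))
  # every dv that lets a single stimulus through also lets the dual pair
  expect_true(all(!single$reached_side_branch | dual$reached_side_branch))
  # and the dual threshold is strictly higher
  expect_gt(attr(dual, "largest_propagating"),
            attr(single, "largest_propagating"))
  expect_false(any(single$inconclusive))

  one <- sweepDv(p_tab, s, dv_grid = 0.1, mode = "single")
  expect_equal(nrow(one), 1L)
  expect_true(one$reached_side_branch)
  expect_error(sweepDv(p_tab, s, dv_grid = numeric(0)), "non-empty")
  expect_error(sweepDv(p_tab, s, dv_grid = c(0.2, 0.1)), "sorted")
})
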