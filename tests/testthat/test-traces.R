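test_that("normalization corrects background and scales to the first sample", {
  # constant trace at background + c normalizes to all ones
  bg <- rep(10, 12)
  raw <- matrix(rep(bg + 5, 2), nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  fts <- fluorescenceTraceSet(raw, background = bg)
  norm <- normalizeTraces(fts)
  expect_true(isNormalized(norm))
  expect_true(all(intensities(norm) == 1))

  # scale invariance: doubling raw and background changes nothing
  fts2 <- fluorescenceTraceSet(2 * raw, background = 2 * bg)
  expect_equal(intensities(normalizeTraces(fts2)), intensities(norm))

  # a pulse with a known 2x peak over baseline keeps its peak after
  # normalization
  pulse <- 20 + c(rep(10, 3), 10 * c(1.5, 2, 1.7, 1.3, 1.1), rep(10, 4))
  fts3 <- fluorescenceTraceSet(matrix(pulse, 1), background = rep(20, 12))
  expect_equal(max(intensities(normalizeTraces(fts3))), 2)

  expect_error(normalizeTraces(norm), "already normalized")
})

test_that("traces with non-positive initial intensity are flagged unusable", {
  raw <- rbind(good = rep(15, 10), dead = rep(5, 10))
  fts <- fluorescenceTraceSet(raw, background = rep(5, 10))
  norm <- normalizeTraces(fts)
  expect_equal(S4Vectors::metadata(norm)$unusable, "dead")
  expect_true(all(is.na(intensities(norm)["dead", ])))
  expect_true(all(intensities(norm)["good", ] == 1))
  # unusable traces yield a non-response, not an error
  call <- callResponse(intensities(norm)["dead", ], 1.2)
  expect_false(call$responded)
})

test_that("running-average rate matches its oracles", {
  # window 1 reproduces the raw first differences
  x <- c(1, 2, 4, 4.5, 4, 3)
  ra1 <- runningAverageRate(x, sample_interval = 1, window = 1)
  expect_equal(ra1$rate, diff(x))
  # a linear ramp has constant smoothed rate equal to its slope
  ramp <- seq(0, 9, by = 1.5)
  ra <- runningAverageRate(ramp, sample_interval = 1.2, window = 4)
  expect_true(all(abs(ra$rate - 1.5 / 1.2) < 1e-12))
  # enumeration oracle for a step change: the maximum of the smoothed rate
  # sits at the first window that fully contains the step
  step <- c(rep(0, 5), rep(1, 5))
  ra4 <- runningAverageRate(step, sample_interval = 1, window = 4)
  means <- vapply(4:9, function(j) mean(diff(step)[(j - 3):j]), numeric(1))
  expect_equal(ra4$rate, means)
  expect_equal(ra4$time[which.max(ra4$rate)], 5)
  expect_error(runningAverageRate(c(1, 2), window = 4), "too short")
})

test_that("response calls separate pulse shapes from flat noise", {
  set.seed(42)
  flat <- 1 + rnorm(40, 0, 0.02)
  expect_false(callResponse(flat, 1.2)$responded)

  t <- (0:39) * 1.2
  pulse <- 1 + ifelse(t < 12, 0, ifelse(t < 15.6, (t - 12) / 3.6,
                                        exp(-(t - 15.6) / 5)))
  call <- callResponse(pulse, 1.2)
  expect_true(call$responded)
  expect_equal(call$method, "raw_rate")
  expect_equal(call$uncertainty, 0.6)
  # response lands on the steepest rise samples
  expect_true(abs(call$response_time - 14.4) <= 1.2)

  weak <- callResponse(pulse, 1.2, weak_signal = TRUE)
  expect_equal(weak$method, "running_average")
  expect_equal(weak$uncertainty, 1.2)
  expect_error(callResponse(pulse[1:5], 1.2), "8 samples")
  # a slow-rise fast-decay transient is not a calcium response
  anti <- 1 + ifelse(t < 24, (t / 24)^1, ifelse(t < 26.4, 1 - (t - 24) / 2.4, 0))
  expect_false(callResponse(anti, 1.2)$responded)
})

test_that("propagation statistics match constructed fixtures", {
  mk <- function(rt) list(responded = !is.na(rt), response_time = rt,
                          method = "raw_rate", uncertainty = 0.6)
  # exact 1.8 s lags
  rts <- seq(0, by = 1.8, length.out = 7)
  calls <- lapply(c(rev(rts[2:4]), rts[1:4]), mk)
  names(calls) <- as.character(1:7)
  st <- propagationStats(calls, origin = "4")
  expect_equal(st$mean_lag, 1.8)
  expect_equal(st$sd_lag, 0)
  expect_equal(unname(st$distance), 3)

  # alternating 1.2 / 2.4 lags: closed-form mean and sd
  lag <- c(1.2, 2.4, 1.2, 2.4)
  rt2 <- c(0, cumsum(lag))
  calls2 <- lapply(rt2, mk)
  names(calls2) <- as.character(1:5)
  st2 <- propagationStats(calls2, origin = "1")
  expect_equal(st2$mean_lag, 1.8)
  expect_equal(st2$sd_lag, stats::sd(lag))
  expect_equal(st2$median_lag, 1.8)

  # a non-responder splits the chain; spanning pairs are excluded
  rt3 <- c(0, 1.8, NA, 5.4, 7.2)
  calls3 <- lapply(rt3, mk)
  names(calls3) <- as.character(1:5)
  st3 <- propagationStats(calls3, origin = "1")
  expect_equal(nrow(st3$pairs), 2L)
  expect_equal(st3$n_excluded_pairs, 2L)

  # dual origins give directional means
  rt4 <- c(0, 1.5, 3.0, 3.5, 2.0, 0)
  calls4 <- lapply(rt4, mk)
  names(calls4) <- as.character(1:6)
  st4 <- propagationStats(calls4, origin = c("1", "6"))
  expect_equal(sort(names(st4$directional)), c("downward", "upward"))
  expect_equal(unname(st4$directional["upward"]), mean(c(1.5, 1.5)))
  expect_equal(unname(st4$directional["downward"]), mean(c(1.5, 2.0)))

  expect_error(propagationStats(list(mk(NA), mk(1)), origin = "1",
                                labels = c("1", "2")),
               "insufficient")
})

test_that("trace CSV wide and long layouts round-trip", {
  sp <- traceGeneratorSpec(n_cells = 5, noise_sd = 0.01, seed = 3)
  g <- generateTraces(sp, style = "raw")
  for (layout in c("wide", "long")) {
    path <- tempfile(fileext = ".csv")
    writeTracesCSV(g$traces, path, layout = layout)
    back <- readTracesCSV(path)
    expect_equal(intensities(back), intensities(g$traces),
                 tolerance = 1e-12)
    expect_equal(S4Vectors::metadata(back)$background,
                 S4Vectors::metadata(g$traces)$background,
                 tolerance = 1e-12)
    expect_equal(sampleTimes(back), sampleTimes(g$traces))
    unlink(path)
  }
})

test_that("trace analysis of noiseless simulated data matches wave metrics", {
  sim <- fx_chain_single()
  cal <- calibrate(0.87)
  out <- tracesFromSimulation(sim, cal, noise_sd = 0,
                              sample_interval = 1.2)
  m <- intensities(out$traces)
  calls <- lapply(rownames(m), function(l) callResponse(m[l, ], 1.2))
  names(calls) <- rownames(m)
  called <- vapply(calls, `[[`, logical(1), "responded")
  truth <- out$truth$responder
  # responder sets agree
  expect_equal(unname(called), unname(truth[names(called)]))
  # response times track the dimensionless metrics: nondecreasing along
  # the propagation direction (up to sampling ties) and within one
  # sampling interval of the calibrated truth
  est <- vapply(calls, `[[`, numeric(1), "response_time")
  keep <- as.character(31:40)
  expect_true(all(diff(est[keep]) >= 0))
  expect_lt(max(abs(est[keep] - out$truth$response_time[keep])), 1.2 + 1e-9)
})

test_that("resampling finer than the recording resolution is rejected", {
  sim <- runChainSingle(reactionParameters(),
                        simulationSettings(n_steps = 200,
                                           record_every = 50))
  cal <- calibrate(0.87)
  expect_error(tracesFromSimulation(sim, cal, sample_interval = 0.5),
               "finer than")
})
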