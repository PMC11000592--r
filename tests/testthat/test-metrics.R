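# Amplitude, period and regime classification on constructed signals with
# known ground truth.

test_that("analysis_region returns the trailing fraction, snapped to the grid", {
  tr <- signal_trajectory(function(t) sin(t), horizon = 500)
  expect_equal(analysis_region(tr), c(250, 500))
  expect_equal(analysis_region(tr, fraction = 1), c(0, 500))
  expect_error(analysis_region(tr, fraction = 0), "fraction")
  expect_error(analysis_region(tr, fraction = 1.5), "fraction")
  # a damped transient with a 5 h envelope is excluded almost entirely
  tr2 <- signal_trajectory(function(t) 5 + exp(-t / 5) * sin(t), horizon = 500)
  r <- analysis_region(tr2)
  expect_lt(exp(-r[1] / 5), 1e-20)
})

test_that("amplitude is the range of the species over the region", {
  expect_equal(amplitude(signal_trajectory(function(t) rep(5, length(t)), 100)), 0)
  tr <- signal_trajectory(function(t) 5 + 2 * sin(2 * pi * t / 7), 100)
  expect_equal(amplitude(tr), 4, tolerance = 1e-3)
  # damped sinusoid: equals direct enumeration over the sampled points
  f <- function(t) 5 + 2 * exp(-t / 50) * sin(2 * pi * t / 7)
  tr <- signal_trajectory(f, 500)
  sel <- tr$times >= 250
  expect_identical(amplitude(tr, region = c(250, 500)),
                   max(f(tr$times[sel])) - min(f(tr$times[sel])))
})

test_that("period averages alternating zero-crossing intervals with interpolation", {
  tr <- signal_trajectory(function(t) sin(2 * pi * t / 5), 100)
  expect_equal(period(tr, region = c(0, 100)), 5, tolerance = 0.01)
  # harmonic distortion does not bias the full-period estimate
  tr2 <- signal_trajectory(function(t) sin(2 * pi * t / 5) +
                             0.3 * sin(4 * pi * t / 5), 100)
  expect_equal(period(tr2, region = c(0, 100)), 5, tolerance = 0.02)
  expect_error(period(signal_trajectory(function(t) rep(2, length(t)), 50)),
               "constant|crossings")
})

test_that("feature recovery is exact across amplitudes and periods", {
  # property sweep: A in [0.1, 100] nM, T in [0.5, 50] h
  for (A in c(0.1, 1, 10, 100)) {
    for (Tp in c(0.5, 2.7, 7, 19, 50)) {
      horizon <- max(20 * Tp, 10)
      horizon <- round(horizon / 0.01) * 0.01
      tr <- signal_trajectory(function(t) 3 * A + A * sin(2 * pi * t / Tp),
                              horizon)
      amp_bound <- 2 * 2 * A * (pi * 0.01 / Tp)^2 + 1e-9
      expect_lt(abs(amplitude(tr, region = c(0, horizon)) - 2 * A), amp_bound)
      expect_lt(abs(period(tr, region = c(0, horizon)) - Tp), 0.02)
    }
  }
})

test_that("classification separates stable, damped, sustained and unbounded", {
  expect_equal(classify(signal_trajectory(function(t) 1 + exp(-t), 100)),
               "stable")
  expect_equal(classify(signal_trajectory(function(t) exp(t / 5), 100,
                                          bounded = FALSE)), "unbounded")
  expect_equal(classify(signal_trajectory(
    function(t) 5 + 2 * sin(2 * pi * t / 7), 200)), "sustained")
  # decaying envelope, oscillation dead before the analysis region
  expect_equal(classify(signal_trajectory(
    function(t) 5 + 2 * exp(-t / 10) * sin(2 * pi * t / 7), 500)), "damped")
  # decaying envelope still active inside the region
  expect_equal(classify(signal_trajectory(
    function(t) 5 + 2 * exp(-t / 120) * sin(2 * pi * t / 7), 500)), "damped")
})

test_that("classification does not flip between sustained and stable on horizon extension", {
  for (id in c("ar_equal_halflives", "ar_nanodeg")) {
    m <- nanodegosc:::scenario_model(scenarios()[[id]])
    c1 <- classify(simulate_model(m, horizon = 500))
    c2 <- classify(simulate_model(m, horizon = 1000))
    expect_equal(c1 == "sustained", c2 == "sustained", label = id)
  }
})

test_that("the period of a sustained limit cycle is species-invariant", {
  tr <- simulate_model(reference_model("activator_repressor"))
  pers <- vapply(c("A", "B", "N", "C"), function(s) period(tr, s), numeric(1))
  expect_lt(diff(range(pers)) / mean(pers), 0.01)
})

test_that("features report NA period for non-oscillating trajectories", {
  f <- oscillation_features(signal_trajectory(function(t) 1 + exp(-t), 100))
  expect_equal(f$dynamic_class, "stable")
  expect_true(is.na(f$period))
  expect_equal(f$n_cycles, 0L)
})
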