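# Integration contracts: closed-form solutions, the fixed reporting grid,
# delay handling, the unboundedness sentinel and CSV round-tripping.

test_that("linear decay matches the closed form on the reporting grid", {
  m <- custom_model(function(t, x, lag) -x, species = "x")
  tr <- integrate_ode(m, x0 = 1, horizon = 10)
  expect_equal(unname(tr$states[, 1]), exp(-tr$times), tolerance = 1e-6)
})

test_that("a zero vector field yields a constant trajectory", {
  m <- custom_model(function(t, x, lag) c(0, 0), species = c("a", "b"))
  tr <- integrate_ode(m, x0 = c(3, 4), horizon = 5)
  expect_true(all(tr$states[, 1] == 3))
  expect_true(all(tr$states[, 2] == 4))
})

test_that("the output grid is constructed by index, bit-identical to 0.01 h steps", {
  tr <- integrate_ode(reference_model("mixed"), horizon = 12.34)
  expect_identical(tr$times, 0.01 * (0:1234))
  expect_identical(nrow(tr$states), 1235L)
  expect_error(integrate_ode(reference_model("mixed"), horizon = 0.005),
               "multiple")
})

test_that("stiff solver agrees with a fixed-step RK4 oracle on a random AR instance", {
  set.seed(101)
  p <- random_ar_params()
  m <- model_instance(p)
  x0 <- c(5, 5, 1, 0)
  tr <- integrate_ode(m, x0 = x0, horizon = 20, rtol = 1e-8, atol = 1e-11)
  oracle <- rk4_integrate(ar_field_oracle(p), x0, t_end = 20, h = 1e-4,
                          keep = 100L)
  scale <- max(abs(oracle))
  expect_lt(max(abs(tr$states - oracle)) / scale, 1e-4)
})

test_that("DDE integration reproduces the method-of-steps closed form", {
  # dx/dt = -x(t - 1), x == 1 for t <= 0:
  # x(t) = 1 - t on [0,1]; 1 - t + (t-1)^2/2 on [1,2]
  m <- custom_model(function(t, x, lag) -lag[1], species = "x", tau = 1)
  tr <- integrate_dde(m, history = function(t) 1, x0 = 1, horizon = 2,
                      rtol = 1e-9, atol = 1e-12)
  tt <- tr$times
  exact <- ifelse(tt <= 1, 1 - tt, 1 - tt + (tt - 1)^2 / 2)
  expect_lt(max(abs(tr$states[, 1] - exact)), 1e-6)
})

test_that("zero delay degenerates exactly to the ODE path", {
  p <- reference_params("goodwin")
  p$tau <- 0
  class(p) <- class(reference_params("goodwin"))
  m <- model_instance(p)
  tr_dde <- integrate_dde(m, horizon = 100, rtol = 1e-10, atol = 1e-13)
  # the delay-free system, integrated as an ODE
  m0 <- custom_model(function(t, x, lag) goodwin_rhs(x, x[1], p),
                     species = m$species)
  tr_ode <- integrate_ode(m0, x0 = c(0, 0, 0), horizon = 100,
                          rtol = 1e-10, atol = 1e-13)
  scale <- max(abs(tr_ode$states))
  expect_lt(max(abs(tr_dde$states - tr_ode$states)) / scale, 1e-8)
})

test_that("DDE solutions are insensitive to the delay-point discontinuities", {
  # refining tolerances near t = tau, 2 tau changes nothing beyond the band
  m <- reference_model("goodwin")
  a <- integrate_dde(m, horizon = 5)
  b <- integrate_dde(m, horizon = 5, rtol = 5e-7, atol = 5e-10)
  expect_lt(max(abs(a$states - b$states)) / max(abs(a$states)), 1e-4)
})

test_that("amplitude and period are robust to halving the solver tolerances", {
  m <- reference_model("activator_repressor")  # sustained at kN = 8
  f1 <- oscillation_features(simulate_model(m))
  f2 <- oscillation_features(simulate_model(m, rtol = 5e-7, atol = 5e-10))
  expect_equal(f1$dynamic_class, "sustained")
  expect_equal(f2$amplitude, f1$amplitude, tolerance = 1e-3)
  expect_equal(f2$period, f1$period, tolerance = 1e-3)
})

test_that("the unboundedness sentinel truncates and flags the trajectory", {
  m <- custom_model(function(t, x, lag) x, species = "x")  # x = e^t
  tr <- integrate_ode(m, x0 = 1, horizon = 30)
  expect_false(tr$bounded)
  expect_lt(tr$times[length(tr$times)], 30)
  # e^t reaches 1e9 at t = ln(1e9) ~ 20.7
  expect_equal(tr$times[length(tr$times)], log(1e9), tolerance = 0.05)
  expect_equal(classify(tr), "unbounded")
  expect_error(amplitude(tr), "unbounded")
})

test_that("trajectory CSV round-trips losslessly at full precision", {
  m <- reference_model("mixed")
  tr <- integrate_ode(m, horizon = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_identical(back$times, tr$times)
  expect_identical(unname(back$states), unname(tr$states))
  expect_identical(back$species, tr$species)
})
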