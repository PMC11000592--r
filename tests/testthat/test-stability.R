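# Linear-stability oracle: eigenvalues, characteristic roots of the delay
# system, and the classical scalar-DDE Hopf delay.

test_that("a linear stable system reports its eigenvalue", {
  m <- custom_model(function(t, x, lag) -x, species = "x")
  s <- linear_stability(m, equilibrium = c(x = 0))
  expect_equal(Re(s$leading_root), -1, tolerance = 1e-6)
  expect_equal(s$class, "stable")
})

test_that("scalar DDE characteristic roots cross the axis at the closed-form delay", {
  a <- 1; b <- 2
  tau_star <- scalar_dde_critical_tau(a, b)   # = (2*pi/3)/sqrt(3) ~ 1.2092
  expect_equal(tau_star, (2 * pi / 3) / sqrt(3), tolerance = 1e-12)
  J0 <- matrix(-a, 1, 1); Jtau <- matrix(-b, 1, 1)
  r_lo <- dde_rightmost_root(J0, Jtau, tau_star * 0.97)
  r_hi <- dde_rightmost_root(J0, Jtau, tau_star * 1.03)
  expect_lt(Re(r_lo), 0)
  expect_gt(Re(r_hi), 0)
  # at the crossing the frequency is sqrt(b^2 - a^2) = sqrt(3)
  r_c <- dde_rightmost_root(J0, Jtau, tau_star)
  expect_equal(abs(Im(c(r_c))), sqrt(3), tolerance = 1e-3)
  expect_lt(abs(Re(r_c)), 1e-3)
  # root residual contract
  expect_lt(attr(r_c, "residual"), 1e-8)
})

test_that("bisection on simulated growth recovers the scalar-DDE critical delay", {
  a <- 1; b <- 2
  grows <- function(tau) {
    m <- scalar_dde_model(a, b, tau)
    tr <- integrate_dde(m, history = function(t) 1, x0 = 1, horizon = 80)
    if (!tr$bounded) return(TRUE)
    x <- abs(tr$states[, 1])
    late <- max(x[tr$times >= 60])
    mid <- max(x[tr$times >= 40 & tr$times < 60])
    late > mid
  }
  r <- critical_parameter(lo = 0.9, hi = 1.6, edge_tolerance = 0.004,
                          predicate = grows)
  expect_equal(r$value, scalar_dde_critical_tau(a, b), tolerance = 0.01)
})

test_that("the Goodwin delay scenarios match their characteristic-root classes", {
  m <- reference_model("goodwin")
  m <- set_param(m, "kN", 0)
  s_short <- linear_stability(set_param(m, "tau", 0.5))
  expect_equal(s_short$class, "stable")
  s_long <- linear_stability(set_param(m, "tau", 15))
  expect_equal(s_long$class, "oscillatory-unstable")
  # near the Hopf point the simulated period matches 2 pi / Im(root)
  f <- simulate_features(set_param(m, "tau", 15), species = "A")
  expect_equal(f$dynamic_class, "sustained")
  expect_equal(f$period, 2 * pi / abs(Im(s_long$leading_root)),
               tolerance = 0.1)
})

test_that("oscillatory instability of the AR model appears inside the NanoDeg window", {
  m <- reference_model("activator_repressor")
  s_in <- linear_stability(m)                      # kN = 8: inside window
  expect_equal(s_in$class, "oscillatory-unstable")
  s_out <- linear_stability(set_param(m, "kN", 0)) # no NanoDeg: stable
  expect_equal(s_out$class, "stable")
  # measured period near the Hopf frequency just inside the window
  f <- simulate_features(m, species = "A")
  expect_equal(f$dynamic_class, "sustained")
})
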