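# Vector fields, parameter plumbing and equilibria of the five topologies.

test_that("hill_response covers its limits and rejects bad parameters", {
  # zero input returns the hi coefficient, for any K/h
  expect_equal(hill_response(0, K = 3, h = 2, lo = 0.1, hi = 7), 7)
  # midpoint gives the mean of the two coefficients at any Hill coefficient
  for (h in c(1, 2, 4.5, 10)) {
    expect_equal(hill_response(5, K = 5, h = h, lo = 2, hi = 10), 6)
  }
  # saturation limit approaches lo
  expect_equal(hill_response(1e6 * 2, K = 2, h = 2, lo = 2, hi = 10), 2,
               tolerance = 1e-9)
  # bounded between the coefficients over a wide input range
  x <- 10^seq(-3, 4, length.out = 50)
  y <- hill_response(x, K = 7, h = 3, lo = 0.5, hi = 20)
  expect_true(all(y >= 0.5 & y <= 20))
  expect_error(hill_response(1, K = 0, h = 2, lo = 0, hi = 1), "K")
  expect_error(hill_response(1, K = 1, h = 0.5, lo = 0, hi = 1), "h")
})

test_that("parameter constructors enforce the circuit invariants", {
  expect_error(ar_params(alpha1 = 1, alpha2 = 2, beta1 = 0, beta2 = 1,
                         KA = 1, KB = 1, m = 2, n = 2, k5 = 2, k6 = 1,
                         deltaA = 1, deltaB = 1), "alpha1 > alpha2")
  expect_error(goodwin_params(beta1 = 2, beta2 = 1, KA = 1, m = 2,
                              deltaA = 1, tau = 1), "beta2 > beta1")
  expect_error(repressilator_params(k1 = 30, k2 = 3, k3 = 3, k4 = 30,
                                    k5 = 3, k6 = 30, KA = 1, KB = 1, KC = 1,
                                    m = 2, n = 2, r = 2, deltaA = 1,
                                    deltaB = 1, deltaC = 1, mode = "common"),
               "leaky rate > repressed floor")
  expect_error(mixed_params(k1 = 1, k2 = 5, k3 = 2, k4 = 0.1, k5 = 2,
                            KA = 1, KB = 1, m = 2, n = 2, deltaA = 1,
                            deltaB = 1, deltaN = 1, kon = 1, koff = 1),
               "k3 > k2")
  # individual mode requires a shared kon/koff across the three NanoDegs
  nd <- function(kon) nanodeg_params(kN = 1, deltaN = 1, kon = kon, koff = 1)
  expect_error(
    repressilator_params(k1 = 1, k2 = 10, k3 = 1, k4 = 10, k5 = 1, k6 = 10,
                         KA = 1, KB = 1, KC = 1, m = 2, n = 2, r = 2,
                         deltaA = 1, deltaB = 1, deltaC = 1,
                         mode = "individual",
                         nanodegs = list(A = nd(1), B = nd(2), C = nd(1))),
    "share a single kon"
  )
})

test_that("half-life conversions are exact and monotone", {
  expect_equal(halflife_to_rate(log(2)), 1)
  expect_equal(halflife_to_rate(0.9), 0.770164, tolerance = 1e-6)
  expect_equal(rate_to_halflife(halflife_to_rate(4)), 4)
  th <- c(0.3, 0.9, 4, 11)
  expect_true(all(diff(halflife_to_rate(th)) < 0))
  expect_error(halflife_to_rate(0), "positive")
  expect_error(halflife_to_rate(-1), "positive")
})

test_that("nominal_nanodeg_rate gives the synthesis rate whose steady state is N0", {
  expect_equal(nominal_nanodeg_rate(0, 1), 0)
  expect_equal(nominal_nanodeg_rate(10, halflife_to_rate(0.9)), 7.70164,
               tolerance = 1e-6)
  # integrating dN/dt = pNT kN - deltaN N from 0 approaches N0
  dN <- halflife_to_rate(0.9)
  kN <- nominal_nanodeg_rate(25, dN, pNT = 2)
  m <- custom_model(function(t, x, lag) 2 * kN - dN * x, species = "N")
  tr <- integrate_ode(m, x0 = 0, horizon = 30)
  expect_equal(unname(tr$states[nrow(tr$states), 1]), 25, tolerance = 1e-6)
  expect_error(nominal_nanodeg_rate(1, 0), "deltaN")
})

test_that("activator-repressor field matches its zero-state and NanoDeg-off limits", {
  p <- reference_params("activator_repressor")
  d0 <- ar_rhs(c(0, 0, 0, 0), p)
  expect_equal(d0, c(p$pAT * p$alpha2 * p$beta2, p$pBT * p$k6,
                     p$nanodeg$pNT * p$nanodeg$kN, 0))
  # with kN = 0 and no NanoDeg present the (A, B) block is the two-species
  # model and the NanoDeg block is inert
  p0 <- p; p0$nanodeg$kN <- 0
  class(p0) <- class(p)
  st <- c(12.3, 45.6, 0, 0)
  d <- ar_rhs(st, p0)
  expect_equal(d[3], 0)
  expect_equal(d[4], 0)
  expect_equal(d[1],
               p$pAT * hill_response(st[1], p$KA, p$m, p$alpha1, p$alpha2) *
                 hill_response(st[2], p$KB, p$n, p$beta1, p$beta2) -
                 p$deltaA * st[1])
  expect_equal(d[2],
               p$pBT * hill_response(st[1], p$KA, p$m, p$k5, p$k6) -
                 p$deltaB * st[2])
})

test_that("Goodwin field uses the mature (delayed) repressor for repression and binding", {
  p <- reference_params("goodwin")
  d0 <- goodwin_rhs(c(0, 0, 0), delayedA = 0, p)
  expect_equal(d0, c(p$pAT * p$beta2, p$nanodeg$pNT * p$nanodeg$kN, 0))
  # saturated repression: synthesis floor beta1 (binding subtracted)
  d <- goodwin_rhs(c(0, 0, 0), delayedA = 1e9, p)
  expect_equal(d[1], p$pAT * p$beta1, tolerance = 1e-6)
  # NanoDeg absent
  p0 <- p; p0$nanodeg$kN <- 0; class(p0) <- class(p)
  d <- goodwin_rhs(c(3, 0, 0), delayedA = 2, p0)
  expect_equal(d[2], 0)
  expect_equal(d[3], 0)
})

test_that("repressilator field is symmetric for identical nodes and reduces when NanoDeg-free", {
  p <- reference_params("repressilator_common")
  s <- c(7, 7, 7, 2, 0.5, 0.5, 0.5)
  d <- repressilator_rhs(s, p)
  expect_equal(d[1], d[2])
  expect_equal(d[2], d[3])
  expect_equal(d[5], d[6])
  expect_equal(d[6], d[7])
  # kN = 0 with empty NanoDeg states: plain three-node ring
  p0 <- p; p0$nanodeg$kN <- 0; class(p0) <- class(p)
  s0 <- c(11, 3, 0.7, 0, 0, 0, 0)
  d0 <- repressilator_rhs(s0, p0)
  expect_equal(d0[4:7], rep(0, 4))
  expect_equal(d0[1], p$pAT * hill_response(0.7, p$KC, p$r, p$k1, p$k2) -
                 p$deltaA * 11)
})

test_that("mixed-mode field matches its constitutive and decoupled limits", {
  p <- reference_params("mixed")
  d0 <- mixed_rhs(c(0, 0, 0, 0), p)
  expect_equal(d0, c(p$pAT * p$k1, p$pBT * p$k3, p$pNT * p$k5, 0))
  # kon = koff = 0 decouples A into a linear birth-death process
  p0 <- p; p0$kon <- 0; p0$koff <- 0; class(p0) <- class(p)
  eq <- find_equilibrium(model_instance(p0))
  expect_equal(unname(eq["A"]), p$pAT * p$k1 / p$deltaA, tolerance = 1e-8)
})

test_that("total-NanoDeg bookkeeping identities hold exactly on random states", {
  set.seed(42)
  for (rep_i in 1:20) {
    # activator-repressor: d(N + C)/dt = pNT kN - deltaN (N + C)
    p <- reference_params("activator_repressor")
    s <- runif(4, 0, 50)
    d <- ar_rhs(s, p)
    expect_equal(d[3] + d[4],
                 p$nanodeg$pNT * p$nanodeg$kN - p$nanodeg$deltaN * (s[3] + s[4]),
                 tolerance = 1e-12)
    # mixed: d(N + C)/dt = pNT hill(B) - deltaN (N + C)
    pm <- reference_params("mixed")
    sm <- runif(4, 0, 50)
    dm <- mixed_rhs(sm, pm)
    expect_equal(dm[3] + dm[4],
                 pm$pNT * hill_response(sm[2], pm$KB, pm$n, pm$k4, pm$k5) -
                   pm$deltaN * (sm[3] + sm[4]),
                 tolerance = 1e-12)
    # common repressilator: one shared pool
    pc <- reference_params("repressilator_common")
    sc <- runif(7, 0, 50)
    dc <- repressilator_rhs(sc, pc)
    expect_equal(sum(dc[4:7]),
                 pc$nanodeg$pNT * pc$nanodeg$kN -
                   pc$nanodeg$deltaN * sum(sc[4:7]),
                 tolerance = 1e-12)
    # individual repressilator: per-node totals d(NX + TX)/dt
    pi_ <- reference_params("repressilator_individual")
    si <- runif(9, 0, 50)
    di <- repressilator_rhs(si, pi_)
    for (k in 1:3) {
      nd <- pi_$nanodegs[[k]]
      expect_equal(unname(di[3 + k] + di[6 + k]),
                   nd$pNT * nd$kN - nd$deltaN * (si[3 + k] + si[6 + k]),
                   tolerance = 1e-12)
    }
  }
})

test_that("compiled vector fields agree with the R reference implementations", {
  set.seed(7)
  topos <- c("activator_repressor", "repressilator_common",
             "repressilator_individual", "mixed")
  for (topo in topos) {
    m <- reference_model(topo)
    for (i in 1:5) {
      x0 <- runif(length(m$species), 0, 40)
      h <- 1e-3
      # one explicit Euler step through the compiled solver recovers the
      # compiled derivative exactly: f = (x1 - x0) / h
      out <- deSolve::ode(y = x0, times = c(0, h),
                          func = nanodegosc:::solver_func_name(m$topology),
                          parms = nanodegosc:::as_solver_parms(m),
                          dllname = "nanodegosc", initfunc = "nd_initmod",
                          method = "euler")
      d_compiled <- (out[2, -1] - x0) / h
      d_r <- model_rhs(m, x0)
      expect_equal(unname(d_compiled), unname(d_r), tolerance = 1e-10)
    }
  }
})

test_that("ar_rhs matches a finite difference of an independently integrated trajectory", {
  set.seed(11)
  p <- random_ar_params()
  f <- ar_field_oracle(p)
  h <- 1e-4
  x0 <- c(5, 5, 1, 0)
  path <- rk4_integrate(f, x0, t_end = 2 * h, h = h)
  fd <- (path[3, ] - path[1, ]) / (2 * h)
  expect_equal(fd, ar_rhs(path[2, ], p), tolerance = 1e-4)
})

test_that("find_equilibrium meets its residual contract and the integration limit", {
  # Goodwin with beta1 ~ beta2 (no effective repression) and kN = 0:
  # A* = pAT beta2 / deltaA
  p <- goodwin_params(beta1 = 20 * (1 - 1e-9), beta2 = 20, KA = 2, m = 3,
                      deltaA = halflife_to_rate(11), tau = 0.5,
                      nanodeg = nanodeg_params(kN = 0, deltaN = 1,
                                               kon = 0.3, koff = 1.323))
  m <- model_instance(p)
  eq <- find_equilibrium(m)
  expect_equal(unname(eq["A"]), 20 / halflife_to_rate(11), tolerance = 1e-6)
  # residual contract
  r <- model_rhs(m, eq, delayed = eq)
  expect_lt(max(abs(r)), 1e-10 * (1 + max(abs(eq))))
  expect_true(all(eq >= 0))
  # a stable instance matches the long-time limit of the integration
  m2 <- reference_model("activator_repressor")   # kN = 8 window...
  m2 <- set_param(m2, "kN", 0)                   # ...switched off: stable
  eq2 <- find_equilibrium(m2)
  tr <- simulate_model(m2, horizon = 2000)
  endv <- tr$states[nrow(tr$states), ]
  expect_equal(unname(eq2), unname(endv), tolerance = 1e-6)
})

test_that("set_param resolves derived symbols and rejects unknown ones", {
  m <- reference_model("activator_repressor")
  expect_equal(set_param(m, "t_half_A", 2)$params$deltaA, log(2) / 2)
  m2 <- set_param(m, "Kd", 0.441)
  expect_equal(m2$params$nanodeg$koff / m2$params$nanodeg$kon, 0.441)
  m3 <- set_param(m, "v", 10)
  expect_equal(m3$params$nanodeg$kon, 10 * m$params$nanodeg$kon)
  expect_equal(nanodeg_kd(m3$params$nanodeg), nanodeg_kd(m$params$nanodeg))
  m4 <- set_param(m, "N0", 10)
  expect_equal(m4$params$nanodeg$kN,
               10 * m$params$nanodeg$deltaN / m$params$nanodeg$pNT)
  expect_error(set_param(m, "zeta", 1), "unknown symbol")
  # setters cannot break invariants: the constructor re-validates
  expect_error(set_param(m, "alpha1", 0.5), "alpha1 > alpha2")
  # individual mode: kN fans out to all three NanoDegs
  mi <- set_param(reference_model("repressilator_individual"), "kN", 3.3)
  expect_equal(vapply(mi$params$nanodegs, `[[`, numeric(1), "kN"),
               c(A = 3.3, B = 3.3, C = 3.3))
})
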