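# Independent oracles used across the suite.  These re-implement the model
# equations and integration from scratch (scalar arithmetic, fixed-step
# RK4) so that agreement with the package's solvers is a genuine
# cross-check, not a tautology.

# Fixed-step classical RK4 for a vector field f(t, x).  Returns the states
# at every `keep`-th step (including t = 0).
rk4_integrate <- function(f, x0, t_end, h, keep = 1L) {
  n_steps <- round(t_end / h)
  out <- matrix(NA_real_, floor(n_steps / keep) + 1L, length(x0))
  out[1L, ] <- x0
  x <- x0
  t <- 0
  row <- 1L
  for (i in seq_len(n_steps)) {
    k1 <- f(t, x)
    k2 <- f(t + h / 2, x + h / 2 * k1)
    k3 <- f(t + h / 2, x + h / 2 * k2)
    k4 <- f(t + h, x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- i * h
    if (i %% keep == 0L) {
      row <- row + 1L
      out[row, ] <- x
    }
  }
  out
}

# Hand-written activator-repressor vector field (duplicated on purpose:
# the oracle must not share code with the implementation under test).
ar_field_oracle <- function(p) {
  nd <- p$nanodeg
  function(t, x) {
    A <- max(x[1], 0); B <- max(x[2], 0); N <- max(x[3], 0); C <- x[4]
    act <- (p$alpha1 * A^p$m + p$alpha2 * p$KA^p$m) / (A^p$m + p$KA^p$m)
    rep <- (p$beta1 * B^p$n + p$beta2 * p$KB^p$n) / (B^p$n + p$KB^p$n)
    synB <- (p$k5 * A^p$m + p$k6 * p$KA^p$m) / (A^p$m + p$KA^p$m)
    bind <- nd$kon * A * N - nd$koff * C
    c(p$pAT * act * rep - p$deltaA * x[1] - bind,
      p$pBT * synB - p$deltaB * x[2],
      nd$pNT * nd$kN - nd$deltaN * x[3] - bind,
      bind - nd$deltaN * C)
  }
}

# Random AR parameter sets on the scale of the calibrated reference set.
random_ar_params <- function() {
  lu <- function(x, spread) x * 10^stats::runif(1, -spread, spread)
  ar_params(
    alpha1 = lu(250, 0.2), alpha2 = lu(1, 0.2),
    beta1 = 0.04, beta2 = 1,
    KA = lu(10, 0.2), KB = lu(26, 0.2), m = 2, n = 4,
    k5 = lu(30, 0.2), k6 = 0.03,
    deltaA = halflife_to_rate(lu(4, 0.2)),
    deltaB = halflife_to_rate(lu(4, 0.2)),
    nanodeg = nanodeg_params(kN = lu(8, 0.4),
                             deltaN = halflife_to_rate(0.9),
                             kon = 3, koff = 13.23)
  )
}

# Critical delay of dx/dt = -a x - b x(t - tau) (b > a > 0):
# tau* = acos(-a/b) / sqrt(b^2 - a^2).
scalar_dde_critical_tau <- function(a, b) acos(-a / b) / sqrt(b^2 - a^2)

# Linear scalar DDE as a custom model.
scalar_dde_model <- function(a, b, tau) {
  custom_model(function(t, x, lag) -a * x - b * lag[1],
               species = "x", tau = tau)
}

# Synthetic signal trajectory on the standard grid.
signal_trajectory <- function(fun, horizon, dt = 0.01, bounded = TRUE) {
  tt <- dt * (0:round(horizon / dt))
  trajectory(tt, matrix(fun(tt), ncol = 1), species = "x",
             bounded = bounded)
}

expected_scenario_classes <- c(
  ar_equal_halflives = "stable",
  ar_fast_activator_088 = "sustained",
  ar_fast_activator_03 = "sustained",
  ar_nanodeg = "sustained",
  goodwin_tau_05 = "stable",
  goodwin_tau_10 = "damped",
  goodwin_tau_15 = "sustained",
  goodwin_short_halflife = "damped",
  goodwin_nanodeg = "sustained",
  rep_no_nanodeg = "stable",
  rep_common_nanodeg = "sustained",
  rep_common_kN_6p5 = "damped",
  rep_common_kN_13 = "damped",
  rep_common_kN_26 = "sustained",
  rep_asym_nodes = "sustained",
  mixed_no_nanodeg = "stable",
  mixed_nanodeg = "sustained"
)
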