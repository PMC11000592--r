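# Amplitude, period and dynamic-regime classification of trajectories.
#
# Amplitude is the range (max - min) of the reported species over the
# analysis region.  Period is obtained from the zero-mean signal: zero
# crossings are located by sign change with linear interpolation between
# grid points, and the mean interval between alternating (same-direction,
# i.e. every second) crossings gives the full period.

#' Analysis region of a trajectory
#'
#' The trailing `fraction` of the horizon (default the final 50 %), over
#' which amplitude and period are measured; the start is snapped to the
#' sampling grid.  The leading part is treated as transient.
#'
#' @param traj An `osc_trajectory` (must be bounded).
#' @param fraction Fraction of the horizon to keep, in (0, 1].
#' @return Numeric `c(t_start, t_end)` in hours.
#' @export
analysis_region <- function(traj, fraction = 0.5) {
  stopifnot(inherits(traj, "osc_trajectory"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  if (!traj$bounded) {
    stop("trajectory is unbounded; analysis region undefined", call. = FALSE)
  }
  tn <- traj$times[length(traj$times)]
  t0 <- (1 - fraction) * tn
  i0 <- which(traj$times >= t0 - 1e-12)[1]
  c(traj$times[i0], tn)
}

region_indices <- function(traj, region) {
  if (is.null(region)) region <- analysis_region(traj)
  if (length(region) != 2L || region[1] >= region[2]) {
    stop("`region` must be an increasing (t_start, t_end) pair", call. = FALSE)
  }
  idx <- which(traj$times >= region[1] - 1e-12 &
               traj$times <= region[2] + 1e-12)
  if (length(idx) < 2L) stop("region contains fewer than 2 grid points",
                             call. = FALSE)
  idx
}

#' Oscillation amplitude
#'
#' Difference between the largest and the lowest concentration of the
#' reported species over the analysis region.
#'
#' @param traj An `osc_trajectory`.
#' @param species Species label (or column index); defaults to the first.
#' @param region `c(t_start, t_end)`; defaults to [analysis_region()].
#' @return Amplitude in nM.
#' @export
amplitude <- function(traj, species = traj$species[1], region = NULL) {
  stopifnot(inherits(traj, "osc_trajectory"))
  if (!traj$bounded) {
    stop("trajectory is unbounded; amplitude undefined", call. = FALSE)
  }
  x <- traj$states[region_indices(traj, region), species_index(traj, species)]
  max(x) - min(x)
}

# All zero crossings of the zero-mean signal, with linear interpolation.
# Returns a data.frame(time, up) ordered in time.
zero_crossings <- function(tt, x) {
  z <- x - mean(x)
  s <- sign(z)
  # treat exact zeros as belonging to the following sign
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  if (s[1] == 0) s[1] <- s[which(s != 0)[1]]
  i <- which(s[-length(s)] * s[-1] < 0)
  if (length(i) == 0) {
    return(data.frame(time = numeric(0), up = logical(0)))
  }
  frac <- z[i] / (z[i] - z[i + 1])
  # direction from the post-crossing sign: robust when z sits exactly on 0
  data.frame(time = tt[i] + frac * (tt[i + 1] - tt[i]), up = s[i + 1] > 0)
}

#' Oscillation period
#'
#' Mean time interval between alternating (same-direction) zero crossings
#' of the zero-mean signal over the analysis region, i.e. the full period.
#' Crossing times are refined by linear interpolation between grid points.
#'
#' @inheritParams amplitude
#' @return Period in hours.
#' @export
period <- function(traj, species = traj$species[1], region = NULL) {
  stopifnot(inherits(traj, "osc_trajectory"))
  if (!traj$bounded) {
    stop("trajectory is unbounded; period undefined", call. = FALSE)
  }
  idx <- region_indices(traj, region)
  x <- traj$states[idx, species_index(traj, species)]
  atol <- if (!is.null(traj$settings$atol)) traj$settings$atol else 1e-9
  if (max(x) - min(x) < atol * 1e3) {
    stop("signal is numerically constant in the region; no period",
         call. = FALSE)
  }
  cr <- zero_crossings(traj$times[idx], x)
  up <- cr$time[cr$up]
  dn <- cr$time[!cr$up]
  if (length(up) < 2 && length(dn) < 2) {
    stop("fewer than 2 same-direction zero crossings; no period",
         call. = FALSE)
  }
  mean(c(if (length(up) >= 2) diff(up), if (length(dn) >= 2) diff(dn)))
}

# Per-cycle peak-to-trough envelope between consecutive same-direction
# crossings.  Internal; returns list(n_cycles, env, period).
cycle_envelope <- function(tt, x) {
  cr <- zero_crossings(tt, x)
  up <- cr$time[cr$up]
  n_cycles <- max(0L, length(up) - 1L)
  env <- numeric(0)
  if (n_cycles >= 1) {
    env <- vapply(seq_len(n_cycles), function(k) {
      sel <- tt >= up[k] & tt <= up[k + 1]
      if (sum(sel) < 2) return(NA_real_)
      max(x[sel]) - min(x[sel])
    }, numeric(1))
    env <- env[!is.na(env)]
  }
  list(n_cycles = n_cycles, env = env)
}

classify_info <- function(traj, species = traj$species[1], fraction = 0.5,
                          envelope_tol = 0.01) {
  stopifnot(inherits(traj, "osc_trajectory"))
  if (!traj$bounded) {
    return(list(class = "unbounded", n_cycles = 0L, env_rel = NA_real_))
  }
  j <- species_index(traj, species)
  region <- analysis_region(traj, fraction)
  idx <- region_indices(traj, region)
  x <- traj$states[idx, j]
  tt <- traj$times[idx]
  atol <- if (!is.null(traj$settings$atol)) traj$settings$atol else 1e-9
  flat_tol <- max(atol * 1e3, 1e-9 * max(abs(x), 1))

  info <- list(class = "stable", n_cycles = 0L, env_rel = NA_real_,
               region = region)
  if (max(x) - min(x) >= flat_tol) {
    ce <- cycle_envelope(tt, x)
    info$n_cycles <- ce$n_cycles
    if (length(ce$env) >= 2) {
      env_rel <- (ce$env[length(ce$env)] - ce$env[1]) / ce$env[1]
      info$env_rel <- env_rel
      if (ce$n_cycles >= 5 && abs(env_rel) < envelope_tol) {
        info$class <- "sustained"
        return(info)
      }
      if (ce$n_cycles >= 3 && env_rel <= -envelope_tol) {
        info$class <- "damped"
        return(info)
      }
      if (env_rel >= envelope_tol) {
        # envelope still growing at the end of the horizon: transient not
        # settled; report for adaptive-horizon callers
        info$growing <- TRUE
      }
    }
    if (ce$n_cycles >= 1 && info$class == "stable") {
      # an oscillation is visibly present but the region holds too few
      # cycles (or an unsettled envelope) to call it: a longer horizon is
      # needed for a conclusive label
      info$inconclusive <- TRUE
    }
  }
  # look for a decaying oscillation in the transient part
  pre <- traj$times < region[1]
  if (sum(pre) > 10) {
    xp <- traj$states[pre, j]
    if (max(xp) - min(xp) >= flat_tol) {
      ce <- cycle_envelope(traj$times[pre], xp)
      if (ce$n_cycles >= 3 && length(ce$env) >= 2 &&
          ce$env[length(ce$env)] < ce$env[1]) {
        info$class <- "damped"
      }
    }
  }
  info
}

#' Classify the long-run dynamic regime of a trajectory
#'
#' One of `"unbounded"` (sentinel hit), `"sustained"` (at least 5 full
#' cycles in the analysis region with the per-cycle peak-to-trough envelope
#' varying by less than `envelope_tol` between the first and last cycle),
#' `"damped"` (a decaying oscillation of at least 3 cycles, in the region
#' or the transient) or `"stable"`.
#'
#' @inheritParams amplitude
#' @param fraction Analysis-region fraction (default 0.5).
#' @param envelope_tol Relative envelope tolerance separating sustained
#'   from decaying/growing oscillation (default 1 %).
#' @return Character class.
#' @export
classify <- function(traj, species = traj$species[1], fraction = 0.5,
                     envelope_tol = 0.01) {
  classify_info(traj, species, fraction, envelope_tol)$class
}

#' Extract all oscillation features of a trajectory
#'
#' @inheritParams classify
#' @return An `oscillation_features` list: `dynamic_class`, `amplitude`
#'   (nM; `NA` when unbounded), `period` (h; `NA` unless the region
#'   contains a measurable oscillation), `region`, `n_cycles`.
#' @export
oscillation_features <- function(traj, species = traj$species[1],
                                 fraction = 0.5, envelope_tol = 0.01) {
  info <- classify_info(traj, species, fraction, envelope_tol)
  amp <- NA_real_
  per <- NA_real_
  region <- c(NA_real_, NA_real_)
  if (info$class != "unbounded") {
    region <- info$region
    amp <- amplitude(traj, species, region)
    per <- tryCatch(period(traj, species, region), error = function(e) NA_real_)
  }
  structure(
    list(dynamic_class = info$class, amplitude = amp, period = per,
         region = region, n_cycles = info$n_cycles,
         env_rel = info$env_rel, species = if (is.character(species))
           species else traj$species[species]),
    class = "oscillation_features"
  )
}

#' @export
print.oscillation_features <- function(x, ...) {
  cat(sprintf("<oscillation_features> %s: class=%s amplitude=%s nM period=%s h cycles=%d\n",
              x$species, x$dynamic_class,
              format(signif(x$amplitude, 6)), format(signif(x$period, 6)),
              x$n_cycles))
  invisible(x)
}

#' Simulate a model and extract its oscillation features
#'
#' Runs the integrator and the feature extractor in one step.  When the
#' per-cycle envelope is still growing at the end of the horizon (a slow
#' transient toward a limit cycle, typical just inside a Hopf bifurcation),
#' the horizon is doubled, at most `max_extensions` times, until the
#' classification settles; classification is otherwise invariant to horizon
#' extension.
#'
#' @param model An `osc_model`.
#' @param species Reported species (default the first).
#' @param horizon Base horizon, h.
#' @param fraction,envelope_tol Passed to the classifier.
#' @param max_extensions Maximum number of horizon doublings (default 2).
#' @param ... Passed to the integrator.
#' @return An `oscillation_features` object with the trajectory attached as
#'   attribute `"trajectory"`.
#' @export
simulate_features <- function(model, species = model$species[1],
                              horizon = default_horizon(model),
                              fraction = 0.5, envelope_tol = 0.01,
                              max_extensions = 2, ...) {
  h <- horizon
  for (k in 0:max_extensions) {
    traj <- simulate_model(model, horizon = h, ...)
    info <- classify_info(traj, species, fraction, envelope_tol)
    settled <- (is.null(info$growing) && is.null(info$inconclusive)) ||
      info$class %in% c("sustained", "unbounded", "damped")
    if (settled || k == max_extensions) break
    h <- 2 * h
  }
  f <- oscillation_features(traj, species, fraction, envelope_tol)
  attr(f, "trajectory") <- traj
  f
}
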