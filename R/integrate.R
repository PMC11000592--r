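#' Uniformly sampled trajectory of a simulated circuit
#'
#' Container for a time course of all species on the fixed reporting grid.
#' The grid is constructed by index (`dt * 0:n`), never by accumulation, so
#' output times are bit-identical across runs.
#'
#' @param times Numeric vector of times, h; must be a uniform grid starting
#'   at 0.
#' @param states Numeric matrix (time x species), nM.
#' @param species Character vector of column labels.
#' @param topology Model identifier (`"synthetic"` for constructed signals).
#' @param bounded `FALSE` if the simulation was cut short by the
#'   unboundedness sentinel.
#' @param settings List of solver settings (tolerances, cap, diagnostics).
#' @return Object of class `osc_trajectory`.
#' @export
trajectory <- function(times, states, species = colnames(states),
                       topology = "synthetic", bounded = TRUE,
                       settings = list()) {
  states <- as.matrix(states)
  if (is.null(species)) {
    species <- paste0("x", seq_len(ncol(states)))
  }
  if (length(times) != nrow(states)) {
    stop("`times` and `states` must have matching lengths", call. = FALSE)
  }
  if (length(times) >= 2) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-9 * max(dt[1], 1)) {
      stop("`times` must be a uniform grid", call. = FALSE)
    }
  }
  colnames(states) <- species
  structure(
    list(times = as.numeric(times), states = states, species = species,
         topology = topology, bounded = bounded, settings = settings),
    class = "osc_trajectory"
  )
}

#' @export
print.osc_trajectory <- function(x, ...) {
  cat(sprintf("<osc_trajectory> %s: %d points, t in [%g, %g] h, species: %s%s\n",
              x$topology, length(x$times), x$times[1],
              x$times[length(x$times)], paste(x$species, collapse = ","),
              if (!x$bounded) " [UNBOUNDED: truncated at sentinel]" else ""))
  invisible(x)
}

# Reporting grid constructed by index; horizon must be a multiple of dt.
sample_grid <- function(horizon, dt = 0.01) {
  if (!is.numeric(horizon) || horizon <= 0) {
    stop("`horizon` must be positive (hours)", call. = FALSE)
  }
  n <- round(horizon / dt)
  if (abs(n * dt - horizon) > 1e-9) {
    stop(sprintf("`horizon` must be a positive multiple of the %g h sampling step",
                 dt), call. = FALSE)
  }
  dt * (0:n)
}

#' Default simulation horizon of a model
#'
#' 500 h for every packaged topology (long enough for transients at the
#' circuits' hour-scale kinetics to die before the analysis region);
#' `NULL` for custom models, which must state a horizon.
#'
#' @param model An `osc_model`.
#' @return Horizon in hours, or `NULL`.
#' @export
default_horizon <- function(model) {
  if (identical(model$topology, "custom")) NULL else 500
}

# Default initial state: all species at 0 nM, except the repressilator
# rings, whose repressors are staggered (10, 1, 0.1 nM).  A symmetric start
# of an identical-node ring lies on the symmetric invariant manifold and
# can never break into oscillation; the stagger emulates sequential
# induction of the three genes.
default_x0 <- function(model) {
  x0 <- numeric(length(model$species))
  if (model$topology %in% c("repressilator_common",
                            "repressilator_individual")) {
    x0[1:3] <- c(10, 1, 0.1)
  }
  x0
}

species_index <- function(traj, species) {
  if (is.numeric(species)) return(as.integer(species))
  i <- match(species, traj$species)
  if (any(is.na(i))) {
    stop(sprintf("species `%s` not in trajectory (have: %s)",
                 paste(species[is.na(i)], collapse = ","),
                 paste(traj$species, collapse = ",")), call. = FALSE)
  }
  i
}

finalize_deSolve <- function(out, times, model, bounded_cap, rtol, atol,
                             extra = list()) {
  tcol <- out[, 1]
  keep <- match(round(tcol / (times[2] - times[1])),
                round(times / (times[2] - times[1])))
  ok <- !is.na(keep) & !duplicated(keep)
  states <- out[ok, -1, drop = FALSE]
  got_times <- times[keep[ok]]
  rowmax <- states[, 1]
  for (j in seq_len(ncol(states))[-1]) rowmax <- pmax(rowmax, states[, j])
  bad <- !is.finite(rowSums(states)) | rowmax >= bounded_cap
  bounded <- TRUE
  if (any(bad)) {
    cut <- which(bad)[1] - 1L
    if (cut < 1L) cut <- 1L
    states <- states[seq_len(cut), , drop = FALSE]
    got_times <- got_times[seq_len(cut)]
    bounded <- FALSE
  } else if (length(got_times) < length(times)) {
    bounded <- FALSE  # solver stopped early (sentinel root or failure)
  }
  trajectory(got_times, states, species = model$species,
             topology = model$topology, bounded = bounded,
             settings = c(list(rtol = rtol, atol = atol, cap = bounded_cap,
                               horizon = times[length(times)]), extra))
}

#' Integrate a non-delayed circuit model
#'
#' Adaptive, stiff-capable integration (deSolve's `lsodar`) with dense
#' output evaluated on the fixed reporting grid.  Integration terminates
#' early, and the trajectory is flagged `bounded = FALSE`, if any species
#' reaches the unboundedness sentinel `cap`.
#'
#' @param model An [model_instance()] (non-delayed) or [custom_model()]
#'   with `tau = 0`.
#' @param x0 Initial state, nM; defaults to all species at 0 except the
#'   repressilator rings, whose repressors start staggered at (10, 1, 0.1)
#'   nM so that the symmetric invariant manifold of identical nodes is
#'   avoided.
#' @param horizon Simulation horizon, h; a positive multiple of `dt`.
#' @param rtol,atol Relative / absolute local error tolerances.
#' @param dt Reporting grid step, h (default 0.01).
#' @param cap Unboundedness sentinel, nM (default 1e9).
#' @return An `osc_trajectory`.
#' @export
integrate_ode <- function(model, x0 = NULL, horizon = default_horizon(model),
                          rtol = 1e-6, atol = 1e-9, dt = 0.01, cap = 1e9) {
  stopifnot(inherits(model, "osc_model"))
  if (model$delayed) {
    stop("model has a delay; use integrate_dde()", call. = FALSE)
  }
  if (is.null(horizon)) {
    stop("`horizon` is required for custom models", call. = FALSE)
  }
  times <- sample_grid(horizon, dt)
  if (is.null(x0)) x0 <- default_x0(model)
  if (length(x0) != length(model$species) || any(x0 < 0) || any(!is.finite(x0))) {
    stop("`x0` must be a nonnegative finite vector matching the species",
         call. = FALSE)
  }
  fname <- solver_func_name(model$topology)
  out <- if (!is.null(fname)) {
    deSolve::ode(
      y = x0, times = times, func = fname,
      parms = as_solver_parms(model, cap = cap),
      dllname = "nanodegosc", initfunc = "nd_initmod",
      method = "lsodar", rootfunc = "nd_root", nroot = 1L,
      rtol = rtol, atol = atol, maxsteps = 50000
    )
  } else {
    rhs <- model$rhs
    deSolve::ode(
      y = x0, times = times,
      func = function(t, y, parms) list(rhs(t, y, y)),
      parms = NULL, method = "lsodar",
      rootfunc = function(t, y, parms) cap - max(y),
      rtol = rtol, atol = atol, maxsteps = 50000
    )
  }
  finalize_deSolve(out, times, model, cap, rtol, atol)
}

#' Integrate a constant-delay circuit model
#'
#' Delay integration with deSolve's history interpolation (`dede`), which
#' realizes the method of steps: on each interval the previously computed
#' segment provides the lagged state.  With `tau = 0` the problem
#' degenerates exactly to [integrate_ode()] of the delay-free system.
#'
#' @param model A delayed [model_instance()] (Goodwin) or [custom_model()]
#'   with `tau > 0`.
#' @param history Pre-simulation history: a numeric vector (constant
#'   history, the default is all species at 0, matching the convention that
#'   no repressor exists before induction) or a function of `t` on
#'   `[-tau, 0]` returning the state vector.
#' @param x0 State at `t = 0`; defaults to the history evaluated at 0.
#' @inheritParams integrate_ode
#' @return An `osc_trajectory`.
#' @export
integrate_dde <- function(model, history = NULL,
                          x0 = NULL, horizon = default_horizon(model),
                          rtol = 1e-6, atol = 1e-9, dt = 0.01, cap = 1e9) {
  stopifnot(inherits(model, "osc_model"))
  nsp <- length(model$species)
  if (is.null(history)) history <- numeric(nsp)
  hist_fun <- if (is.function(history)) {
    history
  } else {
    if (length(history) != nsp || any(history < 0)) {
      stop("constant `history` must be a nonnegative vector matching the species",
           call. = FALSE)
    }
    local({ h <- as.numeric(history); function(t) h })
  }
  if (is.null(x0)) x0 <- hist_fun(0)
  if (is.null(horizon)) {
    stop("`horizon` is required for custom models", call. = FALSE)
  }
  tau <- model$tau

  if (tau <= 0) {
    # degenerate case: solve the delay-free system
    m0 <- if (model$topology == "custom") {
      custom_model(model$rhs, model$species, tau = 0, params = model$params)
    } else {
      rhs <- function(t, y, lag) model_rhs(model, y, t, delayed = y)
      custom_model(rhs, model$species, tau = 0)
    }
    return(integrate_ode(m0, x0 = x0, horizon = horizon, rtol = rtol,
                         atol = atol, dt = dt, cap = cap))
  }
  if (!model$delayed) {
    stop("model has no delay; use integrate_ode()", call. = FALSE)
  }

  times <- sample_grid(horizon, dt)
  use_compiled <- identical(model$topology, "goodwin") && !is.function(history)
  out <- if (use_compiled) {
    deSolve::dede(
      y = x0, times = times, func = "nd_goodwin",
      parms = as_solver_parms(model, cap = cap, history = history),
      dllname = "nanodegosc", initfunc = "nd_initmod",
      rtol = rtol, atol = atol, maxsteps = 50000,
      control = list(mxhist = 1e5)
    )
  } else {
    rhs_model <- model
    f <- function(t, y, parms) {
      lag <- if (t > tau) deSolve::lagvalue(t - tau) else hist_fun(t - tau)
      if (any(y >= cap) || any(!is.finite(y))) {
        return(list(numeric(length(y))))
      }
      list(model_rhs(rhs_model, y, t, delayed = lag))
    }
    deSolve::dede(y = x0, times = times, func = f, parms = NULL,
                  rtol = rtol, atol = atol, maxsteps = 50000,
                  control = list(mxhist = 1e5))
  }
  finalize_deSolve(out, times, model, cap, rtol, atol,
                   extra = list(tau = tau))
}

#' Simulate a model with its default settings
#'
#' Dispatches to [integrate_ode()] or [integrate_dde()] according to the
#' topology.  The default horizon is 500 h, long enough that transients at
#' the circuits' hour-scale kinetics decay well before the analysis region.
#'
#' @param model An `osc_model`.
#' @param ... Passed to the integrator.
#' @return An `osc_trajectory`.
#' @export
simulate_model <- function(model, ...) {
  if (model$delayed) integrate_dde(model, ...) else integrate_ode(model, ...)
}

#' Write / read a trajectory as CSV
#'
#' Full-precision (17 significant digits) plain-text serialization with
#' header `time_h,<species...>`; round-trips losslessly.
#'
#' @param traj An `osc_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "osc_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("time_h", traj$species), collapse = ","), con)
  m <- cbind(traj$times, traj$states)
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param topology,bounded Metadata restored onto the object.
#' @export
read_trajectory_csv <- function(path, topology = "synthetic", bounded = TRUE) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (names(d)[1] != "time_h") {
    stop("not a trajectory CSV (first column must be time_h)", call. = FALSE)
  }
  trajectory(d[[1]], as.matrix(d[, -1, drop = FALSE]),
             species = names(d)[-1], topology = topology, bounded = bounded)
}
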