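# Parameter sweeps, oscillation windows with bisection-refined edges,
# critical (Hopf) parameter values, and 2-D Hill-coefficient scans.  All
# searches are deterministic: grids are fixed, simulations are
# deterministic, and bisection follows a fixed rule.

features_at <- function(model, symbol, value, species, horizon, fraction,
                        envelope_tol, ...) {
  m <- set_param(model, symbol, value)
  if (is.null(species)) species <- m$species[1]
  simulate_features(m, species = species, horizon = horizon,
                    fraction = fraction, envelope_tol = envelope_tol, ...)
}

#' Sweep a parameter symbol over a grid
#'
#' For each grid value: sets the symbol on the base model (derived symbols
#' such as `t_half_N`, `Kd`, `v` or `dna_dose` are resolved relative to the
#' base), simulates, and extracts oscillation features; optionally also runs
#' the linear-stability oracle.
#'
#' @param model Base `osc_model`.
#' @param symbol Symbol to sweep (see [param_symbols()]).
#' @param grid Strictly increasing numeric grid in the symbol's units.
#' @param species Reported species (default first).
#' @param horizon Simulation horizon, h.
#' @param fraction,envelope_tol Classifier settings.
#' @param stability Also attach the leading stability root per value.
#' @param ... Passed to the integrator.
#' @return A data.frame of class `osc_sweep` with columns `value`, `class`,
#'   `amplitude`, `period`, `n_cycles` (plus `root_re`, `root_im` when
#'   `stability = TRUE`); the full features are in `attr(, "features")`.
#' @export
sweep_param <- function(model, symbol, grid, species = NULL,
                        horizon = default_horizon(model),
                        fraction = 0.5, envelope_tol = 0.01,
                        stability = FALSE, ...) {
  stopifnot(inherits(model, "osc_model"))
  if (!symbol %in% param_symbols(model)) {
    stop(sprintf("unknown symbol `%s` for topology %s", symbol,
                 model$topology), call. = FALSE)
  }
  if (length(grid) < 1 || any(diff(grid) <= 0)) {
    stop("`grid` must be nonempty and strictly increasing", call. = FALSE)
  }
  feats <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    f <- tryCatch(
      features_at(model, symbol, grid[i], species, horizon, fraction,
                  envelope_tol, ...),
      error = function(e) e
    )
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(value = grid[i], class = "error",
                              amplitude = NA_real_, period = NA_real_,
                              n_cycles = NA_integer_)
      feats[[i]] <- f
    } else {
      rows[[i]] <- data.frame(value = grid[i], class = f$dynamic_class,
                              amplitude = f$amplitude, period = f$period,
                              n_cycles = f$n_cycles)
      feats[[i]] <- f
    }
    if (stability) {
      rep_i <- tryCatch(
        linear_stability(set_param(model, symbol, grid[i])),
        error = function(e) NULL
      )
      rows[[i]]$root_re <- if (is.null(rep_i)) NA_real_ else
        Re(rep_i$leading_root)
      rows[[i]]$root_im <- if (is.null(rep_i)) NA_real_ else
        Im(rep_i$leading_root)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "features") <- feats
  attr(out, "symbol") <- symbol
  class(out) <- c("osc_sweep", class(out))
  out
}

#' Write a sweep table as CSV
#'
#' @param sw An `osc_sweep` data.frame.
#' @param path Output path.
#' @export
write_sweep_csv <- function(sw, path) {
  utils::write.csv(as.data.frame(sw), path, row.names = FALSE)
  invisible(path)
}

bisect_edge <- function(pred, x_in, x_out, edge_tolerance) {
  # invariant: pred(x_in) is TRUE, pred(x_out) is FALSE
  while (abs(x_out - x_in) > edge_tolerance) {
    mid <- (x_in + x_out) / 2
    if (isTRUE(pred(mid))) x_in <- mid else x_out <- mid
  }
  (x_in + x_out) / 2
}

#' Oscillation window(s) of a swept parameter
#'
#' Finds every maximal contiguous interval of the swept symbol over which
#' the system sustains oscillation: a coarse grid (default 32 points,
#' log-spaced for positive brackets) locates sustained points, then each
#' window edge is refined by bisection on the sustained/not-sustained
#' predicate to `edge_tolerance`.
#'
#' @param model Base `osc_model` (ignored when `predicate` is supplied).
#' @param symbol Swept symbol.
#' @param bracket `c(lo, hi)` search interval in the symbol's units.
#' @param edge_tolerance Edge refinement tolerance (same units).
#' @param n_coarse Coarse grid size.
#' @param log_spaced Log-space the coarse grid (requires `lo > 0`).
#' @param predicate Optional `function(value) -> TRUE/FALSE` replacing the
#'   simulate-and-classify pipeline (used by tests and custom searches).
#' @param ... Passed to [simulate_features()].
#' @return List of windows, each `list(symbol, lower, upper,
#'   edge_tolerance, lower_open, upper_open)`; empty list when no sustained
#'   point is found.  `lower_open`/`upper_open` report whether the edge was
#'   refined (TRUE) or clipped at the bracket (FALSE).
#' @export
oscillation_window <- function(model, symbol, bracket,
                               edge_tolerance = diff(range(bracket)) / 1000,
                               n_coarse = 32, log_spaced = all(bracket > 0),
                               predicate = NULL, species = NULL,
                               horizon = if (!is.null(model))
                                 default_horizon(model) else NULL,
                               ...) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  if (is.null(predicate)) {
    predicate <- function(value) {
      f <- tryCatch(
        features_at(model, symbol, value, species, horizon, 0.5, 0.01, ...),
        error = function(e) NULL
      )
      !is.null(f) && identical(f$dynamic_class, "sustained")
    }
  }
  grid <- if (log_spaced) {
    exp(seq(log(bracket[1]), log(bracket[2]), length.out = n_coarse))
  } else {
    seq(bracket[1], bracket[2], length.out = n_coarse)
  }
  ok <- vapply(grid, function(v) isTRUE(predicate(v)), logical(1))
  if (!any(ok)) return(list())

  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  windows <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 > 1) {
      lower <- bisect_edge(predicate, grid[i0], grid[i0 - 1], edge_tolerance)
      lower_refined <- TRUE
    } else {
      lower <- bracket[1]; lower_refined <- FALSE
    }
    if (i1 < length(grid)) {
      upper <- bisect_edge(predicate, grid[i1], grid[i1 + 1], edge_tolerance)
      upper_refined <- TRUE
    } else {
      upper <- bracket[2]; upper_refined <- FALSE
    }
    windows[[length(windows) + 1]] <- list(
      symbol = symbol, lower = lower, upper = upper,
      edge_tolerance = edge_tolerance,
      lower_refined = lower_refined, upper_refined = upper_refined
    )
  }
  windows
}

#' Critical parameter value at a dynamic-class boundary
#'
#' Bisection on the classification boundary between `lo` and `hi`.  The
#' default predicate is "classify = sustained"; any `function(value)`
#' returning a logical or a class label can be supplied instead (e.g. a
#' growth test for linear oracle systems).
#'
#' @param model Base `osc_model` (ignored when `predicate` is supplied).
#' @param symbol Swept symbol.
#' @param lo,hi Bracket; the predicate must differ between the two.
#' @param edge_tolerance Bisection tolerance (default 0.005 in the symbol's
#'   units).
#' @param predicate Optional replacement predicate.
#' @param ... Passed to [simulate_features()].
#' @return `list(value, lower_class, upper_class)`.
#' @export
critical_parameter <- function(model = NULL, symbol = NULL, lo, hi,
                               edge_tolerance = 0.005, predicate = NULL,
                               species = NULL,
                               horizon = if (!is.null(model))
                                 default_horizon(model) else NULL, ...) {
  stopifnot(lo < hi)
  if (is.null(predicate)) {
    predicate <- function(value) {
      f <- tryCatch(
        features_at(model, symbol, value, species, horizon, 0.5, 0.01, ...),
        error = function(e) NULL
      )
      if (is.null(f)) "error" else f$dynamic_class
    }
  }
  p_lo <- predicate(lo)
  p_hi <- predicate(hi)
  if (identical(p_lo, p_hi)) {
    stop(sprintf("no class boundary in bracket: both ends give %s",
                 format(p_lo)), call. = FALSE)
  }
  a <- lo; b <- hi
  while (b - a > edge_tolerance) {
    mid <- (a + b) / 2
    if (identical(predicate(mid), p_lo)) a <- mid else b <- mid
  }
  list(value = (a + b) / 2, lower_class = p_lo, upper_class = p_hi)
}

#' 2-D Hill-coefficient scan of the mixed-mode repressilator
#'
#' Oscillation features over a grid of Hill-coefficient pairs, plus the
#' minimal coefficient on each axis that admits sustained oscillation with
#' the partner axis held at its reference value (refined by bisection).
#'
#' @param model Base mixed-topology `osc_model`.
#' @param m_grid,n_grid Strictly increasing Hill-coefficient grids.
#' @param symbols Symbol pair (default `c("m", "n")`).
#' @param reference Partner value used for the per-axis minimal
#'   coefficients (default 10).
#' @param edge_tolerance Bisection tolerance for the minimal coefficients.
#' @param ... Passed to [simulate_features()].
#' @return `list(grid, min_first, min_second)`: `grid` is a data.frame
#'   with one row per pair (`m`, `n`, `class`, `amplitude`, `period`),
#'   `min_first`/`min_second` the refined minimal coefficients (`NA` when
#'   no transition lies inside the grid range).
#' @export
scan_2d <- function(model, m_grid, n_grid, symbols = c("m", "n"),
                    reference = 10, edge_tolerance = 0.05,
                    species = NULL, horizon = default_horizon(model),
                    ...) {
  stopifnot(inherits(model, "osc_model"), length(symbols) == 2)
  rows <- list()
  for (mv in m_grid) {
    m1 <- set_param(model, symbols[1], mv)
    for (nv in n_grid) {
      f <- tryCatch(
        features_at(m1, symbols[2], nv, species, horizon, 0.5, 0.01, ...),
        error = function(e) NULL
      )
      rows[[length(rows) + 1]] <- data.frame(
        m = mv, n = nv,
        class = if (is.null(f)) "error" else f$dynamic_class,
        amplitude = if (is.null(f)) NA_real_ else f$amplitude,
        period = if (is.null(f)) NA_real_ else f$period
      )
    }
  }
  grid <- do.call(rbind, rows)
  names(grid)[1:2] <- symbols

  min_along <- function(axis_symbol, partner_symbol, axis_grid) {
    base <- set_param(model, partner_symbol, reference)
    pred <- function(v) {
      f <- tryCatch(
        features_at(base, axis_symbol, v, species, horizon, 0.5, 0.01, ...),
        error = function(e) NULL
      )
      !is.null(f) && identical(f$dynamic_class, "sustained")
    }
    ok <- vapply(axis_grid, pred, logical(1))
    if (!any(ok) || ok[1]) return(NA_real_)
    i <- which(ok)[1]
    bisect_edge(pred, axis_grid[i], axis_grid[i - 1], edge_tolerance)
  }
  list(
    grid = grid,
    min_first = min_along(symbols[1], symbols[2], m_grid),
    min_second = min_along(symbols[2], symbols[1], n_grid)
  )
}
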