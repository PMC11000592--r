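#' Hill response function
#'
#' The saturating input function used throughout the circuit models:
#' `(lo * x^h + hi * K^h) / (x^h + K^h)`.  `hi` is the value at zero input
#' and `lo` the value at saturation, so `hi > lo` encodes repression and
#' `lo > hi` activation; the output is always bounded between the two.
#'
#' @param x Input concentration, nM (>= 0; negative solver excursions are
#'   clamped to 0).
#' @param K Half-maximal constant, nM (> 0).
#' @param h Hill coefficient (>= 1).
#' @param lo Value as `x` saturates.
#' @param hi Value at `x = 0`.
#' @return Synthesis factor, same units as `lo`/`hi`.
#' @export
hill_response <- function(x, K, h, lo, hi) {
  if (!is.numeric(K) || any(K <= 0)) {
    stop("`K` must be positive", call. = FALSE)
  }
  if (!is.numeric(h) || any(h < 1)) {
    stop("Hill coefficient `h` must be >= 1", call. = FALSE)
  }
  x <- pmax(x, 0)
  xh <- x^h
  Kh <- K^h
  (lo * xh + hi * Kh) / (xh + Kh)
}

topology_species <- list(
  activator_repressor = c("A", "B", "N", "C"),
  goodwin = c("A", "N", "C"),
  repressilator_common = c("A", "B", "C", "N", "TA", "TB", "TC"),
  repressilator_individual = c("A", "B", "C", "NA", "NB", "NC",
                               "TA", "TB", "TC"),
  mixed = c("A", "B", "N", "C")
)

#' Build a simulatable model instance from a parameter set
#'
#' Binds a typed parameter object to its topology: state-species labels in
#' fixed order, the delay flag, and the compiled solver entry point.
#'
#' @param params One of [ar_params()], [goodwin_params()],
#'   [repressilator_params()] or [mixed_params()].
#' @return An object of class `osc_model`.
#' @seealso [custom_model()] for user-supplied vector fields.
#' @export
model_instance <- function(params) {
  if (!inherits(params, "osc_params")) {
    stop("`params` must be an osc_params object", call. = FALSE)
  }
  topology <- switch(class(params)[1],
    ar_params = "activator_repressor",
    goodwin_params = "goodwin",
    repressilator_params = paste0("repressilator_", params$mode),
    mixed_params = "mixed",
    stop("unknown parameter class: ", class(params)[1], call. = FALSE)
  )
  m <- list(
    topology = topology,
    params = params,
    species = topology_species[[topology]],
    delayed = identical(topology, "goodwin"),
    tau = if (identical(topology, "goodwin")) params$tau else 0
  )
  class(m) <- "osc_model"
  m
}

#' Wrap a user-supplied vector field as a model instance
#'
#' Used for oracle systems in tests and for generic dynamical systems that
#' are not one of the packaged topologies.  `rhs` must have signature
#' `function(t, state, delayed)`; `delayed` is the full state vector at
#' `t - tau` (ignored for ordinary systems).
#'
#' @param rhs Right-hand-side function returning the state derivative.
#' @param species Character vector of state labels.
#' @param tau Constant delay in hours (0 for an ODE system).
#' @param params Optional list stored alongside (not interpreted).
#' @export
custom_model <- function(rhs, species, tau = 0, params = list()) {
  stopifnot(is.function(rhs), is.character(species), length(species) >= 1,
            is.numeric(tau), tau >= 0)
  m <- list(topology = "custom", params = params, species = species,
            delayed = tau > 0, tau = tau, rhs = rhs)
  class(m) <- "osc_model"
  m
}

#' @export
print.osc_model <- function(x, ...) {
  cat("<osc_model> topology:", x$topology,
      " species:", paste(x$species, collapse = ","),
      if (x$delayed) sprintf(" tau=%g h", x$tau) else "", "\n")
  invisible(x)
}

# ---- right-hand sides (reference R implementations) ------------------------
# These mirror the compiled vector fields in src/models.c and are the module
# surface used by the equilibrium solver, the Jacobians and the tests; the
# integrator calls the compiled versions for speed.

#' Activator-repressor vector field
#'
#' Time derivatives of (A, B, N, C): activator, repressor, free NanoDeg and
#' NanoDeg-activator complex.  Synthesis of A is the product of a
#' self-activation Hill bracket and a repression-by-B bracket; the complex
#' is degraded at the NanoDeg rate and cannot bind the operator.
#'
#' @param state Numeric vector (A, B, N, C), nM.
#' @param p An [ar_params()] object.
#' @return Derivatives in nM h^-1.
#' @export
ar_rhs <- function(state, p) {
  chk_state(state, 4L)
  A <- state[1]; B <- state[2]; N <- state[3]; C <- state[4]
  nd <- p$nanodeg
  bind <- nd$kon * max(A, 0) * max(N, 0) - nd$koff * C
  c(
    p$pAT * hill_response(A, p$KA, p$m, p$alpha1, p$alpha2) *
      hill_response(B, p$KB, p$n, p$beta1, p$beta2) - p$deltaA * A - bind,
    p$pBT * hill_response(A, p$KA, p$m, p$k5, p$k6) - p$deltaB * B,
    nd$pNT * nd$kN - nd$deltaN * N - bind,
    bind - nd$deltaN * C
  )
}

#' Goodwin oscillator vector field
#'
#' Time derivatives of (A, N, C) given the mature (delayed) repressor
#' concentration `delayedA = A(t - tau)`.  Both transcriptional repression
#' and NanoDeg binding act through the mature form.
#'
#' @param state Numeric vector (A, N, C), nM.
#' @param delayedA Mature repressor concentration `A(t - tau)`, nM.
#' @param p A [goodwin_params()] object.
#' @return Derivatives in nM h^-1.
#' @export
goodwin_rhs <- function(state, delayedA, p) {
  chk_state(state, 3L)
  if (!is.numeric(delayedA) || length(delayedA) != 1L || !is.finite(delayedA)) {
    stop("`delayedA` must be a finite numeric scalar", call. = FALSE)
  }
  A <- state[1]; N <- state[2]; C <- state[3]
  nd <- p$nanodeg
  bind <- nd$kon * max(delayedA, 0) * max(N, 0) - nd$koff * C
  c(
    p$pAT * hill_response(delayedA, p$KA, p$m, p$beta1, p$beta2) -
      p$deltaA * A - bind,
    nd$pNT * nd$kN - nd$deltaN * N - bind,
    bind - nd$deltaN * C
  )
}

#' Repressilator vector field (common or individual NanoDegs)
#'
#' Common mode: state (A, B, C, N, TA, TB, TC); the three repressors
#' compete for one free NanoDeg pool.  Individual mode: state
#' (A, B, C, NA, NB, NC, TA, TB, TC) with one NanoDeg per repressor.
#'
#' @param state Numeric state vector (length 7 or 9, matching the mode).
#' @param p A [repressilator_params()] object.
#' @return Derivatives in nM h^-1.
#' @export
repressilator_rhs <- function(state, p) {
  ring <- function(A, B, C) c(
    p$pAT * hill_response(C, p$KC, p$r, p$k1, p$k2),
    p$pBT * hill_response(A, p$KA, p$m, p$k3, p$k4),
    p$pCT * hill_response(B, p$KB, p$n, p$k5, p$k6)
  )
  if (identical(p$mode, "common")) {
    chk_state(state, 7L)
    A <- state[1]; B <- state[2]; C <- state[3]; N <- state[4]
    TT <- state[5:7]
    nd <- p$nanodeg
    b <- nd$kon * pmax(c(A, B, C), 0) * max(N, 0) - nd$koff * TT
    syn <- ring(A, B, C)
    c(
      syn - c(p$deltaA, p$deltaB, p$deltaC) * c(A, B, C) - b,
      nd$pNT * nd$kN - nd$deltaN * N - sum(b),
      b - nd$deltaN * TT
    )
  } else {
    chk_state(state, 9L)
    A <- state[1]; B <- state[2]; C <- state[3]
    NN <- state[4:6]; TT <- state[7:9]
    nds <- p$nanodegs
    kon <- nds$A$kon; koff <- nds$A$koff
    b <- kon * pmax(c(A, B, C), 0) * pmax(NN, 0) - koff * TT
    dN <- vapply(nds, `[[`, numeric(1), "deltaN")
    syn <- ring(A, B, C)
    c(
      syn - c(p$deltaA, p$deltaB, p$deltaC) * c(A, B, C) - b,
      vapply(nds, function(q) q$pNT * q$kN, numeric(1)) - dN * NN - b,
      b - dN * TT
    )
  }
}

#' Mixed-mode repressilator vector field
#'
#' Time derivatives of (A, B, N, C): constitutively expressed Repressor A,
#' Repressor B (repressed by A), NanoDeg (repressed by B, binds A) and the
#' NanoDeg-A complex.
#'
#' @param state Numeric vector (A, B, N, C), nM.
#' @param p A [mixed_params()] object.
#' @return Derivatives in nM h^-1.
#' @export
mixed_rhs <- function(state, p) {
  chk_state(state, 4L)
  A <- state[1]; B <- state[2]; N <- state[3]; C <- state[4]
  bind <- p$kon * max(A, 0) * max(N, 0) - p$koff * C
  c(
    p$pAT * p$k1 - p$deltaA * A - bind,
    p$pBT * hill_response(A, p$KA, p$m, p$k2, p$k3) - p$deltaB * B,
    p$pNT * hill_response(B, p$KB, p$n, p$k4, p$k5) - p$deltaN * N - bind,
    bind - p$deltaN * C
  )
}

chk_state <- function(state, len) {
  if (!is.numeric(state) || length(state) != len || any(is.na(state))) {
    stop(sprintf("state must be a numeric vector of length %d without NAs",
                 len), call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate a model's vector field
#'
#' Generic dispatcher over all topologies (including [custom_model()]
#' systems).  For delayed models `delayed` is the full state vector at
#' `t - tau`; when omitted it defaults to `state` (the convention under
#' which equilibria of the delay system are computed).
#'
#' @param model An [model_instance()] or [custom_model()].
#' @param state Current state vector.
#' @param t Time (only used by custom vector fields).
#' @param delayed Delayed state vector, for delayed models.
#' @return Derivative vector.
#' @export
model_rhs <- function(model, state, t = 0, delayed = NULL) {
  stopifnot(inherits(model, "osc_model"))
  if (is.null(delayed)) delayed <- state
  switch(model$topology,
    activator_repressor = ar_rhs(state, model$params),
    goodwin = goodwin_rhs(state, delayed[1], model$params),
    repressilator_common = ,
    repressilator_individual = repressilator_rhs(state, model$params),
    mixed = mixed_rhs(state, model$params),
    custom = model$rhs(t, state, delayed),
    stop("unknown topology: ", model$topology, call. = FALSE)
  )
}

# ---- solver parameter packing ----------------------------------------------

nd_npar <- 64L
nd_cap_idx <- 61L  # 1-based position of the unboundedness cap

as_solver_parms <- function(model, cap = 1e9, history = NULL) {
  p <- model$params
  v <- switch(model$topology,
    activator_repressor = {
      nd <- p$nanodeg
      c(p$alpha1, p$alpha2, p$beta1, p$beta2, p$KA, p$KB, p$m, p$n,
        p$k5, p$k6, p$deltaA, p$deltaB, p$pAT, p$pBT,
        nd$kN, nd$deltaN, nd$kon, nd$koff, nd$pNT)
    },
    goodwin = {
      nd <- p$nanodeg
      h <- if (is.null(history)) c(0, 0, 0) else history
      c(p$beta1, p$beta2, p$KA, p$m, p$deltaA, p$tau, p$pAT,
        nd$kN, nd$deltaN, nd$kon, nd$koff, nd$pNT, h)
    },
    repressilator_common = {
      nd <- p$nanodeg
      c(p$k1, p$k2, p$k3, p$k4, p$k5, p$k6, p$KA, p$KB, p$KC,
        p$m, p$n, p$r, p$deltaA, p$deltaB, p$deltaC, p$pAT, p$pBT, p$pCT,
        nd$kN, nd$deltaN, nd$kon, nd$koff, nd$pNT)
    },
    repressilator_individual = {
      nds <- p$nanodegs
      c(p$k1, p$k2, p$k3, p$k4, p$k5, p$k6, p$KA, p$KB, p$KC,
        p$m, p$n, p$r, p$deltaA, p$deltaB, p$deltaC, p$pAT, p$pBT, p$pCT,
        vapply(nds, `[[`, numeric(1), "kN"),
        vapply(nds, `[[`, numeric(1), "deltaN"),
        vapply(nds, `[[`, numeric(1), "pNT"),
        nds$A$kon, nds$A$koff)
    },
    mixed = c(p$k1, p$k2, p$k3, p$k4, p$k5, p$KA, p$KB, p$m, p$n,
              p$deltaA, p$deltaB, p$deltaN, p$kon, p$koff,
              p$pAT, p$pBT, p$pNT),
    stop("no compiled vector field for topology ", model$topology,
         call. = FALSE)
  )
  out <- numeric(nd_npar)
  out[seq_along(v)] <- v
  out[nd_cap_idx] <- cap
  out
}

solver_func_name <- function(topology) {
  switch(topology,
    activator_repressor = "nd_ar",
    goodwin = "nd_goodwin",
    repressilator_common = "nd_rep_common",
    repressilator_individual = "nd_rep_individual",
    mixed = "nd_mixed",
    NULL
  )
}
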