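# Linear-stability analysis: equilibria by damped Newton iteration,
# numerical Jacobians by central differences, eigenvalues for the ODE
# topologies and rightmost characteristic roots
# det(lambda I - J0 - Jtau exp(-lambda tau)) = 0 for the delay system.

num_jacobian <- function(f, x, rel_step = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- rel_step * (1 + abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Find an equilibrium of a circuit model
#'
#' Solves `rhs(x) = 0` (for the delayed Goodwin model, the system with the
#' delayed state identified with the current one, whose equilibria coincide
#' with those of the DDE) as a nonnegativity-constrained least-squares
#' problem by Levenberg-Marquardt ([minpack.lm::nls.lm]), seeded from the
#' supplied guess, the long-time end point and time average of a
#' simulation, and a ladder of constant states.
#'
#' @param model An `osc_model`.
#' @param guess Nonnegative starting state; optional.
#' @param tol Residual tolerance: accepts `x` with
#'   `max(abs(rhs(x))) < tol * (1 + max(abs(x)))`.
#' @return Equilibrium state vector (named by species).
#' @export
find_equilibrium <- function(model, guess = NULL, tol = 1e-10) {
  stopifnot(inherits(model, "osc_model"))
  f <- function(x) model_rhs(model, x, delayed = x)
  n <- length(model$species)

  seeds <- list()
  if (!is.null(guess)) {
    if (any(guess < 0)) stop("`guess` must be nonnegative", call. = FALSE)
    seeds <- c(seeds, list(as.numeric(guess)))
  }
  end_state <- tryCatch({
    h <- default_horizon(model)
    if (is.null(h)) h <- 200
    traj <- simulate_model(model, horizon = h)
    list(end = pmax(as.numeric(traj$states[nrow(traj$states), ]), 0),
         # time average: a better seed when the end point rides a limit
         # cycle around the interior equilibrium
         mean = pmax(as.numeric(colMeans(traj$states)), 0))
  }, error = function(e) NULL)
  if (!is.null(end_state)) seeds <- c(seeds, unname(end_state))
  for (s in c(0.1, 1, 10, 100)) seeds <- c(seeds, list(rep(s, n)))

  ctl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  accept <- function(x) {
    x[abs(x) < 1e-12] <- 0
    all(is.finite(x)) && all(x >= 0) &&
      max(abs(f(x))) < tol * (1 + max(abs(x)))
  }
  candidates <- list()
  best_res <- Inf
  for (s in seeds) {
    for (transform in c("linear", "log")) {
      fit <- tryCatch(
        if (transform == "linear") {
          minpack.lm::nls.lm(par = s, fn = f, lower = rep(0, n),
                             control = ctl)
        } else {
          # log-state solve: rescales the decades-spanning concentrations
          # and often escapes shallow least-squares valleys
          minpack.lm::nls.lm(par = log(pmax(s, 1e-6)),
                             fn = function(z) f(exp(z)), control = ctl)
        },
        error = function(e) NULL
      )
      if (is.null(fit)) next
      x <- as.numeric(if (transform == "log") exp(fit$par) else fit$par)
      x[abs(x) < 1e-12] <- 0
      if (accept(x)) {
        if (!any(vapply(candidates, function(c0)
          max(abs(c0 - x)) < 1e-6 * (1 + max(x)), logical(1)))) {
          candidates[[length(candidates) + 1]] <- x
        }
      } else {
        best_res <- min(best_res,
                        suppressWarnings(max(abs(f(pmax(x, 0))))))
      }
    }
  }
  if (length(candidates) == 0) {
    stop(sprintf("equilibrium search failed to converge (best residual %.3g)",
                 best_res), call. = FALSE)
  }
  # with coexisting equilibria, report the one nearest the long-run
  # trajectory (log1p metric balances the concentration decades)
  pick <- 1L
  if (!is.null(end_state) && length(candidates) > 1) {
    anchor <- (end_state$end + end_state$mean) / 2
    d <- vapply(candidates, function(x)
      sum((log1p(x) - log1p(anchor))^2), numeric(1))
    pick <- which.min(d)
  }
  x <- candidates[[pick]]
  names(x) <- model$species
  x
}

# complex determinant by LU with partial pivoting (base det() is real-only)
det_complex <- function(M) {
  n <- nrow(M)
  d <- 1 + 0i
  for (k in seq_len(n - 1)) {
    p <- which.max(Mod(M[k:n, k])) + k - 1
    if (Mod(M[p, k]) == 0) return(0 + 0i)
    if (p != k) {
      tmp <- M[k, ]; M[k, ] <- M[p, ]; M[p, ] <- tmp
      d <- -d
    }
    piv <- M[k, k]
    for (i in (k + 1):n) {
      fac <- M[i, k] / piv
      M[i, ] <- M[i, ] - fac * M[k, ]
    }
  }
  d * prod(diag(M))
}

char_fun <- function(J0, Jtau, tau) {
  n <- nrow(J0)
  I <- diag(n)
  function(lambda) {
    if (n == 1L) {
      lambda - J0[1, 1] - Jtau[1, 1] * exp(-lambda * tau)
    } else {
      det_complex(lambda * I - J0 - Jtau * exp(-lambda * tau))
    }
  }
}

#' Rightmost characteristic root of a linear delay system
#'
#' Finds roots of `det(lambda I - J0 - Jtau exp(-lambda tau)) = 0` by
#' Newton iteration from a fixed grid of complex seeds (plus the
#' eigenvalues of `J0 + Jtau`, exact at `tau = 0`) and returns the root
#' with the largest real part.  Seeds cover `Re in [-5, 2]` h^-1 and
#' `Im in [0, 4 pi / tau]`; roots come in conjugate pairs so only the upper
#' half plane is searched.
#'
#' @param J0 Jacobian with respect to the current state.
#' @param Jtau Jacobian with respect to the delayed state.
#' @param tau Delay, h (> 0).
#' @param re_range,im_range Seed ranges (defaults per above).
#' @param n_re,n_im Seed grid resolution.
#' @return Complex scalar with attribute `"roots"` (all distinct roots
#'   found) and `"residual"`.
#' @export
dde_rightmost_root <- function(J0, Jtau, tau,
                               re_range = c(-5, 2),
                               im_range = c(0, 4 * pi / tau),
                               n_re = 7, n_im = 9) {
  J0 <- as.matrix(J0); Jtau <- as.matrix(Jtau)
  stopifnot(nrow(J0) == ncol(J0), all(dim(J0) == dim(Jtau)), tau > 0)
  n <- nrow(J0)
  f <- char_fun(J0, Jtau, tau)
  scale_mag <- function(l) max(1, Mod(l))^n

  newton_root <- function(l) {
    for (it in 1:80) {
      fl <- f(l)
      if (!is.finite(Mod(fl))) return(NULL)
      h <- 1e-7 * (1 + Mod(l))
      dfl <- (f(l + h) - f(l - h)) / (2 * h)
      if (Mod(dfl) == 0) return(NULL)
      step <- fl / dfl
      # damp very large steps to stay near the seeded basin
      if (Mod(step) > 2) step <- step * (2 / Mod(step))
      l <- l - step
      if (Mod(step) < 1e-12 * (1 + Mod(l)) &&
          Mod(f(l)) < 1e-10 * scale_mag(l)) {
        return(l)
      }
    }
    if (Mod(f(l)) < 1e-10 * scale_mag(l)) l else NULL
  }

  seeds <- as.vector(outer(
    seq(re_range[1], re_range[2], length.out = n_re),
    seq(im_range[1], im_range[2], length.out = n_im),
    function(a, b) complex(real = a, imaginary = b)
  ))
  ev <- eigen(J0 + Jtau, only.values = TRUE)$values
  seeds <- c(as.complex(ev[Im(ev) >= 0]), seeds)

  roots <- complex(0)
  for (s in seeds) {
    r <- newton_root(s)
    if (!is.null(r)) {
      if (Im(r) < 0) r <- Conj(r)
      if (!any(Mod(roots - r) < 1e-6 * (1 + Mod(r)))) {
        roots <- c(roots, r)
      }
    }
  }
  if (length(roots) == 0) {
    stop("characteristic-root search found no roots", call. = FALSE)
  }
  lead <- roots[which.max(Re(roots))]
  structure(lead, roots = roots, residual = Mod(f(lead)) / scale_mag(lead))
}

#' Linear-stability report at the equilibrium
#'
#' Computes the equilibrium, the Jacobian(s) by central differences
#' (relative step 1e-6), and the leading eigenvalue (ODE topologies) or
#' rightmost characteristic root (delayed Goodwin model), then predicts
#' the dynamic class: `"oscillatory-unstable"` for a complex leading pair
#' with positive real part (the post-Hopf regime, where simulation shows a
#' limit cycle), `"non-oscillatory-unstable"` for a real positive leading
#' root, `"marginal"` when `|Re|` is within `margin` of zero, `"stable"`
#' otherwise.
#'
#' @param model An `osc_model`.
#' @param equilibrium Optional pre-computed equilibrium.
#' @param margin Half-width of the marginal band on `Re(lambda)`, h^-1.
#' @param ... Passed to [find_equilibrium()].
#' @return A `stability_report` list: `equilibrium`, `leading_root`
#'   (complex, h^-1), `class`, `method`.
#' @export
linear_stability <- function(model, equilibrium = NULL, margin = 1e-3, ...) {
  stopifnot(inherits(model, "osc_model"))
  eq <- if (is.null(equilibrium)) find_equilibrium(model, ...) else equilibrium

  if (model$delayed && model$tau > 0) {
    J0 <- num_jacobian(function(x) model_rhs(model, x, delayed = eq), eq)
    Jtau <- num_jacobian(function(z) model_rhs(model, eq, delayed = z), eq)
    lead <- dde_rightmost_root(J0, Jtau, model$tau)
    method <- "dde-characteristic-roots"
  } else {
    J <- num_jacobian(function(x) model_rhs(model, x, delayed = x), eq)
    ev <- eigen(J, only.values = TRUE)$values
    lead <- ev[which.max(Re(ev))]
    method <- "jacobian-eigenvalues"
  }
  cls <- if (abs(Re(lead)) < margin) {
    "marginal"
  } else if (Re(lead) > 0) {
    if (abs(Im(lead)) > 1e-9) "oscillatory-unstable" else
      "non-oscillatory-unstable"
  } else {
    "stable"
  }
  structure(
    list(equilibrium = eq, leading_root = as.complex(lead), class = cls,
         margin = margin, method = method),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> class=%s leading root=%.4g%+.4gi h^-1 (%s)\n",
              x$class, Re(x$leading_root), Im(x$leading_root), x$method))
  cat("  equilibrium:", paste(names(x$equilibrium),
                              signif(x$equilibrium, 5), sep = "=",
                              collapse = " "), "\n")
  invisible(x)
}
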