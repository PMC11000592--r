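#' Convert a half-life to a first-order degradation rate
#'
#' All protein stabilities in this package are specified as half-lives in
#' hours; the models consume first-order degradation rate constants
#' \eqn{\delta = \ln 2 / t_{1/2}} in h\eqn{^{-1}}.
#'
#' @param t_half Half-life in hours; must be positive.
#' @return Degradation rate constant in h^-1.
#' @examples
#' halflife_to_rate(0.9)   # a short-lived degron-tagged protein
#' rate_to_halflife(halflife_to_rate(4))
#' @export
halflife_to_rate <- function(t_half) {
  if (!is.numeric(t_half) || any(!is.finite(t_half)) || any(t_half <= 0)) {
    stop("`t_half` must be a positive, finite number (hours)", call. = FALSE)
  }
  log(2) / t_half
}

#' @rdname halflife_to_rate
#' @param rate Degradation rate constant in h^-1; must be positive.
#' @export
rate_to_halflife <- function(rate) {
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate <= 0)) {
    stop("`rate` must be a positive, finite number (h^-1)", call. = FALSE)
  }
  log(2) / rate
}

#' NanoDeg synthesis rate for a nominal steady-state concentration
#'
#' Returns the synthesis rate `kN` at which the unbound NanoDeg, in the
#' absence of its target, settles at the nominal concentration `N0`: the
#' steady state of `dN/dt = pNT * kN - deltaN * N` is `pNT * kN / deltaN`,
#' so `kN = N0 * deltaN / pNT`.
#'
#' @param N0 Nominal free NanoDeg concentration, nM (>= 0).
#' @param deltaN NanoDeg degradation rate, h^-1 (> 0).
#' @param pNT NanoDeg gene dose (default 1).
#' @return Synthesis rate in nM h^-1 per gene dose.
#' @export
nominal_nanodeg_rate <- function(N0, deltaN, pNT = 1) {
  if (!is.numeric(deltaN) || !is.finite(deltaN) || deltaN <= 0) {
    stop("`deltaN` must be positive (h^-1)", call. = FALSE)
  }
  if (!is.numeric(N0) || !is.finite(N0) || N0 < 0) {
    stop("`N0` must be nonnegative (nM)", call. = FALSE)
  }
  if (!is.numeric(pNT) || !is.finite(pNT) || pNT <= 0) {
    stop("`pNT` must be positive", call. = FALSE)
  }
  N0 * deltaN / pNT
}

chk_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("parameter `%s` must be a finite numeric scalar", name),
         call. = FALSE)
  }
  if ((strict && x <= lower) || (!strict && x < lower)) {
    stop(sprintf("parameter `%s` must be %s %g (got %g)", name,
                 if (strict) ">" else ">=", lower, x), call. = FALSE)
  }
  as.numeric(x)
}

#' NanoDeg parameters
#'
#' Kinetic parameters of one NanoDeg species: constitutive synthesis,
#' first-order degradation (shared by the free NanoDeg and the
#' NanoDeg-target complex), and mass-action binding to its target.
#'
#' @param kN Synthesis rate, nM h^-1 per gene dose (>= 0; 0 switches the
#'   NanoDeg off).
#' @param deltaN Degradation rate of free NanoDeg and complex, h^-1 (> 0).
#' @param kon Association rate constant, nM^-1 h^-1 (>= 0).
#' @param koff Dissociation rate constant, h^-1 (>= 0).
#' @param pNT Gene dose (dimensionless multiplier by default; the mixed
#'   topology reinterprets it as nM of NanoDeg-encoding DNA).
#' @return An object of class `nanodeg_params`.
#' @export
nanodeg_params <- function(kN = 0, deltaN = halflife_to_rate(0.9),
                           kon = 1, koff = 4.41, pNT = 1) {
  p <- list(
    kN = chk_num(kN, "kN", 0),
    deltaN = chk_num(deltaN, "deltaN", 0, strict = TRUE),
    kon = chk_num(kon, "kon", 0),
    koff = chk_num(koff, "koff", 0),
    pNT = chk_num(pNT, "pNT", 0)
  )
  class(p) <- c("nanodeg_params", "osc_params")
  p
}

#' Equilibrium dissociation constant of a NanoDeg
#'
#' `Kd = koff / kon`, defined only when `kon > 0` (returns `NA` otherwise).
#'
#' @param nd A [nanodeg_params()] object.
#' @export
nanodeg_kd <- function(nd) {
  stopifnot(inherits(nd, "nanodeg_params"))
  if (nd$kon > 0) nd$koff / nd$kon else NA_real_
}

#' Activator-repressor circuit parameters
#'
#' Two-node relaxation oscillator: an activator A drives its own expression
#' and that of a repressor B, which represses A; an activator-specific
#' NanoDeg sequesters and degrades A.  Synthesis of A follows a
#' multiplicative double Hill form: an activation bracket
#' `(alpha1*A^m + alpha2*KA^m)/(A^m + KA^m)` carrying the rate units
#' (nM h^-1) times a dimensionless repression bracket
#' `(beta1*B^n + beta2*KB^n)/(B^n + KB^n)`.
#'
#' @param alpha1,alpha2 Maximal self-activated / leaky synthesis
#'   coefficients of A, nM h^-1 (requires `alpha1 > alpha2 >= 0`).
#' @param beta1,beta2 Fully repressed / unrepressed repression-bracket
#'   coefficients (dimensionless; requires `beta2 > beta1 >= 0`).
#' @param KA,KB Operator dissociation constants, nM (> 0).
#' @param m,n Hill coefficients (>= 1).
#' @param k5,k6 Maximal activated / leaky synthesis rates of B, nM h^-1
#'   (requires `k5 > k6 >= 0`).
#' @param deltaA,deltaB Degradation rates, h^-1 (> 0).
#' @param pAT,pBT Gene doses.
#' @param nanodeg A [nanodeg_params()] object (activator-specific).
#' @return Object of class `ar_params`.
#' @export
ar_params <- function(alpha1, alpha2, beta1, beta2, KA, KB, m, n, k5, k6,
                      deltaA, deltaB, pAT = 1, pBT = 1,
                      nanodeg = nanodeg_params()) {
  p <- list(
    alpha1 = chk_num(alpha1, "alpha1", 0), alpha2 = chk_num(alpha2, "alpha2", 0),
    beta1 = chk_num(beta1, "beta1", 0), beta2 = chk_num(beta2, "beta2", 0),
    KA = chk_num(KA, "KA", 0, strict = TRUE),
    KB = chk_num(KB, "KB", 0, strict = TRUE),
    m = chk_num(m, "m", 1), n = chk_num(n, "n", 1),
    k5 = chk_num(k5, "k5", 0), k6 = chk_num(k6, "k6", 0),
    deltaA = chk_num(deltaA, "deltaA", 0, strict = TRUE),
    deltaB = chk_num(deltaB, "deltaB", 0, strict = TRUE),
    pAT = chk_num(pAT, "pAT", 0), pBT = chk_num(pBT, "pBT", 0),
    nanodeg = nanodeg
  )
  stopifnot(inherits(nanodeg, "nanodeg_params"))
  if (p$alpha1 <= p$alpha2) {
    stop("activator-repressor requires alpha1 > alpha2 (self-activation ",
         "stronger than leak)", call. = FALSE)
  }
  if (p$beta2 <= p$beta1) {
    stop("activator-repressor requires beta2 > beta1 (unrepressed synthesis ",
         "above the repressed floor)", call. = FALSE)
  }
  if (p$k5 <= p$k6) {
    stop("activator-repressor requires k5 > k6 for the repressor node",
         call. = FALSE)
  }
  class(p) <- c("ar_params", "osc_params")
  p
}

#' Goodwin oscillator parameters
#'
#' Single-gene delayed negative feedback: the nascent repressor A matures
#' with delay `tau`, and only the mature form `A(t - tau)` represses
#' transcription and binds the NanoDeg.
#'
#' @param beta1,beta2 Fully repressed / unrepressed synthesis rates,
#'   nM h^-1 (requires `beta2 > beta1 >= 0`).
#' @param KA Operator dissociation constant, nM.
#' @param m Hill coefficient (>= 1).
#' @param deltaA Repressor degradation rate, h^-1.
#' @param tau Maturation delay, h (>= 0).
#' @param pAT Gene dose.
#' @param nanodeg A [nanodeg_params()] object targeting the mature repressor.
#' @return Object of class `goodwin_params`.
#' @export
goodwin_params <- function(beta1, beta2, KA, m, deltaA, tau, pAT = 1,
                           nanodeg = nanodeg_params()) {
  p <- list(
    beta1 = chk_num(beta1, "beta1", 0), beta2 = chk_num(beta2, "beta2", 0),
    KA = chk_num(KA, "KA", 0, strict = TRUE),
    m = chk_num(m, "m", 1),
    deltaA = chk_num(deltaA, "deltaA", 0, strict = TRUE),
    tau = chk_num(tau, "tau", 0),
    pAT = chk_num(pAT, "pAT", 0),
    nanodeg = nanodeg
  )
  stopifnot(inherits(nanodeg, "nanodeg_params"))
  if (p$beta2 <= p$beta1) {
    stop("Goodwin model requires beta2 > beta1 (unrepressed synthesis above ",
         "the repressed floor)", call. = FALSE)
  }
  class(p) <- c("goodwin_params", "osc_params")
  p
}

#' Repressilator parameters (common or individual NanoDegs)
#'
#' Three repressors in a ring (A represses B, B represses C, C represses A
#' through the `k1/k2` bracket of node A).  Each node's synthesis follows a
#' repression Hill form whose value at zero repressor is the leaky rate
#' (`k2`, `k4`, `k6`) and whose fully repressed floor is `k1`, `k3`, `k5`;
#' each node therefore requires leak > floor.  In `mode = "common"` one
#' NanoDeg binds all three repressors competitively from a single free
#' pool; in `mode = "individual"` three NanoDegs with a shared `kon`/`koff`
#' each target one repressor.
#'
#' @param k1,k3,k5 Fully repressed synthesis floors, nM h^-1.
#' @param k2,k4,k6 Leaky (unrepressed) synthesis rates, nM h^-1; each must
#'   exceed the corresponding floor.
#' @param KA,KB,KC Operator dissociation constants, nM.
#' @param m,n,r Hill coefficients of repression by A, B and C (>= 1).
#' @param deltaA,deltaB,deltaC Repressor degradation rates, h^-1.
#' @param pAT,pBT,pCT Gene doses.
#' @param mode `"common"` or `"individual"`.
#' @param nanodeg Common mode: one [nanodeg_params()].
#' @param nanodegs Individual mode: list of three [nanodeg_params()] named
#'   `A`, `B`, `C`; their `kon`/`koff` must coincide.
#' @return Object of class `repressilator_params`.
#' @export
repressilator_params <- function(k1, k2, k3, k4, k5, k6, KA, KB, KC,
                                 m, n, r, deltaA, deltaB, deltaC,
                                 pAT = 1, pBT = 1, pCT = 1,
                                 mode = c("common", "individual"),
                                 nanodeg = nanodeg_params(),
                                 nanodegs = NULL) {
  mode <- match.arg(mode)
  p <- list(
    k1 = chk_num(k1, "k1", 0), k2 = chk_num(k2, "k2", 0),
    k3 = chk_num(k3, "k3", 0), k4 = chk_num(k4, "k4", 0),
    k5 = chk_num(k5, "k5", 0), k6 = chk_num(k6, "k6", 0),
    KA = chk_num(KA, "KA", 0, strict = TRUE),
    KB = chk_num(KB, "KB", 0, strict = TRUE),
    KC = chk_num(KC, "KC", 0, strict = TRUE),
    m = chk_num(m, "m", 1), n = chk_num(n, "n", 1), r = chk_num(r, "r", 1),
    deltaA = chk_num(deltaA, "deltaA", 0, strict = TRUE),
    deltaB = chk_num(deltaB, "deltaB", 0, strict = TRUE),
    deltaC = chk_num(deltaC, "deltaC", 0, strict = TRUE),
    pAT = chk_num(pAT, "pAT", 0), pBT = chk_num(pBT, "pBT", 0),
    pCT = chk_num(pCT, "pCT", 0),
    mode = mode
  )
  if (p$k2 <= p$k1 || p$k4 <= p$k3 || p$k6 <= p$k5) {
    stop("repressilator requires leaky rate > repressed floor at every node ",
         "(k2 > k1, k4 > k3, k6 > k5)", call. = FALSE)
  }
  if (mode == "common") {
    stopifnot(inherits(nanodeg, "nanodeg_params"))
    p$nanodeg <- nanodeg
  } else {
    if (is.null(nanodegs) || !is.list(nanodegs) ||
        !all(c("A", "B", "C") %in% names(nanodegs)) ||
        !all(vapply(nanodegs[c("A", "B", "C")],
                    inherits, logical(1), "nanodeg_params"))) {
      stop("individual mode needs `nanodegs`, a named list of three ",
           "nanodeg_params (A, B, C)", call. = FALSE)
    }
    nanodegs <- nanodegs[c("A", "B", "C")]
    kons <- vapply(nanodegs, `[[`, numeric(1), "kon")
    koffs <- vapply(nanodegs, `[[`, numeric(1), "koff")
    if (diff(range(kons)) > 0 || diff(range(koffs)) > 0) {
      stop("individual-mode NanoDegs share a single kon and koff",
           call. = FALSE)
    }
    p$nanodegs <- nanodegs
  }
  class(p) <- c("repressilator_params", "osc_params")
  p
}

#' Mixed-mode NanoDeg repressilator parameters
#'
#' Ring of two transcriptional repressors and a NanoDeg: constitutively
#' expressed Repressor A represses Repressor B, B represses the NanoDeg,
#' and the NanoDeg closes the loop post-translationally by binding and
#' degrading A.
#'
#' @param k1 Constitutive synthesis rate of A, nM h^-1 per gene dose.
#' @param k2,k3 Repressed floor / leaky synthesis of B, nM h^-1 (requires
#'   `k3 > k2`).
#' @param k4,k5 Repressed floor / leaky synthesis of the NanoDeg, nM h^-1
#'   per unit `pNT` (requires `k5 > k4`).  With `pNT` read as nM of
#'   NanoDeg-encoding DNA these are per-nM-DNA rates.
#' @param KA,KB Operator dissociation constants, nM.
#' @param m,n Hill coefficients of repression by A and by B (>= 1).
#' @param deltaA,deltaB,deltaN Degradation rates, h^-1 (`deltaN` applies to
#'   free NanoDeg and complex).
#' @param kon,koff NanoDeg-A binding rate constants, nM^-1 h^-1 and h^-1.
#' @param pAT,pBT,pNT Gene doses; `pNT` is the NanoDeg DNA dose (nM).
#' @return Object of class `mixed_params`.
#' @export
mixed_params <- function(k1, k2, k3, k4, k5, KA, KB, m, n,
                         deltaA, deltaB, deltaN, kon, koff,
                         pAT = 1, pBT = 1, pNT = 1) {
  p <- list(
    k1 = chk_num(k1, "k1", 0), k2 = chk_num(k2, "k2", 0),
    k3 = chk_num(k3, "k3", 0), k4 = chk_num(k4, "k4", 0),
    k5 = chk_num(k5, "k5", 0),
    KA = chk_num(KA, "KA", 0, strict = TRUE),
    KB = chk_num(KB, "KB", 0, strict = TRUE),
    m = chk_num(m, "m", 1), n = chk_num(n, "n", 1),
    deltaA = chk_num(deltaA, "deltaA", 0, strict = TRUE),
    deltaB = chk_num(deltaB, "deltaB", 0, strict = TRUE),
    deltaN = chk_num(deltaN, "deltaN", 0, strict = TRUE),
    kon = chk_num(kon, "kon", 0), koff = chk_num(koff, "koff", 0),
    pAT = chk_num(pAT, "pAT", 0), pBT = chk_num(pBT, "pBT", 0),
    pNT = chk_num(pNT, "pNT", 0)
  )
  if (p$k3 <= p$k2) {
    stop("mixed repressilator requires k3 > k2 (leaky expression of B above ",
         "its repressed floor)", call. = FALSE)
  }
  if (p$k5 <= p$k4) {
    stop("mixed repressilator requires k5 > k4 (leaky expression of the ",
         "NanoDeg above its repressed floor)", call. = FALSE)
  }
  class(p) <- c("mixed_params", "osc_params")
  p
}

#' @export
print.osc_params <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  flat <- unlist(x[!vapply(x, is.list, logical(1))])
  for (nm in names(flat)) cat(sprintf("  %-8s %s\n", nm, format(flat[[nm]])))
  if (!is.null(x$nanodeg)) {
    nd <- unlist(x$nanodeg)
    cat("  nanodeg:", paste(names(nd), signif(as.numeric(nd), 6),
                            sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$nanodegs)) {
    for (nm in names(x$nanodegs)) {
      nd <- unlist(x$nanodegs[[nm]])
      cat("  nanodeg", nm, ": ",
          paste(names(nd), signif(as.numeric(nd), 6), sep = "=",
                collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}
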