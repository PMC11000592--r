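# Symbol resolution for parameter sweeps.  Each topology exposes its raw
# parameters plus derived symbols: half-lives (t_half_*), the NanoDeg
# dissociation constant Kd (moved by changing kon at fixed koff, the
# convention used for affinity sweeps), the joint kon/koff scaling factor v
# (Kd-preserving), the nominal NanoDeg concentration N0, and the DNA dose of
# the mixed topology.  Setters always act on the parameter set they are
# given, so sweeps that apply a relative symbol (v) to a base model are
# well-defined: the sweep re-derives from the base at every grid value.

set_in_nanodeg <- function(field) {
  function(p, value) { p$nanodeg[[field]] <- value; p }
}

set_in_all_nanodegs <- function(field) {
  function(p, value) {
    for (nm in names(p$nanodegs)) p$nanodegs[[nm]][[field]] <- value
    p
  }
}

set_plain <- function(field) {
  function(p, value) { p[[field]] <- value; p }
}

nanodeg_symbols <- function() {
  list(
    kN = set_in_nanodeg("kN"),
    deltaN = set_in_nanodeg("deltaN"),
    kon = set_in_nanodeg("kon"),
    koff = set_in_nanodeg("koff"),
    pNT = set_in_nanodeg("pNT"),
    t_half_N = function(p, value) {
      p$nanodeg$deltaN <- halflife_to_rate(value); p
    },
    Kd = function(p, value) {
      if (value <= 0) stop("Kd must be positive", call. = FALSE)
      p$nanodeg$kon <- p$nanodeg$koff / value; p
    },
    v = function(p, value) {
      if (value <= 0) stop("scaling factor v must be positive", call. = FALSE)
      p$nanodeg$kon <- value * p$nanodeg$kon
      p$nanodeg$koff <- value * p$nanodeg$koff
      p
    },
    N0 = function(p, value) {
      p$nanodeg$kN <- nominal_nanodeg_rate(value, p$nanodeg$deltaN,
                                           p$nanodeg$pNT)
      p
    }
  )
}

symbol_table <- function(topology) {
  plain <- function(fields) {
    out <- lapply(fields, set_plain)
    names(out) <- fields
    out
  }
  half <- function(symbol, field) {
    s <- list(function(p, value) { p[[field]] <- halflife_to_rate(value); p })
    names(s) <- symbol
    s
  }
  switch(topology,
    activator_repressor = c(
      plain(c("alpha1", "alpha2", "beta1", "beta2", "KA", "KB", "m", "n",
              "k5", "k6", "deltaA", "deltaB", "pAT", "pBT")),
      half("t_half_A", "deltaA"), half("t_half_B", "deltaB"),
      nanodeg_symbols()
    ),
    goodwin = c(
      plain(c("beta1", "beta2", "KA", "m", "deltaA", "tau", "pAT")),
      half("t_half_A", "deltaA"), half("t_half_R", "deltaA"),
      nanodeg_symbols()
    ),
    repressilator_common = c(
      plain(c("k1", "k2", "k3", "k4", "k5", "k6", "KA", "KB", "KC",
              "m", "n", "r", "deltaA", "deltaB", "deltaC",
              "pAT", "pBT", "pCT")),
      nanodeg_symbols()
    ),
    repressilator_individual = c(
      plain(c("k1", "k2", "k3", "k4", "k5", "k6", "KA", "KB", "KC",
              "m", "n", "r", "deltaA", "deltaB", "deltaC",
              "pAT", "pBT", "pCT")),
      list(
        kN = set_in_all_nanodegs("kN"),
        kNA = function(p, value) { p$nanodegs$A$kN <- value; p },
        kNB = function(p, value) { p$nanodegs$B$kN <- value; p },
        kNC = function(p, value) { p$nanodegs$C$kN <- value; p },
        deltaN = set_in_all_nanodegs("deltaN"),
        t_half_N = function(p, value) {
          d <- halflife_to_rate(value)
          for (nm in names(p$nanodegs)) p$nanodegs[[nm]]$deltaN <- d
          p
        },
        kon = set_in_all_nanodegs("kon"),
        koff = set_in_all_nanodegs("koff"),
        v = function(p, value) {
          if (value <= 0) stop("scaling factor v must be positive",
                               call. = FALSE)
          for (nm in names(p$nanodegs)) {
            p$nanodegs[[nm]]$kon <- value * p$nanodegs[[nm]]$kon
            p$nanodegs[[nm]]$koff <- value * p$nanodegs[[nm]]$koff
          }
          p
        }
      )
    ),
    mixed = c(
      plain(c("k1", "k2", "k3", "k4", "k5", "KA", "KB", "m", "n",
              "deltaA", "deltaB", "deltaN", "kon", "koff",
              "pAT", "pBT", "pNT")),
      half("t_half_A", "deltaA"), half("t_half_B", "deltaB"),
      half("t_half_N", "deltaN"),
      list(
        dna_dose = set_plain("pNT"),
        Kd = function(p, value) {
          if (value <= 0) stop("Kd must be positive", call. = FALSE)
          p$kon <- p$koff / value; p
        },
        v = function(p, value) {
          if (value <= 0) stop("scaling factor v must be positive",
                               call. = FALSE)
          p$kon <- value * p$kon; p$koff <- value * p$koff; p
        }
      )
    ),
    stop("no symbol table for topology ", topology, call. = FALSE)
  )
}

#' Sweepable parameter symbols of a model
#'
#' @param model An [model_instance()].
#' @return Character vector of symbols accepted by [set_param()].
#' @export
param_symbols <- function(model) {
  stopifnot(inherits(model, "osc_model"))
  names(symbol_table(model$topology))
}

#' Set a (possibly derived) parameter symbol on a model
#'
#' Raw parameters are set directly; derived symbols are translated
#' (`t_half_*` to degradation rates via [halflife_to_rate()], `Kd` to `kon`
#' at fixed `koff`, `v` to a joint Kd-preserving scaling of `kon` and
#' `koff`, `N0` to the synthesis rate giving that nominal free-NanoDeg
#' steady state, `dna_dose` to the mixed model's `pNT`).
#'
#' @param model An [model_instance()].
#' @param symbol Symbol name (see [param_symbols()]).
#' @param value New value in the symbol's own units.
#' @return A new model instance (the input is not modified).
#' @export
set_param <- function(model, symbol, value) {
  stopifnot(inherits(model, "osc_model"))
  tab <- symbol_table(model$topology)
  if (!symbol %in% names(tab)) {
    stop(sprintf("unknown symbol `%s` for topology %s; valid symbols: %s",
                 symbol, model$topology,
                 paste(names(tab), collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("`value` must be a finite numeric scalar", call. = FALSE)
  }
  p <- tab[[symbol]](model$params, as.numeric(value))
  # re-validate through the constructor so invariants cannot be broken
  rebuilt <- switch(model$topology,
    activator_repressor = do.call(ar_params, unclass(p)),
    goodwin = do.call(goodwin_params, unclass(p)),
    repressilator_common = ,
    repressilator_individual = do.call(repressilator_params, unclass(p)),
    mixed = do.call(mixed_params, unclass(p))
  )
  model_instance(rebuilt)
}
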