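---
title: "Designing genetic oscillators by NanoDeg-mediated protein degradation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing genetic oscillators by NanoDeg-mediated protein degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodegosc)
```

## The modelling problem

A NanoDeg is a bifunctional molecule — a target-specific nanobody fused to a
degron — that binds a chosen cellular protein and routes the complex to
proteasomal degradation. Because the degron sets the degradation rate and the
nanobody sets the target, a NanoDeg gives post-translational control over one
kinetic parameter of a gene circuit, the target's effective half-life, without
re-engineering the target itself.

This package asks the design question quantitatively: for circuits that are
*almost* oscillators, when does adding a NanoDeg create, destroy or retune a
limit cycle? Five deterministic reduced models are implemented:

1. **Activator–repressor** (`activator_repressor`): a self-activating
   activator A drives a repressor B that represses A; an activator-specific
   NanoDeg N binds A into a complex C. Oscillation requires timescale
   separation — the activator must be degraded faster than the repressor —
   which the NanoDeg supplies post-translationally.
2. **Goodwin oscillator** (`goodwin`): a single repressor whose mature form
   `A(t - tau)` (maturation delay `tau`) represses its own gene; a delay
   differential equation. The NanoDeg binds the mature repressor.
3. **Repressilator with a common NanoDeg** (`repressilator_common`): a ring
   A ⊣ B ⊣ C ⊣ A whose three nodes are all bound by one NanoDeg from a single
   competitive free pool.
4. **Repressilator with individual NanoDegs** (`repressilator_individual`):
   the same ring with three node-specific NanoDegs sharing `kon`/`koff`.
5. **Mixed-mode repressilator** (`mixed`): a ring of two transcriptional
   repressors and the NanoDeg itself as the third node, closing the loop
   post-translationally.

All species are concentrations in nM, time is in hours, binding follows
mass action (`kon` in nM⁻¹h⁻¹, `koff` in h⁻¹), and every gene-expression
input is the Hill form `(lo·xʰ + hi·Kʰ)/(xʰ + Kʰ)` — `hi` at zero input,
`lo` at saturation ([hill_response()]). Two modelling assumptions apply
throughout: the NanoDeg–target complex cannot bind the target's operator,
and the complex is degraded at the NanoDeg's (not the target's) rate. The
degron repertoire is summarized by half-lives; `halflife_to_rate()` converts
`t½` to `δ = ln 2 / t½`, and `nominal_nanodeg_rate()` returns the synthesis
rate whose free-NanoDeg steady state (no target) equals a nominal
concentration `N0`, i.e. `kN = N0·δN/pNT` — the dimensionally consistent
reading of the nominal-expression convention.

Two sign/subscript inconsistencies in the printed ring equations are
corrected to standard mass-action form: complex balances read
`dT/dt = +kon·(target)·(NanoDeg) − koff·T − δN·T`, and in the
individual-NanoDeg ring the B- and C-NanoDegs bind B and C (not A).
Constructor invariants enforce the repression reading of every Hill pair:
the unrepressed ("leaky") rate must exceed the fully repressed floor.

## Integration

Right-hand sides are compiled (C, `src/models.c`) and integrated with
deSolve: `lsodar` for the ODE topologies — adaptive, stiff-capable, with a
root function that terminates integration when any state reaches the
unboundedness sentinel (10⁹ nM, `bounded = FALSE`) — and `dede` for the
delay model, whose history interpolation realizes the method of steps. The
exported R vector fields (`ar_rhs()` and friends) are the readable reference
implementation; a test holds compiled and R versions equal on random states.
Tolerances default to `rtol = 1e-6`, `atol = 1e-9` nM; reference results are
tolerance-robust (halving the tolerances moves amplitude and period by
< 0.1 %). Output is always evaluated on the fixed 0.01 h reporting grid,
constructed by index so repeated runs are bit-identical; the dense sampling
exists to keep the crossing-based period estimator accurate.

Initial conditions default to 0 nM for every species — matching the delay
model's stated history `A(t) = 0` on `[-tau, 0]` — with one deliberate
exception: the two repressilator rings start their repressors staggered at
(10, 1, 0.1) nM. A symmetric start of an identical-node ring lies on the
symmetric invariant manifold, on which the exact dynamics (and any faithful
integrator) can never break into oscillation; the stagger emulates
sequential induction of the three genes. Concentrations entering Hill and
binding terms are clamped at zero inside the RHS so that sub-tolerance
negative excursions cannot act as sources.

One genuine model caveat: in the delay system the mature repressor
`A(t - tau)` drives binding, so the removal flux on nascent A does not
vanish as A → 0 and the state can transiently go negative at very high
NanoDeg synthesis rates. This is a property of the printed equations, not of
the solver; the reference operating points sit where trajectories remain
nonnegative (asserted by test), and the behaviour is visible only far above
the calibrated oscillation windows.

## Amplitude, period and classification

Features are measured over an *analysis region*, by default the final 50 %
of the horizon — long after transients at these circuits' hour-scale
kinetics have died — and configurable via `fraction`:

* **amplitude** — max − min of the reported species over the region;
* **period** — the signal is zero-meaned over the region, zero crossings
  are located by sign change with linear interpolation between grid points,
  and the mean interval between alternating (same-direction, i.e. every
  second) crossings is the full period. Opposite-direction intervals are
  half-periods and would double the frequency; the interpolation step makes
  the estimator accurate to well under the 0.01 h grid.
* **classification** — `unbounded` if the sentinel was hit; `sustained` if
  the region holds ≥ 5 full cycles whose per-cycle peak-to-trough envelope
  changes < 1 % between first and last cycle; `damped` for a decaying
  oscillation of ≥ 3 cycles (in the region or the transient); `stable`
  otherwise. The 1 % envelope tolerance and 5-cycle minimum are robust
  choices: 0.5–2 % gives identical classifications on all reference
  scenarios. Signals whose range is below 10³·atol are treated as constant.

`simulate_features()` adds one pragmatic layer: when the envelope is still
drifting at the end of the horizon, or an oscillation is visible but too few
cycles fit in the region, the horizon is doubled (at most twice). Slow
limit-cycle convergence just inside a Hopf bifurcation otherwise
misclassifies as stable/damped; classification is in all other respects
invariant to horizon extension, and the default horizon is 500 h for every
topology.

## Sweeps, windows and the stability oracle

`sweep_param()` re-derives the model from the base instance at every grid
value, so derived symbols are well-defined: `t_half_*` sets the
corresponding rate, `Kd` moves `kon` at fixed `koff`, `v` scales `kon` and
`koff` jointly (affinity-preserving), `dna_dose` sets the mixed model's
NanoDeg gene dose `pNT` (in nM of DNA, with its synthesis rates per nM).
`oscillation_window()` finds sustained-oscillation windows from a 32-point
coarse grid (log-spaced for rates) and refines every edge by bisection on
the classifier; all maximal windows are returned, not just the first.
`critical_parameter()` bisects any class boundary to a requested tolerance
(default 0.005 in the symbol's units); `scan_2d()` maps Hill-coefficient
pairs and refines the minimal coefficient per axis with the partner at its
reference value (10).

The independent check on all of this is `linear_stability()`: the
equilibrium (Levenberg–Marquardt with nonnegativity bounds, multi-seeded
from the trajectory end point, its time average and a ladder of constants,
in both linear and log state space; with coexisting equilibria the one
nearest the long-run trajectory is reported), the Jacobian by central
differences (relative step 10⁻⁶), and either its eigenvalues (ODE models)
or the rightmost root of the delay characteristic equation
`det(λI − J₀ − J_τ e^{−λτ}) = 0`, found by damped Newton iteration from a
fixed grid of complex seeds plus the eigenvalues of `J₀ + J_τ` (exact at
`τ = 0`). Roots come in conjugate pairs, so only the upper half plane is
seeded. A leading root with `|Re λ| < 10⁻³ h⁻¹` is reported `marginal`:
within that band transients are arbitrarily long and simulation and linear
prediction cannot be compared at finite horizons.

The concordance experiment (in the test suite and the acceptance script)
draws parameters log-uniformly around each reference set and compares the
oracle's verdict with simulated classification. The trajectory is launched
from a small perturbation of the analyzed equilibrium — the local object
the eigenvalues describe. This matters: several of these circuits are
multistable in parts of parameter space (a stable low-activator state
coexisting with a limit cycle, for instance), and a distant initial
condition reports the basin it happens to fall into rather than the local
stability the oracle predicts. With equilibrium-local starts, agreement is
≥ 95 % per topology with every disagreement confined to the marginal band.

## Calibrated reference parameter sets

This package does not bundle any externally published parameter table, so
`reference_params()` provides calibrated synthetic stand-ins (also bundled as
`inst/params/reference_*.yaml`, alongside `sd1_*.yaml` transcription
templates with every symbol slot for users who have the published values).
Calibration targeted the qualitative regime structure of each circuit, not
specific printed numbers; quantities like window edges therefore
carry no claim of matching any externally published values. The calibrated sets
realize, at the documented scenario settings:

* **activator–repressor** — stable at equal 4 h half-lives; Hopf threshold
  for the activator half-life near 0.9 h (0.88 h oscillates, 1 h does not);
  an activator half-life of 0.9 h alone does *not* oscillate while a NanoDeg
  of the same half-life does (sequestration, not just faster decay); a
  NanoDeg synthesis window of roughly 7.4–14.6 nM h⁻¹; amplitude and period
  increasing with NanoDeg half-life across its sustained window; window
  shrinking sharply as Kd decreases. With the calibrated binding rates the
  tightest published affinity (Kd = 0.441 nM) extinguishes the window
  entirely rather than leaving a tenth-width window — the one documented
  divergence in the otherwise-realized trend set.
* **Goodwin** — stable at `tau = 0.5 h`, damped at 10 h, sustained at 15 h
  (delay Hopf near 13.7 h); damped at a repressor half-life of 0.67 h and
  unstable below ≈ 0.45 h; NanoDeg-induced sustained oscillation at
  `tau = 0.5 h` from `kN ≈ 8 nM h⁻¹`, with amplitude increasing throughout
  and period increasing above the onset region.
* **common-NanoDeg repressilator** — the 1.7 % leak floor (4 against
  240 nM h⁻¹) keeps the ring stable; `kN = 6.5` and 13 give damped,
  ≥ 23.1 sustained oscillation inside a window of roughly 16.5–73 nM h⁻¹;
  amplitude grows several-fold across the window while the period varies by
  < 50 %; with identical nodes the free NanoDeg oscillates at three times
  each repressor's frequency and B, C are period/3-shifted copies of A.
* **individual-NanoDeg repressilator** — onset near `kN ≈ 2.5 nM h⁻¹`,
  amplitude peaking shortly after onset and then declining, period
  monotonically decreasing with `kN` above the peak.
* **mixed-mode** — two 11 h repressors in series are stable; the 0.9 h
  NanoDeg third node oscillates across a DNA-dose window of roughly
  5.5–480 nM with amplitude maximal at an intermediate dose; a NanoDeg
  half-life window with an interior optimum; minimal Hill coefficients near
  m ≈ 6.2 (with n = 10) and n ≈ 7.1 (with m = 10) — the ring tolerates a
  less sensitive first repressor than second, the documented
  qualitative asymmetry of this design.

## What the synthetic data do and do not show

The fixture generator emits the reference parameter files, the transcription
templates, and synthetic signals (sinusoid, damped sinusoid, constant,
exponentials) with known ground truth for the metric extractors. Passing
tests demonstrate that the integrators meet closed-form and brute-force
oracles, that the extractors are exact on constructed signals, and that the
calibrated circuits reproduce the qualitative design rules. They do not
validate the reduced models against experimental kinetics: all five models
are deterministic, ignore transcription/translation intermediates collapsed
by the underlying model reduction, use a single global binding affinity per
NanoDeg, and contain no cell-to-cell variability or molecular noise.
Quantitative window edges depend on the calibrated stand-in parameters and
should be recomputed after transcribing a real parameter set into the
bundled templates.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes every headline
quantity (windows, critical values, Hill thresholds, the NanoDeg frequency
ratio, the concordance rate) from scratch against the installed package;
problem sizes are the defaults above (32-point coarse grids, 500 h horizons
with adaptive doubling, 25 concordance draws per sampled topology). The
scenario presets in `scenarios()` cover every documented numeric condition
and write byte-reproducible artifacts via `run_scenario()`.
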