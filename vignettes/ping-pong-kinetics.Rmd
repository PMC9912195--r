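---
title: "Ping-pong kinetics of flavin nitroreductases: models, fitting and simulation"
author: "NTRkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ping-pong kinetics of flavin nitroreductases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NTRkinetics)
```

# The system and the models

Flavin-dependent nitroreductases of the NfsA/NfsB family are homodimeric
FMN enzymes that reduce nitroaromatic antibiotics and prodrugs. Catalysis
is a substituted-enzyme (ping-pong bi-bi) cycle with two half-reactions:

1. **Reductive half.** NAD(P)H (substrate A) binds the oxidized enzyme and
   transfers a hydride to FMN; NAD(P)⁺ (product P1) leaves.
2. **Oxidative half.** The electron acceptor (substrate B — nitrofurazone,
   CB1954, menadione, a quinone) binds the reduced enzyme and is reduced to
   product P2, restoring oxidized FMN.

Because the first product leaves before the second substrate binds, the
steady-state rate law has the classic ping-pong denominator without an
`KmA·KmB` constant term. With a dead-end inhibitor I (here NADP⁺, which can
bind both the oxidized and the reduced enzyme), the package's central
steady-state model is

$$
\frac{v}{E} \;=\;
\frac{k_{cat}\,A\,B}
     {K_{mA}\,B\,(1 + I/K_{iA}) \;+\; K_{mB}\,A\,(1 + I/K_{iB}) \;+\; A\,B}.
$$

Each Ki scales one denominator term, i.e. inhibits one half of the
reaction. The four nested variants are encoded by finiteness of the Ki's
(`Inf` = no inhibition in that half, an exact sentinel rather than a large
number, so the reduced models carry no conditioning artifacts):

| tag                | finite Ki's | free parameters |
|--------------------|-------------|-----------------|
| `none`             | —           | 3               |
| `competitive_vs_A` | KiA         | 4               |
| `competitive_vs_B` | KiB         | 4               |
| `mixed`            | KiA, KiB    | 5               |

For the pre-steady state, a stopped-flow push under substrate excess decays
as a single exponential whose rate constant follows the binding hyperbola

$$ k_{obs} = \frac{k\,S}{K_d + S}, $$

with $k$ the limiting rate of the chemical step and $k/K_d$ the
second-order rate constant that governs the reaction at low substrate.

**Which Ki belongs to which enzyme form?** In the King–Altman algebra of
the scheme, a dead-end complex of the inhibitor with the *oxidized* enzyme
inflates the $K_{mA} B$ term, and with the *reduced* enzyme the $K_{mB} A$
term. The package follows that algebra: `deriveMacroscopic()` maps
$K_{iA} = k_{off,I}^{ox}/k_{on,I}^{ox}$ and
$K_{iB} = k_{off,I}^{red}/k_{on,I}^{red}$. At the level of the macroscopic
fit the assignment is a pure relabelling: swapping the two Ki columns swaps
the estimates, nothing else, so the fitted numbers are unaffected by this
convention.

# Units and parameter conventions

Fixed package-wide, matching how such constants are reported:
concentrations in µM, first-order rate constants in s⁻¹, second-order
constants (kon, k/Kd, kcat/Km) in µM⁻¹·s⁻¹, absorbance in AU, path length
in cm, time in s. No unit conversion happens anywhere inside the package.

# The mechanism simulator

`MechanismScheme` holds 14 microscopic mass-action constants for the
monomer cycle (donor binding/release, hydride transfer `kRed`, NADP⁺
release/rebinding, acceptor binding/release, reoxidation `kOx`, product
release/rebinding, and dead-end inhibitor binding to both free enzyme
forms). Both chemical steps are irreversible — nitro reduction is
effectively one-way — which keeps the King–Altman forms simple.

The experiments behind this package constrain only *macroscopic* constants;
microscopic ones are constructions. `rapidEquilibriumScheme()` therefore
builds a reference parameterization that reproduces the printed macroscopic
values: chemistry at the stopped-flow limiting rates (`kRed` = 440 s⁻¹,
`kOx` = 330 s⁻¹), donor binding with Kd = 100 µM and acceptor binding with
Kd = 660 µM, inhibitor Kd's 249 µM (oxidized) and 147 µM (reduced),
substrate off-rates 100× the adjacent chemical step and product release
1000× the fastest chemical step. The release factor matters: the full-cycle
turnover obeys $1/k_{cat} = 1/k_{red} + 1/k_{ox} + 1/k_{off,P1} +
1/k_{off,P2}$, so release at only 100× chemistry would already depress kcat
by ~1 % and consume the whole oracle tolerance.

With fast release the macroscopic constants follow the lumped closed forms

$$ k_{cat} = \frac{k_{red}k_{ox}}{k_{red}+k_{ox}},\qquad
   K_{mA} = \frac{k_{ox}}{k_{red}+k_{ox}}\cdot
            \frac{k_{off,A}+k_{red}}{k_{on,A}}, $$

(and symmetrically for $K_{mB}$). `deriveMacroscopic()` flags schemes
outside the fast-release regime instead of silently returning biased
constants.

## Numerical integration

No ODE solver package is available in the target environment, so the
integrator is part of the package: an adaptive embedded Cash–Karp 4(5)
Runge–Kutta over a sparse mass-action network, written in C++. Two
properties matter for the science:

* **Conservation.** Total enzyme, nicotinamide (A + P1, free + bound),
  acceptor (B + P2) and inhibitor pools are *linear* invariants, which
  explicit Runge–Kutta steps preserve exactly (to rounding); the solver
  also lands exactly on every requested output time, so reported states
  inherit this. Observed drifts are at the 1e-13 µM level, far inside the
  10·tolerance contract.
* **Stiffness.** The schemes used here spread rate constants over at most
  ~10³, mild enough for an explicit method with step-size control; the
  integrator aborts with a diagnostic rather than returning garbage if a
  pathological scheme exhausts its step budget. Default relative tolerance
  is 1e-8.

## Initial rates from the ODE (the oracle)

`numericalInitialRate()` measures what an experimentalist calls the initial
rate: simulate from free enzyme plus substrates, wait out the
pre-steady-state burst (10 effective chemical turnover times, where the
effective rate accounts for fractional saturation at the given
concentrations), then take the slope of P2 formation per enzyme over the
earliest window in which the instantaneous rate is constant to within 2 %,
always stopping before 5 % depletion of the limiting substrate. Two
numerical choices keep the bias below ~0.2 %:

* default enzyme concentration `E0 = 1e-4 · min(A0, B0)` — substrate
  consumed while waiting out the burst is ~10·E0, so a larger default
  measurably lowers the rate relative to the nominal concentrations;
* the measurement window is capped well before the 5 % depletion bound and
  the *shortest* qualifying window is preferred, because depletion across
  the window biases the average slope low.

Against `deriveMacroscopic()` constants, the worst disagreement with the
closed-form rate law over a 6×6×3 grid spanning 0.1–10× each Km and
inhibitor up to 2×Ki is below 0.1 % (the acceptance suite enforces 1 %).

# The half-of-sites dimer

Structures of this family show asymmetric dimers with a nicotinamide
cofactor in only one site, suggesting negative cooperativity
(half-of-sites / alternating-sites reactivity). The package encodes the
minimal kinetic version: two copies of the monomer cycle, with the donor
on-rate at one site multiplied by a coupling factor α ∈ (0, 1] while the
partner site holds a nicotinamide ligand (A-, P1- or I-bound; the
inhibitor is itself a nicotinamide). α = 1 recovers independent sites;
α → 0 enforces strict one-cofactor-per-dimer behaviour. Applying the
penalty to the on-rate is one concrete choice among several the structural
data leave open; `couple = "off"` instead accelerates release from the
doubly occupied dimer (same equilibrium, different kinetics). Detailed
balance holds in the binding sub-network either way.

For binding only, the grand partition function per dimer is
$1 + 2x + \alpha x^2$ with $x = L/K_d$, giving mean occupancy
$(2x + 2\alpha x^2)/(1 + 2x + \alpha x^2)$ — saturating at 2 sites for
α = 1 and 1 site for α → 0. The ODE dimer (64 enzyme states built
programmatically) relaxes to exactly this value, which is the package's
cross-check that the generated network is right. A stronger site-coupling
(smaller α) monotonically lowers turnover per dimer; the ligand-assisted
product-release variant suggested by the alternating-sites idea (binding at
site 1 ejecting product at site 2) is deliberately *not* implemented — it
is a hypothesis, not a measured mechanism.

# Fitting and inference

All fits minimize unweighted (homoscedastic) residual sums of squares,
matching the equal-weighting convention of the assays. Parameters are
strictly positive, so optimization runs in log-parameter space
(`nlminb`/PORT; positivity by construction, no active bounds in well-posed
problems) from a multistart grid: data-scale heuristics (kcat ~ max rate,
Km ~ median concentration, Ki ~ median inhibitor level) scaled by five
log-spaced factors over 1e-2–1e2; best RSS wins, ties go to the first
start. The kobs hyperbola uses its own grid (k₀ = max(kobs)·{1, 2, 5},
Kd₀ = median(S)·{0.3, 1, 3}, ties to the smallest Kd). The exponential fit
profiles out its conditionally linear parameters (offset, amplitude) and
optimizes only log kobs, which makes it effectively global.

Inference is Wald: SE from $s^2 (J^\top J)^{-1}$ with
$s^2 = RSS/(n - p)$ and a central-difference Jacobian on the natural
scale; t statistics and two-sided P values on $n - p$ degrees of freedom
test the null that a parameter is zero (the convention behind "P" columns
in kinetics tables; the reported P values assume that null).

Corner cases are flagged, never silently repaired:

* `exact_fit` — RSS at or below the numerical resolution of the response
  scale ($n \cdot (10^{-10}\,\mathrm{scale})^2$). Below that floor RSS
  ratios are rounding noise, so AIC/AICc are reported as −Inf and model
  comparison falls through to the parsimony tie-break.
* `unidentifiable: ...` — Jacobian columns that are numerically zero
  (e.g. Ki's when no series contains inhibitor); their SEs are NA.
* `ill-conditioned` — scaled-Jacobian condition number above 1e8.
* `degenerate` — an estimate pinned to the multistart search boundary
  (flat titrations driving Km or Kd to zero).
* `extrapolated` — fitted Km beyond 10× the assayed range, or fitted Kd
  above max(S) (the CB1954/menadione situation, where the plateau is never
  observed and k, Kd carry large correlated errors while k/Kd stays
  well-determined).

## Model selection

`akaike()` uses the Gaussian RSS form with the residual variance counted as
a parameter: $AIC = n\ln(RSS/n) + 2K$, $K = p + 1$, plus the small-sample
correction for AICc (the default criterion — with ~48 points and up to 6
K it is not innocuous). `compareModels()` selects the minimum AICc, except
that a model with fewer parameters within 2 AICc units of the best is
preferred: nested models that tie provide no evidence for the extra
parameter. Published AIC values from other software are not directly
comparable — different tools drop different additive constants — which is
why the package's guarantee is about *selection behaviour* (the generating
model wins on data simulated from it) rather than about reproducing any
particular printed AIC number.

# Transient analysis choices

* The exponential model always includes a fitted offset; real end-point
  absorbances are never exactly zero.
* Samples earlier than the instrument dead time are discarded, not
  back-extrapolated (default dead time 0 for synthetic traces;
  constructors accept the instrument's value, typically ~1.5 ms).
* A configurable `kobsCeiling` flags rate constants beyond an instrument's
  reliable range (~150 s⁻¹ for a photodiode-array setup with a long dead
  time); the value is flagged, never corrected.
* Single exponentials only by default, matching how such traces are
  analysed; a flat trace (amplitude < 3× the noise SD estimated from
  first differences) is an error, not a kobs of zero.
* `fitKobsHyperbola()` propagates the SE of k/Kd from the full parameter
  covariance (delta method), since k/Kd is usually better determined than
  either factor.

# The synthetic-data generators

`defaultInhibitionDesign()` encodes the two-sided inhibition experiment: the
acceptor varied at 100 µM donor and the donor varied at 99 µM acceptor,
with inhibitor at 0, 250 and 500 µM. The exact inhibitor concentrations of
the original bench experiment are not recorded ("two concentrations of
inhibitor"); 250 and 500 µM — bracketing the Ki's — are the package's
stand-in, fixed once. Grids are 8-point two-fold serial dilutions from
10× Km (spanning ~0.08–10× Km), the common bench practice when a titration
must constrain both kcat and Km. Noise is i.i.d. Gaussian on rates
(homoscedastic, consistent with unweighted fitting); 5 % of kcat is the
"realistic" level, chosen so simulated standard errors match the size of
typical reported ± values. Every generator is a pure function of
(parameters, design, seed): the session RNG is never touched, and a seed is
mandatory whenever noise is requested.

What the generators deliberately do **not** emulate: mixing artifacts,
photobleaching, baseline drift, proportional (heteroscedastic) noise
(available as an option nowhere — rates are homoscedastic by design),
instrument response. A green round-trip test therefore establishes that the
estimators are correct and calibrated for the stated noise model, not that
they are robust to every instrumental pathology.

```{r roundtrip}
kp <- kineticParameters(23.1, 72, 12, 249, 147)
fit <- fitGlobalInhibition(generateSteadyState(kp, defaultInhibitionDesign()),
                           "mixed")
round(coef(fit), 4)   # identity on parameters, to optimizer tolerance
```

# Known limitations

* Chemistry is irreversible and two-electron bookkeeping (nitroso →
  hydroxylamine) is out of scope; the simulator tracks one generic P2.
* The explicit integrator is not a general stiff solver; schemes with rate
  spreads far beyond ~10³–10⁴ will be slow or abort (with a diagnostic).
* Wald inference is first-order; for strongly correlated parameters
  (extrapolated hyperbolas) the intervals understate the asymmetry that a
  profile-likelihood analysis would reveal.
* The half-of-sites model couples binding only; ligand-triggered product
  release across the dimer interface is left as an explicit non-feature.
* No weighted or robust regression, and no global progress-curve fitting:
  initial rates only, as in the experimental design the package mirrors.
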