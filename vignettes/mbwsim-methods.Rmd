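---
title: "Modeling the nitrogen multiple-breath washout: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the nitrogen multiple-breath washout: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mbwsim)
```

The multiple-breath washout (MBW) clears a resident inert tracer — here
nitrogen, displaced by breathing pure oxygen — over successive tidal
breaths while flow and tracer concentration are recorded at the mouth.
Its clinical outcomes (the decay shape of the end-expiratory
concentration envelope, the normalized phase III slope $s_{III}$, and
the lung clearance index, LCI) are sensitive to how evenly inspired gas
distributes over the lung periphery. `mbwsim` implements a whole-lung
mechanistic simulator of this test so that structural and mechanical
heterogeneity can be imposed at the level of sub-acinar units and read
back out as the clinical indices.

This vignette describes the model, its numerical treatment, the
parameters that matter, and the design decisions taken where the
problem was genuinely open.

## Morphology: asymmetric conducting tree with trumpet lobules

The conducting airways form a dichotomous tree of rigid cylindrical
pipes. The trachea (generation 0) through generation 4 take the
classical symmetric-model dimensions (18.0/12.2/8.3/5.6/4.5 mm
diameters; 120/47.6/19/7.6/12.7 mm lengths), hard-coded as overridable
defaults in `weibel_default_table()`. Beyond generation 4 each parent
of diameter $d$ spawns a major and a minor daughter with
$d_{maj} = d\,(1-r)^{1/\eta}$ and $d_{min} = d\,r^{1/\eta}$ (lengths
likewise), using the regular branching asymmetry $r = 0.326$,
$\eta = 2.97$. These factors satisfy
$\kappa_{maj}^\eta + \kappa_{min}^\eta = 1$, so the $\eta$-th powers of
the daughter diameters exactly partition the parent's — a property the
test suite checks at every bifurcation. Recursion stops when a newly
created pipe's diameter falls below the limit diameter
$d_{lim} = 1.8$ mm; that pipe is kept and marked terminal. The whole
network is first scaled by $(FRC/FRC_W)^{1/3}$ with $FRC_W = 3.5$ L, and
the $d_{lim}$ screen is applied to the scaled diameters. Under the
default configuration this yields 304 terminal pipes at generations
7–11.

Each terminal pipe feeds one *trumpet lobule*: a single compartment with
axially diverging cross-section that lumps every airway distal to the
terminal pipe (small conducting airways, respiratory bronchioles,
alveolar ducts and alveoli). Assuming a uniform homothety ratio
$\kappa = 0.85$ inside the lobule, generation $z$ holds $2^z$ airways of
diameter $d_t\kappa^z$ and length $l_t\kappa^z$, giving the lumped
cross-section law $S(x) = S_t\hat\kappa^{z(x)}$ with
$\hat\kappa = 2\kappa^2$ and total length
$L = l_t\,\kappa/(1-\kappa)$. (The geometric series makes the airway
diameter taper *linearly* in the cumulative coordinate, which the
implementation uses for the local Péclet diameter.) Because the
exponential law is awkward to integrate and diverges at $x \to L$, the
working cross-section is a two-term power law
$S_{lb}(x,t) = p_1(t)\,x^{n_1} + p_2\,x^{n_2} + S_t$ with
$n_1, n_2 = 20, 2$; $p_1, p_2$ solve the linear system pinning
$S_{lb}$ to the exponential law at a chosen generation $z^*$ and the
integral to the prescribed residual volume $V^0_{lb}$. The system is
solved in the normalized coordinate $x/l_{lb}$ because $x^{20}$
underflows at millimetre scales. Volume changes are carried by $p_1$
alone, which concentrates expansion peripherally
($\partial S/\partial t \propto x^{20}$) — the distal acinar tissue,
not the bronchiolar throat, does the breathing.

Design choices worth flagging:

* **$z^* = 6$** (mid-acinar) by default. The washout outcomes are
  insensitive to $z^* \in \{4, 6, 8\}$ — the test suite asserts that
  the uniform-lung decay rate moves by under 5% across this range — so
  the exact pin generation is not load-bearing.
* **Residual-volume allocation.** The FRC left after subtracting the
  conducting-pipe volume is split *equally* among the 304 lobules by
  default. This follows from the mechanical calibration below: every
  lobule is calibrated against the same nominal tidal volume
  $V_{TV} = TV/N_{lb}$, so under a spatially uniform pleural pressure
  all lobules inhale the same volume per breath. Equal residual volumes
  then give every lobule the same per-breath dilution and the baseline
  washout is uniform — a single-exponential envelope with a flat
  phase III, which is the defining property of the unperturbed
  reference lung. Cross-section-proportional allocation is available
  (`residual_allocation = "cross_section"`) and produces a markedly
  non-uniform "baseline" (envelope weight far below 1), because lobule
  size then varies twofold while tidal increments stay equal.
* An upper-airway/equipment dead space can be added as an elongation of
  the trachea (`trachea_elongation`, in metres); the default is zero.
  Because the washout decay constant is controlled by the effective
  series dead space, this single parameter moves the whole-lung decay
  rate substantially (see *Limitations*).

## Ventilation: nonlinear lumped-parameter network

Pipes are purely resistive, $p_i - p_j = R_{ij}Q_{ij}$, with
$R_{ij}$ the Poiseuille resistance $128\mu l/(\pi d^4)$ times an
oscillatory (Womersley) correction evaluated at the breathing frequency
$\omega = 2\pi/T_B$: the in-phase part of the oscillatory tube
impedance, computed from Kelvin functions, normalized by the Poiseuille
value. At tidal frequency it matters only for the first few generations
(Womersley number $\approx 3$ at the trachea, $< 0.4$ below 2 mm).

Each lobule is a series element of a nonlinear compliance and a
resistance between its terminal-pipe node and the (spatially uniform)
pleural pressure $p_{pl}$:
$$p_i - p_{pl} = \underbrace{\beta e^{\gamma V^0}\left(e^{\gamma \tilde V} - 1\right)}_{p_{el}} + R_{lb} Q_{lb},$$
with $\tilde V = V_{lb} - V^0_{lb}$ the dynamic volume. The two shape
parameters are fixed by two intersection conditions on the elastic
curve, using the reference pressure amplitude $p_{TV} = 1500$ Pa and the
per-lobule tidal volume $V_{TV} = TV/N_{lb}$:

* $\beta$: the curve passes through $(p_{TV},\, V^0 + \varphi V_{TV})$,
  where $\varphi$ is the lobule's compliance factor. Numerically the
  product $\beta e^{\gamma V^0}$ is the stored coefficient (the two
  factors separately overflow/underflow).
* $\gamma$: the curve passes through
  $(p_{TV}/4,\, V^0 + \tfrac34\varphi V_{TV})$ — a quarter-point
  condition placing the curve between the linear ($\gamma\to 0$) and
  right-angled ($\gamma\to\infty$) limits. In the scaled variable
  $g = \gamma\varphi V_{TV}$ the condition
  $(e^{3g/4}-1)/(e^{g}-1) = \tfrac14$ has a single root (the ratio
  falls monotonically from $3/4$ to $0$), found once by bisection;
  hence $\gamma \propto 1/(\varphi V_{TV})$.

$R_{lb}$ is the series sum of per-generation Poiseuille resistances of
the lumped intra-lobule airways ($2^z$ parallel tubes of diameter
$d_t\kappa^z$), a geometric series with ratio $\kappa^{-3}/2 < 1$,
truncated where diameters reach 0.3 mm.

Mass balance at every bifurcation node plus the lobule volume equations
$Q_t = dV_{lb}/dt$ form a differential-algebraic system; the pleural
pressure is the algebraic unknown adjusted so that the summed lobule
inflow matches the prescribed tracheal flow $Q_{in}(t)$ (a sine of
amplitude $\pi TV/T_B$ by default, or a tabulated measured profile).
The step is backward Euler with a damped Newton iteration (tolerance
$10^{-10}$ on the scaled residual, step halving on divergence). The
Newton linear system — diagonal lobule stiffness plus the resistive
path-overlap coupling — is solved exactly in $O(N)$ by a two-pass
admittance sweep over the tree, so no matrix is ever formed. Warm
starts from the previous increments keep the iteration at ~2 Newton
steps. Backward Euler is first-order, but at $dt = 5$ ms the
peak-inspiration lobule volumes change by less than $10^{-4}$ relative
when $dt$ is halved (a test asserts this), and the right-endpoint
quadrature integrates full sinusoidal breaths exactly, so carrier-gas
volume closes to round-off.

## Gas transport: 1D advection–diffusion on the network

The tracer satisfies $\partial_t(Sc) + \partial_x F = 0$ with
$F = S_{ad}\,u\,c - S_{ax}\hat D\,\partial_x c$ on every pipe and
trumpet, where $\hat D = D(1 + Pe^2/192)$ is the Taylor-dispersion
enhanced diffusivity with $Pe = |u|d/D$ built from the local mean
velocity and local airway diameter, and $D = 2.2\times 10^{-5}$ m²/s is
the molecular diffusivity of N₂ in O₂. Inside a trumpet the carrier
velocity follows from mass conservation against the moving wall,
$u(x,t) = (Q_t - \dot p_1 x^{n_1+1}/(n_1+1))/S_{ad}$, which vanishes at
the closed distal end.

**Axial transport cross-section.** The trumpet's total cross-section
$S$ mostly represents alveolarized volume; axial flow and diffusion
physically occur in the duct lumen. By default
(`duct_transport = TRUE`) the axial transport cross-section is the
airway-lumping law $S_t\hat\kappa^{z(x)}$, capped by the total lumen;
the alveolar excess stores tracer but carries no axial flux. This is
the classic trumpet-acinus transport closure. With
`duct_transport = FALSE` the full cross-section transports
($S_{ad} = S_{ax} = S$); the baseline washes out moderately
faster (the test suite brackets the difference between 0 and 10% of the
decay rate) and its phase III plateau flattens.

**Numerics.** The time step couples ventilation and transport in
lockstep (operator split per $dt$): ventilation step, geometry/velocity
update, transport step. At $dt = 5$ ms the advective Courant number
reaches 3–5 in the trachea and in the trumpet throats. A single
implicit step at such Courant numbers either smears fronts by temporal
diffusion ($\sim u^2\Delta t/2$, an order of magnitude above the
physical dispersion in small airways) or, with Crank–Nicolson
weighting, produces bounded-violating oscillations. Transport is
therefore operator-split:

1. *Advection*: explicit second-order finite volumes with minmod
   slope limiting, sub-stepped so that every face Courant number stays
   below 0.45. Bifurcations are zero-volume perfect mixers of their
   instantaneous inflows — conservative, bounded, and robust under flow
   reversal. Face flows are constructed from the same discrete lobule
   volume increments the ventilation step produced, so spatially
   constant fields are preserved exactly and carrier and tracer budgets
   close to round-off.
2. *Diffusion*: implicit (backward Euler by default,
   `theta_time = 0.5` gives Crank–Nicolson) central differences. The
   per-airway tridiagonal blocks are Schur-eliminated onto one shared
   concentration unknown per junction; the reduced junction system is
   again tree-structured and solved leaf-to-root in $O(N)$. The
   junction closure uses conservative half-cell two-point differences
   between the junction value and the adjacent cell centers.

A one-step implicit upwind variant
(`advection_scheme = "implicit_upwind"`) is retained for comparison;
it reproduces the same envelope decay rates to within 2% (asserted in
the test suite; the washout outcomes are controlled by reservoir
dilution and molecular diffusion, not by front sharpness) but smears
the expirogram fronts.

Boundary conditions: the mouth carries fresh gas ($c = 0$, advective +
diffusive Dirichlet) during inspiration and a pure advective outflow
during expiration; trumpet distal ends are closed. Grids: pipes use
uniform cells of at most 2 mm (at least 6 per pipe); trumpets use 60
cells geometrically clustered toward the distal end (distal-to-proximal
width ratio 0.1), where $x^{20}$ concentrates the volume. The single
airway discretization is exposed as a standalone stepper and validated
against a translating front (position error below $2\Delta x$, no
over/undershoot) and the analytic error-function solution of free
diffusion (L2 error under $10^{-3}$); halving $\Delta x$ reduces the
diffusion error by more than a factor 3.

The initial condition is $c = 1$ everywhere (normalized resident
nitrogen); no washin phase is simulated.

## Perturbations

Heterogeneity is imposed per lobule through three factors, all defaulting
to 1:

* $\varphi$ (compliance): recalibrates $\beta, \gamma$; at the
  reference pressure a $\varphi$-lobule holds $\varphi V_{TV}$ above its
  residual volume. $\varphi < 1$ stiffens, $\varphi > 1$ softens.
* $\theta$ (residual volume): $V^0 \leftarrow \theta V^0$ for the
  selected lobules, with all remaining lobules rescaled by one common
  factor so the summed residual volume — hence FRC — is exactly
  preserved; trumpet shapes are refitted and the mechanics stay
  referenced to the new $V^0$.
* $\tau$ (resistance): $R_{lb} \leftarrow \tau R_{lb}$. Under
  Poiseuille $d^{-4}$ scaling, $\tau = 8$ equals a uniform ~40% airway
  narrowing inside the lobule.

Spatial patterns: *regional* assignments occupy successive contiguous
blocks of lobules in depth-first (major-daughter-first) traversal order
of the tree, emulating spatially grouped disease; *local* assignments
spread the modified lobules regularly over the whole traversal order
(with two equal assignments over half the lobules: every other lobule
modified, alternating values). The traversal-order convention is a
documented choice — the true anatomical split of a lung into regions is
not recoverable from a topological tree — and explicit id lists can be
supplied instead. `healthy_lung_preset()` composes four disjoint 12.5%
regional blocks ($\theta = 0.5$ twice, $\varphi = 0.5$, $\varphi = 1.5$)
as a mild physiological inhomogeneity model.

## Washout analysis

Breaths are segmented at inspiratory-onset zero crossings of the flow;
per breath the expirogram (concentration against expired volume) yields
$s_{III}$: the least-squares slope over the 50–95% expired-volume
window normalized by the window-mean concentration. The end-expiratory
envelope, normalized to its first value, is fitted with
$f(t) = A e^{-\alpha_1 t} + (1-A) e^{-\alpha_2 t}$ ($A \in [0,1]$,
$0 < \alpha_1 \le \alpha_2$, $t$ in seconds) by constrained nonlinear
least squares with deterministic multistart (rate guesses from
log-linear fits to the first and last third of the breaths, plus
perturbed restarts). Because $A$ is unidentified as
$\alpha_2 \to \alpha_1$, the two-phase decomposition is only reported
when it earns its keep: if a single exponential leaves at most $10^{-4}$
of the envelope variance unexplained, the fit is reported as uniform
($A = 1$). On the simulated envelopes this margin separates the uniform
cases (single-exponential residual variance fraction $< 10^{-6}$) from
every genuinely bi-phasic case ($> 6\times10^{-4}$) by two orders of
magnitude on either side.

LCI is the cumulative expired volume in units of FRC at the first
breath whose end-expiratory concentration drops below 1/40 of the
pre-washout value; the consensus triplet rule (three consecutive
sub-threshold breaths) is available but off by default.

## What the simulations show — and what they cannot

The default configuration (FRC 3.0 L, TV 0.5 L, $T_B$ 3.2 s, sinusoidal
flow, 50 breaths, 304 lobules, $dt$ 5 ms) is deterministic: rerunning
any experiment reproduces byte-identical breath tables. The experiment
suite covers the canonical perturbations (regional/local compliance,
regional residual volume, regional resistance, healthy composite); the
acceptance script reruns all of them from scratch.

Known limitations, in decreasing order of consequence:

* **Effective dead space.** The model's conducting pipes hold ~56 mL;
  the intra-trumpet airway throat another ~130 mL, but the latter is
  only partially protective because molecular diffusion equilibrates
  the short distal shell of the trumpet (the $x^{20}$ hump concentrates
  ~85% of lobule volume within a few millimetres of the closed end).
  The simulated baseline therefore clears somewhat faster (decay
  constant ~0.037–0.040 1/s depending on transport options) than
  washouts of real lungs whose series dead space — upper airways,
  mouth, measurement equipment — is larger. The `trachea_elongation`
  hook exists precisely to represent that pathway; it is deliberately
  left at zero in the default and acceptance configurations. The
  clearance rate is a converged model property rather than a numerical
  artifact: the refinement and sensitivity tests show it is stable
  under time-step halving, grid refinement, the $z^*$ choice and the
  transport-scheme choice, while adding tracheal dead space slows it
  (also asserted in the test suite).
* No turbulence model: Taylor's laminar $Pe^2$ form is extrapolated
  into the trachea where the flow is transitional; it likely
  misestimates large-airway mixing, though large airways equilibrate
  within a breath regardless.
* Uniform pleural pressure; no gravity, no left/right anatomical
  asymmetry, no tissue viscoelasticity beyond the series
  resistance-plus-nonlinear-elastance element; no gas exchange with
  blood (inert tracer only); washout only (no washin for exogenous
  tracers).
* The trumpet lumps all sub-$d_{lim}$ generations with one homothety
  ratio; real acini have non-uniform branching and the intra-acinar
  duct/alveolus partition of the cross-section is parameterized, not
  anatomical.

## Reproducing the analyses

```{r example}
# baseline washout and outcomes
res <- run_experiment_suite("baseline")
res$outcomes

# regional compliance heterogeneity
rc <- run_experiment_suite("regional_compliance")
rc$summary$envelope

# full acceptance recomputation (writes JSON):
#   Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Each 50-breath whole-lung simulation takes on the order of 80 seconds
on one core; the full six-experiment suite runs in under ten minutes.
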