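---
title: "Methods: modeling and inferring state-dependent sodium-channel block"
author: "statenav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling and inferring state-dependent sodium-channel block}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statenav)
```

# The scientific problem

Voltage-gated sodium channels cycle between resting (closed),
fast-inactivated and slow-inactivated conformations. Many clinically
interesting inhibitors — local anesthetics, antiarrhythmics,
antiepileptics, and cannabinoids such as cannabidiol — bind these
conformations with very different affinities. A compound that binds
the inactivated state a hundred times more tightly than the resting
state can silence a depolarized, hyperexcitable cell at concentrations
that barely touch a cell resting at a hyperpolarized potential. The
quantitative task is to turn routine voltage-clamp measurements —
steady-state availability curves with and without drug, residual block
at hyperpolarized holding, dose-inhibition tables — into
state-specific dissociation constants, and to check that a concrete
kinetic mechanism can reproduce the time-dependent phenomena (slow
onset of block, slowed recovery from inactivation, rapid entry into
slowly-recovering states during depolarization).

# The coupled-equilibrium model

Steady-state availability is described by a two-parameter Boltzmann,

$$ h(V) = \frac{A}{1 + \exp\!\big((V - V_{1/2})/k\big)}, \qquad k > 0, $$

so availability falls with depolarization (`boltzmannAvailability`).
The modulated-receptor picture treats the drug (concentration $D$) as
binding resting channels with dissociation constant $K_r$ and
inactivated channels with $K_i$. Writing the voltage-dependent
equilibrium between unbound resting and inactivated channels as
$\exp((V-V_{1/2})/k)$ and adding the bound states with Boltzmann
weights $D/K_r$ and $D/K_i$, the availability midpoint shifts by

$$ \Delta V_{1/2} = -\,k \,\ln \frac{1 + D/K_i}{1 + D/K_r}, $$

(`coupledShift`): zero when $D = 0$ or $K_i = K_r$, hyperpolarizing
when the inactivated state binds more tightly. The same partition
function gives the occupancy-weighted apparent affinity
$1/K_{app} = h/K_r + (1-h)/K_i$ (`apparentKd`).

Inference inverts this algebra. The residual current fraction $b$ at a
strongly hyperpolarized holding potential reflects pure resting-state
occupancy, $K_r = D\,b/(1-b)$ (`inferKdRest`; $b = 1$ is represented
as an explicit infinite-$K_r$ sentinel). Given the corrected midpoint
shift and a slope factor, the closed form

$$ K_i = \frac{D}{(1 + D/K_r)\,e^{-\Delta V_{1/2}/k} - 1} $$

returns the inactivated-state constant (`inferKdInact`); it
round-trips with `coupledShift` to first-class numerical precision. A
depolarizing shift large enough to make the bracket non-positive is
inconsistent with tighter inactivated-state binding and raises a
classed no-binding error rather than a negative constant.

Two practical details follow the way such experiments are actually
analysed. First, availability midpoints drift slowly during whole-cell
recordings, so the drug-induced shift is corrected by subtracting the
average shift observed in time-matched drug-free controls
(`driftCorrectedShift`; exact subtraction). Second, the inversion uses
the *control* fit's slope factor: the two-state model assumes a common
slope, and the control curve estimates it without the extra
variability that partial resting-state block adds to the drug curve.
Multi-cell data are aggregated by averaging the shift within each cell
and then across cells (`averageShift`), not by pooling points into one
fit.

# The six-state kinetic scheme

`buildScheme` constructs the minimal Markov scheme that reproduces the
four protocol families (availability, application time course,
recovery, entry into slowly-recovering states):

```
 R   <->  IF  <->  IS        gating, drug-free
 |         |        |        binding (on-rate kon*D)
 RD  <-> IFD  <-> ISD        gating, drug-bound
```

Slow inactivation is entered through the fast-inactivated state only;
a direct R–IS edge is omitted because entry into slowly-recovering
states during brief depolarizations is naturally carried by IF. The
R↔IF rates use single-barrier (exponential) voltage dependence,

$$ a(V) = p\,e^{\delta x / k}, \quad b(V) = p\,e^{-(1-\delta) x / k},
   \quad x = V - V^{\mathrm{eff}}_{1/2}, $$

so the equilibrium $a/b = e^{x/k}$ reproduces the target Boltzmann
exactly while $\tau(V) = 1/(a+b)$ sets the kinetics.

**Calibration choices (defaults, units, why).**

* $V_{1/2} = -75.2$ mV, $k = 7.9$ mV — the representative control
  availability fit; all defaults describe the 37 °C steady-state
  dataset. Temperature is not modeled; datasets at other temperatures
  are separate calibrations.
* $\tau_{R\leftrightarrow IF}(-40\,\mathrm{mV}) = 3$ ms (fast
  inactivation during depolarization) and
  $\tau_{R\leftrightarrow IF}(-100\,\mathrm{mV}) = 2$ ms (recovery
  from fast inactivation). The partition fraction $\delta$ and
  prefactor $p$ are **solved from this pair** (numerically, at build
  time; $\delta \approx 0.38$). A fixed symmetric partition
  ($\delta = 0.5$) cannot satisfy two independent time constants —
  with it $\tau(V) \propto 1/\cosh((V-V_{1/2})/2k)$ has only one free
  scale — so the package treats $\delta$ as the second calibration
  degree of freedom. Infeasible pairs are rejected with an error.
* IF→IS time constant 2 s at −40 mV; IS→IF recovery 200 ms
  (voltage-independent). The recovery scale is not fixed by any
  reported number; 200 ms is a realistic slow-recovery scale that
  keeps drug-free entry into slowly-recovering states after a 20-ms
  conditioning step small (the tests assert < 5%), as control entry
  curves show. Because IS sits in series with IF, the bare R↔IF
  midpoint is depolarized by $k\ln(1 + c/d)$ so that the *observed*
  stationary availability equals the target Boltzmann exactly.
* $K_r = 360$ nM, $K_i = 50$ nM. The inactivated-state constant is
  the headline inference result; the resting-state constant is
  calibrated, constrained by the residual current at hyperpolarized
  potentials together with the simulated block level below.
* Drug on-rate $4.72\times10^{-5}$ nM⁻¹ s⁻¹, common to all states;
  off-rates follow from the equilibrium constants. This value is
  calibrated so that a simulated two-minute application of 300 nM at a
  −70 mV holding potential reduces the test-pulse current to 0.29 of
  control, the observed two-minute block level. It implies
  minutes-scale equilibration at 300 nM, consistent with the
  experimental practice of applying drug for ~10 minutes to reach
  steady state — and it means the two-minute figure is itself a
  pre-steady-state quantity: the same simulation run to equilibrium
  settles near 0.19. An important corollary is that a 5-s prepulse
  does *not* re-equilibrate binding; `availabilityFromScheme`
  therefore distinguishes the finite-prepulse protocol curve
  (`init = "holding"`) from the true stationary curve
  (`init = "stationary"`), and the analytic-consistency invariant
  (midpoint shift within 0.1 mV of `coupledShift`) is stated for the
  stationary curve.
* Drug-bound gating uses the same rate law with the midpoint shifted
  by $-k\ln(K_r/K_i)$. This single choice fixes one dependent rate
  per cycle and enforces detailed balance around both binding cycles
  by construction; `checkDetailedBalance` verifies it numerically
  (stationary edge fluxes and Kolmogorov cycle products) and
  `buildScheme` rejects overridden rate sets that break it, naming
  the offending cycle.
* Drug-bound resting channels (RD) do not conduct in availability
  readouts by default: block at hyperpolarized potentials is modeled
  as resting-state binding. A flag (`drugBoundConducts`) flips this.
* Units are mV, ms and nM throughout; the on-rate is accepted in
  nM⁻¹ s⁻¹ and converted internally.

Protocols are piecewise-constant voltage epochs
(`voltageProtocol`), so each epoch is propagated **exactly** with the
matrix exponential of the generator (`propagateOccupancy`,
`Matrix::expm`); there is no integrator step-size error, and the test
suite cross-checks the propagation against an independent fine-step
ODE integration to 10⁻⁶ occupancy on random reversible schemes.
Occupancy vectors conserve probability to 10⁻⁹ along every protocol.

# Curve fitting

Both fits use Levenberg–Marquardt least squares (`minpack.lm::nls.lm`)
with a relative objective tolerance of 10⁻¹⁰ and at most 500
iterations, and both record the objective trace (non-increasing by
construction of the accepted steps; asserted in tests).

* `fitBoltzmann`: midpoint initialized where the curve crosses half
  its maximum (linear interpolation), slope at 8 mV, amplitude at the
  observed maximum; slope bounded to (0.5, 30) mV. Degenerate inputs
  (no spread, no half-maximum crossing) and fits ending on a bound are
  *flagged* (`converged = FALSE`, with a reason), never silently
  returned.
* `fitHill`: IC50 fitted on the log scale (positivity guaranteed),
  initialized by log-linear interpolation at 50% inhibition; Hill
  coefficient bounded to (0.2, 5), initialized at 1, optionally held
  fixed at 1 (`fixHillN`) since assay tables often do not constrain
  it well. All-zero inhibition is flagged.

On noiseless synthetic input both fits recover their generating
parameters to 10⁻⁶ relative, which the acceptance checks exercise at
the study's parameter values (midpoints −75.2/−82.6 mV, slopes
7.9/8.4 mV, IC50s 1.82/4.28 μM).

# Synthetic data: what it emulates, and what it does not

The generators (`genAvailability`, `genPairedAvailability`,
`genPairedCohort`, `genDoseResponse`, `genKineticDataset`,
`genStructureFixtures`) produce every input the analysis consumes,
under a single integer seed that expands deterministically into
per-curve substreams: identical seed and parameters give bit-identical
output, and changing only the seed changes only the noise. Noise is
additive Gaussian on normalized current (default sd 0.02, the rough
size of availability error bars), clipped at physical limits —
additive rather than multiplicative because measurement scatter in
such recordings is fairly uniform along the curve. Cell-to-cell
variability is emulated as a 2 mV Gaussian jitter of the control
midpoint (`genPairedCohort`); real between-cell variance structure is
unknown, so this number is a placeholder for exercising the
aggregation path, not an estimate.

The paired generator produces the drug curve as the control Boltzmann
shifted by `coupledShift` and scaled by the resting block — i.e. data
that satisfy the two-state model exactly. Passing round-trip tests
therefore establishes that *inference inverts generation* (no
algebraic or coding error, correct noiseless limits, noise-robustness
of the estimator), **not** that real channels obey the two-state
model. Real recordings add series-resistance error, rundown,
incomplete drug equilibration during prepulses, and slope changes with
drug, none of which the generator emulates. The drug-condition curve
is normalized to its own maximum by default (the fit has a free
amplitude), matching the package's inference convention; an analysis
normalized to the control fit instead is supported by passing the
control amplitude explicitly.

Structural fixtures carry planted geometry — a 2.8 Å/170° donor
triad, a 4.5 Å decoy beyond the hydrogen-bond cutoff, parallel and
perpendicular ring pairs at 4.0 Å, and a 12-atom chain with a known
rotation whose per-atom displacements follow
$2\sin(\phi/2)\,r_\perp$ in closed form.

# Structure annotation

Atomic structures are read with bio3d (PDB and mmCIF) into a plain
atom table. Geometric criteria default to: contacts at 4.5 Å between
heavy atoms; hydrogen bonds at ≤ 3.5 Å donor–acceptor heavy-atom
distance with a ≥ 120° angle at the donor, evaluated against the
donor's bonded heavy-atom antecedent because deposited models
typically lack hydrogens (when no antecedent exists the bond is
reported distance-only with a `noAngle` flag); π-stacks at ≤ 5.5 Å
ring-centroid distance with interplanar angle ≤ 30° (normals from the
SVD of the centered ring coordinates; rings with fewer than five
resolved atoms are skipped with a warning). All cutoffs are exposed
arguments: the underlying structural observations are qualitative, so
the defaults are sensible field conventions, not measured quantities.
Superposition is a proper-rotation Kabsch solve (SVD with sign
correction), pairing atoms by chain/residue/atom name; the default
selection is Cα atoms, the natural choice for comparing pore-domain
conformations between apo and drug-bound models. Unpaired selections
abort with the offending residues listed (or are dropped on request),
and collinear selections are rejected as degenerate. Detection and
superposition are invariant to rigid motion and atom order, which the
tests assert, alongside an independent all-pairs distance oracle and
a cross-check of the aligned RMSD against bio3d's fitting routine.

# Numerical and design choices, in brief

* Stationary distributions restrict to the communicating class
  reachable from the resting state, so schemes with unreachable
  drug-bound states (zero on-rate) still have the physically correct
  equilibrium; genuinely ambiguous schemes error out.
* `inferKdInact` uses the signed shift, so the no-binding diagnostic
  triggers exactly when the measured shift points the wrong way.
* The pipeline (`runPipeline`) validates its whole configuration —
  unknown keys rejected — before any stage runs, writes each product
  as it is produced (partial outputs survive a downstream failure),
  and emits a provenance record (resolved configuration, package
  version, seed) with no wall-clock content so identical runs are
  byte-identical.
* Problem sizes throughout (23-point voltage grids, five-point dose
  grids, ≤ 100-replicate noise studies, ≤ 100 random schemes in the
  property suites) keep the full test and acceptance runs in the
  seconds-to-minutes range while leaving the estimators'
  noiseless-limit and ordering properties clearly resolvable.

# Known limitations

* The two-state inference assumes a common slope factor and complete
  drug equilibration at every prepulse voltage; the package's own
  kinetic scheme shows how slow binding breaks the second assumption,
  and the discrepancy between protocol and stationary curves is a
  feature to explore, not an inconsistency.
* The kinetic calibration is intentionally minimal: one on-rate for
  all states, voltage-independent slow-inactivation rates, no direct
  R–IS path, no temperature scaling, no conductance waveforms beyond
  the availability readout.
* Hydrogen-bond and stacking detection are heavy-atom heuristics; they
  identify geometric candidates, not energetically validated
  interactions.
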