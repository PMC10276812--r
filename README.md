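# statenav

Quantitative analysis of **state-dependent block of voltage-gated
sodium (Na_v) channels** by small molecules such as cannabidiol.

Drugs of this class bind weakly to resting channels but with high
affinity to inactivated channels. Electrophysiologically this shows up
as a hyperpolarizing shift of the steady-state availability
(inactivation) curve, slowed recovery from inactivation, and strong
inhibition at depolarized holding potentials. `statenav` is for
channel biophysicists and pharmacologists who want to turn those
measurements into state-specific dissociation constants, simulate the
underlying gating/binding kinetics, and annotate the structural
binding sites that produce them.

## What it computes

**Coupled-equilibrium (modulated-receptor) inference.** Availability
follows a Boltzmann function, h(V) = A / (1 + exp((V − V½)/k)) with
slope factor k > 0. A drug at concentration D with resting-state
dissociation constant K_r and inactivated-state constant K_i shifts
the midpoint by

    ΔV½ = −k · ln[ (1 + D/K_i) / (1 + D/K_r) ]

`statenav` fits the Boltzmann curves (`fitBoltzmann`), corrects the
measured shift for the slow drift seen in drug-free controls
(`driftCorrectedShift`), infers K_r from the residual block at
hyperpolarized holding (`inferKdRest`, K_r = D·b/(1−b)), and inverts
the shift equation in closed form for K_i (`inferKdInact`). The whole
chain is `analyzeStateDependence`.

**Kinetic simulation.** A six-state Markov scheme (resting R,
fast-inactivated IF, slow-inactivated IS, plus drug-bound
counterparts RD/IFD/ISD) with voltage-dependent rates, detailed
balance enforced around every cycle, and exact matrix-exponential
propagation through piecewise-constant voltage protocols
(`buildScheme`, `simulateProtocol`, `slowlyRecoveringFraction`).

**Dose-response pharmacology.** Hill fits of concentration-inhibition
data, inhibition = 1 / (1 + (IC50/D)^n), for wild-type/mutant
comparisons (`fitHill`).

**Binding-site geometry.** PDB/mmCIF reading (via bio3d), ligand
contacts, heavy-atom hydrogen-bond detection, aromatic (π-π) stacking,
and Kabsch superposition with per-residue displacements
(`readStructure`, `interactionReport`, `superpose`).

**Synthetic data.** Seeded generators for every input the chain
consumes (`genAvailability`, `genPairedAvailability`,
`genDoseResponse`, `genKineticDataset`, `genStructureFixtures`), so
every stage is testable without downloads.

## Worked example

Generate a noisy control/300 nM pair from a known binding model and
recover the inactivated-state K_d:

```r
library(statenav)

model <- stateBindingModel(drugConc = 300, kdRest = 360,
                           kdInact = 50, slope = 7.9)
model
#> Coupled-equilibrium state-binding model
#>   D = 300 nM, Kr = 360 nM, Ki = 50 nM, k = 7.9 mV
#>   predicted midpoint shift: -10.58 mV

pair <- genPairedAvailability(model, boltzmannParams(-75.2, 7.9),
                              noise = noiseSpec(sd = 0.02, seed = 42))
analyzeStateDependence(pair$control, pair$drug, pair$restingBlock)
#> State-dependence analysis
#>   raw shift -10.85 mV, drift 0.00 mV, corrected -10.85 mV
#>   Kd(resting) = 360 nM, Kd(inactivated) = 46.67 nM
```

With 2% measurement noise the fitted shift (−10.85 mV) scatters
around the model's −10.58 mV and the inferred inactivated-state K_d
(46.7 nM) around the generating 50 nM; with `sd = 0` the recovery is
exact.

Simulate a two-minute application of 300 nM drug at a −70 mV holding
potential with the default calibrated scheme:

```r
sch   <- buildScheme()
free  <- steadyState(sch, v = -70, drugConc = 0)
after <- propagateOccupancy(free, rateMatrix(sch, -70, 300), t = 120000)
availabilityOf(after, sch) / availabilityOf(free, sch)
#> [1] 0.29
```

i.e. the test-pulse current falls to 0.29 of control — strong
inhibition at a physiological holding potential even though 300 nM is
far below the resting-state K_d, because most channels at −70 mV are
inactivated and bind the drug with ~50 nM affinity.

A configuration-driven pipeline (`runPipeline`) ties the stages
together; see `inst/extdata/demo_config.yaml` and the thin CLI wrapper
`inst/scripts/statenav.R` (subcommands `synth`, `simulate`,
`fit-availability`, `infer-kd`, `fit-ic50`, `annotate-site`, `run`).

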