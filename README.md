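# cardiomyosim

Kinetic simulation of cardiomyocyte energy metabolism through ischemia and
reperfusion.

When a coronary vessel is occluded, the downstream heart muscle loses oxygen
and substrate; paradoxically, much of the resulting injury happens at
*reperfusion*, when returning oxygen meets an electron-transport chain whose
redox pools were driven fully reduced during the ischemic period.  The key
suspects for the resulting burst of reactive-oxygen production are reverse
electron transport (RET) at complex I and a spike of the mitochondrial
membrane potential that accelerates complex III.  `cardiomyosim` implements
a five-compartment kinetic ODE model of the underlying metabolism —
glycolysis, glycogen turnover, lactate handling, creatine/adenylate-kinase
ATP buffering, myoglobin-bound oxygen, and a thermodynamically balanced
description of oxidative phosphorylation (lumped TCA dehydrogenase,
complexes I/III/IV, F1F0-ATP synthase, adenine nucleotide translocase,
proton leak, K⁺/H⁺ and phosphate transport) — so that these transition
periods can be simulated and quantified.

At its core are mass-action rate laws of the form

    J = X * (exp(-(dG + n*dG_H)/RT) * [reduced substrate] - [oxidized product])

with the proton-motive energy `dG_H = F*dPsi + RT*ln([H]i/[H]x)` coupling
every pump to the membrane potential, whose own balance

    d(dPsi)/dt = (4*J_C1 + 2*J_C3 + 4*J_C4 - 3*J_F1 - J_ANT - J_Hle)/C_IM

closes the loop.  Because each step is reversible, a reduced ubiquinone pool
plus a recovering potential can drive complex I backwards — the RET injury
surrogate the package's metrics extract.

The package provides:

* `defaultModel()` — the complete tabulated model (61 species + dPsi, five
  compartments, every kinetic and thermodynamic constant), shipped as a
  schema-validated YAML document with lossless serialization;
* `runSimulation()` / `standardProtocol()` / `twoStepProtocol()` — stiff
  time-course integration (compiled RHS + `deSolve`) of piecewise-constant
  perfusion schedules, with automatic grid refinement at reperfusion;
* `findSteadyState()` — physiological pre-equilibration;
* `relativeSensitivities()` / `sensitivityReport()` — finite-difference
  metabolic control analysis over all 37 enzyme/transport activities;
* `irMetrics()` and friends — ATP depletion/recovery times, membrane
  potential plateau/spike, RET interval, complex-III spike ratio;
* `writeTimeseries()`, `writeReport()`, `exportSBML()`/`importSBML()`,
  `loadRunConfig()` and a thin command line (`exec/cardiomyosim`).

## Worked example

```r
library(cardiomyosim)

model  <- defaultModel()
steady <- findSteadyState(model, 1)        # physiological pre-equilibration
round(steady[c("ATP_c", "CrP_c", "dPsi")], 2)
#> ATP_c CrP_c  dPsi
#>  7.00 22.71 184.21

# 1000 s perfusion, 1000 s at 0.5% vessel oxygen, 1000 s reperfusion
sim <- runSimulation(model, standardProtocol(0.005), initState = steady)
irMetrics(sim)[c("atp_depletion_time", "dpsi_ischemic_plateau",
                 "c3_spike_ratio")]
#> $atp_depletion_time
#> [1] 452.8679        # s after ischemia onset until [ATP]c < 5% of baseline
#> $dpsi_ischemic_plateau
#> [1] 113.5463        # mV at the end of the ischemic segment
#> $c3_spike_ratio
#> [1] 4.252766        # complex III rate burst at direct reperfusion

# a 5% first reperfusion step suppresses the complex-III burst
two <- runSimulation(model, twoStepProtocol(0.005, 0.05), initState = steady)
c3SpikeRatio(two)
#> [1] 0.2125737
```

The depletion time says the creatine-phosphate and glycogen stores carry the
cell for about 450 s of deep ischemia before cytosolic ATP collapses; the
plateau is the membrane potential the residual chain can still hold at 0.5%
oxygen; and the spike ratios quantify the package's central protocol
comparison — restoring oxygen through an intermediate 5% step removes the
complex-III burst (0.21x the pre-ischemic rate instead of 4.25x).

Metabolic control analysis:

```r
sens <- relativeSensitivities(model, standardProtocol(0.01),
                              initState = steady)
head(sensitivityReport(sens), 3)
#>  timepoint enzyme    pathway        S rank
#>    physiol     HK Glycolysis 15.83315    1
#>    physiol    PFK Glycolysis 15.19922    2
#>    physiol  PGluM   Glycogen 14.44516    3
```

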