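# mnpkinetics

Kinetic analysis of multiplexed, flow-replenished magneto-nanosensor
binding assays, for biophysicists measuring low-affinity (micromolar)
protein–protein interactions — the regime of immune-checkpoint pairs such
as PD-1/PD-L1/PD-L2/B7-1 — that are hard to quantify by surface plasmon
resonance.

The assay flies Fc-tagged "prey" proteins on protein A-coated magnetic
nanoparticles (MNPs) through microfluidic channels over
giant-magnetoresistive sensors carrying immobilized "bait" proteins. The
multivalent particle–surface interaction boosts apparent affinity into a
measurable range, and continuous flow keeps the complex concentration *C*
constant at the surface, so coverage follows the reaction-limited Langmuir
isotherm:

    dθ/dt = kon·C·(1 − θ) − koff·θ
    S(t)  = A · (1 − exp(−k_obs · (t − t0))),   k_obs = kon·C + koff

(rates are bivalent/avidity-level, written `kon_bi`, `koff_bi` in code).
Each of four channels receives a serial dilution (100/75/50/25 % of the
eluted complex concentration, itself calibrated from absorbance at
425 nm), each channel's traces are reference-subtracted and fit over 80
post-onset samples, and the pooled regression of `k_obs` on *C* decouples
the rates: slope = `kon_bi`, intercept = `koff_bi`,
`KD_bi = koff_bi/kon_bi`. An avidity model with effective local
concentration `c_eff` converts the bivalent constant to the single-site
one: `KD_mono = (KD_bi · c_eff^(v−1))^(1/v)` for valency `v` (default 2).
Transport diagnostics (Stokes–Einstein diffusivity, Péclet numbers,
Damköhler number) verify the reaction-limited assumption from first
principles.

The package also ships a simulator (`simulate_dataset`,
`simulate_two_compartment`, `simulate_calibration_plate`) generating
datasets with known ground truth and the exact statistical structure the
analysis assumes — the basis of its test suite.

## Worked example

```r
library(mnpkinetics)
library(dplyr)

cfg <- run_config(
  layout = chip_layout(),                      # 4 channels x 16 sensors
  seed = 7L, prey = "PD-1",
  truth = list("PD-L2" = kinetic_truth(kon_bi = 1e6, koff_bi = 1e-4)),
  sigma_rel = 0.002, amp_cv = 0.02,            # low-noise demonstration
  c_eff = 0.27,                                # molar; must be explicit
  b_m = 1e-13                                  # bait sites, mol/m^2
)
res <- run_pipeline(cfg, "demo-run")
res$kinetics[["PD-L2"]]
#> <bivalent_kinetics> PD-1 (flowed) -> PD-L2 (immobilized)
#>   kon_bi  8.436e+05 +/- 1.7e+05  M^-1 s^-1
#>   koff_bi 0.0002218 +/- 0.00011  s^-1
#>   KD_bi   2.629e-10 +/- 1.9e-10  M
#>   R^2 0.9265 over 4 points
res$monovalent$kd_mono_uM
#> [1] 8.42
res$regime$verdict
#> [1] "reaction_limited"
```

The simulated truth was `kon_bi = 1e6 M^-1 s^-1`, `koff_bi = 1e-4 s^-1`
(`KD_bi` = 0.1 nM): a single 4-point dilution series at low noise recovers
the association rate within ~16 % (within its reported standard error),
while the intercept — the slow off-rate — is much less certain, which is
why real studies pool several experiments into one regression
(`pool_kobs` accepts points from any number of runs). The monovalent
constant lands in the micromolar range characteristic of checkpoint-ligand
interactions. The reaction-limited verdict reflects a Damköhler number of
~2e−5 at these settings: surface reaction, not transport, limits the
observed rate.

`autoplot()` methods draw the calibration line and the k_obs-vs-C
regression; `plot_traces()` shows the per-channel sensorgrams;
`tidy()`/`glance()` give broom-style summaries of every fitted object.

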