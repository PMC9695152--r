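# phototherm

Evaluation toolkit for plasmonic photothermal agents: estimation of the
photothermal conversion efficiency of nanoparticle suspensions from infrared
heating/cooling traces, plus the supporting computations such an evaluation
needs — LSPR spectrum handling, thermogram region-of-interest extraction, a
finite-difference heat-diffusion simulator for layered tissue-mimicking skin
phantoms, and MTT viability normalization. It is aimed at nanomedicine /
biophotonics groups benchmarking candidate photothermal-therapy (PTT)
nanoheaters, and at anyone who needs a fully synthetic, seeded test bed for
such pipelines.

## The model

A laser-irradiated sample (nanoparticles + solvent + container) is treated as
a lumped thermal capacitance. Its temperature rise above ambient follows

```
ΔT(t) = τ · [ I (1 − 10^(−A_λ)) η + Q₀ ] / Σᵢ mᵢCᵢ · (1 − e^(−t/τ))
```

where `I` is the incident laser power (W), `A_λ` the optical density at the
excitation wavelength (so `1 − 10^(−A_λ)` is the absorbed fraction), `η` the
photothermal conversion efficiency, `Q₀` the parasitic power absorbed by
solvent and container (W), `Σ mᵢCᵢ` the total heat capacity (J/°C), and `τ`
the thermal time constant. After switch-off the rise relaxes as
`ΔT e^(−t/τ)` with the same `τ`.

The efficiency is recovered from a measured trace by the energy balance

```
η = (hA·ΔT_max − I ζ) / ( I (1 − ζ) (1 − 10^(−A_λ)) )
```

with `hA = Σ mᵢCᵢ / τ` (steady-state closure), `τ` fitted by weighted
linear regression of `log θ` over the source-free cooling phase,
`ΔT_max` the steady-state rise extracted from the heating plateau (with an
exact finite-duration correction when heating stops short of the plateau),
and `ζ` — the fraction of laser power absorbed parasitically — calibrated
from an optional water-only control trace.

The phantom simulator integrates `∂T/∂t = ∇·(k∇T)/ρc + S/ρc` with an
explicit flux-form scheme on a 2-D cross-section of a two-layer agarose skin
phantom (4 mm epidermal over 8 mm dermal) holding a 1.25 mm
nanoparticle-doped inclusion, with the laser entering as a Gaussian-profile
volumetric source confined to the inclusion and an exact discrete energy
audit.

## Worked example

Simulate a sample with known efficiency 0.80 under the standard rig
(196 mW laser, OD 0.56, τ = 300 s, 1 g water, 15 min on / 15 min off at one
frame per minute, 0.2 °C camera noise) and re-estimate it:

```r
library(phototherm)

components <- list(heat_component("water", 1, 4.184))
truth <- lumped_params(laser_power = 0.196, absorbance = 0.56,
                       efficiency = 0.80, time_constant = 300,
                       components = components)
trace <- generate_trace(truth, noise = noise_spec(sigma = 0.2, seed = 42))
estimate_eta(trace, laser_power = 0.196, absorbance = 0.56,
             components = components)
#> Photothermal efficiency estimate
#>   eta           : 0.795 (79.5%)
#>   tau           : 303 s (cooling fit R^2 = 0.97674)
#>   hA            : 0.01381 W/°C
#>   dT steady     : 8.177 °C
#>   zeta          : 0.0000
#>   residual RMS  : 0.2492 °C
```

The estimate recovers the ground truth to half a point of efficiency at this
noise level; `tau`, `hA` and the steady-state rise are the intermediate
physical quantities of the energy balance, and the residual RMS matches the
injected camera noise. The same round trip works for viability tables:

```r
plate <- generate_mtt_plate(c(untreated = 1, AuNTs780 = 0.55),
                            noise_cv = 0.05, seed = 42)
compute_viability(plate, "untreated")
#>       group irradiated viability_percent sd_percent n
#> 1  AuNTs780      FALSE          54.78566   1.020551 3
#> 2 untreated      FALSE         100.00000   4.747982 3
```

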