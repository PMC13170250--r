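# photonheat

Simulation toolkit for **scattering–absorption coupled photothermal heating**
in nanoparticle-loaded turbid media.

Efficient near-infrared (NIR) photothermal conversion in gels, tissue and
other turbid matrices is limited by the local photon supply, not only by the
absorber dose. Pairing a broadband dielectric **scatterer** (e.g.
nanodiamond) with a plasmonic **absorber** (e.g. gold nanostars) can trap
photons near the illuminated face — prolonging their path length and raising
the local fluence rate Φ — so that the absorber harvests more energy under an
identical incident dose. `photonheat` is for researchers who want to explore
that design space quantitatively: it links particle loadings to bulk optics,
bulk optics to fluence and absorption maps, absorption maps to thermocouple
temperature traces, and traces to the summary statistics used to judge a
formulation.

## What it computes

* **Composite optics.** Loadings declared in pM, v%, µg/ml or number density
  are converted to effective bulk coefficients under independent-scattering
  additivity: µ_a = µ_a,bkg + Σ ρᵢ σ_abs,i κᵢ, µ_s = µ_s,bkg + Σ ρᵢ σ_sca,i,
  with g_eff the scattering-weighted anisotropy. An optional scalar κ ≥ 1 on
  the absorber cross-section represents the near-field absorption gain when
  the scatterer is co-loaded.
* **Monte Carlo photon transport** (compiled kernel) through a cylindrical
  phantom: Henyey–Greenstein scattering, unpolarized Fresnel boundaries on
  all faces, implicit capture with Russian roulette, and a track-length
  estimator for the fluence rate per incident watt, with per-voxel Monte
  Carlo standard errors and a closed energy budget
  (reflected + transmitted + side-escaped + absorbed = 1).
* **Enhancement analysis.** E(x,z) = Φ_case/Φ_reference and its µ_a·Φ
  analogue, with a noise-floor validity mask, laterally averaged depth
  profiles, entry-region maxima and volume medians.
* **Thermal response.** Axisymmetric transient conduction (implicit finite
  volumes, Robin boundaries) driven by the absorbed-power map, returning
  ΔT(t) at virtual thermocouples, plus a lumped heat-balance model
  (dT_ss = P_abs/hA, τ = mc_p/hA).
* **Summary statistics.** The synergy coefficient
  S_ΔT = ΔT_combined/(ΔT_a + ΔT_b) (S > 1 ⇒ supra-additive heating),
  4-parameter logistic dose–response fits with LD50 and fold reduction,
  beam power-density conversion, and one-at-a-time sensitivity scans of the
  optical parameters.

## Worked example

Compare a scatterer-loaded gel against the blank gel, then run the combined
absorber + scatterer phantom through the thermal solver:

```r
library(photonheat)

case <- scenario_preset("scatterer_gel", n_photons = 1e5)  # ND 3.2e-3 v%
ref  <- scenario_preset("blank_gel",     n_photons = 1e5)
cmp  <- run_compare(case, ref, seed = 42)
cmp$enhancement
#> <enhancement_map> 2400 valid voxels (floor 10 sigma)
#>   max (entry, first 2 mm): 1.382 | volume median: 4.820 | frac E>1: 0.889

cmp$case$fluence
#> <fluence_map> 60 x 40 voxels, 100000 packets
#>   budget: R 0.1965 | T 0.1608 | side 0.3704 | A 0.2723 (sum 1.000000)
#>   mean pathlength 35.332 mm, mean scatter events 7.44

# heating of the combined gel (kappa = 2 models the near-field coupling gain)
r  <- run_scenario(scenario_preset("combined", kappa = 2,
                                   n_photons = 5e4, seed = 42))
tr <- solve_heat(r$absorption, power = 0.5, r$scenario$geometry,
                 r$scenario$thermal, duration = 1200,
                 probes = probe_set(c(3, 6, 9, 12), depth = 3), dt = 4)
tr
#> <temperature_trace> 300 steps to 1200 s, 4 probes
#>   final dT (degC): r3mm=15.946, r6mm=11.791, r9mm=8.797, r12mm=7.234
```

Reading the numbers: the scatterer-loaded gel keeps photons in the phantom
(mean pathlength 35 mm against the 20-mm height; absorbed fraction 0.27
versus 0.20 for the blank), which lifts the fluence throughout the beam
column — a laterally averaged entry-region gain of 1.38× at this modest
loading, with 89% of the valid volume above E = 1. The thermal solve then
turns the absorbed-power map of the combined gel into the ΔT traces a
four-thermocouple rig would record over 20 minutes.

The published reference statistics are one-liners:

```r
synergy_coefficient(9.04, 5.38, 2.6)
#> <synergy_result> S = 1.1328 (synergistic): 9.04 / (5.38 + 2.6)
round(ld50_fold_reduction(143, 34), 1)
#> [1] 4.2
```

Scenario files (YAML or JSON) and a thin command-line front end are also
provided; see `?load_scenario` and `inst/cli/photonheat.R`.

## Documentation

The methods vignette (`vignettes/photothermal-simulation.Rmd`) describes the
transport and thermal models, the estimators, the default parameters and
their provenance, numerical choices, and known limitations.
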