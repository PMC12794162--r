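# pmmspectra

Ensemble UV–vis absorption spectra of a chromophore in a fluctuating
electrostatic environment, by the Perturbed Matrix Method (PMM).

## The problem

Flavoproteins tune the absorption spectrum of their flavin cofactor:
in fatty acid photodecarboxylase the first band of the oxidized FAD sits
~23 nm to the red of lumiflavin in water, and the cofactor adopts an
unusual "butterfly-bent" ring conformation. Is the red shift caused by
the bend, or by the electrostatics of the binding pocket?

`pmmspectra` implements the MD–PMM analysis that answers such questions.
Per trajectory frame, the perturbed electronic Hamiltonian of the quantum
center (QC) is built in the basis of its gas-phase eigenstates,

```
H[j,j'] = δ(j,j') · (ε_j + q·V)  −  Σ_α E_α · μ_α[j,j']        (atomic units)
```

with `V`, `E` the environment's potential and field at the QC expansion
point, and diagonalized to give perturbed transition energies ν and
dipoles μ₀ₙ. Transitions are histogrammed in frequency space and each bin
contributes a Gaussian to the extinction coefficient,

```
ε₀ₙ(ν) ∝ Σ_ref  |μ₀ₙ|²_ref · (η_ref/N) · ν · exp(−(ν−ν_ref)²/2σ²) / (σ√2π)
```

with an empirical 0.94 scaling of all energies (in eV) before conversion
to wavelength. Frames are classified by the C4–N5–N10–C9 bending dihedral
d₁ into planar / partially-bent / bent basins (|d₁| thresholds 6° and
12°), each basin gets its own electronic reference (B1/B3/B5), basin
spectra are weighted by the basin populations, and the package reports
the main peak positions, relative intensities, and the decomposition of
the first-band shift into conformational and electrostatic parts. A
synthetic-data module replaces the MD engine and the quantum-chemistry
code: fluctuating point-charge shells with a controllable ensemble-mean
field, a three-well bending process with configurable basin weights
(default 27/44/29%), and flavin-like 11-state electronic references.

The package is tidyverse-native: functions take data frames first and
return tibbles, fitted objects have `tidy()`/`glance()` methods and
`autoplot()` plots.

## Worked example

Tune the ensemble-mean field, by first-order Stark theory on the B1
reference, to produce a +21 nm red shift of the first band, then run the
whole analysis on a 1000-frame synthetic ensemble:

```r
library(pmmspectra)

s <- make_flavin_like_states("B1", 436.2, 342.8, 0.76, seed = 1)
field <- mean_field_for_shift(s, 21)
cfg <- generator_config(seed = 1, n_frames = 1000, mean_field_target = field)
rep <- run_apo_analysis(cfg)
rep
#> <apo_report>
#>   basins: planar 28%, partially_bent 44%, bent 28%
#>   weighted peaks: lambda1 = 486 nm, lambda2 = 375 nm, I_rel = 0.76
#>   shift decomposition: conformational +2 nm, electrostatic +20 nm (total +22 nm)
#>   seed 1, config 7387148a1bfcf718a5be33534e8aeec8
rep$decomposition
#> # A tibble: 6 × 2
#>   quantity             value_nm
#> 1 lambda1_planar_gas     464.
#> 2 lambda1_weighted_gas   466.
#> 3 lambda1_weighted_pmm   486.
#> 4 conformational_shift     1.94
#> 5 electrostatic_shift     19.9
#> 6 total_shift             21.8
```

Reading the output: with zero mean field the weighted peaks would match
the population-weighted gas-phase bands (the ~2 nm conformational term:
bending barely moves the peaks); the injected field accounts for the
remaining ~20 nm — the electrostatic term recovered within the
sampling/grid resolution of the tuned +21 nm. `autoplot(rep$weighted_spectrum)`
draws the spectrum; `run_counterfactual()` re-runs the analysis with a
residue's charges edited (e.g. an arginine neutralized, +1 → 0) on the
same frames and reports the resulting peak shifts.

The bundled tables `reference_gas_phase_conformers()`,
`reference_pmm_peaks()` and `reference_experimental_peaks()` carry the
published band positions for lumiflavin in the photodecarboxylase; the
same weighting operation applied to them reproduces the published
"MD-weighted" rows (438/344 nm gas phase, 459/352 nm PMM) and the
2 / 21 / 16 / 23 nm shift ledger.

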