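---
title: "Ensemble absorption spectra by the Perturbed Matrix Method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble absorption spectra by the Perturbed Matrix Method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmmspectra)
```

## The model

`pmmspectra` computes the UV-vis absorption spectrum of a chromophore (the
"quantum center", QC) embedded in a fluctuating classical environment, in
the Perturbed Matrix Method (PMM) framework. The flavin chromophore of
fatty acid photodecarboxylase is the motivating system: its lumiflavin
moiety absorbs ~20 nm to the red of lumiflavin in water, and the analysis
implemented here separates how much of that shift comes from the
"butterfly" bending of the isoalloxazine ring and how much from the
electrostatics of the binding pocket.

The QC is described by a fixed basis of gas-phase electronic eigenstates
$\Phi_j^0$: energies $\epsilon_j$, permanent dipoles
$\mu_{jj}$, and ground-to-excited transition dipoles $\mu_{0j}$ (all in
atomic units; excited-to-excited transition dipoles are excluded from the
model because their contribution to the absorption spectrum is
negligible, and fixtures carrying them fail validation). At each
trajectory frame the environment exerts a potential $V$ and field
$\mathbf{E}$ at the QC expansion point, and the perturbed Hamiltonian

$$ H_{jj'} \;=\; \delta_{jj'}\,(\epsilon_j + qV)\;-\;\sum_{\alpha\in xyz}
   E_\alpha\,\mu_{\alpha,jj'} $$

is diagonalized, yielding perturbed transition energies $\nu_{0n}$ and
transition dipoles $\tilde\mu_{0n} = c_0^T \mu\, c_n$. Short-range
(non-electrostatic) corrections are deliberately omitted - the model is
purely electrostatic and the API leaves no hook for them. The
Born-Oppenheimer bookkeeping is encoded in the basin-to-reference map: each
conformational basin is assigned one fixed electronic reference, never
interpolated.

Two conventions are assumptions rather than established facts of the
workflow the package emulates: the dipole matrices are taken to be
computed with origin at the QC center of mass (the same expansion point at
which $V$ and $\mathbf{E}$ are evaluated), and the perturbation sums use a
direct Coulomb sum over the environment charges provided, with no
periodic-boundary/Ewald treatment (an optional inclusion cutoff is
exposed; the default includes every atom supplied).

## Spectrum assembly

Per transition $n$, the perturbed energies are histogrammed in frequency
space and each occupied interval contributes a Gaussian:

$$ \epsilon_{0,n}(\nu) \;\propto\; \sum_{\nu_{ref}}
   \overline{|\mu_{0,n}|^2}_{\nu_{ref}}\;
   \frac{\eta(\nu_{ref})}{N}\;\nu\;
   \frac{e^{-(\nu-\nu_{ref})^2/2\sigma^2}}{\sigma\sqrt{2\pi}} $$

with $\eta$ the interval's frame count, $N$ the total frame count and
$\sigma$ the broadening produced by the neglected semiclassical
vibrations. Absolute prefactors ($1/6\epsilon_0 c\hbar^2$, Planck's
constant) are folded into one arbitrary-units constant because every
comparison the package supports is of peak positions and relative
intensities, never absolute extinction.

Numerical choices worth knowing:

* **$\sigma$ = 0.001 Hartree** by default (about 0.027 eV). The working
  energy unit of the method is the Hartree; the parameter is configurable.
* **Bin width** defaults to $\sigma/5$ so that binning never dominates the
  broadening. The reference frequency of each bin is the *dipole-weighted
  mean* frame energy in the bin, not the geometric center; with that
  choice the integrated extinction $\int \epsilon\, d\nu =
  \sum_i |\mu_i|^2 \nu_i / N$ is exactly independent of the bin width
  (binning is a density estimate, not a truncation).
* **Energy scaling**: the empirical factor 0.94 multiplies all energies in
  eV before Gaussian placement. It calibrates the first computed band of
  lumiflavin in water onto the measured one; it moves positions only and
  cancels in relative intensities.
* **Peak finding** works on the raw grid (no smoothing) with strict
  neighbor comparison, the default grid step of 0.002 eV keeping the
  wavelength resolution below 0.5 nm over the 300-550 nm reporting
  window; equal-height ties resolve toward lower energy. $\lambda_1$ is
  the red-most of the two highest maxima and
  $I_{rel}=h(\lambda_2)/h(\lambda_1)$; that orientation makes $I_{rel}$
  grow as the ring bends, matching how the second band behaves.
* **Degeneracies**: eigenvalues are sorted ascending and each
  eigenvector's largest-magnitude component is made positive, so repeated
  runs are bit-identical even through level crossings.

## Conformational analysis

The bending coordinate $d_1$ is the C4-N5-N10-C9 dihedral. Frames are
classified by $|d_1|$ into planar ($<6^\circ$), partially bent
($6$-$12^\circ$, boundaries included) and bent ($>12^\circ$) basins; the
magnitude is used because the basins are defined on bending amplitude and
the sign only carries the pucker direction. Essential dynamics is a PCA of
the $3N\times 3N$ covariance of ring-atom positional fluctuations after
least-squares superposition on the mean structure (iterated to
self-consistency); superposition is the standard essential-dynamics
convention even where not spelled out, and the coordinates are unweighted
(no mass weighting) - a documented choice, since the original procedure's
weighting is unstated. Projections are in coordinate units (nm), which is
what makes the first-mode projection values of the representative
conformers directly comparable across analyses.

## What the synthetic generators emulate

The package replaces the MD engine and the quantum-chemistry code with
generators whose defaults are the study conditions:

* `make_flavin_like_states()` builds an 11-state reference (ground + 10
  excited) whose two bright bands sit at requested wavelengths with a
  requested intensity ratio; the B1/B3/B5 defaults anchor to the gas-phase
  conformer table bundled in `reference_gas_phase_conformers()`. The
  permanent-dipole difference of the first transition is fixed at
  $(3.0, 0.6, 0)$ a.u. (~7.7 D, the upper end of measured flavin
  excited-state dipole changes); with a realistic but large $\Delta\mu$
  the ensemble fields required for spectroscopically relevant shifts act
  in the linear-response regime, which is what makes first-order Stark
  tuning (`mean_field_for_shift()`) an accurate control knob.
* `make_environment()` produces shells of fictitious fluctuating point
  charges (default: 120 charges of up to 0.1 e between 0.6 and 2.5 nm,
  0.02 nm frame jitter). A fixed two-charge bias layer with zero potential
  contribution at the QC point is added so the ensemble-mean field equals
  the requested target exactly (the bias compensates the sample mean of
  the random part). The charges are statistical stand-ins, not
  force-field values.
* `make_bending_series()` draws $d_1$ from a three-Gaussian mixture
  (centers 2/9/16 degrees, common width 1.2 degrees, weights
  0.27/0.44/0.29 - the observed basin populations) and bends an idealized
  planar three-ring template about the N5-N10 hinge. The template is an
  idealization in one important respect: in the real fused-ring geometry
  the planar C4-N5-N10-C9 pseudo-torsion is 180 degrees and the butterfly
  bend is its supplement, whereas the bend angle is conventionally
  reported with planar = 0. The template's atoms are laid out so the raw
  signed torsion *equals* the bend angle, keeping one coordinate
  convention throughout. Only the atom-name topology matches the real
  chromophore.

Passing tests on these generators therefore demonstrate the statistical
and algebraic correctness of the machinery - Coulomb sums, Stark response,
binning, weighting, classification - not agreement with real protein
electrostatics: the synthetic charges have no chemistry, the bending wells
are exactly Gaussian, and the electronic references are low-rank
caricatures of a TD-DFT calculation.

## Worked decomposition

The analysis that motivated the package decomposes the first-band red
shift of the protein-bound flavin into a conformational and an
electrostatic part using three numbers: the planar gas-phase band, the
population-weighted gas-phase band, and the population-weighted PMM band.
With the bundled reference tables:

```{r decomposition}
pops <- reference_basin_populations()
gas <- reference_gas_phase_conformers()
gas3 <- gas[match(c("B1", "B3", "B5"), gas$conformer), ]
wg <- weighted_peak_average(setNames(gas3$lambda1_nm, names(pops)), pops)
pmm <- reference_pmm_peaks()
round(wg)                                              # weighted gas: 438 nm
pmm$lambda1_nm[pmm$system == "md_weighted"]            # weighted PMM: 459 nm
round(wg) - pmm$lambda1_nm[pmm$system == "planar_gas"] # conformational: 2 nm
459 - round(wg)                                        # electrostatic: 21 nm
```

The same operations run on fully synthetic ensembles in
`run_apo_analysis()`, and `run_counterfactual()` repeats the analysis with
a residue's charges edited (e.g. an arginine neutralized), sharing frames
and basin labels between the two arms so the reported peak shifts isolate
the purely electrostatic effect of the edit.

## Problem sizes and determinism

The shipped tests and the acceptance script use 100&nbsp;000-frame dihedral
series for population recovery, 5000-frame ensembles for the end-to-end
Stark-shift recovery, and a few hundred to a few thousand frames
elsewhere - sizes at which every sampling check has comfortable margin
while a complete run stays in the minutes range on one core. Every
generator is a pure function of its configuration and seed, every report
embeds the seed and a configuration hash, and eigenvector sign and
tie-break conventions are deterministic, so identical inputs give
byte-identical outputs.

## Known limitations

* Purely electrostatic perturbation: no short-range/orbital-overlap
  effects, so strong specific interactions (e.g. an anion hydrogen-bonded
  to the ring) are outside the model's validity - they require an explicit
  quantum treatment.
* No periodic-boundary treatment of the perturbation sums; inputs are
  whatever charge set the caller (or generator) supplies.
* Absolute extinction is not calibrated; only positions and relative
  intensities are meaningful.
* Basin classification is threshold-based on $|d_1|$; trajectories with
  slow pucker-sign dynamics are collapsed onto the amplitude.
* The quadratic Stark contribution is not included in
  `mean_field_for_shift()`; at fields strong enough that
  $\mathbf{E}\cdot\mu_{01}$ approaches the level spacing the tuning
  under-delivers and the full diagonalization should be trusted instead.
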