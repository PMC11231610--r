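---
title: "spinbind: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spinbind: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinbind)
```

This vignette is the package's own account of the science it implements:
the spectroscopic forward model, the decomposition and thermodynamic
chain, the synthetic-data generator, and the numerical and design choices
a maintainer would want to know about. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The three-state picture

A DOXYL-labelled stearic acid mixed with a fatty acid binding protein
(FABP) populates three spectroscopically distinguishable states: free in
solution, intermediately (loosely) bound at the protein surface or portal
region, and strongly bound inside the β-barrel. Their CW EPR signatures
differ chiefly through the rotational correlation time τ_c (≈ 0.1 ns,
≈ 5 ns and ≈ 18–22 ns respectively at 37 °C) and, more subtly, through
the isotropic ¹⁴N hyperfine coupling a_iso, which acts as a polarity
sensor. A measured spectrum is treated as a weighted superposition of the
three single-state spectra; the weights Φ_x, read off as double-integral
shares, are proportional to the number of spins in each state and are the
quantitative link to binding thermodynamics.

## Forward model

Each component is an S = 1/2 electron coupled to one I = 1 nucleus, with
rhombic g and hyperfine tensors (fixture defaults g = (2.0083, 2.0061,
2.0022); A′_xx = A′_yy = 15.5 MHz with A′_zz absorbing changes of a_iso,
since A′_zz dominates the isotropic mean). Isotropic means are always
derived from tensors, never stored.

**Fast engine** (τ_c ≤ 0.5 ns in `engine = "auto"`). Three derivative
Lorentzian lines at the first-order positions B(m_I) = hν/(g_iso μ_B) −
m_I·a_iso (converted to field units), with peak-to-peak widths
ΔB(m_I) = A + B·m_I + C·m_I² from the standard motional-narrowing
(Redfield/Kivelson) coefficients built from the g- and A-tensor
anisotropies, B₀ and τ_c, including the nonsecular spectral densities
j(ω_e) = τ_c/(1 + ω_e²τ_c²). For nitroxide-typical tensors the B
coefficient is negative, so the high-field (m_I = −1) line is broadest —
the familiar asymmetric damping of the fast-motion triplet. Lines are
evaluated as exact bin averages (difference quotients of the absorption
antiderivative) so that double integrals are accurate on coarse grids.

**Slow engine.** A documented partial-anisotropy-averaging lineshape
rather than a stochastic-Liouville solver: a fraction
S(τ_c) = τ_c²/(τ_c² + τ₀²), τ₀ = 3 ns, of the tensor anisotropy is
retained and powder-averaged over orientations (Gauss–Legendre in cos β ×
uniform φ, 60 × 36 by default; the hyperfine frame may be tilted by Euler
angles, fixtures use (0°, 50°, 0°) for the bound states), while the
averaged fraction (1 − S) contributes motional broadening through the
same Redfield coefficients. Sticks are convolved with a unit-mass
absorption Lorentzian and differentiated numerically, which conserves the
double integral by construction. The engine's fidelity contract — rather
than bit-exactness against any particular slow-motion solver — is what
the tests pin down: agreement with the fast engine within 5 % RMS of the
peak-to-peak amplitude at τ_c ≤ 0.3 ns, convergence of the outer-extrema
splitting to 2·A′_zz within 2 % at τ_c ≥ 1 µs, monotone central-line
broadening over τ_c = 0.1–30 ns, and per-component double-integral
conservation. The same forward model generates the synthetic data and
serves as the decomposition basis, so downstream results do not depend on
which slow-motion approximation is used as long as both sides share it.

Heisenberg exchange (2.7 MHz on the intermediate component only, fixture
default) is applied as a uniform extra Lorentzian broadening — the
low-exchange regime; a full line-mixing exchange operator is out of
scope. Field modulation (0.1 mT experimentally) is small against the
linewidths and is **not** convolved by default; `modAmpMT` enables an
arcsine-kernel pseudo-modulation. Residual broadenings follow the
simulation conventions for these systems: Gaussian 0.135 mT
(peak-to-peak) on the free component, Lorentzian 0.1 mT on the strong
component. Whether those literature values are peak-to-peak or FWHM is
not stated; peak-to-peak is assumed throughout.

**Acquisition grid.** The packaged field window is 332.5–342.5 mT. The
default microwave frequency is 9.47 GHz: X-band benchtop spectrometers
run anywhere in ≈ 9.4–9.5 GHz, and 9.47 GHz centres the nitroxide triplet
on this window (at exactly 9.40 GHz the spectrum sits at ≈ 334.8 mT and
its low-field powder wing clips the window edge). The default axis has
4096 points, the digitization such instruments use for a 10 mT sweep;
this samples the ≈ 0.1 mT lines with ~40 points. A truncation check
raises a window error when more than 5 % of the absorption mass sits in
the outermost 2 % of the window or the absorption fails to return to
baseline at the high-field edge; the 5 % default tolerates the slight,
physically real clipping of rigid-limit wings on the experimental window.

## Decomposition

`fitWeights()` solves a nonnegative least-squares problem
(`pracma::lsqnonneg`) over the unit-spins-normalized component spectra
plus an additive linear baseline (offset + slope, entered as ± column
pairs so its sign is free). One global scale factor absorbs the
experimental amplitude; the spectrum is normalized by its peak-to-peak
amplitude rather than its double integral, because the double integral of
a noisy derivative trace is dominated by accumulated low-frequency noise.
Fractions are the double-integral shares of the fitted scaled components
— identical to the solver weights for unit-normalized components, and
invariant to rescaling any component together with its weight.

Uncertainties follow the Φ ± RMSD% reporting rule: the fit RMSD, as a
percentage of the spectrum's peak-to-peak amplitude (the normalization is
an assumption — the convention's reference amplitude is not defined in
the literature), is attached to every fraction as an absolute error and
clipped to [0, 1]. Degenerate designs (condition number > 10⁶) emit a
warning carrying the condition number, and weight shared by numerically
indistinguishable components is pushed onto the smallest-τ_c member —
conservative with respect to claiming strong binding. Refinement of τ_c
and/or A′_zz is opt-in and bounded to ±15 % around the library values
(L-BFGS-B wrapping the linear solve) to keep the fit identifiable.

**Accuracy and its limit.** With white noise the NNLS solution is the
maximum-likelihood estimator, and its scatter tracks the Cramér–Rao bound
of the component design. The intermediate and strong basis spectra are
intrinsically similar (correlation ≈ 0.8 on the packaged axis), so at low
SNR the bound itself is large: at SNR 20 (noise SD = 5 % of the
peak-to-peak amplitude) the per-fraction information bound for the
intermediate/strong pair is ≈ 0.05–0.07, and no estimator can do better.
The test suite therefore asserts the median recovery accuracy across SNR
regimes, and the acceptance suite reports the 95th-percentile band
honestly — at SNR 20 it exceeds the nominal 0.06 target for exactly this
reason. Noise-free decompositions invert the forward model to numerical
precision.

## Thermodynamics

Every transition is modelled with the same 1:1 mass action — the
deliberate simplification used for these systems:
K_D = [P_free][L_free]/[PL] with [PL] = Φ_bound·c_L and
[P_free] = c_P − [PL]; the inverse (bound fraction from K_D) is the exact
quadratic root, and the pair round-trips to 10⁻⁹. Gibbs energies use the
van't Hoff relation ΔG = −R·T·ln K_A (R = 8.314 J mol⁻¹ K⁻¹). EPR-derived
tables are evaluated at 310.15 K (37 °C); MST-derived quantities at
295.15 K (22 °C) — note the MST experiments themselves run at 25 °C, but
295.15 K is the temperature at which the published K_A → ΔG chain
back-calculates exactly, so that convention is kept and flagged. The
caveats of the shared 1:1 form (intermediate binding of multiple ligands,
cooperativity, aggregation effects) are inherited by every derived
number.

The intermediate→strong transition is dimensionless, K_IS = [S]/[I], and
its ΔG is reported along two routes: directly from K_IS, and as the chain
difference ΔG(F-S) − ΔG(F-I). The two coincide only if all three
fractions obey one consistent scheme; the package reports both rather
than forcing agreement, because published tables of this analysis contain
I-S values that are not reproducible from their own F-S and F-I rows.
First-order error propagation (σ_KD = |∂K_D/∂Φ|·σ_Φ, σ_lnKA = σ_KD/K_D,
σ_ΔG = R·T·σ_lnKA) is validated against a finite-difference oracle.

## Binding curves and apparent K′_D

Four models are supported, with the exact parameterizations frozen in the
code documentation: Hill θ(c) = θ_max·cⁿ/(Kⁿ + cⁿ); Bi-Hill as a
fractional split of two Hill terms; Bi-Dose-Response (two logistics in
log₁₀ c) and Double Boltzmann (two logistics in c), both following the
common plotting-software forms with two centres, two slopes and a
fractional amplitude split, baseline fixed at zero. Fits are weighted
least squares (`minpack.lm::nls.lm`) with five deterministic multi-starts
(jittered around a data-driven start; the jitter is a fixed function of
the start index so the global RNG stream is untouched) and
Jacobian-based standard errors. "50 % / 75 % of the totally bound
component" is read as the **absolute** bound fraction 0.50 / 0.75 of
total ligand — not a percentage of the fitted plateau — located by
bracketing and bisection on the fitted curve; curves whose plateau never
reaches the requested level raise an unattainable-level error, matching
real curves that never reach 75 %. No plateau-detection logic is
attempted for intermediate shoulders: their reliability is questionable
at these point densities.

## Temperature series

Per-temperature decompositions are assembled into a Φ_x(T) table (sorted,
duplicates averaged). The total double integral is taken from the fitted
model trace with the baseline removed — the raw double integral of a
noisy trace is a poor spin-count estimate — and normalized to the lowest
analyzed temperature ≥ 273.15 K; frozen-solution rows below 0 °C are
retained but flagged out of the analysis (powder-type spectra, low SNR).
The intermediate-state maximum is located on the grid and refined by
quadratic interpolation through the three neighbouring points; edge
maxima are returned uninterpolated with a warning, and exact ties break
to the lower temperature.

High-temperature classification uses two double-integral/fraction rules,
with thresholds exposed in the configuration: *release* when Φ_free rises
by ≥ 0.15 between 323.15 K and the top temperature while the total double
integral stays ≥ 70 % of its reference; *trap_destroy* when the integral
falls below 50 % with a free-fraction rise < 0.10; otherwise
*dynamics_only*. The thresholds are package defaults chosen to separate
the generator presets cleanly — the underlying phenomenology is described
only qualitatively in the literature — and because only ratios enter, the
classification is invariant to uniform intensity rescaling.

## MST

F_norm is the cold/hot window ratio of the fluorescence trace (cold = the
last 1 s before the IR laser switches on, hot = a 0.2 s window centred at
1.5 s after heating starts; the vendor software's exact windows are not
public, so these are package conventions — the fitted K_D does not depend
on them). The 1:1 isotherm uses the exact quadratic bound fraction at
finite labelled-ligand concentration (80 nM default) and fits baseline
and amplitude as nuisance parameters, making the fit invariant to affine
transformations of raw F_norm. K_D is parameterized on the log scale; the
68 % confidence range comes from the parameter covariance. Replicate
scatter is pooled into a single noise level before weighting: with
duplicate measurements the per-concentration SD has one degree of freedom
and weighting by it degrades the estimator badly. A series whose top
concentration lies below the fitted K_D gets a plateau warning and a
widened (doubled) interval.

## Synthetic-data generator

The generator emulates the study design, not any particular instrument
artifact: ligand fixed at 20 µM; protein at 200, 100, 50, 35, 25, 20, 15,
10 and 5 µM plus a protein-free reference; temperature series over
273.15–363.15 K in 5 K steps; MST as a 12-point twofold dilution from
200 µM at 80 nM ligand, in duplicate. Ground truth is the simplest
structure consistent with the three-state picture: total binding follows
1:1 mass action with the effective dissociation constant
K_I/(1 + K_IS), bound ligand splits as Φ_S/Φ_I = K_IS, and a plateau
factor caps the maximal bound fraction (the sub-unity saturation seen for
FABP5-like systems, preset 0.948). Temperature enters through two-state
van't Hoff weighting, ΔG_x(T) = ΔH_x − T·ΔS_x, anchored at 310.15 K. The
preset enthalpies (ΔH_I = −110 kJ/mol for the association,
ΔH_IS = −40 kJ/mol for I→S in the release-type presets) are *effective*
parameters that lump binding enthalpy with thermal destabilization of the
protein; they are chosen once so that, at 100 µM protein, the strong
state dominates near 0 °C, the intermediate fraction peaks in the 35–45
°C range, and the free fraction rises at high temperature — and they are
documented as package choices, not as published values. The destroy
preset additionally decays the total intensity linearly above 328 K to
30 % (radical loss in the denaturing protein). Noise is additive white
Gaussian on the derivative trace with SNR defined as peak-to-peak
amplitude over noise SD; a fixed seed yields byte-identical datasets, and
the generator saves and restores the caller's RNG state.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: baseline drifts and field offsets beyond a
linear baseline, microwave-power saturation, aggregation-dependent
affinity shifts, a possible fourth spectral component at some
temperatures, spin-probe micelle formation, and instrument-specific
modulation distortion. Recovery results on synthetic data are therefore
statements about the estimator under the model's own assumptions.

## Sequences and hydropathy

Kyte–Doolittle hydropathy and Zimmermann polarity are computed as
whole-sequence sums and as centred moving averages (ProtScale-style,
uniform weights, odd windows; window 1 reproduces the raw values). Totals
include the initiator methionine — canonical sequences are used as-is.
The packaged FABP FASTA is a literature transcription rather than a
database export (`fabpSequenceFile()` documents this): the landmark
residues stated for these proteins (the FABP3 anchor triad
Arg106/Arg126/Tyr128 and the Thr36→Ala36 cavity difference against FABP4
in mature-chain numbering; the FABP5 Cys120–Cys127 pair) all verify, but
a few interior residues may deviate from the canonical database entries,
and whole-sequence sums inherit that uncertainty — the acceptance report
carries the computed values without adjustment.

## Numerical choices, degenerate inputs, sizes

* Field axes must be strictly increasing and uniform for simulation;
  readers sort descending axes with a warning and report the line number
  of any malformed cell.
* Mixture weights must be ≥ 0 and sum to 1 within 10⁻⁹; decomposition
  results enforce a weight sum of 1 within 10⁻⁶.
* Zero intermediate with nonzero strong population makes K_IS undefined
  and raises an error; absent components give NA rows, mirroring report
  tables whose empty fields cannot be calculated.
* Temperature series need ≥ 4 analyzable temperatures and classification
  requires coverage to ≥ 333.15 K.
* Test and acceptance problem sizes are chosen for the statistics they
  need: 100 seeds for recovery rates, 20 seeds per classification preset,
  2048–4096-point axes; the full suite and the acceptance script each run
  in well under a minute of compute per block.
* The component simulation cache keys on all physical parameters plus the
  axis, so repeated fits against one library cost one simulation.

## Known limitations

The slow-motion engine is an interpolating approximation: it honours the
fidelity contract above but is not a stochastic-Liouville solution, and
intermediate-regime lineshape details (τ_c ≈ 1–10 ns) are approximate in
ways the contract does not constrain. Anisotropic diffusion, ordering
potentials (MOMD/SRLS) and microwave saturation are out of scope. The
thermodynamic chain inherits the 1:1 mass-action simplification for every
transition; no ΔH/ΔS decomposition across temperature is attempted.
Intermediate/strong separation at low SNR is information-limited, as
quantified above. Hydropathy totals depend on transcribed sequences as
described.
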