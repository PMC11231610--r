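# spinbind

Ligand-perspective analysis of fatty-acid binding to the human transport
proteins FABP3, FABP4 and FABP5, as seen by continuous-wave EPR of
spin-labelled stearic acids (5-DSA / 16-DSA) and by microscale
thermophoresis (MST).

Fatty acid binding proteins are ~15 kDa β-barrels that shuttle
long-chain fatty acids through the cytosol. When a DOXYL-labelled stearic
acid is mixed with an FABP, its CW EPR spectrum splits into three
overlapping nitroxide components that report the ligand's rotational
dynamics: **free** ligand tumbling in solution (τ\_c ≈ 0.1 ns),
**intermediately bound** ligand loosely attached to the protein surface or
portal region (τ\_c ≈ 5 ns), and **strongly bound** ligand immobilized in
the β-barrel cavity (τ\_c ≈ 18–22 ns). `spinbind` implements the whole
quantitative chain from spectra to thermodynamics:

1. **Forward simulation** of first-derivative nitroxide spectra
   (S = 1/2, I = 1) across motional regimes: a fast-motion
   (Redfield/Kivelson) engine with line widths
   ΔB(m\_I) = A + B·m\_I + C·m\_I², and a slow-motion engine based on
   partial anisotropy averaging that converges to the rigid powder limit
   (outer splitting 2·A′\_zz).
2. **Spectral decomposition**: nonnegative least squares of a measured
   spectrum against simulated components, component fractions Φ\_x from
   double-integral shares, uncertainties as Φ ± RMSD% of the
   peak-to-peak amplitude, and optional bounded refinement of τ\_c and
   A′\_zz.
3. **Binding thermodynamics**: mass-action dissociation constants from
   bound fractions, K\_D = [P\_free]·[L\_free]/[PL], for the transitions
   free→total-bound (F-T), free→intermediate (F-I), free→strong (F-S),
   and the population ratio K\_IS = [S]/[I]; Gibbs energies from the
   van't Hoff relation ΔG = −R·T·ln K\_A with first-order error
   propagation.
4. **Binding curves**: Hill, Bi-Hill, Bi-Dose-Response and Double
   Boltzmann fits of Φ\_bound versus protein concentration, with apparent
   K′\_D read-outs at 50 % and 75 % absolute bound fraction.
5. **Temperature series**: Φ\_x(T) assembly, the interior maximum of the
   intermediate state near physiological temperature, and classification
   of high-temperature behaviour into ligand *release*,
   *trap-and-destruction* (radical signal loss), or *dynamics-only*.
6. **MST**: F\_norm extraction from fluorescence traces and the exact 1:1
   isotherm fit for K\_D with a 68 % confidence range.
7. **Sequence hydropathy**: Kyte–Doolittle and Zimmermann-polarity totals
   and ProtScale-style sliding-window profiles.

A seeded synthetic-data generator (`truthParams()`,
`synthConcentrationSeries()`, `synthTemperatureSeries()`,
`synthMstSeries()`) reproduces the statistical structure the analysis
assumes — three-state mass action in concentration, van't Hoff weighting
in temperature — so every pipeline stage is testable without instrument
data.

## Worked example

Decompose a synthetic 100 µM FABP3 / 20 µM 5-DSA spectrum and derive the
transition thermodynamics at 37 °C:

```r
library(spinbind)

lib   <- fabpComponents("FABP3", "5-DSA")     # free / intermediate / strong
B     <- defaultFieldAxis()                   # 332.5-342.5 mT, 4096 points
truth <- truthFractions(100, 20, truthParams(preset = "fabp3_like"))
trace <- simulateMixture(lib, truth, B)

fit <- fitWeights(trace, lib)
fit
#> DecompositionResult:
#>   Phi_free = 0.0237 +/- 0.0000
#>   Phi_intermediate = 0.7340 +/- 0.0000
#>   Phi_strong = 0.2422 +/- 0.0000
#>   RMSD = 0.00% of peak-to-peak amplitude

equilibriumConstantsThreeState(100, 20, componentWeights(fit),
                               temperatureK = 310.15)
#>   transition  KD_uM KA_perM  lnKA dG_kJ_mol K_IS dG_chain_kJ_mol
#> 1        F-T   1.95  511538 13.15    -33.90   NA              NA
#> 2        F-I  30.91   32350 10.38    -26.78   NA              NA
#> 3        F-S 297.67    3359  8.12    -20.94   NA              NA
#> 4        I-S     NA      NA -1.11      2.86 0.33            5.84
```

Reading the table: total binding (F-T) is strongly exergonic
(ΔG ≈ −34 kJ/mol, K\_D ≈ 2 µM), surface attachment (F-I) is preferred
over direct strong binding (F-S), and the intermediate→strong transition
(I-S) is endergonic at 37 °C — the loosely attached state is the
thermodynamically active one. The I-S row carries two estimates
(population-ratio route and the F-S − F-I chain); they coincide only when
all three fractions obey one consistent mass-action scheme.

The same chain runs on files: `readSpectrumCsv()` /
`readSpectrumJcamp()` for spectra, `readFastaSequences()` for sequences,
and `runPipeline(config, command)` (or the thin wrapper in
`inst/scripts/spinbind.R`) for staged `synth` → `fit` → `thermo` →
`bindcurve` / `tempseries` / `mst` / `hydropathy` runs with CSV/JSON
artifacts.

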