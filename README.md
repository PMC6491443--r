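# chromotune

Colour-tuning analysis of the retinal chromophore in microbial rhodopsins,
written for spectroscopists and protein engineers working on red-shifted
ion-pump variants (the sodium pump KR2 and relatives are the motivating
system).

The absorption maximum λ_max of a rhodopsin is set by the S0→S1 energy gap
ΔE of its protonated retinal Schiff base. Because the chromophore's positive
charge sits at the Schiff base in S0 but delocalises toward the β-ionone
ring in S1, the electrostatics of the binding pocket tune the gap
residue-by-residue: a negative pole near the Schiff base stabilises S0
(blue-shift), one near the ring stabilises S1 (red-shift). Sterics act
through the backbone: lower bond-length alternation
(BLA = mean single-bond − mean double-bond length) means more conjugation
and a red-shift, and the C=C stretch frequency tracks λ_max linearly
(≈ −70 cm⁻¹ per +270 nm).

The package implements the desk-scale side of that analysis:

- **Spectral arithmetic** — shifts on the wavenumber scale
  (Δν = 10⁷/λ_var − 10⁷/λ_ref), additivity analysis of combined mutants,
  the ν_C=C correlation model, unit conversions (nm, cm⁻¹, kcal/mol).
- **Chromophore geometry** — bond lengths, BLA and dihedral distortions of
  the conjugated chain C5…C15=N from PDB coordinates, with
  variant-vs-reference difference tables.
- **Electrostatic tuning** — a two-state point-charge Coulomb surrogate for
  the electrostatic part of ΔE (E = Σ k_e q_a q_s / r), decomposition of
  printed (protein, vacuum) energy tables with consistency flagging, and
  per-residue charge-off attribution ΔE − ΔE_off with direct/indirect
  classification between models.
- **Photocycle kinetics** — closed-form sequential-chain concentrations,
  transient-absorption simulation, SVD denoising and global
  multi-exponential fitting by variable projection, reporting the slowest
  lifetime as the photocycle turnover.
- **Assay analysis** — λ_max from hydroxylamine-bleach difference spectra
  (Gaussian fit in the wavenumber domain) and relative ion-transport
  activity from initial slopes of light-induced pH traces.
- **Synthetic data** — deterministic generators for every input: toy
  retinal structures with exact BLA/twist targets, dipole point-charge
  environments, spectra, pH traces and transient-absorption matrices.

## Worked example

```r
library(chromotune)

bands <- spectral_bands(c("KR2 WT", "P219T", "S254A", "P219T/S254A"),
                        c(525, 542, 545, 565))
sh <- shift_table(bands, "KR2 WT")
sh
#>   reference_label variant_label delta_nm delta_wavenumber delta_wavenumber_int
#> 1 KR2 WT          P219T               17            -597.                 -597
#> 2 KR2 WT          S254A               20            -699.                 -699
#> 3 KR2 WT          P219T/S254A         40           -1349.                -1349
```

The two single-mutant shifts (−597 and −699 cm⁻¹) nearly sum to the double
mutant's −1349 cm⁻¹: `additivity()` reports `predicted_sum_int = -1296` and
`deviation_int = -53`, the signature of mutations acting independently on
the two ends of the chromophore.

Bookkeeping on a printed excitation-energy table splits each variant's gap
into geometric (vacuum) and electrostatic parts:

```r
decompose_printed(make_table1())
#>   label       dE_protein dE_vacuum dE_electrostatic delta_electrostatic
#> 1 KR2 WT            55.2      43.1             12.1                NA
#> 2 P219G             54.3      43.8             10.5               -1.6
#> 3 P219T             53.5      44.5              9.0               -3.1
#> 4 S254A             53.1      43.6              9.5               -2.6
#> 5 P219T/S254A       51.5      45.9              5.6               -6.5
```

The geometry changes alone blue-shift (vacuum energies rise), but the
electrostatic term red-shifts more, dominating the net effect —
strongest in the double mutant (−6.5 kcal/mol). `check_printed_deltas()`
flags parenthetical values that do not match recomputation (two vacuum
deltas in this table are off by 0.1 kcal/mol).

Photocycle turnover from simulated flash-photolysis data:

```r
fit <- global_fit(svd_denoise(make_ta(seed = 1), 4), 4)
fit
#> Global photocycle fit: 4 exponentials
#>   lifetimes (s): 2.98e-05 (+/- 1.3e-07), 0.000301 (+/- 4.1e-07),
#>                  0.000993 (+/- 1.4e-06), 0.00482 (+/- 3.5e-06)
#>   turnover 0.00482 s, residual RMS 6.71e-05 AU
```

The four generating lifetimes (30 µs, 300 µs, 1 ms, 4.8 ms) are recovered;
the slowest is the ground-state-recovery (turnover) time. And the bleach
assay recovers an absorption maximum to well under a nanometre:

```r
sp <- make_spectrum_pair(lambda_max = 542, seed = 1)
bleach_difference(sp$before, sp$after)
#> Bleach difference fit: lambda_max = 542.0 nm (+/- 0.04 nm)
```

`tidy()`, `glance()` and `autoplot()` methods are provided for the fitted
objects, and `plot_shift_table()` / `plot_charge_off()` for the tabular
results.

## Documentation

The methods vignette (`vignettes/colour-tuning-methods.Rmd`) documents the
models, default parameters, numerical choices and known limitations,
including exactly what the synthetic-data generators do and do not emulate.
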