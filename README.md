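# quenchbind

Analysis of small-molecule binding to serum albumin from steady-state
fluorescence quenching titrations and companion spectroscopies, with a
synthetic-data generator that makes every stage verifiable against known
ground truth.

Serum albumin carries most drugs in plasma, so the affinity and mode of a
ligand's albumin binding determine its free concentration and
pharmacokinetics. The standard label-free workup titrates the ligand into a
fixed protein solution (typically 5 µM BSA, ligand at molar ratios 0–6,
three temperatures) and reads the binding out of the quenching of intrinsic
tryptophan fluorescence. `quenchbind` implements that complete chain:

* **Inner-filter correction** — F<sub>cor</sub> = F<sub>obs</sub> ·
  10^((A<sub>ex</sub>+A<sub>em</sub>)/2)
* **Stern–Volmer fit** — F₀/F = 1 + K<sub>SV</sub>[Q], with
  k<sub>q</sub> = K<sub>SV</sub>/τ₀ (τ₀ = 10⁻⁸ s), and static/dynamic
  mechanism classification from the K<sub>SV</sub> temperature trend and
  the 2×10¹⁰ L mol⁻¹ s⁻¹ collisional ceiling
* **Double-log binding fit** — log₁₀((F₀−F)/F) = log₁₀K<sub>b</sub> +
  n·log₁₀[Q]
* **Van't Hoff thermodynamics** — ln K<sub>b</sub> = −ΔH/RT + ΔS/R,
  ΔG = −RT·ln K<sub>b</sub>, with Ross–Subramanian force typing
* **FRET** — overlap integral J = ΣFελ⁴Δλ / ΣFΔλ, Förster radius
  R₀⁶ = 8.8×10⁻²⁵ k² N⁻⁴ Φ J, efficiency E = 1 − F/F₀ and distance
  r = R₀((1−E)/E)^(1/6) with validity flags
* **CD helicity** — MRE = CD(mdeg)/(10·n·l·C<sub>p</sub>);
  α(%) = (−MRE₂₀₈ − 4000)/29000 × 100
* **Synchronous-fluorescence peak shifts** (Δλ = 15/60 nm), **site-marker
  competition** (warfarin/ibuprofen displacement) and
  **multidrug-resistance reversal folds** (RF = IC₅₀ alone / IC₅₀ combo)

See `vignettes/albumin-binding.Rmd` for the methods in full.

## Worked example

Simulate a three-temperature study for an exothermic static binder
(K<sub>b</sub> = 7.8×10⁴ L mol⁻¹, n = 1.08, ΔH = −38 kJ mol⁻¹,
ΔS = −38.1 J mol⁻¹ K⁻¹) and run the analysis:

```r
library(quenchbind)

truth <- ground_truth(kb = 7.8e4, n = 1.08, delta_H = -38e3, delta_S = -38.1)
study <- simulate_temperature_series(truth)
fits_sv <- lapply(study$titrations, stern_volmer_fit)
fits_dl <- lapply(study$titrations, double_log_fit)

fits_dl[["289"]]
#> <binding fit: log Kb = 4.878 (Kb = 7.56e+04 L/mol), n = 1.080, R2 = 1.0000>

classify_mechanism(fits_sv)
#> <quenching mechanism: static >
#>   - Ksv decreases with temperature (static signature)
#>   - all kq > 2.0e+10 L/mol/s diffusion limit (static signature)

thermo_params(default_temperatures(),
              vapply(fits_dl, `[[`, numeric(1), "kb"))
#> <thermodynamics: dH = -38.00 kJ/mol, dS = -38.10 J/mol/K, dG(297 K) = -26.68 kJ/mol, vdw_hbond>
```

The binding fit recovers the log K<sub>b</sub> the forward model used at
289 K (ΔH < 0 makes K<sub>b</sub>(289) = 7.56×10⁴ rather than the nominal
`kb`), the mechanism call shows both static-quenching signatures, and the
Van't Hoff regression returns the generating ΔH and ΔS exactly on
noise-free data. FRET and CD stages work the same way:

```r
donor <- gaussian_band(340, 60, 1000, seq(290, 450, 1))
acceptor <- simulate_absorbance(350, 50, 1.2e4, 3e-5, seq(300, 400, 1))
tr <- study$titrations[["297"]]
fret_analysis(donor, acceptor, 3e-5,
              F_quenched = tail(tr$intensity, 1), F0 = tr$intensity[1])
#> <FRET: J = 1.14e-14 cm^3 L/mol, R0 = 2.50 nm, E = 39.2%, r = 2.70 nm>
#>   flags: in_2_8_nm_range = TRUE, within_half_to_1p5_R0 = TRUE, r_greater_than_R0 = TRUE

helix_change(simulate_cd(0.5861), simulate_cd(0.6417))$delta
#> [1] 5.56
```

A file-based end-to-end run — per-temperature fits, mechanism,
thermodynamics, FRET, CD and site-marker competition with per-stage
failure isolation — is available via `simulate_study()` + `run_study()`,
with JSON/CSV serialisation through `write_study_report()`.

Reference measurements for seven kaempferol glycoside–BSA systems
(binding/thermodynamic table, energy-transfer parameters, reversal-fold
IC₅₀ pairs, site-marker constants, helicities) ship as in-code data frames:
`bsa_binding_reference()`, `fret_reference()`, `mdr_reversal_reference()`,
`site_marker_reference()`, `helicity_reference()`.

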