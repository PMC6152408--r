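---
title: "Characterising ligand-serum-albumin binding from quenching spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising ligand-serum-albumin binding from quenching spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

## The problem

Serum albumin is the main carrier protein of blood plasma; how tightly a
small molecule binds it controls the free drug fraction and hence
distribution and elimination. Bovine serum albumin (BSA, 583 residues, two
tryptophans) is the standard model protein for such measurements. The
binding is usually characterised without labels by titrating the ligand
into a fixed protein solution and following the quenching of the intrinsic
tryptophan fluorescence (excitation 280 nm, emission maximum near 340 nm),
plus companion synchronous-fluorescence, circular dichroism (CD) and
absorbance measurements.

`quenchbind` implements the complete analysis chain for such a study, and a
synthetic-data generator that produces every input with known ground truth
so each stage can be validated end to end.

## Models and procedures

### Inner-filter correction

Absorbing ligand attenuates both the excitation beam and the emitted light.
Observed intensities are corrected with the standard half-path factor

$$F_\mathrm{cor} = F_\mathrm{obs}\,10^{(A_\mathrm{ex}+A_\mathrm{em})/2},$$

where $A_\mathrm{ex}$ and $A_\mathrm{em}$ are the solution absorbances at
the excitation and emission wavelengths for each titration point
(`inner_filter_correct()`). All downstream fits refuse uncorrected series
that carry absorbance columns, which prevents both silent omission and
double correction.

### Stern-Volmer and double-logarithmic fits

Quenching is quantified by ordinary least squares of

$$F_0/F = 1 + K_\mathrm{SV}[Q] = 1 + k_q\tau_0[Q]$$

against the added quencher concentration $[Q]$ over the non-zero titration
points (`stern_volmer_fit()`). $F_0$ is the measured ligand-free intensity,
not a fitted parameter; the intercept is left free so the reported $R^2$
reflects the actual line. The bimolecular quenching constant is
$k_q = K_\mathrm{SV}/\tau_0$ with the unquenched fluorophore lifetime
$\tau_0 = 10^{-8}$ s.

Binding constant and stoichiometry come from the double-logarithmic plot

$$\log_{10}\frac{F_0-F}{F} = \log_{10}K_b + n\,\log_{10}[Q],$$

fit by `double_log_fit()`. $[Q]$ is the total added ligand concentration
(no free-ligand correction), matching how such titrations are almost always
plotted; points with $F \ge F_0$ carry no quenching signal and are dropped
with a warning. Intensities are taken as peak heights at the emission
maximum.

Note that the intercept sits several $\log_{10}$ units of extrapolation
away from the sampled $[Q]$ window (micromolar ligand, intercept at 1 M),
so even sub-percent intensity noise propagates into a few hundredths of a
log unit on $\log_{10}K_b$ — the package's noise tests assert the measured
repeated-draw spread rather than a nominal figure.

### Quenching mechanism

`classify_mechanism()` applies the two standard diagnostics across
temperatures: static (ground-state complex) quenching shows
$K_\mathrm{SV}$ decreasing with temperature, and $k_q$ far above the
diffusion-limited collisional ceiling of $2\times10^{10}$ L mol$^{-1}$
s$^{-1}$. Both rules firing yields `static`, neither `dynamic`; a strictly
increasing $K_\mathrm{SV}$ combined with an above-ceiling $k_q$ is a
genuine conflict and is reported as `ambiguous` with both rule firings
listed, rather than silently resolved. (Systems whose $K_b$ rises with
temperature while $K_\mathrm{SV}$ falls do occur; the classifier reports
its evidence instead of adjudicating such tensions.)

### Thermodynamics and binding forces

`vant_hoff()` regresses $\ln K_b$ on $1/T$:
$\ln K_b = -\Delta H/(RT) + \Delta S/R$, $R = 8.314$ J mol$^{-1}$
K$^{-1}$, and `gibbs()` evaluates $\Delta G = -RT\ln K_b$.
`classify_forces()` applies the Ross-Subramanian sign rules
($\Delta H>0,\Delta S>0$: hydrophobic; both negative: van der Waals +
hydrogen bonds; $\Delta H<0,\Delta S>0$: electrostatic; the remaining
quadrant is `unclassified`). The reference temperature for reported
$\Delta G$ defaults to 297 K, the middle of the usual 289/297/307 K
design. Be aware that $\Delta H$ and $\Delta S$ recomputed from binding
constants rounded to two significant figures can differ substantially from
values obtained from unrounded fits — with three temperatures the Van't
Hoff slope is very sensitive to rounding of the individual $K_b$.

### FRET distance estimation

The overlap integral of donor emission $F(\lambda)$ and acceptor molar
absorptivity $\varepsilon(\lambda)$,

$$J = \frac{\sum F(\lambda)\,\varepsilon(\lambda)\,\lambda^4\,\Delta\lambda}
           {\sum F(\lambda)\,\Delta\lambda},$$

is evaluated by `overlap_integral()` as a discrete Riemann sum on the
merged overlap grid, with $\lambda$ in cm so $J$ carries the conventional
cm$^3$ L mol$^{-1}$ unit (trapezoidal weights are available via
`method = "trapezoid"`; on 1 nm instrument grids the two agree to well
under 0.1%). The Forster radius follows from
$R_0^6 = 8.8\times10^{-25}\,k^2 N^{-4}\Phi J$ (cm$^6$), with isotropic
orientation factor $k^2 = 2/3$ and tryptophan-in-albumin quantum yield
$\Phi = 0.118$. The default refractive index is $N = 1.336$ (aqueous
buffer): this value reproduces reference Forster radii computed from
published overlap integrals to the printed 0.01 nm, whereas the
occasionally quoted 1.366 does not, and is therefore treated as the
correct default (it remains configurable).

Transfer efficiency is $E = 1 - F/F_0$, taken by convention at the highest
titration point (1:6 protein:ligand), and the donor-acceptor distance is
$r = R_0((1-E)/E)^{1/6}$. `fret_analysis()` composes the stages and flags
the standard validity conditions ($2 \le r \le 8$ nm,
$0.5R_0 < r < 1.5R_0$, and $r > R_0$, the last consistent with static
quenching).

### CD helicity

`mean_residue_ellipticity()` normalises the 208 nm CD signal,
$\mathrm{MRE} = \mathrm{CD(mdeg)}/(10\,n\,l\,C_p)$, and `helix_percent()`
maps it linearly between the 208 nm anchors of a random-coil/beta form
($-4000$) and a pure helix ($-33000$):
$\alpha(\%) = (-\mathrm{MRE}_{208} - 4000)/29000 \times 100$. The signal
at exactly 208 nm is obtained by linear interpolation between bracketing
grid points (CD spectra are typically sampled at 1 nm). Values are not
clamped; estimates outside 0-100% are flagged instead, since they indicate
a normalisation or pathlength problem worth surfacing. The cell path
enters in cm (a 1 mm cell is `path_cm = 0.1`), which is the only
convention under which the $10\,n\,l\,C_p$ denominator has its usual
units.

### Synchronous shifts, site markers, reversal folds

`synchronous_shift()` tracks the emission maximum of synchronous scans
($\Delta\lambda = 15$ nm probes tyrosines, 60 nm tryptophans) using
3-point parabolic refinement around the discrete maximum, and calls a
red/blue/unchanged verdict with a 1 nm tolerance, about one instrument
step. `competitive_site_assignment()` compares $\log_{10}K_b$ measured
alone and in the presence of warfarin (site I) and ibuprofen (site II); a
marker competes when it depresses $\log_{10}K_b$ by more than 0.05 — well
above fit noise at typical $R^2 \ge 0.99$, well below real displacement
effects — and the primary site is the marker with the larger depression.
`reversal_fold()` computes the multidrug-resistance reversal potency
RF = IC$_{50}$(cytotoxic drug alone)/IC$_{50}$(drug + modulator); IC$_{50}$
estimation itself is routine dose-response fitting and is out of scope.

## The synthetic-data generator

`ground_truth()` fixes a forward model: static
$F = F_0/(1 + K_b[Q]^n)$ (so $(F_0-F)/F = K_b[Q]^n$ identically) or
collisional $F = F_0/(1 + K_\mathrm{SV}[Q])$; Van't Hoff temperature
dependence $K_b(T) = \exp(-\Delta H/RT + \Delta S/R)$; optional
inner-filter attenuation with recorded per-point absorbances; additive
Gaussian intensity noise of constant sd under a stored seed (constant sd is
the simplest model consistent with the near-unity $R^2$ of real titrations
of this kind). Defaults mirror the standard study design: 5 uM protein,
ligand at molar ratios 0-6 (0-30 uM), temperatures 289/297/307 K,
$K_b$ near $5\times10^4$ L mol$^{-1}$ with $n \approx 1$, exothermic
binding with negative entropy, 58.61% native helicity, and an $F_0$ of
1000 a.u. (emission intensity scales are instrument-arbitrary).
`simulate_cd()` constructs a two-lobe (208/222 nm) helix-like trace whose
208 nm mean residue ellipticity equals $-(4000 + 29000\alpha)$ exactly;
`simulate_absorbance()` produces Beer-Lambert acceptor spectra;
`simulate_study()` writes a complete study (three titrations, donor and
acceptor spectra, free/complex CD pair, ground-truth YAML) as CSVs.

The generator emulates the statistical structure the analysis assumes —
exact binding laws plus homoscedastic noise. It deliberately omits
photobleaching, scatter, baseline drift and ligand depletion, so passing
round-trip tests demonstrates correctness of the estimators, not
robustness to every instrument artifact of real data.

## Worked example

```{r example}
truth <- ground_truth(kb = 7.8e4, n = 1.08, delta_H = -38e3,
                      delta_S = -38.1)
study <- simulate_temperature_series(truth)
fits_sv <- lapply(study$titrations, stern_volmer_fit)
fits_dl <- lapply(study$titrations, double_log_fit)
classify_mechanism(fits_sv)
thermo_params(default_temperatures(),
              vapply(fits_dl, `[[`, numeric(1), "kb"))
```

The full pipeline, including FRET, CD and failure-isolated stage reports,
is available through `run_study()`; see `?run_study` and the README.

## Numerical choices and limitations

* Fits use ordinary least squares (`stats::lm`); $R^2$ is computed
  directly from residuals (a constant response fitted by a constant is
  reported as $R^2 = 1$).
* `resample()` is strictly interpolation-only; requests outside the
  measured range error rather than extrapolate.
* Peak localisation assumes locally uniform grid spacing around the
  maximum; boundary maxima are returned without refinement.
* All wavelength interfaces are in nm; the cm conversion happens only
  inside the overlap integral.
* Test and example problem sizes (7-8 point titrations, 1 nm spectral
  grids, 20-seed noise panels) are the sizes of the real experimental
  design; everything runs in seconds.
* The package analyses summaries it is given: it does not fit fluorescence
  lifetimes, deconvolve CD into full secondary structure, estimate
  orientation factors, or model free-vs-total ligand.
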