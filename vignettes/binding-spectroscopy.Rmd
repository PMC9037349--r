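---
title: "Methods: spectroscopic analysis of protein-ligand binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectroscopic analysis of protein-ligand binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbind)
```

## The problem

When a small ligand binds a fluorescent protein, the protein's intrinsic
(tryptophan) emission is quenched. A titration of the ligand into a fixed
protein concentration, read at several temperatures, carries enough
information to estimate how strongly the ligand binds, how many sites it
occupies, what thermodynamic forces drive the association, whether the
quenching reflects a ground-state complex or collisional encounters, and -
with the ligand's absorption spectrum - how far the ligand sits from the
emitting fluorophore. `specbind` implements that entire analysis chain for
steady-state fluorescence, circular dichroism (CD), and Förster resonance
energy transfer (FRET) data, plus a synthetic-data generator that emulates
the instrument output the chain consumes.

The package was built around a camel-milk lactoferrin / theaflavin
monogallate system (5 µM protein excited at 280 nm, emission 290-450 nm
peaking at 335 nm, ligand titrated 0-15 µM at 298/303/308 K), and the
generator's defaults reproduce that design; every stage is generic over its
inputs.

## Models and procedures

### Inner-filter correction

Absorbing samples attenuate both the excitation beam and the emitted light.
Measured intensities are corrected multiplicatively,

$$F_c = F \, e^{(A_{ex}+A_{em})/2},$$

from the absorbances at the excitation and emission wavelengths. The base-e
form is the default; a base-10 variant (`inner_filter_base = "ten"`) is
provided because both conventions circulate in the literature. With both
absorbances zero the correction is the identity.

### Stern-Volmer quenching

With $F_o$ the unquenched and $F$ the quenched intensity,
$F_o/F = 1 + K_{SV}[Q]$ is fit by ordinary least squares; the slope is the
Stern-Volmer constant $K_{SV}$ (M$^{-1}$). The default fit leaves the
intercept free as a quality check (dilution or uncorrected inner-filter
effects push it away from 1); `sv_intercept = "fixed"` constrains it. The
bimolecular quenching rate constant is $k_q = K_{SV}/\tau_0$ with
$\tau_0 = 5.78\times10^{-9}$ s the unquenched fluorophore lifetime, a
supplied constant (the package does no lifetime fitting).

Quenching mode is classified from two criteria: $k_q$ above the maximum
diffusion-limited collisional constant $2\times10^{10}$ M$^{-1}$s$^{-1}$
(strict inequality, at every temperature) rules out purely dynamic
quenching, and the temperature trend of $K_{SV}$ (strictly decreasing for
static, strictly increasing for dynamic) supplies independent evidence. Only
when both criteria agree is a verdict of static or dynamic returned;
anything else - including a single temperature, where the trend is
unavailable - is `inconclusive`, with the evidence string reporting both
criteria.

### Binding constant and stoichiometry

For static quenching through $n$ equivalent sites,
$\log_{10}\frac{F_o-F}{F} = \log_{10}K_a + n\log_{10}[Q]$. The package fits
this double-log line by OLS over the nonzero-concentration points; points
with $F \ge F_o$ have no defined left side and are excluded with a warning.
Base-10 logarithms are used throughout (the slope is base-invariant; the
intercept is interpreted as $\log_{10}K_a$). Free ligand is approximated by
total ligand, as the double-log method itself assumes.

### How the scalar F is read

All quenching-stage fits consume one scalar intensity per titration point.
Because the quench model scales the emission band uniformly (the analysis
assumes quenching without band-shape change, which the studied system
exhibits), any shape-invariant functional of the spectrum gives identical
$F$ ratios. The default (`intensity_metric = "band_integral"`) integrates
the whole band by the trapezoidal rule: on noise-free data this is exactly
equivalent to a single-wavelength read, and on noisy data it pools the
independent per-wavelength errors (about an 8-fold noise reduction on a
160-point grid). Reading at the fixed wavelength of the unquenched
spectrum's maximum remains available (`intensity_metric = "peak"`); we made
the integral the default after quantifying that single-wavelength reads make
the double-log estimate of $K_a$ extremely variable - the fitted intercept
sits several log units outside the sampled concentration range, so percent-
level intensity noise turns into tens of percent in $K_a$.

### van't Hoff thermodynamics

$\ln K_a$ against $1/T$ is fit by unweighted OLS over at least three
distinct temperatures: $\Delta H = -\mathrm{slope}\cdot R$ and
$\Delta S = \mathrm{intercept}\cdot R$, with $R = 1.987$ cal mol$^{-1}$
K$^{-1}$; $\Delta H$ is reported in kcal mol$^{-1}$ and $\Delta S$ in cal
mol$^{-1}$ K$^{-1}$, the conventional mixed units. At each input temperature
$\Delta G = \Delta H - T\Delta S$ holds as an exact identity of the returned
table. The sign pattern classifies the dominant force: $(+,+)$ hydrophobic,
$(-,+)$ electrostatic, $(-,-)$ hydrogen bonds / van der Waals; zeros count
as positive (with a message), and $(+,-)$ is outside the rule set and
errors. A utility converts free energies to affinities via
$K = e^{-\Delta G/RT}$ (default 298 K when the source states none).

### CD secondary structure

Observed ellipticity (mdeg) converts to mean residue ellipticity,
$\mathrm{MRE} = \theta/(10\,C_p\,n\,l)$, with $C_p$ the molar protein
concentration, $n$ the residue count, and $l$ the path length in cm. The
α-helix fraction uses the single-wavelength 208 nm estimator,

$$\alpha\% = 100\,\frac{-\mathrm{MRE}_{208} - 4000}{33000 - 4000},$$

anchored at $-4000$ (random coil / β) and $-33000$ (pure helix). MRE at
exactly 208 nm is obtained by linear interpolation on the grid; estimates
pushed outside $[0, 100]$ by noise are clipped with a warning rather than
erroring. No multi-basis deconvolution is attempted: the estimator is
deliberately the linear single-wavelength one.

### FRET

The overlap integral
$J = \int F(\lambda)\,\varepsilon(\lambda)\,\lambda^4\,d\lambda \big/ \int F(\lambda)\,d\lambda$
is computed by trapezoidal integration after interpolating the acceptor
molar absorptivity onto the donor grid, restricted to the overlapping
support (no extrapolation - tails invented beyond either spectrum would
silently inflate J). Wavelength enters the $\lambda^4$ term in cm, so with
$\varepsilon$ in M$^{-1}$cm$^{-1}$, $J$ carries M$^{-1}$cm$^3$ - the unit
convention under which the prefactor of
$R_0^6 = 8.79\times10^{-25}K^2 n^{-4}\phi J$ (cm$^6$) reproduces Förster
radii of a few nm from $J \approx 10^{-14}$. Transfer efficiency is
$E = 1 - F/F_o$ and the donor-acceptor distance
$r = R_0\left((1-E)/E\right)^{1/6}$, so $(E, R_0, r)$ triples returned by
the package always satisfy $E = R_0^6/(R_0^6 + r^6)$.

Defaults: $K^2 = 2/3$ (isotropic dipole averaging; never estimated from
structure), refractive index 1.336, donor quantum yield 0.118. In the
pipeline, $F$ for the efficiency is taken at the titration point closest to
equimolar quencher:protein unless the caller designates one.

Documented inconsistencies we do not reproduce: for this system the
literature reports $J = 1.20\times10^{-14}$ M$^{-1}$cm$^3$ together with
$R_0 = 2.54$ nm, $E = 49.6\%$ and $r = 2.44$ nm. Direct evaluation of the
$R_0$ formula on that $J$ gives 2.527 nm (a ~0.5% rounding gap), and the
reported $(E, R_0, r)$ triple is not self-consistent: $E = 49.6\%$ with
$R_0 = 2.54$ nm implies $r \approx 2.55$ nm, not 2.44. Likewise the
reported $k_q$ at 298 K (1.25e13) differs ~1% from the exact quotient
$K_{SV}/\tau_0$ = 1.239e13, and a docking energy of $-9.7$ kcal mol$^{-1}$
converts to $K \approx 1.3\times10^7$, not the $2.03\times10^6$ quoted
alongside it. The package computes the self-consistent values in every case.

## The synthetic-data generator

`generator_spec()` fixes the forward model:

- **Emission**: a Gaussian band (centre 335 nm, σ = 20 nm, amplitude 100) on
  a 290-450 nm, 1 nm grid. Real tryptophan bands are asymmetric, but the
  analysis consumes only peak values and band integrals, for which a
  Gaussian is adequate.
- **Quenching**: `static_binding` scales the band by $1/(1+K_a[Q]^n)$ - the
  model under which the double-log fit is exact - or `linear_sv` by
  $1/(1+K_{SV}[Q])$ for Stern-Volmer-specific tests. The two coincide at
  $n = 1$, $K_a = K_{SV}$.
- **Thermodynamics**: when the `thermo` block is set (default
  $\Delta H = 20.25$ kcal mol$^{-1}$, $\Delta S = 89.13$ cal mol$^{-1}$
  K$^{-1}$), $K_a(T)$ satisfies the van't Hoff relation exactly before
  noise, so the downstream fit must recover the generating pair.
- **Inner filter**: optional absorbance ramps proportional to $[Q]$ whose
  attenuation is applied to the "measured" spectra, so the correction stage
  must undo it.
- **CD**: two negative Gaussian bands at 208/222 nm scaled so the 208 nm MRE
  equals the inverted helix estimator at the target α%.
- **Acceptor**: a Gaussian absorptivity band (centre 370 nm, σ = 40 nm,
  peak $10^4$ M$^{-1}$cm$^{-1}$); because $J$ is linear in the acceptor
  amplitude, `generate_fret_pair(target_J =)` calibrates the amplitude to
  any target exactly. A rectangular-band option exists purely for
  closed-form oracle checks.
- **Noise**: multiplicative Gaussian per wavelength sample, parameterised by
  a coefficient of variation (default 1%, a realistic photomultiplier
  scale), one RNG stream per series, bit-reproducible under a fixed seed.

What the generator does *not* emulate: band asymmetry and solvent Raman
peaks, wavelength-dependent instrument response, ligand depletion (free
ligand is approximated by total, as in the analysis itself), dilution over
the titration, and baseline drift. Passing tests therefore demonstrate
correctness of the estimators under the stated models, not robustness to
every artefact of real instruments.

## Numerical choices and problem sizes

- OLS fits use `stats::lm`; $R^2$ is computed directly from residuals.
- Trapezoidal integration (`pracma::trapz`) and linear interpolation
  (`stats::approx`) everywhere; no splines, no extrapolation.
- Wavelengths are stored in nm in every object; conversion to cm happens
  only inside the overlap integral. Concentrations are molar internally;
  manifests may declare µM and are converted on read.
- Spectrum files are two-column delimited text written with 17 significant
  digits, so write/read round trips are exact.
- Degenerate inputs: constant intensities yield a flagged zero-slope
  Stern-Volmer result rather than an error; $F \ge F_o$ points are dropped
  from the double-log fit; efficiency exactly 0 or 1 has no finite distance
  and errors.
- Test and validation runs use the 7-point, 3-temperature design with
  100-seed Monte Carlo repetitions for the noise calibration; all suites
  complete in well under a minute.

## Known limitations

- $\tau_0$, $K^2$, $\phi$ and the refractive index are always supplied
  constants; none is estimated from data.
- No combined static+dynamic (sphere-of-action) quenching model, no
  heat-capacity term in the van't Hoff fit, no global nonlinear fit across
  temperatures.
- The helix estimator is the linear 208 nm one; β-sheet and turn content are
  out of scope.
- The saturation point of an ANS displacement titration is defined as the
  endpoint of the first titration step whose intensity change falls below
  the tolerance (default 1% of $F_o$, an instrument-noise scale); coarser
  titrations shift it by construction.
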