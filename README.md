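# specbind

Analysis of steady-state spectroscopic protein–ligand binding experiments:
fluorescence quenching titrations, binding thermodynamics, circular
dichroism (CD) secondary structure, and Förster resonance energy transfer
(FRET). The package is aimed at biophysics and food-chemistry labs that
titrate a ligand into an intrinsically fluorescent protein and want the
complete parameter chain — K_SV, k_q, K_a, n, ΔH, ΔS, ΔG, α-helix %, J, R0,
E, r — from plain-text instrument exports, with every fit logged and
testable against synthetic data.

## The models

For a quencher Q titrated into protein at fixed concentration:

- **Inner-filter correction** — F_c = F·e^((A_ex+A_em)/2) from the sample
  absorbances at the excitation and emission wavelengths.
- **Stern–Volmer** — F_o/F = 1 + K_SV[Q]; the bimolecular quenching rate
  constant k_q = K_SV/τ0 against the diffusion limit (2×10¹⁰ M⁻¹s⁻¹),
  combined with the temperature trend of K_SV, classifies quenching as
  static or dynamic.
- **Modified Stern–Volmer** — log10((F_o−F)/F) = log10(K_a) + n·log10[Q]
  gives the association constant and binding-site count.
- **van't Hoff** — ln K_a vs 1/T gives ΔH (−slope·R) and ΔS (intercept·R);
  ΔG = ΔH − TΔS, and the (ΔH, ΔS) sign pattern names the dominant force
  (hydrophobic / electrostatic / H-bond+van der Waals).
- **CD** — MRE = θ/(10·C_p·n·l); α-helix % = 100·(−MRE₂₀₈ − 4000)/29000.
- **FRET** — J = ∫F(λ)ε(λ)λ⁴dλ / ∫F(λ)dλ (M⁻¹cm³);
  R0⁶ = 8.79×10⁻²⁵·K²·n⁻⁴·φ·J; E = 1 − F/F_o; r = R0·((1−E)/E)^(1/6).

A synthetic-data module generates titration series, donor/acceptor spectral
pairs, and CD traces from the same forward models (plus multiplicative
instrument noise), so the whole chain is testable without instrument data.

## Worked example

```r
library(specbind)

gs   <- generator_spec(seed = 42)          # 5 uM protein, 0-15 uM ligand,
fam  <- generate_thermo_family(gs)         # 298/303/308 K, 1% noise
pair <- generate_fret_pair(gs, target_J = 1.2e-14)
rep  <- run_pipeline(pipeline_config(), fam,
                     donor_emission      = pair$donor,
                     acceptor_absorption = pair$acceptor,
                     cd_spectra = list(generate_cd(gs, 32.04),
                                       generate_cd(gs, 33.04)))
rep
```

```
<binding_report>

table_quenching:
 temperature_K Ksv_per_M kq_per_M_s sv_r_squared Ka_per_M n_sites
           298     70778 1.2245e+13      0.99958    43034 0.95485
           303    124406 2.1524e+13      0.99962    72592 0.95123
           308    214646 3.7136e+13      0.99961   130741 0.95500
 bind_r_squared         mode
        0.99998 inconclusive
        0.99998 inconclusive
        1.00000 inconclusive

table_thermo:
 temperature_K dH_kcal_mol dS_cal_mol_K TdS_kcal_mol dG_kcal_mol  force_type
           298      20.258       89.152       26.567     -6.3097 hydrophobic
           303      20.258       89.152       27.013     -6.7555 hydrophobic
           308      20.258       89.152       27.459     -7.2012 hydrophobic

table_fret:
 J_M_cm3  R0_nm   r_nm E_percent
 1.2e-14 2.5271 2.9792     27.14
```

Reading it: each temperature's Stern–Volmer constant (Ksv_per_M, the slope
of F_o/F vs [Q]) converts to a quenching rate constant k_q three orders of
magnitude above the diffusion limit, so the quenching cannot be purely
collisional; the generator's K_a(T) was built on the van't Hoff line
(ΔH = 20.25 kcal/mol, ΔS = 89.13 cal/mol/K) and the fit recovers it to
~0.03% despite the 1% intensity noise. Both ΔH and ΔS are positive —
entropy-driven, hydrophobic association, spontaneous at every temperature
(ΔG < 0). In this generated family K_a rises with temperature, so the K_SV
trend criterion reports `inconclusive` rather than forcing a static call.
The FRET block turns the calibrated overlap integral into a Förster radius
of 2.53 nm and a donor–acceptor distance of 2.98 nm at the equimolar point.

The same stages are scriptable from a shell via the bundled CLI
(`inst/cli/specbind`): subcommands `simulate`, `quench`, `bind`, `thermo`,
`cd`, `fret`, and `report`, each emitting a delimited table.

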