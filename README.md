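# reorient

Tools for characterizing molecular reorientations — methyl-group jumps in
particular — in amorphous and recrystallizing organic solids, from two
complementary experiments:

* **¹H spin–lattice relaxometry**: the temperature dependence of the
  relaxation time T₁ is decomposed into a sum of
  Bloembergen–Purcell–Pound (BPP) processes, each with an Arrhenius
  correlation time, to extract activation energies of individual
  reorientations;
* **quasielastic neutron scattering (QENS)**: S(Q, ω) spectra are fitted
  with the three-site jump model for methyl rotation — or, for disordered
  solids, with a log-normal distribution of jump rates — after numerical
  convolution with the instrument resolution, yielding correlation times
  and their distribution.

A third component follows **recrystallization kinetics**: saturation-recovery
traces that turn bi-exponential as a crystalline phase grows are fitted,
the component amplitudes converted to phase fractions, and the time to
complete recrystallization estimated.

The package is aimed at solid-state NMR / neutron-scattering practitioners
studying amorphous pharmaceuticals and similar molecular glasses. Because
such datasets are rarely deposited, a first-class synthetic-data module
generates every input type from known ground truth, so the whole chain is
validated by parameter recovery.

## Models

**BPP relaxation.** Each thermally activated reorientation contributes

    1/T1 = C [ τc/(1 + ω₀²τc²) + 4τc/(1 + 4ω₀²τc²) ],   τc = τ₀ exp(EA/RT)

with ω₀ the Larmor angular frequency. Rates of independent processes add.
A single process passes through a T₁ minimum where ω₀τc ≈ 0.616 (the
maximizer of x/(1+x²) + 4x/(1+4x²)), which `t1_minimum_condition()`
computes numerically.

**Saturation recovery.** One phase recovers as
Mz(t) = M₀(1 − e^(−t/T₁)); a two-phase sample recovers bi-exponentially,
and the amplitudes M₀¹, M₀² are proportional to the proton counts — hence
phase fractions — of the two phases.

**Three-site jumps (QENS).**

    S(Q,ω) = A e^(−⟨u²⟩Q²) { [c + (1−c)A₀(Q)] δ(ω) + (1−c)(1−A₀(Q)) L(ω;Γ) } ⊗ R(Q,ω)

with EISF A₀(Q) = ⅓[1 + 2 j₀(Qr√3)], immobile fraction c, Debye–Waller
factor e^(−⟨u²⟩Q²), a unit-area Lorentzian L of HWHM Γ, and instrument
resolution R. The rate-distribution variant replaces L with a mixture of
L = 21 Lorentzians log-spaced over ln Γ̄ ± s√(2 ln(1/A_min)) (A_min = 0.1)
with log-normal weights, and Γ converts to a correlation time via
τc = ħ/Γ.

## Worked example

```r
library(reorient)

# --- relaxometry: simulate the packaged six-process amorphous scenario
model <- amorphous_t1_scenario()          # EAs 7.8, 6.8, 5.4, 4.4, 3.7, 3.0 kJ/mol
curve <- generate_t1_curve(model$processes, 25,
                           seq(20, 300, length.out = 60),
                           noise_spec(relative_sd = 0.02, seed = 7))
fit <- fit_relaxation(curve, 6, seed = 7,
                      share = list(groups = c(1, rep(2, 5)),
                                   tau0 = TRUE, strength = TRUE))
fit
#> BPP relaxation fit: 6 process(es), weighted RSS = 37.59, converged
#> Arrhenius process [high-T]: tau0 = 5.25e-12 s, EA = 7.83 kJ/mol, C = 2.19e+09 s^-2
#> Arrhenius process [low-T 5]: tau0 = 7.94e-13 s, EA = 6.95 kJ/mol, C = 4.53e+08 s^-2
#> ...
predict_minimum_temperature(fit$model$processes[[1]], 25)
#> [1] 142.4   # K: the high-temperature T1 minimum of the fitted process
```

Every activation energy is recovered within a few percent of the
generating values, and the fitted high-temperature process places its T₁
minimum at 142 K, as built into the scenario.

```r
# --- QENS: rate-distribution spectra and their refit
inst <- instrument_config(q_values = seq(0.3, 1.8, length.out = 6))
truth <- rate_distribution_model(gamma_center = 0.16, sigma_log = 1.0,
                                 immobile_fraction = 12/18, msd = 0.05)
spectra <- generate_qens_spectrum(truth, inst, noise_spec(0.02, 7))
qfit <- fit_distribution(spectra, generate_resolution(inst), seed = 7)
qfit
#> Rate-distribution fit: Gamma_center = 0.158 meV, s = 1.040, c = 0.662,
#>   <u^2> = 1.33 A^2, RSS = 128.8 (single-Gamma RSS 479.1)
tau_distribution(qfit$model)$summary
#> tau mode 4.17 ps, span 0.45-38.78 ps
```

The distribution fit recovers the center half-width and width s of the
rate distribution, its residual beats the nested single-Lorentzian fit
(128.8 vs 479.1), and the implied correlation-time distribution peaks
near 4 ps. (⟨u²⟩ is reported but poorly identified when per-Q amplitudes
are free; see the vignette.)

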