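---
title: "Modelling molecular reorientations: BPP relaxometry, recovery kinetics and QENS jump models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling molecular reorientations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reorient)
```

This vignette documents the models implemented in `reorient`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
choices that matter when reproducing or extending the analyses.

## The scientific problem

Amorphous (melt-quenched) molecular solids — amorphous drugs in
particular — differ from their crystalline forms in the dynamics of their
methyl groups and side chains, and they spontaneously recrystallize over
days to months. Two observables track this:

* the ¹H spin–lattice relaxation time T₁ as a function of temperature,
  whose minima locate reorientations with rates near the Larmor
  frequency; and
* quasielastic neutron scattering, where stochastic hydrogen motion
  broadens the elastic line on the ps timescale.

Both are modelled here for the motion that dominates in
methyl-bearing organics: jump rotation of CH₃ groups among three
equivalent sites.

## BPP relaxation with Arrhenius correlation times

Each reorientation contributes a rate

$$\frac{1}{T_1} = C\left[\frac{\tau_c}{1+\omega_0^2\tau_c^2} +
\frac{4\tau_c}{1+4\omega_0^2\tau_c^2}\right],\qquad
\tau_c = \tau_0 e^{E_A/RT},$$

and rates of independent processes add (`model_rate()`). The constant
$C$ (s⁻²) absorbs all dipolar prefactors; no decomposition into second
moments is attempted, because only the product structure matters for
fitting. $E_A$ is accepted in kJ mol⁻¹ and converted once internally
($R = 8.3145$ J mol⁻¹ K⁻¹); $\omega_0 = 2\pi\nu_0$ with $\nu_0$ in MHz
(default 25 MHz, a typical field for solid-state relaxometry of
organics).

Viewed against $x = \omega_0\tau_c$, the reduced rate
$f(x) = x/(1+x^2) + 4x/(1+4x^2)$ has a unique maximum;
`t1_minimum_condition()` locates it by bounded scalar optimization
(`stats::optimize`, tol 1e-12) at $x^\ast = 0.6158$, with
$f(x^\ast) = 1.4252$. This is the classic "T₁ minimum condition"
$\omega_0\tau_c \approx 0.616$, and `predict_minimum_temperature()`
inverts it for a given process by bracketed root finding on
[1, 2000] K (computed in log space so that large $E_A/RT$ cannot
overflow).

### Fitting T₁ curves

`fit_relaxation()` performs weighted least squares **on log T₁** — the
space in which relaxometry curves are conventionally plotted and judged —
with weights from relative uncertainties when present. Parameters per
process are $(\log_{10}\tau_0,\ E_A,\ \log_{10}C)$, bounded to
physically sensible boxes ($\tau_0 \in [10^{-16}, 10^{-8}]$ s,
$E_A \in [0, 60]$ kJ mol⁻¹, $C \in [10^4, 10^{13}]$ s⁻²), optimized by
Levenberg–Marquardt (`minpack.lm::nls.lm`). Multi-start is seeded: the
supplied or heuristic starting point first, then Gaussian perturbations
in the transformed space; the best residual wins, ties broken by the
lowest total activation energy (a parsimony rule that prefers the least
activated interpretation).

Two design points deserve comment:

* **Shared parameters.** A barrier *distribution* of a single methyl
  species is naturally modelled as several processes that differ only in
  $E_A$. The `share` argument ties $\tau_0$ and/or $C$ within process
  groups (e.g. one high-temperature process plus a five-component
  low-temperature group). Without sharing, an 18-parameter six-process
  fit on a 60-point curve is under-identified — many parameter
  combinations fit equally well — and activation energies cannot be
  recovered reliably; with the physically motivated grouping the fit has
  10 parameters and recovers every $E_A$ to a few percent at 2% noise.
* **Low-temperature exclusion.** At the lowest temperatures other
  relaxation channels (e.g. proton dynamics in hydrogen bridges) can
  dominate T₁. Rather than adding a model term of a different physical
  origin, `exclude_below` omits points below a configurable temperature
  from the fit.

The identifiability heuristic (points/parameters < 3) only records a
warning; it never blocks a fit.

## Saturation recovery and recrystallization kinetics

One phase recovers mono-exponentially,
$M_z(t) = M_0(1-e^{-t/T_1})$; a two-phase sample with slow spin exchange
recovers bi-exponentially, and the amplitudes are proportional to the
proton counts of the phases. Assuming equal (or nearly equal) phase
densities, the amplitude share *is* the volume fraction — both
assumptions are stated, not tested, by the package.

* `fit_mono()` initializes $T_1$ from the delay where $M_z$ first
  crosses $(1-e^{-1})\max M_z$. A trace saturated at every delay
  identifies only an upper bound on $T_1$; such fits are flagged
  (`t1` at a bound, or below a quarter of the first sampled delay) and
  never silently reported as converged.
* `fit_biexp()` enforces amplitudes ≥ 0 and the canonical ordering
  $T_1^{(1)} < T_1^{(2)}$ by parameterizing the second time as
  $T_1^{(1)}e^{\mathrm{gap}}$, gap > 0, so that permuting initial
  components cannot change the reported order. Multi-start uses seeded
  log-spaced $T_1$ pairs spanning the delay range. A fitted ratio
  $T_1^{(2)}/T_1^{(1)} < 1.5$ yields a degeneracy warning: such
  components are not separable from a single trace, which is exactly the
  regime near complete recrystallization.
* `select_model()` formalizes the by-eye mono/bi decision with an F-test
  ($\alpha = 0.05$, 2 degrees-of-freedom difference) or AIC; equal
  residuals select mono (parsimony). Selection is refused only when a
  fit fails structurally — a bi-exponential fit wandering on the flat
  amplitude-zero ridge of mono-like data still provides a valid nested
  residual.
* `build_kinetics()` assigns the **longer-T₁ component to the
  crystalline phase** by default (at the temperatures where kinetics are
  followed, the crystalline phase relaxes more slowly; the assignment is
  overridable). Mono-selected traces map to fraction 0 or 1 by whichever
  reference T₁ (amorphous or crystalline, from the config) is nearer in
  log T₁. Completion is operationalized as the earliest timestamp from
  which the fraction stays at or above a threshold, default 0.99 —
  a fraction-space proxy for "the recovery became one-exponential
  again". The resolution of the completion time is therefore one
  sampling interval of the time series.

No Avrami/JMAK law is fitted: the package reports the fraction–time
curve and completion time and deliberately stops there. The logistic
trajectory in the generator is a convenience parameterization of a
sigmoidal time course, documented as a stand-in, with defaults reaching
0.99 at day 105 (midpoint 60 days, rate ln(99)/45 per day) — the
completion time of the most stable storage scenario modelled.

## QENS: three-site jumps and rate distributions

The measured scattering law is modelled as

$$S(Q,\omega) = A\,e^{-\langle u^2\rangle Q^2}\Big\{\big[c + (1-c)A_0(Q)\big]\,\delta(\omega)
+ (1-c)\big(1-A_0(Q)\big)\,\mathcal{L}(\omega;\Gamma)\Big\} \otimes R(Q,\omega)$$

with $A_0(Q) = \tfrac13[1+2 j_0(Qr\sqrt3)]$ the EISF of three-site
circular jumps. Choices the literature leaves open, fixed here:

* **Immobile fraction.** Hydrogens static on the instrumental timescale
  contribute only elastically: the elastic weight is
  $c + (1-c)A_0(Q)$. This preserves the sum rule
  $\int S\,d\omega = A e^{-\langle u^2\rangle Q^2}$ exactly for the
  symbolic (pre-convolution) law.
* **Debye–Waller.** $e^{-\langle u^2\rangle Q^2}$ with
  $\langle u^2\rangle$ an effective fitted parameter (no 1/3
  convention). When per-Q amplitudes are free, $\langle u^2\rangle$ is
  nearly degenerate with them — the amplitudes can absorb any smooth
  $Q$-dependence — so its fitted value should not be over-interpreted;
  it is kept in the model because fixing amplitudes across $Q$ is the
  less common experimental situation.
* **Jump radius.** Default $r = 1.03$ Å, the hydrogen distance from the
  C₃ axis of a standard methyl group; fixed by default, fittable via
  `config$fit_radius`.
* **Rate distribution.** The mixture replaces the single Lorentzian with
  $L$ components equally spaced in $\ln\Gamma$ over
  $\ln\bar\Gamma \pm s\sqrt{2\ln(1/A_{\min})}$ — the span where a
  log-normal density of standard deviation $s$ stays above $A_{\min}$
  of its maximum — with weights from that density, normalized to sum
  to 1 (defaults $L = 21$, $A_{\min} = 0.1$). With $s = 0$ the mixture
  degenerates to the single-Γ model *exactly*, which the tests assert
  pointwise at 1e-12. The cutoff is interpreted on the density of
  $\ln\Gamma$; this is the only reading consistent with equal spacing on
  a logarithmic scale.
* **Γ → τc.** $\tau_c = \hbar/\Gamma$ with $\hbar = 0.658212$ meV ps.
  Only inverse proportionality is physically fixed; the constant is a
  convention and is recorded as an attribute on every conversion so
  residence-time variants (e.g. $2\hbar/3\Gamma$) can be re-derived.

### Convolution engine

The elastic δ is kept **symbolic** until convolution — it becomes
`elastic_weight * R(ω)` — avoiding any grid-dependent delta
approximation. The quasielastic part is convolved by discrete (midpoint
rule) convolution on the common grid. Grids must share their spacing and
the resolution grid must contain ω = 0; resampling is refused, not
attempted. On the default grid (−2 to 2 meV, 801 points, i.e. 5 μeV
spacing against a 0.04 meV FWHM Gaussian resolution) the engine agrees
with an adaptive-quadrature Voigt evaluation to better than 1e-6
relative over ±1 meV, and the convolution step conserves the on-grid
integral to well under 0.5%.

Note what the 801-point grid does *not* capture: a Lorentzian of
HWHM Γ keeps only $\tfrac2\pi\arctan(2/\Gamma)$ of its mass inside
±2 meV (97.4% at Γ = 0.1 meV, 87.4% at Γ = 0.6 meV). Sum-rule checks
against the symbolic total must account for this analytic wing mass;
the tests do.

### Global fits

`fit_three_site()` and `fit_distribution()` fit all spectra
simultaneously: shared Γ (or $\bar\Gamma, s$), $c$,
$\langle u^2\rangle$, plus one amplitude per Q, weighted by per-point
uncertainties, Levenberg–Marquardt with seeded multi-start. The
distribution fit is applied globally with per-Q amplitudes (not
independently per Q). A fitted half-width below a tenth of the
resolution FWHM is reported with an "unresolved" warning.
`fit_distribution()` always also runs the nested single-Γ fit and
attaches its residual, so the mixture's improvement is quantified, never
assumed.

## The synthetic-data module

The generator is the package's substitute for instrument data and
defines the conditions under which the chain is validated:

* **Relaxometry scenario** (`amorphous_t1_scenario()`): one
  high-temperature process ($E_A$ = 7.8 kJ mol⁻¹) plus five
  low-temperature processes ($E_A$ = 6.8, 5.4, 4.4, 3.7,
  3.0 kJ mol⁻¹) sharing $\tau_0$ and $C$ — a barrier distribution of one
  methyl species. No $\tau_0$ or $C$ accompany published barrier tables,
  so the scenario derives $\tau_0$ from the minimum condition to place
  the two T₁ minima at 142 K and 63 K at 25 MHz, and sets $C$ so the
  minima sit at tens of milliseconds — representative magnitudes for
  proton relaxometry of methyl-bearing organics.
* **Noise**: multiplicative Gaussian for T₁ curves and QENS spectra
  (relative errors are what counting statistics deliver after
  normalization), additive Gaussian scaled to the total $M_0$ for
  recovery traces (fixed receiver gain). Neither instrument's true noise
  level is published; the defaults used in tests (2% for curves and
  spectra, 1% for traces) are conventions chosen once. QENS
  uncertainties are floored at 5% of the per-spectrum maximum times the
  relative level so that 1/σ weights stay finite near zero intensity.
* **QENS instrument**: Gaussian resolution of 0.04 meV FWHM, Q from 0.3
  to 1.8 Å⁻¹, ω grid −2 to 2 meV with 801 points — the geometry of a
  cold-neutron time-of-flight spectrometer probing ps motions. The
  crystalline-like scenario uses immobile fraction $c = 12/18$: two of
  four methyls mobile among 18 hydrogens per molecule, a geometric
  default, never asserted as a fitted truth.
* **Determinism**: every generator takes a `noise_spec(relative_sd,
  seed)` and restores the caller's RNG state; identical seeds and
  parameters give bit-identical output. Ground truth is embedded in each
  object's metadata so recovery tests are self-contained.

What the generator does **not** emulate: detector-level counting noise,
background, self-absorption, Bragg contamination (assumed removed
upstream by the reduction software; contaminated detectors would be
handled by an exclusion list), multiple scattering, tunneling at low
temperature, and any correlation between neighbouring energy channels.
Passing recovery tests therefore demonstrate the correctness and
conditioning of the *fitting chain* under the stated noise model, not
robustness to every artifact of real spectra.

## Problem sizes and tolerances used in validation

The shipped tests run the chain at desk scale, chosen to exercise the
statistics the models assume: 60-temperature T₁ curves over 20–300 K at
2% noise (ten seeds; every $E_A$ within 10%), 12-delay recovery traces
at 1% noise (ten seeds; fractions within ±0.03; 200-replicate type-I
simulation for the F-test at α = 0.05 with an empirical error ≤ 0.1),
six-Q QENS sets at 2% noise (s within 15%, $\bar\Gamma$ within 10%,
nested single-Γ residual strictly larger), and an 18-point weekly
kinetics series whose completion day is recovered within one sampling
interval. The acceptance script reports the one quantity that is purely
analytic — the BPP minimum condition, 0.616 at three decimals.

## Known limitations

* The BPP fit assumes uncorrelated processes and pure BPP spectral
  densities; no Cole–Davidson or stretched forms.
* $\langle u^2\rangle$ and per-Q amplitudes are jointly nearly
  unidentifiable (see above).
* Phase fractions assume equal phase densities and slow spin exchange.
* Completion-time resolution equals the sampling interval of the
  kinetics series; no kinetic law is fitted.
* The fit uncertainties are curvature-based (Gauss–Newton covariance at
  the optimum) and share that approximation's usual caveats near bounds.
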