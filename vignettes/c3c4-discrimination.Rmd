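---
title: "Quantifying C4-cycle activity in C3-C4 intermediate leaves from coupled gas-exchange and 13C discrimination curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying C4-cycle activity in C3-C4 intermediate leaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kranz)
```

## The scientific setting

Leaves of C3-C4 intermediate species run a partial C4 cycle on top of an
ordinary mesophyll C3 cycle. Their dry-matter δ13C is usually C3-like, so
the standard isotopic shortcut for spotting C4 metabolism fails. What does
carry the signal is *instantaneous* discrimination Δ measured online while
the leaf's CO2 response is traversed: PEP carboxylase (net fractionation
b4 ≈ −5.7 ‰) and Rubisco (b3 ≈ 29 ‰) differ so strongly that even a small
C4 flux shifts Δ measurably, provided diffusional contributions are
modelled out. `kranz` implements the forward models for both observables
(net assimilation A and discrimination Δ), an inversion for the
biochemical fractionation, and a concurrent fitting procedure over the two
response curves that makes the C4 share of assimilation and the
bundle-sheath leakiness φ estimable.

## The assimilation model

The leaf is two compartments. The C4 pump delivers CO2 to the bundle
sheath at `Vp + β·Fm` (PEPC carboxylation plus the fraction β of
mesophyll-photorespired CO2 released there); a fraction φ leaks back:

* `Vp = min(Cm·Vp,max/(Cm + Kp), Vpr)` — Michaelis–Menten PEPC with a
  PEP-regeneration ceiling `Vpr`,
* `Vm = min(Wc, Wj)` — mesophyll Rubisco, Rubisco-limited
  `Wc = Cm·Vm,max/(Cm + Kc(1 + O/Ko))` or electron-transport-limited
  `Wj = J·Cm/(4Cm + 8Γ*)`,
* `L = φ(Vp + β·Fm)`, `As = Vp + β·Fm − L`, `A = Vm − Rm − Fm + Vp − L`,
  `Am = A − As`.

`J` follows the usual non-rectangular hyperbola in irradiance with
curvature θ, absorptance and a spectral-quality correction, evaluated at
the mesophyll allocation `Jm`; the total capacity `Jt` is carried for
reporting only, with no energy-sharing constraint imposed on `Vp` (none is
defined for this model family, and we found the fits do not require one).
Mesophyll CO2 is implicit, `Cm = Ci − A/gm`.

Three structural choices deserve a note:

* **Compartment bookkeeping.** The printed compartment equations are
  mutually inconsistent once `Fm > 0` and β ≠ 1 − the sum of the
  compartment budgets does not reproduce the stated total. We take the
  total-A equation as authoritative for `A`, the bundle-sheath budget as
  authoritative for `As`, and *define* `Am = A − As`. This guarantees
  exact conservation (`A = As + Am` to machine precision, property-tested
  on 10^4 random states) and is inconsequential in the quantitative regime
  used throughout, where photorespiration is negligible and all forms
  coincide.
* **Limiting-rate combination.** `Vm` is a strict minimum of `Wc` and
  `Wj`; no co-limitation smoothing is applied because none is defined for
  this model family. The resulting kink is handled by the derivative-free
  fitting machinery (below).
* **Bundle-sheath photorespiration** `Fs` is fixed at 0: the model is
  used at low O2 where it vanishes, and no bundle-sheath O2/CO2 pool model
  is provided to compute it from.

## The discrimination model

On the measurement scale,

$$\Delta = \frac{a'}{1-t} + \frac{1+t}{1-t}\,(a_l + b_s -
\Delta_{bio})\frac{A}{g_m C_a} + \frac{(1+t)\Delta_{bio} - a'}{1-t}\,
\frac{C_i}{C_a},$$

with `a′` the CO2-drop-weighted mean of the boundary-layer (2.9 ‰) and
free-air (4.4 ‰) diffusional fractionations, and
`t = (1 + a′)·E/(2·g_ac)` the ternary transpiration correction (`a′`
fractional there). The biochemical fractionation in the
low-photorespiration regime is

$$\Delta_{bio} = \Big(b_3 - \frac{e R_m}{A}\Big) + \frac{A_s}{A}\Big[(b_3 -
s)\,\varphi + (b_4 - b_3)\Big] - \frac{e R_s}{A}\varphi,$$

the limit of the full photorespiration-bearing expression (also
implemented; the reduction at `Fm = Fs = 0` is property-tested). The
respiration terms use the apparent offset `e = δ13C_cylinder −
δ13C_atmosphere`, i.e. respiration itself is assumed non-fractionating and
`e` only accounts for the isotopic mismatch between growth and measurement
CO2. `Rm = Rs = Rd/2` by default (`rm_fraction` is exposed for sensitivity
analysis). The sign convention groups `e·Rm` with the photorespiratory
term so that the reduced form above is recovered exactly; the net
bundle-sheath respiration correction is negative (it lowers Δbio),
consistent with the mesophyll term.

The model is inverted in closed form for Δbio given an observed Δ; the
liquid-phase term `a_i` of the inversion is `a_l + b_s`, which is what
makes the inversion the exact algebraic inverse of the forward model
(property-tested to 10⁻⁹ ‰ over 10³ random states). Observed Δ comes from
the standard two-point open-chamber formula with `ξ = Ce/(Ce − Co)`.
Per-mil quantities enter all linear expressions in ‰; only the ternary
factor uses the fractional form — the one place where a 10³ slip is
possible.

## Mesophyll conductance

For a C3 leaf, Δbio collapses to `b3 − e·Rd/A` (all respiration is
mesophyll respiration in a one-compartment leaf) and `gm` is the only
unknown left in the discrimination equation, so it is estimated point by
point in closed form. Note the convention difference from the
two-compartment forward model, which splits `Rd` between the
compartments: applied to data generated by the full model with
`rm_fraction = 0.5`, the single-compartment estimator recovers `gm` with a
few-percent bias (the fitted scaling constant on a noiseless synthetic
C3 run is 0.672 rather than the generating 0.666). This mirrors the
methodological reality that the C3 estimator and the intermediate-leaf
model are different instruments.

Across species, `gm(Ci) = 10⁻⁶·Ci² − 0.0013·Ci + c`: the curvature is
shared and only `c` (mol m⁻² s⁻¹ bar⁻¹) is species-specific, estimated by
intercept-only least squares. The polynomial's vertex is at 650 µbar;
beyond it the curve is evaluated as printed by default (matching how the
fitted curves were produced), floored at 0.01 mol m⁻² s⁻¹ bar⁻¹, with an
optional `clamp = "vertex"` mode that holds `gm` at its vertex value for
users who prefer the "stable at high CO2" description.

## Concurrent fitting and hypothesis diagnosis

The fit minimises

$$w_A \sum_i (A_i^{obs} - A_i^{mod})^2 + w_\Delta \sum_i
(\Delta_i^{obs} - \Delta_i^{mod})^2$$

over a chosen free set (default `{φ, c}`; any of
`φ, c, Vpr, Vm,max, Vp,max, Jm, Jt` may be freed). The two blocks have
different units and magnitudes, so by default each weight is the inverse
mean square of the observed block, making the objective unit-free; raw
(unweighted) and user-specified weights, including `w_Δ = 0` for A-only
data, are available. Because the objective is kinked at the `Wc/Wj` and
`Vp/Vpr` crossovers, optimisation is derivative-free: a 25-point scan
refined by golden-section search for one free parameter, and bounded
Nelder–Mead on a logit-transformed scale from a deterministic
three-start grid otherwise. A finite-difference curvature probe at the
optimum reports near-flat objective directions — e.g. freeing
`{φ, Vp,max}` against A-only data is flagged as unidentified because
`Vp,max` is invisible wherever `Vp` is capped at `Vpr`, while the same
pair is well identified once the Δ block is present.

`diagnose_c4()` formalises the qualitative argument "the curves can only
be fitted under one premise": it fits a hypothesis pair — C4-active vs
no-C4 for a putative intermediate, mesophyll-Rubisco vs strict-C4 for a
C4-like leaf — and reports objectives, per-block RMSEs and their ratio.
The preference is labelled *decisive* when the losing hypothesis carries
more than twice the Δ-block SSR of the winner; the factor 2 is a package
convention, not an inferential claim, and no formal likelihood model is
attached (the measurement error model needed for one is not specified by
the method).

## Bundle-sheath contribution

After fitting, the C4-cycle share of assimilation is the bundle-sheath
share `100·As/A` along the Ci range — valid at low O2 because essentially
all bundle-sheath CO2 then arrives via the C4 pump. Whether the
bundle-sheath respiration `Rs` should be charged against that budget is
ambiguous in this model family (`Rs` is absent from the compartment budget
but present in the discrimination equation), so both variants are always
computed: `bs_share = 100·As/A` and `bs_share_net_Rs = 100·(As − Rs)/A`.
For the *F. floridana* parameter set over the measured Ci range
(~35–800 µbar) the respiration-adjusted share peaks at 21% at very low Ci
and declines to ~10–12% at the high-CO2 end, which is the behaviour the
concurrent-fitting approach is designed to expose; the unadjusted share
peaks substantially higher (~33%) because dividing a respiration-free
numerator by a respiration-charged total inflates the ratio exactly where
A is small. The respiration-adjusted variant is the package's reported
convention.

## The synthetic-data generator

`generate_dataset()` emulates one online measurement run: the reference
CO2 stepped through 392, 980, 686, 490, 294, 196, 98, 49, 392 µbar,
stomata reduced to a fixed operating ratio `Ci = 0.7·Ca` (0.4 recommended
for C4-like leaves, matching observed operating ranges); leaf-surface CO2
midway between ambient and intercellular; transpiration and conductances
derived self-consistently from the modeled fluxes (`g_ac = A/(Ca − Ci)`,
`E = 1.6·gs·0.01` for a 10 mbar bar⁻¹ vapour-pressure deficit). Noise is
additive, independent, homoscedastic Gaussian on A (sd 0.5 µmol m⁻² s⁻¹)
and Δ (sd 0.3 ‰) — defaults chosen to resemble between-replicate scatter
of online TDL systems, and package conventions rather than measured error
models. The TDL record is then synthesised to be *exactly* consistent with
the noisy Δ (entering air = cylinder composition, drawdown 2 µbar per unit
A, outgoing δ13C solved from the two-point formula), so the reader path
and the generator are mutually inverse by construction.

What the generator deliberately does not emulate: stomatal dynamics (the
fit never uses a stomatal rule, only the realised Ci), instrument drift
and TDL calibration cycles, autocorrelated or heteroscedastic noise, and
any real biology of the measured species beyond the parameter presets.
Passing the parameter-recovery and diagnosis tests therefore demonstrates
that the estimation machinery is correct and well-conditioned under the
model's own assumptions — not that those assumptions hold for any
particular leaf.

An O2-series generator scales the photorespiratory term
`Γ* = 0.000193·pO2` (the standard Rubisco-specificity value at 25 °C)
to exercise the compensation-point and O2-inhibition utilities; the main
pipeline keeps `Γ* = 0`, consistent with measurements at 19–20 mbar O2.

## Numerical choices

* Implicit `Cm` balance: Brent bracketing of
  `h(Cm) = Cm − Ci + A(Cm)/gm` on `[0, Ci + 50]`, tolerance 10⁻¹⁰
  (defining residual < 10⁻⁶ µbar asserted in tests); `h` is monotone for
  physical parameters and bracketing is indifferent to the rate-cap
  kinks. Infinite `gm` short-circuits to `Cm = Ci`. Agreement with an
  independently coded dense-grid bisection oracle is better than
  10⁻⁴ µbar across random parameter draws.
* Compensation points: model-based via root bracketing on `[0, 200]`
  µbar; data-based via linear interpolation between the bracketing
  measured points (no interpolation model is claimed beyond that).
* Units: partial pressures µbar, fluxes µmol m⁻² s⁻¹, conductances
  mol m⁻² s⁻¹ bar⁻¹ — so `A/gm` is in µbar directly and every preset
  value is usable as printed. "Not applicable" entries of the preset
  table are pathway-disabled sentinels (`Vp,max = 0` switches the C4
  cycle off; φ, b4, s are then inert zeros), never missing values, which
  keeps the C3 leaf a strict special case of one code path.
* The photorespiratory fractionation `f` (default 11 ‰, a conventional
  value) is consulted only when `Γ* > 0`; it is absent from the preset
  table because all quantitative use is at `Γ* = 0`.

## Problem sizes

The shipped tests run the full battery at desk scale: 10⁴ random states
for conservation, 10³ for the discrimination inversion, 100 random draws
against the solver oracle, 50 noisy replicates for leakiness recovery
(median |φ̂ − φ| ≤ 0.05) and 100 labeled noisy replicates for the
diagnosis preference rate (≥ 95% correct), completing in a few minutes on
one core. These sizes were chosen as the smallest that make the Monte
Carlo assertions stable; all are parameters of the test code, not of the
package.

## Known limitations

* No temperature dependence of kinetic constants (everything is at
  25 °C), no triose-phosphate-utilisation limitation, no bundle-sheath
  CO2 pool dynamics, no Δ18O pathway.
* The diagnosis statistic is a descriptive objective ratio; users needing
  formal model selection must supply an error model and do so outside the
  package.
* The gm polynomial is an empirical description fitted for one C3
  species and transferred across species by a single scaling constant;
  outside roughly 0–800 µbar it extrapolates and the floor/vertex clamps
  take over.
* `Jt` is reported but unused: if a future energy-budget constraint
  linking `Jt − Jm` to `Vp` is established, it belongs in the
  assimilation model.
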