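---
title: "A steady-state model of C4 leaf gas exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A steady-state model of C4 leaf gas exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4leaf)
```

## The model

C4 leaves concentrate CO2: phosphoenolpyruvate carboxylase (PEPC) fixes
bicarbonate in the mesophyll at rate $V_p$, the resulting C4 acids are
decarboxylated inside the nearly gas-tight bundle sheath, and Rubisco
(confined to the bundle sheath) refixes the released CO2 at rate $V_c$.
Because the bundle-sheath wall has a small but finite CO2 conductance
$g_{bs}$, some of the concentrated CO2 leaks back out at rate
$L = g_{bs}(C_s - C_m)$. Net assimilation can be written from either side of
the bundle-sheath wall:

$$A = V_c - 0.5\,V_o - R_d = V_p - L - R_m,$$

with $V_o$ the Rubisco oxygenation rate and $R_d = R_m + R_s$ dark
respiration split between mesophyll and bundle sheath. Leakiness
$\phi = L/V_p$ measures the efficiency of the CO2 pump; overcycling $L/A$
is the excess C4-cycle flux relative to net fixation.

As in the standard biochemical model of C3 photosynthesis, the realized rate
is the minimum of two co-solved limitations:

* **Enzyme-limited** ($A_c$): Michaelis–Menten PEPC supply
  ($V_p = \min\{C_m V_{pmax}/(C_m+K_p),\,V_{pr}\}$, the second argument being
  the PEP-regeneration ceiling) against RuBP-saturated Rubisco demand
  ($V_c = C_s V_{cmax} / (C_s + K_c(1 + O_s/K_o))$), closed by the
  bundle-sheath CO2 and O2 diffusion balances. Eliminating $C_s$ and $O_s$
  gives a quadratic $a A_c^2 + b A_c + c = 0$.
* **Electron-transport-limited** ($A_j$): whole-chain linear electron flow
  $J$ is partitioned between PEP regeneration (fraction $x$, 2 ATP per PEP)
  and the C3 cycle (fraction $1-x$, $3 + 7\gamma^* O_s/C_s$ ATP per
  carboxylation including photorespiration). ATP per linear electron is
  $z = (3 - f_{cyc}) / (h(1 - f_{cyc}))$, with $f_{cyc}$ the cyclic fraction
  of PSI flow and $h$ protons per ATP; light allocation to PSII is
  $\rho = (1-f_{cyc})/(2-f_{cyc})$, and $J$ follows a non-rectangular
  hyperbola in the absorbed light $I_2$ with curvature $\theta$ and maximum
  $J_{max}(T)$. Eliminating the internal pressures again yields a quadratic.

The closed-form coefficients of both quadratics, and of the inverse quadratic
for the electron transport $J_a$ that sustains a measured $A$, were re-derived
from the flux balances in this package; their correctness is *defined* by
simultaneity oracles in the test suite (monotone bisection on the component
equations), not by transcription. The physical root is the smaller root for
$A_c$ and $A_j$ (the larger exceeds both limiting branches) and the larger
root for $J_a$ (both cycles must be served, so the binding requirement wins).

Mesophyll conductance couples intercellular to cytosolic CO2 through
$A = g_m(C_i - C_m)$. Substituting this into the enzyme-limited quadratic
yields a cubic, so the package solves $A(C_m) = g_m(C_i - C_m)$ numerically
(see below) rather than algebraically; the closed-form low-CO2 quadratic
(`lowco2_assimilation_with_gm()`) is exposed separately because it drops the
Rubisco and leak terms and is valid only on the initial slope. That slope is
$\mathrm{d}A/\mathrm{d}C_i|_{0} = g_m V_{pmax} / (g_m K_p + V_{pmax})$ — a
series combination showing why ignoring $g_m$ badly understates PEPC
capacity (with the defaults, the apparent $V_{pmax}$ read from the slope is
58 rather than 200 µmol m⁻² s⁻¹).

## Parameters, units, temperature

Defaults describe a *Setaria viridis*-type NADP-ME leaf at 25 °C; every
field, unit and default is documented in `?c4_parameters`. The unit
convention is the chief user hazard and is enforced everywhere: CO2 pressures
and $K_c, K_p$ in **µbar**; O2 pressures and $K_o$ in **mbar**; fluxes in
µmol m⁻² s⁻¹; conductances in mol m⁻² s⁻¹ bar⁻¹. All products such as
$\gamma^* O_s$ convert O2 to µbar first, so compensation pressures emerge in
µbar (defaults give $\Gamma^* = \gamma^* O_s \approx 76$ µbar at 200 mbar
O2). CSV interfaces carry the units in the column names (`Ci_ubar`,
`Om_mbar`, ...).

Temperature scaling uses the simple Arrhenius form
$f(T) = f(25)\exp[(T-25)E/(298 R (273+T))]$ with per-parameter activation
energies in kJ mol⁻¹ (converted to J mol⁻¹ inside the exponential);
$g_{bs}$ and $V_{pr}$ are temperature-invariant, and $J_{max}$ follows the
Gaussian $J_{max}(T_o) e^{-((T-T_o)/\Omega)^2}$ (defaults 400 µmol e⁻ m⁻²
s⁻¹ at $T_o = 43$ °C, $\Omega = 26$ °C, giving 248 at 25 °C). $R_d$ defaults
to $0.01\,V_{cmax}(25)$ at construction and is then scaled with its own
activation energy, not re-derived from $V_{cmax}(T)$. $K_p$ is a CO2
pressure converted from a bicarbonate $K_m$ assuming cytosolic pH 7.2
(pKa 6.12); `rescale_kp_for_ph()` applies the Henderson–Hasselbalch factor
$10^{\mathrm{pH_{ref}} - \mathrm{pH_{new}}}$ for other pH assumptions
(82 µbar becomes ≈ 51.7 µbar at pH 7.4).

## Numerical choices

* **Quadratic roots.** Written in cancellation-free forms where it matters:
  the light-response root uses $2 I_2 J_{max}/(s + \sqrt{s^2 - 4\theta I_2
  J_{max}})$, which degrades gracefully into the rectangular hyperbola at
  $\theta = 0$. When a leading coefficient falls below $10^{-12}$ the linear
  fallback $-c/b$ is used; a negative discriminant raises an error naming
  the offending solve.
* **Degenerate co-limitation.** When the two branches of a quadratic
  coincide (a double root, e.g. the idealized $x = 0.4$ partition with no
  respiration or photorespiration), root accuracy is limited to
  $O(\sqrt{\varepsilon})$; tests assert at that level.
* **Mesophyll CO2 solve.** $A(C_m) = g_m(C_i - C_m)$ is solved by monotone
  vectorized bisection ($A$ is non-decreasing in $C_m$, the supply line
  decreasing) to $|\Delta C_m| < 10^{-8}$ µbar, with the upper bracket
  widened above $C_i$ so sub-compensation states (where $C_m > C_i$) are
  reachable.
* **Limitation flag.** `enzyme` / `electron_transport` by the min rule, with
  `co-limited` declared within an absolute tolerance of $10^{-3}$ µmol m⁻²
  s⁻¹ — a float-comparability guard, not a biological claim. $\phi$ and
  overcycling are reported from the winning branch and set to `NA` (never
  clamped) when $A \le 0$ or $V_p = 0$.
* **Capacity balance near the plateau.** With the default capacities at
  25 °C the PEP-regeneration cap ($V_{pr} = 80$) holds the enzyme-limited
  plateau at ≈ 34.7 µmol m⁻² s⁻¹, *just below* the light-saturated
  electron-transport rate (≈ 35.6 at 2000 µmol quanta m⁻² s⁻¹). Which
  process reads as limiting at high CO2 is therefore delicately balanced:
  raising $V_{pr}$ by ~20% (or lowering irradiance slightly) flips the flag
  to electron transport. Interpret high-CO2 limitation flags with this
  sensitivity in mind.
* **Inverse electron transport.** Every $J_a$ returned by
  `actual_electron_transport()` is validated by a forward round trip; if the
  companion quadratic root is the one that reproduces the input (which the
  default parameterization never triggers), it is used and a warning logged.

## Fitting

`fit_curve()` estimates any subset of $V_{pmax}, V_{cmax}, V_{pr}, J_{max},
g_m$ (as their 25 °C values) by bounded Levenberg–Marquardt least squares on
the full forward model. Two practical points follow from the min rule:

* **Start capacities low.** A capacity whose branch is inactive has exactly
  zero gradient, so the optimizer must approach each capacity from the side
  on which its branch limits. Starting values below the plausible range are
  safe; starting above the plateau strands the estimate.
* **Identifiability is design-limited.** On initial-slope-only data $g_m$
  and $V_{pmax}$ act through nearly one number (the slope) and separate only
  via Michaelis curvature; on sparse low-CO2 grids $V_{pmax}$ is informed
  only by points with $C_m \lesssim 55$ µbar once $V_{pr}$ caps the supply.
  The default A–Ci grid (`default_aci_grid()`: 15 points, 20–1500 µbar,
  denser low-CO2 coverage) reflects this. Fits report a weak-identifiability
  flag when the condition number of the column-normalized curvature matrix
  $J^\top J$ exceeds 100 — i.e. when errors are inflated ≥ 10-fold along the
  weakest parameter direction — or when any column is identically zero.
  Approximate standard errors come from the residual-variance-scaled
  $(J^\top J)^{-1}$.

## The synthetic-data generator

`synthesize_curve()` adds independent homoscedastic Gaussian noise (default
sd 0.5 µmol m⁻² s⁻¹, a typical IRGA scatter) to a model-generated curve,
reproducibly for a recorded seed. It emulates *measurement* error only: real
gas-exchange data additionally carry systematic leaks, slow stomatal and
induction transients, patchiness, and real leaves deviate from the model
itself (e.g. triose-phosphate limitation at high CO2, carbonic-anhydrase
limitation at low CO2, stomatal behaviour — all outside this model's scope).
Passing parameter-recovery tests on synthetic curves therefore demonstrates
estimator correctness under the model, not robustness to model error.

Problem sizes used by the test suite were chosen to finish quickly while
exercising the full domain: 200 random parameter draws (±50% around the
defaults, $\alpha \in \{0, 0.5, 1\}$, O2 at 50/200/400 mbar) for the
oracle-equivalence properties, 50 draws for the inversion round trip, and
100 seeded replicates of the 15-point A–Ci recovery study at noise sd 0.5.

## Known limitations

Single NADP-ME-flavoured parameter set (the reduced mesophyll ATP demand of
PCK types is not modelled beyond $\alpha$); no triose-phosphate limitation;
no carbonic-anhydrase kinetics (hydration assumed non-limiting); no stomatal
or boundary-layer model ($C_i$ is an input); steady state only — no
induction or fluctuating-light dynamics; leakiness is *diagnosed from*
measurements, not predicted, since a flux model says little about
non-limiting steps.
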