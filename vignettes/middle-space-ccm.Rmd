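---
title: "A flux model of CO2 concentration in the diatom middle space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A flux model of CO2 concentration in the diatom middle space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diatomccm)
```

## The biological question

RuBisCO fixes CO₂, not HCO₃⁻, and does so with low affinity, so
phytoplankton run CO₂-concentrating mechanisms (CCMs) to raise CO₂ at the
carboxylation site. Diatom plastids sit inside four membranes; the
compartment just inside the outermost membrane (the chloroplast
endoplasmic reticulum membrane) is called the *middle space*. A light-driven
proton-pumping rhodopsin on that membrane can acidify the middle space, and
because carbonate speciation is steeply pH-dependent, acidification converts
the large HCO₃⁻ pool into CO₂ right outside the inner plastid membranes.
`diatomccm` quantifies how much carbon fixation can gain from that.

## Model structure and assumptions

The model couples two pieces.

**Carbonate speciation in the middle space.** DIC is partitioned among CO₂,
HCO₃⁻ and CO₃²⁻ by the two apparent dissociation constants of carbonic
acid, themselves empirical functions of absolute temperature and practical
salinity (`carb_pk1()`, `carb_pk2()`). The CO₂ fraction is

$$[CO_2]_m = \frac{[DIC]_m}{1 + K_1/[H^+] + K_1 K_2/[H^+]^2},
  \qquad [H^+] = 10^{-pH_m}\ \mathrm{mol\,L^{-1}}.$$

Only the dimensionless ratios $K_1/[H^+]$ and $K_1K_2/[H^+]^2$ enter, so DIC
and all species can be carried in µmol L⁻¹ while the constants stay in
mol L⁻¹; no unit conversion of DIC is needed or wanted. Temperature must be
Kelvin: the $\ln T$ terms of the pK regressions are only meaningful on that
scale (the shell interface accepts °C and converts once at the boundary).

**Flux balance in the plastid.** Plastid CO₂ evolves by diffusion across the
inner membranes against Michaelis–Menten fixation,

$$\frac{d[CO_2]_p}{dt} = D\left([CO_2]_m - [CO_2]_p\right)
  - \frac{V_{max}[CO_2]_p}{[CO_2]_p + K}.$$

Setting the derivative to zero gives a quadratic in $[CO_2]_p$ with exactly
one non-negative root (the other root is negative whenever $[CO_2]_m > 0$;
the tests confirm this over randomized parameters). The steady state depends
on $V_{max}$ and $D$ only through the concentration-scale ratio
$V_{max}/D$; time units are arbitrary and cancel from all fold changes, so
the API accepts either the pair or the ratio (with $D$ normalized to 1) and
both paths are tested to agree.

Key simplifying assumptions, kept deliberately:

* **Constant DIC.** The middle-space DIC pool is not depleted by the flux
  into the plastid. Leakage into the cytosol could change DIC, but the
  magnitude is not experimentally constrained, so the pool is held fixed.
* **No HCO₃⁻ transporters on the inner membranes.** Such transporters would
  allow $[CO_2]_p > [CO_2]_m$, but have not been discovered in this system;
  the model moves carbon inward only by CO₂ diffusion.
* **Two-constant carbonate system.** No borate/phosphate alkalinity,
  fugacity or pressure corrections; whether the pK regressions are on the
  mol kg⁻¹ or mol L⁻¹ scale is immaterial here because only the ratio
  structure of the speciation formula is used.
* **Alkalization needs no separate mechanism.** pH grid points above the
  reference simply give fold changes below 1.

## Parameters, defaults and why

| parameter | default | units | meaning |
|---|---|---|---|
| `dic` | 993 | µmol L⁻¹ | middle-space DIC, a measured diatom value |
| `reference_ph` | 7.59 | — | the one mean intracellular pH measured for a diatom; fold changes are relative to it |
| `k` | 44 | µmol L⁻¹ | half-saturation of fixation, a RuBisCO-scale affinity |
| `temperature` | 298.15 | K | standard seawater conditions; together with `salinity = 35` these reproduce the commonly quoted CO₂ values at this DIC and pH to their printed precision |
| `salinity` | 35 | — | practical salinity of standard seawater |
| `ph` | 5–8 by 0.05 | — | covers the plotted span and contains 5, 6, 7 and 7.59 exactly |
| `vmax_over_d` | 7 log-spaced values in 0.1–10⁴ | µmol L⁻¹ | wide enough to show both kinetic regimes; the source analysis never prints its exact grid, so this is a package choice, overridable in `scan_config()` |

## Numerical choices

* **Stable quadratic root.** With $b = V_{max}/D + K - [CO_2]_m$, the root
  $(-b + \sqrt{b^2 + 4K[CO_2]_m})/2$ loses all significant digits when
  $b \gg \sqrt{K[CO_2]_m}$ (large $V_{max}/D$). When $b > 0$ the package
  computes the algebraically identical form
  $2K[CO_2]_m / (b + \sqrt{b^2 + 4K[CO_2]_m})$; a test checks the
  cancellation-free identity $x(x+b) = K[CO_2]_m$ at ratios up to $10^{12}$.
* **Degenerate cases by contract.** $V_{max} = 0$ returns
  $[CO_2]_p = [CO_2]_m$; $D = 0$ returns 0 when $V_{max} > 0$ and
  $[CO_2]_m$ otherwise. Neither path divides by zero.
* **ODE oracle.** `integrate_dynamics()` integrates the balance equation
  with an adaptive-step solver (deSolve's lsoda, rtol 1e-10) and flags
  convergence when the final derivative magnitude falls below
  `reltol * D * max(1, [CO2]m)`. The derivative at 0 is non-negative for
  $[CO_2]_m \ge 0$, so trajectories stay non-negative and approach the
  fixed point monotonically. The tests require the terminal state to match
  the closed-form root to 1e-6 relative over 100 random draws spanning
  $V_{max}/D \in [10^{-3}, 10^5]$ µmol L⁻¹ — the ODE is the independent
  route, the root the production path.
* **Undefined fold changes.** If the reference fixation rate is zero
  (e.g. `vmax_over_d = 0`) the fold change is `NA`, never infinity.
* **Deterministic output.** CSV numbers are written at 10 significant
  digits so identical configurations give byte-identical files across
  platforms; every output carries a JSON provenance sidecar with all
  parameter values, defaults included.

## The scan and its analytic envelope

```{r}
scan <- run_scan(scan_config(ph = c(5, 6, 7, 7.59),
                             vmax_over_d = c(0.1, 44, 1e4)))
scan
fold_change_bounds(c(7, 6, 5))
```

The middle-space CO₂ column depends on pH alone; plastid CO₂ and the fold
change interpolate between the uptake-limited bound (the Michaelis–Menten
ratio, reached as $V_{max}/D \to 0$) and the diffusion-limited bound (the
plain concentration ratio, reached as $V_{max}/D \to \infty$). The
fold-change sandwich, the exact normalization to 1 at the reference pH, and
the invariance of existing records under pH-grid refinement (the model is
pointwise — there is no discretization error to refine away) are all
asserted in the test suite.

```{r, fig.width = 6, fig.height = 4}
autoplot(run_scan(scan_config()), panel = "fold_change")
```

## What the tests do and do not show

The test suite exercises desk-scale problems: speciation over a thousand
random (DIC, pH, T, S) draws, steady states over a thousand random
parameter draws, ODE-vs-root agreement over a hundred draws, and the full
default scan (61 pH × 7 ratio points) — all closed-form or one-dimensional,
running in seconds. Passing them shows the implementation solves *this*
model correctly and reproduces its published outputs. It does not validate
the model against a living diatom: real cells have DIC depletion, carbonic
anhydrases, membrane potentials and pH regulation that the model
deliberately omits, and the true in vivo $V_{max}/D$ is unknown — which is
precisely why results are reported as an envelope over that ratio.

## Known limitations

* The exact temperature and salinity behind the published reference values
  are not printed in the source text; the standard-seawater defaults
  (298.15 K, S = 35) reproduce them to their printed precision and are
  documented as the package's choice.
* The model is single-compartment and open-loop: no feedback of carbon
  drawdown on middle-space pH or DIC.
* The pK regressions are fitted for oceanic conditions; the package warns
  above salinity 40 and refuses beyond 50.
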