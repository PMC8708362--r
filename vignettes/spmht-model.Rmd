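---
title: "Modelling specific loss power in superparamagnetic hyperthermia with Co-ferrite nanoparticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling specific loss power in superparamagnetic hyperthermia with Co-ferrite nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferroheat)
library(dplyr)
```

## The physical picture

Superparamagnetic hyperthermia heats a tumour by dispersing single-domain
magnetic nanoparticles in it and driving them with an alternating magnetic
field at a few hundred kHz. For particles small enough to be
superparamagnetic and fixed in tissue, the dominant dissipation channel is
Néel relaxation: the particle moment hops thermally over the
magnetocrystalline anisotropy barrier, and lags the driving field. This
package models that channel — and only that channel — for the
Co~x~Fe~3−x~O~4~ ferrite series, in which substituting Co^2+^ for Fe^2+^ on
octahedral sites sweeps the anisotropy constant over more than an order of
magnitude between magnetite (x = 0) and cobalt ferrite (x = 1).

The model chain, all in SI internally:

* Langevin argument $\xi = \pi\mu_0 M_s D^3 H / (6 k_B T)$ and equilibrium
  law $L(\xi) = \coth\xi - 1/\xi$;
* initial susceptibility
  $\chi_i = \varepsilon\,\pi\mu_0 M_s^2 D^3/(18 k_B T)$ and static
  susceptibility $\chi_0 = 3\chi_i L(\xi)/\xi$;
* Néel relaxation time $\tau = \tau_0 \exp[\pi K D^3/(6 k_B T)]$;
* Debye out-of-phase susceptibility
  $\chi'' = \chi_0\,\omega\tau/(1+(\omega\tau)^2)$, $\omega = 2\pi f$;
* specific loss power $P_s = \pi\mu_0 \chi'' f H^2/\rho$.

`specific_loss_power()` returns all of these per evaluation point, so
anomalies can always be traced to the intermediate that produced them.

### Assumptions and what is deliberately left out

Monodisperse rigid spheres, no size distribution; no Brownian rotation
(particles are assumed mechanically fixed in tissue); no hysteresis or
eddy-current losses; no interparticle dipolar interaction (dilute ensemble,
packing fraction $\varepsilon \le 0.1$); material constants at room
temperature with no explicit temperature dependence; and no heat-transfer
model — the package predicts the power source term, not the temperature the
tissue reaches.

## Units

$P_s$ is reported in W per gram of magnetic material, the scale on which
hyperthermia dose tables are customarily printed; the SI evaluation of
$\pi\mu_0\chi'' f H^2/\rho$ with $\rho$ in kg/m³ yields W/kg, and the
reported value is exactly that divided by 1000. Columns in emitted tables
carry explicit unit suffixes (`PsM_W_per_g`, `D_M_nm`, `H_kA_per_m`).

## Material models

The anchor table (`cofe_anchors()`, also shipped as CSV so measured values
can be substituted) fixes nine compositions. Three modelling choices were
open and are resolved as follows:

* **K(x)** — only anchor values and a smooth single-peaked trend are known,
  so the package uses shape-preserving piecewise-cubic interpolation:
  the anchors are split into maximal monotone runs at the interior maximum
  (x = 0.67) and each run is fitted with the monotone Fritsch–Carlson
  cubic. This is exact at anchors, continuous, and cannot overshoot the
  peak — a plain cubic spline (and even a single Fritsch–Carlson fit across
  the non-monotone sequence) places a spurious maximum above 294 kJ/m³ at
  x ≈ 0.73. The interpolant only matters between anchors; every reference
  result is evaluated at an anchor.
* **M~s~(x)** — stated to vary linearly; the line is fixed by the x = 0 and
  x = 1 endpoints (480 and 425 kA/m), which reproduces every intermediate
  anchor to its printed rounding (≤ 0.5 kA/m).
* **ρ(x)** — no functional form is stated; a line through the endpoints
  (5.24 → 5.29 × 10³ kg/m³) matches all anchors to their printed precision.

```{r materials}
material_properties(c(0, 0.67, 1))
```

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `T` | absolute temperature, K | 300 | room-temperature anchor constants; the default reproduces the reference tables to < 2%, and T is configurable for body-temperature studies |
| `epsilon` | packing volumetric fraction | 0.1 | the customary dilute-dispersion value of the study box; enters only through $\chi_i$ |
| `tau0` | attempt time, s | 1e-9 | the standard order of magnitude for ferrites |
| `D_range` | diameter search interval | 1–20 nm | brackets both the ~16 nm magnetite and ~6 nm cobalt-ferrite optima |
| `limit_product` | safety cap on H·f, A·Hz/m | 5e9 | the admissible biological exposure product |

## Numerical choices

* **Langevin evaluation.** $\coth\xi - 1/\xi$ cancels catastrophically for
  small $\xi$; below $|\xi| \le 10^{-4}$ the series $\xi/3 - \xi^3/45$ is
  used (`langevin()`), and $L(\xi)/\xi$ gets its own series so
  $\chi_0 \to \chi_i$ smoothly as the field vanishes.
* **Debye factor.** $u/(1+u^2)$ is computed as $1/(u + 1/u)$, which cannot
  overflow for extreme $\omega\tau$ and makes the $\chi'' \le \chi_0/2$
  bound explicit.
* **Néel exponent.** $\exp$ overflows past ~709; the largest exponent on
  the study box is ≈ 300 (K = 294 kJ/m³, D = 20 nm), and anything beyond
  700 raises an explicit overflow error naming the exponent rather than
  returning `Inf`.
* **Diameter optimization.** $P_s(D)$ is extremely sharp (±30% in D loses
  more than half the power), so `find_optimal_diameter()` does a 0.05 nm
  coarse scan of the whole interval — no unimodality assumption — then
  golden-section refinement between the bracketing neighbours to 10⁻⁴ nm.
  Tables round D to 0.1 nm and powers to two decimals; JSON mirrors keep
  full precision. Near-degenerate double peaks (not observed on the study
  box) report the smaller diameter with a warning; a maximum on the search
  boundary is returned flagged, with a warning.
* **Determinism.** There is no randomness anywhere: identical configs give
  byte-identical CSV output.

## The biological-limit layer

Safe exposure caps the product H·f at `limit_product`. Along
$f_l = C/H$ the optimum is recomputed per field amplitude
(`limit_optimum()`, `psml_vs_field()`). The operating-window recommendation
(`operating_window()`) encodes two explicit rules: the window starts at the
smallest grid field whose limit power reaches a dose `threshold` (default
10 W/g), and ends at the hardware cap (50 kA/m default — larger coils are
impractical) unless the marginal gain per 10 kA/m step falls below
`saturation_rel_gain` (5%) first, in which case the last worthwhile field
ends the window. All three knobs are configurable; the published
recommendations these rules emulate were drawn by visual inspection of the
saturation curves, and the quantitative rules reproduce them for the
soft-ferrite compositions (x = 0: 10–30 kA/m; x = 0.1: 10–50; x = 0.2:
20–50) but extend the x = 0.05 window to 50 kA/m where the recommendation
stops at 40 — the computed marginal gain on that last step is ~8%, above
the 5% cutoff, so the discrepancy is a genuine difference between rule and
judgment, not a tuning target.

```{r window}
operating_window(x = 0) |> select(x, H_lo, H_hi, saturation_capped)
```

## Known reference discrepancies

Two cells of the shipped reference tables disagree with the model by more
than print rounding, and both are documented rather than absorbed:

* the bio-limit cell (x = 0.2, H = 30 kA/m) prints 20.07 W/g where the
  model (verified by two independent implementations) gives 22.18 W/g; the
  printed column's own increments are irregular exactly there, while the
  other 39 cells agree within 2%, so the reference value is treated as a
  misprint (its `reference_limit_optima()` entry keeps the printed value);
* the reference diameter for x = 0.4 at 250 kHz is truncated in print and
  stored as `NA`; the model computes 6.0 nm.

## What the reproduction shows — and what it does not

All inputs here are closed-form: there is no synthetic data generator and
no sampling noise, so "reproduction" means recomputing deterministic tables
(24 optima at H = 20 kA/m, 40 bio-limit optima, the operating windows) at
the study box and matching them cell by cell within print rounding
(`reproduce_study()` writes the comparison). Passing those checks validates
the implementation of the model, not the model's fidelity to real tissue:
polydispersity, particle mobility, aggregation-driven dipolar interactions
and temperature feedback all move real-world loss powers away from these
curves, typically downwards. The package's numbers are best read as an
upper-bound design map across composition, size and field parameters.
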