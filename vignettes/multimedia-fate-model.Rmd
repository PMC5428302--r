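---
title: "A gridded level-IV fugacity model for semivolatile pollutant fate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A gridded level-IV fugacity model for semivolatile pollutant fate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`fugrid` simulates the environmental fate of semivolatile organic
pollutants — the bundled default profile is PCB28, a light polychlorinated
biphenyl — over a regular latitude–longitude grid at a daily time step.
The science it targets is the air–soil exchange cycle that controls these
chemicals: primary emissions enter the atmosphere, disperse by wind,
deposit to soils, re-volatilize when warm ("secondary emission"), and hop
their way toward cold regions where they accumulate ("cold trapping").

Each grid cell is a dynamic (level-IV) fugacity model with 28
compartments: a two-layer atmosphere (boundary layer, 0–1000 m, and lower
troposphere, 1000–4000 m), a water column with an active sediment layer,
and six land-use soil types (urban, dry cropland, paddy, forest,
grassland, uncultivated) each resolved in four vertical layers (0.1 cm,
1 cm, 20 cm, 50 cm; the fourth depth is not constrained by observation
and is configurable). In fugacity form the concentration in a phase is
$C = Z f$ with $Z$ (mol m$^{-3}$ Pa$^{-1}$) the phase capacity and $f$
(Pa) the escaping tendency; transfers are conductances $D$
(mol Pa$^{-1}$ h$^{-1}$) with flux $D f$. The cell dynamics are

$$V_i Z_i \frac{df_i}{dt} = \sum_{j \ne i} D_{ji} f_j -
  \Big(\sum_{j \ne i} D_{ij} + D^{loss}_i\Big) f_i + s_i,$$

with $s_i$ the primary emission source. Capacities use the standard
closed forms: $Z_{air} = 1/RT$, $Z_{water} = 1/H(T)$, soil solids
$Z = f_{OC} K_{OC}\, \rho\, Z_{water}/1000$ with $f_{OC} = 0.56\,
f_{OM}$, and volumetric mixing for bulk phases. Aerosol capacity comes
from a Koa-based particle–gas partition
($\log K_p = \log_{10}(K_{OA} f_{OM}) - 11.91$) when $\log K_{OA}$ is
known, else a Junge-style fall-back from vapor pressure. Temperature
enters through van 't Hoff / Arrhenius corrections with per-chemical
energies (defaults 70 kJ mol$^{-1}$ for vaporization, 50 kJ mol$^{-1}$
for the Henry constant, 30 kJ mol$^{-1}$ for degradation — typical
semivolatile magnitudes).

## Transfer pathways

Between compartments of one cell (`build_transfer_system()`):

* air ↔ soil layer 1: an air-side film (mass-transfer coefficient
  3 m h$^{-1}$) in series with gas- and water-phase pore diffusion
  through half the layer depth, with Millington–Quirk tortuosity;
* one-way air → surface deposition: dry particle deposition
  (10.8 m h$^{-1}$ on the aerosol fraction), wet particle scavenging
  (scavenging ratio $2\times10^5$) and rain dissolution, apportioned to
  soils and water by land-use fraction;
* soil layer ↔ layer: pore diffusion, bulk-phase mixing (below), and
  one-way downward leaching advection at 30% of precipitation, leaving
  the column as a deep-leaching loss below layer 4;
* air ↔ water two-film exchange; water ↔ sediment diffusion; sediment
  burial (10$^{-4}$ m yr$^{-1}$);
* boundary layer ↔ lower troposphere exchange (36 m h$^{-1}$);
* first-order degradation everywhere, from per-compartment half-lives.

Every constant above is a named entry of `model_params()`.

### Why the soil layers carry a bulk mixing term

With pore diffusion alone, the 1-mm surface layer exchanges with air on
a time scale of about two days but with the layer below on a scale of
months. Its fugacity then simply tracks air, and the air–soil fugacity
fraction degenerates to a near-equilibrium value biased by wet
deposition. Real soils are stirred: bioturbation and cultivation move
bulk solids between layers, and multimedia soil models include this as a
mixing diffusivity. `fugrid` uses `soil_mixing_diff = 1e-7` m$^2$
h$^{-1}$ (≈ 9 cm$^2$ yr$^{-1}$, a literature-typical bioturbation
magnitude) acting on the bulk capacity. This couples the thin surface
skin to the larger sub-surface reservoir, which is what gives surface
soil a seasonal memory: the burden responds slowly while $Z_{soil}(T)$
swings with temperature, so soil fugacity surges in summer (net
volatilization) and collapses in winter (net deposition). One
consequence: because layers 1 and 2 act as a coupled pair, increasing
the leaching flux displaces burden mostly into layers 3–4 rather than
raising layer 2 specifically; the vertical-transfer checks therefore
assert the downward displacement (first layer down, sub-surface burden
up, burden-weighted mean depth up).

## Transport

Horizontal transport (`advect()`) moves the amounts in each air layer by
first-order upwind finite volumes on cell-centered winds, chosen for
exact mass conservation and positivity; its numerical diffusion is
acceptable at the model's box resolution. Boundaries are open: outflow
is ledgered as advective export, inflow is zero (clean far-field air).
Sub-stepping keeps the Courant number at or below 1 — the scheme's
stability and positivity limit, at which a pulse translates exactly one
cell per step. Water-current transport is omitted: over a mostly
land-covered domain it is negligible for an air-driven chemical.

## Numerical scheme

The per-cell system is stiff (capacities span many orders of magnitude),
so cells advance by implicit (backward) Euler on the 28×28 dense system,
one solve per cell-day. The sign structure (non-negative off-diagonals,
diagonally dominant columns) makes the implicit update non-negativity
preserving for any step size, and its fixed point is exactly the
level-III steady state, which the test suite verifies against an
independent linear solve. State is carried between days as amounts (mol)
and re-expressed in fugacity each morning with that day's capacities, so
temperature-driven changes of $Z$ cannot create or destroy mass; the
whole-run ledger (emissions in; degradation, deep leaching, burial and
boundary export out; holdings) closes to solver precision, far inside
the 0.1% audit bound the model is held to.

# Diagnostics

* **Fugacity fraction** $ff = f_S/(f_A + f_S)$ between the boundary-layer
  air and the first layer of urban soil (the soil type most exposed to
  the historical use of the chemical): 0.5 is equilibrium, below net
  deposition, above net volatilization. Monthly mean fields and site
  series are produced by `run_simulation()`.
* **Leaching potential** $L_p = S/(K_{OC} V_P)$ at 25 °C, the
  comparative index of transfer into deeper soil. The bundled PCB28
  property set (S = 0.27 g m$^{-3}$, $V_P$ = 0.034 Pa,
  $\log_{10} K_{OC}$ = 4.51) yields $2.45\times10^{-4}$, within 1% of
  the widely cited $2.47\times10^{-4}$; the residual reflects
  property-set uncertainty and is deliberately not forced away.
* **Secondary emissions**: cells whose cumulative inventory is zero are
  non-source; their soil burden arises from deposition alone. The
  emission factor EF = (window's volatilized amount)/(window-mean soil
  burden) is computed per calendar month (`monthly_ef()`); the residue
  is the full soil column by default. The windowing is a package
  decision — the underlying bookkeeping is daily, so other windows can
  be built from the outputs.
* **Mass-balance audit** (`mass_balance_audit()`): relative closure
  error of the ledger in percent.
* **Model evaluation** (`evaluate_pearson()`): sample Pearson R with the
  t-transform p-value between paired modeled and observed series, with
  an explicit exclusion list rather than any implicit outlier rule.

# The synthetic-data module

`synth_spec()` defines seeded, bit-reproducible study setups so every
stage is testable without external data: temperature as a linear
south–north gradient plus a sinusoidal seasonal cycle (peak mid-July)
and daily noise; Bernoulli wet days with exponential rain amounts;
uniform, rotating or random-walk wind regimes; and emission inventories
(single-cell, clustered, or banded patterns) confined to the warm third
of the domain with an exact domain total.

The standard fixture is a 10×10 grid at 1° resolution run for 5 years —
small enough to simulate in well under a minute, large enough to carry
gradients and transport. Its defaults compress a continental climate
into the domain: annual means 296 K at the warm edge to 272 K at the
cold edge (the span of a large mid-latitude country), 10 K seasonal
half-range, 3 mm day$^{-1}$ mean precipitation on 30% wet days, 50 t
yr$^{-1}$ total emission in clustered warm-band sources. Because the
transfer dynamics are linear in amounts, the absolute emission total
cancels from every ratio diagnostic.

For the climatic-mechanism experiments (seasonal ff cycle, EF–temperature
association, cold trapping) the test suite uses the *rotating* wind
regime on an 8×8 grid over 3 years. Seasonally reversing winds are the
monsoon analogue of the study setting; under steady westerlies a small
domain flushes most airborne mass across its eastern boundary within
days, leaving source proximity — not climate — to control deposition
patterns, which emulates a continental domain poorly. Paired single-cell
runs (identical seeds, one parameter varied) isolate the precipitation
and leaching responses.

What the generator does *not* emulate: orography, dynamical consistency
of winds with temperature, monsoonal moisture coupling, land-use
heterogeneity beyond a SOM gradient, and any real inventory. Passing the
mechanism tests therefore demonstrates that the model's process
representations respond in the documented directions under controlled
forcing — not that the package reproduces any particular observed field.

# Degenerate inputs and edge cases

Compartments with zero land-use fraction have zero volume and are
excluded from the solve (a cell with no water simply has no water or
sediment column). A fugacity fraction with both fugacities zero is
undefined and reported as missing, as is an emission factor with zero
burden and zero emission; a positive emission over a zero burden is
flagged as an inconsistency. The audit over a run with no inputs is
undefined rather than zero. The calendar is a 365-day no-leap calendar;
dates serialize as ISO-8601 ordinal dates (`YYYY-DDD`). Grid indexing is
`(row, col)` with row 1 at the southern edge.

# Interfaces

All gridded inputs and outputs travel as long-format CSV with full
double precision (bit-identical round trips), chemical profiles and run
configurations as YAML; the formats the package writes are exactly the
formats it reads. The command-line entry point
(`system.file("cli", "fugrid.R", package = "fugrid")`) offers `synth`,
`run`, `diagnose` and `evaluate` subcommands over the same exported
functions.

# Known limitations

* The water column carries no suspended-particle phase; water–sediment
  coupling is diffusive plus burial. Sediment is a minor compartment for
  an air-driven chemical over land.
* Vegetation canopies, snow, particle size spectra and congener
  interconversion are out of scope.
* First-order upwind transport is diffusive; fronts smear over a few
  cells.
* The EF magnitude depends on the air–soil exchange and mixing
  coefficients, which stand in for process detail that only
  site-specific data could constrain; the package's claims about EF are
  therefore directional (warm > cold, seasonal), not absolute.
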