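---
title: "Modelling synchrotron X-ray dose to roots imaged in soil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling synchrotron X-ray dose to roots imaged in soil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizodose)
```

## The problem

Time-resolved synchrotron X-ray computed tomography (4D XCT) images a living
root growing in soil by rotating the sample through 180 degrees under an
intense X-ray beam, repeatedly, over hours. The deposited dose can reach
kilograys per scan and visibly slows or arrests root growth. `rhizodose`
models that dose budget end to end: the beam spectrum delivered to the
sample, its attenuation through the soil as the sample rotates, the absorbed
dose rate in a root segment, the dose per scan and per experiment, and the
relationship between cumulative dose and the measured root growth rate. The
package is a desk-scale model: every stage is deterministic and fast, with a
Monte Carlo photon-transport engine as the scatter-aware cross-check.

## Beam spectra

A storage-ring bending magnet with critical energy $E_c$ emits the universal
spectrum $G_1(y) = y\int_y^\infty K_{5/3}(x)\,dx$ with $y = E/E_c$, where
$G_1$ is the flux per *relative* bandwidth (the familiar "per 0.1% bandwidth"
curve). The photon density per unit energy therefore carries an extra $1/E$:
`bending_magnet_spectrum()` bins $G_1(E/E_c)/E$ on a 0.5 keV grid from 1 to
400 keV and normalises the 5--400 keV total to the configured flux
(default $4.61\times10^{13}$ photons/s/mA). $K_{5/3}$ is integrated by
adaptive quadrature (`besselK`), cached on a log grid with the analytic
$y^{1/3}$ and $\sqrt{y}\,e^{-y}$ asymptotes outside it.

Two peak conventions coexist in practice and `spectrum_stats()` reports
both: `e_peak` is the maximal-flux bin of the photon histogram, while
`e_peak_bw` is the peak of the flux-per-bandwidth display curve
($E\,\phi(E)$), which is how a "peak energy" is customarily quoted for a
bending-magnet beamline. For the default beamline configuration
(critical energy $0.665\,E^2[\mathrm{GeV}]\,B[\mathrm{T}] = 19.15$ keV for a
3 GeV ring and a 3.2 T dipole, a 0.2 mm diamond exit window and a 1.434 m
air path), the delivered beam has `e_peak_bw` 17.25 keV and mean 24.6 keV;
hardening through 0.36 and 2.45 mm of silicon moves these to 23.3/30.9 and
34.8/42.3 keV. Only this display-curve peak is consistent with the
photon-weighted means and the measured sample transmissions; the photon
histogram itself peaks lower.

Quasi-monochromatic multilayer-mirror beams are modelled as a Gaussian peak
(default FWHM 5% of the peak energy) plus a uniform low-energy tail between
1 keV and peak $- 3\cdot$FWHM carrying a configurable flux fraction
(default 5%). The mirror spectra are not tabulated publicly, so this is a
deliberate, documented approximation; packaged scenarios pass the
construction through the scenario's silicon filter and rescale to the quoted
at-sample flux, since those fluxes count "all photons reaching the sample".

## Materials

Elemental mass attenuation ($\mu/\rho$) and mass energy-absorption
($\mu_{en}/\rho$) coefficients are shipped as a plain-text table on the
standard compilation grid (1--500 keV, duplicated nodes at absorption
edges; a query exactly at an edge takes the above-edge value). Mixtures use
the standard rule $\sum_i w_i c_i(E)$ with log--log interpolation, exact at
the nodes (water at 50 keV reproduces 0.2269 cm$^2$/g). Partial coefficients
for the Monte Carlo engine are constructed at load: incoherent scattering
from the free-electron Klein--Nishina cross-section, coherent scattering
from a Thomas--Fermi-screened hydrogenic form-factor quadrature, and
photoelectric absorption as the residual, so the partials sum to the total
by construction. For the minor constituents Ar, K, Ca and Ti the
energy-absorption column is reconstructed from the photoelectric residual
(with a K-fluorescence escape correction) plus the Klein--Nishina
energy-transfer component; these elements carry a few percent tabulation
uncertainty but under 4% of the soil mass.

The packaged soil is an Oxisol-like nine-element emulation: a kaolinitic /
gibbsitic assemblage with quartz, a few percent iron oxide, minor Ti, K and
Ca and some organic carbon, chosen once so that (i) oxygen, silicon and
aluminium make up 90% of the solid mass, and (ii) the monochromatic
transmissions of the bulk material at 22 and 67 keV are consistent with the
measured sample transmissions of the beamline experiments. Raising the iron
content to hematite-rich levels would steepen the angular dose contrast but
is excluded by those same transmissions. The bulk material combines the
solid (particle density 2.7 g/cm$^3$, 70% v/v), pore water (15% v/v) and
pore air (15% v/v) by mass, giving 2.04 g/cm$^3$. The root is modelled as
water.

## Geometry and fluence

The sample is a 2.9 mm diameter soil cylinder with a 0.6 mm diameter,
5.25 mm tall water "root" offset 1 mm from the rotation axis (0 for the
cone-beam comparisons); the illuminated root segment is the 0.077 mm square
beamlet through the root. Ray path lengths are exact ray--cylinder chords;
`theta = 0` puts the root directly upstream of the beam and rotation is
clockwise, so a clockwise scan from angle $a$ sweeps $[a, a+180]$ in
increasing angle.

Two fluence normalisations are supported, and the choice matters more than
any other single parameter:

* **Divergence footprint** (`mogno_a_beam()`, the unfocused polychromatic
  configuration): the total flux passes through a slit-limited
  0.43 mrad cone and spreads over $(0.43\,\mathrm{mrad} \times
  22.915\,\mathrm{m})^2 \approx 9.85\times9.85$ mm$^2$ at the sample. The
  2.9 mm field of view is a detector crop of that wider beam, so spreading
  the flux over the FOV would overstate the fluence roughly tenfold.
* **FOV-uniform** (`mogno_b_beam()`, the focused cone beam): all photons
  pass through the FOV by construction, so the fluence is flux/FOV$^2$ and
  grows as the inverse square of the focus--sample distance.

Both are built from printed beamline geometry only; no dose value was used
to calibrate them.

## Dose engines

The kerma engine is deterministic: for quadrature points $x$ in the region,
$\dot D(x) = \sum_b \phi_b\,e^{-\sum_j \mu_j \ell_j(x)}\,E_b\,
(\mu_{en}/\rho)(E_b)$, volume-averaged (chord-weighted midpoint quadrature,
converged to better than $10^{-4}$ at the default 15$\times$21 grid).
Secondary electrons deposit locally — the kerma approximation, appropriate
because the CSDA range below 70 keV is tens of micrometres, far below the
root diameter. Fluorescence of the low-Z matrix is ignored (sub-percent,
reabsorbed within ~50 um). Scattered photons are not transported.

The Monte Carlo engine (`mc_run()`, C++ via Rcpp) transports photons with
Woodcock (delta) tracking through the soil/root geometry: photoelectric
events absorb fully, incoherent events sample the Klein--Nishina ratio by
Kahn's rejection method and deposit the recoil energy locally, coherent
events resample the direction against the screened form factor. Photons
below the 1 keV cutoff deposit their remainder. Air inside and around the
sample is treated as vacuum (optical depth below $10^{-4}$ on the mm
scale). Tallies are normalised per primary, converted to dose with the
$1.602176462\times10^{-7}$ GeV/g $\to$ Gy constant, and scaled by the
photon rate through the simulated cross-section; uncertainties come from
ten independent batches. On an absorbing-only toy material the two engines
agree within Monte Carlo noise (a few tenths of a percent at $6\times10^6$
primaries); under full-sample illumination scattered photons add roughly
8--10% to the root dose and 5--8% to the soil-increment dose for the
packaged spectra, which bounds the kerma engine's systematic deficit. A
Woodcock collision estimator scores the scatter-aware dose-to-water map on
the soil shells (`radial_dose_map(engine = "mc")`, `mc_run(n_azimuth=)`).

The transported partial cross-sections are rescaled on the fine (0.1 keV)
lookup grid so their sum reproduces the interpolated total attenuation
exactly; source photons carry bin-center energies, matching the kerma
discretisation.

## Scan doses and the angular profile

`angular_profile()` evaluates the segment dose rate every 30 degrees over
0--180 and completes the circle by mirror symmetry. `integrate_scan()` fits
an even polynomial in $\cos\theta$ (degree at most 6) to the 13-point
profile — automatically 360-periodic and symmetric, so it cannot develop
Runge artifacts at the arc ends — integrates it in closed form over the
scan arc and divides by the arc length; a trapezoid rule on the sampled
profile is available as a cross-check and agrees within 5% on all packaged
scenarios. Dose per timepoint is mean rate $\times$ ring current $\times$
full acquisition time, with the conventional 10% uncertainty; cumulative
dose multiplies by the number of timepoints (the start angle is fixed
between scans).

`radial_dose_map()` removes the root and maps the dose rate per degree in
four concentric 0.29 mm soil increments, then integrates five reference
arcs. Because the map is used to judge the dose a root *at that position*
would receive, it reports dose to root-equivalent tissue (water) by
default; `dose_to = "soil"` gives the mineral dose, which is 3--4 times
higher at these energies owing to the mineral's photoelectric
energy-absorption. Published increment values are commensurate with the
water convention. The published table's kGy/s/mA unit is internally
inconsistent with the per-scan doses (it would imply about $10^6$ kGy per
scan); the package interprets those values as Gy/s/mA throughout.

Two reconciliations worth knowing about: the printed illuminated-segment
volume ($2.93\times10^{-6}$ cm$^3$) differs by ~18% from the analytic
beamlet-root intersection ($3.55\times10^{-6}$ cm$^3$); the analytic volume
is the default and the printed constant is accepted as
`segment_volume_cm3`. And the angular max/min contrast reported for the
wall-adjacent root (about fivefold with light filtering) is stronger than
primary-beam attenuation allows given the same experiments' measured
transmissions — with the packaged soil the model gives 3.7 (0.36 mm Si) and
1.6 (2.45 mm Si). The package reproduces the transmissions and the arc
orderings exactly and accepts the weaker contrast as the price of that
consistency.

## Synthetic growth series

`simulate_growth_series()` generates segmented-mask time series with a
linear dose response: the rate in interval $k$ is $\max(0,\ \beta_0 -
\beta_1 D_k + \varepsilon_k)$, with cumulative dose $D_k$ after $k$ scans,
Gaussian noise truncated at zero (rates are nonnegative), and defaults of
$\beta_0 \sim U(0.5, 0.8)$ mm/h (the unexposed growth range),
$\beta_1 = 2\times10^{-5}$ mm/h per Gy (0.02 mm/h per kGy, the scale at
which kilogray-per-scan doses arrest growth within a few scans) and
$\sigma = 0.02$ mm/h. Masks are voxelised cylinders advanced along the
growth axis; `growth_between()` measures tip advance (default) or
new-voxel volume divided by the mean cross-sectional area — the two agree
exactly on straight cylinders. `dose_response()` fits ordinary least
squares and returns a classed object with the usual accessor methods.

The generator emulates the *measurement process* (nested masks, voxel
quantisation at 2.88 um, clamping at growth arrest), not real root biology:
no branching, no tortuosity, no diameter growth, no dose-rate or
fractionation effects. Passing recovery tests therefore demonstrates that
the estimator chain is unbiased and calibrated on its own model, not that a
linear dose response is biologically true.

One sizing note: $\pm2\,\mathrm{SE}$ coverage of the slope approaches its
nominal ~95% only with enough residual degrees of freedom (with four points
the $t_2$ reference makes it ~82% by construction). The packaged coverage
experiment therefore uses 16 timepoints at 1.5 kGy per scan (coverage ~92%
over 200 seeds), while the worked single-seed example keeps the four-point
design of a real experiment.

## Numerical choices and problem sizes

* Energy grid 0.5 keV over 1--400 keV (resolves silicon hardening without
  bloating tallies); Monte Carlo coefficient lookups on a 0.1 keV grid.
* Absorption edges: duplicated nodes, above-edge value at the edge.
* Angular profiles at 30-degree steps (13 points), radial maps per degree;
  arc integrals analytic for the cosine polynomial, trapezoid for dense
  curves.
* Monte Carlo checks in the test suite use $10^5$--$6\times10^6$ primaries
  in 10 batches; the acceptance script uses $2\times10^6$. These sizes give
  sub-percent engine agreement and stable scatter fractions.
* Degenerate inputs fail loudly: non-normalised compositions, energies
  outside the table, descending spectrum files, all-zero spectra, masks of
  mismatched shape, degenerate dose designs.

## Known limitations

* No electron transport, no fluorescence, no detector backscatter; absolute
  doses are primary-beam collision kerma (the Monte Carlo engine bounds the
  scatter correction at ~5--10% for the packaged scenarios).
* The quasi-monochromatic spectra are single-peak models of multi-peak
  mirror output; configuration *ratios* are robust to this, absolute
  cone-beam doses less so.
* Coefficient tables are transcribed, not fetched; minor elements carry a
  few percent uncertainty.
* The soil is homogeneous; no particle microstructure, moisture gradients
  or conical sample taper.
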