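---
title: "Methods: a discrete statistical model of trabecular bone remodelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a discrete statistical model of trabecular bone remodelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`bmusim` simulates bone remodelling and mineralisation on a 2D pixel
lattice representing a slice of a trabecular representative volume element
(RVE). Each pixel of side `lambda` (µm) is either bone matrix or marrow,
so the areas obey `A_RVE = A_Bm + A_Ma` exactly, and the area fractions
`f_Bm + f_Ma = 1`. Each bone pixel is a three-phase mixture of organic
matter, mineral and water with `phi_m + phi_o + phi_w = 1`; the organic
fraction `phi_o = 1/3` is the same for every pixel and constant in time,
so mineralisation is a balanced exchange of water for mineral.

The mineral content of a pixel is tracked through its ash fraction
`alpha = m_mineral / m_dry`, from which

* the mineral area fraction follows as
  `phi_m = alpha * rho_o * phi_o / (rho_m * (1 - alpha))`,
* the matrix density as `rho = rho_m phi_m + rho_o phi_o + rho_w phi_w`
  (defaults `rho_m = 3.2`, `rho_o = 1.1`, `rho_w = 1.0` g/cm³),
* the calcium content as `Ca wt% = 100 * 0.3989 * alpha`, with 0.3989 the
  calcium-to-mineral mass ratio of hydroxyapatite `Ca10(PO4)6(OH)2`.

The apparent density of the RVE is the bone-pixel density summed over the
lattice, `rho_app = f_Bm * mean(rho)`.

### Remodelling events

Remodelling is carried out by discrete basic multicellular units (BMUs)
activated on the bone perimeter (bone pixels 4-adjacent to marrow) at
frequency `Ac.f` (BMU/mm²/year). Events are evenly spaced in time with
period `T_rep = 1 / (Ac.f * A_RVE)`; `N = floor(Ac.f * T * A_RVE)` events
occur over a run of `T` years. Activation is *targeted*: the mean ash
fraction within a search disc (default radius = the mean hemiosteon
radius) is computed around every perimeter point, and the BMU seeds at the
most highly mineralised surface region, ties broken uniformly at random.

Each BMU executes the classic resorption–reversal–formation sequence as a
hemiosteon of radius `R_On ~ Normal(100, 2.5)` µm (sampled once per BMU,
truncated at three standard deviations and at zero):

* **Resorption** (`Rs.P` = 21 d): the resorption radius grows linearly,
  `r_Rs = R_On * tau_b / Rs.P`; every bone pixel whose centre lies within
  `r_Rs` of the seed becomes marrow. On a flat surface this digs the
  familiar semi-circular (hemiosteonal) cavity; marrow within the disc is
  unaffected.
* **Reversal** (`Rv.P` = 10 d): quiescent.
* **Formation** (`FP` = 91 d): the formation radius shrinks linearly from
  the cement line, `r_F = R_On * (1 - (tau_b - tau2)/FP)`; marrow pixels
  of the BMU's own resorbed set with distance in `[r_F, R_On]` become
  unmineralised osteoid (`phi_m = 0`, `phi_w = 2/3`). Underfilling stops
  formation as soon as `r_F` drops below `u_f * R_On`: `u_f = 0` refills
  completely (balanced remodelling), `u_f = 1` forms nothing (uncoupling).

Formation is restricted to the BMU's own resorbed pixels: the cement line
bounds refilling, so a BMU can never ossify pre-existing marrow. When
BMUs overlap, a later BMU may resorb pixels formed (or queued) by an
earlier one; the earlier BMU simply skips pixels that are no longer
marrow of its own cavity (first-writer-loses). Net-balance statements are
therefore asserted only for isolated BMUs. BMU discs reaching beyond the
lattice frame are clipped; the frame itself never counts as marrow for
perimeter detection.

### Mineralisation kinetics

Osteoid begins to mineralise after a lag `Mlt` (10 d). Each pixel carries
a clock `tau_m` and its ash fraction follows the double-exponential law

```
M(tau) = c1 (1 - exp(-tau/t1)) + (c_max - c1)(1 - exp(-tau/t2))
```

The calibration, applied by `calibrate_mineralisation_law()`:

* `c1 = 0.45`, the primary-phase ash plateau;
* `c_max = 0.30 / 0.3989 = 0.752`, the ash fraction at the ~30 wt%
  calcium cap;
* `t1 = T_prim / ln 20 = 3.34 d`, so the first exponential reaches 95% of
  `c1` within the ~10-day primary phase;
* `t2` solved numerically so that `M(Tsec) = 0.95 * c_max`, making `Tsec`
  (in years) the duration of secondary mineralisation.

The "95% completion" convention is a documented choice: sources defining
the exact completion level used for published `Tsec` values are not
explicit, so the level is a configurable parameter (`completion`). We
treat `t2` as the secondary time constant (it multiplies the second
exponential); descriptions attributing the secondary slope to `t1`
conflict with the law itself and are not followed.

A pixel freezes when `alpha >= 0.999 * c_max`, which bounds per-step work
and produces the pile-up of never-remodelled bone just below 30 wt%
observed in measured distributions. An alternative rule that also freezes
at `tau_m >= Tsec` was considered and rejected: with the calibration
above it pins never-remodelled bone at `0.95 * c_max` (28.5 wt%), which
contradicts the ~30 wt% modal pile-up the low-turnover distributions
should show.

Initial bone is assigned the uniform ash fraction 0.70 together with the
*consistent* clock `M^{-1}(0.70)` (numerical bisection, tolerance 1e-10),
so never-remodelled bone keeps maturing towards the cap instead of being
parked at its initial value.

Pixels formed by a BMU keep their clock paused until that BMU completes
(configurable via `mineralise_in_active`); the maximal consequence is a
shift of at most one formation period (~3 months) in the onset of
mineralisation, negligible against `Tsec` values of years.

### The simulation loop

Time advances in 1-day steps (1 year = 365.25 days). Within a day:
activation (if `t` crosses `n * T_rep`; the first event is at `T_rep`,
configurable), then each active BMU advances one step in activation
order, then background mineralisation, then recording (default stride
7 days). Ordering matters only for same-day collisions and is fixed so
runs are reproducible; the whole simulation is deterministic given the
master seed. Internally mineralisation is stored as the day each pixel's
clock started, so the daily update is O(1) and the ash field is evaluated
on demand; this is an exact reformulation, not an approximation.

## Synthetic geometry

The built-in generator emulates a binarised in-silico micro-CT slice:
1 µm (or coarser) resolution and strut thickness in a 200–400 µm band. A
periodic Gaussian random field (spectral synthesis, exact Gaussian
transfer function) is thresholded at the exact pixel-count quantile of
the target bone fraction. The field's correlation length is set from the
midpoint of the requested thickness band via `sigma = t_mid / K` with
`K = 2.0`, calibrated once against the distance-transform ridge oracle
(local thickness = twice the Euclidean distance-map value at ridge
pixels) on 2000 × 2000 px fields and then frozen. The generator verifies
the realised median thickness and reports unattainable requests instead
of clipping them; the check carries a 20% margin because the ridge median
is estimated from only a handful of struts on millimetre-scale lattices.

The default target bone fraction is 0.42. It is a configurable choice,
not a measured value: published apparent trabecular densities of
0.6–0.75 g/cm³ together with an initial ash fraction of 0.70 (matrix
density 1.62 g/cm³) imply `f_Bm ≈ 0.37–0.46`, and 0.42 places the initial
apparent density (0.68 g/cm³) mid-band.

What the generator does *not* emulate: 3D connectivity (2D slices
over-represent isolated interstitial cores, since BMUs only act on the
in-plane surface), plate-and-rod architecture, anisotropy,
lacuno-canalicular porosity (~3–5%), and scanner noise. Results that pass
on this geometry therefore validate the remodelling/mineralisation
machinery, not micro-CT realism.

## Tunable parameters

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `Ac_f` | 4 | BMU/mm²/y | activation frequency (free parameter) |
| `Tsec` | 4 | years | secondary mineralisation time (free parameter) |
| `u_f` | 0 | – | underfilling coefficient |
| `Rs_P`, `Rv_P`, `FP` | 21, 10, 91 | days | phase periods |
| `Mlt` | 10 | days | mineralisation lag time |
| `R_On_mean`, `R_On_sd` | 100, 2.5 | µm | hemiosteon radius distribution |
| `search_radius` | `R_On_mean` | µm | targeted-search disc radius |
| `alpha0` | 0.70 | – | initial uniform ash fraction |
| `lambda` | 2 | µm | pixel size |
| `dt` | 1 | day | time step |

## Numerical choices

* Distances are Euclidean between pixel centres in µm; a pixel is inside
  a radius iff its centre distance is ≤ the radius (ties included, with a
  1e-9 µm guard against floating-point edges).
* Targeted-search means are computed by FFT disc convolution with
  periodic wrap — consistent with the periodic synthetic geometry, and an
  approximation near the frame for imported images. Ties in the argmax
  are any means within 1e-9 of the maximum.
* The search disc is the full disc intersected with bone (not a
  semi-circle oriented into the bone); this is configurable by radius
  only.
* `M^{-1}` uses bisection to 1e-10 on alpha; the law calibration solves
  for `t2` with `uniroot` at tolerance 1e-10.
* BMDD bins are 0.25 wt% wide (fine enough to resolve the near-30 wt%
  pile-up, coarse enough for stable modes); `Ca_MEAN` averages raw pixel
  values, never bin midpoints; FWHM interpolates linearly across the
  outermost half-maximum crossings; skewness is the adjusted
  Fisher–Pearson standardised third moment.
* Degenerate inputs error early: all-marrow BMDDs, geometry below
  100 px a side, thickness bands outside (50, 1000) µm, ash fractions
  outside their domains. A simulation whose perimeter vanishes (fully
  resorbed or fully solid RVE) halts with a warning and returns the
  partial result flagged `halted`.

## Study conditions and problem sizes

The packaged experiments run at a reduced desk scale chosen as this
package's own default study condition: a 1 mm² RVE at `lambda = 2` µm
(500 × 500 px), bone fraction 0.42, thickness 200–400 µm, five replicate
dynamics seeds sharing one geometry. The full-scale setting (`lambda =
1` µm, 15 replicates, 8 × 8 sweep grids) is available through the same
configuration interface. Scenario chains warm up for 5 years of
physiological remodelling (Ac.f = 4, Tsec = 4, u_f = 0) and then branch
into 3-year pathology runs (high FP = 475 d; high Ac.f = 8; underfilling
u_f = 0.5; no filling u_f = 1), all compared against a 3-year
physiological control from the same warm-up state.

## Known limitations

* 2D stereology: in-plane surfaces only; no bulk (cylindrical-osteon)
  remodelling, so thick-strut cores can never be reached — at small
  hemiosteon radii this leaves a large never-remodelled fraction near the
  calcium cap and raises the simulated `Ca_MEAN` above measured
  trabecular values.
* No mechanics: no load-driven targeting, no microcrack dynamics.
* Idealised BMU shape: semi-circular cross-section; no trench-like
  progression along the surface, no curved/branched/lens-shaped
  hemiosteons.
* No cell-population dynamics: phase durations are fixed inputs.
* The appendix-level derivation of the published mineralisation-law
  constants is replaced by the documented calibration above; parameters
  are configurable where the original convention is unknown.
```{r}
library(bmusim)
law <- calibrate_mineralisation_law(Tsec = 8)
law
```
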