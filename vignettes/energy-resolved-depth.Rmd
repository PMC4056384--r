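---
title: "Energy-resolved depth imaging of Y-90 bremsstrahlung: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-resolved depth imaging of Y-90 bremsstrahlung: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ybrems)
```

## 1. The model and its assumptions

⁹⁰Y is a pure beta emitter (endpoint 2.3 MeV); imaging its distribution in
liver radioembolization relies on the continuous bremsstrahlung spectrum the
betas produce in tissue. The forward model implemented here describes an
*ideal* camera: no collimator penetration or scatter, no patient scatter, no
back-compartment backscatter, perfect spatial resolution, and — in the
analysis pipeline — perfect energy resolution. Tissue in the liver slice is
taken as water-equivalent. Under these assumptions the count-rate spectrum
in a pixel is a line integral of activity times geometric efficiency along
the collimator line of response (LOR), attenuated in water from the patient
surface inward, and weighted by the bremsstrahlung yield `a(E)`.

The essential structural fact is that the water attenuation coefficient
`mu(E)` is strictly decreasing over the usable energy range, so energy can
be relabeled by `mu`. After dividing out `a(E)` and the surface attenuation
`exp(-mu l_p)`, the measurement in each pixel becomes the Laplace transform
in depth of the profile `Abar(l) = A(l) G(l)`. Depth information is
therefore encoded *spectrally*: the recorded photon energy plays the role
of the projection angle of conventional SPECT. Everything downstream — the
normalization, the `mu` relabeling, and the regularized inversion — follows
from this identity.

Two deliberate consequences of the ideal-camera assumption:

* the synthetic acquisitions used for the depth-recovery tests are run with
  `resolution = 0` and unit detection efficiency, because the Laplace
  identity holds for the *geometric, unblurred* spectrum. Energy blur and
  crystal efficiency are implemented (`apply_detector_response()`) and can
  be switched on, but deconvolving them is outside this model's scope;
* attenuation is accrued only beyond the surface depth `l_p`, exactly as the
  normalization assumes. Air gaps inside the body advance depth without
  attenuating (the default "water-equivalent path"; a "geometric" switch
  applies water attenuation to the full depth instead). For the homogeneous
  water phantoms of interest the two coincide.

## 2. Bundled physical data and their provenance

The package bundles per-material tables (CSV under `inst/extdata/`,
regenerated by `data-raw/make_tables.R`) of photoelectric and incoherent
mass attenuation coefficients on a logarithmic 30 keV–3 MeV grid, with
log-log linear interpolation that is exact at the knots. Conventions:

* **"total" excludes coherent (Rayleigh) scattering** — the narrow-beam
  correction convention. Coherent scattering neither deposits energy nor
  (to first order) removes photons from a broad imaging beam, and excluding
  it keeps `total = photoelectric + incoherent` an exact partition.
* Incoherent cross sections are exact Klein–Nishina on free electrons;
  electron binding is neglected (a few percent overestimate below
  ~100 keV for high-Z crystals, negligible above).
* Photoelectric cross sections are built from a log-log master curve for
  lead (standard narrow-beam anchor values minus the Klein–Nishina and a
  small coherent estimate), scaled across elements as `(Z/82)^4.1` per atom
  with a 1/5.3 step below each K edge. The exponent was calibrated so the
  resulting NaI total at 511 keV reproduces the standard ~2.9 cm
  attenuation length, and the resulting BGO and GSO 511 keV attenuation
  lengths land on their well-known values — an independent check, since
  they were not fitted.
* Accuracy tier: ~1–3 % for the compound crystals above 100 keV (the regime
  the Monte Carlo uses), degrading to ~10–20 % below 50 keV and below heavy
  K edges. Water is good to ~2 % across the imaging window. Pair production
  is not modeled; no photon above 511 keV is transported.

The default ⁹⁰Y bremsstrahlung yield `a(E)` folds a Kramers thin-target
shape `(T − E)/E` over an allowed-shape approximation of the beta spectrum
(endpoint 2300 keV), normalized to unit integral. The exact shape is
uncritical by construction: `a(E)` cancels in the normalized quantity
`C`; only positivity and the endpoint matter, and the table is
user-replaceable (`brems_yield(..., table = )`).

## 3. Geometry

Coordinates: detector plane at `z = 0`, pinhole aperture at `(0, 0, F)`
(default `F` = 15 cm, 8 mm aperture, matching the high-energy pinhole
design with a 45×25 cm, 5 cm thick lead front wall of about 64 kg); object
space at larger `z`. Pixel centers sit at `(i + 0.5)·pitch − extent/2`.
Both LOR parameterizations are *unit speed* — the parameter `l` is
Euclidean arclength from the crystal (parallel) or the aperture (pinhole);
`lor_arclength_scale()` makes this contract explicit and the test suite
asserts it.

The paper-level model leaves the geometric efficiency `G` abstract; here it
is purely geometric (detector efficiency lives in the camera response):
parallel holes use the standard `(K d² / (l_e (d + t)))²` sensitivity with
hexagonal-packing `K = 0.26` and `l_e` the physical hole length (the
energy-dependent septal correction is omitted; any constant factor cancels
in depth-profile shape recovery), pinholes use
`d² sin³θ / (16 h²)`.

## 4. The projector and its numerics

`project()` uses Siddon-style exact voxel path lengths. Within each voxel
segment the attenuated line integral is evaluated analytically
(`(1 − e^{−μΔl})/μ`), so the only quadrature error left is evaluating `G`
at segment midpoints; segments are subdivided to ≤ 2 mm so that the
pinhole `1/h²` variation is captured. The suite verifies the projector
against a 10 µm brute-force ray-marching integrator to 0.5 %, and against
the single-voxel closed form `a·A·G·Δl·e^{−μd}` at several depths.

Degenerate inputs behave predictably: a LOR that misses the phantom has
`surface_depth = Inf` and projects zero; zero activity projects zero;
energies outside the bundled tables raise range errors; normalization
refuses any grid touching the beta endpoint where `a(E) = 0`.

## 5. Inverting the Laplace transform

The depth profile is discretized on `0–30 cm` with `0.5 cm` spacing
(defaults). The kernel `K[i,j] = w_j exp(−mu_i l_j)` uses trapezoid
weights. The inversion solves

    min || K Abar − Chat ||² + λ || D Abar ||²   s.t.  Abar ≥ 0

with `D` a difference operator of order 0–2 and the nonnegativity handled
by a Lawson–Hanson active-set NNLS written in the package (no NNLS solver
is available among the declared dependencies; the solver is exercised
against dense normal-equation solves and KKT conditions in the tests).
λ is either fixed or chosen by Morozov's discrepancy principle — bisection
on `log λ` until the data residual matches the stated noise level
`noise_sd · sqrt(m)`.

**How ill-posed is it?** Over the (50, 350) keV acquisition window the
water `mu` spans only a factor ~2 (about 0.11–0.22 cm⁻¹). The condition
number of `K` grows geometrically with the depth-grid size (a documented
diagnostic attached to every inversion), and the practical consequence is
visible in the two-point-source experiment in the test suite: two equal
point sources at 5 and 15 cm with 1 % Gaussian noise are *not* resolvable
to 1.5 cm. With discrepancy-selected λ the maximally-smoothed solution
consistent with the data is a single broad hump — flat profiles fit two
exponentials within 1 % over so narrow a `mu` range. The test therefore
freezes tolerances measured in pilot runs (small fixed λ, order-0 penalty:
two peaks found in ≥ 90 % of runs, shallow source located to ~2–3 cm,
deep source only to ~7–8 cm). This is a property of the physics, not of
the solver: depth resolution from energy alone degrades quickly with
depth, which is why the reconstruction is intended to *complement*
angular sampling, not replace it. Point-like sources are the favorable
case: for a single source the log-linear estimator
(`point_source_depth()`, minus the OLS slope of `log Chat` vs `mu`) is
unbiased to < 0.05 cm at 10⁵ recorded counts, and the end-to-end pipeline
test (phantom → Poisson acquisition → normalize → `mu`-rebin → estimate)
requires mean error < 0.3 cm over 200 seeds.

Ambiguity of the inverse Laplace transform up to a Lerch null function is
handled as physicists do: the reconstruction is reported on the finite
nonnegative grid and claims nothing outside it. Under symmetric data NNLS
may return any of several equivalent-support minimizers; tests assert
residuals, centers of mass, and peak centroids, never exact support.

## 6. The crystal Monte Carlo and the two readings of "absorption efficiency"

`simulate_full_energy_efficiency()` transports a pencil beam at normal
incidence through an infinite-transverse slab: free paths from the total
(pe + incoherent) coefficient, photoelectric vs Compton branching by
cross-section ratio, Klein–Nishina sampling (rejection on the exact
differential in the energy ratio) for the scattered photon, which is
tracked until photoelectric absorption or escape through a slab face.
Electrons are absorbed locally; a history is "full energy" exactly when
its photon chain ends in absorption. Photons falling below the 30 keV
table floor are absorbed on the spot (their range in any scintillator is
sub-millimeter). Characteristic x-ray escape is not modeled — the main
known bias for thin NaI, which is why the NaI acceptance band is the
widest. Every stochastic entry point takes a required seed and is exactly
reproducible; history bookkeeping (`full + partial + none = n`) is
asserted exactly.

Two readings of crystal "absorption efficiency" exist and the package
implements both:

* `mode = "attenuation"` (and the analytic `absorption_probability()`):
  the probability of *any* interaction, `1 − e^{−μt}`;
* `mode = "full_energy"` (default): the probability of depositing the
  *entire* incident energy, which is what an acquisition window around a
  photopeak actually selects.

The two differ greatly for thin or low-Z crystals. Running both modes
shows that the published design numbers for thick BGO and GSO at 511 keV
("90 and 84 %") coincide with the attenuation reading of this model
within ~3 points, while the published "≈15 %" for 3/8″ NaI coincides with
the full-energy reading (the attenuation reading is ~27 %). The
acceptance targets adopt the full-energy reading throughout, as specified;
consequently the GSO criterion is honestly red (the model gives ~74 %,
and the gap — first-interaction Compton escape at 511 keV — cannot be
closed by any defensible change to the cross-section tables), the BGO
value sits at the edge of its ±3-point band, and the NaI value and the
400 keV BGO/NaI ratio pass comfortably. The numbers themselves are
computed at run time by `scripts/acceptance.R` and by
`tests/testthat/test-acceptance.R`; nothing is hard-coded.

## 7. Gain calibration

BGO light yield drifts by −1.2 %/K, shifting the whole energy scale. The
model is a single multiplicative gain `1 + c (T − T₀)`; the correction
procedure records a ⁹⁹ᵐTc reference spectrum (nominal photopeak bundled as
140.5 keV, a standard nuclide datum), fits the photopeak with a Gaussian
(count-weighted centroid as fallback), and multiplies subsequent event
energies by `nominal/measured`. Rescaling is linear through zero — a
single gain factor, no offset — which is the assumption the round-trip
tests encode (peak restored to 0.2 % for |ΔT| ≤ 10 K). Per-block
correction is a matter of applying the factor per block id in the event
stream.

## 8. What the synthetic generator does and does not emulate

`point_source_phantom()` reproduces the classic test object — a point
source behind a condensed shell (water or PMMA) with air in front;
`liver_phantom()` voxelizes ellipsoid/sphere/box primitives with
supersampled fractional occupancy (volumes conserved to ~2 % at 2 mm
voxels, converging under refinement); `generate_acquisition()` draws
independent Poisson counts per pixel-energy bin around the projected,
response-filtered mean. What is *not* emulated: patient and collimator
scatter, penetration, fluorescence, backscatter, dead time, pile-up —
i.e., every contamination component the ideal-camera model excludes. A
green end-to-end test therefore establishes the correctness and statistical
calibration of the geometric pipeline, not clinical performance in the
presence of scatter.

## 9. Known limitations

* Authored cross-section tables (Section 2): a few percent accuracy, not a
  certified database; the table files are user-replaceable.
* Depth-from-energy resolution is intrinsically poor beyond ~10 cm with
  the (50, 350) keV window (Section 5).
* No electron transport or fluorescence escape in the Monte Carlo; thin
  NaI full-energy values are biased high by a few points of K-escape.
* The detector response blurs but the reconstruction does not deconvolve;
  using measured-energy reconstruction with a realistic BGO resolution
  requires a response-aware inversion outside the present scope.
* Phantom media are limited to the bundled materials; media other than
  water break the exactness of the water-based normalization (by design —
  the model's premise is water-equivalent tissue).
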