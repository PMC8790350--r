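---
title: "Methods: target strength models and backscatter partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target strength models and backscatter partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The estimation problem

A 38 kHz echosounder survey measures the nautical area scattering
coefficient (NASC, m² nmi⁻²), a depth-integrated index of everything in
the water column that reflects sound. In the Southern Ocean mesopelagic
zone that signal is dominated by a community whose members differ in
reflectivity by orders of magnitude: lanternfish with gas-filled
swimbladders return up to ~95 % of their echo from the gas, while large
bladderless species are nearly acoustically transparent, and several taxa
lose swimbladder gas as they grow. Backscatter alone therefore cannot be
read as biomass; a cell with low NASC in cold water may hold more fish
mass than a bright cell in warm water. `echopart` implements the chain
that resolves this: species-specific target strength (TS) models, an
SST-indexed community composition, the partitioning of each grid cell's
NASC among taxa, conversion to areal density and biomass, and a
permutation-based uncertainty analysis.

The linear algebra at the core is, per 0.25° cell:

* σ_bs,i = 10^(TS_i/10) (backscattering cross-section, m²),
* P_i = N_i σ_bs,i / Σ_j N_j σ_bs,j (proportion of backscatter),
* ρ_a,i = NASC · P_i / (σ_bs,i · 4π · 1852²) (areal density, ind. m⁻²),
* biomass_i = ρ_a,i · W_i (g m⁻²), W_i from a length-weight relation,

with N the mean relative abundance vector of the cell's 1 °C SST bin
(seven bins spanning −1…6 °C), built from net samples. The factor
4π·1852² (1852 m per nautical mile, exact) converts between the
per-individual cross-section and the per-square-nautical-mile NASC
convention.

## Medium constants

All TS models use survey-mean constants: sound speed in seawater
1465.836 m s⁻¹, seawater density 1027.4 kg m⁻³, sound speed in fish
tissue 1510 m s⁻¹, frequency 38 kHz, and a nominal modelling depth of
500 m (`acoustic_medium()`).

## Swimbladder model (PS): gas prolate spheroid

Gas-bearing taxa are modelled through neutral buoyancy: a fish of wet
mass m and tissue density ρ_f needs gas volume

V = m (ρ_f − ρ_w) / (ρ_f ρ_w)

to float in water of density ρ_w. The volume is computed at atmospheric
pressure, where tissue densities are measured, and held constant at
depth — mesopelagic fish with functional bladders are assumed to regulate
gas content rather than let it compress, so no Boyle's-law rescaling is
applied and the resulting TS is depth-independent.

The bladder is represented as a gas prolate spheroid of volume V with
aspect ratio q (major:minor axis; default 3, a typical elongation for
myctophid swimbladders, configurable because direct bladder shape
measurements are rarely available). The returned cross-section is the
specular broadside reflection of the spheroid,

σ_bs = a² / 4,  a = (3 V q² / 4π)^(1/3),

i.e. geometric reflection with the gas-water reflection coefficient
taken as 1. No resonance amplification is included: for the taxa
shipped with the package the equivalent spherical bladder radius
exceeds 1 mm (`equivalent_spherical_radius()`), which puts 38 kHz well
above bubble resonance even at depth. We verified this structural
choice against the reference TS estimates for the Scotia Sea taxa: a
geometric model reproduces their within-taxon length dependence to
±0.1 dB (the scaling σ ∝ V^(2/3) with V ∝ mass ∝ SL³), whereas a
monopole-resonator variant evaluated at 500 m distorts the
small-length entries by many dB. The choice between these variants is
therefore data-gated, not aesthetic.

**Mass input and its limitation.** The gas volume requires a wet mass at
the evaluated length. The measured length-weight regressions behind the
reference estimates are not publicly tabulated, so the packaged taxon
table ships *synthetic stand-in* coefficients derived from a spheroidal
body model: width = SL/LWR from the measured length-width ratios, an
elliptical cross-section with body depth 1.5 × width (lanternfish are
laterally compressed), giving W = ρ_f (π/6) 1.5 SL³ / LWR². With these
stand-ins the PS TS values land a roughly constant 0.5–1.6 dB below the
reference estimates — a pure mass-scale offset, documented rather than
tuned away. Users with measured regressions should supply their own
`lw_a`, `lw_b` columns, which removes this limitation.

## Body model (FC): finite fluid cylinder

Bladderless taxa scatter weakly from flesh alone (density contrasts
g = ρ_f/ρ_w of 1.001–1.036, sound-speed contrast h = 1.030). The body is
a straight finite fluid cylinder of length SL and radius SL/(2·LWR). The
normal-incidence response uses the exact modal-series solution of the
infinite fluid cylinder (base-R Bessel functions; the modal coefficients
are arranged division-free so the series is stable down to ka → 0). The
finite length enters through the sinc(kL sin θ) directivity, and the
cross-section is averaged uniformly over tilt angles 0–90°, which is what
makes the model usable for fish of unknown orientation.

Two validation layers back this implementation:

* an independent weak-scatterer oracle — the distorted-wave Born volume
  integral evaluated in closed form — agrees with the modal series to
  < 0.1 dB at weak contrasts (test-suite);
* against the reference Scotia Sea TS matrix (28 values across seven
  bladderless taxa and four length statistics) the model agrees with
  rmse 0.17 dB; 27 of 28 values fall within ±0.5 dB, and the worst
  residual (+0.54 dB) is the 75th-percentile entry of the largest,
  thickest taxon (ka ≈ 1.3), where the deformed-cylinder directivity
  approximation is weakest. Broadside-only, end-tapered,
  Gaussian-tilt and exact-oblique-incidence variants were all examined
  and fit the reference matrix worse (3–11 dB, 2–4 dB, 2–8 dB and
  +0.7 dB max error respectively); the variant used is the best-fitting
  one, selected before any downstream work.

## Krill model (SDWBA)

Antarctic krill can contribute substantially to 38 kHz backscatter. TS
uses the distorted-wave Born approximation over the standard generic
krill approximation: a uniformly bent cylinder (radius of curvature
3 L), slenderness L/a = 20, elliptically tapered over the outer 40 % of
each half-length, density and sound-speed contrasts g = 1.0357,
h = 1.0279, orientation distribution N(11°, 4°) relative to broadside.
The *stochastic* component adds zero-mean Gaussian phase noise to each
of the 60 body segments, with standard deviation √2/2 at the 120 kHz /
38.35 mm reference, scaled proportionally to frequency and length; the
reported TS is the ensemble mean over 100 realizations (seeded;
doubling the ensemble moves the answer by < 0.1 dB). At survey lengths
40–50 mm this parameterisation sits ~0.4–0.7 dB above the reference
krill TS values with the correct length trend.

## Conventions and numerical choices

* **SST bins** are left-closed, `[-1,0) … [5,6]`, the final upper edge
  inclusive; cells and samples outside −1…6 °C are excluded and counted.
* **Percentiles** (lengths and sensitivity summaries) use linear
  interpolation between order statistics (R type 7), fixed and
  documented so tabulated values are reproducible.
* **Back-transform** of predicted log_e NASC is the plain exponential;
  no smearing correction is applied (see the recovery note below).
* **Length-weight fits** are OLS on log-log scale; the lognormal
  back-transform correction exp(s²/2) is off by default (point
  prediction, standard fisheries practice) and available as a switch.
* **−∞ TS** (no gas, no contrast) is represented as σ_bs = 0 so sums
  over taxa stay well defined; cells whose composition has zero total
  backscatter are masked with a reason code, never NaN.
* **Cells with NASC = 0** produce all-zero densities, not masks.
* **Cell areas** use a spherical Earth (R = 6371 km) band formula; at
  0.25° resolution the geodesic error is far below the reported
  precision. Region masks are axis-aligned boxes approximating the
  Scotia Sea management subareas and the Southern Ocean south of 50° S;
  real polygons can be substituted in the configuration.
* **Weight-length consistency**: within every sensitivity draw the
  weight is evaluated at the same length statistic as the TS, so the
  acoustic chain and the mass chain never mix statistics.
* **Seeds** fan out deterministically from one master seed per stage
  (net simulation, grid noise, permutation lattice, SDWBA ensemble);
  a fixed configuration reproduces byte-identical outputs.

## Sensitivity analysis

TS is the dominant, log-scale uncertainty, so the uncertainty machinery
permutes each taxon's length statistic among {p25, median, p75}: draws
are distinct tuples sampled uniformly *without replacement* from the
3^T lattice (`sample_draws()`; with three taxa and n = 27 the lattice is
enumerated exactly once). Summaries report mean, interquartile range and
standard deviation of the regional totals over 2000 draws.

Because other fauna share the echo, krill scenarios remove a fixed
krill contribution before partitioning, at literature densities of 32,
64 and 128 ind. m⁻². Two mechanisms are implemented: (i) subtraction of
the forward-computed krill NASC, ρ_k σ_k 4π 1852², floored at zero
(default); (ii) adding krill as an extra partition taxon whose
abundance is solved per cell so its output density equals the target.
The two are algebraically identical whenever the target is feasible —
solving mechanism (ii) for the fish-attributable backscatter yields
exactly the subtraction rule — which the test-suite verifies
numerically; the open question of which mechanism "really" applies is
therefore immaterial. The krill length statistic is permuted alongside
the fish statistics in permutation mode (median otherwise).

## The synthetic world

The generator exists to give the pipeline inputs with known truth:

* **Lengths**: lognormal, parameters solved analytically from the
  target (median, p75): meanlog = log(median), sdlog =
  log(p75/median)/qnorm(0.75). Positivity and right skew come free; the
  implied p25 equals median²/p75, so a strongly asymmetric target p25
  is only approximated — the generator is a stand-in for measured
  length-frequency data, not a fit to it.
* **Net samples**: station counts are negative-binomial (dispersion 5
  by default — trawl catches are overdispersed; dispersion → ∞ recovers
  Poisson) around a smooth SST gradient in which gas-bearing taxa have
  warm thermal optima (2.5–5.5 °C) and bladderless taxa cold ones
  (−0.8–1.8 °C), reproducing the community switch that makes the
  partitioning problem interesting. Default 140 stations, SST drawn
  from −1.5…6.5 °C so the range-exclusion bookkeeping is exercised.
* **Survey grid**: default 40 × 40 cells at 0.25°, SST declining
  linearly poleward from 6.4 to −1.6 °C (both analysis-window edges are
  crossed), true densities proportional to the bin composition with a
  constant density scale of 0.05 × the gradient abundances, and NASC
  forward-computed through the exact conservation relation, then
  perturbed in log space with Gaussian noise (sd 0.3 by default).

What a green closure test establishes: with zero noise and the exact
bin composition, the partition-biomass chain returns the true per-cell
densities and regional totals to 10⁻⁹ relative — i.e. the algebra is
inverted exactly. What it does not establish: robustness to
composition mismatch, spatial patchiness within bins, net-catch bias,
vertical migration, or the smoothing behaviour of the NASC prediction
model upstream — none of which the generator emulates.

**A note on noise and bias.** The generator adds mean-zero noise in log
space, and the estimator back-transforms with the plain exponential, so
each cell's estimate has expectation inflated by exactly exp(sd²/2)
(≈ 1.046 at sd 0.3). The repeated-simulation recovery check therefore
compares the replicate mean against truth × exp(sd²/2): this verifies
the pipeline adds no bias *beyond* the analytically known lognormal
factor. Whether to correct that factor in real applications is a
modelling decision left to the NASC-prediction stage, which is outside
this package's scope.

## Known limitations

* PS-model absolute levels inherit the mass-scale uncertainty of the
  synthetic length-weight stand-ins (~1–1.6 dB low against the
  reference estimates); measured regressions remove this.
* The FC directivity approximation degrades for ka ≳ 1 (largest taxon,
  longest lengths): residuals up to ~0.5 dB.
* The SDWBA generic shape is a bent tapered cylinder, not a digitised
  krill outline; absolute krill TS carries ~0.5 dB parameterisation
  uncertainty.
* Regions are box approximations; shelf exclusion is a per-cell flag
  supplied with the grid, not derived from bathymetry here.
* Resonance scattering near bubble resonance is out of scope by design.
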