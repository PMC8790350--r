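# echopart

Acoustic target-strength models and backscatter partitioning for
mesopelagic fish biomass estimation.

## The problem

Echosounder surveys of the mesopelagic zone measure the nautical area
scattering coefficient (NASC, m² nmi⁻²) — a depth-integrated index of
acoustic reflection — on large spatial grids. In the Southern Ocean the
mesopelagic fish community mixes small lanternfish whose gas-filled
swimbladders dominate their echo with large bladderless species that are
nearly transparent at 38 kHz, and the balance between these groups
shifts with latitude and temperature. Low backscatter near the Antarctic
continent therefore does not mean few fish; it can mean many weakly
scattering fish. Turning NASC maps into biomass requires
species-specific target strength (TS) and a way to split each cell's
signal among taxa.

`echopart` is aimed at fisheries acousticians and quantitative marine
ecologists. It implements:

* **TS models** at 38 kHz — a neutral-buoyancy gas prolate-spheroid
  model for gas-bearing taxa (PS), an orientation-averaged finite
  fluid-cylinder model for bladderless taxa (FC, exact modal series),
  and a stochastic distorted-wave Born approximation krill model
  (SDWBA);
* **partitioning** of each 0.25° cell's NASC among taxa via
  SST-binned community composition from net samples:
  `P_i = N_i σ_i / Σ_j N_j σ_j`, `ρ_i = NASC · P_i / (σ_i · 4π · 1852²)`;
* **biomass**: `biomass_i = ρ_i W_i` (g m⁻²), aggregated over spherical
  cell areas to regional megatonne totals (Southern Ocean south of
  50° S; Scotia Sea box approximations);
* **sensitivity analysis**: 2000 distinct permutations of each taxon's
  TS among its length percentiles {p25, median, p75}, plus
  krill-exclusion scenarios at 32 / 64 / 128 krill m⁻²;
* a **synthetic-data generator** (net samples, SST surface, forward
  NASC grid) with known ground truth for end-to-end validation.

A packaged taxon table carries the Scotia Sea survey parameters for 12
fish classes (11 taxa with *Electrona antarctica* split at 51.378 mm
into gas-bearing small and bladderless large classes) plus Antarctic
krill. Its length-weight coefficients are clearly-marked synthetic
stand-ins (see the methods vignette); supply measured coefficients for
absolute PS-model work.

## Worked example

```r
library(echopart)
tax <- scotia_sea_taxa()
med <- acoustic_medium()   # 1465.836 m/s, 1027.4 kg/m3, 38 kHz, 500 m

finite_cylinder_ts(tax$profiles$GYR, 86, med)  # -79.97 dB (bladderless)
prolate_spheroid_ts(tax$profiles$KRA, 43, med) # -59.56 dB (gas-bearing)
sdwba_krill_ts(45, med, seed = 1)              # -79.48 dB (krill)
```

The ~20 dB gap between a 43 mm gas-bearing lanternfish and an 86 mm
bladderless one is the heart of the matter: per individual, the small
fish returns two orders of magnitude more energy.

A full synthetic run (simulate → compose → partition → aggregate →
permute):

```r
cfg <- pipeline_config(n_draws = 200, seed = 1, noise_sd = 0.2)
res <- run_pipeline(cfg)
res$mask_counts
#>      total_cells            shelf sst_out_of_range        empty_bin
#>             1600                0              200                0
#> zero_denominator           usable
#>                0             1400
res$sensitivity[res$sensitivity$region == "southern_ocean" &
                res$sensitivity$taxa_set == "all_fish", ]
#>          region taxa_set krill_density mean_mt p25_mt p75_mt sd_mt area_km2
#>  southern_ocean all_fish             0  12.523 11.003 13.869 2.221   458913
#>  southern_ocean all_fish            32  11.580 10.368 12.814 2.103   458913
#>  southern_ocean all_fish            64  10.637  9.286 11.941 2.061   458913
#>  southern_ocean all_fish           128   8.965  7.442 10.278 2.035   458913
```

Reading this: 200 of 1600 simulated cells fall outside the −1…6 °C
analysis window and are masked; over the remaining 458 913 km² the
fish-only mean biomass across 200 TS permutations is 12.5 Mt with an
interquartile range of 11.0–13.9 Mt, and attributing part of the signal
to krill at 32/64/128 ind. m⁻² lowers the fish total monotonically —
the krill scenarios absorb backscatter budget that would otherwise be
booked as fish.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/echopart.R", package = "echopart"))')
Rscript "$CLI" ts-table --out out/            # Table of TS per taxon/statistic
Rscript "$CLI" simulate --seed 7 --out bundle/ # synthetic input bundle
Rscript "$CLI" run --draws 2000 --krill 0,32,64,128 --out results/
```

## Package layout

* `R/` — medium & dB conversions, buoyancy, TS models, morphometrics,
  community composition, partitioning, biomass, sensitivity, synthetic
  generator, IO/pipeline
* `inst/extdata/taxon_parameters.csv` — packaged taxon table
* `inst/cli/echopart.R` — command-line entry point
* `vignettes/acoustic-biomass-methods.Rmd` — model assumptions,
  conventions, synthetic-world design, limitations
* `tests/testthat/` — unit, property and acceptance suites
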