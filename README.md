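# echomix

Micronekton — the actively swimming 1–20 cm fish, crustaceans and
gelatinous animals of the mesopelagic zone — dominate the world's deep
scattering layers (DSLs) and are surveyed almost entirely by acoustics.
`echomix` is an R package for relating acoustic estimates of micronekton
abundance to the hydrography they inhabit along a ship transect.  It is
aimed at fisheries-acoustics and quantitative marine-ecology users who
have (or want to emulate) three data streams: CTD casts, calibrated
volume-backscatter grids from hull-mounted echosounders, and single-echo
detections from a trawl-mounted or towed echosounder.

The package implements the full chain as composable, pipe-friendly
functions over tibbles:

1. **Water-mass mixing inversion.** Within potential-density layers
   (σ<sub>θ</sub> ≤ 27, 27 < σ<sub>θ</sub> ≤ 27.25, σ<sub>θ</sub> > 27.25
   kg m⁻³), each observed (T, S) sample is decomposed over three
   water-type endmembers by the exactly determined linear system

   x₁T₁ + x₂T₂ + x₃T₃ = T,  x₁S₁ + x₂S₂ + x₃S₃ = S,  x₁ + x₂ + x₃ = 1,

   and each sample is labelled by the type with the highest contribution.
   σ<sub>θ</sub> comes from the EOS-80 seawater equation of state.

2. **Echo integration.** Sv grids are thresholded (−85 dB re 1 m⁻¹),
   surface-excluded (upper 15 m), absorption-corrected, daylight-filtered
   by solar geometry, and integrated into Nautical Area Scattering
   Coefficient cells of 5 m × 600 s:
   NASC = 4π·1852²·s̄ᵥ·dz (m² nmi⁻²).  DSLs are detected per column and
   their widths measured as the full width at half maximum of the linear
   backscatter profile.  Cells inherit water-mass labels from the nearest
   classified CTD station, giving per-water-mass backscatter tables.

3. **Echo counting.** Single-echo detections are filtered by the standard
   SED criteria (TS ≥ −80 dB re 1 m², echo length 0.6–1.4 of the pulse,
   phase deviation ≤ 10 steps, gain compensation ≤ 3 dB), range-gated,
   and converted to volumetric densities by dividing counts per 40-m
   depth bin by the acoustically sampled volume
   V = n·(Ω/3)(r³max − r³min), Ω = 10^(EBA/10) sr.  Paired-frequency
   density profiles can be compared by OLS regression and overall ratio.

4. **Habitat models.** Responses (NASC or echo density), split at 200 m
   into surface and deep strata and joined to interpolated hydrographic
   covariates, are modelled with Tweedie GAMs — hour-of-day factor plus
   thin-plate spline smooths, power parameter and smoothing estimated by
   REML (via mgcv) — with covariate screening by variance inflation
   (cutoff 3) and smooth concurvity (cutoff 0.8), and AIC model
   selection.  Fits have `tidy()`, `glance()` and `autoplot()` methods.

A synthetic-scene generator (`scene_config()`, `simulate_ctd_transect()`,
`simulate_echogram()`, `simulate_sed()`) produces a 17–48° N transect
with five mixing water types, an oxygen-minimum zone, latitude-drifting
Gaussian scattering layers and Poisson single-echo streams — all with
stored ground truth, so every stage of the chain is testable end to end
without survey data.

## Worked example

```r
library(echomix)

cfg     <- scene_config(seed = 1, n_stations = 8,
                        echogram_hours = 8, time_step = 600)
casts   <- simulate_ctd_transect(cfg)
section <- classify_profile(casts)
table(section$dominant)
#>   AAIW l-NACW    MOW   STUW u-NACW
#>    886    373     58     99    512

eg    <- simulate_echogram(cfg)
cells <- eg$sv |>
  apply_threshold(-85) |>
  exclude_surface(15) |>
  filter_daylight("sunrise_sunset_1h") |>
  integrate_cells(dz = 5, dt = 600) |>
  label_cells_by_watermass(section)
summarize_by_watermass(cells)
#>   frequency water_mass mean_nasc sd_nasc max_nasc     n
#> 1        38 AAIW           1.05     2.00     7.03  4633
#> 2        38 MOW            0        0        0      164
#> 3        38 STUW          11.6      7.47    21.7    518
#> 4        38 l-NACW         6.90     4.81    13.8   1907
#> 5        38 u-NACW         0.968    3.48    21.7   2495

sed  <- simulate_sed(cfg)
prof <- sed$echoes |> sed_filter() |>
  density_profile(sed$pings, cfg$beam, bin_height = 40)
max(prof$density_m3, na.rm = TRUE)
#> [1] 0.132   # echoes m^-3, peaking at 360-400 m
```

The water-mass table reads as a per-oceanographic-zone backscatter
summary: in this scene the near-surface southern types (STUW, l-NACW)
carry the highest mean NASC while the deep MOW cells fall below the
−85 dB threshold, and the echo-counting profile recovers the mesopelagic
density peak the generator placed near 400 m.  `run_pipeline(demo_config(),
out_dir)` executes the whole chain — simulation, classification,
integration, DSL detection, counting, modelling, reporting — writing
every product as CSV with a manifest; the same config and seed give
byte-identical products.

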