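# ecohydrocity

Raster analysis of how urbanization, vegetation greenness and climate
jointly shape where vertebrate biodiversity is under threat.

`ecohydrocity` is for spatial ecologists and remote-sensing analysts who
work with co-registered global grids — nighttime-light brightness (integer
DN 0–63, ~1 km), annual NDVI series (~8 km), climatological surface fluxes
(evapotranspiration *E*, sensible heat *H*, precipitation *P*) and gridded
vertebrate census layers (species abundance and threatened-species counts,
~10 km) — and who want a reproducible, testable pipeline from those layers
to city-level biodiversity diagnostics.

## What it computes

**Cities from lights.** Spatially contiguous pixels with DN ≥ 12 form a
city *j*; its size is the sum of the spherical pixel areas of its members,
size(*j*) = Σᵢ aᵢ(*j*). City sizes are binned into exponentially widening
bins (base 2 km², Zipf-style spectrum), and a power-law exponent can be
recovered from the binned counts.

**Budyko eco-hydrological state space.** Fluxes are expressed in water
equivalents (m/yr; half-day energy integrals convert at 2.920 × 10⁻⁷ m/yr
per J m⁻² (12 h)⁻¹, using L = 0.25 × 10⁷ J kg⁻¹). In the (*E*, *H*)
diagram, net radiation *N* = *E* + *H* gives off-diagonal isolines, the
Bowen ratio *B* = *H*/*E* rays through the origin, and Schreiber's
equation of state *E*/*P* = 1 − exp(−*D*) (with dryness *D* = *N*/*P*)
yields precipitation isolines *H* = −*P* ln(1 − *E*/*P*) − *E* and dryness
isolines *E* = *H*(1 − e⁻ᴰ)/(*D* − 1 + e⁻ᴰ). Dryness classifies the
geobotanic regimes (tundra *D* < 1/3, forest to 1, steppe/savanna to 2,
semi-desert to 3, desert beyond). Any layer can be embedded as a weighted
2-D frequency distribution over (*E*, *H*) bins, optionally smoothed by a
mass-preserving Gaussian kernel.

**NDVI-conditioned biodiversity statistics.** Within half-open NDVI bins
[*T*, *T* + 0.1) and for the strata city / non-city / land (= city plus
non-city), the package aggregates species abundance, threatened counts,
the threatened-species indicator (threatened / abundance, a ratio of bin
sums that cancels the area/population effect), the coefficient of
interannual NDVI variability (σ/μ per pixel), and area fractions (NDVI
percentage of a region, city percentage of city area).

**Green and brown city effects.** Annual area-weighted mean NDVI series
for the city and land strata within an NDVI interval are fit by OLS; the
city-over-land slope ratio classifies the city effect: *green* when cities
green at least twice as fast as land, *brown* when the trends are alike
(ratio within 0.25 of 1) or cities are browning.

**Synthetic worlds with known truth.** A deterministic generator plants
Zipf-sized city blobs, stratum-specific NDVI trends, Schreiber-consistent
flux fields and Poisson/binomial species layers with U-shape, step-jump or
flat threatened-indicator profiles, so every stage of the pipeline is
testable without external downloads.

## Worked example

```r
library(ecohydrocity)

w  <- simulateWorld(seed = 1)                       # 200 x 200, 32 years
ct <- citySizes(extractCities(w$light, dnThreshold = 12))
ct
#> CityTable: 49 cities (DN >= 12, 8-connectivity)
#>   lighted pixels: 163; sizes [2.08e+03, 1.58e+05] km^2

nd    <- GridRaster(w$ndviClim, w$grid$latEdges, w$grid$lonEdges)
masks <- stratumMasks(cityMask(ct))
compareTrends(w$ndvi, masks$city, masks$land,
              interval = c(0.2, 0.5), ndviClim = nd)
#> TrendComparison over NDVI [0.2, 0.5), 32 years
#>            slope intercept     resid_sd
#> city 0.002992049 -5.622782 1.200606e-03
#> land 0.001012152 -1.671029 9.140791e-05
#>   slope ratio city/land: 2.956; effect: green
```

The generator planted slopes of 0.003 NDVI/yr in cities and 0.001 over
land; the fitted slopes recover them, the ratio is ~3 and the city effect
is classified green. The same world yields the NDVI-binned statistics:

```r
bs <- binStats(nd, w$abundance, w$threatened,
               cv = coefficientOfVariability(w$ndvi), mask = masks$land)
head(bs[, c("bin_lo", "bin_hi", "abundance", "threatened",
            "indicator", "cv")], 5)
#>   bin_lo bin_hi abundance threatened indicator     cv
#> 1    0.0    0.1     83725       7521    0.0898 0.1877
#> 2    0.1    0.2    221685      11285    0.0509 0.0916
#> 3    0.2    0.3    310023       8616    0.0278 0.0540
#> 4    0.3    0.4    396974       7817    0.0197 0.0393
#> 5    0.4    0.5    484269      13367    0.0276 0.0299
```

Abundance rises with greenness while the indicator traces the planted
U-shape: its minimum falls in the planted 0.3–0.4 bin, and the NDVI
variability coefficient declines with greenness. `runPipeline(list(seed =
1, out_dir = "out"))` chains all stages and writes every table as CSV with
a run manifest; `inst/scripts/ecohydrocity-pipeline.R` wraps the same
functions for shell use.

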