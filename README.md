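# cloudpoint

Image-based determination of apparent protein cloud-point temperatures
(T<sub>Cloud,app</sub>) and ice-nucleation temperatures (T<sub>Nuc</sub>)
from time-lapse images of microtiter-plate wells on a cooling ramp.

## The problem

The cloud-point temperature of a protein solution — the temperature at
which it demixes into protein-rich and protein-poor liquid phases and turns
turbid — is a practical proxy for the strength of attractive protein–protein
interactions. A cheap, high-throughput way to measure it is to cool a sealed
well plate on a cryogenic device while a camera photographs the wells, and
to read the clouding event out of the image series. Cooling further, the
supercooled samples eventually freeze, releasing latent heat; that event
gives the ice-nucleation temperature.

The catch is that the instrument reports the *device* temperature, not the
sample temperature. A sample of volume V relaxes toward the device
temperature at a finite rate, so on a ramp of rate r it sits a roughly
constant r/k °C above the device reading (k the relaxation rate, smaller
for larger thermal mass). Every detected cloud point is therefore
*apparent*: faster ramps and larger volumes push it further below the true
value. `cloudpoint` implements both the detection pipeline and a synthetic
well-plate generator with exactly this first-order thermal lag, so the
whole chain — rendering, trace extraction, event detection, replicate
aggregation — can be validated against known ground truth, and the
rate/volume depression of T<sub>Cloud,app</sub> reproduced and quantified.

## What it computes

Per-frame traces from each well image sequence:

* **TID** — total intensity difference vs. the first (t₀) frame:
  Σ|I − I₀| over all pixels and channels;
* **TWP** — total white pixels after binarizing the gray image at a white
  level: fixed (0.50, 0.75, 0.85) or data-dependent per well (Otsu
  threshold of the t₀ frame, or its mean gray intensity);
* **MGL/MRL/MGrL/MBL** — mean gray/red/green/blue levels.

Events on traces smoothed with a centered moving mean (window 5 % of the
data points, 2.5 % fallback):

* T<sub>Cloud,app</sub> from TID: the temperature where the sharp increase
  flattens (first difference falls below 10 % of its peak);
* T<sub>Cloud,app</sub> from TWP: the trace minimum before nucleation;
* T<sub>Nuc</sub>: the maximum TWP gradient — freezing turns protein and
  buffer wells abruptly white (TWP increase) and water wells gray
  (TWP decrease).

Replicates are aggregated by median and unscaled MAD after Tukey-fence
outlier rejection (0.75 × IQR whiskers); strategies and conditions are
compared with RMSE (per-series, total and average), R², one-way ANOVA, and
min–max-normalized RMSE against an optional reference table.

## Worked example

Six synthetic protein wells (three cloud points, two replicates each) on
the standard ramp — 15 to −40 °C at 0.5 °C/min, one image every 10 s, 20 µL
wells:

```r
library(cloudpoint)

prof  <- cooling_profile(15, -40, rate = 0.5, capture_interval = 10)
lag   <- thermal_lag(volume = 20)
specs <- lapply(c(5.6, 3.9, 1.8), function(tc)
  replicate_specs(well_spec("protein", true_t_cloud = tc), 2))
plate <- generate_plate(unlist(specs, recursive = FALSE), prof, lag, seed = 7)

det <- detect_events(plate, strategies = c("TID", "TWP:0.50"))
dplyr::select(det, well_id, strategy, t_cloud_app_C, t_nuc_C)
#> # A tibble: 12 × 4
#>    well_id strategy t_cloud_app_C t_nuc_C
#>    <chr>   <chr>            <dbl>   <dbl>
#>  1 A1      TID              2       -22.5
#>  2 A1      TWP:0.50         2.17    -22.5
#>  3 A2      TID              2       -22.5
#>  4 A2      TWP:0.50         2.17    -22.5
#>  5 A3      TID              0.333   -22.5
#>  6 A3      TWP:0.50         0.417   -22.5
#>  ...

compare_strategies(det)
#> <strategy_comparison> TID vs TWP:0.50 on 6 wells
#>   total RMSE 0.144, average RMSE 0.144, R^2 0.9995, ANOVA F 0.0198 (p 0.891)
```

Reading the numbers: the wells with a true cloud point of 5.6 °C are
*detected* near 2 °C on the device grid — clouding completes one transition
width (1 °C) below onset, and the 20 µL sample runs ≈2.5 °C warmer than the
device at 0.5 °C/min, which is the apparentness depression the thermal-lag
model exists to expose (`extract_trace(..., temperature = "sample")`
recovers the true value). The two strategies agree to 0.14 °C RMSE. All
wells freeze at a device reading of −22.5 °C, the true −20 °C minus the
same lag. `autoplot()` methods display traces and strategy-agreement
scatter plots; `sampling_plan()` reproduces the images-per-°C bookkeeping
that matches camera intervals to cooling rates.

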