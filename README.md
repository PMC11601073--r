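# dvmtrack

Estimation of diel vertical migration (DVM) rates of a bloom-dominant
phytoplankton species from repeated vertical chlorophyll-*a* fluorescence
profiles in a shallow water column.

Many harmful-bloom dinoflagellates swim to the surface around dawn and back
to the bottom around dusk. Measuring how fast they migrate in the field
usually requires counting cells from bottle samples at a handful of depths
— laborious and coarse. When one species dominates the phytoplankton
biomass, the bulk chlorophyll profile measured by a profiling sonde becomes
a usable proxy for that species' vertical position, with far better depth
and time resolution. `dvmtrack` implements that analysis end to end and
ships a water-column simulator so that every stage can be verified by
parameter recovery against a known truth.

## The method

For each cast, chlorophyll is averaged into 0.2 m depth bins and normalized
by its depth integral:

```
Rel_CHL(z) = Chl(z) / ∫₀ᵈ Chl(z) dz          [units 1/m]
```

`Rel_CHL` is invariant to multiplying the whole profile by a constant, so
cast-to-cast changes in total biomass (water advecting past the fixed
station) do not displace the depth of its maximum, `z_MAX`. Profiles whose
binned chlorophyll has a coefficient of variation ≤ 5% are flagged as
vertically homogeneous — no unambiguous maximum exists — and are excluded
from rate calculations (their time still counts toward elapsed intervals).

The migration rate between adjacent retained profiles is

```
w_DVM = |Δz_MAX| / Δt                        [m/h]
```

Within fixed local clock windows (ascent 04:00–09:00, descent 16:00–20:00),
an event runs from the last profile whose maximum sits in the bottom band
(within 1 m of the bottom) to the first whose maximum reaches the surface
band (≤ 1 m), or vice versa. The event's **mean** rate averages all
pairwise `w_DVM` between those bounding profiles; the **maximum** rate is
reported only when the event is resolved by more than two profiles. If no
bracketing pair exists the event is reported as not observed. With 0.2 m
bins each endpoint is quantized to ±0.1 m.

Supporting stages: a pooled OLS calibration of raw sonde fluorescence
against extracted chlorophyll from bottle samples; dominance gating
(analysis is licensed only when the focal taxon exceeds 80% of total carbon
biomass at study initiation); and a proxy check correlating `Rel_CHL` with
the focal taxon's relative cell abundance over depth (Spearman rank, average
ranks, exact permutation p for n ≤ 10).

The simulator advects a Gaussian chlorophyll layer through a 6 m column
with a first-order upwind, mass-conserving advection–diffusion scheme
(no-flux boundaries), a diel target-seeking velocity schedule, lognormal
per-cast biomass heterogeneity, lognormal sensor noise, and Poisson bottle
counts for a dominant taxon plus a background taxon.

## Worked example

```r
library(dvmtrack)

cfg <- simulation_config(v_ascend_m_per_h = 1.3, v_descend_m_per_h = 1.4,
                         cast_interval_h = 1, seed = 101)
sim <- generate_series(cfg)                      # 25 hourly casts over 24 h
res <- estimate_dvm_rates(sim$series, study = "DEMO")
res$rate_table
#>         day    kind mean_rate_m_per_h max_rate_m_per_h n_segments       status
#>  2016-08-16  ascent                NA               NA          0 not_observed
#>  2016-08-16 descent              1.30              1.6          4     observed
#>  2016-08-17  ascent              1.35              1.4          4     observed
#>  2016-08-17 descent                NA               NA          0 not_observed
```

The series starts at noon, so the first day has no ascent to observe and
the second ends before dusk. The dusk descent (true speed 1.4 m/h) is
recovered at 1.30 m/h and the dawn ascent (true 1.3 m/h) at 1.35 m/h —
both within the quantization error of the 0.2 m bins. Individual profiles
carry their diagnostics:

```r
res$rel_profiles[[13]]
#> <dvm_relchl> C013 @ 2016-08-17T00:00:00-0400: z_max 5.90 m, CV 183.1%, integral 84.8 mg/m^2
```

(at midnight the layer is holding near the 6 m bottom). The numbered
scripts under `analysis/` run the full narrative — simulate, calibrate,
estimate rates, validate the proxy, and measure parameter recovery — and
write their tables under `results/`.

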