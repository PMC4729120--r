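# sparrowtrack

Tools for tracking small songbirds through an automated VHF radiotelemetry
array, built around the fall migration of the Ipswich Sparrow
(*Passerculus sandwichensis princeps*) — an island endemic that breeds only
on Sable Island, Nova Scotia, and must begin every fall migration with an
overwater flight.  The package turns raw coded-tag detections into validated
detection runs, per-bird tracks and behavioural events, and tests whether
timing, routes, stopovers and overwater orientation differ between adults
and juveniles.

It is written for movement ecologists working with coded-tag detection data
(Motus-style networks of SensorGnome receivers), and for anyone who needs a
fully simulated, ground-truthed testbed for detection filtering and track
segmentation.

## What it does

**Detection filtering.** A coded tag transmits every *b* seconds (its burst
interval).  Raw receiver output includes false positives, so detections of a
tag at a station are chained when consecutive gaps match *b* within a small
tolerance, and only chains of ≥ 3 consecutive bursts are accepted.
Uniformly timed noise essentially never forms such a chain.  An optional,
explicitly parameterized rescue rule can re-admit 2-detection chains that
sit between accepted runs in space and time at a plausible ground speed
(≤ 25 m/s).

**Geodesy.** Flight geometry is rhumb-line (loxodrome) on a sphere of
radius 6371.0088 km: the bearing of the constant-compass-course path
between two towers,

    θ = atan2( Δλ, ln(tan(π/4 + φ₂/2) / tan(π/4 + φ₁/2)) ),

and the corresponding distance; ground speed is rhumb distance over elapsed
time.

**Track segmentation.** Departure is the local calendar date (UTC−3) of the
first mainland detection.  A stopover is > 8 h of detections at one receiver
with nothing heard elsewhere, or a gap > 10 h between adjacent receivers
along the coastal chain.  A flight with bearing in (0°, 90°] is a reverse
migration.  Overwater crossing bearings are computed only for prompt
crossings (< 100 h) and, for the Gulf of Maine, only from the Bon Portage
Island (BPI) terminus.  Detections at Cape Cod are excluded from stopover
statistics; a span > 16 days there marks a completed migration.  Each bird
gets a route class: Gulf of Maine via the northern or southern shore,
presumed direct flight south from BPI, Nova Scotia only, or never detected
off the island.

**Statistics.** Age comparisons use, per the field's conventions: Gaussian
GLMs for timing, a Poisson GLM for stopover counts, a random-intercept
linear mixed model (REML, lme4) for stopover durations, Fisher's exact test
(computed from the hypergeometric distribution) for 2×2 detection tables,
the Watson–Williams circular ANOVA for mean bearings, and Watson's
two-sample U² for bearing homogeneity.  All fixed effects report the
juvenile coefficient with adult as the reference level.

**Simulation.** `simulate_cohort()` / `simulate_detections()` generate a
synthetic tagged cohort — age-specific departure dates, von Mises overwater
headings, route choices, Poisson/exponential stopovers, occasional reverse
migrations — and the detection log an imperfect array records (15 km
detection range in flight, ~2 km on the ground, configurable per-burst
detection probabilities, off-grid false positives).  Every event is kept as
ground truth, so the filter and the segmenter can be scored exactly.

## Worked example

```r
library(sparrowtrack)

res <- run_pipeline("demo_out", params = cohort_params(seed = 42))
res$summary
```

```
      age tagged detected_ns final_ns_bpi final_ns_not_bpi detected_gulf
    ADULT     31          31           30                1             6
 JUVENILE     33          33           23               10            27
    TOTAL     64          64           53               11            33
 gulf_north gulf_south pct_detected_ns pct_gulf_of_mainland
          0          6             100                   19
         10         17             100                   82
         10         23             100                   52

Stopover behaviour
      age mean_stopovers mean_stopover_duration_days n_stopovers
    ADULT       1.096774                    2.722356          34
 JUVENILE       3.333333                    6.801212         110
```

The counts table mirrors the study's detection-by-location summary: no
adult reaches the northern Gulf of Maine while juveniles split between the
northern (overland) and southern (BPI crossing) shores, and juveniles make
about twice as many, and longer, stopovers.  (With the default detection
probabilities nearly every simulated bird is detected on the mainland;
tag failure and mortality, which reduced the real study's mainland
detections to 39/64, are deliberately not simulated.)

```r
res$results[, c("comparison", "model", "estimate", "se", "p_value")]
```

```
                  comparison             model estimate    se  p_value
1             departure_date      GAUSSIAN_GLM   -26.56 2.166 3.17e-18
2               last_ns_date      GAUSSIAN_GLM   -14.67 4.276 1.08e-03
3             stopover_count       POISSON_GLM     1.11 0.196 1.47e-08
4          stopover_duration      GAUSSIAN_LMM     4.18 1.091 3.65e-04
5      gulf_detection_by_age      FISHER_EXACT    18.75    NA 9.11e-07
...
```

Row 1 says juveniles in this simulated cohort initiated migration 26.6 ±
2.2 days before adults (the generator's true effect is −24 days); row 3's
Poisson coefficient 1.11 is the log ratio of juvenile to adult stopover
counts; row 5's Fisher test shows juveniles are far more likely to be
detected around the Gulf of Maine.

Published contingency tables can be tested directly:

```r
# Gulf-of-Maine detection among mainland-detected birds:
# 25/28 juveniles vs 4/11 adults
fisher_exact(matrix(c(25, 3, 4, 7), 2, 2, byrow = TRUE))
#> <inference_result> FISHER_EXACT
#>   estimate = 14.58, p = 0.0018
#>   n = row1 28, row2 11
```

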