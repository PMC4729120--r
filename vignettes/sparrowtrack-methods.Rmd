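---
title: "Methods: detection filtering, track segmentation and age-group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection filtering, track segmentation and age-group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparrowtrack)
```

## The study system and what the pipeline assumes

Ipswich Sparrows breed only on Sable Island, ~160 km off Nova Scotia, and
winter on the US Atlantic coast, so every fall migration starts with an
overwater flight and later confronts a second barrier, the Gulf of Maine.
An array of 34 automated VHF receivers — four towers on the island, a
coastal chain through mainland Nova Scotia ending at Bon Portage Island
(BPI), groups along the northern and southern Gulf of Maine, and a Cape Cod
terminus — records coded-tag transmissions as birds pass.  The pipeline in
this package reconstructs migration behaviour from those detections and
asks where adults and juveniles differ.

Three assumptions shape everything downstream:

* **Detections are sparse and one-sided.**  A bird on the ground is heard
  only within a few km; a bird aloft up to ~15 km.  Absence of detections
  is therefore weak evidence, and all rules are phrased in terms of
  detections that did occur.
* **The burst interval is the signature of truth.**  Coded tags transmit on
  a fixed per-tag period; receiver noise does not.  Filtering exploits only
  this structure.
* **Between receivers, movement is summarized by the rhumb line.**  Bearings
  and ground speeds are computed along the constant-compass-course path
  between tower coordinates, the natural model for a bird holding a heading.

## Detection filtering

Detections of one tag at one station are chained whenever the gap between
consecutive detections matches the tag's burst interval within
`burst_tolerance_s` (default 0.2 s; receiver clocks drift far less than
this over one burst, and the tolerance is configurable).  Chains with at
least `min_run = 3` detections are accepted.  Chaining is per
(tag, station): a bird within range of two stations at once interleaves
rows in the time-sorted log, and a per-row chain would break spuriously.
Detections at the same station with a zero gap are the same burst heard on
two antennas and never break a chain.

Whether a chain may bridge one missed burst (a gap of exactly two
intervals) is genuinely undecidable from the published rule; the default is
strict (`allow_skip = FALSE`), with the permissive variant available.

The published analysis also hand-admitted two 2-detection sets judged
"consistent with the movement of the bird".  Manual judgement is not
reproducible, so the rescue rule here is an explicit interpretation: a
2-detection chain on the burst grid is admitted only if the implied ground
speeds to the nearest accepted runs before and after are ≤ 25 m/s (observed
direct flights were 10–13 m/s; the cap leaves wind headroom) and its
station lies between theirs in coastal order.  It is off by default.

## Track segmentation

* **Departure** is the local calendar date of the first mainland detection.
  Timestamps are stored in UTC; only date derivation applies the display
  offset (default UTC−3), so nocturnal departures shortly after midnight
  UTC fall on the local evening's date.
* **Stopovers**: a maximal period of detections at one station with nothing
  heard elsewhere counts when its span exceeds 8 h; a gap exceeding 10 h
  between consecutive runs at *adjacent* stations also counts, located at
  the earlier station with the full gap as its duration.  Adjacency means
  consecutive coastal order — the chain's natural neighbour relation.  No
  transit time is subtracted from gap durations; the bias is at most a few
  hours against multi-day durations.  Two regions are excluded: Cape Cod
  (spans there, typically > 16 days, are overwintering; such spans instead
  set `migration_complete`) and Sable Island itself (pre-departure
  residence is not a migration stopover).
* **Reversals**: a flight between different stations whose rhumb bearing
  falls in the half-open northeast sector (0°, 90°] — the operational
  definition of "northeast" is configurable since the published one is
  verbal.  Hops between the island's own towers are excluded: Sable's four
  towers sit within in-flight detection range of one another, so a
  departing bird is momentarily "seen" at towers behind it, which is island
  movement, not reverse migration.  Context is `PRE_STOPOVER` when a
  stopover starts at the destination on arrival, `POST_STOPOVER` when one
  ended at the origin on departure.
* **Crossing bearings** are eligible only when the bird was detected across
  the water body within 100 h, and for the Gulf of Maine only when the
  final Nova Scotia detection was at BPI — a bird last seen northeast of
  BPI may have cut overland, and the tower-to-tower bearing would not be an
  overwater heading.  Ineligible crossings carry machine-readable reasons
  (`DELAY_EXCEEDED`, `NOT_BPI`, `NO_ARRIVAL`).
* **Route classes** follow the regions visited: first Gulf detection in the
  northern vs southern group, `PRESUMED_DIRECT_SOUTH` for birds whose final
  Nova Scotia detection is BPI with nothing after (flagged `censored`,
  since a successful flight beyond the array and a failed crossing are
  indistinguishable), `NS_ONLY`, or `NOT_DETECTED_MAINLAND`.
* The share of birds first detected on the mainland within 12 h of leaving
  Sable is reported as a descriptive statistic of array efficiency; it is
  not a filter.

When two nearby stations detect a bird simultaneously, the transit time
between their runs is unmeasurable; such flight segments keep their
geometry but report `speed_mps = NA` rather than a meaningless value.
Direct flights are those with measured ground speed at or above 5 m/s
(exemplar direct crossings were 10 and 13 m/s; the threshold is
configurable and the direct count is monotone in it).

## Statistical models

All fixed effects use adult as the reference level and report the juvenile
coefficient.

* **Timing** (departure date, last Nova Scotia date): Gaussian GLM; the
  coefficient is the difference of group means in days.
* **Stopover count**: Poisson GLM with log link; the coefficient is the log
  ratio of group means.  Both GLM fits are checked against these closed
  forms to 1e−8.
* **Stopover duration**: birds contribute repeated events, so a linear
  mixed model with a per-bird random intercept is fitted by REML (lme4).
  With one event per bird the random effect is singular and the model
  falls back to the Gaussian GLM — the estimates then agree by
  construction.  Wald p-values use a t reference with between-bird degrees
  of freedom.
* **2×2 detection tables**: Fisher's exact test computed from the
  hypergeometric distribution; the two-sided p sums the probabilities of
  all tables with the observed margins that are no more probable than the
  observed one (relative tolerance 1e−7 against floating-point ties;
  mid-p is not used).  A zero margin yields p = 1.
* **Bearings**: compass degrees at every interface, radians only inside the
  trigonometry.  The Watson–Williams F uses the high-concentration
  correction 1 + 3/(8κ̂), with κ̂ from the pooled resultant length via the
  standard piecewise ML inversion; it warns below n = 5 per group or when
  the pooled concentration is low.  Watson's two-sample U² is computed from
  the pooled circular order with mid-rank ties and is rotation invariant;
  in table mode the p-value is reported as a bracket against the asymptotic
  0.10/0.05/0.01 critical values (0.152/0.187/0.268), matching how such
  results are conventionally printed, with a Monte-Carlo permutation mode
  as the small-sample fallback.

One caution on U² with tiny samples: with n = 5 per group in two tight
antipodal clusters, every circular rotation of the extreme labelling
attains the same statistic, so the exact permutation p is about 10/252 ≈
0.04 — no smaller value is attainable.  The test suite checks the
permutation p against full enumeration of all 252 splits rather than
against a nominal level.

## The synthetic cohort generator

The generator is the package's testbed: it draws a cohort and plays it
through an imperfect array, keeping every event as ground truth.

Defaults encode the study's observed conditions: 31 adults and 33
juveniles; mean departures 27 October (adult) vs 3 October (juvenile) —
a −24 day juvenile effect — with a common 9-day spread (this spread makes
the two-group standard error at n = 11 vs 28 come out near 3.15 d);
overwater bearing means 288°/299° (Sable leg) and 252°/282° (Gulf
crossing); stopover counts Poisson with means 1.6/3.8 and durations
exponential with means 2.8/5.8 d truncated at 0.1 d; reversal
displacements constrained to receiver spacings of 18–34 km; Cape Cod spans
averaging 4 d (adults) vs 28 d (juveniles); cruise speed 12 m/s.  Route
probabilities per age follow the observed splits (adults never take the
northern, partially overland route).  The published mean resultant lengths
for bearings are internally inconsistent with the reported tests and were
not used to set the concentration; κ = 8 (~20° angular sd) was chosen once
as a realistic orientation concentration.  The reversal *attempt*
probability (0.30 for juveniles) was calibrated so the *realized* rate —
attempts succeed only when a qualifying stopover and receiver spacing
exist — matches the observed ~0.11 reversals per juvenile.

Choices without a published value, set once and documented here: per-burst
detection probabilities 0.9 (flight) / 0.6 (ground); false positives at
0.005 per station-hour with uniform timing (no false-positive rate is
published for SensorGnome data — both are synthetic, free parameters); tag
burst intervals around 300 s, a tag-programming choice that keeps
multi-week stationary periods to realistic log sizes; 24 h of pre-departure
island residence simulated (earlier weeks carry no information about
migration).  Movement between stations is constant-speed along the rhumb
line, matching the geodesy the analysis assumes; burst-time jitter is off
by default so that filter logic and tolerance handling can be tested
separately; reversals are inserted as explicit events so recall and
precision are well defined.

What the generator deliberately does not emulate: tag loss and mortality
(the study detected only 39/64 birds on the mainland; simulated birds all
depart), weather-dependent departure decisions, fuel physiology, and
continuous coastlines between towers.  Passing tests therefore validate
the *processing* — filtering, segmentation, geodesy, inference — under
known truth; they do not certify behavioural realism of real sparrows.

### Truth recovery and its tolerances

With perfect detection and no false positives, route classes, stopovers
and reversals are recovered exactly (recall = precision = 1) on simulated
cohorts.  Stopover events are matched by (bird, station): the 15 km
in-flight detection range necessarily extends the detection span at a
stopover station by roughly `range/speed` (~20 min) on each side, so
endpoint agreement is asserted within that approach window, and a
behavioural stopover just under the 8 h rule can be detected with a span
just over it — precision is therefore defined against stopovers of any
true duration, recall against those exceeding 8 h.

## Numerical details

* Sphere of radius 6371.0088 km, not an ellipsoid: consistent with the
  whole-degree precision of reported bearings and the default behaviour of
  the standard geodesy toolchain at these scales.
* Near-meridian guard: when the longitude difference is below 1e−12 rad the
  bearing is exactly 0 or 180, avoiding 0/0 in the Mercator term; a
  circular mean that rounds onto 360° is mapped to 0.
* Longitudes normalized to (−180, 180], differences taken the shortest way.
* GLMs run with convergence epsilon 1e−12 so iterative fits meet the
  closed forms to 1e−8.
* All randomness flows from explicit integer seeds; identical seed and
  parameters reproduce simulator output bit for bit.

## Problem sizes used by the tests

The suite exercises: truth recovery on cohorts of 24–100 birds with
perfect detection; the false-positive check at ~5% off-grid records;
departure-effect recovery over 500 cohorts of 11 + 28 birds; Watson–
Williams size over 2000 null replicates (n = 15, κ = 5) and power over
1000 replicates at 90° separation; 1000 random tables against exhaustive
hypergeometric enumeration; and 100 random point pairs against a 1 m-step
constant-bearing integration.  These sizes were chosen so the full suite
and the acceptance script each complete in about a minute on a single CPU
while leaving Monte-Carlo noise well inside the asserted bands.

## Known limitations

* `ADJACENT_GAP` stopovers are placed at the earlier station; the bird may
  in fact have rested anywhere between the two receivers.
* Route classes for birds last seen at BPI are censored labels, not
  observations.
* The U² critical-value bracket uses asymptotic constants; for groups
  smaller than ~8 the permutation mode is preferable.
* The simulator's array geometry is invented (tower coordinates are not
  published); it is seed-reproducible and labelled synthetic throughout.
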