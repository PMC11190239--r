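---
title: "Sleep phenotype landscapes and their temporal dynamics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep phenotype landscapes and their temporal dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepscape)
```

`sleepscape` turns epoch-level (30-second) sleep-stage series from wearable
devices into a small number of interpretable *sleep phenotypes* — cluster
memberships of 3–6-night sleep periods in a 2-D feature landscape — and then
models how individuals move between phenotypes over time as a
conditional-transition-probability (CTP) graph. The end question is
quantitative: how much more information do those *transition dynamics* carry
about a health condition than static phenotype membership does? This
vignette explains each stage's model and assumptions, the tunable
parameters, what the synthetic-data generator does and does not emulate,
and the numerical choices that matter for reproducibility.

## From stages to sleep windows

Each night is a vector of 30-s stage codes (0 = wake; 1–3 = light/deep/REM
sleep, collapsed to "sleep" throughout) between the device's predicted
sleep onset and wake onset. Nights that are empty or all-wake are removed,
as are predicted "nights" shorter than 30 minutes that fall on the same
calendar day as a longer night (the calendar day is the date of the
midnight nearest the onset; an onset at exactly noon breaks toward the
later date). Sleep windows are then built by four ordered rules:

(a) wake runs shorter than 10 min become sleep;
(b) sleep runs shorter than 10 min become wake (on the updated series);
(c) sleep segments separated by less than 60 min of contiguous wake merge
    into one window, while separations of 60 min or more split windows;
(d) windows shorter than 3 h are *short*, the rest *long*.

Two boundary conventions are frozen and worth stating. First, a wake gap
of exactly 60 min **splits** (`gap_rule = "lt"`); the alternative reading
(a 60-min gap still merges) is available as `gap_rule = "le"` because the
verbal descriptions of this rule in the literature are ambiguous between
the two. Second, runs at the ends of the sequence are eligible for the
smoothing rules, so 5 min of leading wake is absorbed into the first
window. Sleep and wake time within each window are computed from the
*original* stage labels over the window's span, not from the smoothed
series — smoothing decides the window geometry only.

Nine nightly features follow: sleep percent (total sleep time across all
windows divided by the onset-to-wake-onset span), sleep/wake time in long
and in short windows (hours, summed over windows of a kind), long/short
window counts, and long/short mean window lengths. Features of an absent
window kind are zero-filled. Where one night holds several windows of a
kind, times are sums and lengths are means: sums keep the sleep-percent
numerator consistent with its definition, and mean length keeps "window
length" interpretable when the count exceeds one.

## Sleep periods

Periods are non-overlapping blocks of 6 consecutive calendar days, tiled
from each individual's first recorded night; gaps do not re-anchor the
tiling, so period identity is a pure function of the input. Within a
block, nights with no sleep windows are removed first; the block is kept
if at least 3 nights remain and no contiguous 3-day section accumulates
5 h or more of non-wear time. Missing nights contribute no non-wear to
those sums — non-wear is a property of recorded nights, and the 3-night
minimum is what penalises missingness. The period's feature vector is the
mean and the *population* SD (divide by n; with as few as 3 nights the
choice matters and is documented here) of each zero-filled nightly
feature: 18 values in a frozen order (9 means, then 9 SDs).

## The landscape: embedding, clustering, validation

Period features are z-scored (constant columns dropped with a warning)
and embedded to 2-D with UMAP — 15 neighbours, minimum distance 0.1, 2
components, fixed seed — via the reference `umap-learn` Python
implementation through a subprocess bridge; `method = "pca"` gives a
deterministic linear fallback. UMAP is nondeterministic across platforms
even with a fixed seed, so tests assert *partition* agreement, never
coordinates. DBSCAN (our own grid-indexed implementation; no R
implementation is available in this stack) clusters the embedding with
`eps = 0.5` embedding units and `min_pts = 15`. These two values are
artifact choices: the source analyses report that the precise clustering
method is flexible because the clusters are widely separated, and they do
not report DBSCAN settings. Noise points are assigned to the nearest
cluster centroid by default so every period receives a phenotype
(`assign_noise = FALSE` keeps them out instead).

Clusters are validated with per-cluster mean silhouette scores computed
on the embedding, and mapped onto *semantic* cluster ids by their
dominant night composition: Cluster 0 — every night exactly one long
window; Cluster 1 — some night whose windows are all short; Cluster 2 —
some long+short night; Cluster 3 — some multi-long night; Cluster 4 —
only very-short-sleep nights. The same composition rules, applied per
period with the precedence 4, 1, 2, 3, 0, form a deterministic
**rule-based classifier** that needs no embedding; it anchors the
semantic mapping, serves as the labeller in pipelines that must avoid
embedding nondeterminism (`labeller = "rules"`), and is the reference
against which synthetic ground-truth recovery is measured. DBSCAN may
legitimately split one semantic cluster into several islands (discrete
count features produce separated clumps); the mapping then flags itself
as ambiguous and reports, rather than guessing which island is "the"
cluster.

## The 13 phenotypes

Cluster 1 is subdivided by rules with precedence: any night with more
than one long window gives 1-c; otherwise any night with more than one
short window gives 1-b; the remainder is 1-a. Cluster 0 is subdivided
geometrically: from the centroid (mean x, y of Cluster-0 periods), the
periods at or above the `1 - periphery_fraction` radial quantile form the
periphery, split into six 60° sectors counter-clockwise from −180°
(half-open: sector k covers [−180°+60k, −120°+60k), so −180° itself is
0-A). The centre is the recommended ("rec") monophasic phenotype.

`periphery_fraction` is the single largest reproducibility gap in the
source analyses, which never state how the periphery was delimited; the
default 0.084 is back-calculated from the published subcluster sizes
(54,628 peripheral of 650,339 Cluster-0 periods, i.e. 91.6% central). The
sector letters are positional; the correspondence to any particular
published letter assignment depends on the embedding's arbitrary
orientation, which is why the equivariance of sectors under rotation is a
tested property rather than a fixed letter map.

Eight phenotypes are flagged insomnia-like — 1-a, 1-b, 1-c, 2, 3, 4 (all
marked by >60-min wake blocks or short sleep) plus the two
low-sleep-percentage peripheral sectors 0-E/0-F; that last inclusion is
subjective in the source and is therefore a config override
(`insomnia_peripheral`). The insomnia-like set splits by total sleep time
into short-fractured {1-a, 1-b, 4} and long-fractured {1-c, 2, 3} groups.
The per-subcluster report prints count and sleep-percent columns as
period-feature means, but window-*length* (and long-window time) columns
as conditional means over the nights that actually contain such a window:
the published tables print "–", not 0.000, for absent-kind lengths, and
describe 1-b by its genuinely short long-windows — both only consistent
with the conditional reading.

## Transition dynamics

Every pair of successive retained periods of one individual is a
transition; "successive" ignores calendar gaps by default
(`require_adjacent = TRUE` restricts to abutting 6-day blocks). The CTP
matrix divides each from→to count by the total transitions leaving the
from-phenotype; occupied rows sum to 1 within 1e-9, rows with no outgoing
transitions stay all-zero and flagged — they are *not* uniform-smoothed,
because silent smoothing would bias every downstream comparison. Grouped
summaries sum CTP mass from each fractured source into its own vs the
opposite fracture group and report the relative reduction
100·(p_same − p_other)/p_same, the statistic under which the published
transition asymmetries (73.6%, 70.8%, 97.4%; 74.3%, 65.7%, 70.1%) are
reproduced exactly from their printed inputs.

## Health conditions: static vs dynamic information

Chronic cohorts split individuals by survey response (positive vs
negative; no-answer excluded). Acute cohorts split an individual's own
timeline: periods starting within ±14 days of the report are "during",
periods starting more than 50 days before it are "baseline", and the gap
zone between belongs to neither; individuals with another report in the
50 days before a report are excluded, as are reports with no baseline
data. Transitions are windowed by the *from*-period start date (the
to-period alternative is a config choice the source leaves open). Days
are calendar days, inclusive.

The chi-square statistic is the goodness-of-fit form: the positive
(during) group's category counts against the negative (baseline) group's
proportions scaled to the positive total, with dof = categories − 1.
Categories empty in both groups are dropped; a category observed but with
zero expected raises an error unless a pseudocount is explicitly enabled
— a silent infinite statistic is worse than a loud failure. Note a
statistical property of this design: because the reference group's
proportions are treated as the null, the test attains its nominal size
only when the reference sample is much larger than the observed one (the
regime of the cohorts it mirrors, e.g. 10,017 vs 1,111); at comparable
sizes the neglected reference noise makes it anti-conservative. The
type-I calibration test draws the reference at 100× the observed size for
exactly this reason.

Information gain IG(P, C) = H[P] − H[P|C] is computed in bits from the
joint counts (the ratio of interest is base-invariant; bits are frozen
for reporting). The static model's categories are the phenotype
memberships of periods; the dynamic model's are the ordered phenotype
pairs of transitions; the ratio IG(P, C)/IG(P, S) quantifies how many
times more information the dynamics carry. Two planted-effect
constructions bound its behaviour and are tested: a dynamics-only effect
(two transition kernels with the same stationary distribution) drives the
ratio far above 1, and a prevalence-only effect — one shared next-state
kernel with different current-state margins, the construction under which
a pair carries exactly the information of its first element — keeps it at
1. A naive "prevalence-only" construction with independent draws per
pair would instead double the information and give ratio ≈ 2, which is
why the conditional construction is the right null for this comparison.

## The synthetic generator

The proprietary cohort behind the source analyses is not available, so
the package ships a generator whose defaults are calibrated to the
published per-phenotype profiles: one archetype per phenotype, each a
mixture over night structures (one long window; long+short; long+long;
one or two short-only windows) with window-length and sleep-percent
targets taken from the published subcluster tables (e.g. rec: one 8.087-h
long window at 87.0% sleep; 1-b: 4.606-h long windows and
two-short-window nights; c4: single ~0.51-h short windows).

Mechanically, a night is a *plan* — windows with lengths rounded to
epochs, interior wake placed by random bouts of 0.5–55 min separated by
sleep runs of at least 10 min, gaps of more than 60 min between windows,
and an optional trailing wake run to hit the sleep-percent target —
followed by epoch emission. The bout bounds are chosen so the plan is
*invariant* under the window-construction rules: every planned window is
recovered exactly, which turns window construction into a round-trip
property that is tested for 100% of sd-0 nights. Non-wake epochs are
spread over stages 1–3 at fixed proportions (0.55/0.25/0.20); nothing
downstream reads the distinction. Non-wear is an explicit per-night hours
value (exponential, mean 0.4 h) because the exclusion rule only consumes
the aggregate. Onsets are anchored near 23:00 with truncated-normal
jitter (SD 0.75 h), so the day-assignment rule behaves deterministically;
missingness is i.i.d. per night at 8%, matching the published 91.89%
usable-night share.

The latent phenotype process is a Markov chain that steps once per
6-night block (recorded per night), so period-level labels estimate the
planted transition matrix directly — the granularity at which the CTP
model operates. Each block opens with the archetype's "signature" night
structure (e.g. a two-short-window night for 1-b), making sd-0 blocks
deterministically classifiable by the rule-based classifier; recovery and
matrix-recovery tests rest on this. Condition effects replace the
transition matrix — for all blocks of chronic-positive individuals, or
for blocks starting within ±14 days of an acute report.

What the generator does **not** emulate: physiological stage sequencing
within sleep, circadian phase, seasonal structure, non-wear correlated
with behaviour, and the continuous feature gradients that give the real
Cluster 0 its periphery (synthetic Cluster-0 periods form tight clumps,
so the geometric subdivision is exercised on constructed geometries in
tests rather than on generator output). Passing tests therefore show the
*pipeline* is correct under known dynamics; they do not show that real
cohorts have 13 phenotypes. Two published table values cannot be
satisfied simultaneously by any generator consistent with the
classification rules (the 1-a archetype's long-window count 0.811 and
short-window count 0.215 would require some two-short nights, which the
1-b rule would claim), so 1-a uses a 0.8/0.2 one-long/short-only mixture
and accepts approximate counts.

## Problem sizes and numerical choices

Simulation-based tests use populations between 2,700 and 63,000 nights:
matrix recovery runs 350 individuals × 180 sd-0 nights (≈10,100
transitions, observed max-abs CTP error ≈0.01 against the planted
matrix), the end-to-end run 500 × 60, and the null-calibration and
planted-effect studies 1,000 replicates and ≈10,000 units respectively —
sizes at which the Monte-Carlo error is comfortably inside each
property's tolerance. All durations are hours as doubles derived from
integer epoch counts (one epoch = 30 s exactly); intervals are half-open;
a window spanning epochs [s, e] has length (e−s+1)·30 s. Every stochastic
stage flows from one master seed: individuals carry derived sub-seeds, so
generating any subset of individuals (batch processing) reproduces
exactly the nights a full run would give them. Identical config and seed
give byte-identical outputs on one platform; UMAP coordinates are
platform-dependent, which is the reason the deterministic rule-based
labeller exists and is the default.

## Known limitations

The periphery quantile, DBSCAN parameters, and the insomnia flag for
0-E/0-F are reasoned defaults for undocumented choices in the source
analyses; exact published cluster sizes and condition p-values depend on
the inaccessible cohort and are reproduced in structure, not value (the
printed *derived* quantities — shares, means, relative reductions — are
reproduced exactly from their printed inputs). The chi-square design
inherits the reference-as-null asymmetry discussed above. Transition
modelling is first-order over phenotypes; higher-order or hidden-state
dynamics are out of scope.
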