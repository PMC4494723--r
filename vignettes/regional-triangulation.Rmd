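---
title: "Triangulating regional social-media users around a localized disaster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating regional social-media users around a localized disaster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When a tornado, flood, or explosion hits a locality, the social-media
stream carries a burst of messages from the affected population — buried in
a global stream where the same keywords trend worldwide. Disaster-response
research and surveillance need the *regional* subset: the users who were
plausibly in or tied to the affected area. Platform geotags alone cannot
deliver it; in practice only a few percent of users post with GPS enabled.

`crisistri` implements a rule-based triangulation approach to this problem,
modelled on the 2013 Hattiesburg, Mississippi EF-4 tornado: a user is
declared regional if **any** of three independent evidence channels fires
over the observation span,

1. **Tweet** — the user mentioned (or retweeted) the handle of a regional
   news media outlet;
2. **Biography** — the profile biography contains a regional term
   (*Mississippi, Alabama, Hattiesburg, Birmingham, USM, Ole Miss, SMTTT*);
3. **Location** — the free-text location field contains a regional term, a
   two-letter state code (*MS, AL*), or a regional ZIP code.

Because the channels are independent, each one catches users the others
miss; the per-row *exclusive* counts (users caught by exactly one
criterion) quantify that unique contribution, while *inclusive* counts
(users caught by that row and at least one other) measure redundancy.
Classification is deliberately rule-based rather than probabilistic: every
verdict is auditable against the criterion table, which is what makes the
downstream GPS validation and human quality assessment meaningful.

## Pipeline structure

The full flow, orchestrated by `run_pipeline()` and mirrored by the
numbered scripts under `analysis/`, is

```
JSON-lines corpus
  -> ingest/normalize (flat tab-delimited table, round-trippable)
  -> broad first-pass extraction rules (keywords, hashtags, profile terms,
     news handles, statewide geotag region)
  -> homonym purge
  -> triangulated regional classification + inclusive/exclusive accounting
  -> GPS validation against region polygons + QA sampling
  -> event-centered window summaries, hourly series, fold changes
```

Each stage persists its intermediate, and the manifest records the count at
every stage boundary; counts can only shrink through the funnel.

### Word-boundary matching and the homonym purge

The motivating event's extraction famously pulled in ~800,000 records from
Petaling, Malaysia while hunting for Petal, Mississippi — a substring
match. The package's default matcher therefore tokenizes on
non-alphanumerics and matches terms as contiguous token sequences:
`"petal"` matches `"Petal, MS"` but not `"Petaling Jaya"`, and `"MS"`
matches `"Hattiesburg, MS"` but not `"MSU"`. A `match_mode = "substring"`
compatibility switch reproduces the permissive behaviour, and the explicit
`purge_homonyms()` stage is retained regardless, because real term lists
will always contain the occasional ambiguous prefix: it drops records whose
location contains an exclusion term as a token, and records whose geotag
lies outside the region envelope when their only reason for matching was a
term that is a proper prefix of an exclusion term.

### Profile fields that drift

A user's biography, location, and time zone can change within the span. The
package resolves each user's profile to the values on their most recent
record, a single consistent convention applied in classification, window
summaries, and time-zone tabulation.

### GPS validation

Regional users who geotag at least one tweet form the validation
population. A user is *confirmed* if any geotag falls inside a region
polygon (even-odd ray casting; boundary points count as inside — the
generous convention, chosen so that border-straddling fixtures behave
predictably). Unconfirmed GPS users whose location field still matches a
location criterion are counted *location-consistent* — plausibly residents
travelling — and confirmed + consistent users give the likely-regional
accuracy. The shipped polygons are deliberately coarse synthetic rectangles
for the two states (the logic under test is containment, not cartography);
real boundaries load from any GeoJSON `FeatureCollection`.

### Sampling standards

Quality-assessment samples are sized by Cochran's formula
$n_0 = z^2 p(1-p)/e^2$ at the configured confidence and margin of error
(default 99% and 3.0%, with the worst-case $p = 0.5$), corrected for finite
populations by $n = n_0/(1 + (n_0-1)/N)$ and capped at $N$. At 99%/3.0%
this gives $n_0 = 1844$; at $N = 8423$ the FPC brings it to 1513. The
historical analysis this design follows reviewed 900 users per stratum, a
figure that does not follow from these standards for any population size in
play; `run_pipeline()` therefore exposes both the formula and an explicit
`qa_sample_override`, and makes no attempt to reconcile the two. Error
rates on judged samples are reported with Wilson score intervals (a
deliberate choice: Wilson behaves sensibly at zero observed failures, which
is the expected QA outcome).

### Event windows

The analysis window runs from 50 hours before impact to 46 hours after,
split at impact — two 48-hour windows shifted two hours left so the run-up
to impact is fully inside the pre window. Both this reading and a plain
±48 h design are expressible through `event_window_spec()`. A record at
exactly the event instant is *post*. Hourly series bin by
`floor((t - event)/1h)` and always sum back to their window totals, an
invariant the tests enforce. Note that summing the two windows' user counts
double-counts individuals active in both; `combined_totals()` labels that
figure `user_windows` for this reason.

Fold changes are computed from the package's own window summaries as plain
post/pre ratios. The motivating study's headline multipliers are not
reconcilable with its own table inputs under any simple reading of
"fold change"; this package reports only ratios it can derive.

## The synthetic corpus generator

No public corpus exists for this problem — platform firehose data is
proprietary — so the generator is a first-class module, not a test helper.
It emulates the features the pipeline's correctness depends on:

* **Tweet times** follow an inhomogeneous Poisson process per user:
  baseline ~1.2 tweets/user/day, a sinusoidal diurnal cycle (amplitude 0.5,
  peaking mid-afternoon local time), and, for regional users, a
  multiplicative post-event spike (default peak 3×, half-life 24 h) —
  roughly doubling post-window volume, matching the reported regime.
  Simulation is by thinning against the maximum intensity: simple, exact,
  and testable against the closed-form intensity integral.
* **Population structure**: 30% regional users; regional profiles draw
  bios/locations from configurable term pools with missingness (14% empty
  biographies, 4% empty locations — the reported completeness rates);
  non-regional users get disjoint generic profiles, except a 20% confounder
  subpopulation carrying a homonym location ("Petaling Jaya, Malaysia").
* **Geolocation**: 6% of users GPS-enabled, geotagging about half their
  tweets; 3% of regional geotags planted outside the region (travel noise).
* **Planted signal rates**: 33% retweets, 24% hashtag tweets, 4% of
  regional tweets mention a news handle. Non-regional contamination is
  explicit and small: 0.1% of non-regional tweets mention a news handle
  (the rare false positive a QA review catches) and 5% carry a trending
  event keyword (so the broad extraction filter retains outside chatter,
  as it does in reality).
* **Determinism**: each user's randomness is seeded independently from the
  master seed, so corpora are byte-reproducible and individual users are
  stable under unrelated configuration edits.

Ground truth records each user's planted label, each geotag's true
in/out-of-region status, and directly-computed per-window tallies; the
tests require the analytics modules to reproduce those tallies exactly.

The generator's defaults were fixed once, from the reported event
statistics where available and from ordinary practice where not, and they
are the conditions every test and the acceptance script run under. Truth
covers only users who emitted at least one tweet — silent accounts are
invisible to every stage, so recall is defined over observable users.

What the generator does **not** emulate: linguistically realistic text,
follower graphs, retweet cascade structure, coordinated bots, or real
cartographic boundaries. Passing tests therefore demonstrate that the
*mechanics* — matching, accounting, containment, windowing, sampling — are
correct under controlled conditions, not that the shipped term lists would
achieve any particular precision/recall on live data, which depends
entirely on term-list quality for the region at hand.

## Scale choices

The analysis scripts and acceptance checks run the generator at 3,000 users
(~40,000 tweets), and the property suites at 100–600 users across many
seeds — sizes chosen so the full corpus regime (multi-day span, spike,
confounders) is represented while the whole analysis replays in about a
minute on a laptop. The `paper_regime` preset (10,000 users, ~10^5 tweets)
reproduces the full scale when wanted.

## Known limitations

* Term lists are the method: the shipped defaults encode one event's
  geography and will not transfer without editing.
* Mention-based news detection requires mention/retweet metadata; plain-text
  outlet references deliberately do not count.
* The flat-table escaping scheme (backslash escapes, `\N` for missing) is a
  package convention for round-trip fidelity, not an external standard.
* Time zones are tabulated but, as in the motivating analysis, are too
  noisy to serve as a regional criterion; the table is descriptive output.
* ZIP matching uses a shipped contiguous-range convention for the two
  states, not an authoritative ZIP directory.
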