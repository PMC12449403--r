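---
title: "Analysing clinician secure-messaging networks around clinical deterioration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing clinician secure-messaging networks around clinical deterioration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carenet)
```

## The problem

Hospitals increasingly route interdisciplinary communication through
secure, encounter-linked text messaging. The metadata of such a platform
— who messaged whom, when, about which admission — defines a directed,
weighted social network among healthcare providers. carenet implements a
three-stage analysis of such message logs centred on inpatient clinical
deterioration events (activation of a rapid response or code team, whose
timestamp is called **Time 0**):

1. a **global network** over all encounter-linked messages, with nodes
   labelled by provider role and directed edges weighted by message
   volume per ordered sender–recipient pair;
2. **encounter subnetworks**, one per admission; for admissions with a
   deterioration, only messages sent *strictly before* Time 0 enter the
   graph, and encounters whose messages all follow Time 0 ("post-only")
   are excluded from the deterioration stratum;
3. **epoch subnetworks** built from messages in half-open 12-hour
   windows `[-36,-24)`, `[-24,-12)`, `[-12,0)` hours relative to Time 0.

Because real hospital messaging data are protected and not shareable,
the package ships a seeded synthetic generator that reproduces the
statistical structure this analysis assumes, so every stage is testable
end to end.

## Network measures and their conventions

All centralities are normalized so that values are comparable across
networks of different sizes. Fragmented little graphs (a typical
encounter subnetwork has a dozen nodes, often in several components)
make the usually-invisible conventions consequential, so they are
explicit and, where reasonable, switchable:

* **Distances** (betweenness, closeness, eccentricity, diameter, radius)
  are computed on the *unweighted undirected projection* of the message
  graph. Undirected unweighted distances are the most robust choice in
  highly fragmented graphs; directed variants are available via the
  `directed` argument of the centrality functions.
* **Betweenness** follows Brandes' pair-dependency accumulation,
  normalized by `(n-1)(n-2)/2`; unreachable pairs contribute nothing,
  and graphs with fewer than three nodes score zero everywhere. In a
  graph that is a union of dyads, every node scores exactly zero — the
  signature of networks with no intermediaries.
* **Closeness** uses the reachable-set (Wasserman–Faust) correction:
  `C(v) = (|R|/(n-1)) * (|R| / sum of distances to R)` with `R` the set
  reachable from `v`. Isolated nodes score 0; no infinite-distance
  placeholder is ever used.
* **Eigenvector centrality** is the leading eigenvector of the
  *weighted* undirected adjacency, scaled so the maximum entry is 1
  (max-scaling, not unit norm: in small networks it keeps values on the
  interpretable 0–1 range). It is computed by power iteration from the
  all-ones vector with the iteration applied to `I + A` — the shift
  leaves eigenvectors unchanged but guarantees convergence on bipartite
  components, where iterating on `A` alone oscillates. Convergence is
  declared when successive max-normalized iterates differ by less than
  1e-10 (cap 10,000 iterations; exceeding the cap is an error reporting
  the residual). Nodes outside the dominant component retain their
  near-zero converged values.
* **Density** is the directed edge count over `n(n-1)` ordered pairs.
* The **global clustering coefficient** is transitivity — three times
  the triangle count over the number of connected triples — not the
  mean local coefficient; the latter is available via
  `network_summary(..., clustering = "average_local")`.

Node degree counts distinct in-neighbours plus distinct out-neighbours,
ignoring weights, which is what the degree–frequency table summarises.

## The synthetic cohort generator

`generate_cohort()` draws, from a single seeded stream: a provider pool
with fixed role proportions (41% registered nurses, 13% frontline
providers — advanced practice providers and housestaff analysed as one
role — 10% attending physicians, remainder split across nursing
assistants, pharmacists, respiratory therapists and other roles); one
year of encounters with lognormal lengths of stay; message linkage for
47% of encounters; a deterioration in 120/4328 ≈ 2.8% of linked
encounters; and an admission-to-deterioration time that is lognormal
with median 1.6 days and log-scale sigma 2.1 (the sigma solves
`exp(±0.6745·sigma)·1.6 = (0.4, 6.6)`, placing the quartiles at 0.4 and
6.6 days), truncated to the stay by resampling (up to 1000 attempts)
rather than clipping, to avoid a probability mass at discharge.

Messages arrive per encounter as a homogeneous process
(`base_rate = 0.75` per encounter-hour) over a care team sampled
weight-proportionally from the shared pool. Three choices matter and
deserve their rationale:

* **Provider selection weights are Pareto-distributed**
  (`activity_shape = 1.2`). A tail exponent near 1 concentrates team
  membership on a minority of recurring providers, producing the
  strongly right-skewed degree distribution (many low-degree nodes, few
  hubs) that real hospital messaging networks show. The package treats
  max degree at least ten times the median as the structural signature
  to preserve.
* **Care teams total 25 providers** (8 nurses, 5 frontline providers,
  3 physicians, 3 nursing assistants, 2 pharmacists, 2 respiratory
  therapists, 2 other). Teams of this size reflect shift turnover
  across a multi-day stay and keep epoch subnetworks on the steep part
  of the team-occupancy curve, at the scale of roughly 9–20 active
  nodes per 12-hour window.
* **Escalation is a linear rate ramp**, not a step: the message rate
  rises linearly from `base_rate` at `escalation_window_h` (default
  36 h) before Time 0 to `escalation_multiplier × base_rate` at Time 0.
  A step confined to the final 12-hour window cannot produce growth
  between the two earlier windows — they would share one distribution —
  whereas a ramp over the whole 36-hour horizon yields the graded
  increase in nodes and edges toward Time 0 that escalating
  communication implies. The ramp is sampled exactly by superposing
  triangular-density arrivals on the homogeneous base process.

Senders are drawn by configured role shares (35% registered nurse, 29%
frontline provider), then by weight within the role's team members;
recipient counts are `1 + geometric`, capped at team size minus one,
drawn without replacement. Message length and minutes-to-first-read are
lognormal; neither feeds any network quantity, they exist so the
ingest/egest layer round-trips realistic records.

What the generator does *not* emulate: provider shift schedules, message
content, read-receipt dynamics, diurnal rhythms, and any dependence of
messaging on severity beyond the deterioration flag. Tests passing on
synthetic data therefore certify the pipeline's correctness and the
recoverability of planted effects — not any clinical claim about real
hospitals.

## Study-condition experiments

Two designed experiments anchor the epoch analysis:

* **Planted escalation**: 100 deteriorating encounters, all linked,
  multiplier 2, with long stays (median 10 days) and deterioration
  around day 4 so the full 36-hour pre-deterioration horizon lies
  within the admission. Median nodes and edges then increase strictly
  across the three windows and Kruskal–Wallis rejects comfortably.
* **Matched null**: the same full-coverage design with multiplier 1.
  Full coverage is essential to the *null being a null*: under the
  default 1.6-day median deterioration time, many encounters are
  admitted less than 36 h before Time 0, so earlier windows are
  truncated by admission and window counts differ for reasons that have
  nothing to do with escalation. With full coverage the three windows
  are exchangeable and the Kruskal–Wallis rejection rate sits at its
  nominal 5% (the suite checks 200 replicate seeds against a 3–7%
  band). This truncation is also why, at the default timing, the
  `[-12,0)` window is diluted by small graphs from short-stay
  encounters: real-data analyses face the same selection, which is
  worth remembering when reading epoch tables.

## Statistics

Group comparisons use the field-standard nonparametric battery:
Mann–Whitney U (exact by enumeration when both samples have at most 8
untied observations, otherwise normal approximation with tie and
continuity corrections), Kruskal–Wallis with tie correction, chi-square
without continuity correction, switching to Fisher's exact test for 2×2
tables with any expected cell below 5, and Bonferroni adjustment with
`m` equal to the number of pairwise comparisons actually performed per
measure family. Quantiles use linear interpolation (type 7). Node-level
comparisons pool node-in-subnetwork observations — each node in each
subnetwork is one observation, with no within-encounter clustering
adjustment; this is the simplest reading consistent with per-role
medians over thousands of subnetworks, and a known limitation (messages
from one encounter are not independent).

Display rounding in the cohort summary is declared once: integer
percent for encounter linkage, one decimal elsewhere; raw proportions
are always retained so nothing is lost to rounding.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(default_config(seed = 7))
co

g <- build_global_network(co$messages, co$providers)
ct <- centrality_table(g)
cmp <- compare_roles_within_network(ct)
head(cmp$omnibus)

out <- tempfile()
manifest <- run_full_analysis(list(seed = 7), out)
list.files(out)
```

Problem sizes used throughout the package's own test suite are scaled
for a laptop-class single core: the default cohort is 400 providers and
800 encounters (about 28,000 messages), calibration checks draw 10,000
deterioration times and one cohort of 100,000+ messages, and the null
epoch experiment runs 200 replicates of 40 encounters.

## Known limitations

* The exact conventions a given graph library would use (directed vs
  undirected distances, eigenvector scaling) vary; published tables
  computed under other conventions are behaviourally, not numerically,
  comparable. All of this package's conventions are stated above.
* Epoch anchoring uses the *first* deterioration of an encounter;
  subsequent rapid-response activations in the same admission are
  ignored by design.
* No mixed-effects or clustered-variance modelling; Bonferroni is the
  only multiplicity control offered.
* Unknown role labels map to `other` with a warning; role-level
  inference is only as good as the provider directory.
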