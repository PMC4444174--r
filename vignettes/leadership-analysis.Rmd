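---
title: "Measuring leadership in collective movements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring leadership in collective movements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movelead)
```

## The problem

When a group of animals moves from one site to another, who decides?
Three classical proxies operationalise "leadership": the individual that
departs first, the individual at the front of the travel progression, and
the individual whose departure recruits followers fastest. `movelead` turns
time-stamped behavioural event logs into these three per-individual tallies
and asks, for each, whether the distribution across group members could be
uniform — the statistical signature of shared decision-making — or is
concentrated on consistent individuals.

The package was designed around observations of family groups of Przewalski
horses (6–12 individuals, roughly 40 collective movements per group), but
nothing in the machinery is species-specific: any event stream with
departures, joining, pre-departure intent behaviours, optional front-position
annotations and optional agonistic interactions fits the input contract.

## From events to collective movements

An `event_log` is a time-sorted table of `(time_s, actor_id, kind,
target_id)` records. Times are seconds from session start (field protocols
based on tape recorders yield relative time only). Segmentation proceeds in
one pass:

1. **Clustering.** Departure/joining events separated by at least
   `movement_gap_s` (default 600 s) of movement silence belong to different
   candidate movements.
2. **Participation rule.** A cluster is a collective movement when its
   distinct movers reach `ceiling(participation_fraction × N)` — with the
   default 0.5, at least half the group. Tightening the fraction can only
   remove movements, a monotonicity the tests check.
3. **First movers.** All individuals departing within
   `simultaneity_window_s` (default 10 s, inclusive) of the earliest
   departure are simultaneous first movers. Field protocols record "departed
   at the same time" without stating a resolution, so the window is a
   package choice and configurable; the set never depends on the ordering of
   equal-timestamp records.
4. **Pre-departure window.** Intent behaviours (moving away, staying
   peripheral, following a mover, joining a peripheral individual, pausing)
   are attributed to a movement when they fall in the half-open window
   `[t0 − 1200 s, t0)`. The window is half-open because an event at exactly
   `t0` is the departure itself.
5. **Bouts.** A group-level pause (pause events by at least the
   participation fraction of the movement's movers) followed by renewed
   movement after `bout_gap_s` (default 60 s) opens a new bout. Downstream
   leadership analyses use single-bout movements only, so that a tally never
   counts one interrupted journey twice.
6. **Front position.** The walking order is taken from dedicated `front`
   annotations; the record closest to the movement's temporal midpoint
   (first departure to last arrival) identifies the front individual, and a
   movement is dropped from front tallies — not from departure tallies —
   when no record exists or two individuals share the closest record
   (travelling abreast). This mirrors the different sample sizes of the
   front-position and departure analyses in field datasets.
7. **Joining duration.** Last departure time minus first departure time;
   undefined (never zero) for a single-departure record.

## The inference layer

**Uniformity.** Each proxy tally is tested with the log-likelihood-ratio
statistic \(G = 2\sum_i o_i \ln(o_i/e_i)\) against uniform expected counts
\(e_i = n/k\), divided by the Williams small-sample factor
\(q = 1 + (k^2-1)/(6n(k-1))\). With per-individual expected counts of 2–6,
the chi-square approximation is unreliable, so the null distribution is
simulated: `B = 2000` multinomial draws of size \(n\) over \(k\) equiprobable
cells, each reduced to its corrected G, and
\(p = (1 + \#\{G^{sim} \ge G^{obs}\})/(B+1)\). The add-one estimator keeps p
off zero, and the simulated statistics receive the same correction as the
observed one so the comparison is exchangeable. Degrees of freedom are
reported as \(k - 1\).

**Chance-level post-hocs.** Which individuals drive a significant G? The
package uses an exact two-sided binomial test of each individual's count out
of \(n\) against success probability \(1/k\), Holm-corrected across the
\(k\) tests. The two-sided choice reflects that both above-chance
(candidate leaders) and below-chance individuals are informative. Flags are
raised at family-wise \(\alpha = 0.05\).

**Correlations and joining efficiency.** Spearman correlations use mid-ranks
for ties and an exact permutation p over all \(n!\) orderings when
\(n \le 9\) (group sizes in this design are 6–12), falling back to the
t-approximation above that. Joining durations of single-first-mover
movements, grouped by first movers with at least three initiations, are
compared with the tie-corrected Kruskal-Wallis test; with fewer than two
qualifying movers the grouping is returned with an explicit
not-applicable flag.

**Dominance.** Agonistic events (actor = winner) accumulate into a win
matrix. Each dyad is directed by strict majority of wins; exact ties and
never-interacting dyads are *unknown*. Linearity uses Landau's index with
every unknown dyad contributing its expectation of half a win,
\(h = \frac{12}{N^3-N}\sum_i (v_i - \frac{N-1}{2})^2\), and the corrected
\(h' = h + 6u/(N^3-N)\) adds the binomial variance of \(u\) randomly
directed unknown dyads — so \(h' > h\) exactly when unknowns exist,
\(h' = h = 1\) for a complete transitive hierarchy, and \(h' = 3/(N+1)\)
(the coin-flip expectation) when every dyad is tied. Significance is the
right-tail share of linearity values among random tournaments. Rank order
itself comes from a deterministic local search (pairwise swaps and
relocations from a dominated-count start) minimising order-inconsistent
dyads; it is a documented heuristic, validated against exhaustive
enumeration at small N, not a re-implementation of any particular
rank-ordering program.

## Reconstruction from published summaries

Published tables report per-individual *percentages*; the underlying integer
counts are recoverable because a percentage printed to two decimals pins
\(o_i\) to within \(0.005\,d/100\) of an integer once the denominator \(d\)
is known. `reconstruct_counts()` searches candidate denominators and accepts
the one whose products are all integer-consistent at printing precision
(optionally also matching a known column total). This matters because the
bundled tables use different denominators per column — the front-position
percentages of one group are over the 35 single-first-mover movements while
its front sample is 21 — and, in the retrospective columns, the source used
sole-first-mover counts as denominators for *both* conditionals, with blank
cells exactly where that count is zero. `run_from_summary()` mirrors those
conventions so the printed column means are recoverable; the event-stream
`concordance()` instead uses each column's own logical denominator (front
counts for the front retrospective), which we consider the coherent
definition. Undefined cells are `NA`, never 0, and column means average
defined cells only.

One ambiguity is flagged rather than resolved: the pre-departure percentage
denominator is integer-consistent with the single-first-mover movement count
(28/35), not with the count of movements showing collective pre-departure
display, and neither reading exactly recovers the published mean number of
displaying individuals per movement. The package reports what it computes
from the reconstruction and does not force agreement.

## The synthetic generator

`generate_events()` realizes the data-generating process the analysis
assumes, with every latent quantity recorded as ground truth: per-individual
first-mover propensities (fixed, or symmetric Dirichlet with concentration
κ — large κ is shared leadership, a fixed spike is despotism), Bernoulli
pre-departure participation, a coupling probability that the first mover
comes from the participant set (coupling 1 makes every first mover a prior
displayer; coupling 0 decouples intent from initiation), a probability of
2–3 simultaneous first movers inside the simultaneity window, exponential
joining-process durations, front annotations present with a configurable
probability, optional two-bout movements, and arrivals from a fixed travel
time. All randomness derives from one seed via per-movement substreams.
Within a movement, departure gaps are capped below the movement-separation
threshold (preserving the total joining duration) so a long exponential
joining process cannot be split into two spurious movements by the
segmentation it is meant to exercise.

Calibrated presets encode the two study regimes: `bo_like` (N = 12, 42
movements, simultaneity 14/42, propensities proportional to the
reconstructed departure counts, joining mean 471 s, front scored in 11/42)
and `ad_like` (N = 6, 43 movements, simultaneity 8/43, joining mean 249 s,
front scored in 21/43); `null_uniform` and `concentrated` (one individual at
propensity 0.8) bracket the sharing axis. Preset pre-departure rates are the
printed percentages over single-first-mover movements, giving about 2.4
displaying individuals per movement — the lower of the two readings of the
ambiguity above.

What the generator does *not* emulate: spatial trajectories and direction
changes, seasonal herding dynamics, inter-individual behavioural contagion
beyond the single coupling parameter, and observer error (missed or
misattributed events). Passing recovery tests therefore show that the
pipeline inverts its own generative assumptions — segmentation recovers the
injected movements record for record, tallies equal the generator's
bookkeeping, type-I error is nominal under the uniform null and a despotic
leader is detected with high power — not that field data satisfy those
assumptions.

## Numerical choices and degenerate inputs

* Zero-count cells contribute 0 to G; an all-zero tally gives an undefined
  (`NA`) G rather than 0.
* Monte-Carlo and randomization p-values use add-one estimators, bounded
  below by \(1/(B+1)\).
* Ties in Spearman use mid-ranks; a constant rank vector yields `NA` rather
  than an arbitrary coefficient.
* Identical observations across Kruskal-Wallis groups give H = 0, p = 1.
* Single-departure movements have undefined joining durations; undefined is
  distinguished from zero throughout.
* An all-zero win matrix yields id-order ranks with an explicit degeneracy
  warning; ranking tie-breaks are deterministic (dominated count, then win
  total, then id).
* Reports contain no timestamps, and every stochastic result carries its
  seed, so identical inputs and seeds give byte-identical reports.

## Problem sizes used in the test suite

Simulation-based checks run at the scale of the study design: uniformity
type-I error over 500 null tallies at B = 2000; despotic-leader power over
100 replicates of 500 movements; propensity recovery at 10⁴ movements
(maximum absolute deviation below 0.02); exhaustive oracles at N ≤ 6 for
Spearman permutation p-values and rank-order optimality, and over all 64
tournament orientations at N = 4 for the linearity index.

## Limitations

Group-level percentages and counts make the G statistics, Spearman
coefficients, post-hoc flags and concordance means recomputable from print,
but movement-level quantities that require the raw event streams —
joining-duration means, Kruskal-Wallis H values, and the dominance matrices
behind published h′ values — are not recoverable from summaries; for those
the package offers the synthetic route instead. The rank-ordering heuristic
guarantees determinism, not global optimality (it is within one
inconsistency of the exhaustive optimum in the tested regime). The exact
Spearman permutation test with ties can differ from printed p-values
produced by approximate methods, a difference that does not affect the
coefficients themselves.
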