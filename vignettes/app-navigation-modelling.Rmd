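---
title: "Modelling in-app navigation with Markov chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling in-app navigation with Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clicktrails)
```

## The model

clicktrails treats a user's path through a mobile app as a realisation of a
first-order Markov chain. The state space is the set of $n$ app pages plus a
surrogate absorbing *exit* state $s_{n+1}$ representing leaving the app. A
session's *trail* $\{s_{(1)}, \dots, s_{(k)}\}$ is its ordered page views;
appending the exit state, the chain assigns it the likelihood

$$L(\text{trail}) = \prod_{j=1}^{k} p_{(j),(j+1)},$$

the product of one transition probability per step, with $s_{(k+1)} = s_{n+1}$.
The transition matrix $P$ is estimated by counting observed transitions into a
matrix $M$ — each adjacent pair in a trail contributes one count, and every
session contributes one final count into the exit state — and normalising each
row of $M$ to sum to 1. The initial distribution $\pi$ is estimated as the
share of sessions whose first view is each page. The first-order assumption
(the next page depends only on the current page) is deliberate: it keeps the
matrix readable and estimable from small field-trial logs, at the cost of
ignoring longer navigation history. Higher-order and dwell-time models are out
of scope.

Three conventions matter downstream:

* the exit row of $P$ is all zero and never sampled from; simulation stops on
  reaching exit;
* rows with no observed outgoing transitions are left all-zero and flagged
  *dangling* rather than imputed;
* zeros in $P$ are preserved at the estimation stage — no smoothing — so the
  fitted matrix reports exactly what was observed. Smoothing enters only in
  clustering (below), where it is required.

## Sessionization

Field logs often carry no session identifier, so sessions are reconstructed
from timestamps: a new session starts when the gap to the user's previous
event *strictly exceeds* the inactivity threshold (default 30 minutes). A gap
of exactly the threshold stays in-session — the phrase "no longer than 30
minutes of inactivity" is read as inclusive; logs with exact-threshold gaps
are vanishingly rare in practice, but the convention is fixed and documented
here because it is a genuine reading choice, not a measured fact.

Consecutive repeats of the same page within a session are collapsed into one
state occurrence by default, because a transition matrix with an empty
diagonal (no self-transitions) is what the estimation stage expects; the
`collapse_repeats` switch exists for logs where refreshes are meaningful.
Trail-length filtering (`filter_sessions()`, default 2–20) is counted on the
collapsed trail.

## Sequence clustering

`cluster_sequences()` groups trails into $K$ clusters, each represented by its
own chain, with classification (hard) EM: random initial assignment, per-cluster
matrix construction, likelihood scoring of every trail under every cluster
chain, argmax reassignment, and repetition until the assignment vector is
identical to the previous iteration's. Design choices the algorithm statement
leaves open, and how this package resolves them:

* **Smoothing.** A product likelihood is zero the moment a trail uses a
  transition unseen in a cluster, which stalls reassignment. A pseudocount
  (default 0.5) is added to every non-exit-row cell, exit column included,
  before normalising cluster chains. As the pseudocount goes to zero on data
  where every cluster observes every transition, the cluster chains converge
  to the unsmoothed per-cluster MLE.
* **Initial term.** The per-trail likelihood used for assignment is the
  product of transition probabilities only; $\pi$ is estimated per cluster but
  excluded, matching the worked product form above. `include_initial` is
  available on the scoring function.
* **Ties.** Argmax ties go to the lowest cluster index, deterministically.
* **Empty clusters.** A cluster left empty by a reassignment is re-seeded with
  the currently worst-fitting trail, keeping $K$ components alive.
* **Convergence safeguard.** `max_iter` (default 100) caps the loop; expiry is
  flagged `converged = FALSE`.
* **Restarts.** Hard EM from uniform random partitions is greedy and
  frequently converges to blended local optima; `n_restarts` runs independent
  initialisations and keeps the fit with the highest total assigned
  log-likelihood. Ten restarts is a sensible default scale for a few hundred
  sessions.

Everything is computed in log space; a zero-probability step scores `-Inf`
rather than erroring, and with a positive pseudocount cluster likelihoods are
always finite.

$K$ is not selected automatically: the method is exploratory, and the choice
of $K$ is left to the analyst.

## The synthetic field-trial generator

`generate_log()` emulates the kind of small mHealth field trial the package's
reference data comes from, so every pipeline stage is testable without any
download, with ground truth attached to every event. The defaults are the
study conditions, fixed once:

* 22 users; per-user session counts drawn from a zero-truncated negative
  binomial with mean 37 and SD 29.35 (size $\mu^2/(\sigma^2-\mu) \approx
  1.66$), reproducing heavy overdispersion in engagement;
* sessions drawn from a mixture of three archetype chains —
  *gamification* 0.45, *route_tracking* 0.40, *bug_report* 0.15 (bug-report
  sessions are described as infrequent);
* within-session gaps uniform on 2–300 s, between-session gaps uniform on
  40 min–20 h, so 30-minute sessionization recovers the generated partition
  exactly by construction; timestamps are whole seconds from 2017-09-01 UTC,
  mirroring a ~25-day trial window with no diurnal structure;
* trail lengths arise from the chains rather than being imposed; exit masses
  are calibrated (via the absorbing-chain fundamental matrix) so the default
  mixture's mean trail length is ≈ 5 actions.

The archetype chains (`make_archetype_chains()`) are a design in their own
right. Each routes through the shared *Coach* hub every couple of steps, where
the three chains send users to disjoint wings (leaderboards; tracking pages;
personal/bug pages), and sessions rarely end directly on the start page —
users who open the app overwhelmingly do something before leaving, so exit
mass sits on the wing pages. Two properties motivated this structure, found
by examining when likelihood-based clustering can and cannot separate
mixtures of chains:

* if two archetypes use *disjoint* page vocabularies, merging them into one
  cluster is almost free — their rows never compete inside a blended chain —
  so a likelihood criterion can prefer blends over the true partition.
  Discrimination has to live on *shared* rows with contrasting targets, which
  is exactly what the common Coach hub provides;
* trails consisting of a single page view carry no transition signal beyond
  their exit step, and the assignment likelihood excludes $\pi$; keeping
  immediate exits rare keeps such unclassifiable singletons rare.

With this design, hard EM at $K=3$ with 10 restarts recovers generator labels
with ~93–94% best-match agreement on average across independent draws of
100 sessions per archetype.

What the generator does *not* emulate: dropout over time, diurnal or weekly
rhythm, per-user behavioural drift, push-notification effects, or any
relation between app use and cycling outcomes. Tests passing on generated
data therefore demonstrate correctness of the estimation and clustering
machinery under the stated mixture model, not robustness to the full
messiness of production logs.

## The packaged reference model

`start2cycle_model()` returns the published 9-page transition matrix of the
*Start2Cycle* recreational-cycling app (25-day trial, 22 users, 824
sessions), stored exactly as printed, with unobserved transitions as 0. Two
caveats are inherited from the printed table:

* printed rows sum to 1 only up to two-decimal rounding (row sums range
  0.99–1.01); the model constructor is told to tolerate this, and simulation
  normalises row weights at sampling time, so quantities recovered by
  simulate-then-fit equal printed value divided by row sum;
* the *Coach → Route* entry is printed `0.00` while other absent transitions
  are printed as dashes; the fixture stores both as 0.

The published initial distribution puts 0.769 on *Coach*; only the total of
the complement (0.231) is published, so its split — *Track* 0.15,
*Competition* 0.081 — is an emulation choice reflecting the reported
observation that resumed sessions most often restart on those two pages.

## Visualization exports

`threshold_edges()` retains transitions with probability at least the cutoff
(default 0.13, which yields a readable figure on the reference model). Any
page whose incoming edges all fall below the cutoff would be visually
isolated, so its single strongest incoming edge is additionally retained and
flagged as an exception; ties go to the earlier source state in state order.
On the reference model this rule isolates-then-rescues exactly the *Trophies*
page (via *Routes → Trophies*, 0.06), while *Personal* is already reached by
an above-cutoff edge (*Bug report → Personal*, 0.29). The exporters write
d3-style node-link JSON (probabilities at full precision, so the edge set
round-trips exactly), GraphViz DOT, and a cluster-by-session trail table for
heatmap rendering.

## Problem sizes and numerical choices

Row-stochasticity is validated to $10^{-9}$ on fitted models and to 0.02 on
models transcribed from rounded published tables. Likelihoods are summed in
log space. Simulation draws next states with row weights normalised at
sampling time and caps trails at `max_len` (default 100), flagging
truncation.

The test suite runs its heavier checks at deliberately desk-scale sizes: the
simulate–sessionize–refit round trip of the reference model uses ~50,000
sessions (entrywise recovery to ±0.01); parameter-recovery properties use a
few thousand sessions; clustering recovery uses 100 sessions per archetype
with 10 restarts. `scripts/acceptance.R` reruns the 50,000-session round trip
end to end and reports the recovered transition probabilities.
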