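---
title: "Mesoscale network dynamics during Go/No-Go learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale network dynamics during Go/No-Go learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mesorank implements a complete analysis chain for chronic multi-region
single-unit recordings from mice learning a visual Go/No-Go discrimination:
from raw spike times and trial events to behavioral staging, activity-onset
sequences, functional-connectivity rank dynamics, and stimulus-encoding
profiles. This vignette is the package's account of the underlying models,
the parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic cohort does and does not establish
about real recordings.

## The task and the behavioral model

Head-fixed mice view an 800-ms grating (Go or No-Go, pseudo-randomized so
that every block of six trials contains three of each), then a response
signal opens a response window. Licking in the window after a Go stimulus
is a Hit (rewarded); failing to lick is a Miss. Licking after a No-Go
stimulus is a False Alarm (8-s timeout); withholding is a Correct Rejection
(2-s reduction of the 4–6-s inter-trial interval). `assign_outcomes()`
derives the four outcomes purely from the lick record; a stored outcome
column is never trusted. The response window is `(signal, signal + 1.7 s)`,
so the full response period spans 800–2500 ms after stimulus onset.

Discriminability is the signal-detection index
$d' = \Phi^{-1}(\text{hit rate}) - \Phi^{-1}(\text{FA rate})$, computed per
trial over a sliding window of the 10 trials before and 10 after (the index
trial included; edge windows clipped to the session). Trials after a
session's last lick are discarded first — a mouse that has stopped licking
is no longer doing the task. Trials with $d' < 2$ are labelled *early*,
$d' > 3$ *expert*, anything between (or undefined) *excluded*.

Two open choices are resolved as follows:

* **Window membership.** "10 before and 10 after" leaves the index trial
  and edge policy unstated; we include the index trial (21-trial windows)
  and clip at session bounds, which maximizes the number of labelled
  trials.
* **Extreme-rate correction.** Perfect windows give infinite $d'$; we apply
  the log-linear rule $k/n \to (k+0.5)/(n+1)$ before the quantile. A
  consequence worth knowing: a 21-trial window tops out at $d' \approx
  3.4$, and a *single* error inside it already drops $d'$ below 3 — the
  expert label therefore marks stretches of essentially perfect
  performance. This is a property of the staging rule itself, not of the
  implementation, and it drives the near-perfect expert schedules in the
  synthetic cohort defaults.

## Firing rates and activity onset timing

Spikes are aligned to stimulus onset (all intervals half-open, times in ms,
negative = pre-stimulus) over an analysis span of −600 to +2800 ms. The
−600 ms pre-stimulus extent is this package's choice: it accommodates the
−500–0 ms baseline window plus two spare rate windows. Rates are spike
counts in non-overlapping 25-ms windows (on a 1-ms grid) divided by 25 ms,
averaged over trials. `bootstrap_rate_traces()` re-draws five trials per
session with replacement (500 times by default) to check that rate
contrasts survive equalized trial counts.

A unit's **activity onset** is found by comparing, per 25-ms window, the
across-trial rates to the baseline (−500–0 ms) by t-test and taking the
start of the earliest run of at least three consecutive windows with
p < 0.05. Resolved choices:

* The test is **paired** per trial (window rate minus that trial's mean
  baseline rate); pairing absorbs slow across-trial rate drift.
* Both increases and decreases qualify (two-sided), since correct-rejection
  trials show prominent rate *decreases*.
* The onset time is the **start** of the first significant window; centers
  would shift every onset by +12.5 ms.
* Runs are scanned forward; only the earliest qualifying run defines onset.

A calibration caveat: at very low firing rates the per-window t-test runs
on counts that are mostly 0/1 and becomes anticonservative — in simulation
the stationary-null detected-onset fraction is ≈0.09 at 2 Hz, ≈0.03 at
10 Hz, ≈0.01 at 20 Hz. Sparse units should be interpreted with care (or
excluded); the test-suite null calibration runs at 10 Hz, a typical rate
for units entering this analysis.

Per region, the 25-ms window holding the largest number of unit onsets is
the **regional peak activation time** (ties: earliest window), and the
mean absolute pairwise difference of regional peak times is the
**temporal-compression** statistic: it shrinks when learning compresses the
activation sequence. Stage contrasts of onset times use two-sample t-tests
with Sidak adjustment $1-(1-p)^m$ over the regions tested.

## TSPE functional connectivity

Connectivity is scored per ordered unit pair from the cross-correlogram of
their spike trains (1-ms lag bins; the bin at lag $\ell$ counts pairs with
target-minus-source difference in $[\ell, \ell+1)$ ms). The
total-spiking-probability-edge (TSPE) score emphasizes sharp short-latency
peaks over slow co-modulation: the correlogram is normalized by
$\min(n_\text{src}, n_\text{tgt})$, convolved with a stack of zero-sum
edge-detection kernels, accumulated by a running-total boxcar, summed over
a small parameter grid, and read out at the lag with maximal absolute
response within (0, 20] ms. The sign is preserved — positive = putative
excitation, negative = putative inhibition — and only positive scores at
delays within (0, 20] ms (the monosynaptic-like excitatory range) pass the
excitatory filter.

Numerical choices for the kernels:

* Each kernel is a **peak detector**: flanks of width $a$ at height $-b$
  and a centre plateau of width $b$ at height $+2a$, so a correlogram
  delta at lag $\ell$ produces its extremal response exactly *at* $\ell$.
* Coefficients are integers, so the kernel's zero sum cancels exactly in
  floating point and a flat correlogram scores exactly 0.
* The default grid is $a \in \{2,4,6\}$, $b \in \{1,3\}$, running total
  $c \in \{3,5\}$ ms; $b$ and $c$ are odd so every kernel has an exact
  centre bin. The grid is exposed in `tspe_config()`.
* Convolution is implemented once as a summed kernel (all steps are
  linear), applied with zero padding; `max_lag` (30 ms) covers the delay
  range plus the widest kernel half-width.

**Significance** uses jitter surrogates: every spike of both trains is
displaced uniformly within ±25 ms (clipped to the segment) and the score
recomputed. Jitter destroys the ≤20-ms structure being tested while
preserving segment rates and slow comodulation, which is exactly the null
the excitatory-delay test needs (ISI or trial shuffling would destroy
rate structure too and anticonservatively inflate detections). A
connection is significant when its score exceeds the 95th percentile of
its own surrogate scores; the per-pair false-positive rate of this rule is
by construction ≈0.05, which the test suite verifies. Scoring is per trial
by default (one 200-ms window segment per trial, with a shared null pooled
across trials to keep cost reasonable); a pooled mode (correlograms summed
across segments before scoring) is provided for low-rate data.

Because the 95% rule *admits* a 5% false-pair baseline, it is the right
tool for the strength pipeline (below) where that baseline washes out of
proportions and ranks, but the wrong tool for calling *individual* edges
among thousands of candidate pairs. Pooled mode therefore offers
`edge_rule = "max"`: an edge is called only when its score exceeds *every*
surrogate (exact permutation p = 1/(n_surrogates+1)). With 750 surrogates
this keeps the expected number of false edges near one across ~1200
candidate pairs, and the planted-network benchmark recovers 20 edges with
precision ≳0.95 and recall 1.0.

Known limitations, inherent to correlational edge detection:

* **Common input.** Two targets of one source co-fluctuate at the
  difference of their delays and are indistinguishable from a direct edge;
  in benchmarks with freely sampled planted edges this costs precision
  (≈0.74 vs ≈0.95 with disjoint edges, identical detector). The recovery
  benchmark (`simulate_edge_network()`) plants disjoint edges to isolate
  detector performance; real-data edge lists inherit the ambiguity.
* **Rebound lobes.** A deep trough (suppression) flanked by normal rates
  produces positive side lobes in any zero-sum edge filter; sustained
  suppression scores negative and is excluded, but short troughs can
  occasionally register as excitation at an adjacent delay.

## Strength matrices and rank dynamics

For each (trial, 200-ms window), the **functional strength** from region
$r$ to region $s$ is the proportion of significant excitatory pairs among
all $n_r \times n_s$ ordered interregional pairs; within-region pairs are
excluded everywhere and a region with zero units has *undefined* (never
zero) strength. A region's summed row (output) or column (input) strength
is then ranked 1–10 across regions, tie-averaged, 10 = strongest. Ranking
deliberately discards strength magnitudes: firing-rate differences bias
raw cross-correlation counts, whereas ranks are invariant under any
strictly monotone transform of the strengths.

Tie-averaging makes the mean rank over regions exactly $(R+1)/2 = 5.5$ in
every (trial, window) — the exchangeability baseline against which hub
structure is read (for random data all regions hover at 5.5; this package
states the baseline as 5.5 rather than the rounded "rank 5" sometimes
quoted). Consequences: period means average to 5.5 exactly, and stage
differences (ΔRank = expert − early period mean) sum to zero over regions
when no region was excluded. Excluded regions (zero units) are rescaled
onto 1..R linearly and flagged rather than silently renormalized.

Per-connection **decile ranks** (1 = weakest 10% of the 90 interregional
connections in the window) use the tie rule `ceiling(10 k / N)` on
tie-averaged sort positions; with all 90 strengths equal every connection
lands at rank 6 — a documented artifact of the rule, asserted as such in
the tests.

Stage contrasts are two-sample t-tests on per-trial period ranks, Sidak
adjusted. The adjustment family is all (region × period) cells within one
direction and trial type (m = 40 for the full design); the family is not
dictated by the source analyses and is configurable.

## Stimulus encoding (auROC)

Per 200-ms window, a unit's Go-vs-NoGo discriminability is the area under
the ROC curve of its spike-count distributions, computed by the
Mann–Whitney identity from midranks; selectivity is $2|auROC - 0.5|$. To
balance behavioral choice within stimulus groups, each of 500 bootstraps
resamples 50 trials with replacement from each outcome type, so Go (= Hit
+ Miss) and NoGo (= CR + FA) both contain 50 lick and 50 no-lick trials.
Units require at least five trials of each outcome type in their session.
Pre-stimulus windows are analyzed identically (pre-onset encoding reflects
trial history and is reported, not suppressed).

The **shuffle null is built at the trial level**: outcome labels are
permuted across trials and the identical balanced-resample pipeline is run
on the permuted data (200 permutations by default), giving one null
selectivity distribution per unit-window; a bootstrap is "significant"
when its selectivity exceeds the null's 95th percentile, and the unit is
selective in the window iff ≥95% of bootstraps are significant. The
alternative — permuting group labels *within* a bootstrap's resampled
counts — is anticonservative and was rejected after simulation: resampling
with replacement duplicates trials, the observed statistic keeps
duplicates clustered inside their outcome group while within-bootstrap
permutation scatters them, and the inflated observed selectivity classified
stimulus-independent units as selective. Under the trial-level null the
empirical false-classification rate is 0 of hundreds of null units, with
per-bootstrap exceedance ≈0.05 as designed.

Per (region, window), the percentage of selective units among included
units summarizes encoding; the **peak encoding time** of a region within a
trial period is the centre of the window with the highest percentage
(ties: earliest). The link between network position and encoding timing is
the Pearson correlation between per-region period-mean rank and peak
encoding time — negative when higher-ranked regions encode earlier.

## The synthetic cohort: what it emulates, and what it does not

`generate_learning_dataset()` produces multi-session cohorts with known
ground truth; every pipeline stage is validated against it. The model:

* **Behavior.** Balanced six-trial blocks; per-trial Bernoulli responses
  at session-specific hit/FA probabilities; lick bursts ~350 ms after the
  response signal; ITI rules (4–6 s, −2 s after CR, +8 s timeout after FA)
  emulated in trial timing. Defaults: 4 sessions × 300 trials; early
  sessions at hit 0.95 / FA 0.75–0.65 ($d' \approx 1$, rising CR rate),
  expert sessions near error-free (forced by the staging rule, as
  explained above).
* **Spikes.** Homogeneous Poisson baseline (5 Hz) plus an evoked component
  per trial: a step of 20 Hz at the region's latency decaying with
  $\tau = 200$ ms (a single-latency shape chosen so onsets are detectable
  and the planted latency is unambiguous). Stimulus selectivity is planted
  as evoked-gain asymmetry (×1.3 Go / ×0.7 NoGo), confined to visual
  regions in the early stage and network-wide in the expert stage.
* **Connectivity.** Spike transfer: each source spike independently
  inserts a delayed (1–20 ms, ≤1 ms jitter) spike in the target with
  probability p. Ground-truth edges are thus exactly the
  monosynaptic-like excitatory interactions the TSPE stage targets, and
  insertion counts are Binomial(source count, p) — trivially verifiable.
  No cascades (one insertion pass), no inhibitory generation (inhibition
  is tested via suppression-thinned trains in the test suite).
* **Learning trajectory.** Early sessions: regional latencies spread so
  the mean pairwise difference is ≈170 ms; baseline edge motifs only.
  Expert sessions: compressed, earlier latencies (≈57 ms spread) and
  additional visual→frontal motifs (V1/V2M → OFC, mPFC, M2). The two
  spreads are *simulator inputs* shaped by the reported phenomenology;
  they are design inputs, not reproduction targets.

What passing tests on this cohort do **not** show about real data: the
generator has no oscillations, bursting, refractoriness, slow state
drift, movement-locked activity or inhibitory coupling; its units are
stationary within session; its lick behavior is memoryless. Calibrations
(surrogate null rates, onset false positives, encoding false
classifications) therefore certify the *implementation* under the stated
null models, not robustness to every physiological confound.

## Problem sizes, determinism and orchestration

`run_pipeline()` executes behavior → rates/onsets → connectivity → ranks →
encoding → correlation on one spikes/trials pair, writing each stage as
CSV plus a manifest with input/output digests. All randomness derives from
one config seed via `stage_seed(seed, stage_name)` (a fixed integer
congruence), so stages can be re-run individually and full runs are
byte-identical — verified by digest comparison in the tests.

The `analysis/` drivers run the workflow at desk scale: a 3-session,
2-units-per-region cohort of 240-trial sessions, six scored 200-ms
windows, 30 connectivity surrogates and 60 encoding bootstraps — minutes
on one core. Statistical properties are established at larger sizes in the
test suite and `scripts/acceptance.R`: d′ against a root-finding quantile
oracle on a 1024-point grid; onset calibration on 1000 stationary units ×
100 trials and step recovery on 200 units; correlogram/TSPE equality with
brute-force and direct-convolution oracles; surrogate calibration on 1000
independent pairs × 200 surrogates; 20-edge network recovery at 40 units /
750 surrogates; rank conservation and hub/ΔRank recovery over 20 cohorts;
encoding calibration (200 null units) and power (5 vs 15 Hz, 50
trials/type, 200 bootstraps); and rank–latency correlation recovery over
30 planted cohorts with shuffled controls.
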