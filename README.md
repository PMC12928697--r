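# mesorank

Functional-network analysis of chronic multi-region single-unit recordings
from mice learning a visual Go/No-Go discrimination. The package takes raw
spike times (with region labels) and per-trial event tables and produces,
per learning stage:

- **Behavioral staging** — per-trial sliding d′ = Φ⁻¹(hit rate) − Φ⁻¹(FA
  rate) over 21-trial windows; trials labelled *early* (d′ < 2), *expert*
  (d′ > 3) or excluded.
- **Activity onset timing** — per-unit onset = start of the earliest run of
  ≥3 consecutive 25-ms windows whose rates differ from the −500–0 ms
  baseline (paired t-test, p < 0.05); regional peak activation times and
  the temporal-compression statistic (mean pairwise difference of regional
  peaks).
- **TSPE functional connectivity** — per (trial, 200-ms window), an
  edge-filtered cross-correlogram score for every ordered interregional
  unit pair, significance against jitter-surrogate nulls (95% rule), and an
  excitatory filter (positive score, delay ≤ 20 ms). Regional strength =
  proportion of significant pairs among all possible pairs.
- **Rank dynamics** — regions ranked 1–10 by summed input/output strength
  (tie-averaged, 10 = hub; mean rank exactly 5.5 under exchangeability),
  period means, ΔRank = expert − early, and Sidak-corrected stage tests;
  plus per-connection decile ranks.
- **Stimulus encoding** — balanced-bootstrap auROC selectivity
  (2×|auROC − 0.5|) per 200-ms window with a trial-label shuffle null and
  the double-95% rule; regional selective fractions, peak encoding times,
  and the Pearson correlation between a region's network rank and its
  encoding peak time.

A synthetic cohort generator (`generate_learning_dataset()`,
`simulate_edge_network()`) plants directed connectivity, region latencies,
stimulus gains and a learning trajectory, so every stage is testable
against known ground truth — the study's recorded data are not required.

Audience: systems neuroscientists analyzing multi-region spike recordings
in learning paradigms, and anyone needing a tested reference implementation
of TSPE-style connectivity ranking or balanced-bootstrap auROC selectivity.

## Worked example

The `analysis/` directory is the workflow, numbered in execution order:

```sh
Rscript analysis/01_simulate.R          # simulate the cohort
Rscript analysis/02_behavior.R          # stage trials by sliding d'
Rscript analysis/03_pipeline.R          # full pipeline + report (~4 min)
Rscript analysis/04_network_recovery.R  # detector calibration + recovery
Rscript analysis/05_encoding.R          # classifier calibration + rank-latency
```

`02_behavior.R` prints, for the simulated three-session cohort:

```
stage counts per session:
     early excluded expert
  s1   239        0      0
  s2     0       27    213
  s3    30      155     54
  s1: median d' = 0.34  (CR rate 0.28)
  s2: median d' = 3.42  (CR rate 0.99)
  s3: median d' = 2.74  (CR rate 0.95)
```

i.e. the error-rich first session is uniformly early-stage, the
near-perfect second session is expert, and the proficient-but-imperfect
third session contributes a mixture, as its intermediate d′ implies.
`03_pipeline.R` then writes every stage's tables under `results/pipeline/`
and a consolidated `report.md`, which for this cohort contains:

```
## Activity onsets
- 80 (unit, stage, type) onset records, 78 with onset
- early CR: peak-time spread 165.0 +/- 103.1 ms
- expert CR: peak-time spread 62.2 +/- 50.2 ms
```

— the learning-related temporal compression of the activation sequence
(the simulator plants latency spreads of ≈170 ms early vs ≈57 ms expert,
and the onset pipeline recovers them), and

```
## Stimulus encoding
- selective fractions for 120 (stage, region, window) cells; max 100.0% (V1, early stage, 0 ms)
```

with early-stage selectivity confined to visual regions and expert-stage
selectivity spread across the network, as planted. `04_network_recovery.R`
reports the connectivity detector's calibration and ground-truth recovery:

```
null significance rate (95% rule): 0.083 on 300 pairs
planted 20-edge network: 21 called, 20 true -> precision 0.95, recall 1.00
```

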