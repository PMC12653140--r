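---
title: "Learning depressive-symptom networks by metabolic-syndrome status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning depressive-symptom networks by metabolic-syndrome status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phqnet)
```

## The question and the model

Depression is heterogeneous: the same questionnaire total can hide very
different symptom architectures. phqnet compares how the ten PHQ items (the
nine PHQ-9 symptoms plus the tenth functional-difficulty item) organise in
adults with major depressive disorder *with* versus *without* metabolic
syndrome (MetS), by learning a directed acyclic graph (DAG) over the items
in each group.

A DAG over items $X_1,\dots,X_p$ factorises the joint distribution as
$P(X_1,\dots,X_p)=\prod_j P(X_j \mid Pa_j)$. Structure is estimated by
score-based search: each candidate graph is scored with the decomposable
Bayesian Information Criterion

$$\mathrm{score}(G) = \sum_j \left[\log L(X_j \mid Pa_j) -
\frac{k_j}{2}\log n\right],$$

maximised here (equivalent to minimising the classic $-2\log L + k\log n$).
Two local-likelihood families are available:

* **`bic_gaussian`** (default): each item is regressed on its parents by
  least squares, with the MLE residual variance; $k_j = |Pa_j| + 2$. Ordinal
  0–3 items are treated as numeric — the conventional default of score-based
  learners on PHQ-type data, and the assumption the synthetic generator
  matches.
* **`bic_discrete`**: multinomial likelihood per parent configuration;
  $k_j = (r_j - 1)\,q_j$ with $q_j$ the product of the parents' observed
  level counts.

Search is plain hill-climbing from the empty graph over single-arc
additions, deletions and reversals that preserve acyclicity, accepting the
best move while it improves the score by more than `epsilon` (default 0,
strict inequality). There is no tabu list and no random restart by default
(`restarts = 0`); optional seeded restarts exist for exploration. Ties are
broken deterministically (add < delete < reverse, then lexicographic
(from, to)), so a dataset maps to exactly one output graph.

Because no single fit should be over-read, stability is assessed by a
nonparametric bootstrap: `bootstrap_networks()` relearns the graph on `R`
row-resamples, `edge_stability()` tallies how often each node pair appears
(in either orientation) and how often each orientation wins conditional on
presence, and `averaged_network()` retains pairs appearing in at least 85%
of replicates, oriented by majority direction (at least 50%). Arc strengths
for reporting are score deltas on the full data: the change in network score
caused by removing the arc, so supported arcs are negative and "stronger"
means more negative.

## Parameters that matter

| parameter | default | units / scale | why |
|---|---|---|---|
| `score_kind` | `bic_gaussian` | — | standard default on numeric 0–3 items; discrete scorer selectable |
| `epsilon` | 0 | score units | accept any strict improvement; BIC's penalty already guards complexity |
| `R` (bootstrap) | 5000 | replicates | reference analysis value; tests and examples use 100–200, which already stabilises tallies to ±0.05 |
| `strength_threshold` | 0.85 | fraction | retention rule for the averaged network |
| `direction_threshold` | 0.5 | fraction | majority orientation; exact 50/50 ties are oriented lexicographically and flagged |
| MetS thresholds | waist 102/88 cm, TG 150 mg/dL, HDL < 40/50 mg/dL, BP 130/80 mmHg, glucose 100 mg/dL | clinical units | the 3-of-5 rule as analysed; all inclusive except HDL (strict <). The diastolic cut-off of 80 (rather than the 85 of some guideline variants) is the one used in the analysed definition and is configurable via `mets_thresholds()` |

Cohort inclusion is deliberately strict: subjects must be on psychotropic
medication *and* carry ICD-10 code F32.9 or F33.9 (exact match on
normalised codes — no prefix matching, to avoid pulling in other F32/F33
subcodes) *and* have all ten PHQ items *and* a complete metabolic panel.
Incomplete records are excluded, not imputed.

Descriptive contrasts use the pooled-SD Cohen's d (the $(n-1)$-weighted
pooled standard deviation, no Hedges correction) and the pooled Student's t
(Welch optional, off by default); categorical contrasts use the uncorrected
Pearson chi-square and the odds ratio oriented as odds of female sex in the
MetS group. These conventions reproduce the published effect-size column
from the published group summaries, which is exactly what
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` verify. Two
published rows (fasting glucose and triglycerides) are not reproducible
from the printed group summaries under any standard pooling — they were
most plausibly computed on a fasting subsample with a different n — and are
therefore not asserted.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces tables shaped like the survey extract: one row
per participant with demographics, a metabolic panel, ten PHQ items, an MDD
ICD-10 code and the medication flag, plus a ground-truth `group` label.

* **Group structure.** Group sizes are fixed at `round(prevalence *
  n_total)` (default 315/1779). Metabolic values are drawn from each
  group's published mean/SD presets (`table1_presets()`), truncated at
  zero, and rejection-sampled so every MetS-group member meets ≥ 3 criteria
  and every comparison member ≤ 2. The classifier therefore recovers the
  generator's labels *exactly* — that round trip is the pipeline's
  strongest end-to-end check.
* **Symptoms.** Items are sampled from group-specific ground-truth DAGs —
  presets with the 11-arc (MetS) and 21-arc (non-MetS) published
  structures — as linear-Gaussian latents generated in topological order.
  Each child's noise variance is set to $1 - b^\top\Sigma_{Pa}b$ so all
  latents have unit marginal variance; for a single arc the latent
  correlation then equals its coefficient. Latents are discretised to 0–3
  at cutpoints $(-0.15, 0.75, 1.60)$, giving item means near 0.85, inside
  the 0.2–1.7 range typical of PHQ items in depressed cohorts. Default arc
  coefficients taper with the child's in-degree (0.65 / 0.5 / 0.33 for
  1 / 2 / ≥3 parents) purely so the standardisation stays feasible; they
  are arbitrary test magnitudes, not estimates.

Known departures from real data, all deliberate:

* **Class enforcement distorts marginals.** Conditioning each group on its
  criterion count selects MetS members towards criterion-exceeding values,
  so generated between-group contrasts are larger than the unconditional
  presets imply (the waist Cohen's d comes out near 0.7 rather than the
  preset 0.5). The generator guarantees labels and direction/scale of
  contrasts, not exact effect sizes.
* **No metabolic covariance.** Panel variables are drawn independently
  within groups (no copulas), and there is no survey design, weighting or
  missingness.
* **Published arc strengths are not targeted.** Strength values are
  data- and n-dependent; only the structures are preset.
* **Discretisation leakage.** Coarsening a latent mediator to four levels
  leaves residual partial correlation along two-step paths of order
  0.05–0.10 at the default coefficients — above BIC's detection threshold
  at $n = 5000$ (roughly $\sqrt{\log n / n} \approx 0.04$). A single
  full-data fit on generated ordinal items therefore adds several spurious
  arcs; bootstrap averaging at the 85% threshold removes most but not
  always all of them, so skeleton recovery lands at a structural Hamming
  distance of about 3–5 from the 11-arc truth at $n = 5000$, $R = 100$. On
  the *latent* continuous symptoms the same learner recovers the structure
  exactly, which locates the gap in the ordinal measurement model, not the
  search. The practical reading for real questionnaire data: treat
  thin high-stability edges between items that share a strong neighbour
  with caution.

## Numerical and design choices

* Gaussian local scores are computed from the dataset's MLE covariance
  matrix (one pass per dataset), making each local score a small solve that
  is independent of n — this is what keeps 100+ bootstrap relearns cheap.
  Collinear parent sets and zero residual variances are errors, and moves
  that would produce them are simply unavailable to the search.
* `exhaustive_best_dag()` enumerates every DAG on up to five nodes
  (1, 3, 25, 543, 29281 graphs) by parent-set recursion with acyclicity
  pruning; it exists as the exact oracle against which hill-climbing is
  validated (the greedy search attains the exhaustive optimum score on the
  large majority of random 4-node problems; being a heuristic it is not
  guaranteed to, and the tests allow isolated misses).
* Bootstrap replicates use per-replicate substream seeds drawn once from
  the master seed, so any replicate is reproducible in isolation and
  results do not depend on execution order. Unscorable resamples are
  retried (at most 3 times) and logged, never silently dropped.
* Degenerate inputs: a single-symptom analysis yields an empty graph and
  empty arc tables but a complete manifest; a direction tie at exactly 0.5
  is oriented lexicographically and flagged; a cyclic consensus (possible
  in principle when orientations are averaged) is an error that names the
  cycle.
* Problem sizes in the tests — bootstrap R of 8–200, recovery at
  $n = 5000$, $R = 100$ — were chosen as the smallest sizes at which the
  checked properties are stable; the reference analysis scale (R = 5000)
  remains the package default.

## Limitations

Cross-sectional DAGs support no causal claims; score-equivalent structures
(e.g. a two-node graph's two orientations) cannot be distinguished by the
Gaussian BIC, so orientation evidence comes only from bootstrap direction
frequencies; the Gaussian score on 0–3 items is an approximation whose
leakage behaviour is described above; and the descriptive table applies no
multiple-testing correction, mirroring the reference analysis.
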