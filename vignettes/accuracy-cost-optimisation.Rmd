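---
title: "Accuracy-cost optimisation of assessment items: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accuracy-cost optimisation of assessment items: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfaopt)
```

## The problem

Staging dementia severity in the clinic relies on batteries of cognitive and
functional assessment (CFA) items — individual questions from instruments such
as the MMSE, ADAS-Cog, FAQ, GDS and ECog. A full battery is accurate but can
take hours; a clinical consultation offers minutes. `cfaopt` treats item
selection as an explicit accuracy-versus-administration-time trade-off: it
searches for small item subsets that classify subjects into the three
severity groups — cognitively normal (CN), mild cognitive impairment (MCI)
and Alzheimer's disease (AD, with mild/moderate/severe amalgamated) — while
accounting for how many seconds each item takes to administer. Severity
ground truth is the Clinical Dementia Rating Sum-of-Boxes (CDR-SB, 0–18 in
0.5 steps), recoded to the three groups.

## The model

### CFS merit and its cost-sensitive extension

Correlation-based feature selection (CFS) scores a candidate subset $S$ of
$k$ items by the merit heuristic

$$\mathrm{Merit}(S) = \frac{k\,\overline{r_{cf}}}{\sqrt{k + k(k-1)\,\overline{r_{ff}}}},$$

where $\overline{r_{cf}}$ is the mean item–class association and
$\overline{r_{ff}}$ the mean pairwise association within $S$. Merit rewards
subsets whose items predict the class but do not duplicate one another; the
denominator grows with $k$, so small subsets are favoured. The cost-sensitive
extension subtracts a mean-time penalty,

$$\mathrm{Merit}_\lambda(S) = \mathrm{Merit}(S) - \lambda\,\frac{\sum_{i \in S} C_i}{k},$$

with $C_i$ the administration time of item $i$ in seconds and $\lambda \ge 0$
the cost weight. Costs enter raw (in seconds, not normalised): this is what
makes the working $\lambda$ range 0–0.05 meaningful against second-scale
times — at $\lambda = 0.01$ a 100-second difference in mean item time
outweighs a merit difference of 1. At $\lambda = 0$ the function is exactly
plain CFS. Items without a time estimate default to 1001 s, deliberately
high so that un-costed items are avoided once any cost pressure is applied.

Subsets are searched by forward best-first search: all singletons are scored
into an open list, the best open subset is repeatedly expanded by one item,
and the search stops after `max_stale = 5` consecutive expansions that fail
to improve the best score. The search is deterministic given the pool order
(ties resolve toward the earlier-generated, then lexicographically smaller
subset); `exhaustive_search()` provides a brute-force oracle on pools of at
most 20 items, used throughout the tests to confirm that best-first reaches
the global merit optimum.

### Association measures and the two cache modes

The class is categorical and items are mixed discrete/continuous, so the
item–class and item–item associations feeding merit need care:

* **`fselector` mode (default)** follows the toolbox convention the method
  was originally run with: mutual information (in nats, plug-in estimator)
  for discrete–discrete pairs and for everything involving the class, and
  absolute Pearson correlation for continuous–continuous pairs. Continuous
  vectors entering an MI computation are first discretized into 5
  equal-frequency bins.
* **`symmetrical_uncertainty` mode** is fully scale-consistent in the spirit
  of Hall's original CFS: every association, including continuous pairs, is
  symmetrical uncertainty $2\,\mathrm{MI}/(H_x + H_y) \in [0,1]$ computed on
  the (discretized) variables.

The distinction matters. In `fselector` mode, MI-scale class associations
(typically 0.2–0.4 nats here) sit on a different axis than Pearson-scale
item–item correlations (which reach 0.5 between items that both track
severity). The redundancy term then dominates the numerator and the merit
optimum systematically excludes some genuinely informative items whenever
many items share the severity signal — on the synthetic recovery benchmark
below, the `fselector`-mode optimum keeps only 5–6 of 8 planted informative
items, and this is a property of the heuristic's mixed scales, not of the
search (the exhaustive oracle agrees). The scale-consistent mode recovers
all 8. We therefore keep `fselector` as the faithful default for
reproducing the original analysis style, and use
`mode = "symmetrical_uncertainty"` wherever recovery of planted structure is
the goal; the recovery tests run in that mode.

The 5-bin equal-frequency discretization is the simplest deterministic
choice; MDL-based discretization is out of scope. MI uses natural
logarithms; the base cancels in all relative comparisons.

### Companion selectors

Two further multivariate selectors provide independent views of the data:

* **Consistency selection** scores a subset by $1 -$ the inconsistency rate:
  rows are grouped by their joint item-value pattern and every row outside
  its pattern's majority class counts as inconsistent. Adding items can only
  refine patterns, so the rate is monotone non-increasing; the best-first
  tie-break toward earlier-generated subsets therefore acts as a
  smallest-subset preference.
* **Boruta-style selection** wraps a random-forest importance measure: each
  iteration appends a shuffled "shadow" copy of every undecided item, and an
  item scores a *hit* when its importance beats the best shadow. After a
  5-iteration warm-up, hit counts are tested against Binomial($n$, 0.5) with
  two one-sided tails, Bonferroni-corrected over the undecided items;
  significant winners are confirmed, significant losers rejected, and the
  remainder stay tentative until the iteration cap (default 100). The
  importance backend is pluggable: the default is seeded `ranger`
  permutation importance with 500 trees; a fast bootstrap Kruskal–Wallis
  backend is provided for quick runs and unit tests.

### Accuracy: Hand–Till multiclass AUC under two CV schemes

Accuracy of an item set is the Hand–Till multiclass AUC of a seeded
500-tree probability forest: for each unordered class pair, the binary
rank-statistic AUC (midrank tie handling) is computed in both score
directions and averaged, and the three pairwise values are averaged again.
Probability estimates are vote fractions; AUC is invariant to monotone
transforms of each class's score column.

Two cross-validation orchestrations are implemented:

* `fs_fold_cv()` — the leakage-guarding scheme for comparing selectors: the
  selector sees exactly one fold; that fold is then excluded, and each
  remaining fold serves as test set with the other $k-2$ folds as training
  data. Reported per-fold AUC is the mean over the $k-1$ test folds.
* `standard_cv_auc()` — plain stratified $k$-fold for a fixed item set, used
  when pricing the subsets found in the $\lambda$ sweep.

Folds are stratified (the three-class mix is preserved per fold, fold sizes
differ by at most one) and seeded; plain random folds would risk a class
vanishing from a small fold, which the AUC cannot tolerate.

### The pipeline

`run_full_pipeline()` chains the stages: each selector is evaluated with
`fs_fold_cv()` (3 selectors × 5 folds = 15 selected sets), the sets are
pooled by `consensus_features()` (items selected at least twice enter the
pool), the pool is swept with cost-sensitive CFS over
$\lambda \in \{0, 0.0005, \ldots, 0.05\}$ (101 points; the grid range is the
published working range, and the step is fine enough to resolve set
transitions at second-scale costs), duplicate item sets are collapsed to the
smallest $\lambda$ producing them, every unique set is priced and scored,
and the Pareto front of (total time, AUC) is extracted. The whole run is
byte-reproducible from one master seed: all stage seeds derive from it.

## The synthetic generator

Because the original data source is access-restricted, every stage is
testable against `generate_assessment_data()`, which plants known structure:

* labels drawn from a 3-class mixture (default uniform);
* informative continuous items: class-conditional Gaussians with means
  $0, d, 2d$ and unit variance ($d$ = `effect_size`, default 1.2 — a strong,
  clinically plausible severity gradient);
* informative ordinal items: the same latent shift thresholded into 4
  equal-frequency levels, mirroring Likert-style CFA items (FAQ 0–3,
  GDS 0–1);
* redundant items: a parent plus Gaussian noise scaled to a target
  correlation (default 0.9), re-discretized for ordinal parents;
* noise items of both kinds, class-independent, split evenly;
* per-item costs drawn from the published time scale
  {28, 60, 200, 300, 600, 900} s, or fixed per role.

The default study condition is $n = 600$ subjects and 52 items
(5 + 3 informative, 4 redundant, 40 noise). What the generator does *not*
emulate: realistic marginal distributions of real assessment items, floor
and ceiling effects, item-level missingness, practice effects, and
longitudinal visit structure. Passing the recovery tests therefore shows
the machinery is correct and well-calibrated on mixtures of informative,
redundant and irrelevant items — not that selected item sets on real
clinical data would match published ones.

`duplicate_item_scenario()` is the targeted fixture for cost sensitivity: a
single informative signal exists only as two near-identical copies
(correlation ≥ 0.95), one cheap (60 s) and one expensive (900 s), and every
other item is priced at the cheap rate. That uniform pricing is deliberate:
the mean-cost penalty is then constant across equally priced subsets, so
plain-CFS behaviour is preserved and the only cost signal in the table is
the twins' 840 s difference. With heterogeneous costs everywhere, a
$\lambda$ of 0.01 (penalty ≈ 3–4 merit units at 300–400 s mean cost) would
swamp the merit landscape and the scenario would no longer isolate the
effect it is built to demonstrate.

## Numerical choices and degenerate inputs

* Best-first score comparisons use a $10^{-12}$ improvement epsilon; exact
  ties fall back to generation order, making permuted candidate pools reach
  equal best scores (possibly via different tied sets).
* Constant vectors: `discretize()` collapses to one bin with a warning;
  `pearson_abs()` returns 0 with a warning; SU returns 0 when both
  entropies vanish.
* Empty selections: `total_cost()` returns 0 with a warning; the sweep
  records a degenerate point rather than aborting (unreachable with the
  default search, which always retains the best singleton).
* CDR-SB recoding validates the 0.5-step grid and range and names the
  offending value; the default stage cut-offs (0 → CN; 0.5–4.0 → MCI;
  4.5–9.0, 9.5–15.5, 16–18 → mild/moderate/severe, amalgamated to AD) are
  configurable because published analyses differ in where they place them.
* `ranger` runs single-threaded with explicit seeds; this trades speed for
  bit-level reproducibility of every forest fit.

## Problem sizes used in the tests

The test-suite and the acceptance script run at the generator's default
study scale: recovery and twin-scenario checks across 10–20 generator seeds
at $n = 600$ with 52–54 items; search-oracle comparisons on 20 tables with
10-item pools (1023 subsets each); the full pipeline (3 selectors, 5 folds,
101-point grid, 500-tree forests) twice for the byte-reproducibility check,
which completes in well under a minute per run on one core.

## Known limitations

* The `fselector` association mode mixes measurement scales by design
  (fidelity to the original toolbox); use the SU mode when comparable
  scales matter, as the recovery analyses here do.
* The plug-in MI estimator is biased upward at small $n$; with 5 bins and
  $n \ge 600$ the bias (≈ $(B-1)(L-1)/2n$ nats) is negligible relative to
  the planted signals but would matter for very small tables.
* Boruta's binomial test treats iterations as independent; importance
  correlations across iterations make the test conservative rather than
  anti-conservative.
* The consistency selector discretizes continuous items before pattern
  matching; with many continuous items and few subjects, patterns become
  unique and the rate saturates at 0, carrying little signal.
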