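---
title: "Methods: multicriteria gap scoring of medical conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicriteria gap scoring of medical conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapscore)
```

## The problem and the model

Funding for biomedical product innovation does not always track unmet public
health need: decisions driven by single metrics such as mortality can
overlook disability, treatment cost, and health disparities. `gapscore`
integrates three domains of evidence about a set of medical conditions —
public health burden, health care cost, and biomedical product innovation
activity — into a single **overall gap score** per condition, and
rank-orders conditions so that those with low innovation activity relative
to high burden and cost surface as investment opportunities.

The integration engine is TOPSIS (Technique for Order of Preference by
Similarity to Ideal Solution). Given an alternatives-by-criteria decision
matrix $x_{ij}$ with direction flags $\delta_j$ and weights $w_j$:

1. **Normalize** each column. The default is vector (root-sum-square)
   normalization, $r_{ij} = x_{ij} / \sqrt{\sum_i x_{ij}^2}$ — the classic
   TOPSIS choice, which makes scores invariant to the units of each
   criterion. Min-max scaling is available as a configuration option for
   sensitivity analysis; under min-max, a constant column maps to 0.5
   (no information, neutral contribution).
2. **Weight**: $v_{ij} = \hat w_j r_{ij}$ with $\hat w_j = w_j / \sum_j w_j$,
   so only relative weight magnitudes matter.
3. **Reference points**: the *ideal* point $A^+$ takes, per criterion, the
   most favorable weighted value (the minimum for gap-increasing criteria
   such as burden and cost, the maximum for gap-decreasing criteria such as
   innovation activity); the *anti-ideal* $A^-$ takes the least favorable.
   $A^+$ is the theoretical condition with the lowest burden, lowest cost
   and highest innovation; $A^-$ the reverse.
4. **Separation and score**: with Euclidean separations
   $d_i^+ = \lVert v_i - A^+\rVert_2$ and $d_i^- = \lVert v_i - A^-\rVert_2$,
   the gap score is $G_i = d_i^+ / (d_i^+ + d_i^-) \in [0,1]$. We orient the
   score towards the **anti-ideal**, so a *high* score means a *large* gap
   (high burden/cost, low innovation). If every alternative is identical
   ($d_i^+ = d_i^- = 0$) all scores are 0.5 — the symmetric convention that
   avoids a division by zero and says "no alternative is distinguishable".

Key consequences, all verified by property tests against an independent
brute-force implementation: $G$ is unchanged by rescaling all weights, by
per-column unit changes (under vector normalization), and by permuting
alternatives or criteria; an alternative that is componentwise worst scores
exactly 1 and a componentwise best one exactly 0; flipping every direction
flag maps $G \mapsto 1 - G$ when reference points are unique.

## Domain scores and the overall gap

Each domain's score is itself a TOPSIS run on that domain's criteria:

* **Burden**: cross-sectional mortality, YLD and prevalence rates (per
  100 000) at the burden reference year (default 2019); their longitudinal
  trends over 2015–2019, entered as *relative* change because rates across
  metrics live on very different scales; and the disparity summary rate
  ratio (below). All gap-increasing.
* **Cost**: total, public and out-of-pocket spending (dollar totals) at the
  cost reference year (default 2016), plus *absolute* dollar changes over
  2012–2016. All gap-increasing.
* **Innovation**: 16 activity metrics in 6 categories (patents, federal
  investment, private investment, clinical trials, regulatory approvals,
  venture capital), each entered as its annual mean over 2015–2019. The
  domain score is oriented so *more activity scores higher* (diabetes-like
  conditions near 1, neglected conditions near 0); its complement, the
  innovation deficit $1 - s$, is available via `innovation_deficit()` for
  reporting.

The **overall gap** integrates the three domain scores. The architecture
was a genuinely open design choice and both variants are implemented:

* **Hierarchical** (default): a 3-criterion TOPSIS on
  $(S_{burden}, S_{cost}, S_{innov})$ with directions (increasing,
  increasing, decreasing) and equal domain weights of 1. This reads most
  naturally from a two-stage description — domain scores first, then the
  overall calculation — and makes the overall score depend on the domains
  only through their scores.
* **Flat**: one pooled matrix of all underlying metrics, with each domain's
  weight mass equalized (its metrics share the domain weight), so no domain
  dominates merely by having more metrics.

Applying standard-convention TOPSIS to a published table of domain scores
does not generally reproduce that table's printed overall scores — the
exact matrix contents and normalization behind published numbers are
typically not recoverable — so the package treats such tables as ingestible
worked examples (`rank_conditions()`, report-only mode) rather than
recomputable ones, and claims reproduction only of the arithmetic that *is*
determined: complements, maxima, ranking and tiering.

Ranks are assigned descending by $G$ with ties broken by condition name
(ascending) for determinism.

## The disparity summary rate ratio

For an adverse outcome stratified into groups (sex, age, race/ethnicity),
the most favorable group is the one with the minimum rate, and the ratio is
the mean rate of all other groups divided by the most favorable rate; for a
favorable outcome the reference is the maximum-rate group and the ratio is
inverted. Both orientations give a ratio $\ge 1$ that equals 1 exactly under
perfect equality and is invariant to rescaling all rates — so "twice the
rate" means the same disparity whether rates are per 1 000 or per 100 000.
We orient rather than follow a literal numerator/denominator reading
because a ratio below 1 would invert the disparity direction. Across
stratifications the *maximum* ratio is taken (the most unequal lens), and
the attaining stratification is reported; a pooled alternative would hide
which axis carries the inequality. Groups with absent or zero rates are
dropped from a stratification with a warning — a zero reference rate makes
the ratio undefined, and the caller is told rather than given an infinity.

## Tiering and opportunity identification

Scores are classified by their interquartile range: high above Q3, low
below Q1, middle otherwise. Quartiles use linearly interpolated order
statistics (`stats::quantile` type 7, the convention label `"linear"`;
Tukey hinges and nearest-order-statistic variants are selectable). Boundary
scores — exactly Q1 or Q3 — are *middle*: "high" and "low" are read
strictly, so the extreme tiers only contain scores strictly beyond the
quartiles. With fewer than 4 scores quartiles are unstable and tiering
refuses to run.

A condition is flagged as an **innovation opportunity** when its innovation
tier is low while its burden or cost tier is middle or high. Conditions
with both high cost and high innovation are *annotated* as the
high-cost/high-innovation paradox — spending growth may itself reflect
innovation uptake, so routing more innovation funding there may not address
the burden — but are deliberately not flagged by the opportunity rule.

## Configuration parameters

| parameter | default | meaning |
|---|---|---|
| `domain_weights` | 1, 1, 1 | relative domain influence (unitless; only ratios matter) |
| `within_domain_weights` | equal | per-metric weights inside a domain |
| `normalization` | `vector` | column normalization variant |
| `aggregation_mode` | `hierarchical` | overall-gap architecture |
| `missing_policy` | `zero` | `zero` (warn), `drop_criterion`, `mean_impute` |
| `quantile_convention` | `linear` | quartile method for tiering |
| `reference_years` | burden 2019 (trend 2015–2019), cost 2016 (trend 2012–2016), innovation 2015–2019 | per-domain years |
| `trend_form` | burden `relative`, cost `absolute` | scale on which trends enter |
| `display_digits` | 2 | rounding in the human-readable CSV only |

The `zero` missing policy keeps the decision matrix rectangular and mirrors
the situation where a source records no deaths for a condition; it is a
conservative "no signal" imputation for gap-increasing criteria. Criteria
with *no* data for any condition are dropped with a warning rather than
zero-filled, since an all-zero column is degenerate under vector
normalization. Full precision is kept throughout the computation; rounding
happens only at the display layer.

## The synthetic-data generator

Real inputs for this kind of study (burden rates, spending totals,
innovation counts) are positive and right-skewed, so the generator draws
each condition-metric level from a log-normal distribution, then evolves it
across years with a small multiplicative drift (log-slope, sd 0.03/year)
and year-to-year log-noise (sd 0.08). Innovation counts (patents, trials,
approvals, deals) are drawn Poisson around the log-normal level so they
stay integral; dollar metrics stay continuous. Stratified mortality rates
are emitted per sex, age and race/ethnicity group with the most favorable
group scaled down so that the disparity summary ratio concentrates around a
configurable between-group ratio (default 2, small log-noise sd 0.05).

A **planted gap** condition has all burden and cost level generators
shifted up, and all innovation generators down, by `effect_size` log-sd
units (default 4, a strong quartile separation), and its drift shifted in
the same planted direction so trend criteria align with the planted
structure. With `effect_size = 0` the shift vanishes entirely and all
conditions are exchangeable — the null case used to check that recovery
falls to chance (1/13). A **planted paradox** condition gets top cost *and*
top innovation generators, the diabetes-like case.

What the generator does *not* emulate: calibration to actual surveillance
magnitudes, autocorrelated shocks beyond linear drift, correlation between
domains (real high-burden conditions attract innovation), missingness
patterns, and measurement revision. Passing the planted-recovery tests
therefore shows the pipeline correctly propagates a strong, consistent
multi-domain signal to rank 1 — not that it would resolve the subtler,
correlated differences between real conditions.

## Validation problem sizes

The test and acceptance suites validate the engine against an independent
naive-loop TOPSIS implementation on 1 000 random matrices (up to 8
alternatives × 6 criteria, agreement to 1e−12), endpoint behavior on 500
constructed dominance matrices, invariances on randomized suites of 200,
disparity-ratio scale invariance on 1 000 random strata, and planted-gap
rank recovery on 200 pipeline replicates (with 200 null replicates checked
against the 99% binomial band around 1/13). These sizes give tight Monte
Carlo control while keeping a full run in the tens of seconds.

## Known limitations

* The overall-gap architecture behind any given published score table is
  generally underdetermined; both implemented modes are principled, but
  neither is claimed to replicate externally computed overall scores.
* The disparity ratio is computed on the strata as given; rates are assumed
  pre-standardized upstream, and no age-standardization is applied.
* ICD-10 code sets are carried as labels only; no validation against an
  official code list or mapping between classification systems is
  performed.
* The opportunity rule is tier-based and deliberately coarse; it flags
  misalignment, not root causes.
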