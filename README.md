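# gapscore

Multicriteria gap scoring of medical conditions: where does biomedical
product innovation lag behind public health need?

Health research funding is often steered by single metrics (usually
mortality) or by stakeholder consensus, which can overlook disability,
treatment cost, and health disparities. `gapscore` is for epidemiologists
and health-policy analysts who want a transparent, data-driven ranking: it
scores each medical condition on three domains — **public health burden**
(mortality, years lived with disability, prevalence, their 2015–2019
trends, and a disparity summary rate ratio), **health care cost** (total,
public and out-of-pocket spending and their 2012–2016 changes), and
**biomedical product innovation activity** (16 metrics across patents,
federal investment, private investment, clinical trials, regulatory
approvals and venture capital) — and integrates them into an **overall gap
score** per condition.

## The model

The engine is TOPSIS (Technique for Order of Preference by Similarity to
Ideal Solution). For a decision matrix `x_ij` (conditions × criteria) with
direction flags and weights `w_j`:

    r_ij = x_ij / sqrt(Σ_i x_ij²)          (vector normalization)
    v_ij = ŵ_j · r_ij,  ŵ_j = w_j / Σ w    (weighting)
    A⁺_j = most favorable v_ij per criterion;  A⁻_j = least favorable
    d_i⁺ = ‖v_i − A⁺‖₂,  d_i⁻ = ‖v_i − A⁻‖₂
    G_i  = d_i⁺ / (d_i⁺ + d_i⁻)            (gap score in [0, 1])

The ideal point `A⁺` is the theoretical condition with the lowest burden,
lowest cost and highest innovation; the anti-ideal `A⁻` the reverse. A
*high* `G_i` therefore means a *large* gap: heavy burden and cost with
relatively little innovation activity. Domains are weighted equally by
default. Conditions are ranked by `G`, classified into high/middle/low
tiers by the interquartile range of each score, and flagged as **innovation
opportunities** when the innovation tier is low while burden or cost is
middle or high. See the methods vignette
(`vignettes/gap-scoring-methods.Rmd`) for assumptions, conventions and
design choices.

## Worked example

The package ships the 13-condition pilot composite-score table as a worked
example. Report-only mode ingests the pre-computed domain and overall
scores and applies ranking, tiering and opportunity flagging:

```r
library(gapscore)
res <- rank_conditions(read_score_csv(pilot_scores_path()))
gap_report(res)
```

```
1. Diabetes mellitus: overall gap 0.61 (high); burden 0.46 (middle), cost 0.77 (high), innovation 0.77 (high); dominant domain: health care cost [high-cost/high-innovation paradox: cost growth may itself reflect innovation uptake]
2. Osteoarthritis: overall gap 0.46 (high); burden 0.47 (high), cost 0.41 (high), innovation 0.27 (middle); dominant domain: low biomedical product innovation
3. Drug use disorders: overall gap 0.39 (high); burden 0.48 (high), cost 0.26 (middle), innovation 0.22 (middle); dominant domain: low biomedical product innovation
...
6. Chronic kidney disease: overall gap 0.36 (middle); burden 0.32 (middle), cost 0.27 (middle), innovation 0.05 (low); dominant domain: low biomedical product innovation [innovation opportunity: low innovation activity relative to middle public health burden and middle health care cost]
...
13. Lower respiratory infections: overall gap 0.27 (low); burden 0.16 (low), cost 0.18 (low), innovation 0.18 (middle); dominant domain: low biomedical product innovation
```

Diabetes ranks first (overall gap 0.61), driven by the highest cost score
(0.77) — but since its innovation score is also the highest (0.77,
innovation deficit `1 − 0.77 = 0.23`), it is the paradox case: more
innovation funding alone may not close its gap. Chronic kidney disease,
COPD and cirrhosis carry the lowest innovation activity (deficits 0.95,
0.91 and 0.90) against mid-tier burden and cost, so they are flagged as
innovation opportunities.

A full run from raw long-format metrics, and a synthetic study with a
planted top-gap condition:

```r
gap_simulate("sim", spec_path = NULL)       # writes sim/metrics.csv
gap_run("sim/metrics.csv", "out")           # scores, ranks, tiers, flags
spec <- synthetic_spec(planted_gap = "cond_07", seed = 11)
planted_rank_recovery(spec, n_replicates = 200)$recovery
#> [1] 1
```

A thin command-line wrapper is installed at `inst/cli/gapscore.R`
(`run`, `simulate`, `report` subcommands; exit codes 0/2/3/4 for
success/validation/computation/I/O failure).

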