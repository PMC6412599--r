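# cdssaudit

Systematic auditing of a **black-box treatment-advice system** against an
**executable clinical guideline**. The package is for evaluators of clinical
decision support systems (CDSS) whose internal reasoning cannot be
inspected: the only way to characterize such a system is empirical
input–output testing against a trusted reference.

The harness, end to end:

1. **Encode the guideline** as a declarative decision tree
   (`guideline_ruleset()`, JSON on disk). A hard-coded oracle of the Dutch
   guideline for adjuvant treatment of resected stage I–III colon cancer
   (`dutch_advice()`) and an equivalent declarative tree (`dutch_tree()`)
   are shipped; the two routes are proven equivalent case-by-case in the
   test suite.
2. **Enumerate synthetic patient cases** from *decision points* — every
   patient, clinical or tumor characteristic that can change a
   recommendation (`default_plan()`, `enumerate_cases()`). Categorical
   points are tested at every value; continuous points at a purposive
   sample (age: 45/60/75). The default plan tests 11 points
   (3·4·3·2⁸ = 9216 cases full-factorial) and holds resection margin,
   perineural invasion and ECOG status constant at normal/absent. A
   `PATH_DEDUP` mode keeps one representative per distinct
   (guideline-advice, stage) signature.
3. **Obtain both advices per case.** Each source assigns every option of a
   treatment catalogue (default: observation, two fluoropyrimidine
   monotherapies, two oxaliplatin doublets, other systemic; 6 options) a
   category **R** (recommended), **C** (for consideration) or **NR** (not
   recommended). The advisor side is the `advise()` contract: a
   ruleset-backed mock with configurable perturbation probabilities
   (`ruleset_advisor()`, `perturbation_config()`) or replayed recordings of
   a real system (`recorded_advisor()`, `load_recorded()`).
4. **Score concordance** per option with a cross-tabulation matrix
   *M*(guideline, advisor) ∈ [−2, +2] (agreement = +2, R↔NR reversal = −2;
   `default_matrix()`, configurable via JSON) and sum to the overall case
   score in [−2k, +2k] — **−12..+12** for the default k = 6 catalogue
   (`score_case()`).
5. **Flag safety-relevant discordance**: a case is **RED** if the advisor
   *recommends* a chemotherapy the guideline marks not recommended,
   **ORANGE** if it only *suggests it for consideration*; red takes
   precedence (`assign_flag()`).
6. **Aggregate** by tumor stage: score min/median/max, per-stage score
   histograms, flag counts and integer percentages
   (`aggregate_results()`, `run_evaluation()`).

## Worked example

Audit a deliberately discordant mock advisor (40% chance of promoting an NR
option to C, 20% chance of demoting an R option to NR) over the
deduplicated recommendation paths of the Dutch tree:

```r
library(cdssaudit)
plan   <- default_plan(mode = "PATH_DEDUP")
cfg    <- perturbation_config(c("NR->C" = 0.4, "R->NR" = 0.2), seed = 42)
bundle <- run_evaluation(plan, advisor = ruleset_advisor(dutch_tree(), cfg))
bundle$results[, c("case_id", "stage", "overall_score", "flag")]
#>   case_id stage overall_score   flag
#> 1    0001     I             9 ORANGE
#> 2    0257   III             2 ORANGE
#> 3    0261   III            -2 ORANGE
#> 4    0269   III            12   NONE
#> 5    1537    II             8 NONE
#> 6    1541    II             2 ORANGE
bundle$summary$flag_percent
#>    RED ORANGE   NONE
#>      0     67     33
```

Six cases cover the six (advice, stage) recommendation paths. Case `0001`
is a stage I patient for whom all chemotherapy is NR; the perturbed advisor
suggested CAPOX for consideration, which costs one matrix point per
affected option (overall 9 instead of the perfect 12) and earns an orange
flag — the advisor floated a chemotherapy the guideline prohibits, but did
not outright recommend it (that would be red). Its analysis table:

```r
case <- bundle$cases[1, , drop = FALSE]
g <- dutch_advice(case); a <- advise(ruleset_advisor(dutch_tree(), cfg), case)
render_case_table(case, g, a, score_case(g, a)$per_option_scores)
#>                                   option guideline advisor score comment
#> 1      Observation (no adjuvant therapy)         R       R     2
#> 2               Capecitabine monotherapy        NR      NR     2
#> 3            5-FU/leucovorin monotherapy        NR      NR     2
#> 4     CAPOX (capecitabine + oxaliplatin)        NR       C    -1
#> 5 FOLFOX (5-FU/leucovorin + oxaliplatin)        NR      NR     2
#> 6                 Other systemic regimen        NR      NR     2
```

With the identity advisor (no perturbation) every case scores +12 with no
flags — the harness's internal consistency law.

## Command line

A wrapper is installed under `system.file("cli", "cdssaudit.R")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","cdssaudit.R",package="cdssaudit"))')" \
  run --shift 'NR->C=0.4,R->NR=0.2' --seed 42 --mode PATH_DEDUP --out audit_out
```

Subcommands `generate`, `advise`, `score`, `report` expose the individual
stages; all stage artifacts are plain CSV/JSON and round-trip through the
package loaders.

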