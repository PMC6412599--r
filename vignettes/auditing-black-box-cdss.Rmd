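---
title: "Auditing a black-box treatment advisor against an executable guideline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a black-box treatment advisor against an executable guideline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdssaudit)
```

## The evaluation model

A black-box clinical decision support system (CDSS) cannot be audited by
reading its rules, only by probing its input–output behavior. The model
implemented here treats the audit as a three-part experiment:

1. a **reference**: guideline logic encoded as an executable decision tree
   mapping a patient case to a total advice — one category in
   {R, C, NR} (recommended / for consideration / not recommended) for each
   option of a fixed treatment catalogue;
2. a **probe set**: synthetic patient cases enumerated from the *decision
   points*, the characteristics that can change a recommendation, so that
   every recommendation path of the reference is exercised;
3. a **comparison statistic**: per-option cross-tabulation scores summed to
   an overall case concordance score, plus a categorical safety flag.

Binary agree/disagree is too coarse for treatment advice: "the advisor
suggests considering a treatment the guideline recommends" and "the advisor
recommends a prohibited treatment" are both disagreements of very different
gravity. The cross-tabulation matrix $M(g, a) \in \{-2,\dots,+2\}$ grades
this, and the case score $\sum_{o \in \mathrm{catalogue}} M(g_o, a_o)$
ranges over $[-2k, +2k]$ — $-12..+12$ for the default $k = 6$ catalogue.

## The clinical reference: Dutch adjuvant colon-cancer logic

The shipped reference covers adjuvant treatment after curative-intent
resection of stage I–III colon cancer. Stage is the standard TNM grouping
(node-positive = III; T1–2N0 = I; T3–4N0 = II). The encoded logic:

* **Stage I** and **low-risk stage II**: favourable prognosis, observation
  only; all chemotherapy NR.
* **High-risk stage II** — any of pT4, fewer than 10 examined nodes,
  poor/undifferentiated histology, (extramural) vascular invasion,
  obstruction/perforation: an oxaliplatin doublet (CAPOX/FOLFOX) *may be
  considered* provided the tumor is MSS and oxaliplatin is not
  contraindicated. Encoded as OBSERVATION = R with doublets = C:
  observation remains fully acceptable while chemotherapy is optional.
* **Stage III**: doublets are the regimen of choice (R). Under oxaliplatin
  contraindication, fluoropyrimidine monotherapy if MSS; if MSI,
  chemotherapy is not indicated (MSI tumors derive no benefit from
  fluoropyrimidine monotherapy).

Two encoding decisions were genuinely open and are resolved as follows.
First, the source logic states the MSI prohibition only for monotherapy, so
**stage III MSI without contraindication still receives doublet = R**; a
stricter reading would route these patients to observation, and users can
express that by editing the tree JSON. Second, **age and ECOG status are
carried on every case but never branch the tree** — the reference guideline
trees do not condition on them — so their effect on a real advisor is
exactly what the audit can reveal.

The reference exists twice on purpose: a hard-coded oracle
(`dutch_advice()`) and a declarative tree (`dutch_tree()`, shipped as
JSON). The test suite proves the two agree option-by-option on all 9216
enumerated cases, which is the package's defence against transcription
errors in either route.

## Decision points and the synthetic case space

The default plan (`default_plan()`) tests:

| point | values | rationale |
|---|---|---|
| age | 45, 60, 75 years | purposive sample: young / average / older |
| pT stage | T1–T4 | all values |
| pN stage | N0–N2 | all values |
| nodes examined | <10 / ≥10 | dichotomized to fit advisor interfaces |
| differentiation | well–moderate / poor–undifferentiated | two levels |
| vascular invasion | absent / present | collapsed to one boolean |
| obstruction/perforation | absent / present | |
| MSI status | MSS / MSI | |
| oxaliplatin contraindication | no / yes | guideline-only point |
| serious liver disease | absent / present | advisor-only point |
| serious kidney disease | absent / present | advisor-only point |

Held constant at normal/absent: resection margin (negative), perineural
invasion (absent), ECOG functional status (0). The guideline attribution
has 9 points and the advisor's minimum variable set 13; they share 8, so
the union holds 14 unique decision points and 5 are advisor-only (the two
tested comorbidities plus the three constants). This membership is
reconstructed to be uniquely consistent with those printed counts, with
oxaliplatin contraindication taken as the one guideline-only point; it is a
recorded assumption, and the plan file is user-editable JSON.

Full-factorial enumeration gives $3 \cdot 4 \cdot 3 \cdot 2^8 = 9216$
cases in deterministic lexicographic order with zero-padded ordinal ids
(reproducible diffs). The historical feasibility study worked from a
manually pruned 190-case set whose pruning rule is not recorded; that set
is therefore *not* reconstructable, and the package instead offers
`PATH_DEDUP`, which keeps the lexicographically first case per distinct
(guideline-advice, stage) signature — the minimal probe set with identical
advice-signature coverage.

## What the mock advisor emulates — and what it does not

`ruleset_advisor()` with a `perturbation_config()` emulates *a* discordant
black box: each option's backing category shifts to another category with
configured probability, independently per option, using a stream keyed by
`(seed, case_id, option)` (FNV-1a hash feeding R's RNG, ambient RNG state
preserved). Keying by content rather than call order means case order,
repetition and parallel evaluation cannot change outcomes.

This generator emulates *marginal* discordance rates only. Real advisors
disagree *systematically* — e.g. along guideline-version or
country-of-origin lines — with correlations across options and cases that
independent per-option shifts cannot produce. A green identity-law or
rate-recovery test therefore establishes that the harness measures
correctly, **not** that any real advisor is concordant; auditing a real
system requires its recorded advice (`load_recorded()`).

## Scoring, flags, and numerical conventions

* **Default matrix** (guideline × advisor): diagonal +2; (R,C) and (C,R)
  +1; (C,NR) and (NR,C) −1; (R,NR) and (NR,R) −2. The source protocol
  prints only the range endpoints, so the ±1 cells are this package's
  choice, guided by the principle that *suggesting* a contraindicated
  treatment for consideration is a less serious error than *recommending*
  it. The matrix is a config file (`read_score_matrix()`); published
  alternatives drop in without code change. Construction enforces the
  invariants (diagonal +2, R/NR reversals −2, all cells in [−2, 2]), and
  the diagonal being each row's strict maximum yields the degradation-
  monotonicity law tested in the suite.
* **Flags** consider chemotherapy options only (observation exempt): the
  safety question is whether the advisor endorses chemotherapy the
  guideline marks not indicated. RED = advisor R on a guideline-NR
  chemotherapy; ORANGE = advisor C; red strictly precedes orange.
* **Median** of an even count is the *lower* middle value; the convention
  is emitted in the summary metadata since downstream spreadsheets differ.
* **Percentages** are rounded to integer percent (hence they sum to
  100 ± 1), matching how such audits are conventionally reported.
* **Advice totality**: options absent from any advice listing are coerced
  to NR at construction and at file load. Without totality the fixed score
  range (and hence cross-study comparability) collapses.
* **Degenerate inputs**: empty case sets aggregate to zero counts with NA
  medians; a case value matching no tree edge is a *ruleset defect* error,
  which `validate_ruleset()` (disjointness, completeness, acyclicity,
  reachability checks, defects returned as a data.frame) makes unreachable
  for validated trees; `run_evaluation()` refuses defective rulesets up
  front.

## Known limitations

* The shipped NCCN-style ruleset file is a synthetic editable *template*
  (marked as such), not a transcription of any published NCCN table.
* Decision nodes branch only on finite-domain fields; a tree cannot branch
  on raw age — by design, matching the reference trees, but a limitation
  if a future guideline encodes age cut-offs (add a categorical
  age-band field in that event).
* Concordance scoring is symmetric in gravity but silent on *direction*:
  it does not judge whether a discordant advisor is clinically better or
  worse than the guideline. That judgment is explicitly out of scope.

## Reproducing the checks

```{r, eval = FALSE}
# identity law: perfect concordance when advisor == guideline
bundle <- run_evaluation(default_plan(mode = "PATH_DEDUP"))
stopifnot(all(bundle$results$overall_score == 12),
          all(bundle$results$flag == "NONE"))

# oracle equivalence, enumeration cardinality, rate recovery, flag laws:
# see tests/testthat/test-acceptance.R
```
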