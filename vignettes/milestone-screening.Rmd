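---
title: "Milestone-based screening for early language development: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Milestone-based screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langscreen)
```

## The screening problem

Language acquisition shows its largest inter-individual variability in the
first four years of life, which makes developmental language disorder (DLD)
and simple language delay (SLD) hard to distinguish from ordinary variation
at preschool ages — precisely the ages at which intervention is most
effective. Milestone-based screening addresses this by asking an observer
(typically a preschool teacher, not a language specialist) whether a child
performs concrete, age-indexed behaviours, and by converting the answers into
a graded, actionable suggestion: typical development, a repeat assessment in
1–3 months, or direct referral to an early-intervention centre. The tool
screens; it does not diagnose, and it does not attempt to separate DLD from
SLD.

`langscreen` implements this pipeline end to end: a knowledge-base model, an
age-adaptive screening engine, a cohort simulator, the evaluation statistics
of a screening field study, and that study's printed summary tables as a
packaged fixture.

## The knowledge base

The screening content is a small graph: **month nodes** (ages in completed
months) link to **questions**, and questions link — through their severity
class — to **suggestions**. Each question belongs to exactly one of four
language domains (sensory reception, language perception, production,
pragmatics), applies to one or more months, and is either a *warning* item
(failure prompts re-evaluation) or an *alarm* item (failure prompts
referral). Structural rules enforced by `validate_kb()`:

* every covered month carries 3–6 questions (the expert panel's rule for an
  adequate per-month measure);
* per-domain question counts equal declared quotas — the default quotas
  3/32/48/25 total 108 questions;
* sensory-reception items are confined to months 1–12, where their purpose
  is ruling out hearing problems.

The deployed knowledge base treats "questions" as the atomic unit. The
screening content is described in its source as roughly one hundred
milestones alongside a slightly larger question count; since the mapping
between the two is not published, this package makes the 108 questions
atomic and leaves milestone grouping to optional metadata. The question
texts of the real knowledge base are likewise unpublished, so the package
ships a schema, a generator (`gen_kb()`), and a hand-written toy file —
synthetic content with **no clinical validity**.

Coverage defaults to months 1–36 (the focus age range of the field study;
the historical knowledge base spans 1–72 and the range is configurable).
Question order within a month is file order; no ordering is specified by
the screening protocol, so none is imposed.

`export_graph()` emits the month→question→suggestion structure as
Cypher-style `CREATE` statements for loading into a graph database. Each
question links to the suggestion its *isolated* failure produces (alarm →
referral, warning → 3-month repeat), which keeps the export a pure function
of the knowledge base.

## The decision rule

`decide()` applies a two-layer rule to a completed session:

1. any alarm-class question answered "no" → `refer_early_intervention`;
2. otherwise the count *w* of warning-class "no" answers selects a rung of a
   repeat ladder: *w* = 0 → typical development, *w* = 1 → repeat in 3
   months, *w* = 2 → repeat in 2 months, *w* ≥ 3 → repeat in 1 month.

The three repeat intervals are fixed screening outcomes, but the mapping
from failure count to interval is not dictated by the protocol; the ladder
above is this package's default — graded follow-up intensity, more failures
meaning a sooner recheck — and it is a pluggable `decision_policy()`, so a
deployment that assigns intervals per-item rather than per-count can encode
that instead. The policy in force travels with the output.

**"Do not know" answers.** By default `dk` answers never count as failures:
a missing observation should not escalate a child's suggestion. A session
answered entirely with `dk` therefore returns typical development, but is
flagged `low_information` so a consumer can treat it as uninformative
rather than reassuring. `decision_policy(dk_as_no = TRUE)` switches to the
conservative reading.

**Control data.** Gestational age, birth complications, family history and
bilingual context are collected as a baseline, carried into reports and
stratified statistics, but do not modify the decision rule: no published
rule links them to the suggestion, and silently adjusting thresholds on
their basis would make the tool's behaviour unauditable. A gestational age
below 37 weeks does imply the preterm flag on the profile.

**Ages** are completed calendar months (floor, incrementing on monthly
anniversaries). Month arithmetic clamps to month ends (Jan 31 + 1 month =
Feb 28/29). A session is valid only when the child's age lies inside the
knowledge base's coverage.

**Re-asking.** A follow-up form contains the child's current month node
plus any question failed in the *immediately previous* session that is
still within its applicable-months window. Carrying the full failure
history forward would let early misses shadow a child indefinitely; one
session of memory matches the observed behaviour of repeated questions
across consecutive assessments.

## The cohort simulator

No child-level data from the field study are available, so every
record-level computation is exercised against synthetic cohorts.

**Demographics are assigned, not sampled.** The default
`cohort_config()` reproduces the study cohort exactly: 218 children, 134 in
the nursery school and 84 in the psychopedagogical centre, 99 girls and 119
boys, with the centre-by-gender-by-age-band cells of the packaged cohort
table (band totals 26 / 102 / 90; where the table's printed band header
disagrees with its own cells, the cells — which are consistent with the
total of 218 — are used). Exact counts also govern the rarer labels: 8
preterm children, 13 with some birth complication, 2 with a family history
of neurodevelopmental disorder, 10 bilingual children confined to the
nursery school (the only centre where bilingual context was recorded).
Randomness is confined to which child receives which label, ages within
bands, and the latent variables. Scaling `n_children` rescales cells and
label counts proportionally (largest remainder).

**The answer model** is a logistic item-response-style rule. Child *i*
evaluated at age *t* answers question *q* "yes" with probability

$$P(\text{yes}) = \operatorname{logit}^{-1}\!\big(b_0 + a\,(t - m_q) + \theta_i - \delta\,Z_i\big),$$

where $m_q$ is the question's first applicable month, $\theta_i \sim N(0,1)$
is latent ability, $Z_i \sim \text{Bernoulli}(p_{\text{imp}})$ is a latent
impairment label with deficit $\delta > 0$, and each answer is masked to
`dk` with probability `dk_rate`. Defaults: slope $a = 5$ per month, shift
$\delta = 10$, intercept $b_0 = 6$, `dk_rate` 0.05, $p_{\text{imp}} = 0.10$
(the share of preschool children expected to show language-acquisition
difficulty, most of which resolves as SLD).

The intercept deserves a note. Screening milestones are chosen so that a
typically developing child has, with high probability, already attained
them by the first month they are asked; $b_0 = 6$ encodes that (≈ 99.8%
attainment at $\theta = 0$, and about 98% per session after integrating
over $\theta$). Without an intercept, a median typical child would fail
half of all home-month items, and the simulator could not exhibit the basic
property that an unimpaired cohort screens overwhelmingly typical.
$a > 0$ makes attainment strictly increase with age; with $\delta = 10$ the
impaired group fails essentially every item within its window, so the
flagged (alarm + warning) prevalence among latest assessments is a
consistent estimator of $p_{\text{imp}}$ — the package's parameter-recovery
check runs at $a = 5$, $\delta = 10$, $p_{\text{imp}} = 0.2$, $n = 2000$,
three seeds, within three binomial standard errors.

**Follow-up** is capped at two sessions per child, echoing the observed
mean of 1.24 assessments per child without modelling calendar constraints.
Evaluator concordance is drawn per suggestion type; the default decline
probabilities (5/50 for referrals, 2/31 for 2-month repeats, zero
otherwise) are calibrated to the study's acceptance table.

**What the simulator does not emulate.** Item-level psychometrics (no
per-question difficulty or discrimination beyond the home-month offset);
evaluator behaviour beyond per-type decline rates; calendar effects; and —
notably — the *within-class relative-age* effect: because questions are
age-matched to the month, birth quarters are exchangeable in simulation,
whereas the field study observed poorer results for the youngest children
of each class year. The birth-quarter test therefore checks only that the
oldest quarter is not flagged more than the youngest beyond binomial noise.
Passing tests demonstrate the pipeline's correctness under the stated
model, not clinical validity on real children.

## The packaged study tables and record reconstruction

The study's printed summary tables are packaged as CSV (with an MD5
manifest and load-time consistency checks that tie the tables to each
other: suggestions sum to 218 children, the gender table's alarms equal the
43 referrals, the alarm table's cells sum to its centre totals 18 and 25,
the acceptance table sums to 270 assessments with 7 declines).

`reconstruct_records()` expands those marginals into a 270-row synthetic
record set: the 43 referred children are fully pinned (centre, gender,
month) by the alarm table; the remaining children fill the cohort cells,
with warning types split across genders by largest remainder against the
final-suggestion totals; the 52 non-final assessments are assigned at
earlier dates to children with non-typical final rows first; and the seven
recorded declines attach to sessions matching the reported suggestion,
gender and month where possible. Unpinned cells (dates, identities, ages
within bands) are filled deterministically under a seed — the output is
reproducible, *synthetic*, and faithful only in its marginals. Answers
consistent with each suggestion are synthesized against a generated
knowledge base so answer-level statistics run end to end.

## Statistics and conventions

* `latest_per_child()` keeps each child's maximal evaluation date —
  the convention for all child-level outcome tables.
* Percentages in stratified tables use the full record count as base and
  one decimal; concordance uses two decimals; sample sizes round up. Raw
  fractions are always emitted alongside, since printed tables mix
  conventions.
* Every stratified table conserves its grand total; this is asserted in the
  test suite across groupings.
* `sample_size()` implements $n_0 = z^2 p (1-p) / e^2$ with the finite
  population correction $n = n_0 / (1 + (n_0 - 1)/N)$; the correction never
  increases $n$, and $n \to n_0$ as $N \to \infty$. At $N = 150{,}000$,
  $p = 0.07$, $z = 1.96$, $e = 0.05$ it returns 100.
* Degenerate inputs: empty record sets yield empty distributions;
  concordance and assessments-per-child on empty sets signal an error
  rather than returning `NaN`.

## Problem sizes

The shipped tests run the decision-rule enumeration over all $3^k$ answer
vectors for $k \le 4$; knowledge-base properties over several generator
configurations; simulator recovery at $n = 2000$ children × 3 seeds; and the
birth-quarter and monotonicity checks at $n = 400{-}600$. These sizes were
chosen so the full suite completes in well under a minute while keeping
binomial noise far below the tested tolerances.

## Known limitations

* Synthetic knowledge bases carry placeholder text; no clinical content.
* The answer model's slope, shift and intercept cannot be calibrated to
  real response data (none are published); they are exposed parameters, not
  empirical claims.
* The reconstructed record set is one maximum-agreement completion of the
  printed tables, not the study data; statistics outside the encoded
  marginals (e.g. control-information cross-tabulations) will not match the
  study.
* Per-grade concordance rates and a handful of in-text ratios whose
  denominators are not derivable from any printed table are deliberately
  not encoded.
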