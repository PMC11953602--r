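# langscreen

Milestone-based screening of language development for children aged 1–36
months, aimed at clinical-decision-support developers and researchers in
early-childhood language surveillance. The package lets a non-specialist
observer's yes/no/don't-know answers to age-indexed milestone questions be
turned into a graded, auditable suggestion — typical development, repeat
the assessment within 1–3 months, or refer to an early-intervention centre
— and provides everything needed to study such a screener quantitatively:
a validated knowledge-base model, a cohort simulator, and the summary
statistics of a real screening field study.

## The model

The screening content is a graph of **month nodes → questions →
suggestions**. Each question belongs to one of four language domains
(sensory reception, language perception, production, pragmatics; default
domain quotas 3/32/48/25 = 108 questions), applies to one or more months
(3–6 questions per covered month), and is a *warning* or an *alarm* item.
For a completed session the decision rule is:

- any alarm-class "no"  →  `refer_early_intervention`;
- otherwise, with *w* warning-class "no" answers:
  *w* = 0 → `typical_development`, *w* = 1 → `repeat_3mo`,
  *w* = 2 → `repeat_2mo`, *w* ≥ 3 → `repeat_1mo`.

"Don't know" never escalates by default. Follow-up forms re-ask the
previous session's failed questions while they remain age-applicable.

The simulator draws answers from a logistic item-response-style model,
`P(yes) = plogis(b0 + a (t − m_q) + θ_i − δ Z_i)`, with latent ability
`θ_i ~ N(0,1)` and impairment label `Z_i ~ Bernoulli(p_imp)`; the
evaluation layer includes the finite-population sample-size formula
`n = n0 / (1 + (n0 − 1)/N)`, `n0 = z² p (1 − p) / e²`.

See `vignettes/milestone-screening.Rmd` for the full methods account.

## Worked example

Screen one 14-month-old child against the packaged toy knowledge base:

```r
library(langscreen)
kb <- load_kb(system.file("extdata", "toy-kb.json", package = "langscreen"))
child <- child_profile("k0142", birth_date = "2022-03-10", gender = "male",
                       center = "nursery_school", gestational_weeks = 39)
ses <- screening_session(child, kb, evaluation_date = "2023-05-15")
ses$asked
#> [1] "q1" "q2" "q3"
ses <- answer_session(ses, c(q1 = "no", q2 = "no", q3 = "yes"))
decide(kb, ses)
#> <suggestion_result> repeat_2mo (severity: warning)
#>   triggered by: q1, q2
```

Two warning-class failures land on the middle rung of the repeat ladder:
re-assess within 2 months (the report, via `render_report()`, prints the
follow-up date 2023-07-15). No alarm item failed, so no referral.

Reproduce the field study's outcome table from the packaged summary tables:

```r
rec <- reconstruct_records(load_fixture(), seed = 1)
suggestion_distribution(latest_per_child(rec))
#>                 suggestion   n  pct       frac
#> 1      typical_development 117 53.7 0.53669725
#> 2               repeat_3mo  28 12.8 0.12844037
#> 3               repeat_2mo  19  8.7 0.08715596
#> 4               repeat_1mo  11  5.0 0.05045872
#> 5 refer_early_intervention  43 19.7 0.19724771
accuracy(rec)$pct
#> [1] 97.41
sample_size(150000, 0.07, 1.96, 0.05)
#> [1] 100
```

Of 218 children (latest assessment each), 53.7% screened typical and 19.7%
were referred; evaluators accepted 263 of 270 suggestions (97.41%
concordance); and the study's enrolment target under the finite-population
correction is 100 participants.

A command-line interface wraps the same functions
(`inst/scripts/langscreen`): subcommands `kb`, `screen`, `simulate`,
`evaluate`, `report`, `fixtures`; exit codes 0/1/2 for success / data
error / usage error.

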