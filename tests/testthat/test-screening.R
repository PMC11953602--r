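test_that("age in completed months floors at monthly anniversaries", {
  expect_equal(age_in_months("2021-03-10", "2021-10-10"), 7L)
  expect_equal(age_in_months("2021-03-11", "2021-10-10"), 6L)
  expect_equal(age_in_months("2021-03-10", "2021-03-10"), 0L)
  expect_equal(age_in_months("2021-01-31", "2021-02-28"), 0L)
  expect_equal(age_in_months("2021-01-31", "2021-03-01"), 1L)
  expect_error(age_in_months("2021-10-10", "2021-03-10"), "precedes")
})

test_that("question selection covers the age's month node and re-asks recent failures", {
  kb <- load_kb(system.file("extdata", "toy-kb.json", package = "langscreen"))
  eval14 <- as.Date("2023-05-15")
  child <- toy_child(14, eval14)
  expect_equal(select_questions(kb, child, eval14), c("q1", "q2", "q3"))

  # q3 (applicable months 14 and 15) failed at 14 -> re-asked at 15;
  # q1 (only month 14) failed too but its window has passed
  s14 <- screening_session(child, kb, eval14)
  s14 <- answer_session(s14, c(q1 = "no", q2 = "yes", q3 = "no"))
  eval15 <- month_add_t(eval14, 1)
  sel <- select_questions(kb, child, eval15, history = list(s14))
  expect_equal(sel, c("q3", "q4", "q5", "q6"))

  # clean history: just the month node
  s14b <- answer_session(screening_session(child, kb, eval14),
                         c(q1 = "yes", q2 = "yes", q3 = "yes"))
  expect_equal(select_questions(kb, child, eval15, history = list(s14b)),
               c("q3", "q4", "q5", "q6"))
  expect_error(select_questions(kb, child, as.Date("2030-01-01")),
               "outside the coverage range")
})

test_that("decision rules map alarm failures to referral and warning counts to the ladder", {
  kb <- toy_kb_single_month(c("warning", "warning", "warning", "alarm"), month = 10)
  ids <- names(kb$questions)
  ans <- function(...) stats::setNames(c(...), ids)

  expect_equal(run_decision(kb, ans("yes", "yes", "yes", "yes"), 10)$type,
               "typical_development")
  expect_equal(run_decision(kb, ans("yes", "yes", "yes", "no"), 10)$type,
               "refer_early_intervention")
  expect_equal(run_decision(kb, ans("no", "yes", "yes", "yes"), 10)$type,
               "repeat_3mo")
  expect_equal(run_decision(kb, ans("no", "no", "yes", "yes"), 10)$type,
               "repeat_2mo")
  expect_equal(run_decision(kb, ans("no", "no", "no", "yes"), 10)$type,
               "repeat_1mo")
  # dk never escalates under the default policy, and an all-dk session is
  # flagged low-information
  expect_equal(run_decision(kb, ans("dk", "dk", "dk", "dk"), 10)$type,
               "typical_development")
  expect_true(run_decision(kb, ans("dk", "dk", "dk", "dk"), 10)$low_information)
  # ... but counts as failure when the policy says so
  strict <- decision_policy(dk_as_no = TRUE)
  expect_equal(run_decision(kb, ans("dk", "dk", "dk", "dk"), 10, strict)$type,
               "refer_early_intervention")
})

test_that("decide matches the brute-force rule table on every 3^k answer vector (k <= 4)", {
  severity_sets <- list(
    c("warning", "warning", "warning"),
    c("warning", "warning", "alarm"),
    c("alarm", "alarm", "warning"),
    c("warning", "warning", "warning", "warning"),
    c("warning", "alarm", "warning", "alarm"))
  for (sev in severity_sets) {
    kb <- toy_kb_single_month(sev, month = 12)
    ids <- names(kb$questions)
    for (vec in all_answer_vectors(length(sev))) {
      got <- run_decision(kb, stats::setNames(vec, ids), 12)
      expect_equal(got$type, oracle_decide(vec, sev),
                   info = paste(sev, collapse = ","))
      expect_equal(got$severity_class, suggestion_severity(got$type))
      expect_setequal(got$triggered_by, ids[vec == "no"])
    }
  }
})

test_that("flipping a 'no' to 'yes' never increases suggestion severity", {
  kb <- gen_kb(kb_gen_config(seed = 3))
  withr::with_seed(99, {
    for (rep in 1:40) {
      m <- sample(1:36, 1)
      ids <- vapply(questions_for_month(kb, m), `[[`, "", "id")
      ans <- sample(answer_levels(), length(ids), replace = TRUE)
      names(ans) <- ids
      base <- run_decision(kb, ans, m)
      for (j in which(ans == "no")) {
        improved <- ans
        improved[j] <- "yes"
        res <- run_decision(kb, improved, m)
        expect_lte(suggestion_rank(res$type), suggestion_rank(base$type))
      }
    }
  })
})

test_that("decide is deterministic and rejects incomplete sessions", {
  kb <- toy_kb_single_month(c("warning", "warning", "alarm"))
  ids <- names(kb$questions)
  ans <- stats::setNames(c("no", "yes", "yes"), ids)
  r1 <- run_decision(kb, ans, 10)
  r2 <- run_decision(kb, ans, 10)
  expect_identical(r1, r2)
  ses <- screening_session(toy_child(10), kb, as.Date("2023-05-15"))
  ses <- answer_session(ses, ans[1:2])
  expect_error(decide(kb, ses), "incomplete")
})

test_that("evaluator response requires a reason for declines", {
  kb <- toy_kb_single_month(c("warning", "warning", "warning"))
  ids <- names(kb$questions)
  ses <- screening_session(toy_child(10), kb, as.Date("2023-05-15"))
  ses <- answer_session(ses, stats::setNames(rep("yes", 3), ids))
  expect_error(record_evaluator_response(ses, TRUE), "no suggestion")
  ses <- set_suggestion(ses, decide(kb, ses))
  ok <- record_evaluator_response(ses, TRUE)
  expect_true(ok$evaluator_accepted)
  declined <- record_evaluator_response(
    ses, FALSE, "The questions do not align with the child's developmental stage.")
  expect_false(declined$evaluator_accepted)
  expect_match(declined$decline_reason, "developmental stage")
  expect_error(record_evaluator_response(ses, FALSE, ""), "reason")
  expect_error(record_evaluator_response(ses, FALSE), "reason")
})

test_that("reports carry Q/A rows, domain tallies and follow-up dates", {
  kb <- toy_kb_single_month(c("warning", "warning", "warning", "warning"))
  ids <- names(kb$questions)
  eval_date <- as.Date("2023-03-15")
  child <- toy_child(10, eval_date, id = "rep01")
  ses <- screening_session(child, kb, eval_date)
  expect_error(render_report(child, ses, kb), "pending")
  ses <- answer_session(ses, stats::setNames(c("no", "no", "yes", "yes"), ids))
  ses <- set_suggestion(ses, decide(kb, ses)) # 2 warning failures -> repeat_2mo
  rep <- render_report(child, ses, kb)
  expect_equal(rep$data$suggestion, "repeat_2mo")
  expect_equal(rep$data$follow_up_date, as.Date("2023-05-15"))
  expect_equal(nrow(rep$data$questions), 4)
  expect_equal(sum(rep$data$domain_summary$failed), 2)
  expect_match(rep$markdown, "Follow-up evaluation due: 2023-05-15")

  # referral report flags the alarm and lists the triggering items
  kb2 <- toy_kb_single_month(c("warning", "warning", "alarm"))
  ids2 <- names(kb2$questions)
  ses2 <- screening_session(child, kb2, eval_date)
  ses2 <- answer_session(ses2, stats::setNames(c("yes", "yes", "no"), ids2))
  ses2 <- set_suggestion(ses2, decide(kb2, ses2))
  rep2 <- render_report(child, ses2, kb2)
  expect_equal(rep2$data$severity_class, "alarm")
  expect_match(rep2$markdown, "ALARM")
  expect_match(rep2$markdown, ids2[3])
})

test_that("preterm gestational age implies the preterm complication flag", {
  ch <- child_profile("p1", "2022-01-01", gestational_weeks = 35)
  expect_true("preterm" %in% ch$birth_complications)
  ch2 <- child_profile("p2", "2022-01-01", gestational_weeks = 40)
  expect_false("preterm" %in% ch2$birth_complications)
})
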