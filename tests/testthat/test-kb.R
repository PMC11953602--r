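test_that("generated knowledge base loads, validates and round-trips through JSON", {
  kb <- gen_kb(kb_gen_config(seed = 42))
  expect_s3_class(kb, "knowledge_base")
  expect_length(kb$questions, 108)
  expect_equal(kb$coverage_range, c(1L, 36L))
  expect_equal(nrow(validate_kb(kb)), 0)

  tmp <- withr::local_tempfile(fileext = ".json")
  write_kb(kb, tmp)
  expect_identical(load_kb(tmp), kb)
})

test_that("round-trip identity holds across generator configurations", {
  configs <- list(kb_gen_config(seed = 1),
                  kb_gen_config(seed = 2, alarm_fraction = 0, multi_month_fraction = 0),
                  kb_gen_config(seed = 3, coverage_range = c(1, 12),
                                quotas = c(sensory_reception = 3,
                                           language_perception = 20,
                                           production = 30, pragmatics = 10)))
  for (cfg in configs) {
    kb <- gen_kb(cfg)
    tmp <- withr::local_tempfile(fileext = ".json")
    write_kb(kb, tmp)
    expect_identical(load_kb(tmp), kb)
  }
})

test_that("load_kb rejects malformed documents with informative errors", {
  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("{}", empty)
  expect_error(load_kb(empty), "lacks key")

  # month node referencing an undefined question id
  dangling <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "coverage_range": [14, 14],
    "questions": [
      {"id": "q1", "text": "t", "domain": "production", "applicable_months": [14], "severity_class": "warning"},
      {"id": "q2", "text": "t", "domain": "pragmatics", "applicable_months": [14], "severity_class": "warning"},
      {"id": "q3", "text": "t", "domain": "production", "applicable_months": [14], "severity_class": "alarm"}
    ],
    "months": [{"month": 14, "question_ids": ["q1", "q2", "q3", "ghost"]}]
  }', dangling)
  expect_error(load_kb(dangling), "undefined question id.*ghost")

  truncated <- withr::local_tempfile(fileext = ".json")
  writeLines('{"coverage_range": [1, 2], "questions": [{"id": "q1"}], "months": []}',
             truncated)
  expect_error(load_kb(truncated), "missing field")
})

test_that("validate_kb reports per-month count, quota and sensory-range violations", {
  # 7 questions on one month
  ids <- sprintf("x%d", 1:7)
  qs <- lapply(ids, function(i) kb_question(i, "t", "production", 20, "warning"))
  kb7 <- knowledge_base(c(20, 20), qs, list(list(month = 20, question_ids = ids)))
  v <- validate_kb(kb7)
  expect_true(any(v$rule == "questions_per_month" & grepl("month 20", v$location)))

  # declared quotas disagree with actual counts in one domain
  kb <- toy_kb_two_months()
  kb$quotas[["pragmatics"]] <- kb$quotas[["pragmatics"]] + 1L
  v <- validate_kb(kb)
  expect_true(any(v$rule == "quota" & grepl("pragmatics", v$location)))

  # sensory-reception item past month 12
  qs <- list(kb_question("s1", "t", "sensory_reception", c(13, 14), "warning"),
             kb_question("s2", "t", "production", 13, "warning"),
             kb_question("s3", "t", "pragmatics", c(13, 14), "warning"),
             kb_question("s4", "t", "production", 14, "alarm"))
  kbs <- knowledge_base(c(13, 14), qs,
                        list(list(month = 13, question_ids = c("s1", "s2", "s3")),
                             list(month = 14, question_ids = c("s1", "s3", "s4"))))
  expect_true(any(validate_kb(kbs)$rule == "sensory_range"))

  # a month missing from coverage
  kbm <- toy_kb_two_months()
  kbm$months[["6"]] <- NULL
  expect_true(any(validate_kb(kbm)$rule == "missing_month"))
})

test_that("questions_for_month returns node questions in order and honors sharing", {
  kb <- load_kb(system.file("extdata", "toy-kb.json", package = "langscreen"))
  q14 <- questions_for_month(kb, 14)
  expect_equal(unname(vapply(q14, `[[`, "", "id")), c("q1", "q2", "q3"))
  q15 <- questions_for_month(kb, 15)
  # the shared question appears in both months
  expect_true("q3" %in% vapply(q14, `[[`, "", "id"))
  expect_true("q3" %in% vapply(q15, `[[`, "", "id"))
  expect_error(questions_for_month(kb, 99), "outside the coverage range")
})

test_that("graph export emits one node per month, question and suggestion type", {
  kb <- toy_kb_two_months()
  g <- parse_graph_statements(export_graph(kb))
  expect_equal(nrow(g$nodes), 2 + 6 + 5)
  expect_equal(sum(g$nodes$label == "Month"), 2)
  expect_equal(sum(g$nodes$label == "Question"), 6)
  expect_equal(sum(g$nodes$label == "Suggestion"), 5)
  # month->question edges equal the per-month listings; question->suggestion
  # edges one per question
  expect_equal(sum(g$edges$rel == "ASKS"), 6)
  expect_equal(sum(g$edges$rel == "ON_FAILURE"), 6)
})

test_that("graph export round-trips to the expected node/edge multiset on a generated KB", {
  kb <- gen_kb(kb_gen_config(seed = 5))
  g <- parse_graph_statements(export_graph(kb))
  expect_equal(nrow(g$nodes), length(kb$months) + length(kb$questions) + 5)
  asks_expected <- sort(unlist(lapply(kb$months, function(m) {
    paste0("m", m$month, "->", m$question_ids)
  })))
  asks_got <- sort(paste0(g$edges$from[g$edges$rel == "ASKS"], "->",
                          g$edges$to[g$edges$rel == "ASKS"]))
  expect_equal(asks_got, unname(asks_expected))
  # a question spanning two months has exactly two incoming month edges
  spans <- Filter(function(q) length(q$applicable_months) > 1, kb$questions)
  expect_true(length(spans) > 0)
  shared <- spans[[1]]$id
  expect_equal(sum(g$edges$to == shared & g$edges$rel == "ASKS"), 2)
})

test_that("export refuses an invalid knowledge base", {
  kb <- toy_kb_two_months()
  kb$quotas[["production"]] <- 99L
  expect_error(export_graph(kb), "invalid")
})
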