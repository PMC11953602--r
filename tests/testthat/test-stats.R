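# small hand-built record set: 3 children, 5 sessions
make_records <- function() {
  s <- data.frame(
    child_id = c("a", "a", "b", "c", "c"),
    center = c("nursery_school", "nursery_school", "nursery_school",
               "psychopedagogical_center", "psychopedagogical_center"),
    gender = c("female", "female", "male", "male", "male"),
    birth_date = as.Date(c("2022-01-10", "2022-01-10", "2021-06-01",
                           "2020-11-02", "2020-11-02")),
    evaluation_date = as.Date(c("2023-03-01", "2023-05-01", "2023-04-01",
                                "2023-02-01", "2023-05-20")),
    suggestion = c("repeat_2mo", "typical_development", "repeat_3mo",
                   "repeat_1mo", "refer_early_intervention"),
    accepted = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    decline_reason = c(NA, NA, NA, "not needed at this stage", NA),
    stringsAsFactors = FALSE)
  s$age_months <- age_in_months(s$birth_date, s$evaluation_date)
  s$severity_class <- suggestion_severity(s$suggestion)
  evaluation_records(s)
}

test_that("latest_per_child keeps exactly the maximal evaluation date per child", {
  rec <- make_records()
  latest <- latest_per_child(rec)
  s <- latest$sessions
  expect_equal(nrow(s), 3)
  expect_equal(sort(unique(s$child_id)), c("a", "b", "c"))
  expect_equal(s$suggestion[s$child_id == "a"], "typical_development")
  expect_equal(s$suggestion[s$child_id == "c"], "refer_early_intervention")
  # single-session children are retained untouched
  expect_equal(s$evaluation_date[s$child_id == "b"], as.Date("2023-04-01"))
})

test_that("suggestion_distribution counts conserve the total and handle edge cases", {
  rec <- make_records()
  d <- suggestion_distribution(rec)
  expect_equal(sum(d$n), 5)
  expect_equal(d$n[d$suggestion == "repeat_2mo"], 1)
  expect_equal(d$pct, round(100 * d$n / 5, 1))
  empty <- evaluation_records(NULL)
  expect_equal(nrow(suggestion_distribution(empty)), 0)
  all_typ <- make_records()
  all_typ$sessions$suggestion <- "typical_development"
  all_typ$sessions$severity_class <- "none"
  d2 <- suggestion_distribution(evaluation_records(all_typ$sessions))
  expect_equal(d2$pct[d2$suggestion == "typical_development"], 100)
  expect_equal(sum(d2$n > 0), 1)
})

test_that("stratified tables conserve the grand total for any grouping", {
  rec <- reconstruct_records(load_fixture(), seed = 3)
  latest <- latest_per_child(rec)
  for (by in list("gender", "center", c("gender", "severity"),
                  c("center", "age_band"), c("center", "gender", "month"),
                  "suggestion")) {
    tab <- rate_by(latest, by)
    expect_equal(sum(tab$n), nrow(latest$sessions))
    expect_equal(tab$pct, round(100 * tab$n / nrow(latest$sessions), 1))
  }
  # conservation also on filtered sets
  alarms <- filter_records(latest, severity = "alarm")
  tab <- rate_by(alarms, c("center", "month"))
  expect_equal(sum(tab$n), nrow(alarms$sessions))
  expect_error(rate_by(latest, "star_sign"), "unknown grouping")
})

test_that("accuracy reports accepted over total with per-type breakdown", {
  rec <- make_records()
  a <- accuracy(rec)
  expect_equal(a$accepted_n + a$declined_n, a$total)
  expect_equal(a$pct, round(100 * 4 / 5, 2))
  ab <- accuracy(rec, by = "suggestion")
  expect_equal(ab$by_table$declined_n[ab$by_table$suggestion == "repeat_1mo"], 1)
  expect_equal(sum(ab$by_table$accepted_n + ab$by_table$declined_n), 5)
  all_ok <- make_records()
  all_ok$sessions$accepted <- TRUE
  all_ok$sessions$decline_reason <- NA_character_
  expect_equal(accuracy(evaluation_records(all_ok$sessions))$pct, 100)
  expect_error(accuracy(evaluation_records(NULL)), "empty")
})

test_that("domain distributions conserve answers and flag late sensory items", {
  rec <- reconstruct_records(load_fixture(), seed = 2)
  tab <- domain_response_distribution(rec)
  expect_equal(sum(tab$n), nrow(rec$answers))
  sens <- tab[tab$domain == "sensory_reception" & tab$age_band != "<=12", ]
  expect_equal(sum(sens$n), 0)
  # inject a sensory answer past month 12
  bad <- rec
  i <- which(bad$answers$age_months > 12)[1]
  bad$answers$domain[i] <- "sensory_reception"
  expect_warning(domain_response_distribution(bad), "past month 12")
})

test_that("birth quarter analysis buckets children by calendar quarter and year", {
  rec <- make_records()
  tab <- birth_quarter_analysis(latest_per_child(rec))
  expect_equal(sum(tab$n), 3)
  expect_equal(unique(tab$quarter[tab$birth_year == 2020 & tab$n > 0]), 4L)
  expect_equal(unique(tab$quarter[tab$birth_year == 2022 & tab$n > 0]), 1L)
})

test_that("older-quarter children are flagged no more often than the youngest quarter", {
  # questions are age-matched, so birth quarters are exchangeable in the
  # simulator: the oldest quarter's flag rate must not exceed the youngest
  # quarter's beyond binomial noise (3 SEs of the difference)
  kb <- gen_kb(kb_gen_config(seed = 21))
  for (seed in c(31L, 32L, 33L)) {
    co <- gen_cohort(cohort_config(n_children = 600, p_imp = 0.15, seed = seed))
    rec <- simulate_study(kb, co, ability_model(slope = 0.8, intercept = 2,
                                                shift = 8),
                          seed = seed)
    s <- latest_per_child(rec)$sessions
    q <- (as.integer(format(s$birth_date, "%m")) - 1) %/% 3 + 1
    flagged <- s$severity_class != "none"
    old <- flagged[q == 1]
    young <- flagged[q == 4]
    se <- sqrt(mean(old) * (1 - mean(old)) / length(old) +
                 mean(young) * (1 - mean(young)) / length(young))
    expect_lte(mean(old), mean(young) + 3 * se)
  }
})

test_that("assessments per child summarizes session counts", {
  rec <- make_records()
  apc <- assessments_per_child(rec)
  expect_equal(apc$mean, 5 / 3)
  expect_equal(apc$n_children, 3)
  one_each <- latest_per_child(rec)
  apc1 <- assessments_per_child(one_each)
  expect_equal(apc1$mean, 1)
  expect_equal(apc1$sd, 0)
  # 2 children with 1 and 3 sessions -> mean 2
  s <- one_each$sessions[c(1, 2, 2, 2), ]
  s$child_id <- c("x", "y", "y", "y")
  s$evaluation_date <- as.Date("2023-01-01") + c(0, 0, 30, 60)
  expect_equal(assessments_per_child(evaluation_records(s))$mean, 2)
})

test_that("finite population correction shrinks but never inflates the sample size", {
  expect_equal(sample_size(150000, 0.07, 1.96, 0.05), 100L)
  expect_equal(sample_size(Inf, 0.5, 1.96, 0.05), 385L)
  # tightening the margin of error from 5% to 1% scales n0 by ~25x
  n_wide <- sample_size(Inf, 0.07, 1.96, 0.05)
  n_tight <- sample_size(Inf, 0.07, 1.96, 0.01)
  expect_equal(n_tight / n_wide, 25, tolerance = 0.02)
  for (N in c(200, 5000, 1e5, 1e7)) {
    expect_lte(sample_size(N, 0.07), sample_size(Inf, 0.07))
  }
  expect_lte(sample_size(1000, 0.5), sample_size(2000, 0.5)) # monotone in N
  expect_gte(sample_size(1e5, 0.1, e = 0.02), sample_size(1e5, 0.1, e = 0.05))
  expect_error(sample_size(0, 0.5), "N")
  expect_error(sample_size(1000, 1.5), "p")
})

test_that("record sets round-trip through the CSV and JSON dialects", {
  kb <- gen_kb(kb_gen_config(seed = 12))
  co <- gen_cohort(cohort_config(n_children = 40, seed = 12))
  rec <- simulate_study(kb, co, seed = 12)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_records(rec, csv)
  write_records(rec, js)
  back_csv <- read_records(csv)
  back_js <- read_records(js)
  for (back in list(back_csv, back_js)) {
    expect_equal(nrow(back$sessions), nrow(rec$sessions))
    o1 <- order(rec$sessions$child_id, rec$sessions$evaluation_date)
    o2 <- order(back$sessions$child_id, back$sessions$evaluation_date)
    expect_equal(back$sessions$suggestion[o2], rec$sessions$suggestion[o1])
    expect_equal(back$sessions$accepted[o2], rec$sessions$accepted[o1])
    expect_equal(nrow(back$answers), nrow(rec$answers))
  }
})

test_that("record validation enforces uniqueness, consistency and decline reasons", {
  rec <- make_records()
  dup <- rec$sessions[c(1, 1), ]
  expect_error(evaluation_records(dup), "duplicate")
  bad_sev <- rec$sessions
  bad_sev$severity_class[1] <- "alarm"
  expect_error(evaluation_records(bad_sev), "inconsistent")
  no_reason <- rec$sessions
  no_reason$decline_reason[no_reason$accepted == FALSE] <- NA
  expect_error(evaluation_records(no_reason), "decline_reason")
})
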