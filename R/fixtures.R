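#' Load the packaged field-study summary tables
#'
#' The package ships the study's printed summary tables as plain CSV files:
#' the cohort composition by center, gender and age band; the distribution of
#' final suggestions; the suggestion-severity split by gender; the alarm
#' counts by center, gender and month; the control-information outcomes; the
#' acceptance counts by suggestion type; the evaluators' decline reasons; and
#' a handful of scalar constants (270 assessments, 218 children, 108
#' questions, ...). File integrity is checked against an MD5 manifest, and
#' the tables' internal consistency is verified at load time: the final
#' suggestions sum to the child count, the gender table's alarm total equals
#' the referral count, the alarm table's center totals match its cells, and
#' the acceptance table sums to the assessment total with the stated number
#' of declines.
#'
#' @param dir Directory containing the fixture CSVs; defaults to the copy
#'   installed with the package.
#' @return An object of class `study_fixture`: a list of data frames
#'   (`cohort`, `suggestions`, `gender`, `alarms`, `control`, `acceptance`,
#'   `declines`) plus a named numeric vector `constants`.
#' @export
#' @examples
#' fx <- load_fixture()
#' sum(fx$suggestions$n) # 218
load_fixture <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- system.file("extdata", "study", package = "langscreen")
  }
  manifest <- utils::read.csv(file.path(dir, "MANIFEST.csv"),
                              stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$file[i])
    if (!file.exists(f)) stop("fixture file missing: ", manifest$file[i])
    h <- unname(tools::md5sum(f))
    if (!identical(h, manifest$md5[i])) {
      stop("fixture checksum mismatch for ", manifest$file[i],
           " (expected ", manifest$md5[i], ", got ", h, ")")
    }
  }
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  constants_df <- rd("constants.csv")
  constants <- stats::setNames(constants_df$value, constants_df$name)
  fx <- structure(list(cohort = rd("table2_cohort.csv"),
                       suggestions = rd("table3_suggestions.csv"),
                       gender = rd("table4_gender.csv"),
                       alarms = rd("table5_alarms.csv"),
                       control = rd("table6_control.csv"),
                       acceptance = rd("table7_acceptance.csv"),
                       declines = rd("table8_declines.csv"),
                       constants = constants),
                  class = "study_fixture")
  check_fixture_consistency(fx)
  fx
}

check_fixture_consistency <- function(fx) {
  k <- fx$constants
  fail <- function(...) stop("fixture consistency error: ", sprintf(...), call. = FALSE)
  if (sum(fx$suggestions$n) != k[["n_children"]]) {
    fail("final suggestions sum to %d, expected %d children",
         sum(fx$suggestions$n), k[["n_children"]])
  }
  if (sum(fx$cohort$n) != k[["n_children"]]) {
    fail("cohort cells sum to %d, expected %d", sum(fx$cohort$n), k[["n_children"]])
  }
  refer_n <- fx$suggestions$n[fx$suggestions$suggestion == "refer_early_intervention"]
  alarm_by_gender <- sum(fx$gender$n[fx$gender$severity == "alarm"])
  if (alarm_by_gender != refer_n) {
    fail("gender-table alarms (%d) != referral count (%d)", alarm_by_gender, refer_n)
  }
  if (sum(fx$gender$n) != k[["n_children"]]) {
    fail("gender table sums to %d, expected %d", sum(fx$gender$n), k[["n_children"]])
  }
  if (sum(fx$alarms$n) != refer_n) {
    fail("alarm table sums to %d, expected %d", sum(fx$alarms$n), refer_n)
  }
  if (sum(fx$acceptance$declined_n + fx$acceptance$accepted_n) != k[["n_evaluations"]]) {
    fail("acceptance table sums to %d, expected %d assessments",
         sum(fx$acceptance$declined_n + fx$acceptance$accepted_n),
         k[["n_evaluations"]])
  }
  if (sum(fx$acceptance$declined_n) != nrow(fx$declines)) {
    fail("%d declines in the acceptance table but %d decline reasons",
         sum(fx$acceptance$declined_n), nrow(fx$declines))
  }
  m18 <- sum(fx$alarms$n[fx$alarms$month == 18])
  if (m18 != k[["month18_alarms"]]) {
    fail("month-18 alarms (%d) != constant (%d)", m18, k[["month18_alarms"]])
  }
  invisible(fx)
}

#' @export
print.study_fixture <- function(x, ...) {
  cat(sprintf("<study_fixture> %d children, %d assessments, %d tables\n",
              x$constants[["n_children"]], x$constants[["n_evaluations"]],
              length(x) - 1L))
  invisible(x)
}

# Largest-remainder split of `total` proportional to `weights`.
largest_remainder <- function(total, weights) {
  if (sum(weights) == 0) return(rep(0L, length(weights)))
  raw <- total * weights / sum(weights)
  f <- floor(raw)
  left <- total - sum(f)
  if (left > 0) {
    take <- order(raw - f, decreasing = TRUE)[seq_len(left)]
    f[take] <- f[take] + 1
  }
  as.integer(f)
}

#' Reconstruct a child-level record set from the summary tables
#'
#' The study's child-level data are not deposited, so this builds a
#' *synthetic* maximum-agreement record set: one session row per assessment
#' whose marginals reproduce the encoded tables exactly — the final
#' suggestion distribution, the severity-by-gender split, the alarm counts by
#' center, gender and month, the cohort's center/gender/age-band cells, and
#' the per-suggestion acceptance counts (decline reasons are attached to
#' sessions matching the reported suggestion, gender and month). Cells the
#' printed tables do not pin down — which individual child carries which
#' label, exact dates, the identity of re-assessed children — are filled by a
#' deterministic allocator under `seed`: non-final assessments (the
#' difference between total assessments and distinct children) are assigned,
#' at earlier dates, to children with non-typical final rows first. Answers
#' consistent with each suggestion are synthesized against a generated
#' knowledge base so answer-level statistics can run end to end.
#'
#' The result is deterministic given `seed` and is in no sense the real
#' study data; only the encoded marginals are faithful.
#'
#' @param fixture A [load_fixture()] result.
#' @param seed Integer seed for the unconstrained fills.
#' @param kb Optional [knowledge_base()] used to synthesize answers; defaults
#'   to `gen_kb(kb_gen_config(seed = seed))`.
#' @return An [evaluation_records()] with 270 sessions over 218 children
#'   (under the packaged tables).
#' @export
#' @examples
#' rec <- reconstruct_records(load_fixture(), seed = 1)
#' nrow(latest_per_child(rec)$sessions) # 218
reconstruct_records <- function(fixture, seed = 1L, kb = NULL) {
  stopifnot(inherits(fixture, "study_fixture"))
  if (is.null(kb)) kb <- gen_kb(kb_gen_config(seed = seed))
  with_seed(seed, {
    bands <- c("<=12", "13-24", "25-36")
    band_ranges <- list(6:12, 13:24, 25:36)
    ## --- alarm (referred) children: fully pinned by the alarm table
    al <- fixture$alarms
    alarm <- data.frame(center = rep(al$center, al$n),
                        gender = rep(al$gender, al$n),
                        age_months = rep(al$month, al$n),
                        suggestion = "refer_early_intervention")
    alarm$band <- as.character(age_band(alarm$age_months))
    ## --- non-alarm children: cohort cells minus alarm cells
    co <- fixture$cohort
    non_alarm <- list()
    for (i in seq_len(nrow(co))) {
      a_n <- sum(alarm$center == co$center[i] & alarm$gender == co$gender[i] &
                   alarm$band == co$band[i])
      k <- co$n[i] - a_n
      if (k < 0) {
        stop(sprintf("infeasible fixture: alarm table exceeds cohort cell %s/%s/%s",
                     co$center[i], co$gender[i], co$band[i]))
      }
      if (k > 0) {
        rng <- band_ranges[[match(co$band[i], bands)]]
        non_alarm[[length(non_alarm) + 1L]] <- data.frame(
          center = co$center[i], gender = co$gender[i],
          age_months = rng[(seq_len(k) - 1L) %% length(rng) + 1L],
          suggestion = NA_character_, band = co$band[i])
      }
    }
    non_alarm <- do.call(rbind, non_alarm)
    ## --- assign warning/typical final suggestions within genders
    sug <- fixture$suggestions
    gen <- fixture$gender
    repeat_types <- setdiff(suggestion_types(),
                            c("typical_development", "refer_early_intervention"))
    warn_by_gender <- stats::setNames(gen$n[gen$severity == "warning"],
                                      gen$gender[gen$severity == "warning"])
    genders <- names(warn_by_gender)
    split <- matrix(0L, nrow = length(genders), ncol = length(repeat_types),
                    dimnames = list(genders, repeat_types))
    for (g in genders[-length(genders)]) {
      split[g, ] <- largest_remainder(
        warn_by_gender[[g]],
        sug$n[match(repeat_types, sug$suggestion)])
    }
    g_last <- genders[length(genders)]
    split[g_last, ] <- sug$n[match(repeat_types, sug$suggestion)] -
      colSums(split[genders[-length(genders)], , drop = FALSE])
    if (any(split < 0)) stop("infeasible fixture: gender and suggestion tables conflict")
    for (g in genders) {
      idx <- which(non_alarm$gender == g)
      idx <- idx[sample.int(length(idx))]
      assign_types <- c(rep(repeat_types, times = split[g, ]),
                        rep("typical_development", length(idx) - sum(split[g, ])))
      if (sum(split[g, ]) > length(idx)) {
        stop("infeasible fixture: more warnings than non-alarm children for ", g)
      }
      non_alarm$suggestion[idx] <- assign_types
    }
    children <- rbind(alarm, non_alarm)
    n_children <- nrow(children)
    children$child_id <- sprintf("f%03d", sample.int(n_children))
    ## --- dates: final assessments spread over the enrolment window
    children$evaluation_date <- as.Date("2023-03-06") +
      (seq_len(n_children) * 7L) %% 92L
    children$birth_date <- month_add(children$evaluation_date,
                                     -children$age_months) -
      (seq_len(n_children) %% 15L)
    children$severity_class <- suggestion_severity(children$suggestion)
    ## --- non-final (earlier) assessments to reach the assessment total
    acc <- fixture$acceptance
    total_by_type <- stats::setNames(acc$declined_n + acc$accepted_n, acc$suggestion)
    extra_by_type <- total_by_type -
      stats::setNames(sug$n, sug$suggestion)[names(total_by_type)]
    if (any(extra_by_type < 0)) {
      stop("infeasible fixture: acceptance table has fewer sessions than final suggestions")
    }
    extra_types <- rep(names(extra_by_type), times = extra_by_type)
    host_order <- order(-suggestion_rank(children$suggestion))
    if (length(extra_types) > n_children) {
      stop("infeasible fixture: more extra assessments than children")
    }
    hosts <- children[host_order[seq_along(extra_types)], ]
    extras <- data.frame(center = hosts$center, gender = hosts$gender,
                         age_months = pmax(1L, hosts$age_months - 2L),
                         suggestion = extra_types, band = hosts$band,
                         child_id = hosts$child_id,
                         evaluation_date = hosts$evaluation_date - 70L,
                         birth_date = hosts$birth_date,
                         severity_class = suggestion_severity(extra_types))
    extras$age_months <- age_in_months(extras$birth_date, extras$evaluation_date)
    sessions <- rbind(children[names(extras)], extras)
    ## --- evaluator acceptance: attach the reported declines
    sessions$accepted <- TRUE
    sessions$decline_reason <- NA_character_
    de <- fixture$declines
    for (i in seq_len(nrow(de))) {
      cand <- which(sessions$suggestion == de$suggestion[i] & sessions$accepted &
                      sessions$gender == de$gender[i] &
                      sessions$age_months == de$month[i])
      if (length(cand) == 0) {
        cand <- which(sessions$suggestion == de$suggestion[i] & sessions$accepted &
                        sessions$gender == de$gender[i])
      }
      if (length(cand) == 0) {
        cand <- which(sessions$suggestion == de$suggestion[i] & sessions$accepted)
      }
      if (length(cand) == 0) {
        stop("infeasible fixture: no session available for a recorded decline")
      }
      sessions$accepted[cand[1]] <- FALSE
      sessions$decline_reason[cand[1]] <- de$reason[i]
    }
    per_type_declined <- tapply(!sessions$accepted, sessions$suggestion, sum)
    want <- stats::setNames(acc$declined_n, acc$suggestion)
    for (t in names(want)) {
      got <- if (t %in% names(per_type_declined)) per_type_declined[[t]] else 0L
      if (got != want[[t]]) {
        stop(sprintf("infeasible fixture: %d declines reconstructed for %s, table says %d",
                     got, t, want[[t]]))
      }
    }
    rownames(sessions) <- NULL
    answers <- synthesize_answers(sessions, kb)
    evaluation_records(
      sessions[, c("child_id", "center", "gender", "birth_date",
                   "evaluation_date", "age_months", "suggestion",
                   "severity_class", "accepted", "decline_reason")],
      answers,
      metadata = list(seed = as.integer(seed), source = "reconstruct_records",
                      synthetic = TRUE))
  })
}

# Per-session answers consistent with each stored suggestion: a referral
# fails one alarm-class question (or, lacking one at that month, the first
# question), a k-month repeat fails 4-k warning-class questions, typical
# sessions pass everything; every 17th passing answer is masked as "dk".
synthesize_answers <- function(sessions, kb) {
  cov <- kb$coverage_range
  rows <- vector("list", nrow(sessions))
  tick <- 0L
  for (i in seq_len(nrow(sessions))) {
    m <- min(max(sessions$age_months[i], cov[1]), cov[2])
    qs <- questions_for_month(kb, m)
    ids <- vapply(qs, `[[`, "", "id")
    sev <- vapply(qs, `[[`, "", "severity_class")
    dom <- vapply(qs, `[[`, "", "domain")
    ans <- rep("yes", length(ids))
    type <- sessions$suggestion[i]
    if (type == "refer_early_intervention") {
      j <- which(sev == "alarm")
      ans[if (length(j)) j[1] else 1L] <- "no"
    } else if (type != "typical_development") {
      need <- 4L - follow_up_months(type)
      j <- which(sev == "warning")
      ans[utils::head(j, need)] <- "no"
    }
    pass <- which(ans == "yes")
    for (j in pass) {
      tick <- tick + 1L
      if (tick %% 17L == 0L) ans[j] <- "dk"
    }
    rows[[i]] <- data.frame(child_id = sessions$child_id[i],
                            evaluation_date = sessions$evaluation_date[i],
                            age_months = sessions$age_months[i],
                            question_id = ids, domain = dom,
                            severity_class = sev, answer = ans)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
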