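#' Age in completed months
#'
#' Completed calendar months between two dates (floor): the count increments
#' on each monthly anniversary of the birth date.
#'
#' @param birth_date,evaluation_date Dates (or strings coercible to `Date`);
#'   `evaluation_date` must not precede `birth_date`.
#' @return Integer vector of completed months.
#' @export
#' @examples
#' age_in_months("2021-03-10", "2021-10-10") # 7
#' age_in_months("2021-03-11", "2021-10-10") # 6
age_in_months <- function(birth_date, evaluation_date) {
  b <- as.Date(birth_date); e <- as.Date(evaluation_date)
  if (anyNA(b) || anyNA(e)) stop("dates must be valid Dates")
  if (any(e < b)) stop("evaluation_date precedes birth_date")
  lb <- as.POSIXlt(b); le <- as.POSIXlt(e)
  m <- 12L * (le$year - lb$year) + (le$mon - lb$mon) - as.integer(le$mday < lb$mday)
  as.integer(m)
}

# Add k calendar months to a date, clamping the day to the target month's end
# (e.g. Jan 31 + 1 month -> Feb 28/29).
month_add <- function(date, k) {
  date <- as.Date(date)
  lt <- as.POSIXlt(date)
  total <- lt$year * 12L + lt$mon + as.integer(k)
  y <- total %/% 12L + 1900L
  m <- total %% 12L + 1L
  nxt <- total + 1L
  dim <- as.integer(format(as.Date(sprintf("%04d-%02d-01", nxt %/% 12L + 1900L,
                                           nxt %% 12L + 1L)) - 1L, "%d"))
  as.Date(sprintf("%04d-%02d-%02d", y, m, pmin(lt$mday, dim)))
}

#' Create a child profile
#'
#' Control data collected before screening: demographics, gestational age,
#' birth complications, family history of neurodevelopmental disorders and
#' bilingual context. These data serve as a baseline for the report and for
#' cohort stratification; the default decision policy does not alter the
#' decision rule based on them. A gestational age below 37 weeks implies the
#' `"preterm"` birth complication (added automatically).
#'
#' @param child_id Anonymized identifier (must not carry identifying
#'   information; use a random code).
#' @param birth_date Date of birth.
#' @param gender `"female"` or `"male"`.
#' @param center `"nursery_school"` or `"psychopedagogical_center"`.
#' @param gestational_weeks Positive number, or `NA` if unknown.
#' @param birth_complications Character subset of
#'   `c("prenatal", "perinatal", "preterm")`.
#' @param family_history_ndd,bilingual Logical or `NA` if unknown.
#' @return An object of class `child_profile`.
#' @export
child_profile <- function(child_id, birth_date,
                          gender = c("female", "male"),
                          center = c("nursery_school", "psychopedagogical_center"),
                          gestational_weeks = NA_real_,
                          birth_complications = character(),
                          family_history_ndd = NA, bilingual = NA) {
  gender <- match.arg(gender)
  center <- match.arg(center)
  stopifnot(is.character(child_id), length(child_id) == 1L, nzchar(child_id))
  birth_complications <- unique(as.character(birth_complications))
  bad <- setdiff(birth_complications, c("prenatal", "perinatal", "preterm"))
  if (length(bad)) stop("unknown birth complication: ", paste(bad, collapse = ", "))
  if (!is.na(gestational_weeks)) {
    if (gestational_weeks <= 0) stop("gestational_weeks must be positive")
    if (gestational_weeks < 37 && !("preterm" %in% birth_complications)) {
      birth_complications <- c(birth_complications, "preterm")
    }
  }
  structure(list(child_id = child_id, birth_date = as.Date(birth_date),
                 gender = gender, center = center,
                 gestational_weeks = as.numeric(gestational_weeks),
                 birth_complications = birth_complications,
                 family_history_ndd = family_history_ndd, bilingual = bilingual),
            class = "child_profile")
}

#' Select the questions for a screening session
#'
#' The form is adapted to the child: it contains the questions of the month
#' node matching the child's age in completed months, plus any question the
#' child failed (answered "no") in the most recent prior session that is
#' still within its applicable-months window (current age not past its last
#' applicable month). The result is de-duplicated and ordered by
#' knowledge-base question order.
#'
#' @param kb A [knowledge_base()].
#' @param child A [child_profile()].
#' @param evaluation_date Date of the assessment.
#' @param history List of prior [screening_session()]s for this child (only
#'   the most recent is consulted).
#' @return Character vector of question ids (always at least 3 for a valid
#'   knowledge base).
#' @export
select_questions <- function(kb, child, evaluation_date, history = list()) {
  age <- age_in_months(child$birth_date, evaluation_date)
  ids <- vapply(questions_for_month(kb, age), `[[`, "", "id")
  if (length(history) > 0) {
    dates <- as.Date(vapply(history, function(s) as.character(s$evaluation_date), ""))
    last <- history[[which.max(dates)]]
    failed <- names(last$answers)[unlist(last$answers) == "no"]
    keep <- failed[vapply(failed, function(id) {
      q <- kb$questions[[id]]
      !is.null(q) && age <= max(q$applicable_months)
    }, TRUE)]
    ids <- union(ids, keep)
  }
  unname(ids[order(match(ids, names(kb$questions)))])
}

#' Screening sessions
#'
#' A screening session records one assessment of one child: the questions
#' asked (chosen by [select_questions()]), the answers collected, the derived
#' suggestion, and the evaluator's acceptance of it. Build the session, fill
#' in answers with `answer_session()`, derive the suggestion with [decide()],
#' and record concordance with [record_evaluator_response()].
#'
#' @param child A [child_profile()].
#' @param kb A [knowledge_base()].
#' @param evaluation_date Date of the assessment; the child's age at this
#'   date must fall inside the knowledge base's coverage range.
#' @param history List of prior sessions (drives re-asking of failed items).
#' @return An object of class `screening_session`.
#' @export
screening_session <- function(child, kb, evaluation_date, history = list()) {
  stopifnot(inherits(child, "child_profile"))
  evaluation_date <- as.Date(evaluation_date)
  asked <- select_questions(kb, child, evaluation_date, history)
  structure(list(child_id = child$child_id,
                 evaluation_date = evaluation_date,
                 age_months = age_in_months(child$birth_date, evaluation_date),
                 asked = asked,
                 answers = list(),
                 suggestion = NULL,
                 evaluator_accepted = NA,
                 decline_reason = NA_character_),
            class = "screening_session")
}

#' @rdname screening_session
#' @param session A `screening_session`.
#' @param answers Named character vector or list mapping question ids (a
#'   subset of the asked questions) to [answer_levels()].
#' @export
answer_session <- function(session, answers) {
  stopifnot(inherits(session, "screening_session"))
  answers <- as.list(answers)
  extra <- setdiff(names(answers), session$asked)
  if (length(extra)) stop("answers for questions that were not asked: ",
                          paste(extra, collapse = ", "))
  vals <- unlist(answers)
  bad <- setdiff(vals, answer_levels())
  if (length(bad)) stop("invalid answer value(s): ", paste(unique(bad), collapse = ", "))
  session$answers[names(answers)] <- answers
  session
}

#' @export
print.screening_session <- function(x, ...) {
  cat(sprintf("<screening_session> child %s, age %d months, %d questions\n",
              x$child_id, x$age_months, length(x$asked)))
  if (!is.null(x$suggestion)) {
    cat("  suggestion:", x$suggestion$type, "\n")
  } else {
    cat(sprintf("  %d/%d answered, suggestion pending\n",
                length(x$answers), length(x$asked)))
  }
  invisible(x)
}

#' Derive the graded suggestion for a completed session
#'
#' Applies the warning/alarm decision rules (see [decision_policy()]) to a
#' fully answered session. Any alarm-class "no" yields a referral; otherwise
#' the count of warning-class "no" answers selects a rung of the repeat
#' ladder, and zero failures yield typical development. "dk" answers do not
#' count as failures under the default policy; a session answered entirely
#' with "dk" is flagged `low_information` in the result.
#'
#' @param kb A [knowledge_base()].
#' @param session A [screening_session()] whose asked questions are all
#'   answered.
#' @param policy A [decision_policy()].
#' @return An object of class `suggestion_result` with fields `type`,
#'   `severity_class` (`"none"`, `"warning"` or `"alarm"`, always consistent
#'   with `type`), `triggered_by` (ids of the failed questions) and
#'   `low_information`.
#' @export
decide <- function(kb, session, policy = decision_policy()) {
  stopifnot(inherits(session, "screening_session"), inherits(policy, "decision_policy"))
  pending <- setdiff(session$asked, names(session$answers))
  if (length(pending)) {
    stop("incomplete session: unanswered question(s) ", paste(pending, collapse = ", "))
  }
  ans <- unlist(session$answers[session$asked])
  sev <- vapply(session$asked, function(id) kb$questions[[id]]$severity_class, "")
  failed <- ans == "no" | (policy$dk_as_no & ans == "dk")
  triggered <- session$asked[failed]
  if (any(failed & sev == "alarm")) {
    type <- "refer_early_intervention"
  } else {
    w <- sum(failed & sev == "warning")
    type <- if (w == 0L) "typical_development" else policy$ladder[min(w, 3L)]
  }
  suggestion_result(type, triggered_by = triggered,
                    low_information = length(ans) > 0 && all(ans == "dk"))
}

#' @rdname decide
#' @param type One of [suggestion_types()].
#' @param triggered_by Character vector of failed question ids.
#' @param low_information Logical flag for sessions with no informative
#'   answers.
#' @export
suggestion_result <- function(type, triggered_by = character(),
                              low_information = FALSE) {
  structure(list(type = type,
                 severity_class = suggestion_severity(type),
                 triggered_by = as.character(triggered_by),
                 low_information = isTRUE(low_information)),
            class = "suggestion_result")
}

#' @export
print.suggestion_result <- function(x, ...) {
  cat(sprintf("<suggestion_result> %s (severity: %s)\n", x$type, x$severity_class))
  if (length(x$triggered_by)) cat("  triggered by:", paste(x$triggered_by, collapse = ", "), "\n")
  if (x$low_information) cat("  low-information session (all answers 'dk')\n")
  invisible(x)
}

#' @rdname screening_session
#' @param result A [suggestion_result()] to attach to the session.
#' @export
set_suggestion <- function(session, result) {
  stopifnot(inherits(session, "screening_session"),
            inherits(result, "suggestion_result"))
  session$suggestion <- result
  session
}

#' Record the evaluator's acceptance of a suggestion
#'
#' Evaluators either accept the system's suggestion or decline it; declining
#' requires a stated reason, which is stored verbatim.
#'
#' @param session A [screening_session()] with a suggestion set (see
#'   [set_suggestion()]).
#' @param accepted Logical.
#' @param reason Free-text justification; required when `accepted = FALSE`.
#' @return The updated session.
#' @export
record_evaluator_response <- function(session, accepted, reason = NULL) {
  stopifnot(inherits(session, "screening_session"))
  if (is.null(session$suggestion)) stop("session has no suggestion yet")
  if (!isTRUE(accepted) && !isFALSE(accepted)) stop("accepted must be TRUE or FALSE")
  if (!accepted && (is.null(reason) || !nzchar(trimws(reason)))) {
    stop("a declined suggestion requires a non-empty reason")
  }
  session$evaluator_accepted <- accepted
  session$decline_reason <- if (accepted) NA_character_ else trimws(reason)
  session
}

#' Render a psychopedagogical screening report
#'
#' Produces the structured report forwarded to early-intervention
#' professionals: the child's profile and control data, each question asked
#' with its domain label and answer, per-domain pass/fail counts, the
#' suggestion with its severity, the triggering items for a referral, and —
#' for repeat suggestions — the follow-up date (evaluation date plus the
#' repeat interval).
#'
#' @param child A [child_profile()].
#' @param session A finalized [screening_session()] (suggestion set).
#' @param kb The [knowledge_base()] used.
#' @return An object of class `screening_report`: a list with the structured
#'   `data` and a `markdown` rendering. `as.character()` returns the
#'   markdown.
#' @export
render_report <- function(child, session, kb) {
  stopifnot(inherits(child, "child_profile"), inherits(session, "screening_session"))
  if (is.null(session$suggestion)) stop("cannot render a report for a pending session")
  sug <- session$suggestion
  qa <- do.call(rbind, lapply(session$asked, function(id) {
    q <- kb$questions[[id]]
    data.frame(question_id = id, domain = q$domain, severity_class = q$severity_class,
               text = q$text, answer = session$answers[[id]])
  }))
  domain_summary <- do.call(rbind, lapply(unique(qa$domain), function(d) {
    sub <- qa[qa$domain == d, ]
    data.frame(domain = d, asked = nrow(sub),
               passed = sum(sub$answer == "yes"),
               failed = sum(sub$answer == "no"),
               dk = sum(sub$answer == "dk"))
  }))
  k <- follow_up_months(sug$type)
  follow_up <- if (!is.na(k)) month_add(session$evaluation_date, k) else as.Date(NA)
  data <- list(child = child[c("child_id", "birth_date", "gender", "center",
                               "gestational_weeks", "birth_complications",
                               "family_history_ndd", "bilingual")],
               evaluation_date = session$evaluation_date,
               age_months = session$age_months,
               questions = qa, domain_summary = domain_summary,
               suggestion = sug$type, severity_class = sug$severity_class,
               triggered_by = sug$triggered_by,
               low_information = sug$low_information,
               follow_up_date = follow_up,
               evaluator_accepted = session$evaluator_accepted,
               decline_reason = session$decline_reason)
  md <- c(
    sprintf("# Screening report: child %s", child$child_id),
    "",
    sprintf("- Evaluation date: %s (age %d months)", session$evaluation_date,
            session$age_months),
    sprintf("- Gender: %s; center: %s", child$gender, child$center),
    sprintf("- Gestational weeks: %s; birth complications: %s",
            ifelse(is.na(child$gestational_weeks), "unknown",
                   format(child$gestational_weeks)),
            if (length(child$birth_complications)) paste(child$birth_complications, collapse = ", ") else "none"),
    sprintf("- Family history of NDD: %s; bilingual: %s",
            as.character(child$family_history_ndd), as.character(child$bilingual)),
    "",
    "## Questions",
    "",
    "| question | domain | class | answer |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %s | %s |", qa$question_id, qa$domain, qa$severity_class, qa$answer),
    "",
    "## Domain summary",
    "",
    "| domain | asked | passed | failed | dk |",
    "|---|---|---|---|---|",
    sprintf("| %s | %d | %d | %d | %d |", domain_summary$domain, domain_summary$asked,
            domain_summary$passed, domain_summary$failed, domain_summary$dk),
    "",
    sprintf("## Suggestion: %s (severity: %s)", sug$type, sug$severity_class))
  if (sug$severity_class == "alarm") {
    md <- c(md, "", "ALARM: direct referral to early intervention.",
            sprintf("Triggered by: %s", paste(sug$triggered_by, collapse = ", ")))
  }
  if (!is.na(follow_up)) {
    md <- c(md, "", sprintf("Follow-up evaluation due: %s", follow_up))
  }
  if (isTRUE(sug$low_information)) {
    md <- c(md, "", "Note: low-information session (all answers 'do not know').")
  }
  if (isFALSE(session$evaluator_accepted)) {
    md <- c(md, "", sprintf("Evaluator declined the suggestion: %s", session$decline_reason))
  }
  structure(list(data = data, markdown = paste(md, collapse = "\n")),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(x$markdown, "\n")
  invisible(x)
}

#' @export
as.character.screening_report <- function(x, ...) x$markdown
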