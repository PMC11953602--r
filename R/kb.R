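#' Construct a milestone knowledge base
#'
#' A knowledge base is a small graph linking month nodes (ages in completed
#' months) to screening questions and, through each question's severity class,
#' to the graded suggestions an assessment can produce. Every question belongs
#' to exactly one language domain (see [language_domains()]), applies to one
#' or more months, and is either a *warning* item (failure prompts a repeat
#' assessment) or an *alarm* item (failure prompts direct referral).
#'
#' The constructor normalizes types and checks basic structure (unique ids,
#' well-formed months); the content rules — 3-6 questions per covered month,
#' month membership, domain quotas, sensory-reception items confined to the
#' first year — are checked by [validate_kb()], which reports violations as
#' data rather than raising errors.
#'
#' @param coverage_range Integer vector `c(min_month, max_month)`, a closed
#'   1-based range of completed months.
#' @param questions List of question objects as built by [kb_question()].
#' @param months List of month nodes, each `list(month =, question_ids =)`.
#' @param quotas Named integer vector of declared per-domain question counts;
#'   defaults to the observed per-domain counts.
#' @param metadata List of scalar metadata (e.g. `version`).
#' @return An object of class `knowledge_base`.
#' @seealso [validate_kb()], [load_kb()], [write_kb()], [gen_kb()]
#' @export
knowledge_base <- function(coverage_range, questions, months, quotas = NULL,
                           metadata = list(version = "1")) {
  coverage_range <- as.integer(coverage_range)
  if (length(coverage_range) != 2L || anyNA(coverage_range) ||
      coverage_range[1] < 1L || coverage_range[2] < coverage_range[1]) {
    stop("coverage_range must be c(min_month, max_month) with 1 <= min <= max")
  }
  questions <- lapply(questions, function(q) {
    kb_question(q$id, q$text, q$domain, q$applicable_months, q$severity_class)
  })
  ids <- vapply(questions, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate question id: ", ids[duplicated(ids)][1])
  }
  names(questions) <- ids
  months <- lapply(months, function(m) {
    list(month = as.integer(m$month),
         question_ids = as.character(unlist(m$question_ids)))
  })
  mm <- vapply(months, `[[`, 1L, "month")
  if (anyNA(mm) || anyDuplicated(mm)) stop("month nodes must have unique integer months")
  months <- months[order(mm)]
  names(months) <- as.character(sort(mm))
  if (is.null(quotas)) {
    dom <- vapply(questions, `[[`, "", "domain")
    quotas <- vapply(language_domains(), function(d) sum(dom == d), 0L)
  }
  # tolerate partial/unordered quota names
  q2 <- stats::setNames(integer(4), language_domains())
  keep <- intersect(names(quotas), language_domains())
  q2[keep] <- as.integer(quotas[keep])
  structure(list(coverage_range = coverage_range,
                 quotas = q2,
                 questions = questions,
                 months = months,
                 metadata = canonical_metadata(metadata)),
            class = "knowledge_base")
}

#' @rdname knowledge_base
#' @param id Stable string key of the question.
#' @param text Human-readable prompt.
#' @param domain One of [language_domains()].
#' @param applicable_months Integer vector of months (>= 1) the question
#'   applies to.
#' @param severity_class `"warning"` or `"alarm"`.
#' @export
kb_question <- function(id, text, domain, applicable_months, severity_class) {
  structure(list(id = as.character(id), text = as.character(text),
                 domain = as.character(domain),
                 applicable_months = sort(unique(as.integer(unlist(applicable_months)))),
                 severity_class = as.character(severity_class)),
            class = "kb_question")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base> months %d-%d, %d questions\n",
              x$coverage_range[1], x$coverage_range[2], length(x$questions)))
  cat("  domain quotas:",
      paste(sprintf("%s=%d", names(x$quotas), x$quotas), collapse = ", "), "\n")
  v <- validate_kb(x)
  cat(if (nrow(v) == 0) "  valid\n" else sprintf("  %d violation(s); see validate_kb()\n", nrow(v)))
  invisible(x)
}

#' Validate a knowledge base
#'
#' Checks every content invariant and returns the violations found as a data
#' frame (zero rows when the knowledge base is valid). Violations are data,
#' not errors: each row names the rule broken and where.
#'
#' Rules checked: every month in the coverage range has a month node
#' (`missing_month`); each covered month lists between `min_per_month` and
#' `max_per_month` questions (`questions_per_month`); every listed question id
#' resolves (`dangling_reference`) and its question applies to that month
#' (`month_membership`); each question has a known domain (`domain`), a known
#' severity class (`severity_class`) and non-empty applicable months inside
#' coverage (`applicable_months`); sensory-reception questions apply only to
#' months 1-12 (`sensory_range`); and per-domain question counts equal the
#' declared quotas (`quota`).
#'
#' @param kb A [knowledge_base()].
#' @param min_per_month,max_per_month Allowed per-month question counts
#'   (default 3 and 6, the expert panel's rule).
#' @return Data frame with columns `rule`, `location`, `message`.
#' @export
#' @examples
#' kb <- gen_kb(kb_gen_config(seed = 1))
#' nrow(validate_kb(kb)) # 0
validate_kb <- function(kb, min_per_month = 3L, max_per_month = 6L) {
  stopifnot(inherits(kb, "knowledge_base"))
  out <- list()
  bad <- function(rule, location, message) {
    out[[length(out) + 1L]] <<- data.frame(rule = rule, location = location,
                                           message = message)
  }
  cov <- kb$coverage_range
  covered <- cov[1]:cov[2]
  have <- vapply(kb$months, `[[`, 1L, "month")
  for (m in setdiff(covered, have)) {
    bad("missing_month", paste0("month ", m), "no month node inside coverage range")
  }
  for (node in kb$months) {
    m <- node$month
    loc <- paste0("month ", m)
    n <- length(node$question_ids)
    if (m %in% covered && (n < min_per_month || n > max_per_month)) {
      bad("questions_per_month", loc,
          sprintf("%d questions; expected %d-%d per month", n,
                  min_per_month, max_per_month))
    }
    for (id in node$question_ids) {
      q <- kb$questions[[id]]
      if (is.null(q)) {
        bad("dangling_reference", loc, paste0("question '", id, "' is not defined"))
      } else if (!(m %in% q$applicable_months)) {
        bad("month_membership", loc,
            paste0("question '", id, "' does not list month ", m,
                   " among its applicable months"))
      }
    }
  }
  for (q in kb$questions) {
    loc <- paste0("question ", q$id)
    if (!(q$domain %in% language_domains())) {
      bad("domain", loc, paste0("unknown domain '", q$domain, "'"))
    }
    if (!(q$severity_class %in% c("warning", "alarm"))) {
      bad("severity_class", loc, paste0("unknown severity class '", q$severity_class, "'"))
    }
    if (length(q$applicable_months) == 0L) {
      bad("applicable_months", loc, "applicable_months is empty")
    } else if (any(q$applicable_months < cov[1] | q$applicable_months > cov[2])) {
      bad("applicable_months", loc, "applicable months outside coverage range")
    }
    if (identical(q$domain, "sensory_reception") &&
        length(q$applicable_months) > 0L && any(q$applicable_months > 12L)) {
      bad("sensory_range", loc,
          "sensory_reception questions are administered only in months 1-12")
    }
  }
  dom <- vapply(kb$questions, `[[`, "", "domain")
  for (d in language_domains()) {
    n <- sum(dom == d)
    if (n != kb$quotas[[d]]) {
      bad("quota", paste0("domain ", d),
          sprintf("%d questions but declared quota is %d", n, kb$quotas[[d]]))
    }
  }
  if (length(out) == 0) {
    data.frame(rule = character(), location = character(), message = character())
  } else {
    do.call(rbind, out)
  }
}

#' Read and write a knowledge base as JSON
#'
#' The on-disk format is a JSON document with top-level keys `coverage_range`,
#' `quotas`, `questions` (array of `{id, text, domain, applicable_months,
#' severity_class}`) and `months` (array of `{month, question_ids}`), plus an
#' optional `metadata` object. A schema description ships with the package at
#' `system.file("extdata", "kb-schema.json", package = "langscreen")`.
#' `load_kb(write_kb(kb, path))` is the identity.
#'
#' `load_kb()` raises an error on structural problems (missing keys, a month
#' node referencing an undefined question); content-rule violations are left
#' to [validate_kb()].
#'
#' @param source Path to a JSON file, or a JSON string.
#' @return `load_kb()`: a [knowledge_base()].
#' @export
load_kb <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  raw <- tryCatch(jsonlite::fromJSON(source, simplifyVector = FALSE),
                  error = function(e) stop("knowledge base is not valid JSON: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(raw)) stop("knowledge base document is not a JSON object")
  need <- c("coverage_range", "questions", "months")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("knowledge base document lacks key(s): ",
                         paste(miss, collapse = ", "))
  questions <- lapply(raw$questions, function(q) {
    f <- setdiff(c("id", "text", "domain", "applicable_months", "severity_class"),
                 names(q))
    if (length(f)) stop("question entry missing field(s) ",
                        paste(f, collapse = ", "),
                        if (!is.null(q$id)) paste0(" (question '", q$id, "')"))
    q
  })
  months <- lapply(raw$months, function(m) {
    if (is.null(m$month) || is.null(m$question_ids)) {
      stop("month entry must have fields 'month' and 'question_ids'")
    }
    m
  })
  quotas <- if (!is.null(raw$quotas)) unlist(raw$quotas) else NULL
  kb <- knowledge_base(coverage_range = unlist(raw$coverage_range),
                       questions = questions, months = months, quotas = quotas,
                       metadata = if (is.null(raw$metadata)) list(version = "1") else raw$metadata)
  ids <- names(kb$questions)
  for (node in kb$months) {
    dangling <- setdiff(node$question_ids, ids)
    if (length(dangling)) {
      stop(sprintf("month %d references undefined question id(s): %s",
                   node$month, paste(dangling, collapse = ", ")))
    }
  }
  kb
}

#' @rdname load_kb
#' @param kb A [knowledge_base()].
#' @param path Output file path.
#' @return `write_kb()`: `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  stopifnot(inherits(kb, "knowledge_base"))
  doc <- list(
    coverage_range = kb$coverage_range,
    quotas = as.list(kb$quotas),
    questions = lapply(unname(kb$questions), function(q) {
      list(id = q$id, text = q$text, domain = q$domain,
           applicable_months = I(q$applicable_months),
           severity_class = q$severity_class)
    }),
    months = lapply(unname(kb$months), function(m) {
      list(month = m$month, question_ids = I(m$question_ids))
    }),
    metadata = kb$metadata
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Questions attached to a month node
#'
#' Returns the questions of one month node in knowledge-base order. A question
#' linked to several months is returned for each of them.
#'
#' @param kb A [knowledge_base()].
#' @param month Integer month inside the coverage range.
#' @return List of question objects.
#' @export
questions_for_month <- function(kb, month) {
  stopifnot(inherits(kb, "knowledge_base"))
  month <- as.integer(month)
  cov <- kb$coverage_range
  if (length(month) != 1L || is.na(month) || month < cov[1] || month > cov[2]) {
    stop(sprintf("month %s is outside the coverage range [%d, %d]",
                 as.character(month), cov[1], cov[2]))
  }
  node <- kb$months[[as.character(month)]]
  if (is.null(node)) stop(sprintf("no month node for month %d", month))
  kb$questions[node$question_ids]
}

#' Export a knowledge base as graph CREATE statements
#'
#' Emits plain-text Cypher-style `CREATE` statements describing the
#' month-question-suggestion graph: one node per month, one per question, one
#' per suggestion type (always five), an `ASKS` relationship from each month
#' to each of its questions, and an `ON_FAILURE` relationship from each
#' question to the suggestion its isolated failure produces under the default
#' policy (alarm items point at referral, warning items at the 3-month
#' repeat). Node statements therefore number `|months| + |questions| + 5`, and
#' relationship statements `sum(questions per month) + |questions|`.
#'
#' @param kb A valid [knowledge_base()]; an invalid one is refused with its
#'   validation report.
#' @return A single character string of newline-separated statements.
#' @export
export_graph <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  v <- validate_kb(kb)
  if (nrow(v) > 0) {
    stop("knowledge base is invalid; first violation: [", v$rule[1], "] ",
         v$location[1], ": ", v$message[1])
  }
  esc <- function(s) gsub("'", "\\\\'", s)
  var <- function(s) gsub("[^A-Za-z0-9_]", "_", s)
  lines <- character()
  for (m in kb$months) {
    lines <- c(lines, sprintf("CREATE (m%d:Month {month: %d});", m$month, m$month))
  }
  for (q in kb$questions) {
    lines <- c(lines, sprintf(
      "CREATE (%s:Question {id: '%s', domain: '%s', severity: '%s'});",
      var(q$id), esc(q$id), q$domain, q$severity_class))
  }
  for (s in suggestion_types()) {
    lines <- c(lines, sprintf("CREATE (s_%s:Suggestion {type: '%s'});", s, s))
  }
  for (m in kb$months) {
    for (id in m$question_ids) {
      lines <- c(lines, sprintf("CREATE (m%d)-[:ASKS]->(%s);", m$month, var(id)))
    }
  }
  for (q in kb$questions) {
    target <- if (q$severity_class == "alarm") "refer_early_intervention" else "repeat_3mo"
    lines <- c(lines, sprintf("CREATE (%s)-[:ON_FAILURE]->(s_%s);", var(q$id), target))
  }
  paste(lines, collapse = "\n")
}
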