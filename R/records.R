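#' Evaluation record sets
#'
#' The tidy container feeding every summary statistic: a session-level table
#' (one row per assessment, with demographics, suggestion, severity class and
#' evaluator acceptance) and an optional answer-level table (one row per
#' question asked, with domain label and answer). `(child_id,
#' evaluation_date)` pairs must be unique and severity classes must be
#' consistent with the suggestions.
#'
#' @param sessions Data frame with columns `child_id`, `center`, `gender`,
#'   `birth_date`, `evaluation_date`, `age_months`, `suggestion`,
#'   `severity_class`, `accepted`, `decline_reason`.
#' @param answers Optional data frame with columns `child_id`,
#'   `evaluation_date`, `age_months`, `question_id`, `domain`,
#'   `severity_class`, `answer`.
#' @param metadata List of provenance metadata (seeds, source).
#' @return An object of class `evaluation_records`.
#' @export
evaluation_records <- function(sessions, answers = NULL, metadata = list()) {
  if (is.null(sessions)) sessions <- empty_sessions_df()
  need <- c("child_id", "center", "gender", "birth_date", "evaluation_date",
            "age_months", "suggestion", "severity_class", "accepted",
            "decline_reason")
  miss <- setdiff(need, names(sessions))
  if (length(miss)) stop("sessions lacks column(s): ", paste(miss, collapse = ", "))
  sessions$birth_date <- as.Date(sessions$birth_date)
  sessions$evaluation_date <- as.Date(sessions$evaluation_date)
  sessions$age_months <- as.integer(sessions$age_months)
  key <- paste(sessions$child_id, sessions$evaluation_date)
  if (anyDuplicated(key)) {
    stop("duplicate (child_id, evaluation_date) pair: ", key[duplicated(key)][1])
  }
  if (nrow(sessions) > 0) {
    expect <- suggestion_severity(sessions$suggestion)
    bad <- which(expect != sessions$severity_class)
    if (length(bad)) {
      stop(sprintf("severity_class '%s' inconsistent with suggestion '%s' (row %d)",
                   sessions$severity_class[bad[1]], sessions$suggestion[bad[1]], bad[1]))
    }
    undec <- !is.na(sessions$accepted) & !sessions$accepted &
      (is.na(sessions$decline_reason) | !nzchar(sessions$decline_reason))
    if (any(undec)) stop("declined session without a decline_reason (row ",
                         which(undec)[1], ")")
  }
  if (!is.null(answers) && nrow(answers) > 0) {
    answers$evaluation_date <- as.Date(answers$evaluation_date)
    bad <- setdiff(answers$answer, answer_levels())
    if (length(bad)) stop("invalid answer value(s): ", paste(unique(bad), collapse = ", "))
  }
  rownames(sessions) <- NULL
  structure(list(sessions = sessions, answers = answers,
                 metadata = metadata),
            class = "evaluation_records")
}

empty_sessions_df <- function() {
  data.frame(child_id = character(), center = character(), gender = character(),
             birth_date = as.Date(character()),
             evaluation_date = as.Date(character()), age_months = integer(),
             suggestion = character(), severity_class = character(),
             accepted = logical(), decline_reason = character())
}

#' @export
print.evaluation_records <- function(x, ...) {
  cat(sprintf("<evaluation_records> %d sessions, %d children%s\n",
              nrow(x$sessions), length(unique(x$sessions$child_id)),
              if (!is.null(x$answers)) sprintf(", %d answers", nrow(x$answers)) else ""))
  invisible(x)
}

#' @export
as.data.frame.evaluation_records <- function(x, ...) x$sessions

#' Read and write evaluation record sets
#'
#' Two serializations are supported. The CSV dialect is a single flat file
#' with a `record_type` column: `"session"` rows carry the session-level
#' fields and `"answer"` rows one question each. The JSON dialect nests the
#' answers inside each session object under a `metadata`-bearing envelope.
#' `read_records(write_records(x, path))` reproduces the record set.
#'
#' @param records An [evaluation_records()] object.
#' @param path Output file; format is inferred from the extension (`.csv` or
#'   `.json`) unless `format` is given.
#' @param format `"csv"` or `"json"`.
#' @return `write_records()` returns `path` invisibly; `read_records()`
#'   returns an [evaluation_records()].
#' @export
write_records <- function(records, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(records, "evaluation_records"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  s <- records$sessions
  a <- records$answers
  if (format == "csv") {
    scols <- c("child_id", "center", "gender", "birth_date", "evaluation_date",
               "age_months", "suggestion", "severity_class", "accepted",
               "decline_reason")
    acols <- c("child_id", "evaluation_date", "age_months", "question_id",
               "domain", "answer")
    flat_s <- data.frame(record_type = rep("session", nrow(s)), s[scols],
                         question_id = NA_character_, domain = NA_character_,
                         answer = NA_character_)
    if (!is.null(a) && nrow(a) > 0) {
      flat_a <- data.frame(record_type = "answer",
                           child_id = a$child_id, center = NA_character_,
                           gender = NA_character_, birth_date = as.Date(NA),
                           evaluation_date = a$evaluation_date,
                           age_months = a$age_months,
                           suggestion = NA_character_,
                           severity_class = a$severity_class,
                           accepted = NA, decline_reason = NA_character_,
                           question_id = a$question_id, domain = a$domain,
                           answer = a$answer)
      flat_s <- rbind(flat_s, flat_a)
    }
    utils::write.csv(flat_s, path, row.names = FALSE)
  } else {
    doc <- list(metadata = records$metadata,
                sessions = lapply(seq_len(nrow(s)), function(i) {
                  row <- as.list(s[i, ])
                  row$birth_date <- as.character(row$birth_date)
                  row$evaluation_date <- as.character(row$evaluation_date)
                  if (!is.null(a)) {
                    sub <- a[a$child_id == s$child_id[i] &
                               a$evaluation_date == s$evaluation_date[i], ]
                    row$answers <- lapply(seq_len(nrow(sub)), function(j) {
                      list(question_id = sub$question_id[j], domain = sub$domain[j],
                           severity_class = sub$severity_class[j],
                           answer = sub$answer[j])
                    })
                  }
                  row
                }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    flat <- utils::read.csv(path, stringsAsFactors = FALSE)
    s <- flat[flat$record_type == "session", , drop = FALSE]
    a <- flat[flat$record_type == "answer", , drop = FALSE]
    sessions <- data.frame(child_id = s$child_id, center = s$center,
                           gender = s$gender, birth_date = as.Date(s$birth_date),
                           evaluation_date = as.Date(s$evaluation_date),
                           age_months = as.integer(s$age_months),
                           suggestion = s$suggestion,
                           severity_class = s$severity_class,
                           accepted = as.logical(s$accepted),
                           decline_reason = as.character(s$decline_reason))
    answers <- if (nrow(a) > 0) {
      data.frame(child_id = a$child_id,
                 evaluation_date = as.Date(a$evaluation_date),
                 age_months = as.integer(a$age_months),
                 question_id = a$question_id, domain = a$domain,
                 severity_class = a$severity_class, answer = a$answer)
    }
    evaluation_records(sessions, answers, metadata = list(source = path))
  } else {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    srows <- lapply(doc$sessions, function(row) {
      data.frame(child_id = row$child_id, center = row$center,
                 gender = row$gender, birth_date = as.Date(row$birth_date),
                 evaluation_date = as.Date(row$evaluation_date),
                 age_months = as.integer(row$age_months),
                 suggestion = row$suggestion, severity_class = row$severity_class,
                 accepted = isTRUE(row$accepted),
                 decline_reason = if (is.null(row$decline_reason)) NA_character_ else row$decline_reason)
    })
    arows <- lapply(doc$sessions, function(row) {
      if (is.null(row$answers) || length(row$answers) == 0) return(NULL)
      do.call(rbind, lapply(row$answers, function(ans) {
        data.frame(child_id = row$child_id,
                   evaluation_date = as.Date(row$evaluation_date),
                   age_months = as.integer(row$age_months),
                   question_id = ans$question_id, domain = ans$domain,
                   severity_class = ans$severity_class, answer = ans$answer)
      }))
    })
    arows <- arows[!vapply(arows, is.null, TRUE)]
    evaluation_records(do.call(rbind, srows),
                       if (length(arows)) do.call(rbind, arows),
                       metadata = if (is.null(doc$metadata)) list() else doc$metadata)
  }
}

#' Filter an evaluation record set
#'
#' Row-subsets the session table (and the matching answer rows) by severity
#' class, suggestion type, center or gender.
#'
#' @param records An [evaluation_records()].
#' @param severity,suggestion,center,gender Optional values to keep.
#' @return A filtered [evaluation_records()].
#' @export
filter_records <- function(records, severity = NULL, suggestion = NULL,
                           center = NULL, gender = NULL) {
  stopifnot(inherits(records, "evaluation_records"))
  s <- records$sessions
  keep <- rep(TRUE, nrow(s))
  if (!is.null(severity)) keep <- keep & s$severity_class %in% severity
  if (!is.null(suggestion)) keep <- keep & s$suggestion %in% suggestion
  if (!is.null(center)) keep <- keep & s$center %in% center
  if (!is.null(gender)) keep <- keep & s$gender %in% gender
  subset_records(records, keep)
}

subset_records <- function(records, keep) {
  s <- records$sessions[keep, , drop = FALSE]
  a <- records$answers
  if (!is.null(a) && nrow(a) > 0) {
    key <- paste(s$child_id, s$evaluation_date)
    a <- a[paste(a$child_id, a$evaluation_date) %in% key, , drop = FALSE]
    rownames(a) <- NULL
  }
  evaluation_records(s, a, metadata = records$metadata)
}
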