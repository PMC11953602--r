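#' Keep only each child's latest assessment
#'
#' When summarizing outcomes, children assessed more than once contribute
#' only their most recent session.
#'
#' @param records An [evaluation_records()].
#' @return An [evaluation_records()] with one session per distinct child (the
#'   maximal evaluation date).
#' @export
latest_per_child <- function(records) {
  stopifnot(inherits(records, "evaluation_records"))
  s <- records$sessions
  if (nrow(s) == 0) return(records)
  ord <- order(s$child_id, s$evaluation_date, decreasing = c(FALSE, TRUE),
               method = "radix")
  keep_rows <- !duplicated(s$child_id[ord])
  keep <- logical(nrow(s))
  keep[ord[keep_rows]] <- TRUE
  subset_records(records, keep)
}

#' Distribution of suggestions
#'
#' Counts and percentages of each suggestion type over a record set, in
#' severity order. Percentages use the record count as base and are reported
#' to one decimal (the raw fraction is included alongside).
#'
#' @param records An [evaluation_records()].
#' @return Data frame with columns `suggestion`, `n`, `pct`, `frac`; zero
#'   rows for an empty record set.
#' @export
suggestion_distribution <- function(records) {
  stopifnot(inherits(records, "evaluation_records"))
  s <- records$sessions
  if (nrow(s) == 0) {
    return(data.frame(suggestion = character(), n = integer(), pct = numeric(),
                      frac = numeric()))
  }
  n <- vapply(suggestion_types(), function(t) sum(s$suggestion == t), 0L)
  frac <- n / nrow(s)
  data.frame(suggestion = suggestion_types(), n = unname(n),
             pct = round(100 * unname(frac), 1), frac = unname(frac),
             row.names = NULL)
}

#' Stratified counts and rates
#'
#' Cross-tabulates sessions by one or more grouping keys. Cell counts always
#' conserve the grand total, and percentages use the full record count as
#' base (so, e.g., an alarm-by-gender table expresses each cell as a share of
#' all assessments, the convention of the study's gender table). To tabulate
#' only one severity class, filter first with [filter_records()]; the
#' percentages then use the filtered total as base.
#'
#' @param records An [evaluation_records()].
#' @param by Character vector of grouping keys among `"gender"`, `"center"`,
#'   `"age_band"`, `"month"`, `"severity"`, `"suggestion"`.
#' @param drop_empty Drop zero-count cells (default `TRUE`; totals are
#'   unaffected).
#' @return Data frame with the grouping columns plus `n`, `pct`, `frac`.
#' @export
rate_by <- function(records, by, drop_empty = TRUE) {
  stopifnot(inherits(records, "evaluation_records"))
  known <- c(gender = "gender", center = "center", age_band = "age_band",
             month = "month", severity = "severity_class",
             suggestion = "suggestion")
  bad <- setdiff(by, names(known))
  if (length(bad)) stop("unknown grouping key(s): ", paste(bad, collapse = ", "),
                        " (known: ", paste(names(known), collapse = ", "), ")")
  s <- records$sessions
  s$age_band <- as.character(age_band(s$age_months))
  s$month <- s$age_months
  cols <- lapply(unname(known[by]), function(col) factor(s[[col]]))
  names(cols) <- by
  tab <- as.data.frame(table(cols), stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n"
  if (drop_empty) tab <- tab[tab$n > 0, , drop = FALSE]
  total <- nrow(s)
  tab$frac <- if (total > 0) tab$n / total else NA_real_
  tab$pct <- round(100 * tab$frac, 1)
  rownames(tab) <- NULL
  tab[, c(by, "n", "pct", "frac")]
}

#' Evaluator concordance (accuracy)
#'
#' The fraction of suggestions the evaluators accepted: accepted count over
#' total assessments, reported as a percentage to two decimals. With `by =
#' "suggestion"` a per-type breakdown of accepted and declined counts is
#' included (percentages against the grand total).
#'
#' @param records An [evaluation_records()] whose `accepted` field is set on
#'   every row.
#' @param by Optional grouping (`"suggestion"`, `"gender"`, `"center"`,
#'   `"age_band"`).
#' @return A list with `accepted_n`, `declined_n`, `total`, `frac` and `pct`,
#'   plus a `by_table` data frame when `by` is given.
#' @export
accuracy <- function(records, by = NULL) {
  stopifnot(inherits(records, "evaluation_records"))
  s <- records$sessions
  if (nrow(s) == 0) stop("accuracy is undefined for an empty record set")
  if (anyNA(s$accepted)) stop("accepted is not set on every session")
  out <- list(accepted_n = sum(s$accepted), declined_n = sum(!s$accepted),
              total = nrow(s), frac = mean(s$accepted),
              pct = round(100 * mean(s$accepted), 2))
  if (!is.null(by)) {
    known <- c(suggestion = "suggestion", gender = "gender", center = "center",
               age_band = "age_band")
    if (!(by %in% names(known))) stop("unknown grouping key: ", by)
    s$age_band <- as.character(age_band(s$age_months))
    g <- s[[known[[by]]]]
    levels <- if (by == "suggestion") intersect(suggestion_types(), unique(g)) else sort(unique(g))
    out$by_table <- do.call(rbind, lapply(levels, function(l) {
      sub <- s[g == l, ]
      data.frame(group = l, declined_n = sum(!sub$accepted),
                 accepted_n = sum(sub$accepted),
                 declined_pct = round(100 * sum(!sub$accepted) / nrow(s), 2),
                 accepted_pct = round(100 * sum(sub$accepted) / nrow(s), 2))
    }))
    names(out$by_table)[1] <- by
  }
  out
}

#' Per-domain answer distributions by age band
#'
#' Counts of yes/no/dk answers per language domain within each age band.
#' Sensory-reception items are administered only in the first year; an
#' answer to one recorded past 12 months triggers a validation warning.
#'
#' @param records An [evaluation_records()] carrying an answer table.
#' @param breaks Age-band upper bounds passed to [age_band()].
#' @return Data frame with columns `age_band`, `domain`, `answer`, `n`.
#' @export
domain_response_distribution <- function(records, breaks = c(12L, 24L)) {
  stopifnot(inherits(records, "evaluation_records"))
  a <- records$answers
  if (is.null(a) || nrow(a) == 0) {
    return(data.frame(age_band = character(), domain = character(),
                      answer = character(), n = integer()))
  }
  late_sens <- a$domain == "sensory_reception" & a$age_months > 12L
  if (any(late_sens)) {
    warning(sprintf("%d sensory_reception answer(s) recorded past month 12",
                    sum(late_sens)))
  }
  tab <- as.data.frame(table(age_band = age_band(a$age_months, breaks),
                             domain = factor(a$domain, language_domains()),
                             answer = factor(a$answer, answer_levels())),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n"
  rownames(tab) <- NULL
  tab
}

#' Suggestion outcomes by birth quarter
#'
#' Nursery classes group children by birth year, so children born in the last
#' calendar quarter are the youngest of their class. This tabulates
#' suggestion counts by birth year and calendar birth quarter.
#'
#' @param records An [evaluation_records()].
#' @return Data frame with columns `birth_year`, `quarter`, `suggestion`,
#'   `n`.
#' @export
birth_quarter_analysis <- function(records) {
  stopifnot(inherits(records, "evaluation_records"))
  s <- records$sessions
  if (nrow(s) == 0) {
    return(data.frame(birth_year = integer(), quarter = integer(),
                      suggestion = character(), n = integer()))
  }
  year <- as.integer(format(s$birth_date, "%Y"))
  quarter <- (as.integer(format(s$birth_date, "%m")) - 1L) %/% 3L + 1L
  tab <- as.data.frame(table(birth_year = year, quarter = quarter,
                             suggestion = factor(s$suggestion, suggestion_types())),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n"
  tab$birth_year <- as.integer(tab$birth_year)
  tab$quarter <- as.integer(tab$quarter)
  tab <- tab[tab$n > 0 | TRUE, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Assessments per child
#'
#' Mean and standard deviation of the number of assessments each distinct
#' child received (computed on the full record set, before
#' [latest_per_child()] filtering).
#'
#' @param records An [evaluation_records()].
#' @return List with `mean`, `sd`, `n_children`, `n_assessments`.
#' @export
assessments_per_child <- function(records) {
  stopifnot(inherits(records, "evaluation_records"))
  s <- records$sessions
  if (nrow(s) == 0) stop("assessments_per_child is undefined for an empty record set")
  counts <- as.integer(table(s$child_id))
  list(mean = mean(counts), sd = stats::sd(counts),
       n_children = length(counts), n_assessments = nrow(s))
}

#' Finite-population sample size
#'
#' Required sample size for estimating a prevalence `p` with margin of error
#' `e` at the confidence level of quantile `z`, with the finite population
#' correction: `n0 = z^2 p (1 - p) / e^2`, then
#' `n = n0 / (1 + (n0 - 1) / N)`, rounded up. The correction never increases
#' the size (`n <= ceiling(n0)`), and `n` approaches `n0` as `N` grows.
#'
#' @param N Population size (may be `Inf` for no correction).
#' @param p Expected prevalence in (0, 1).
#' @param z Normal quantile (default 1.96, a 95% confidence level).
#' @param e Margin of error (> 0).
#' @return Integer required sample size.
#' @export
#' @examples
#' sample_size(150000, 0.07, 1.96, 0.05) # 100
#' sample_size(Inf, 0.5) # 385
sample_size <- function(N, p, z = 1.96, e = 0.05) {
  if (!is.numeric(N) || length(N) != 1 || N < 1) stop("N must be >= 1")
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (!is.numeric(e) || e <= 0) stop("e must be positive")
  if (!is.numeric(z) || z <= 0) stop("z must be positive")
  n0 <- z^2 * p * (1 - p) / e^2
  n <- if (is.finite(N)) n0 / (1 + (n0 - 1) / N) else n0
  as.integer(ceiling(n))
}
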