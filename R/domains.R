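#' Language development domains
#'
#' The four areas of speech and language development assessed by the screening
#' knowledge base: sensory reception (hearing, administered only in the first
#' year of life), language perception (receiving, processing and comprehending
#' linguistic information), production (phonology, morphosyntax, semantics,
#' non-verbal communication) and pragmatics (conversational skills, coherence
#' and the social use of language).
#'
#' @return Character vector of the four domain names, in canonical order.
#' @export
#' @examples
#' language_domains()
language_domains <- function() {
  c("sensory_reception", "language_perception", "production", "pragmatics")
}

#' Graded screening suggestions
#'
#' The five possible outcomes of a screening session, in increasing order of
#' severity: typical development, repeat the assessment within 3, 2 or 1
#' months, or refer the child to an early intervention centre. The order is
#' total: `suggestion_rank()` gives the position on the severity scale, and
#' `suggestion_severity()` maps each outcome to its severity class
#' (`"none"`, `"warning"` for the repeat outcomes, `"alarm"` for referral).
#'
#' @return `suggestion_types()`: character vector of the five outcome names in
#'   increasing severity order.
#' @export
#' @examples
#' suggestion_types()
#' suggestion_rank("repeat_2mo") > suggestion_rank("typical_development")
suggestion_types <- function() {
  c("typical_development", "repeat_3mo", "repeat_2mo", "repeat_1mo",
    "refer_early_intervention")
}

#' @rdname suggestion_types
#' @param type Character vector of suggestion type names.
#' @return `suggestion_rank()`: integer severity rank (1 = lowest).
#' @export
suggestion_rank <- function(type) {
  r <- match(type, suggestion_types())
  if (anyNA(r)) {
    stop("unknown suggestion type: ",
         paste(setdiff(type, suggestion_types()), collapse = ", "))
  }
  r
}

#' @rdname suggestion_types
#' @return `suggestion_severity()`: one of `"none"`, `"warning"`, `"alarm"`
#'   per element of `type`.
#' @export
suggestion_severity <- function(type) {
  suggestion_rank(type) # validates
  ifelse(type == "typical_development", "none",
         ifelse(type == "refer_early_intervention", "alarm", "warning"))
}

#' @rdname suggestion_types
#' @return `follow_up_months()`: the repeat interval in months (3, 2 or 1) for
#'   the repeat outcomes, `NA` otherwise.
#' @export
follow_up_months <- function(type) {
  suggestion_rank(type)
  k <- c(typical_development = NA_integer_, repeat_3mo = 3L, repeat_2mo = 2L,
         repeat_1mo = 1L, refer_early_intervention = NA_integer_)
  unname(k[type])
}

#' Answer levels
#'
#' The three admissible answers to a screening question: `"yes"` (the child
#' performs the action), `"no"` (the child does not), and `"dk"`
#' (do not know / no answer).
#'
#' @return Character vector of the three levels.
#' @export
answer_levels <- function() c("yes", "no", "dk")

#' Age bands used for cohort stratification
#'
#' Maps an age in completed months to the preschool-grade bands used
#' throughout the summary statistics: up to 12 months, 13-24 months, and 25
#' months and over (labelled `"25-36"`; the handful of children evaluated at
#' 37-38 months fall in this grade).
#'
#' @param age_months Integer vector of ages in completed months.
#' @param breaks Upper bounds of the lower bands (default `c(12, 24)`).
#' @return Factor with levels `"<=12"`, `"13-24"`, `"25-36"`.
#' @export
#' @examples
#' age_band(c(7, 18, 30, 37))
age_band <- function(age_months, breaks = c(12L, 24L)) {
  labels <- c("<=12", "13-24", "25-36")
  cut(as.integer(age_months), breaks = c(-Inf, breaks, Inf), labels = labels)
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Canonicalize a metadata list for byte-stable JSON round-trips: whole-number
# scalars become integers (matching what jsonlite parses back).
canonical_metadata <- function(metadata) {
  lapply(metadata, function(x) {
    if (is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) &&
        abs(x) < .Machine$integer.max) {
      as.integer(x)
    } else {
      x
    }
  })
}
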