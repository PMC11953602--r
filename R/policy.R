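#' Decision policy for a screening session
#'
#' The decision rule has two layers. Any *alarm*-class question answered "no"
#' triggers an immediate referral suggestion, whatever else was answered.
#' Otherwise the number of *warning*-class "no" answers is mapped through a
#' repeat-interval ladder: with the default ladder, 0 failures mean typical
#' development, 1 failure a repeat within 3 months, 2 failures within 2
#' months, and 3 or more failures within 1 month. The graded intervals
#' themselves (1, 2 and 3 months) are fixed screening outcomes; the mapping
#' from failure count to interval is configurable here because only the
#' intervals, not the mapping, are fixed by the screening protocol.
#'
#' "Do not know" answers never count as failures by default — a missing
#' observation should not escalate a suggestion. Set `dk_as_no = TRUE` to
#' treat them as failures.
#'
#' @param ladder Character vector of length 3: the suggestion for 1, 2 and
#'   three-or-more warning failures. Each entry must be a repeat-type
#'   suggestion.
#' @param dk_as_no Should "dk" answers count as failures? Default `FALSE`.
#' @return An object of class `decision_policy`.
#' @seealso [decide()]
#' @export
#' @examples
#' decision_policy() # the default ladder
decision_policy <- function(ladder = c("repeat_3mo", "repeat_2mo", "repeat_1mo"),
                            dk_as_no = FALSE) {
  repeats <- setdiff(suggestion_types(),
                     c("typical_development", "refer_early_intervention"))
  if (length(ladder) != 3L || !all(ladder %in% repeats)) {
    stop("ladder must be 3 repeat-type suggestions (for 1, 2 and >=3 failures)")
  }
  structure(list(ladder = as.character(ladder), dk_as_no = isTRUE(dk_as_no)),
            class = "decision_policy")
}

#' @export
print.decision_policy <- function(x, ...) {
  cat("<decision_policy>\n  alarm 'no' -> refer_early_intervention\n")
  cat(sprintf("  warning failures 1/2/>=3 -> %s\n", paste(x$ladder, collapse = "/")))
  cat(sprintf("  dk counts as failure: %s\n", x$dk_as_no))
  invisible(x)
}
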