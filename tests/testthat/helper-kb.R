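# Toy knowledge base with k questions on a single month node.
# severities: character vector of "warning"/"alarm", one per question.
toy_kb_single_month <- function(severities, month = 10L) {
  k <- length(severities)
  stopifnot(k >= 3, k <= 6)
  ids <- sprintf("t%02d", seq_len(k))
  doms <- rep(c("production", "pragmatics", "language_perception"), length.out = k)
  questions <- lapply(seq_len(k), function(i) {
    kb_question(ids[i], paste("toy item", i), doms[i], month, severities[i])
  })
  knowledge_base(c(month, month), questions,
                 list(list(month = month, question_ids = ids)))
}

# Two-month toy KB: 3 questions on each month, no sharing.
toy_kb_two_months <- function() {
  qs <- list(
    kb_question("a1", "item a1", "production", 5, "warning"),
    kb_question("a2", "item a2", "pragmatics", 5, "warning"),
    kb_question("a3", "item a3", "language_perception", 5, "alarm"),
    kb_question("b1", "item b1", "production", 6, "warning"),
    kb_question("b2", "item b2", "pragmatics", 6, "warning"),
    kb_question("b3", "item b3", "language_perception", 6, "alarm"))
  knowledge_base(c(5, 6), qs,
                 list(list(month = 5, question_ids = c("a1", "a2", "a3")),
                      list(month = 6, question_ids = c("b1", "b2", "b3"))))
}

# A child whose age at `eval_date` is exactly `age_months`.
toy_child <- function(age_months, eval_date = as.Date("2023-05-15"),
                      id = "tc01", gender = "female") {
  child_profile(id, month_add_t(eval_date, -age_months) - 3, gender = gender)
}

month_add_t <- function(date, k) {
  lt <- as.POSIXlt(as.Date(date))
  total <- lt$year * 12L + lt$mon + as.integer(k)
  as.Date(sprintf("%04d-%02d-%02d", total %/% 12L + 1900L, total %% 12L + 1L,
                  min(lt$mday, 28L)))
}

# Build a completed session on `kb` at the given month with the given answers
# (named by question id), and return decide()'s result.
run_decision <- function(kb, answers, month, policy = decision_policy()) {
  child <- toy_child(month)
  ses <- screening_session(child, kb, as.Date("2023-05-15"))
  ses <- answer_session(ses, answers)
  decide(kb, ses, policy)
}

# Independent brute-force oracle for the decision rule table, operating on
# raw answer/severity vectors only.
oracle_decide <- function(answers, severities,
                          ladder = c("repeat_3mo", "repeat_2mo", "repeat_1mo"),
                          dk_as_no = FALSE) {
  fail <- answers == "no" | (dk_as_no & answers == "dk")
  if (any(fail & severities == "alarm")) return("refer_early_intervention")
  w <- sum(fail & severities == "warning")
  if (w == 0) "typical_development"
  else if (w == 1) ladder[1]
  else if (w == 2) ladder[2]
  else ladder[3]
}

# All 3^k answer vectors over k questions.
all_answer_vectors <- function(k) {
  grid <- expand.grid(rep(list(answer_levels()), k), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ], use.names = FALSE))
}

# Parse a graph export back into node and edge tables (the parse-back oracle
# for export_graph).
parse_graph_statements <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  node_m <- regmatches(lines, regexec("^CREATE \\(([A-Za-z0-9_]+):(Month|Question|Suggestion) ", lines))
  nodes <- do.call(rbind, lapply(node_m, function(m) {
    if (length(m) == 3) data.frame(var = m[2], label = m[3])
  }))
  edge_m <- regmatches(lines, regexec("^CREATE \\(([A-Za-z0-9_]+)\\)-\\[:([A-Z_]+)\\]->\\(([A-Za-z0-9_]+)\\);$", lines))
  edges <- do.call(rbind, lapply(edge_m, function(m) {
    if (length(m) == 4) data.frame(from = m[2], rel = m[3], to = m[4])
  }))
  list(nodes = nodes, edges = edges)
}
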