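#' Configuration for the synthetic knowledge-base generator
#'
#' The real screening knowledge base is expert-authored and unpublished, so
#' the package ships a generator that emulates its documented shape: a closed
#' month coverage range (default 1-36), per-domain question quotas (default
#' 3/32/48/25, totalling 108), 3-6 questions per month, sensory-reception
#' items confined to months 1-12, a fraction of alarm-class items, and a
#' fraction of items spanning two consecutive months. Synthetic question
#' texts are placeholders; no clinical validity is claimed for generated
#' content.
#'
#' @param coverage_range Integer `c(min_month, max_month)`, default `c(1, 36)`.
#' @param quotas Named integer vector of per-domain question counts.
#' @param questions_per_month Allowed per-month count range, default `c(3, 6)`.
#' @param alarm_fraction Probability a question is alarm-class (default 0.25).
#' @param multi_month_fraction Probability a question is extended to the next
#'   month where capacity allows (default 0.15).
#' @param seed Integer RNG seed; the same configuration always yields a
#'   byte-identical knowledge base.
#' @return An object of class `kb_gen_config`.
#' @export
kb_gen_config <- function(coverage_range = c(1L, 36L),
                          quotas = c(sensory_reception = 3L,
                                     language_perception = 32L,
                                     production = 48L,
                                     pragmatics = 25L),
                          questions_per_month = c(3L, 6L),
                          alarm_fraction = 0.25,
                          multi_month_fraction = 0.15,
                          seed = 1L) {
  stopifnot(length(coverage_range) == 2L, length(questions_per_month) == 2L)
  if (alarm_fraction < 0 || alarm_fraction > 1 ||
      multi_month_fraction < 0 || multi_month_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  q <- stats::setNames(integer(4), language_domains())
  keep <- intersect(names(quotas), language_domains())
  if (length(keep) < length(quotas)) stop("quotas has unknown domain names")
  q[keep] <- as.integer(quotas[keep])
  if (any(q < 0)) stop("quotas must be non-negative")
  structure(list(coverage_range = as.integer(coverage_range), quotas = q,
                 questions_per_month = as.integer(questions_per_month),
                 alarm_fraction = alarm_fraction,
                 multi_month_fraction = multi_month_fraction,
                 seed = as.integer(seed)),
            class = "kb_gen_config")
}

#' Generate a synthetic knowledge base
#'
#' Places `sum(quotas)` questions on the covered months so that every month
#' carries a count inside the allowed range, sensory-reception items sit only
#' in months up to 12, per-domain counts equal the quotas exactly, and a
#' random subset of items additionally spans the following month. The result
#' always passes [validate_kb()]; infeasible configurations (quotas that
#' cannot fill every month with at least the minimum, or cannot fit sensory
#' items into the first year) raise an error.
#'
#' @param config A [kb_gen_config()].
#' @return A [knowledge_base()].
#' @export
#' @examples
#' kb <- gen_kb(kb_gen_config(seed = 7))
#' length(kb$questions) # 108
gen_kb <- function(config = kb_gen_config()) {
  stopifnot(inherits(config, "kb_gen_config"))
  cov <- config$coverage_range
  months <- cov[1]:cov[2]
  n_m <- length(months)
  total_q <- sum(config$quotas)
  qmin <- config$questions_per_month[1]
  qmax <- config$questions_per_month[2]
  if (total_q < qmin * n_m || total_q > qmax * n_m) {
    stop(sprintf("infeasible quotas: %d questions cannot give every one of %d months %d-%d questions",
                 total_q, n_m, qmin, qmax))
  }
  with_seed(config$seed, {
    # Even base allocation of one home month per question.
    cnt <- rep(total_q %/% n_m, n_m)
    extra <- total_q %% n_m
    if (extra > 0) {
      bump <- sample.int(n_m, extra)
      cnt[bump] <- cnt[bump] + 1L
    }
    slot_month <- rep(months, cnt)
    sens_ok <- slot_month <= min(12L, cov[2])
    n_sens <- config$quotas[["sensory_reception"]]
    if (sum(sens_ok) < n_sens) {
      stop("infeasible quotas: not enough first-year slots for sensory_reception questions")
    }
    domain <- character(total_q)
    sens_idx <- if (n_sens > 0) sample(which(sens_ok), n_sens) else integer()
    domain[sens_idx] <- "sensory_reception"
    rest <- setdiff(seq_len(total_q), sens_idx)
    pool <- rep(setdiff(language_domains(), "sensory_reception"),
                config$quotas[setdiff(language_domains(), "sensory_reception")])
    domain[rest] <- sample(pool)
    ord <- order(slot_month)
    slot_month <- slot_month[ord]
    domain <- domain[ord]
    ids <- sprintf("q%03d", seq_len(total_q))
    severity <- ifelse(stats::runif(total_q) < config$alarm_fraction, "alarm", "warning")
    node_count <- stats::setNames(cnt, months)
    applicable <- vector("list", total_q)
    extend <- stats::runif(total_q) < config$multi_month_fraction
    for (i in seq_len(total_q)) {
      m <- slot_month[i]
      app <- m
      nxt <- m + 1L
      if (extend[i] && nxt <= cov[2] &&
          (domain[i] != "sensory_reception" || nxt <= 12L) &&
          node_count[[as.character(nxt)]] < qmax) {
        app <- c(m, nxt)
        node_count[[as.character(nxt)]] <- node_count[[as.character(nxt)]] + 1L
      }
      applicable[[i]] <- app
    }
    questions <- lapply(seq_len(total_q), function(i) {
      kb_question(ids[i],
                  sprintf("Synthetic %s milestone item expected from month %d (%s)",
                          gsub("_", " ", domain[i]), slot_month[i], ids[i]),
                  domain[i], applicable[[i]], severity[i])
    })
    names(questions) <- ids
    month_nodes <- lapply(months, function(m) {
      in_m <- vapply(questions, function(q) m %in% q$applicable_months, TRUE)
      list(month = m, question_ids = ids[in_m])
    })
    kb <- knowledge_base(cov, questions, month_nodes, quotas = config$quotas,
                         metadata = list(version = "1",
                                         generator = "gen_kb",
                                         seed = config$seed,
                                         alarm_fraction = config$alarm_fraction,
                                         multi_month_fraction = config$multi_month_fraction))
    v <- validate_kb(kb, qmin, qmax)
    if (nrow(v) > 0) {
      stop("internal error: generated knowledge base is invalid: ", v$message[1])
    }
    kb
  })
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the field-study cohort: 218 children across a nursery
#' school (center 1, n=134) and a psychopedagogical centre (center 2, n=84),
#' 99 girls and 119 boys, stratified over the three preschool-grade age bands
#' with the exact center-by-gender-by-band cell counts of the study; 8
#' preterm births (<37 gestational weeks), 13 children with some birth
#' complication, 2 with a family history of neurodevelopmental disorder, and
#' 10 bilingual children (center 1 only). Demographic counts are assigned
#' exactly (stratified assignment, not sampling); randomness is confined to
#' which child gets which label, ages within bands, latent abilities and the
#' impairment indicator.
#'
#' @param n_children Total cohort size. When it differs from the sum of the
#'   default cells, cell counts are rescaled proportionally (largest
#'   remainder).
#' @param cells Optional integer array `[center, gender, band]` of exact cell
#'   counts; overrides `n_children` scaling.
#' @param age_ranges List of integer age ranges for the three bands; default
#'   6-12, 13-24, 25-36 months (the study enrolled from 6 months).
#' @param preterm_n,complication_n,family_history_n Exact label counts.
#' @param bilingual_n Exact count of bilingual children, assigned within
#'   center 1 only (the study recorded bilingual context only there).
#' @param p_imp Prevalence of the latent language impairment label (default
#'   0.10, the proportion of preschool children in the field expected to show
#'   language-acquisition difficulty).
#' @param study_start First evaluation date; anchors are spread over
#'   `study_days` days from it.
#' @param study_days Length of the enrolment window in days.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_children = 218L, cells = NULL,
                          age_ranges = list(6:12, 13:24, 25:36),
                          preterm_n = 8L, complication_n = 13L,
                          family_history_n = 2L, bilingual_n = 10L,
                          p_imp = 0.10,
                          study_start = as.Date("2023-03-01"),
                          study_days = 100L, seed = 1L) {
  base <- default_cohort_cells()
  if (is.null(cells)) {
    cells <- if (n_children == sum(base)) base else scale_cells(base, n_children)
    # default label counts follow the cohort size proportionally
    if (n_children != sum(base)) {
      f <- n_children / sum(base)
      if (missing(preterm_n)) preterm_n <- as.integer(round(preterm_n * f))
      if (missing(complication_n)) complication_n <- as.integer(round(complication_n * f))
      if (missing(family_history_n)) family_history_n <- as.integer(round(family_history_n * f))
      if (missing(bilingual_n)) bilingual_n <- as.integer(round(bilingual_n * f))
      complication_n <- max(complication_n, preterm_n)
    }
  } else {
    storage.mode(cells) <- "integer"
    if (is.null(dimnames(cells))) dimnames(cells) <- dimnames(base)
  }
  if (sum(cells) != n_children) {
    stop(sprintf("cell counts sum to %d but n_children is %d", sum(cells), n_children))
  }
  if (p_imp < 0 || p_imp > 1) stop("p_imp must lie in [0, 1]")
  center1_n <- sum(cells["nursery_school", , ])
  if (bilingual_n > center1_n) stop("bilingual_n exceeds the center-1 headcount")
  if (any(c(preterm_n, complication_n, family_history_n) > n_children)) {
    stop("label counts cannot exceed n_children")
  }
  if (preterm_n > complication_n) stop("preterm_n cannot exceed complication_n")
  structure(list(n_children = as.integer(n_children), cells = cells,
                 age_ranges = age_ranges, preterm_n = as.integer(preterm_n),
                 complication_n = as.integer(complication_n),
                 family_history_n = as.integer(family_history_n),
                 bilingual_n = as.integer(bilingual_n), p_imp = p_imp,
                 study_start = as.Date(study_start),
                 study_days = as.integer(study_days), seed = as.integer(seed)),
            class = "cohort_config")
}

# The study cohort's center x gender x age-band cell counts.
# Fill order per band: [c1 F, c2 F, c1 M, c2 M].
default_cohort_cells <- function() {
  array(c(10L, 5L, 8L, 3L,    # <=12
          22L, 22L, 24L, 34L, # 13-24
          31L, 9L, 39L, 11L), # 25-36
        dim = c(2L, 2L, 3L),
        dimnames = list(center = c("nursery_school", "psychopedagogical_center"),
                        gender = c("female", "male"),
                        band = c("<=12", "13-24", "25-36")))
}

# Proportional rescale of cell counts to a new total (largest remainder).
scale_cells <- function(cells, n) {
  raw <- as.numeric(cells) * n / sum(cells)
  f <- floor(raw)
  left <- n - sum(f)
  if (left > 0) {
    take <- order(raw - f, decreasing = TRUE)[seq_len(left)]
    f[take] <- f[take] + 1
  }
  out <- array(as.integer(f), dim = dim(cells), dimnames = dimnames(cells))
  out
}

#' Generate a synthetic child cohort
#'
#' Expands the configured cell counts into one [child_profile()]-shaped row
#' per child with an exact demographic composition, draws ages uniformly
#' within each band, assigns gestational weeks so that exactly the configured
#' number of children fall below 37 weeks, labels the configured numbers of
#' children with birth complications, family history and bilingual context,
#' draws a latent ability `theta ~ N(0, 1)` per child and an impairment
#' indicator `Bernoulli(p_imp)`, and derives a birth date from each child's
#' evaluation anchor date and age.
#'
#' @param config A [cohort_config()].
#' @return A data frame of class `child_cohort`, one row per child.
#' @export
#' @examples
#' cohort <- gen_cohort(cohort_config(seed = 1))
#' table(age_band(cohort$age_months))
gen_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_children == 0L) {
    return(structure(empty_cohort_df(), class = c("child_cohort", "data.frame")))
  }
  with_seed(config$seed, {
    dn <- dimnames(config$cells)
    rows <- list()
    for (ci in dn$center) for (gi in dn$gender) for (bi in seq_along(dn$band)) {
      k <- config$cells[ci, gi, bi]
      if (k > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          center = ci, gender = gi, band = dn$band[bi],
          age_months = sample(config$age_ranges[[bi]], k, replace = TRUE))
      }
    }
    df <- do.call(rbind, rows)
    n <- nrow(df)
    df <- df[sample.int(n), , drop = FALSE]
    df$child_id <- sprintf("c%04d", seq_len(n))
    df$theta <- stats::rnorm(n)
    df$impaired <- stats::runif(n) < config$p_imp
    # gestational age: exact preterm count below 37 weeks
    gw <- 37 + abs(stats::rnorm(n, 2.4, 1.1))
    gw <- pmin(gw, 42.5)
    preterm_idx <- if (config$preterm_n > 0) sample.int(n, config$preterm_n) else integer()
    gw[preterm_idx] <- stats::runif(length(preterm_idx), 31, 36.9)
    df$gestational_weeks <- round(gw, 1)
    comp <- rep("", n)
    comp[preterm_idx] <- "preterm"
    extra_n <- config$complication_n - config$preterm_n
    if (extra_n > 0) {
      others <- sample(setdiff(seq_len(n), preterm_idx), extra_n)
      comp[others] <- sample(c("prenatal", "perinatal"), extra_n, replace = TRUE)
    }
    df$birth_complications <- comp
    df$family_history_ndd <- FALSE
    if (config$family_history_n > 0) {
      df$family_history_ndd[sample.int(n, config$family_history_n)] <- TRUE
    }
    df$bilingual <- NA
    c1 <- which(df$center == "nursery_school")
    df$bilingual[c1] <- FALSE
    if (config$bilingual_n > 0) {
      df$bilingual[sample(c1, config$bilingual_n)] <- TRUE
    }
    df$anchor_date <- config$study_start +
      sample.int(config$study_days + 1L, n, replace = TRUE) - 1L
    df$birth_date <- month_add(df$anchor_date, -df$age_months) -
      sample.int(20L, n, replace = TRUE) + 1L
    rownames(df) <- NULL
    df <- df[, c("child_id", "center", "gender", "band", "age_months",
                 "birth_date", "anchor_date", "gestational_weeks",
                 "birth_complications", "family_history_ndd", "bilingual",
                 "theta", "impaired")]
    structure(df, class = c("child_cohort", "data.frame"))
  })
}

empty_cohort_df <- function() {
  data.frame(child_id = character(), center = character(), gender = character(),
             band = character(), age_months = integer(),
             birth_date = as.Date(character()), anchor_date = as.Date(character()),
             gestational_weeks = numeric(), birth_complications = character(),
             family_history_ndd = logical(), bilingual = logical(),
             theta = numeric(), impaired = logical())
}

#' Latent-ability answer model
#'
#' Answers in the simulator follow a logistic item-response-style rule:
#' the probability that child *i*, evaluated at age *t* months, passes
#' question *q* is
#' `plogis(intercept + slope * (t - m_q) + theta_i - shift * impaired_i)`,
#' where `m_q` is the first month the question applies to, `theta_i ~ N(0,1)`
#' is the child's latent ability and `shift` is the deficit applied to
#' children carrying the latent impairment label. The positive `slope` makes
#' attainment strictly increase with age, emulating age-graded milestone
#' acquisition with inter-individual variability. The `intercept` encodes
#' that screening milestones are chosen so that a typically developing child
#' has already attained them by the first month they are asked. Each answer
#' is independently replaced by "dk" with probability `dk_rate`.
#'
#' @param slope Positive age slope per month (default 5).
#' @param shift Positive ability deficit for impaired children (default 10).
#' @param intercept Baseline logit at the question's first applicable month
#'   for a child with `theta = 0` (default 6, i.e. ~99.8% attainment).
#' @param dk_rate Probability an answer is recorded as "dk" (default 0.05).
#' @return An object of class `ability_model`.
#' @export
ability_model <- function(slope = 5, shift = 10, intercept = 6, dk_rate = 0.05) {
  stopifnot(slope > 0, shift >= 0, dk_rate >= 0, dk_rate <= 1)
  structure(list(slope = slope, shift = shift, intercept = intercept,
                 dk_rate = dk_rate),
            class = "ability_model")
}

#' @rdname ability_model
#' @param model An `ability_model`.
#' @param delta_months Age minus the question's first applicable month.
#' @param theta Latent ability.
#' @param impaired Logical impairment indicator.
#' @return `p_yes()`: probability in (0, 1) of a "yes" answer (before "dk"
#'   masking).
#' @export
p_yes <- function(model, delta_months, theta, impaired) {
  stats::plogis(model$intercept + model$slope * delta_months + theta -
                  model$shift * as.numeric(impaired))
}

#' Default evaluator concordance model
#'
#' Per-suggestion-type probabilities that the evaluator declines the
#' suggestion, calibrated to the field study's acceptance table: referrals
#' were declined in 5 of 50 cases and 2-month repeats in 2 of 31; other
#' suggestions were always accepted.
#'
#' @return Named numeric vector of decline probabilities, one per
#'   [suggestion_types()].
#' @export
default_accept_model <- function() {
  c(typical_development = 0, repeat_3mo = 0, repeat_2mo = 2 / 31,
    repeat_1mo = 0, refer_early_intervention = 5 / 50)
}

#' Simulate a screening study
#'
#' Runs the full screening pipeline over a synthetic cohort: each child is
#' assessed at their anchor date with the questions [select_questions()]
#' chooses, answers are drawn from the [ability_model()], the suggestion is
#' derived with [decide()], and evaluator acceptance is drawn from the
#' decline probabilities in `accept_model`. A repeat suggestion triggers a
#' follow-up session after the suggested interval when the child is still
#' within coverage and the per-child session cap (default 2, echoing the
#' field study's mean of 1.24 assessments per child) has not been reached;
#' failed questions are re-asked per the selection rule.
#'
#' @param kb A [knowledge_base()].
#' @param cohort A [gen_cohort()] data frame; all children must be within
#'   coverage at their anchor date.
#' @param ability An [ability_model()].
#' @param policy A [decision_policy()].
#' @param accept_model Named decline probabilities per suggestion type (see
#'   [default_accept_model()]); use `accept_always()` for perfect
#'   concordance.
#' @param max_sessions Per-child session cap.
#' @param seed Integer RNG seed for answers and acceptance draws.
#' @return An [evaluation_records()] object.
#' @export
simulate_study <- function(kb, cohort, ability = ability_model(),
                           policy = decision_policy(),
                           accept_model = default_accept_model(),
                           max_sessions = 2L, seed = 1L) {
  stopifnot(inherits(kb, "knowledge_base"), is.data.frame(cohort))
  miss <- setdiff(suggestion_types(), names(accept_model))
  if (length(miss)) stop("accept_model lacks decline probabilities for: ",
                         paste(miss, collapse = ", "))
  cov <- kb$coverage_range
  if (nrow(cohort) > 0 &&
      (min(cohort$age_months) < cov[1] || max(cohort$age_months) > cov[2])) {
    stop("cohort contains children outside the knowledge base's coverage range")
  }
  qids <- names(kb$questions)
  m_q <- vapply(kb$questions, function(q) min(q$applicable_months), 1L)
  sev <- vapply(kb$questions, `[[`, "", "severity_class")
  dom <- vapply(kb$questions, `[[`, "", "domain")
  decline_reason_text <- "The questions do not align with the child's developmental stage."
  with_seed(seed, {
    srows <- vector("list", nrow(cohort) * max_sessions)
    arows <- vector("list", nrow(cohort) * max_sessions)
    nrec <- 0L
    for (i in seq_len(nrow(cohort))) {
      ch <- cohort[i, ]
      child <- child_profile(ch$child_id, ch$birth_date, ch$gender, ch$center,
                             gestational_weeks = ch$gestational_weeks)
      ev <- ch$anchor_date
      history <- list()
      for (s in seq_len(max_sessions)) {
        t <- age_in_months(ch$birth_date, ev)
        if (t < cov[1] || t > cov[2]) break
        ses <- screening_session(child, kb, ev, history)
        idx <- match(ses$asked, qids)
        p <- p_yes(ability, t - m_q[idx], ch$theta, ch$impaired)
        ans <- ifelse(stats::runif(length(p)) < p, "yes", "no")
        ans[stats::runif(length(p)) < ability$dk_rate] <- "dk"
        names(ans) <- ses$asked
        ses <- answer_session(ses, ans)
        res <- decide(kb, ses, policy)
        ses <- set_suggestion(ses, res)
        declined <- stats::runif(1) < accept_model[[res$type]]
        ses <- record_evaluator_response(ses, !declined,
                                         if (declined) decline_reason_text)
        nrec <- nrec + 1L
        srows[[nrec]] <- data.frame(
          child_id = ch$child_id, center = ch$center, gender = ch$gender,
          birth_date = ch$birth_date, evaluation_date = ev, age_months = t,
          suggestion = res$type, severity_class = res$severity_class,
          accepted = !declined,
          decline_reason = if (declined) decline_reason_text else NA_character_,
          n_questions = length(ses$asked),
          n_failed = length(res$triggered_by),
          low_information = res$low_information)
        arows[[nrec]] <- data.frame(
          child_id = ch$child_id, evaluation_date = ev, age_months = t,
          question_id = ses$asked, domain = dom[idx],
          severity_class = sev[idx], answer = unname(ans))
        history <- c(history, list(ses))
        k <- follow_up_months(res$type)
        if (is.na(k)) break
        ev2 <- month_add(ev, k)
        if (age_in_months(ch$birth_date, ev2) > cov[2]) break
        ev <- ev2
      }
    }
    evaluation_records(do.call(rbind, srows[seq_len(nrec)]),
                       do.call(rbind, arows[seq_len(nrec)]),
                       metadata = list(seed = seed, source = "simulate_study"))
  })
}

#' @rdname default_accept_model
#' @return `accept_always()`: decline probabilities of zero for every type.
#' @export
accept_always <- function() {
  stats::setNames(rep(0, 5), suggestion_types())
}
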