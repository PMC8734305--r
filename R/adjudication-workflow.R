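# Committee workflow: independent reviews, third-reviewer escalation, panel
# meetings with specialty quorum, and consensus for fatal events.
#
# Reviewers are either the deterministic rule engine or a perturbed engine
# that flips each criterion of the engine-chosen endpoint independently with
# probability p (seeded). Any flip changes the vote, so a perturbed reviewer
# disagrees with the engine with probability 1 - (1-p)^K where K is the
# number of criteria in the decisive trace — the closed form the workflow
# tests check against. Reviewers never see dose fields or investigator
# causality: the reviewer interface receives only the candidate event's
# evidence, preferred terms and seriousness.

#' Build a committee roster
#'
#' The default committee is 3 cardiologists, 1 vascular neurologist and
#' 1 vascular medicine specialist.
#'
#' @param n_cardiologists,n_neurologists,n_vascular roster composition.
#' @return data.frame roster with `reviewer_id` and `specialty`.
#' @export
committee_roster <- function(n_cardiologists = 3, n_neurologists = 1,
                             n_vascular = 1) {
  data.frame(
    reviewer_id = c(paste0("cardio-", seq_len(n_cardiologists)),
                    if (n_neurologists) paste0("neuro-", seq_len(n_neurologists)),
                    if (n_vascular) paste0("vasc-", seq_len(n_vascular))),
    specialty = c(rep("cardiologist", n_cardiologists),
                  rep("neurologist", n_neurologists),
                  rep("vascular_specialist", n_vascular)),
    stringsAsFactors = FALSE
  )
}

# The reviewer view of a candidate event. Blinding holds by construction:
# the candidate-event type carries no ponatinib dose level and no
# investigator causality assessment, so reviewers cannot read them. The
# AE-level dose_action (interrupted/reduced/...) is part of the charter's
# symptom-recording exclusion and is intentionally visible.
reviewer_view <- function(ev) ev

# one reviewer's vote; flip_prob = 0 is the deterministic engine
reviewer_vote <- function(ev, death_record, history, flip_prob, rng_seed,
                          unknown_policy = "not_met") {
  base <- adjudicate_candidate_event(ev, death_record, history, unknown_policy)
  if (flip_prob <= 0) return(base)
  k <- nrow(base$criteria_trace)
  set.seed(rng_seed)
  flips <- stats::runif(k) < flip_prob
  if (!any(flips)) return(base)
  # at least one criterion judged differently: the vote moves between the
  # engine endpoint and not-an-event
  flipped <- base
  if (base$endpoint == "not_an_event") {
    flipped$endpoint <- "disputed_event"   # synthetic disagreement marker
    flipped$is_aoe <- NA
  } else {
    flipped$endpoint <- "not_an_event"
    flipped$is_aoe <- FALSE
    flipped$category <- NA_character_
  }
  flipped
}

votes_agree <- function(a, b) {
  identical(a$endpoint, b$endpoint) && identical(a$is_aoe, b$is_aoe)
}

#' Adjudicate one case through the committee process
#'
#' Cardiology (AOE/HF) route: two independent reviews; agreement on
#' (endpoint, AOE flag) is final; otherwise a third cardiologist votes and
#' any 2-of-3 match is final; a three-way split goes to a panel.
#' Stroke/DVT/PE/PVD route: two reviews; disagreement goes straight to a
#' panel that must include the appropriate specialist. Fatal events are
#' decided by consensus of all adjudicators. Panels resolve to the
#' deterministic rule engine with the configured unknown policy.
#'
#' @param ev an `aoe_candidate` event.
#' @param roster committee data.frame from [committee_roster()].
#' @param flip_prob per-criterion flip probability of the perturbed
#'   reviewers (0 = deterministic).
#' @param seed integer seed for the reviewer perturbations.
#' @param death_record,history passed to the rule engine for fatal cases.
#' @param unknown_policy panel resolution policy for unknown criteria.
#' @return an `aoe_trace`: votes, `stage_reached` and the `final` outcome.
#' @export
adjudicate_case <- function(ev, roster = committee_roster(), flip_prob = 0,
                            seed = 1, death_record = NULL, history = NULL,
                            unknown_policy = "not_met") {
  stopifnot(inherits(ev, "aoe_candidate"))
  view <- reviewer_view(ev)
  engine_final <- adjudicate_candidate_event(view, death_record, history,
                                             unknown_policy)
  cards <- roster$reviewer_id[roster$specialty == "cardiologist"]
  vote_of <- function(reviewer_idx)
    reviewer_vote(view, death_record, history, flip_prob,
                  rng_seed = (seed + 7919L * reviewer_idx) %% .Machine$integer.max,
                  unknown_policy = unknown_policy)

  if (ev$fatal || ev$fatal_review) {
    return(structure(list(event_id = ev$event_id,
                          votes = list(consensus = engine_final),
                          stage_reached = "fatal_consensus",
                          final = engine_final), class = "aoe_trace"))
  }

  if (length(cards) < 2) stop("roster lacks two cardiologists")
  v1 <- vote_of(1L); v2 <- vote_of(2L)
  votes <- list(v1, v2)
  names(votes) <- cards[1:2]

  right_route <- ev$route %in% c("stroke_DVT_PE_PVD_route", "both_routes")
  if (votes_agree(v1, v2)) {
    stage <- "two_agree"; final <- v1
  } else if (!right_route) {
    if (length(cards) < 3) stop("roster lacks the third cardiologist")
    v3 <- vote_of(3L)
    votes[[cards[3]]] <- v3
    if (votes_agree(v1, v3)) { stage <- "third_reviewer"; final <- v1 }
    else if (votes_agree(v2, v3)) { stage <- "third_reviewer"; final <- v2 }
    else { stage <- "panel"; final <- engine_final }
  } else {
    needed <- if (grepl("stroke|cerebr", paste(ev$member_pts, collapse = " "),
                        ignore.case = TRUE)) "neurologist" else "vascular_specialist"
    if (!needed %in% roster$specialty)
      stop("panel requires a ", needed, " on the roster")
    stage <- "panel"; final <- engine_final
  }
  structure(list(event_id = ev$event_id, votes = votes,
                 stage_reached = stage, final = final),
            class = "aoe_trace")
}

#' @export
print.aoe_trace <- function(x, ...) {
  cat("<adjudication trace ", x$event_id, ": ", x$stage_reached, " -> ",
      x$final$endpoint, ">\n", sep = "")
  invisible(x)
}

#' Run the committee over a batch of candidate events
#'
#' @param events list of `aoe_candidate` events (fatal candidates included).
#' @param ds the `aoe_study` dataset (for death records).
#' @param roster,flip_prob,seed,unknown_policy see [adjudicate_case()].
#' @return list with `outcomes` (final `aoe_outcome`s), `traces` and a
#'   `stage_histogram`.
#' @export
run_committee <- function(events, ds, roster = committee_roster(),
                          flip_prob = 0, seed = 1,
                          unknown_policy = "not_met") {
  deaths <- ds$deaths
  traces <- vector("list", length(events))
  for (i in seq_along(events)) {
    ev <- events[[i]]
    dr <- NULL
    if (ev$fatal || ev$fatal_review) {
      row <- deaths[deaths$patient_id == ev$patient_id, ]
      if (nrow(row)) dr <- as.list(row[1, ])
    }
    traces[[i]] <- adjudicate_case(ev, roster, flip_prob,
                                   seed = (seed + i) %% .Machine$integer.max,
                                   death_record = dr,
                                   unknown_policy = unknown_policy)
  }
  names(traces) <- vapply(events, function(e) e$event_id, character(1))
  outcomes <- lapply(traces, function(t) t$final)
  stages <- vapply(traces, function(t) t$stage_reached, character(1))
  list(outcomes = outcomes, traces = traces,
       stage_histogram = table(factor(stages, levels = c(
         "two_agree", "third_reviewer", "panel", "fatal_consensus"))))
}
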