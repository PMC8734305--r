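# 48-hour clustering of a patient's screened records into candidate clinical
# events. Records are chained transitively (single linkage): two records fall
# in the same cluster iff they are connected by pairwise onset gaps of at
# most `window_hours`. The charter treats such a run of records as one
# clinical event evolving over time.

onset_hours_of <- function(ae) {
  h <- ae$onset_hour
  if (is.null(h) || length(h) == 0 || is.na(h)) h <- NA_real_
  d <- ae$onset_day
  if (is.null(d) || length(d) == 0 || is.na(d)) return(NA_real_)
  (d - 1) * 24 + ifelse(is.na(h), 0, h)
}

# gap in hours between two records; date-only records compare at day
# granularity: <= 2 calendar days apart counts as within a 48 h window.
record_gap_hours <- function(ae1, ae2) {
  h1 <- ae1$onset_hour; h2 <- ae2$onset_hour
  date_only <- is.null(h1) || is.na(h1) || is.null(h2) || is.na(h2)
  if (date_only) {
    abs(ae1$onset_day - ae2$onset_day) * 24
  } else {
    abs(onset_hours_of(ae1) - onset_hours_of(ae2))
  }
}

#' Group case packages into candidate events
#'
#' Partitions each patient's case packages into clusters using transitive
#' chaining of the pairwise gap rule: records whose onsets are within
#' `window_hours` of each other (directly or through intermediate records)
#' form one candidate event. Output is independent of input order. A record
#' without an onset becomes a singleton cluster with a warning.
#'
#' @param packages list of case packages from [assemble_case_packages()].
#' @param window_hours clustering window; the charter value is 48.
#' @return list of candidate events (class `aoe_candidate`), each with
#'   `event_id`, `patient_id`, ordered `member_record_ids`, window bounds,
#'   `serious`/`fatal` flags (OR over members), pooled `merged_evidence`,
#'   member preferred terms and the panel `route`.
#' @export
group_into_candidate_events <- function(packages, window_hours = 48) {
  stopifnot(window_hours > 0)
  if (!length(packages)) return(list())
  pid <- vapply(packages, function(p) p$patient_id, character(1))
  events <- list()
  for (patient in sort(unique(pid))) {
    pks <- packages[pid == patient]
    onset <- vapply(pks, function(p) onset_hours_of(p$ae), numeric(1))
    if (anyNA(onset)) {
      warning("record(s) without onset become singleton clusters: ",
              paste(names(pks)[is.na(onset)], collapse = ", "))
    }
    ord <- order(onset, names(pks), na.last = TRUE)
    pks <- pks[ord]
    onset <- onset[ord]
    n <- length(pks)
    # union-find over the pairwise gap graph; records without an onset stay
    # singletons. A record pair mixing hour-level and date-only onsets is
    # compared at date granularity, so clusters are the connected components
    # of the full graph, not of a sorted chain.
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L)) {
      if (is.na(onset[i])) next
      for (j in (i + 1L):n) {
        if (is.na(onset[j])) next
        if (record_gap_hours(pks[[i]]$ae, pks[[j]]$ae) <= window_hours) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (cl in unique(comp)) {
      members <- pks[comp == cl]
      events[[length(events) + 1]] <- build_candidate_event(patient, members)
    }
  }
  names(events) <- vapply(events, function(e) e$event_id, character(1))
  events
}

build_candidate_event <- function(patient, members) {
  ids <- vapply(members, function(p) p$record_id, character(1))
  pts <- vapply(members, function(p) p$ae$preferred_term, character(1))
  days <- vapply(members, function(p) p$ae$onset_day, numeric(1))
  serious <- any(vapply(members, function(p) isTRUE(p$ae$serious), logical(1)))
  fatal <- any(vapply(members, function(p) isTRUE(p$ae$fatal), logical(1)))
  fatal_review <- any(vapply(members, function(p) isTRUE(p$fatal_review), logical(1)))
  anat <- vapply(members, function(p) {
    v <- p$ae$anatomic_diagnosis
    if (is.null(v) || is.na(v)) "" else as.character(v)
  }, character(1))
  structure(list(
    event_id = paste0("EV-", patient, "-", min(days, na.rm = TRUE), "-",
                      substr(ids[[1]], 1, 24)),
    patient_id = patient,
    member_record_ids = ids,
    member_pts = pts,
    member_grades = vapply(members, function(p) as.numeric(p$ae$severity_grade), numeric(1)),
    member_dose_actions = vapply(members, function(p) {
      v <- p$ae$dose_action
      if (is.null(v) || is.na(v)) NA_character_ else as.character(v)
    }, character(1)),
    member_resolved = vapply(members, function(p) isTRUE(p$ae$resolved), logical(1)),
    anatomic_diagnoses = anat[nzchar(anat)],
    onset_day = min(days, na.rm = TRUE),
    window_start_day = min(days, na.rm = TRUE),
    window_end_day = max(days, na.rm = TRUE),
    serious = serious,
    fatal = fatal,
    fatal_review = fatal_review,
    merged_evidence = merge_evidence(lapply(members, function(p) p$evidence)),
    route = route_for_terms(pts)
  ), class = "aoe_candidate")
}

#' @export
print.aoe_candidate <- function(x, ...) {
  cat("<candidate event ", x$event_id, ": ", length(x$member_record_ids),
      " record(s), route ", x$route, if (x$fatal) ", FATAL", ">\n", sep = "")
  invisible(x)
}

# Fig-1B style panel routing from member preferred terms: stroke / TIA / DVT /
# PE / PVD-suggestive terms go to the neurology-vascular panel, everything
# else to the cardiology (AOE/HF) panel; a cluster with both kinds is run on
# both routes and reconciled by the workflow.
RIGHT_ROUTE_PATTERNS <- c(
  "stroke", "cerebr", "cerebell", "carotid", "transient isch", "lacunar",
  "intracranial", "brain", "hemiplegia", "hemiparesis", "aphasia",
  "amaurosis", "retinal", "deep vein", "vein thrombosis", "venous thrombosis",
  "pulmonary embolism", "thrombophlebitis", "peripheral arterial",
  "peripheral artery", "peripheral vascular", "peripheral isch",
  "claudication", "mesenteric", "iliac", "femoral", "subclavian artery",
  "basilar", "gangrene", "embolism venous"
)

route_for_terms <- function(pts) {
  n <- normalize_pt(pts)
  right <- vapply(n, function(t) any(vapply(RIGHT_ROUTE_PATTERNS, grepl, logical(1), x = t, fixed = TRUE)), logical(1))
  if (all(right)) "stroke_DVT_PE_PVD_route"
  else if (any(right)) "both_routes"
  else "AOE_HF_route"
}

#' Pool the evidence packages of a cluster's member records
#'
#' Set fields are unioned; numeric fields take the extreme favouring
#' criterion satisfaction (max); known values beat unknown; an explicit
#' absent beats unknown. Contradictory booleans (TRUE vs explicit FALSE)
#' keep TRUE and log the conflict.
#'
#' @param members list of `aoe_evidence` packages (length >= 1).
#' @return a single merged `aoe_evidence` package.
#' @export
merge_evidence <- function(members) {
  stopifnot(length(members) >= 1)
  out <- list()
  conflicts <- character()
  for (ev in members) {
    for (f in names(ev)) {
      ty <- EVIDENCE_FIELDS[[f]]
      new <- ev[[f]]
      old <- out[[f]]
      if (is.null(old)) { out[[f]] <- new; next }
      out[[f]] <- switch(ty,
        set = union(old, new),
        num = max(old, new, na.rm = TRUE),
        bool = {
          if (!is.na(old) && !is.na(new) && old != new)
            conflicts <- c(conflicts, f)
          isTRUE(old) || isTRUE(new)
        },
        enum = if (!is.na(old)) old else new,
        list = if (length(old)) old else new
      )
    }
  }
  if (length(conflicts))
    message("merge_evidence: contradictory booleans kept TRUE: ",
            paste(unique(conflicts), collapse = ", "))
  do.call(evidence_package, out)
}
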