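# Preferred-term screening: identify candidate AOE records by exact matching
# of normalized MedDRA preferred terms against the packaged 604-term list
# (plus a heart-failure term set standing in for the Cardiac Failure SMQ),
# and pull in investigator-unattributed deaths for fatal review.

#' Load a preferred-term list
#'
#' One term per line; blank lines and `#` comments are ignored. Terms are
#' normalized (case-folded, whitespace-collapsed, straight apostrophes) on
#' load. Duplicates after normalization raise a warning listing the
#' collisions; an empty file is a hard failure.
#'
#' @param path path to the term-list file.
#' @param name optional list name (defaults to the file name).
#' @param source_version label of the dictionary release the terms came from.
#' @return an object of class `aoe_term_list`.
#' @export
#' @examples
#' tl <- load_term_list(aoe_term_file("aoe_terms_604.txt"))
#' length(tl$terms)
load_term_list <- function(path, name = basename(path),
                           source_version = "MedDRA 21.0") {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("term list is empty: ", path)
  norm <- normalize_pt(lines)
  if (anyDuplicated(norm)) {
    dups <- unique(norm[duplicated(norm)])
    warning("duplicate terms after normalization: ", paste(dups, collapse = ", "))
    norm <- unique(norm)
  }
  message(sprintf("term list '%s': %d terms", name, length(norm)))
  structure(list(name = name, terms = norm, source_version = source_version),
            class = "aoe_term_list")
}

#' @export
print.aoe_term_list <- function(x, ...) {
  cat("<term list '", x$name, "': ", length(x$terms), " terms (",
      x$source_version, ")>\n", sep = "")
  invisible(x)
}

#' Path to a packaged term list
#' @param file file name under the package's `extdata` directory.
#' @export
aoe_term_file <- function(file) {
  p <- system.file("extdata", file, package = "aoe")
  if (!nzchar(p)) stop("no packaged file ", file)
  p
}

#' Screen adverse events against the AOE term lists
#'
#' A record is flagged iff its normalized preferred term is in the union of
#' the AOE list and the cardiac-failure list. The screen is a pure,
#' idempotent filter over records; it reads nothing but the preferred term.
#'
#' @param ds an `aoe_study` dataset.
#' @param aoe_terms,cardiac_failure_terms `aoe_term_list` objects; defaults
#'   are the packaged lists.
#' @return an object of class `aoe_screen` with `flagged_records`,
#'   `flagged_patients`, `fatal_review_records` and per-stage `totals`.
#' @export
screen_adverse_events <- function(ds,
                                  aoe_terms = load_term_list(aoe_term_file("aoe_terms_604.txt")),
                                  cardiac_failure_terms = load_term_list(aoe_term_file("cardiac_failure_terms.txt"))) {
  stopifnot(inherits(ds, "aoe_study"))
  terms <- union(aoe_terms$terms, cardiac_failure_terms$terms)
  a <- ds$adverse_events
  hit <- normalize_pt(a$preferred_term) %in% terms
  flagged_records <- a$record_id[hit]
  flagged_patients <- unique(a$patient_id[hit])
  fatal_review <- screen_deaths(ds)
  res <- structure(list(
    flagged_records = flagged_records,
    flagged_patients = flagged_patients,
    fatal_review_records = fatal_review,
    totals = c(records_screened = nrow(a),
               records_flagged = length(flagged_records),
               patients_flagged = length(flagged_patients),
               fatal_review = length(fatal_review))
  ), class = "aoe_screen")
  message(sprintf("screen: %d/%d records flagged across %d patients; %d fatal review",
                  length(flagged_records), nrow(a), length(flagged_patients),
                  length(fatal_review)))
  res
}

#' @export
print.aoe_screen <- function(x, ...) {
  cat("<AOE screen>\n")
  print(x$totals)
  invisible(x)
}

#' Deaths qualifying for fatal review
#'
#' Returns the fatal AE record ids of all deaths the investigator did not
#' attribute to disease progression; those go to the committee chair for
#' consensus review regardless of preferred term.
#'
#' @param ds an `aoe_study` dataset.
#' @return character vector of record ids.
#' @export
screen_deaths <- function(ds) {
  d <- ds$deaths
  if (!nrow(d)) return(character())
  d$record_id[!d$progression_attributed]
}

#' Assemble per-record case packages for adjudication
#'
#' One package per flagged or fatal-review record, deduplicated by record id
#' (a fatal record whose preferred term is itself in-list is packaged once).
#' A flagged record without an evidence object gets an all-unknown package
#' and a warning, mirroring retrospective databases where no further source
#' material exists.
#'
#' @param screen an `aoe_screen` result.
#' @param ds the `aoe_study` dataset the screen came from.
#' @return list of case packages, each with the AE row, patient row,
#'   evidence and a `fatal_review` flag.
#' @export
assemble_case_packages <- function(screen, ds) {
  stopifnot(inherits(screen, "aoe_screen"), inherits(ds, "aoe_study"))
  ids <- union(screen$flagged_records, screen$fatal_review_records)
  a <- ds$adverse_events
  idx <- match(ids, a$record_id)
  if (anyNA(idx))
    stop("fatal-review record(s) missing from adverse_events: ",
         paste(ids[is.na(idx)], collapse = ", "))
  missing_ev <- character()
  pkgs <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    rid <- ids[[k]]
    row <- a[idx[[k]], ]
    ev <- ds$evidence[[rid]]
    if (is.null(ev)) {
      missing_ev <- c(missing_ev, rid)
      ev <- evidence_package()
    }
    pkgs[[k]] <- list(
      record_id = rid,
      patient_id = row$patient_id,
      ae = as.list(row),
      evidence = ev,
      fatal_review = rid %in% screen$fatal_review_records
    )
  }
  names(pkgs) <- ids
  if (length(missing_ev))
    warning(length(missing_ev), " case package(s) assembled with all-unknown evidence")
  message(sprintf("assembled %d case packages (%d flagged + %d fatal, %d overlap)",
                  length(pkgs), length(screen$flagged_records),
                  length(screen$fatal_review_records),
                  length(intersect(screen$flagged_records,
                                   screen$fatal_review_records))))
  pkgs
}
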