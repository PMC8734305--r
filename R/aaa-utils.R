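# Shared helpers: preferred-term normalization, tri-state (Kleene) logic for
# criterion evaluation, rounding and time-unit conventions.

DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

#' Normalize a MedDRA preferred term for exact matching
#'
#' Case-folds, collapses internal whitespace, and maps typographic (curly)
#' apostrophes to straight ones. Matching against term lists is exact on the
#' normalized string: no substring or fuzzy matching, since preferred terms
#' are a controlled vocabulary.
#'
#' @param x character vector of preferred terms.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_pt("Raynaud’s  Phenomenon")
normalize_pt <- function(x) {
  x <- gsub("[’‘]", "'", x)
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

#' Round half away from zero
#'
#' The reporting convention for printed percentages: 2.5 rounds to 3,
#' -2.5 to -3. R's `round()` rounds half to even and would disagree.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @rdname round_half_away
#' @param num,den numerator and denominator counts.
#' @export
percent_of <- function(num, den) {
  if (any(den == 0)) stop("percent_of(): zero denominator")
  round_half_away(100 * num / den)
}

days_to_months <- function(days) days / DAYS_PER_MONTH
days_to_years <- function(days) days / DAYS_PER_YEAR

# ---- tri-state criterion logic ----------------------------------------------
# Criterion statuses are "met", "not_met" or "unknown" (Kleene strong logic).
# Evidence fields are tri-state: a value is known; an explicit FALSE / empty
# set is known-absent; a missing field or NA is unknown.

ST_MET <- "met"
ST_NOT <- "not_met"
ST_UNK <- "unknown"

st_and <- function(...) {
  s <- unlist(list(...), use.names = FALSE)
  if (any(s == ST_NOT)) ST_NOT else if (any(s == ST_UNK)) ST_UNK else ST_MET
}

st_or <- function(...) {
  s <- unlist(list(...), use.names = FALSE)
  if (any(s == ST_MET)) ST_MET else if (any(s == ST_UNK)) ST_UNK else ST_NOT
}

st_not <- function(s) {
  switch(s, met = ST_NOT, not_met = ST_MET, unknown = ST_UNK)
}

# logical field -> status
st_bool <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) ST_UNK
  else if (isTRUE(x)) ST_MET else ST_NOT
}

# numeric comparison; unknown value -> unknown
st_gt <- function(x, cut, strict = TRUE) {
  if (is.null(x) || length(x) == 0 || is.na(x)) return(ST_UNK)
  ok <- if (strict) x > cut else x >= cut
  if (ok) ST_MET else ST_NOT
}

# set membership: NULL set is unknown, empty set is known-absent
st_has <- function(set, items) {
  if (is.null(set)) return(ST_UNK)
  if (any(items %in% set)) ST_MET else ST_NOT
}

st_resolve <- function(status, unknown_policy = c("not_met", "met")) {
  unknown_policy <- match.arg(unknown_policy)
  ifelse(status == ST_UNK, unknown_policy, status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
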